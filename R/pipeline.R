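#' Pipeline configuration
#'
#' Defaults follow standard screening practice: k = 21 with 10% systematic
#' subsampling for contamination screening, k = 31 for spectra, minimum
#' clipped length 25.
#'
#' @param k_screen screening k-mer size.
#' @param k_spectra spectrum k-mer size.
#' @param subsample_fraction screening subsample fraction.
#' @param min_length minimum clipped mate length.
#' @param thresholds named list of red-flag minima (see [summarizeRun()]).
#' @param store_path metric-store file ("" disables storage).
#' @param spectra run the k-mer spectra stage.
#' @param seed seed for any randomized step.
#' @return Named list of configuration values.
#' @export
pipelineConfig <- function(k_screen = 21L, k_spectra = 31L,
                           subsample_fraction = 0.10, min_length = 25L,
                           thresholds = list(), store_path = "",
                           spectra = FALSE, seed = 1L) {
    list(k_screen = as.integer(k_screen), k_spectra = as.integer(k_spectra),
         subsample_fraction = as.numeric(subsample_fraction),
         min_length = as.integer(min_length), thresholds = thresholds,
         store_path = store_path, spectra = isTRUE(spectra),
         seed = as.integer(seed))
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; keys mirror [pipelineConfig()] arguments and
#' missing keys take the defaults. CLI flags override config values.
#'
#' @param path YAML file.
#' @return Configuration list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, vals)
}

.log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg))
}

#' Run the primary analysis pipeline over one run
#'
#' Chains the analytic stages over one (optionally paired) FASTQ run:
#' read metrics, contamination screening against each reference, optional
#' k-mer spectra, and an MD5 manifest of inputs and reports; all metrics
#' are loaded into the metric store when one is configured. Reports are
#' deterministic (no timestamps), so reruns on identical inputs are
#' byte-identical. Red flags are reported but do not change the exit
#' status; a stage error does.
#'
#' @param r1_path FASTQ path (read 1).
#' @param r2_path optional FASTQ path (read 2).
#' @param references named character vector of reference FASTA or k-mer
#'   table (`.tsv` from [saveKmerTable()]) paths to screen against.
#' @param output_dir directory for reports.
#' @param config a [pipelineConfig()].
#' @param run_alias run identifier used in the metric store.
#' @return list with `status` (0 ok, 2 a stage failed), `failed_stage`
#'   (NA when ok), `reports` (named paths) and `summary` objects.
#' @export
runPipeline <- function(r1_path, r2_path = NULL, references = character(),
                        output_dir, config = pipelineConfig(),
                        run_alias = "run") {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    reports <- character(0)
    objects <- list()
    failed <- NA_character_
    store <- if (nzchar(config$store_path)) metricStore(config$store_path)
             else NULL
    key <- runKey(run_alias, sample = basename(r1_path))
    stage <- function(name, expr) {
        if (!is.na(failed)) return(invisible(NULL))
        .log_stage(name, "start")
        res <- tryCatch(expr, error = function(e) {
            .log_stage(name, paste("ERROR:", conditionMessage(e)))
            failed <<- name
            NULL
        })
        if (is.na(failed)) .log_stage(name, "done")
        res
    }

    reads <- stage("read", {
        r1 <- readFastq(r1_path)
        r2 <- if (!is.null(r2_path)) readFastq(r2_path) else NULL
        if (is.null(r2)) r1
        else new("ReadSet", id = c(r1@id, r2@id),
                 sequence = c(r1@sequence, r2@sequence),
                 quality = c(r1@quality, r2@quality))
    })

    stage("metrics", {
        summary <- summarizeRun(reads, thresholds = config$thresholds)
        p <- file.path(output_dir, "run_summary.json")
        writeReport(summary, p)
        reports["run_summary"] <- p
        objects$run_summary <- summary
        pbq <- perBaseQuality(reads)
        p2 <- file.path(output_dir, "per_base_quality.tsv")
        write.table(pbq@stats, p2, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        reports["per_base_quality"] <- p2
        objects$per_base_quality <- pbq
        if (!is.null(store)) {
            putMetrics(store, parseToolkitReport(summary, key))
            putMetrics(store, parseToolkitReport(pbq, key))
        }
        if (nrow(summary@flags))
            .log_stage("metrics",
                       paste("red flags:",
                             paste(summary@flags$metric, collapse = ", ")))
    })

    stage("screen", {
        sub <- subsampleSpec(config$subsample_fraction, seed = config$seed)
        for (ref in names(references)) {
            path <- references[[ref]]
            if (!file.exists(path)) stop("missing reference: ", path)
            tab <- if (grepl("\\.(tsv|tab|kmt)(\\.gz)?$", path))
                loadKmerTable(path, k = config$k_screen)
            else buildReferenceTable(path, k = config$k_screen)
            rep_ <- screenReads(reads, tab, subsample = sub,
                                reference_name = ref)
            p <- file.path(output_dir, sprintf("screen_%s.json", ref))
            writeReport(rep_, p)
            reports[paste0("screen_", ref)] <- p
            objects[[paste0("screen_", ref)]] <- rep_
            if (!is.null(store))
                putMetrics(store, parseToolkitReport(rep_, key))
        }
    })

    if (config$spectra) stage("spectra", {
        r1 <- readFastq(r1_path)
        r2 <- if (!is.null(r2_path)) readFastq(r2_path) else NULL
        ss <- computeSpectra(r1, r2, k = config$k_spectra)
        p <- file.path(output_dir, "spectra_overlay.tsv")
        exportOverlay(ss, p)
        reports["spectra_overlay"] <- p
        ana <- analyzeSpectrum(ss@combined)
        p2 <- file.path(output_dir, "spectra_analysis.json")
        writeReport(ana, p2)
        reports["spectra_analysis"] <- p2
        objects$spectra <- ana
        if (!is.null(store))
            putMetrics(store, parseToolkitReport(ana, key))
    })

    stage("manifest", {
        files <- c(r1_path, r2_path, unname(reports))
        p <- file.path(output_dir, "manifest.md5")
        md5Manifest(files, out = p, labels = basename(files))
        reports["manifest"] <- p
    })

    list(status = if (is.na(failed)) 0L else 2L, failed_stage = failed,
         reports = reports, summary = objects)
}
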