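.store_columns <- c("run_alias", "instrument", "chemistry_version",
                    "software_version", "lane", "sample", "barcode",
                    "metric", "scope", "position_from", "position_to",
                    "value_num", "value_text")

.empty_records <- function() {
    data.frame(run_alias = character(), instrument = character(),
               chemistry_version = character(), software_version = character(),
               lane = integer(), sample = character(), barcode = character(),
               metric = character(), scope = character(),
               position_from = integer(), position_to = integer(),
               value_num = numeric(), value_text = character(),
               stringsAsFactors = FALSE)
}

#' Run key: metadata identifying one sequencing run/sample
#'
#' The store keys every metric by run alias, instrument, chemistry and
#' software versions, lane, sample and barcode; `(run_alias, lane, sample,
#' barcode)` identifies a record source uniquely.
#'
#' @param run_alias run identifier.
#' @param instrument,chemistry_version,software_version free-text metadata.
#' @param lane lane number or `NA`.
#' @param sample sample name.
#' @param barcode barcode or `NA`.
#' @return A named list usable as `key` in record builders.
#' @export
runKey <- function(run_alias, instrument = "", chemistry_version = "",
                   software_version = "", lane = NA_integer_, sample = "",
                   barcode = NA_character_) {
    list(run_alias = run_alias, instrument = instrument,
         chemistry_version = chemistry_version,
         software_version = software_version, lane = as.integer(lane),
         sample = sample, barcode = barcode)
}

#' Build metric records
#'
#' One record is a named QC value scoped to a whole run (`scope = "run"`,
#' no positions), one base position (`scope = "base"`,
#' `position_from == position_to`) or an inclusive 1-based base range
#' (`scope = "range"`).
#'
#' @param key a [runKey()].
#' @param metric metric name(s).
#' @param value numeric or character value(s).
#' @param scope "run", "base" or "range" (recycled).
#' @param position_from,position_to 1-based inclusive positions (`NA` for
#'   run scope; `position_to` defaults to `position_from` for base scope).
#' @return records data.frame for [putMetrics()].
#' @export
metricRecords <- function(key, metric, value, scope = "run",
                          position_from = NA_integer_,
                          position_to = position_from) {
    n <- max(length(metric), length(value), length(scope),
             length(position_from))
    df <- data.frame(run_alias = key$run_alias, instrument = key$instrument,
                     chemistry_version = key$chemistry_version,
                     software_version = key$software_version,
                     lane = key$lane, sample = key$sample,
                     barcode = key$barcode,
                     metric = rep_len(metric, n),
                     scope = rep_len(scope, n),
                     position_from = as.integer(rep_len(position_from, n)),
                     position_to = as.integer(rep_len(position_to, n)),
                     stringsAsFactors = FALSE)
    value <- rep_len(value, n)
    if (is.numeric(value)) {
        df$value_num <- as.numeric(value)
        df$value_text <- NA_character_
    } else {
        suppressWarnings(num <- as.numeric(value))
        df$value_num <- num
        df$value_text <- ifelse(is.na(num), as.character(value),
                                NA_character_)
    }
    df[.store_columns]
}

#' Create or open a metric store
#'
#' A single-file warehouse of QC metrics with per-run/per-base/per-range
#' scoping. The store is environment-backed: [putMetrics()] mutates it in
#' place. With a `path`, an existing store file is loaded and every put is
#' persisted back to it; with `path = ""` the store is in-memory (persist
#' explicitly with [saveStore()]).
#'
#' @param path backing TSV file, or `""` for in-memory.
#' @return A [MetricStore-class].
#' @export
metricStore <- function(path = "") {
    env <- new.env(parent = emptyenv())
    env$records <- if (nzchar(path) && file.exists(path))
        .read_store_file(path) else .empty_records()
    new("MetricStore", env = env, path = path)
}

#' @rdname metricStore
#' @param store a [MetricStore-class].
#' @return `storeRecords`: the records data.frame.
#' @export
storeRecords <- function(store) {
    stopifnot(is(store, "MetricStore"))
    store@env$records
}

.read_store_file <- function(path) {
    int_cols <- c("lane", "position_from", "position_to")
    classes <- setNames(rep("character", length(.store_columns)),
                        .store_columns)
    classes[int_cols] <- "integer"
    classes["value_num"] <- "numeric"
    df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                     colClasses = classes)
    df[.store_columns]
}

#' @rdname metricStore
#' @export
saveStore <- function(store, path = store@path) {
    if (!nzchar(path)) stop("no path to save the store to")
    out <- storeRecords(store)
    ## 17 significant digits keep doubles bit-exact across the round trip
    out$value_num <- ifelse(is.na(out$value_num), NA_character_,
                            sprintf("%.17g", out$value_num))
    ## quote the genuinely textual columns only, so numerics scan cleanly
    quote_cols <- which(!.store_columns %in%
                        c("lane", "position_from", "position_to",
                          "value_num"))
    write.table(out, path, sep = "\t", quote = quote_cols,
                row.names = FALSE, na = "NA")
    invisible(path)
}

.validate_records <- function(records) {
    stopifnot(is.data.frame(records))
    missing <- setdiff(.store_columns, names(records))
    if (length(missing))
        stop("records are missing columns: ", paste(missing, collapse = ", "))
    bad_scope <- which(!records$scope %in% c("run", "base", "range"))
    if (length(bad_scope))
        stop("record ", bad_scope[1], ": scope must be run, base or range")
    run <- records$scope == "run"
    bad <- which(run & (!is.na(records$position_from) |
                        !is.na(records$position_to)))
    if (length(bad))
        stop("record ", bad[1], ": run-scope records must carry no positions")
    pos <- !run
    bad <- which(pos & (is.na(records$position_from) |
                        is.na(records$position_to)))
    if (length(bad))
        stop("record ", bad[1], ": base/range-scope records need positions")
    bad <- which(records$scope == "base" &
                 records$position_from != records$position_to)
    if (length(bad))
        stop("record ", bad[1], ": base-scope records need equal positions")
    bad <- which(records$scope == "range" &
                 records$position_from > records$position_to)
    if (length(bad))
        stop("record ", bad[1], ": range-scope needs position_from <= position_to")
    records[.store_columns]
}

.record_key <- function(df) {
    do.call(paste, c(lapply(df[c("run_alias", "instrument",
                                 "chemistry_version", "software_version",
                                 "lane", "sample", "barcode", "metric",
                                 "scope", "position_from", "position_to")],
                            as.character),
                     sep = "\r"))
}

#' Store metric records
#'
#' Idempotent upsert on the full record identity (run key, metric name,
#' scope and positions): re-storing a record replaces its value rather
#' than duplicating the row.
#'
#' @param store a [MetricStore-class].
#' @param records data.frame from [metricRecords()], [parseFastqcReport()]
#'   or [parseToolkitReport()].
#' @return Number of records stored/updated, invisibly.
#' @export
putMetrics <- function(store, records) {
    stopifnot(is(store, "MetricStore"))
    records <- .validate_records(records)
    ## last occurrence wins within the incoming batch
    records <- records[!duplicated(.record_key(records),
                                   fromLast = TRUE), , drop = FALSE]
    existing <- store@env$records
    hit <- match(.record_key(records), .record_key(existing))
    upd <- which(!is.na(hit))
    if (length(upd)) {
        existing$value_num[hit[upd]] <- records$value_num[upd]
        existing$value_text[hit[upd]] <- records$value_text[upd]
    }
    add <- records[is.na(hit), , drop = FALSE]
    store@env$records <- rbind(existing, add)
    rownames(store@env$records) <- NULL
    if (nzchar(store@path)) saveStore(store)
    invisible(nrow(records))
}

#' Parse a FastQC data report into metric records
#'
#' Understands the `fastqc_data.txt` dialect: blocks delimited by
#' `>>Module Name<TAB>status` ... `>>END_MODULE`, TSV rows inside,
#' `#`-prefixed column headers. Basic Statistics rows become run-scope
#' records; Per base sequence quality rows become base-scope (positions
#' like `10`) or range-scope (positions like `10-14`) records named
#' `mean_quality`; Per sequence GC content rows become run-scope histogram
#' records (`gc_content_<gc>`); other modules fall back to the same
#' position-aware mapping. The pass/warn/fail status of each module is
#' stored as `module_status:<module>`. One record is emitted per data row.
#'
#' @param x path to a `fastqc_data.txt` file, or its lines as a character
#'   vector.
#' @param key a [runKey()].
#' @return records data.frame for [putMetrics()].
#' @export
parseFastqcReport <- function(x, key) {
    lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
    lines <- lines[!startsWith(lines, "##")]
    starts <- which(startsWith(lines, ">>") &
                    !startsWith(lines, ">>END_MODULE"))
    ends <- which(startsWith(lines, ">>END_MODULE"))
    out <- list()
    for (i in seq_along(starts)) {
        s <- starts[i]
        e <- ends[ends > s][1]
        if (is.na(e) || any(starts > s & starts < e)) {
            hdr <- strsplit(sub("^>>", "", lines[s]), "\t")[[1]][1]
            stop("module '", hdr, "' has no >>END_MODULE terminator")
        }
        hdr <- strsplit(sub("^>>", "", lines[s]), "\t", fixed = TRUE)[[1]]
        module <- hdr[1]
        status <- if (length(hdr) > 1L) hdr[2] else NA_character_
        out[[length(out) + 1L]] <- metricRecords(
            key, paste0("module_status:", module), status)
        body <- lines[seq(s + 1L, e - 1L, length.out = max(0L, e - s - 1L))]
        body <- body[nzchar(body) & !startsWith(body, "#")]
        if (!length(body)) next
        cells <- strsplit(body, "\t", fixed = TRUE)
        col1 <- vapply(cells, `[[`, "", 1L)
        col2 <- vapply(cells, function(r)
            if (length(r) > 1L) r[[2]] else NA_character_, "")
        slug <- gsub("[^a-z0-9]+", "_", tolower(module))
        if (module == "Basic Statistics") {
            out[[length(out) + 1L]] <- metricRecords(key, col1, col2)
        } else if (module == "Per sequence GC content") {
            out[[length(out) + 1L]] <- metricRecords(
                key, paste0("gc_content_", col1), as.numeric(col2))
        } else if (grepl("^\\d+(-\\d+)?$", col1[1])) {
            ## positional module: single ints -> base, "a-b" -> range
            from <- as.integer(sub("-.*$", "", col1))
            to <- ifelse(grepl("-", col1, fixed = TRUE),
                         suppressWarnings(as.integer(sub("^.*-", "", col1))),
                         from)
            name <- if (module == "Per base sequence quality")
                "mean_quality" else slug
            out[[length(out) + 1L]] <- metricRecords(
                key, name, as.numeric(col2),
                scope = ifelse(from == to, "base", "range"),
                position_from = from, position_to = to)
        } else {
            out[[length(out) + 1L]] <- metricRecords(
                key, paste0(slug, ":", col1), col2)
        }
    }
    if (!length(out)) return(.empty_records())
    do.call(rbind, out)
}

#' Convert a toolkit report to metric records
#'
#' Every scalar in a report becomes a run-scope record (lossless); series
#' become base-scope records (per-cycle quality) or named run-scope
#' histogram records (GC bins).
#'
#' @param report a ScreenReport, RunSummary, MatePairReport, DemuxReport,
#'   SpectraAnalysis or PerBaseQuality object, or the path to a JSON file
#'   written by [writeReport()].
#' @param key a [runKey()].
#' @return records data.frame for [putMetrics()].
#' @export
parseToolkitReport <- function(report, key) {
    if (is.character(report) && length(report) == 1L) {
        if (!file.exists(report)) stop("no such report file: ", report)
        lst <- jsonlite::read_json(report, simplifyVector = TRUE)
        return(.records_from_list(lst, key))
    }
    if (is(report, "PerBaseQuality")) {
        st <- report@stats
        return(metricRecords(key, "mean_quality", st$mean, scope = "base",
                             position_from = st$cycle,
                             position_to = st$cycle))
    }
    .records_from_list(.report_list(report), key)
}

.records_from_list <- function(lst, key) {
    type <- lst$type
    if (is.null(type)) stop("unknown report type: no 'type' field")
    gc_records <- function(gh) {
        if (is.null(gh) || !nrow(gh)) return(NULL)
        metricRecords(key, paste0("gc_content_", gh$gc_bin),
                      as.numeric(gh$reads))
    }
    out <- switch(type,
        screen = {
            pre <- paste0("screen_", lst$reference_name, "_")
            flds <- c("reads_screened", "reads_with_hit",
                      "reads_with_hit_pct", "ref_kmers_total",
                      "ref_kmers_observed", "ref_covered_pct",
                      "subsample_fraction")
            metricRecords(key, paste0(pre, flds),
                          as.numeric(unlist(lst[flds])))
        },
        run_summary = rbind(
            metricRecords(key,
                          c("read_count", "mean_q30_bases_per_read",
                            "q30_read_pct"),
                          as.numeric(unlist(lst[c("read_count",
                                                  "mean_q30_bases_per_read",
                                                  "q30_read_pct")]))),
            gc_records(as.data.frame(lst$gc_histogram))),
        matepair = rbind(
            metricRecords(key,
                          paste0("lmp_category_",
                                 names(lst$category_counts)),
                          as.numeric(unlist(lst$category_counts))),
            metricRecords(key, "duplication_rate",
                          as.numeric(lst$duplication_rate)),
            gc_records(as.data.frame(lst$gc_histogram))),
        demux = rbind(
            metricRecords(key, paste0("demux_", names(lst$assigned)),
                          as.numeric(unlist(lst$assigned))),
            metricRecords(key, c("demux_undetermined", "demux_ambiguous"),
                          as.numeric(c(lst$undetermined, lst$ambiguous)))),
        spectra = rbind(
            metricRecords(key,
                          c("error_threshold", "main_peak",
                            "genome_size_estimate"),
                          as.numeric(c(lst$error_threshold, lst$main_peak,
                                       lst$genome_size_estimate))),
            metricRecords(key, "zygosity", as.character(lst$zygosity))),
        stop("unknown report type: ", type))
    out
}

#' Query the metric store
#'
#' Exact-equality filters over the run-key fields plus metric name and
#' scope; optionally grouped aggregation (mean, min, max, n) over the
#' numeric values of the matching records - the consolidated-table view
#' that makes metrics comparable across runs and instruments.
#'
#' @param store a [MetricStore-class].
#' @param filters named list of run-key fields to match exactly (e.g.
#'   `list(lane = 1L)`).
#' @param metric optional metric name(s) to match.
#' @param scope optional scope to match.
#' @param group_by optional key columns to group by (e.g. "instrument").
#' @param agg aggregate(s) over `value_num`: any of "mean", "min", "max",
#'   "n". Aggregating records holding text values is an error.
#' @return The matching records (no `group_by`), or one row per group with
#'   the requested aggregates.
#' @export
queryMetrics <- function(store, filters = list(), metric = NULL,
                         scope = NULL, group_by = NULL, agg = "mean") {
    rec <- storeRecords(store)
    keep <- rep(TRUE, nrow(rec))
    for (f in names(filters)) {
        if (!f %in% names(rec)) stop("unknown filter field: ", f)
        v <- filters[[f]]
        keep <- keep & (rec[[f]] %in% v |
                        (is.na(rec[[f]]) & any(is.na(v))))
    }
    if (!is.null(metric)) keep <- keep & rec$metric %in% metric
    if (!is.null(scope)) keep <- keep & rec$scope %in% scope
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
    if (is.null(group_by)) return(rec)
    stopifnot(all(group_by %in% names(rec)),
              all(agg %in% c("mean", "min", "max", "n")))
    if (nrow(rec) && any(!is.na(rec$value_text)))
        stop("cannot aggregate over text-valued records")
    if (!nrow(rec)) {
        out <- rec[, group_by, drop = FALSE]
        for (a in agg) out[[a]] <- numeric(0)
        return(out)
    }
    groups <- interaction(rec[group_by], drop = TRUE, lex.order = TRUE)
    split_vals <- split(rec$value_num, groups)
    out <- unique(rec[order(groups), group_by, drop = FALSE])
    rownames(out) <- NULL
    fns <- list(mean = mean, min = min, max = max, n = length)
    for (a in agg)
        out[[a]] <- vapply(split_vals, fns[[a]], numeric(1),
                           USE.NAMES = FALSE)
    out
}
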