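#' Compute k-mer spectra for read 1, read 2 and their pooled counts
#'
#' Makes a separate canonical k-mer count for read 1, for read 2, and for
#' both files pooled, and returns the three multiplicity spectra. The
#' combined spectrum is built from a single pooled count table - it is not
#' the sum of the two histograms, because a k-mer seen m1 times in R1 and
#' m2 times in R2 lands in bin m1+m2.
#'
#' @param r1 read 1, a [ReadSet-class] or character vector.
#' @param r2 optional read 2; when absent the combined spectrum equals the
#'   r1 spectrum and the r2 spectrum is empty.
#' @param k k-mer length (default 31, the spectrum default).
#' @return A [SpectraSet-class].
#' @export
computeSpectra <- function(r1, r2 = NULL, k = 31L) {
    k <- as.integer(k)
    s1 <- .as_sequences(r1)
    h1 <- kmerSpectrum(countKmers(s1, k))
    if (is.null(r2)) {
        empty <- new("SpectrumHistogram", multiplicity = integer(),
                     count = numeric())
        return(new("SpectraSet", r1 = h1, r2 = empty, combined = h1, k = k))
    }
    s2 <- .as_sequences(r2)
    h2 <- kmerSpectrum(countKmers(s2, k))
    pooled <- kmerSpectrum(countKmers(c(s1, s2), k))
    new("SpectraSet", r1 = h1, r2 = h2, combined = pooled, k = k)
}

#' Locate the error threshold of a k-mer spectrum
#'
#' Sequencing errors produce an abundance of k-mers with very low coverage,
#' visible as an initial spectrum peak around multiplicity 1. The error
#' threshold is the first local minimum separating that error peak from
#' genomic content: the smallest m >= 1 whose dense bin is exceeded by the
#' next one (`bins[m+1] > bins[m]`). When the bins decrease monotonically
#' there is no valley; the threshold is 1 and the result carries
#' `attr(, "undetermined") = TRUE`.
#'
#' @param hist a [SpectrumHistogram-class].
#' @return Integer multiplicity (with attribute `undetermined`).
#' @export
findErrorThreshold <- function(hist) {
    stopifnot(is(hist, "SpectrumHistogram"))
    if (!length(hist@multiplicity)) stop("empty histogram")
    bins <- spectrumBins(hist)
    rise <- which(diff(bins) > 0)
    if (length(rise)) return(structure(rise[1], undetermined = FALSE))
    structure(1L, undetermined = TRUE)
}

## centered moving average; edge windows shrink to the available bins
.smooth_ma <- function(x, window) {
    if (window <= 1L || length(x) < 2L) return(as.numeric(x))
    half <- window %/% 2L
    n <- length(x)
    vapply(seq_len(n), function(i) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        mean(x[lo:hi])
    }, numeric(1))
}

#' Interpret a k-mer spectrum
#'
#' Detects genomic coverage peaks above the error threshold, flags
#' heterozygosity, and estimates genome size.
#'
#' The histogram is smoothed with a centered moving average before peak
#' detection. Candidate peaks are local maxima at multiplicities above the
#' error threshold; those reaching at least `min_peak_frac` of the tallest
#' candidate are retained. The main peak is the retained peak at the
#' highest multiplicity: in a diploid sample the homozygous-content peak
#' sits at twice the multiplicity of the heterozygous peak and corresponds
#' to the full sequencing depth, so anchoring on the right-most major peak
#' makes the estimator ploidy-stable. The sample is flagged heterozygous
#' when a second retained peak lies within `het_tolerance` of half the
#' main-peak multiplicity. Genome size (in distinct-k-mer units, a proxy
#' for bases) is the total above-threshold k-mer mass divided by the
#' main-peak multiplicity:
#' \deqn{\hat G = \sum_{m > t} m \, bins[m] \; / \; m_{main}.}
#'
#' @param hist a [SpectrumHistogram-class].
#' @param smoothing_window moving-average window in bins (default 5).
#' @param het_tolerance relative tolerance around main/2 for the secondary
#'   peak (default 0.25).
#' @param min_peak_frac minimum smoothed height of a retained peak,
#'   relative to the tallest candidate (default 0.25).
#' @return A [SpectraAnalysis-class]. When nothing lies above the error
#'   threshold, or the threshold itself was undetermined, zygosity is
#'   `"undetermined"` and the estimates are `NA`.
#' @export
analyzeSpectrum <- function(hist, smoothing_window = 5L,
                            het_tolerance = 0.25, min_peak_frac = 0.25) {
    stopifnot(is(hist, "SpectrumHistogram"))
    thr <- findErrorThreshold(hist)
    undet <- isTRUE(attr(thr, "undetermined"))
    thr <- as.integer(thr)
    bins <- spectrumBins(hist)
    above <- seq_along(bins) > thr
    no_analysis <- function(zyg) new("SpectraAnalysis",
        error_threshold = thr,
        peaks = data.frame(multiplicity = integer(), height = numeric()),
        main_peak = NA_integer_, zygosity = zyg,
        genome_size_estimate = NA_real_)
    if (undet || !any(above & bins > 0)) return(no_analysis("undetermined"))
    sm <- .smooth_ma(bins, as.integer(smoothing_window))
    n <- length(sm)
    left <- c(-Inf, sm[-n]); right <- c(sm[-1], -Inf)
    is_peak <- sm > left & sm >= right & above & sm > 0
    cand <- which(is_peak)
    if (!length(cand)) return(no_analysis("undetermined"))
    keep <- sm[cand] >= min_peak_frac * max(sm[cand])
    peaks_m <- cand[keep]
    main_peak <- peaks_m[length(peaks_m)]
    half <- main_peak / 2
    secondary <- setdiff(peaks_m, main_peak)
    het <- any(abs(secondary - half) <= het_tolerance * half)
    mass <- sum(seq_along(bins)[above] * bins[above])
    new("SpectraAnalysis", error_threshold = thr,
        peaks = data.frame(multiplicity = as.integer(peaks_m),
                           height = sm[peaks_m]),
        main_peak = as.integer(main_peak),
        zygosity = if (het) "heterozygous" else "homozygous",
        genome_size_estimate = mass / main_peak)
}

#' Export a spectra overlay table
#'
#' Writes a dense TSV (`multiplicity`, `r1`, `r2`, `combined`) covering
#' every multiplicity from 1 to the largest observed in any of the three
#' spectra, with explicit zeros, so the file reproduces the histograms
#' exactly. Optionally renders an overlay plot.
#'
#' @param spectra a [SpectraSet-class].
#' @param path output TSV path.
#' @param plot_path optional PNG path for an overlay plot.
#' @return `path`, invisibly.
#' @export
exportOverlay <- function(spectra, path, plot_path = NULL) {
    stopifnot(is(spectra, "SpectraSet"))
    upto <- max(1L, spectra@r1@multiplicity, spectra@r2@multiplicity,
                spectra@combined@multiplicity)
    df <- data.frame(multiplicity = seq_len(upto),
                     r1 = unname(spectrumBins(spectra@r1, upto)),
                     r2 = unname(spectrumBins(spectra@r2, upto)),
                     combined = unname(spectrumBins(spectra@combined, upto)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(plot_path)) {
        grDevices::png(plot_path, width = 800, height = 500)
        on.exit(grDevices::dev.off())
        plot(df$multiplicity, df$combined, type = "l", col = "black",
             xlab = "kmer multiplicity", ylab = "distinct kmers",
             main = sprintf("kmer spectra (k=%d)", spectra@k))
        graphics::lines(df$multiplicity, df$r1, col = "blue")
        graphics::lines(df$multiplicity, df$r2, col = "red")
        graphics::legend("topright", legend = c("combined", "r1", "r2"),
                         col = c("black", "blue", "red"), lty = 1)
    }
    invisible(path)
}
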