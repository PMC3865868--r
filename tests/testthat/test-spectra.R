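mk_hist <- function(bins) {
    m <- as.integer(names(bins))
    new("SpectrumHistogram", multiplicity = m[order(m)],
        count = as.numeric(bins)[order(m)])
}

test_that("pooling identical files doubles every multiplicity", {
    reads <- vapply(1:30, function(i) random_dna(200, 800 + i), "")
    ss <- computeSpectra(reads, reads, k = 31)
    expect_identical(ss@r1@multiplicity, ss@r2@multiplicity)
    expect_identical(ss@r1@count, ss@r2@count)
    expect_identical(ss@combined@multiplicity, 2L * ss@r1@multiplicity)
    expect_identical(ss@combined@count, ss@r1@count)
})

test_that("absent read 2 collapses combined onto read 1", {
    reads <- vapply(1:10, function(i) random_dna(150, 900 + i), "")
    ss <- computeSpectra(reads, k = 31)
    expect_identical(spectrumBins(ss@combined), spectrumBins(ss@r1))
    expect_equal(length(ss@r2@multiplicity), 0L)
})

test_that("combined distinct kmers respect the union bound", {
    r1 <- vapply(1:10, function(i) random_dna(150, 910 + i), "")
    r2 <- vapply(1:10, function(i) random_dna(150, 930 + i), "")
    ss <- computeSpectra(r1, r2, k = 21)
    expect_lte(sum(ss@combined@count), sum(ss@r1@count) + sum(ss@r2@count))
})

test_that("error threshold is the first valley after the error peak", {
    t1 <- findErrorThreshold(mk_hist(c("1" = 10000, "2" = 300, "3" = 50,
                                       "4" = 80, "5" = 120, "6" = 90)))
    expect_equal(as.integer(t1), 3L)
    expect_false(attr(t1, "undetermined"))

    t2 <- findErrorThreshold(mk_hist(c("1" = 100, "2" = 50, "3" = 10)))
    expect_equal(as.integer(t2), 1L)
    expect_true(attr(t2, "undetermined"))

    t3 <- findErrorThreshold(mk_hist(c("1" = 5, "2" = 50, "3" = 10)))
    expect_equal(as.integer(t3), 1L)
    expect_error(findErrorThreshold(new("SpectrumHistogram",
                                        multiplicity = integer(),
                                        count = numeric())),
                 "empty histogram")
})

test_that("a single concentrated peak yields the forced genome size", {
    ana <- analyzeSpectrum(mk_hist(c("10" = 1000)))
    expect_equal(nrow(ana@peaks), 1L)
    expect_equal(ana@peaks$multiplicity, 10L)
    expect_equal(ana@main_peak, 10L)
    expect_equal(ana@zygosity, "homozygous")
    expect_equal(ana@genome_size_estimate, 1000)  # 10 * 1000 / 10
})

test_that("monotone-decreasing spectra give an undetermined analysis", {
    ana <- analyzeSpectrum(mk_hist(c("1" = 100, "2" = 50, "3" = 10)))
    expect_equal(ana@zygosity, "undetermined")
    expect_true(is.na(ana@genome_size_estimate))
})

test_that("substitution errors inflate the multiplicity-1 bin", {
    cfg0 <- simConfig(seed = 55, genome_size = 30000, depth = 30,
                      read_length = 100, substitution_error_rate = 0)
    g <- simGenome(cfg0)
    cfg1 <- simConfig(seed = 55, genome_size = 30000, depth = 30,
                      read_length = 100, substitution_error_rate = 0.01)
    b0 <- spectrumBins(computeSpectra(simReads(g, cfg0)$reads, k = 31)@r1)
    b1 <- spectrumBins(computeSpectra(simReads(g, cfg1)$reads, k = 31)@r1)
    expect_gt(b1[["1"]], b0[["1"]])
})

test_that("overlay export is dense and round-trips the histograms", {
    r1 <- vapply(1:20, function(i) random_dna(200, 940 + i), "")
    ss <- computeSpectra(r1, r1, k = 21)
    f <- withr::local_tempfile(fileext = ".tsv")
    exportOverlay(ss, f)
    df <- read.delim(f)
    expect_equal(df$multiplicity, seq_len(nrow(df)))  # dense, explicit zeros
    upto <- nrow(df)
    expect_equal(df$r1, unname(spectrumBins(ss@r1, upto)))
    expect_equal(df$r2, unname(spectrumBins(ss@r2, upto)))
    expect_equal(df$combined, unname(spectrumBins(ss@combined, upto)))

    ss1 <- computeSpectra(r1, k = 21)
    exportOverlay(ss1, f)
    expect_true(all(read.delim(f)$r2 == 0))
})
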