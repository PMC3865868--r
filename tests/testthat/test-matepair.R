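J <- nexteraJunction()

test_that("junction detection finds embedded, boundary and absent adaptors", {
    stem <- random_dna(30, 1001)
    tail <- random_dna(10, 1002)
    expect_equal(findJunction(paste0(stem, J, tail)), 30L)

    ## 18-base junction prefix flush at the 3' end
    read <- paste0(random_dna(82, 1003), substr(J, 1, 18))
    expect_equal(findJunction(read), 82L)

    ## below min_overlap the prefix must not trigger
    read17 <- paste0(random_dna(83, 1004), substr(J, 1, 17))
    expect_true(is.na(findJunction(read17)))

    ## mismatch tolerance: 4 of 38 allowed, 5 rejected
    J4 <- J; substr(J4, 3, 6) <- "AAAA"
    mism4 <- sum(strsplit(J4, "")[[1]] != strsplit(J, "")[[1]])
    read4 <- paste0(stem, J4, tail)
    if (mism4 == 4) expect_equal(findJunction(read4), 30L)
    J5 <- J4; substr(J5, 10, 10) <- if (substr(J, 10, 10) == "A") "C" else "A"
    read5 <- paste0(stem, J5, tail)
    expect_true(is.na(findJunction(read5)))
})

test_that("random 100-mers almost never contain a junction hit", {
    reads <- vapply(1:100, function(i) random_dna(100, 1100 + i), "")
    hits <- sum(!is.na(findJunction(reads)))
    expect_lte(hits, 1L)
})

test_that("pairs are categorized per mate and clipped at the junction", {
    g1 <- random_dna(50, 1201); g2 <- random_dna(60, 1202)
    r1 <- ReadSet("p/1", substr(paste0(g1, J, random_dna(40, 1203)), 1, 100))
    r2 <- ReadSet("p/2", substr(paste0(g2, J, random_dna(40, 1204)), 1, 100))
    cc <- classifyAndClip(r1, r2)
    expect_equal(cc$category, "A")
    expect_equal(nchar(sequences(cc$r1_clipped)), 50L)
    expect_equal(nchar(sequences(cc$r2_clipped)), 60L)
    expect_true(cc$kept)

    ## junction only in read 2 -> B, read 1 untouched
    r1b <- ReadSet("q/1", random_dna(100, 1205))
    cb <- classifyAndClip(r1b, r2)
    expect_equal(cb$category, "B")
    expect_identical(sequences(cb$r1_clipped), sequences(r1b))

    ## early junction trips the length gate but is still counted
    r1s <- ReadSet("s/1", substr(paste0(random_dna(10, 1206), J,
                                        random_dna(60, 1207)), 1, 100))
    cs <- classifyAndClip(r1s, r2, min_length = 25)
    expect_equal(cs$category, "A")
    expect_false(cs$kept)
})

test_that("category counts always sum to the pair count", {
    cfg <- simConfig(seed = 61, genome_size = 50000, read_length = 100)
    g <- simGenome(cfg)
    lmp <- simLmpLibrary(g[1], 400, cfg)
    rep <- analyzeMatePairs(lmp$r1, lmp$r2)
    expect_equal(sum(rep@category_counts), 400)
})

test_that("duplicate rate follows the closed forms", {
    base <- ReadSet(sprintf("d%d", 1:100),
                    vapply(1:100, function(i) random_dna(50, 1300 + i), ""))
    mate <- ReadSet(sprintf("d%d", 1:100),
                    vapply(1:100, function(i) random_dna(50, 1400 + i), ""))
    expect_equal(as.numeric(duplicateRate(base, mate)), 0)

    ## 100 distinct + 10 copies of the first -> 100*(1 - 100/110)
    r1 <- base[c(1:100, rep(1, 10))]
    r2 <- mate[c(1:100, rep(1, 10))]
    expect_equal(as.numeric(duplicateRate(r1, r2)), 100 * (1 - 100 / 110))

    n <- 7
    allsame <- base[rep(1, n)]
    expect_equal(as.numeric(duplicateRate(allsame, allsame)),
                 100 * (1 - 1 / n))

    short <- ReadSet(c("a", "b"), c("ACGTACGTACGTACGTAC", "ACGT"))
    dr <- duplicateRate(short, short)
    expect_equal(attr(dr, "skipped"), 1L)
})

test_that("GC percent excludes N from the denominator", {
    expect_equal(gcPercent(c("GGCC", "ACGT", "ANGT")),
                 c(100, 50, 100 / 3))
    expect_true(is.na(gcPercent("NNNN")))
    h <- gcReadHistogram(c("GGCC", "GGCC", "ACGT", "NNNN"))
    expect_equal(h$reads[h$gc_bin == 100], 2)
    expect_equal(attr(h, "skipped"), 1L)
})

test_that("orientation and insert size follow the geometric rules", {
    ap <- data.frame(
        qname = c("pe", "mp", "td"),
        ref1 = "chr1", pos1 = c(100L, 100L, 100L),
        strand1 = c("+", "-", "+"), alen1 = 50L, mapped1 = TRUE,
        ref2 = "chr1", pos2 = c(1000L, 1000L, 1000L),
        strand2 = c("-", "+", "+"), alen2 = 50L, mapped2 = TRUE,
        stringsAsFactors = FALSE)
    rep <- orientationAnalysis(ap)
    got <- rep@pairs
    expect_equal(got$orientation[got$qname == "pe"], "paired_end")
    expect_equal(got$orientation[got$qname == "mp"], "mate_pair")
    expect_equal(got$orientation[got$qname == "td"], "tandem")
    expect_equal(got$insert, rep(950L, 3))  # 1049 - 100 + 1

    ap$ref2[1] <- "chr2"
    ap$mapped2[2] <- FALSE
    rep2 <- orientationAnalysis(ap)
    expect_equal(rep2@discordant, 1)
    expect_equal(rep2@unmapped, 1)
    expect_equal(nrow(rep2@pairs), 1L)
})

test_that("clipped per-category files round-trip through FASTQ", {
    cfg <- simConfig(seed = 62, genome_size = 50000, read_length = 100)
    g <- simGenome(cfg)
    lmp <- simLmpLibrary(g[1], 200, cfg)
    dir <- withr::local_tempdir()
    rep <- analyzeMatePairs(lmp$r1, lmp$r2, output_dir = dir)
    expect_true(all(file.exists(rep@clipped_paths)))
    a1 <- readFastq(rep@clipped_paths[["A_R1"]])
    det <- attr(rep, "detail")
    sel <- det$category == "A" & det$kept
    expect_equal(length(a1), sum(sel))
    expect_identical(sequences(a1), sequences(det$r1_clipped)[sel])
})
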