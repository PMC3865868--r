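test_that("genomes are reproducible with controlled GC and heterozygosity", {
    cfg <- simConfig(seed = 5, genome_size = 1e5, gc_fraction = 0.5)
    g1 <- simGenome(cfg)
    g2 <- simGenome(cfg)
    expect_identical(g1, g2)
    gc <- gcPercent(g1[["hap1"]])
    expect_gte(gc, 49); expect_lte(gc, 51)

    dip <- simConfig(seed = 6, genome_size = 1e5, ploidy = 2,
                     het_snp_rate = 0.01)
    gd <- simGenome(dip)
    expect_equal(names(gd), c("hap1", "hap2"))
    d <- sum(strsplit(gd[[1]], "")[[1]] != strsplit(gd[[2]], "")[[1]])
    sigma <- sqrt(1e5 * 0.01 * 0.99)
    expect_lte(abs(d - 1000), 3 * sigma)
})

test_that("read simulation honours count, coordinates and error rate", {
    cfg <- simConfig(seed = 7, genome_size = 20000, depth = 5,
                     read_length = 100)
    g <- simGenome(cfg)
    sim <- simReads(g, cfg)
    expect_equal(length(sim$reads), 5 * 20000 / 100)
    expect_equal(nrow(sim$truth), length(sim$reads))

    ## error-free reads are exact substrings at the truth coordinates
    for (i in sample(length(sim$reads), 20)) {
        tr <- sim$truth[i, ]
        sub <- substr(g[[tr$haplotype]], tr$start, tr$start + 99)
        if (tr$strand == "-") sub <- oracle_revcomp(sub)
        expect_identical(sequences(sim$reads)[i], sub)
    }

    cfgE <- simConfig(seed = 7, genome_size = 20000, depth = 5,
                      read_length = 100, substitution_error_rate = 0.01)
    simE <- simReads(g, cfgE)
    total_err <- sum(simE$truth$errors)
    expect_lte(abs(total_err / (1000 * 100) - 0.01),
               3 * sqrt(0.01 * 0.99 / 1e5))
    ## truth error counts match observed mismatches
    i <- which(simE$truth$errors > 0)[1]
    tr <- simE$truth[i, ]
    sub <- substr(g[[tr$haplotype]], tr$start, tr$start + 99)
    if (tr$strand == "-") sub <- oracle_revcomp(sub)
    mism <- sum(strsplit(sequences(simE$reads)[i], "")[[1]] !=
                strsplit(sub, "")[[1]])
    expect_equal(mism, tr$errors)
})

test_that("paired simulation writes mates from fragment ends", {
    cfg <- simConfig(seed = 8, genome_size = 20000, depth = 4,
                     read_length = 100)
    g <- simGenome(cfg)
    sim <- simReads(g, cfg, paired = TRUE, insert_mean = 500, insert_sd = 40)
    expect_equal(length(sim$r1), round(4 * 20000 / 100 / 2))
    tr <- sim$truth[1, ]
    expect_identical(sequences(sim$r1)[1],
                     substr(g[[tr$haplotype]], tr$start, tr$start + 99))
    expect_identical(sequences(sim$r2)[1],
                     oracle_revcomp(substr(g[[tr$haplotype]],
                                           tr$start + tr$insert - 100,
                                           tr$start + tr$insert - 1)))
})

test_that("contaminant spiking hits the exact formula and conserves truth", {
    host <- ReadSet(sprintf("h%d", 1:9000), rep("ACGT", 9000))
    cont <- ReadSet(sprintf("c%d", 1:2000), rep("TTTT", 2000))
    mix <- spikeContaminant(host, cont, 0.10, seed = 3)
    expect_equal(length(mix$reads), 10000)
    expect_equal(sum(mix$truth$origin == "contaminant"), 1000)
    expect_equal(nrow(mix$truth), length(mix$reads))
    expect_identical(mix$truth$read_id, readIds(mix$reads))

    same <- spikeContaminant(host, cont, 0)
    expect_identical(readIds(same$reads), readIds(host))
})

test_that("LMP construction places junctions at the arm length", {
    cfg <- simConfig(seed = 9, genome_size = 50000, read_length = 100)
    g <- simGenome(cfg)
    lmp <- simLmpLibrary(g[1], 300, cfg, true_mp_fraction = 1)
    tr <- lmp$truth
    expect_true(all(tr$is_true_mp))
    J <- nexteraJunction()
    with_j <- which(!is.na(tr$junction1))
    for (i in head(with_j, 20)) {
        a <- tr$arm1[i]
        expect_equal(tr$junction1[i], a)
        jlen <- min(100 - a, 38)
        expect_identical(substr(sequences(lmp$r1)[i], a + 1, a + jlen),
                         substr(J, 1, jlen))
    }
    no_j <- tr$arm1 >= 100
    expect_true(all(is.na(tr$junction1[no_j])))
    ## in-read junctions always show at least the minimum detection overlap
    expect_true(all(100 - tr$arm1[with_j] >= 18))
})

test_that("RAD reads embed barcode, overhang and uniform offsets", {
    specs <- barcodeSpecs(c("S1", "S2"), c("ACGTAC", "TGCATG"),
                          offsets = list(0:3), overhang = "TGCAG")
    cfg <- simConfig(seed = 10, genome_size = 50000, read_length = 80)
    g <- simGenome(cfg)
    sim <- simRadReads(g[1], specs, locus_count = 40, n_reads = 4000, cfg)
    expect_equal(nrow(sim$truth), 4000)
    tr <- sim$truth
    bc <- specs$barcode[match(tr$sample, specs$sample)]
    emb <- substr(sequences(sim$reads), tr$offset + 1,
                  tr$offset + nchar(bc))
    expect_identical(emb, bc)
    oh <- substr(sequences(sim$reads), tr$offset + nchar(bc) + 1,
                 tr$offset + nchar(bc) + 5)
    expect_true(all(oh == "TGCAG"))
    ## offsets uniform over the allowed set +- 3 sigma
    tab <- table(tr$offset)
    expect_equal(sort(as.integer(names(tab))), 0:3)
    exp_n <- 4000 / 4
    sigma <- sqrt(4000 * 0.25 * 0.75)
    expect_true(all(abs(tab - exp_n) <= 3 * sigma))

    ## single sample, offset 0: every read starts with the barcode
    s1 <- barcodeSpecs("S1", "ACGTAC", offsets = list(0L),
                       overhang = "TGCAG")
    sim0 <- simRadReads(g[1], s1, locus_count = 10, n_reads = 50, cfg)
    expect_true(all(startsWith(sequences(sim0$reads), "ACGTAC")))
})

test_that("all generators are byte-identical under a fixed seed", {
    cfg <- simConfig(seed = 42, genome_size = 10000, depth = 3,
                     read_length = 80)
    g <- simGenome(cfg)
    a <- simReads(g, cfg)
    b <- simReads(g, cfg)
    expect_identical(sequences(a$reads), sequences(b$reads))
    expect_identical(a$truth, b$truth)
    l1 <- simLmpLibrary(g[1], 50, cfg)
    l2 <- simLmpLibrary(g[1], 50, cfg)
    expect_identical(sequences(l1$r1), sequences(l2$r1))
    expect_identical(l1$truth, l2$truth)
})
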