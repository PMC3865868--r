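specs1 <- barcodeSpecs("S1", "ACGT", offsets = list(0:1), overhang = "TGCAG")

test_that("barcode matching scores candidates jointly over offsets", {
    ## exact barcode + overhang at offset 0
    m <- matchBarcode(paste0("ACGTTGCAGG", random_dna(30, 2001)), specs1)
    expect_equal(m$status, "assigned")
    expect_equal(m$sample, "S1")
    expect_equal(m$offset, 0L)

    ## offset-1 exact barcode; the offset-0 candidate fails its overhang
    m1 <- matchBarcode(paste0("NACGTTGCAG", random_dna(30, 2002)), specs1)
    expect_equal(m1$sample, "S1")
    expect_equal(m1$offset, 1L)

    ## tie between two samples at one mismatch each -> ambiguous
    two <- barcodeSpecs(c("S1", "S2"), c("ACGT", "ACGA"),
                        offsets = list(0L), overhang = "TGCAG")
    mt <- matchBarcode(paste0("ACGCTGCAG", random_dna(30, 2003)), two)
    expect_equal(mt$status, "ambiguous")
    expect_true(is.na(mt$sample))

    ## too short for every candidate -> undetermined
    ms <- matchBarcode("ACGTTGC", specs1)
    expect_equal(ms$status, "undetermined")

    ## overhang gate: correct barcode, wrong overhang
    mo <- matchBarcode(paste0("ACGTCCCCC", random_dna(30, 2004)), specs1)
    expect_equal(mo$status, "undetermined")
})

test_that("demultiplexing conserves reads and trims to the overhang", {
    bcs <- c(S1 = "AAGGTCAC", S2 = "CTTCAGGA", S3 = "GCAATCTG")
    specs <- barcodeSpecs(names(bcs), bcs, offsets = list(0:3),
                          overhang = "TGCAG")
    cfg <- simConfig(seed = 63, genome_size = 50000, read_length = 80)
    g <- simGenome(cfg)
    sim <- simRadReads(g[1], specs, locus_count = 50, n_reads = 600, cfg)
    dir <- withr::local_tempdir()
    rep <- demultiplex(sim$reads, specs, output_dir = dir)
    expect_equal(sum(rep@assigned) + rep@undetermined + rep@ambiguous,
                 600)
    m <- attr(rep, "assignments")
    expect_equal(m$sample[m$status == "assigned"],
                 sim$truth$sample[m$status == "assigned"])
    ## trimmed outputs start with the overhang (it is genomic sequence)
    for (s in names(bcs)) {
        out <- readFastq(rep@paths[[paste0(s, "_R1")]])
        expect_equal(length(out), unname(rep@assigned[s]))
        expect_true(all(startsWith(sequences(out), "TGCAG")))
    }
    expect_true(file.exists(rep@paths[["Undetermined_R1"]]))
})

test_that("paired demultiplexing routes mates together, read 2 untouched", {
    specs <- barcodeSpecs(c("A1", "B2"), c("ACGTAC", "TGCATG"),
                          offsets = list(0:2), overhang = "TGCAG")
    cfg <- simConfig(seed = 64, genome_size = 20000, read_length = 60)
    g <- simGenome(cfg)
    sim <- simRadReads(g[1], specs, locus_count = 20, n_reads = 100, cfg)
    r2 <- ReadSet(sub("^rad", "mate", readIds(sim$reads)),
                  vapply(1:100, function(i) random_dna(60, 2100 + i), ""))
    dir <- withr::local_tempdir()
    rep <- demultiplex(sim$reads, specs, r2 = r2, output_dir = dir)
    a1 <- readFastq(rep@paths[["A1_R1"]])
    a2 <- readFastq(rep@paths[["A1_R2"]])
    expect_equal(length(a1), length(a2))
    expect_true(all(nchar(sequences(a2)) == 60))  # untrimmed
})

test_that("empty input demultiplexes to zero counts and valid empty files", {
    dir <- withr::local_tempdir()
    rep <- demultiplex(ReadSet(), specs1, output_dir = dir)
    expect_equal(sum(rep@assigned), 0)
    expect_equal(rep@undetermined, 0)
    expect_equal(rep@ambiguous, 0)
    expect_equal(length(readFastq(rep@paths[["S1_R1"]])), 0L)
})

test_that("sample sheets round-trip through TSV", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tbarcode\toffsets\toverhang",
                 "S1\tACGTAC\t0,1,2\tTGCAG",
                 "S2\tTGCATG\t0,1,2\tTGCAG"), f)
    specs <- readSampleSheet(f)
    expect_equal(specs$sample, c("S1", "S2"))
    expect_equal(attr(specs, "offsets")[[1]], 0:2)
    expect_equal(specs$overhang, c("TGCAG", "TGCAG"))
    expect_error(barcodeSpecs(c("a", "a"), c("ACGT", "ACGA")),
                 "unique")
    expect_error(barcodeSpecs(c("a", "b"), c("ACGT", "ACGA"),
                              overhang = c("TG", "CA")),
                 "identical")
})
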