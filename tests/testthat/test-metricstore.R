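key1 <- runKey("run1", instrument = "HS2500", lane = 1L, sample = "s1")

test_that("puts are idempotent upserts on the record identity", {
    store <- metricStore()
    rec <- metricRecords(key1, "q30_read_pct", 80)
    expect_equal(putMetrics(store, rec), 1L)
    expect_equal(putMetrics(store, rec), 1L)
    expect_equal(nrow(storeRecords(store)), 1L)

    rec$value_num <- 85
    putMetrics(store, rec)
    expect_equal(storeRecords(store)$value_num, 85)

    bad <- metricRecords(key1, "x", 1, scope = "range",
                         position_from = 5L, position_to = 2L)
    expect_error(putMetrics(store, bad), "position_from <= position_to")
    badrun <- metricRecords(key1, "x", 1)
    badrun$position_from <- 3L
    expect_error(putMetrics(store, badrun), "no positions")
})

test_that("large stores round-trip through the backing file exactly", {
    set.seed(91)
    n <- 10000
    keys <- sprintf("run%d", sample(1:20, n, TRUE))
    recs <- do.call(rbind, lapply(split(seq_len(n), keys), function(idx) {
        k <- runKey(keys[idx[1]], instrument = "inst",
                    lane = sample(1:8, 1), sample = "s")
        metricRecords(k, sprintf("metric_%06d", idx),
                      round(runif(length(idx)) * 1000, 6))
    }))
    store <- metricStore()
    putMetrics(store, recs)
    expect_equal(nrow(storeRecords(store)), n)
    f <- withr::local_tempfile(fileext = ".tsv")
    saveStore(store, f)
    back <- metricStore(f)
    a <- storeRecords(store); a <- a[order(a$metric), ]
    b <- storeRecords(back); b <- b[order(b$metric), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
    ## text values survive bit-exact
    txt <- metricRecords(key1, "zygosity", "heterozygous")
    putMetrics(back, txt)
    saveStore(back, f)
    again <- storeRecords(metricStore(f))
    expect_equal(again$value_text[again$metric == "zygosity"],
                 "heterozygous")
})

test_that("the FastQC dialect parser maps scopes and conserves rows", {
    recs <- parseFastqcReport(fastqc_fixture(), key1)
    data_rows <- recs[!startsWith(recs$metric, "module_status:"), ]
    ## 3 + 4 + 3 data rows in the fixture
    expect_equal(nrow(data_rows), 10L)
    pb <- recs[recs$metric == "mean_quality", ]
    expect_equal(nrow(pb), 4L)
    expect_equal(pb$scope, c("base", "base", "range", "range"))
    expect_equal(pb$position_from, c(1L, 2L, 10L, 15L))
    expect_equal(pb$position_to, c(1L, 2L, 14L, 19L))
    expect_equal(pb$value_num[3], 30.0)
    bs <- recs[recs$metric == "Total Sequences", ]
    expect_equal(bs$scope, "run")
    expect_equal(bs$value_num, 20000)
    gc <- recs[startsWith(recs$metric, "gc_content_"), ]
    expect_equal(nrow(gc), 3L)
    expect_true(all(gc$scope == "run"))
    st <- recs[recs$metric == "module_status:Per sequence GC content", ]
    expect_equal(st$value_text, "warn")

    broken <- fastqc_fixture()[-7]  # drop the first END_MODULE
    expect_error(parseFastqcReport(broken, key1), "Basic Statistics")
})

test_that("toolkit reports convert to records losslessly for scalars", {
    rep <- new("ScreenReport", reference_name = "ecoli", k = 21L,
               reads_screened = 1000, reads_with_hit = 120,
               reads_with_hit_pct = 12.0, ref_kmers_total = 10000,
               ref_kmers_observed = 80, ref_covered_pct = 0.8,
               subsample_fraction = 0.1)
    recs <- parseToolkitReport(rep, key1)
    expect_true(all(recs$scope == "run"))
    expect_equal(
        recs$value_num[recs$metric == "screen_ecoli_reads_with_hit_pct"],
        12.0)
    expect_equal(
        recs$value_num[recs$metric == "screen_ecoli_ref_covered_pct"], 0.8)

    ## JSON round trip through writeReport
    f <- withr::local_tempfile(fileext = ".json")
    writeReport(rep, f)
    recs2 <- parseToolkitReport(f, key1)
    expect_equal(recs2$value_num[match(recs$metric, recs2$metric)],
                 recs$value_num)

    rs <- ReadSet(sprintf("r%d", 1:5), rep("ACGT", 5), rep("II?!", 5))
    pbq <- perBaseQuality(rs)
    prec <- parseToolkitReport(pbq, key1)
    expect_equal(nrow(prec), 4L)  # one record per cycle
    expect_true(all(prec$scope == "base"))
    expect_equal(prec$position_from, 1:4)

    expect_error(parseToolkitReport(list(a = 1), key1), "unknown report")
})

test_that("queries filter exactly and aggregate like a brute force", {
    store <- metricStore()
    putMetrics(store, metricRecords(
        runKey("r1", instrument = "HS", lane = 1L), "q30_read_pct", 80))
    putMetrics(store, metricRecords(
        runKey("r2", instrument = "HS", lane = 2L), "q30_read_pct", 90))
    agg <- queryMetrics(store, metric = "q30_read_pct",
                        group_by = "instrument", agg = c("mean", "n"))
    expect_equal(agg$mean, 85)
    expect_equal(agg$n, 2)
    lane1 <- queryMetrics(store, filters = list(lane = 1L))
    expect_equal(nrow(lane1), 1L)
    expect_equal(lane1$run_alias, "r1")
    expect_equal(nrow(queryMetrics(store, metric = "absent")), 0L)

    putMetrics(store, metricRecords(runKey("r3"), "zygosity", "het"))
    expect_error(queryMetrics(store, group_by = "instrument"),
                 "text-valued")
})

test_that("aggregation matches brute-force recomputation on random stores", {
    for (seed in 1:25) {
        set.seed(seed + 400)
        store <- metricStore()
        n <- sample(20:60, 1)
        inst <- sample(c("HS", "MS", "NS"), n, TRUE)
        run <- sprintf("run%d", sample(1:5, n, TRUE))
        val <- round(runif(n) * 100, 4)
        recs <- do.call(rbind, lapply(seq_len(n), function(i)
            metricRecords(runKey(run[i], instrument = inst[i],
                                 lane = i %% 4L, sample = "s"),
                          "metric_x", val[i])))
        putMetrics(store, recs)
        got <- queryMetrics(store, metric = "metric_x",
                            group_by = "instrument",
                            agg = c("mean", "min", "max", "n"))
        stored <- storeRecords(store)
        for (g in unique(inst)) {
            v <- stored$value_num[stored$instrument == g]
            row <- got[got$instrument == g, ]
            expect_equal(row$mean, mean(v))
            expect_equal(row$min, min(v))
            expect_equal(row$max, max(v))
            expect_equal(row$n, length(v))
        }
    }
})
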