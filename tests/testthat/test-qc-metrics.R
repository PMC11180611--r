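test_that("per-barcode totals, uniques and duplication rate are exact", {
  tbl <- fragment_table(data.table(
    chrom = "chr1", start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
    barcode = "BC1", count = c(3L, 1L, 2L)))
  st <- per_barcode_stats(tbl)
  expect_equal(st$total_reads, 6L)
  expect_equal(st$unique_fragments, 3L)
  expect_equal(st$dup_rate, 0.5)
  # all-singleton counts give zero duplication
  st2 <- per_barcode_stats(fragment_table(data.table(
    chrom = "chr1", start = c(0L, 9L), end = c(5L, 90L),
    barcode = "B", count = 1L)))
  expect_equal(st2$dup_rate, 0)
})

test_that("per-barcode stats match a brute-force per-line tally", {
  dt <- random_fragment_dt(2000, n_barcodes = 20, seed = 77)
  st <- per_barcode_stats(fragment_table(dt))
  for (bc in unique(dt$barcode)) {
    rows <- dt[barcode == bc]
    expect_equal(st[barcode == bc]$total_reads, sum(rows$count))
    expect_equal(st[barcode == bc]$unique_fragments,
                 length(unique(paste(rows$chrom, rows$start, rows$end))))
  }
  expect_equal(sum(st$total_reads), sum(dt$count))
})

test_that("uniform insertion coverage scores ~1 and a TSS pile-up scores >> 1", {
  tss <- data.table(chrom = "chr1", position = 50000L, strand = "+")
  # fragments tiling the window uniformly: one start cut every position,
  # long enough that the end cuts all land outside the window
  pos <- seq(48000L, 52000L)
  uni <- fragment_table(data.table(chrom = "chr1", start = pos,
                                   end = pos + 10000L, barcode = "U",
                                   count = 1L))
  score_u <- tss_enrichment(uni, tss)$scores$tss_enrichment
  expect_lt(abs(score_u - 1), 0.15)
  # all insertions exactly at the TSS
  sharp <- fragment_table(data.table(chrom = "chr1",
                                     start = rep(50000L, 60),
                                     end = 50000L + seq(30L, 89L),
                                     barcode = "S", count = 1L))
  score_s <- tss_enrichment(sharp, tss)$scores$tss_enrichment
  expect_gt(score_s, 5)
  # score grows with insertion count at the TSS (pseudocount-limited)
  sharp2 <- fragment_table(data.table(chrom = "chr1",
                                      start = rep(50000L, 120),
                                      end = 50000L + seq(30L, 149L),
                                      barcode = "S", count = 1L))
  expect_gt(tss_enrichment(sharp2, tss)$scores$tss_enrichment, score_s)
})

test_that("minus-strand TSS profiles mirror plus-strand ones", {
  p <- 50000L
  offs <- c(-300L, -120L, 40L, 900L)
  plus_tbl <- fragment_table(data.table(
    chrom = "chr1", start = p + offs, end = p + offs + 100L,
    barcode = "B", count = 1L))
  plus_tss <- data.table(chrom = "chr1", position = p, strand = "+")
  # reflect every cut site around the TSS for the minus-strand version
  cuts <- c(p + offs, p + offs + 99L)
  refl <- 2L * p - cuts
  minus_tbl <- fragment_table(data.table(
    chrom = "chr1", start = refl[5:8], end = refl[1:4] + 1L,
    barcode = "B", count = 1L))
  minus_tss <- data.table(chrom = "chr1", position = p, strand = "-")
  sp <- tss_enrichment(plus_tbl, plus_tss)
  sm <- tss_enrichment(minus_tbl, minus_tss)
  expect_equal(sp$scores$tss_enrichment, sm$scores$tss_enrichment)
  expect_equal(sp$profile$insertions, sm$profile$insertions)
})

test_that("tss_enrichment depends on profile shape, not depth", {
  # deterministic profile: uniform coverage of the whole window plus a
  # pile-up at the TSS; k-fold replication scales every window count by k
  tss <- data.table(chrom = "chr1", position = 50000L, strand = "+")
  make_tbl <- function(k) {
    parts <- lapply(seq_len(k) - 1L, function(j) {
      rbind(data.table(chrom = "chr1", start = seq(48000L, 52000L),
                       end = seq(48000L, 52000L) + 10000L + j,
                       barcode = "B", count = 1L),
            data.table(chrom = "chr1", start = 50000L,
                       end = 50000L + 5000L + j * 1000L + seq_len(40),
                       barcode = "B", count = 1L))
    })
    fragment_table(rbindlist(parts))
  }
  s1 <- tss_enrichment(make_tbl(1), tss)$scores$tss_enrichment
  s3 <- tss_enrichment(make_tbl(3), tss)$scores$tss_enrichment
  expect_gt(s1, 1)
  expect_lt(abs(s3 / s1 - 1), 0.1)
})

test_that("empty TSS annotation errors", {
  tbl <- fragment_table(random_fragment_dt(10))
  expect_error(tss_enrichment(tbl, data.table(chrom = character(),
                                              position = integer(),
                                              strand = character())),
               "empty")
})

test_that("FRIP counts any-overlap once per fragment, half-open", {
  peaks <- data.table(chrom = "chr1", start = c(200L, 240L), end = c(300L, 350L))
  tbl <- fragment_table(data.table(
    chrom = "chr1",
    start = c(100L, 250L, 500L, 290L),
    end   = c(200L, 260L, 600L, 400L),  # [100,200) misses [200,300)
    barcode = "B", count = 1L))
  fr <- frip(tbl, peaks)
  # fragments 2 and 4 overlap peaks (fragment 2 overlaps both, counted once)
  expect_equal(fr$frip, 0.5)
  expect_equal(fr$fragments_in_peaks, 2L)
})

test_that("FRIP agrees with an exhaustive pairwise overlap scan", {
  withr::with_seed(91, {
    peaks <- data.table(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                        start = sample.int(9500L, 60))
    peaks[, end := start + sample.int(300L, 60, replace = TRUE)]
  })
  dt <- random_fragment_dt(3000, n_barcodes = 12, seed = 92)
  tbl <- fragment_table(dt)
  fr <- frip(tbl, peaks)
  hits <- overlap_oracle(tbl, peaks)
  oracle <- data.table(barcode = tbl$barcode, hit = hits)[
    , .(frip = mean(hit)), by = barcode][order(barcode)]
  expect_equal(fr[order(barcode)]$frip, oracle$frip)
})

test_that("fragment-length medians are computed over unique fragments", {
  tbl <- fragment_table(data.table(chrom = "chr1", start = 0L,
                                   end = c(100L, 200L, 300L),
                                   barcode = "B", count = c(10L, 1L, 1L)))
  fs <- fragment_size_stats(tbl)
  expect_equal(fs$pooled_median, 200)     # counts ignored
  expect_equal(fs$per_barcode$median_fragment_length, 200)
  one <- fragment_table(data.table(chrom = "chr1", start = 0L, end = 123L,
                                   barcode = "B", count = 5L))
  expect_equal(fragment_size_stats(one)$pooled_median, 123)
})

test_that("simulated fragment lengths match the analytic mixture median", {
  cfg <- sim_config(n_cells = 60, n_noise_barcodes = 50,
                    mean_reads_per_cell = 2000, library_complexity = 1500,
                    error_rate = 0, seed = 12)
  tr <- simulate_experiment(cfg)
  fs <- fragment_size_stats(tr$fragments)
  # numeric median of the truncated normal mixture
  trunc_cdf <- function(x, mu, sd) {
    lo <- pnorm(cfg$len_range[1], mu, sd); hi <- pnorm(cfg$len_range[2], mu, sd)
    (pnorm(x, mu, sd) - lo) / (hi - lo)
  }
  mix_cdf <- function(x) cfg$frac_short * trunc_cdf(x, cfg$len_short_mean,
                                                    cfg$len_short_sd) +
    (1 - cfg$frac_short) * trunc_cdf(x, cfg$len_long_mean, cfg$len_long_sd)
  analytic <- uniroot(function(x) mix_cdf(x) - 0.5, cfg$len_range)$root
  expect_lt(abs(fs$pooled_median - analytic), 3)
})

test_that("fragment-file comparison returns exact Jaccard agreement", {
  a <- fragment_table(random_fragment_dt(500, seed = 1))
  expect_equal(compare_fragment_files(a, a)$weighted_mean_jaccard, 1)
  expect_true(all(compare_fragment_files(a, a)$per_barcode$jaccard == 1))
  b <- copy(a)[, start := start + 1L][, end := end + 1L]
  expect_equal(compare_fragment_files(a, fragment_table(b))$weighted_mean_jaccard, 0)
  # hand-built: 3 shared of 4 vs 4 -> jaccard 3/5
  x <- fragment_table(data.table(chrom = "chr1", start = c(0L, 10L, 20L, 30L),
                                 end = c(5L, 15L, 25L, 35L), barcode = "B",
                                 count = 1L))
  y <- fragment_table(data.table(chrom = "chr1", start = c(0L, 10L, 20L, 40L),
                                 end = c(5L, 15L, 25L, 45L), barcode = "B",
                                 count = 1L))
  expect_equal(compare_fragment_files(x, y)$per_barcode$jaccard, 0.6)
})

test_that("simulator FRIP converges to the configured target", {
  cfg <- sim_config(n_cells = 100, n_noise_barcodes = 100,
                    mean_reads_per_cell = 3000, library_complexity = 2000,
                    error_rate = 0, multiplet_rate = 0, seed = 40)
  tr <- simulate_experiment(cfg)
  cells <- tr$cell_beads$barcode
  fr <- frip(tr$fragments[barcode %chin% cells], tr$peaks)
  agg <- sum(fr$fragments_in_peaks) / sum(fr$unique_fragments)
  expect_gt(agg, cfg$target_frip - 0.05)
  expect_lt(agg, cfg$target_frip + 0.05)
})
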