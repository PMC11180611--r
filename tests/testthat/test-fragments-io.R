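test_that("reading an empty file yields an empty collapsed table", {
  path <- tempfile(fileext = ".tsv")
  file.create(path)
  tbl <- read_fragments(path)
  expect_s3_class(tbl, "fragment_table")
  expect_equal(nrow(tbl), 0L)
})

test_that("duplicate coordinate/barcode rows are collapsed by summing counts", {
  dt <- data.table(chrom = "chr1", start = 10L, end = 60L,
                   barcode = "ACGT", count = c(2L, 3L))
  path <- write_tmp_fragments(dt)
  tbl <- read_fragments(path)
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$count, 5L)
  # collapsing is idempotent and conserves reads
  expect_identical(fragment_table(tbl), tbl)
  expect_equal(total_reads(tbl), sum(dt$count))
})

test_that("per-barcode totals of a random file match a line-by-line tally", {
  dt <- random_fragment_dt(1000, n_barcodes = 8, seed = 7)
  path <- write_tmp_fragments(dt, gz = TRUE)
  tbl <- read_fragments(path)
  # independent tally straight off the raw rows
  oracle <- tapply(dt$count, dt$barcode, sum)
  got <- tapply(tbl$count, tbl$barcode, sum)
  expect_equal(got[order(names(got))], oracle[order(names(oracle))])
  expect_equal(total_reads(tbl), sum(dt$count))
})

test_that("a 4-column (per-read) fragments file is read with count 1", {
  dt <- data.table(chrom = c("chr1", "chr1", "chr1"),
                   start = c(5L, 5L, 9L), end = c(50L, 50L, 90L),
                   barcode = "AAAA")
  path <- write_tmp_fragments(dt)
  tbl <- read_fragments(path)
  expect_equal(sort(tbl$count), c(1L, 2L))
  expect_equal(total_reads(tbl), 3L)
})

test_that("malformed fragment rows fail with the offending line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\t60\tACGT\t1", "chr1\t90\t40\tACGT\t1"), path)
  expect_error(read_fragments(path), "line 2")
  writeLines(c("chr1\tten\t60\tACGT\t1"), path)
  expect_error(read_fragments(path), "line 1")
  expect_error(read_fragments(tempfile()), "not found")
})

test_that("write/read round-trip is the identity on collapsed tables", {
  tbl <- fragment_table(random_fragment_dt(300, seed = 11))
  for (gz in c(FALSE, TRUE)) {
    path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
    write_fragments(tbl, path)
    back <- read_fragments(path)
    expect_equal(as.data.frame(back), as.data.frame(tbl))
  }
})

test_that("written fragments are coordinate-sorted; empty table gives empty file", {
  dt <- random_fragment_dt(200, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_fragments(fragment_table(dt), path)
  raw <- fread(path, header = FALSE)
  ord <- order(raw$V1, raw$V2, raw$V3, raw$V4)
  expect_identical(ord, seq_len(nrow(raw)))
  write_fragments(fragment_table(), path)
  expect_equal(length(readLines(path)), 0L)
})

test_that("fragment table invariants are enforced", {
  expect_error(fragment_table(data.table(chrom = "chr1", start = 5L,
                                         end = 5L, barcode = "A",
                                         count = 1L)), "start < end")
  expect_error(fragment_table(data.table(chrom = "chr1", start = -1L,
                                         end = 5L, barcode = "A",
                                         count = 1L)), "negative")
  expect_error(fragment_table(data.table(chrom = "chr1", start = 1L,
                                         end = 5L, barcode = "A",
                                         count = 0L)), "counts")
})

test_that("BED intervals keep the half-open convention and reject bad rows", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", path)
  iv <- read_intervals(path)
  expect_equal(iv[, .(chrom, start, end)],
               data.table(chrom = "chr1", start = 100L, end = 200L))
  # position 199 is covered, 200 is not
  frag_in <- data.table(chrom = "chr1", start = 199L, end = 201L)
  frag_out <- data.table(chrom = "chr1", start = 200L, end = 300L)
  expect_true(fragqc:::overlaps_any(frag_in, iv))
  expect_false(fragqc:::overlaps_any(frag_out, iv))
  writeLines("chr1\t200\t100", path)
  expect_error(read_intervals(path), "malformed")
  file.create(path2 <- tempfile(fileext = ".bed"))
  expect_equal(nrow(read_intervals(path2)), 0L)
})

test_that("interval membership queries agree with a linear scan", {
  withr::with_seed(19, {
    peaks <- data.table(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                        start = sample.int(99000L, 100))
    peaks[, end := start + sample.int(400L, 100, replace = TRUE)]
    frag <- random_fragment_dt(500, seed = 20)
  })
  got <- fragqc:::overlaps_any(frag, peaks)
  expect_equal(got, overlap_oracle(frag, peaks))
})

test_that("TSS tables parse, deduplicate and validate strand", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000\t+", "chr1\t1000\t+", "chr2\t500\t-"), path)
  tss <- read_tss(path)
  expect_equal(nrow(tss), 2L)
  expect_equal(tss$strand, c("+", "-"))
  writeLines("chr1\t1000\t*", path)
  expect_error(read_tss(path), "strand")
})

test_that("mixed-strand TSS counts match a manual tally", {
  withr::with_seed(5, {
    strands <- sample(c("+", "-"), 50, replace = TRUE)
    dt <- data.table(chrom = "chr1", position = sample.int(1e6, 50),
                     strand = strands)
  })
  path <- tempfile(fileext = ".tsv")
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  tss <- read_tss(path)
  expect_equal(sum(tss$strand == "+"), sum(strands == "+"))
  expect_equal(sum(tss$strand == "-"), sum(strands == "-"))
})

test_that("whitelists validate length, alphabet and uniqueness", {
  path <- tempfile()
  writeLines(c("ACGT", "TTTT"), path)
  wl <- read_whitelist(path)
  expect_length(wl, 2L)
  expect_equal(attr(wl, "barcode_length"), 4L)
  writeLines(c("ACGT", "ACGT"), path)
  expect_length(read_whitelist(path), 1L)
  writeLines(c("ACGT", "ACGTT"), path)
  expect_error(read_whitelist(path), "mixed lengths")
  writeLines(c("ACGN"), path)
  expect_error(read_whitelist(path), "non-ACGT")
})
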