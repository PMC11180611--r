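#' Per-barcode read and fragment counts
#'
#' Summarises a collapsed fragment table into one record per barcode:
#' `total_reads` (sum of counts), `unique_fragments` (rows) and
#' `dup_rate = 1 - unique_fragments / total_reads`, the fraction of reads
#' that are PCR/optical copies of an already-seen fragment. TSS enrichment
#' and FRIP columns are initialised to `NA` and filled in by
#' [tss_enrichment()] and [frip()].
#'
#' @param table A [fragment_table()].
#' @return A `data.table` with columns `barcode`, `total_reads`,
#'   `unique_fragments`, `dup_rate`, `tss_enrichment`, `frip`,
#'   `median_fragment_length`, `is_cell`.
#' @export
per_barcode_stats <- function(table) {
  table <- fragment_table(table)
  if (nrow(table) == 0L)
    return(data.table(barcode = character(), total_reads = integer(),
                      unique_fragments = integer(), dup_rate = numeric(),
                      tss_enrichment = numeric(), frip = numeric(),
                      median_fragment_length = numeric(),
                      is_cell = logical()))
  out <- table[, .(total_reads = sum(count),
                   unique_fragments = .N,
                   median_fragment_length = as.numeric(median(end - start))),
               by = barcode]
  out[, dup_rate := 1 - unique_fragments / total_reads]
  out[, `:=`(tss_enrichment = NA_real_, frip = NA_real_, is_cell = NA)]
  setcolorder(out, c("barcode", "total_reads", "unique_fragments",
                     "dup_rate", "tss_enrichment", "frip",
                     "median_fragment_length", "is_cell"))
  setkey(out, barcode)
  out[]
}

#' TSS enrichment scores and aggregate profile
#'
#' Scores the enrichment of Tn5 insertion sites around transcription start
#' sites, the peak-free signal-to-noise metric of ATAC-seq QC. Each unique
#' fragment contributes its two cut sites (`start` and `end - 1`); cut sites
#' falling within `window` bp of a TSS are binned by their offset from that
#' TSS (offsets negated for minus-strand TSSs, and a site overlapping several
#' TSS windows contributes to each). The background is the mean insertion
#' count in the outermost `flank` bp at each end of the window plus
#' `pseudocount`; the score is the mean of count/background over the central
#' +/- `center` bp. Uniform coverage therefore scores ~1 and sharp TSS
#' pile-ups score far above 1.
#'
#' @param table A [fragment_table()].
#' @param tss A TSS annotation (`chrom`, `position`, `strand`), e.g. from
#'   [read_tss()].
#' @param window Half-width of the window around each TSS, bp (default 2000).
#' @param flank Width of the background flank at each window end, bp
#'   (default 100).
#' @param center Half-width of the scored central region, bp (default 50).
#' @param pseudocount Added to the background mean (default 0.1).
#' @return A list with `scores` (data.table `barcode`, `tss_enrichment`),
#'   and `profile` (data.table `offset` from -window..window with pooled raw
#'   `insertions` and flank-normalised `normalized` depth).
#' @export
tss_enrichment <- function(table, tss, window = 2000, flank = 100,
                           center = 50, pseudocount = 0.1) {
  table <- fragment_table(table)
  tss <- as.data.table(tss)
  if (nrow(tss) == 0L)
    stop("empty TSS annotation")
  window <- as.integer(window)
  cuts <- rbind(table[, .(chrom, pos = start, barcode)],
                table[, .(chrom, pos = end - 1L, barcode)])
  hits <- if (nrow(cuts)) {
    cut_gr <- GenomicRanges::GRanges(cuts$chrom,
                                     IRanges::IRanges(cuts$pos, width = 1L))
    tss_gr <- GenomicRanges::GRanges(tss$chrom,
                                     IRanges::IRanges(tss$position - window,
                                                      tss$position + window))
    ov <- GenomicRanges::findOverlaps(cut_gr, tss_gr, ignore.strand = TRUE)
    data.table(barcode = cuts$barcode[S4Vectors::queryHits(ov)],
               offset = {
                 raw <- cuts$pos[S4Vectors::queryHits(ov)] -
                   tss$position[S4Vectors::subjectHits(ov)]
                 ifelse(tss$strand[S4Vectors::subjectHits(ov)] == "-",
                        -raw, raw)
               })
  } else {
    data.table(barcode = character(), offset = integer())
  }
  in_flank <- abs(hits$offset) > window - flank
  in_center <- abs(hits$offset) <= center
  n_flank_pos <- 2L * flank
  n_center_pos <- 2L * center + 1L
  per_bc <- hits[, .(flank_cuts = sum(in_flank[.I]),
                     center_cuts = sum(in_center[.I])), by = barcode]
  per_bc[, background := flank_cuts / n_flank_pos + pseudocount]
  per_bc[, tss_enrichment := (center_cuts / n_center_pos) / background]
  scores <- per_bc[data.table(barcode = unique(table$barcode)),
                   on = "barcode"][, .(barcode, tss_enrichment)]
  scores[is.na(tss_enrichment), tss_enrichment := 0]
  profile <- data.table(offset = seq(-window, window))
  pooled <- hits[, .(insertions = .N), by = offset]
  profile <- pooled[profile, on = "offset"]
  profile[is.na(insertions), insertions := 0L]
  flank_mean <- profile[abs(offset) > window - flank, mean(insertions)]
  profile[, normalized := insertions / (flank_mean + pseudocount)]
  setkey(scores, barcode)
  list(scores = scores[], profile = profile[order(offset)])
}

#' Fraction of unique fragments in peaks (FRIP)
#'
#' For each barcode, the fraction of its unique fragments that overlap any
#' peak interval by at least one base (0-based half-open convention on both
#' sides; a fragment overlapping several peaks is counted once).
#'
#' @param table A [fragment_table()].
#' @param peaks An interval set (`chrom`, `start`, `end`), e.g. from
#'   [read_intervals()].
#' @return A `data.table` with columns `barcode`, `unique_fragments`,
#'   `fragments_in_peaks`, `frip`.
#' @export
frip <- function(table, peaks) {
  table <- fragment_table(table)
  peaks <- as.data.table(peaks)
  in_peak <- overlaps_any(table, peaks)
  out <- table[, .(unique_fragments = .N,
                   fragments_in_peaks = sum(in_peak[.I])), by = barcode]
  out[, frip := fragments_in_peaks / unique_fragments]
  setkey(out, barcode)
  out[]
}

# logical vector: does each fragment row overlap >=1 interval (half-open)?
overlaps_any <- function(table, intervals) {
  if (nrow(table) == 0L) return(logical())
  if (nrow(intervals) == 0L) return(rep(FALSE, nrow(table)))
  # convert half-open [start, end) to 1-based closed [start+1, end]
  frag_gr <- GenomicRanges::GRanges(table$chrom,
                                    IRanges::IRanges(table$start + 1L,
                                                     table$end))
  peak_gr <- GenomicRanges::GRanges(intervals$chrom,
                                    IRanges::IRanges(intervals$start + 1L,
                                                     intervals$end))
  IRanges::overlapsAny(frag_gr, peak_gr)
}

#' Fragment length distributions and medians
#'
#' Lengths (`end - start`) are computed over unique fragments, not weighted
#' by read count, matching the convention used for median-fragment-length
#' comparisons between techniques.
#'
#' @param table A [fragment_table()].
#' @return A list with `per_barcode` (data.table `barcode`,
#'   `median_fragment_length`, `n`), `pooled_median`, and `length_counts`
#'   (data.table `length`, `n` over all unique fragments).
#' @export
fragment_size_stats <- function(table) {
  table <- fragment_table(table)
  lens <- table$end - table$start
  per_barcode <- table[, .(median_fragment_length = as.numeric(
    median(end - start)), n = .N), by = barcode]
  setkey(per_barcode, barcode)
  list(per_barcode = per_barcode[],
       pooled_median = if (length(lens)) as.numeric(median(lens)) else NA_real_,
       length_counts = if (length(lens))
         data.table(length = lens)[, .(n = .N), by = length][order(length)]
       else data.table(length = integer(), n = integer()))
}

#' Per-barcode agreement between two fragment files
#'
#' Compares two collapsed fragment tables (e.g. the same library processed by
#' two pipelines): for every barcode present in either table, the Jaccard
#' index of its `(chrom, start, end)` coordinate sets, plus a summary mean
#' weighted by the barcode's union fragment count — so large barcodes
#' dominate the aggregate agreement the way aligned fragments do.
#'
#' @param a,b Fragment tables.
#' @return A list with `per_barcode` (data.table `barcode`, `n_a`, `n_b`,
#'   `n_shared`, `jaccard`) and `weighted_mean_jaccard`.
#' @export
compare_fragment_files <- function(a, b) {
  a <- fragment_table(a); b <- fragment_table(b)
  key_cols <- c("chrom", "start", "end", "barcode")
  shared <- if (nrow(a) && nrow(b)) {
    merge(a[, ..key_cols], b[, ..key_cols], by = key_cols)[
      , .(n_shared = .N), by = barcode]
  } else data.table(barcode = character(), n_shared = integer())
  na <- a[, .(n_a = .N), by = barcode]
  nb <- b[, .(n_b = .N), by = barcode]
  per <- merge(na, nb, by = "barcode", all = TRUE)
  per <- merge(per, shared, by = "barcode", all = TRUE)
  for (col in c("n_a", "n_b", "n_shared"))
    per[is.na(get(col)), (col) := 0L]
  per[, jaccard := n_shared / (n_a + n_b - n_shared)]
  union_n <- per$n_a + per$n_b - per$n_shared
  wmean <- if (nrow(per)) sum(per$jaccard * union_n) / sum(union_n) else NA_real_
  setkey(per, barcode)
  list(per_barcode = per[], weighted_mean_jaccard = wmean)
}

#' Assemble the full per-barcode QC table
#'
#' Convenience wrapper running [per_barcode_stats()], [tss_enrichment()] and
#' [frip()] and merging the results into one table.
#'
#' @param table A [fragment_table()].
#' @param tss TSS annotation (optional; scores stay `NA` when absent).
#' @param peaks Peak interval set (optional; FRIP stays `NA` when absent).
#' @param ... Passed to [tss_enrichment()].
#' @return A per-barcode `data.table` as in [per_barcode_stats()], with
#'   `tss_enrichment` and `frip` filled in where inputs were given.
#' @export
barcode_qc <- function(table, tss = NULL, peaks = NULL, ...) {
  table <- fragment_table(table)
  stats <- per_barcode_stats(table)
  if (!is.null(tss)) {
    sc <- tss_enrichment(table, tss, ...)$scores
    stats[sc, tss_enrichment := i.tss_enrichment, on = "barcode"]
  }
  if (!is.null(peaks)) {
    fr <- frip(table, peaks)
    stats[fr, frip := i.frip, on = "barcode"]
  }
  stats[]
}
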