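#' Read-loss waterfall and sequencing efficiency
#'
#' Decomposes the total raw sequencing reads of a sample into five disjoint,
#' exhaustive categories, as fractions of `total_raw_reads`:
#' \describe{
#'   \item{lost_barcode_or_mapping}{reads that never made it into the
#'     fragment table (invalid barcode or failed mapping upstream):
#'     `1 - sum(counts) / total`.}
#'   \item{reads_in_noncell_barcodes}{reads of barcodes not in the cell set.}
#'   \item{duplicate_reads_in_cells}{within cells, `count - 1` reads of every
#'     unique fragment (its first read is the unique one).}
#'   \item{unique_in_cells_not_in_peaks}{unique cell fragments that miss all
#'     peaks.}
#'   \item{unique_in_cells_in_peaks}{unique cell fragments overlapping a
#'     peak — the sequencing efficiency, the fraction of raw reads that end
#'     up usable in a peak count matrix.}
#' }
#' The five fractions sum to 1 exactly.
#'
#' @param total_raw_reads Total raw sequencing reads (must be at least the
#'   table's read count).
#' @param table A [fragment_table()].
#' @param cells Character vector of cell barcodes.
#' @param peaks Interval set of peaks.
#' @return A list of class `waterfall_report` with the five fractions and
#'   `sequencing_efficiency` (= `unique_in_cells_in_peaks`).
#' @export
waterfall <- function(total_raw_reads, table, cells, peaks) {
  table <- fragment_table(table)
  tbl_reads <- total_reads(table)
  if (total_raw_reads < tbl_reads)
    stop("total_raw_reads (", total_raw_reads,
         ") is smaller than the table's read count (", tbl_reads, ")")
  in_cells <- table[barcode %chin% cells]
  noncell_reads <- tbl_reads - total_reads(in_cells)
  unique_cells <- nrow(in_cells)
  dup_reads <- total_reads(in_cells) - unique_cells
  in_peak <- overlaps_any(in_cells, as.data.table(peaks))
  unique_in_peaks <- sum(in_peak)
  tot <- as.numeric(total_raw_reads)
  out <- list(
    total_raw_reads = total_raw_reads,
    lost_barcode_or_mapping = (total_raw_reads - tbl_reads) / tot,
    reads_in_noncell_barcodes = noncell_reads / tot,
    duplicate_reads_in_cells = dup_reads / tot,
    unique_in_cells_not_in_peaks = (unique_cells - unique_in_peaks) / tot,
    unique_in_cells_in_peaks = unique_in_peaks / tot)
  out$sequencing_efficiency <- out$unique_in_cells_in_peaks
  structure(out, class = "waterfall_report")
}

#' @export
print.waterfall_report <- function(x, ...) {
  pct <- function(v) sprintf("%5.1f%%", 100 * v)
  cat("read-loss waterfall (", format(x$total_raw_reads, big.mark = ","),
      " raw reads)\n",
      "  lost to barcode/mapping:      ", pct(x$lost_barcode_or_mapping), "\n",
      "  in non-cell barcodes:         ", pct(x$reads_in_noncell_barcodes), "\n",
      "  duplicates in cells:          ", pct(x$duplicate_reads_in_cells), "\n",
      "  unique in cells, not in peaks:", pct(x$unique_in_cells_not_in_peaks), "\n",
      "  unique in cells, in peaks:    ", pct(x$unique_in_cells_in_peaks),
      "  <- sequencing efficiency\n", sep = "")
  invisible(x)
}
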