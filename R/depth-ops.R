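#' Seeded downsampling of reads in a fragment table
#'
#' Thins reads by independent Bernoulli retention (the behaviour of
#' seed-matched FASTQ subsamplers such as seqtk, transported to the fragment
#' table): each of a row's `count` reads is kept with probability `p`, so the
#' retained count is `Binomial(count, p)` per row, and rows reaching zero are
#' dropped. `p` is either the given `fraction`, or — in target mode —
#' `target_per_cell * |cells| / total_cell_reads`, one global probability
#' derived from the cell set's mean depth and applied to the whole table.
#'
#' @param table A [fragment_table()].
#' @param fraction Retention probability in `[0, 1]` (exclusive with
#'   `target_per_cell`).
#' @param target_per_cell Target mean reads per cell; requires `cells`.
#' @param cells Character vector of cell barcodes (target mode only).
#' @param seed Integer seed; identical seed and input give identical output.
#' @return A downsampled, collapsed [fragment_table()].
#' @export
downsample_reads <- function(table, fraction = NULL, target_per_cell = NULL,
                             cells = NULL, seed = 1L) {
  table <- fragment_table(table)
  if (is.null(fraction) == is.null(target_per_cell))
    stop("give exactly one of fraction or target_per_cell")
  if (!is.null(target_per_cell)) {
    if (is.null(cells) || !length(cells))
      stop("target mode requires a non-empty cell set")
    cell_total <- total_reads(table[barcode %chin% cells])
    if (cell_total == 0L)
      stop("no reads found for the given cell set")
    fraction <- target_per_cell * length(cells) / cell_total
    if (fraction > 1 + 1e-12)
      stop("target of ", target_per_cell, " reads/cell exceeds current ",
           "mean depth of ", round(cell_total / length(cells), 1),
           "; no upsampling")
    fraction <- min(fraction, 1)
  }
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  if (fraction == 1) return(table)
  if (fraction == 0 || nrow(table) == 0L) return(fragment_table())
  out <- copy(table)
  withr::with_seed(as.integer(seed), {
    out[, count := rbinom(.N, count, fraction)]
  })
  fragment_table(out[count > 0L])
}
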