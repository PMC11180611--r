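#' Otsu threshold of a numeric sample
#'
#' Computes the histogram threshold that maximizes the between-class variance
#' of the binned values, i.e. Otsu's method applied to an arbitrary numeric
#' sample rather than an 8-bit image. Values are binned into `n_bins`
#' equal-width bins over their range; every interior bin boundary is scored by
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} (class weights times squared difference of
#' class means, with bin midpoints as class values) and the boundary with the
#' largest score is returned. Ties are broken toward the lower boundary.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 100).
#' @return A list of class `otsu_result` with elements `threshold` (the
#'   winning bin boundary), `breaks` (all bin edges), `between_var` (the
#'   between-class variance at the optimum) and `scores` (the between-class
#'   variance at every interior boundary).
#' @export
otsu_threshold <- function(values, n_bins = 100) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || length(unique(values)) < 2L)
    stop("otsu_threshold needs at least two distinct finite values")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  n <- sum(counts)
  w0 <- cumsum(counts)[-n_bins]
  sum0 <- cumsum(counts * mids)[-n_bins]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(counts * mids) - sum0) / w1, 0)
  score <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  score[w0 == 0 | w1 == 0] <- -Inf
  if (!any(is.finite(score)) || max(score) <= 0)
    stop("degenerate Otsu input: no boundary separates two classes")
  # ties (within fp tolerance) break toward the lower bin edge
  best <- which(score >= max(score) * (1 - 1e-9))[1]
  structure(list(threshold = breaks[best + 1L],
                 breaks = breaks,
                 between_var = score[best],
                 scores = score),
            class = "otsu_result")
}

#' Call cells from per-barcode QC statistics
#'
#' Separates true cells from ambient/low-quality barcodes by a dual Otsu
#' threshold: barcodes with fewer than `min_unique_floor` unique fragments
#' are excluded outright; among the rest, one Otsu threshold is derived on
#' `log10(unique_fragments)` and a second on TSS enrichment (linear scale),
#' and a barcode is called a cell only if it passes both.
#'
#' @param stats A `data.table` of per-barcode statistics as returned by
#'   [per_barcode_stats()], with a `tss_enrichment` column filled in (see
#'   [tss_enrichment()]).
#' @param min_unique_floor Minimum unique fragments for a barcode to enter
#'   thresholding at all (default 10).
#' @param n_bins Histogram bins for both Otsu runs (default 100).
#' @return A list of class `cell_calls`: `calls` (data.table of `barcode`,
#'   `is_cell`), `threshold_unique` (on the linear fragment-count scale),
#'   `threshold_tss`, `min_unique_floor`, and `n_considered` (barcodes above
#'   the floor).
#' @export
call_cells <- function(stats, min_unique_floor = 10, n_bins = 100) {
  stopifnot(all(c("barcode", "unique_fragments", "tss_enrichment") %in%
                  names(stats)))
  stats <- as.data.table(stats)
  eligible <- stats[unique_fragments >= min_unique_floor]
  if (nrow(eligible) < 2L)
    stop("fewer than 2 barcodes above the ", min_unique_floor,
         "-fragment floor: no callable population")
  thr_log_unique <- otsu_threshold(log10(eligible$unique_fragments),
                                   n_bins = n_bins)$threshold
  thr_tss <- otsu_threshold(eligible$tss_enrichment,
                            n_bins = n_bins)$threshold
  calls <- stats[, .(barcode,
                     is_cell = unique_fragments >= min_unique_floor &
                       log10(unique_fragments) >= thr_log_unique &
                       tss_enrichment >= thr_tss)]
  structure(list(calls = calls,
                 threshold_unique = 10^thr_log_unique,
                 threshold_tss = thr_tss,
                 min_unique_floor = min_unique_floor,
                 n_considered = nrow(eligible)),
            class = "cell_calls")
}

#' @export
print.cell_calls <- function(x, ...) {
  cat("cell calls: ", sum(x$calls$is_cell), " cells / ",
      nrow(x$calls), " barcodes (", x$n_considered, " above floor of ",
      x$min_unique_floor, ")\n",
      "  unique-fragment threshold: ", signif(x$threshold_unique, 4), "\n",
      "  TSS-enrichment threshold:  ", signif(x$threshold_tss, 4), "\n",
      sep = "")
  invisible(x)
}
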