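#' Saturation curve by iterative downsampling
#'
#' Restricts a fragment table to the given cell barcodes and, for each
#' subsampling fraction, downsamples the reads ([downsample_reads()]) and
#' records the mean reads per cell, the mean per-cell duplication rate and
#' the mean unique fragments per cell. The point at fraction 1 is computed on
#' the full data (no resampling), so it equals the full-data statistics
#' exactly.
#'
#' @param table A [fragment_table()].
#' @param cells Character vector of cell barcodes (non-empty).
#' @param fractions Numeric vector of subsampling fractions in `(0, 1]`.
#' @param seed Integer seed; fraction `i` uses `seed + i` so points are
#'   independent but reproducible.
#' @return A `data.table` with columns `fraction`, `mean_reads_per_cell`,
#'   `mean_dup_rate`, `mean_unique_per_cell`, sorted by fraction.
#' @export
saturation_curve <- function(table, cells, fractions, seed = 1L) {
  table <- fragment_table(table)
  if (is.null(cells) || !length(cells))
    stop("empty cell set")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  sub <- table[barcode %chin% cells]
  if (nrow(sub) == 0L)
    stop("no fragments for the given cell set")
  one_point <- function(f, i) {
    ds <- if (f == 1) sub else
      downsample_reads(sub, fraction = f, seed = as.integer(seed) + i)
    st <- per_barcode_stats(ds)
    data.table(fraction = f,
               mean_reads_per_cell = sum(st$total_reads) / length(cells),
               mean_dup_rate = mean(st$dup_rate),
               mean_unique_per_cell = sum(st$unique_fragments) /
                 length(cells))
  }
  out <- rbindlist(Map(one_point, fractions, seq_along(fractions)))
  setorder(out, fraction)
  out[]
}

#' Fit saturation models to a downsampling curve
#'
#' Fits two saturating hyperbolas to the downsampling points by nonlinear
#' least squares: a Michaelis–Menten curve for the duplication rate,
#' `dup(r) = r / (K_dup + r)` (asymptote fixed at 1, so duplication reaches
#' 50% exactly at `r = K_dup` reads per cell — the saturation depth), and a
#' Langmuir curve for the unique-fragment yield,
#' `U(r) = U_max * r / (K_L + r)`. The two fits are independent; the
#' expected unique fragments at saturation is `U(K_dup)`. Fits are
#' initialised from the linearised (double-reciprocal) estimates and refined
#' with `minpack.lm::nlsLM`.
#'
#' @param points A `data.table` from [saturation_curve()] (or any table with
#'   `mean_reads_per_cell`, `mean_dup_rate`, `mean_unique_per_cell`), at
#'   least 3 points with distinct depths.
#' @return A list of class `saturation_fit` with `K_dup`, `U_max`, `K_L`,
#'   `saturation_depth` (= `K_dup`), `expected_unique`
#'   (= `U(saturation_depth)`) and the two `nls` fits.
#' @export
fit_saturation <- function(points) {
  points <- as.data.table(points)
  req <- c("mean_reads_per_cell", "mean_dup_rate", "mean_unique_per_cell")
  stopifnot(all(req %in% names(points)))
  pts <- points[is.finite(mean_reads_per_cell) & mean_reads_per_cell > 0]
  if (uniqueN(pts$mean_reads_per_cell) < 3L)
    stop("need at least 3 points with distinct depths")
  r <- pts$mean_reads_per_cell
  dup <- pts$mean_dup_rate
  u <- pts$mean_unique_per_cell
  # linearised starts: dup = r/(K+r)  =>  K = r (1 - dup) / dup
  pos <- dup > 0 & dup < 1
  k0 <- if (any(pos)) median(r[pos] * (1 - dup[pos]) / dup[pos]) else mean(r)
  fit_dup <- tryCatch(
    minpack.lm::nlsLM(dup ~ r / (K + r), start = list(K = k0),
                      lower = c(K = .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) stop("duplication-rate fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  # Langmuir start from double-reciprocal regression 1/U ~ 1/Umax + (KL/Umax)/r
  oku <- u > 0
  lin <- stats::lm(I(1 / u[oku]) ~ I(1 / r[oku]))
  umax0 <- 1 / max(coef(lin)[1], .Machine$double.eps)
  kl0 <- max(coef(lin)[2] * umax0, 1)
  if (!is.finite(umax0) || umax0 <= 0) umax0 <- max(u) * 2
  fit_u <- tryCatch(
    minpack.lm::nlsLM(u ~ Umax * r / (KL + r),
                      start = list(Umax = umax0, KL = kl0),
                      lower = c(Umax = .Machine$double.eps,
                                KL = .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) stop("unique-yield fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  K_dup <- unname(coef(fit_dup)["K"])
  U_max <- unname(coef(fit_u)["Umax"])
  K_L <- unname(coef(fit_u)["KL"])
  structure(list(K_dup = K_dup, U_max = U_max, K_L = K_L,
                 saturation_depth = K_dup,
                 expected_unique = U_max * K_dup / (K_L + K_dup),
                 fit_dup = fit_dup, fit_unique = fit_u,
                 points = pts),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("saturation fit over ", nrow(x$points), " points\n",
      "  dup(r) = r / (", round(x$K_dup), " + r)",
      "   [50% duplicates at ", round(x$saturation_depth),
      " reads/cell]\n",
      "  U(r) = ", round(x$U_max), " r / (", round(x$K_L), " + r)",
      "   [", round(x$expected_unique),
      " expected unique fragments at saturation]\n", sep = "")
  invisible(x)
}

# round half away from zero (R's round() is half-to-even)
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Per-cell sequencing cost model
#'
#' Computes the cost of a hypothetical experiment sequenced to its
#' saturation depth: `sequencing_cost = n_cells_sequenced * saturation_depth
#' * price_per_million_reads / 1e6`, rounded to the nearest dollar, and
#' `total_cost_per_cell = (assay_price + sequencing_cost) / n_cells`,
#' rounded to 3 decimals — rounding is half-away-from-zero in both cases.
#' The sequencing term always prices a fixed cohort (default 5,000 cells,
#' the standard comparison unit) while the per-cell denominator uses the
#' actually recovered `n_cells`, which may differ (e.g. 5,760 cells from
#' four 1,440-cell plates). When `expected_unique` and `median_frip` are
#' given, the expected unique fragments falling in peaks per cell is also
#' reported.
#'
#' @param assay_price Assay price per run, USD.
#' @param n_cells Recovered cells (per-cell cost denominator).
#' @param saturation_depth Reads per cell at 50% duplication.
#' @param price_per_million_reads Sequencing price, USD per million reads
#'   (default 2.875).
#' @param median_frip Optional median FRIP of the technique.
#' @param expected_unique Optional expected unique fragments per cell at
#'   saturation (see [fit_saturation()]).
#' @param n_cells_sequenced Cells priced in the sequencing term
#'   (default 5000).
#' @return A list of class `cost_breakdown`: `sequencing_cost` (whole USD),
#'   `total_cost_per_cell` (USD, 3 decimals), `expected_unique_in_peaks`
#'   (or `NA`), plus the echoed inputs.
#' @export
estimate_cost <- function(assay_price, n_cells, saturation_depth,
                          price_per_million_reads = 2.875,
                          median_frip = NA_real_,
                          expected_unique = NA_real_,
                          n_cells_sequenced = 5000) {
  stopifnot(n_cells > 0, assay_price >= 0, saturation_depth >= 0,
            price_per_million_reads >= 0)
  sequencing_cost <- round_half_away(
    n_cells_sequenced * saturation_depth * price_per_million_reads / 1e6)
  total_cost_per_cell <- round_half_away(
    (assay_price + sequencing_cost) / n_cells, 3)
  structure(list(sequencing_cost = sequencing_cost,
                 total_cost_per_cell = total_cost_per_cell,
                 expected_unique_in_peaks =
                   if (is.na(median_frip) || is.na(expected_unique))
                     NA_real_ else expected_unique * median_frip,
                 assay_price = assay_price, n_cells = n_cells,
                 saturation_depth = saturation_depth,
                 price_per_million_reads = price_per_million_reads,
                 n_cells_sequenced = n_cells_sequenced,
                 median_frip = median_frip,
                 expected_unique = expected_unique),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("cost model: assay $", format(x$assay_price, big.mark = ","),
      " + sequencing $", format(x$sequencing_cost, big.mark = ","),
      " (", format(x$n_cells_sequenced, big.mark = ","), " cells x ",
      format(x$saturation_depth, big.mark = ","), " reads/cell at $",
      x$price_per_million_reads, "/M)\n  total cost per cell: $",
      format(x$total_cost_per_cell, nsmall = 3), " over ",
      format(x$n_cells, big.mark = ","), " cells\n", sep = "")
  if (!is.na(x$expected_unique_in_peaks))
    cat("  expected unique fragments in peaks per cell: ",
        round(x$expected_unique_in_peaks), "\n", sep = "")
  invisible(x)
}
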