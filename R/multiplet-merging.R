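#' Score candidate barcode pairs by shared fragment coordinates
#'
#' First stage of bead-multiplet detection: restrict to barcodes carrying at
#' least `min_unique` unique fragments, then score every pair of such
#' barcodes that share at least `min_shared` exact `(chrom, start, end)`
#' coordinates. The Jaccard index of a pair is
#' `n_shared / (unique_A + unique_B - n_shared)`. Pairs are found by
#' inverting a coordinate-to-barcodes index (only coordinates seen in two or
#' more eligible barcodes generate work), never by all-pairs set
#' intersection.
#'
#' @param table A [fragment_table()].
#' @param min_unique Minimum unique fragments for a barcode to be considered
#'   (default 1000, the multiplet-detection eligibility floor).
#' @param min_shared Minimum shared coordinates for a pair to be reported
#'   (default 5, a denoising pre-filter on rare chance collisions).
#' @return A `data.table` with columns `barcode_a`, `barcode_b`
#'   (`barcode_a < barcode_b` lexicographically), `n_shared`, `unique_a`,
#'   `unique_b`, `jaccard`, sorted by decreasing `jaccard`.
#' @export
candidate_pairs <- function(table, min_unique = 1000, min_shared = 5) {
  table <- fragment_table(table)
  empty <- data.table(barcode_a = character(), barcode_b = character(),
                      n_shared = integer(), unique_a = integer(),
                      unique_b = integer(), jaccard = numeric())
  if (nrow(table) == 0L) return(empty)
  uniq <- table[, .(n = .N), by = barcode]
  eligible <- uniq[n >= min_unique]
  if (nrow(eligible) < 2L) return(empty)
  sub <- table[barcode %chin% eligible$barcode,
               .(chrom, start, end, barcode)]
  # coordinate -> barcodes index; only multi-barcode coordinates matter
  sub[, coord_id := .GRP, by = .(chrom, start, end)]
  multi <- sub[, if (.N > 1L) .(barcode = barcode), by = coord_id]
  if (nrow(multi) == 0L) return(empty)
  pairs <- multi[multi, on = "coord_id", allow.cartesian = TRUE][
    barcode < i.barcode,
    .(n_shared = .N), by = .(barcode_a = barcode, barcode_b = i.barcode)]
  pairs <- pairs[n_shared >= min_shared]
  if (nrow(pairs) == 0L) return(empty)
  pairs[eligible, unique_a := i.n, on = c(barcode_a = "barcode")]
  pairs[eligible, unique_b := i.n, on = c(barcode_b = "barcode")]
  pairs[, jaccard := n_shared / (unique_a + unique_b - n_shared)]
  pairs[order(-jaccard)]
}

#' Detect barcode multiplets from pair scores
#'
#' Second stage of bead-multiplet detection: the candidate-pair Jaccard
#' scores are thresholded with Otsu's method on the `log10(jaccard)` scale
#' (the background and multiplet populations are separated by orders of
#' magnitude, so the bimodality lives in log space). Pairs above the
#' threshold form edges of a graph whose connected components are the
#' multiplet groups; each group's merged identity is the underscore-joined,
#' lexicographically sorted list of its member barcodes.
#'
#' Otsu assumes both populations are present. When the candidate list is
#' effectively unimodal — the two Otsu classes differ by less than
#' `min_mode_separation` orders of magnitude in mean Jaccard — the split
#' would land inside a single population, so the classifier falls back to
#' the absolute floor `min_jaccard`: chance coordinate collisions between
#' unrelated high-count barcodes sit well below it (about 1e-3) while
#' genuine multiplet pairs sit well above (0.1 and up). The floor is also
#' applied on top of the Otsu threshold in the bimodal regime.
#'
#' @param pairs A pair-score table from [candidate_pairs()].
#' @param n_bins Histogram bins for the Otsu threshold (default 100).
#' @param min_jaccard Absolute Jaccard floor below which a pair is never
#'   merged (default 0.02).
#' @param min_mode_separation Minimum separation (log10 units) between the
#'   mean Jaccard of the two Otsu classes for the split to be accepted as
#'   bimodal (default 1, i.e. one order of magnitude).
#' @return A list of class `merge_map`: `map` (data.table `barcode` ->
#'   `merged`), `threshold` (the threshold used, on the jaccard scale, `NA`
#'   if none was derived), `n_groups` (number of multi-barcode groups) and
#'   `degenerate` (TRUE when all scores were identical and an identity map
#'   was returned with a warning).
#' @export
detect_multiplets <- function(pairs, n_bins = 100, min_jaccard = 0.02,
                              min_mode_separation = 1) {
  empty_map <- data.table(barcode = character(), merged = character())
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(structure(list(map = empty_map, threshold = NA_real_,
                          n_groups = 0L, degenerate = FALSE),
                     class = "merge_map"))
  lj <- log10(pairs$jaccard)
  if (length(unique(lj)) < 2L) {
    warning("all candidate-pair Jaccard scores are identical; ",
            "no threshold can be derived, returning identity map")
    bcs <- sort(unique(c(pairs$barcode_a, pairs$barcode_b)))
    return(structure(list(map = data.table(barcode = bcs, merged = bcs),
                          threshold = NA_real_, n_groups = 0L,
                          degenerate = TRUE),
                     class = "merge_map"))
  }
  thr <- otsu_threshold(lj, n_bins = n_bins)$threshold
  upper <- lj >= thr
  bimodal <- any(upper) && any(!upper) &&
    (mean(lj[upper]) - mean(lj[!upper])) >= min_mode_separation
  if (bimodal) {
    keep <- upper & pairs$jaccard >= min_jaccard
    thr_used <- max(10^thr, min_jaccard)
  } else {
    keep <- pairs$jaccard >= min_jaccard
    thr_used <- min_jaccard
  }
  above <- pairs[keep]
  if (nrow(above) == 0L)
    return(structure(list(map = empty_map, threshold = thr_used,
                          n_groups = 0L, degenerate = FALSE),
                     class = "merge_map"))
  g <- igraph::graph_from_data_frame(
    above[, .(barcode_a, barcode_b)], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  map <- rbindlist(lapply(members, function(m) {
    m <- sort(m)
    data.table(barcode = m, merged = paste(m, collapse = "_"))
  }))
  setkey(map, barcode)
  structure(list(map = map[], threshold = thr_used,
                 n_groups = sum(comp$csize > 1L), degenerate = FALSE),
            class = "merge_map")
}

#' @export
print.merge_map <- function(x, ...) {
  cat("multiplet merge map: ", nrow(x$map), " barcodes in ", x$n_groups,
      " merged group(s); jaccard threshold ",
      if (is.na(x$threshold)) "NA" else signif(x$threshold, 4),
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' Rewrite a fragment table under a multiplet merge map
#'
#' Replaces each barcode by its merged identity (barcodes absent from the
#' map keep their own identity) and re-collapses rows that became identical
#' in `(chrom, start, end, merged)`, summing read counts. Total reads are
#' conserved; the merged group's unique-fragment count is the size of the
#' union of its members' fragment sets.
#'
#' @param table A [fragment_table()].
#' @param map A `merge_map` from [detect_multiplets()], or its `map`
#'   data.table.
#' @return A merged, collapsed [fragment_table()].
#' @export
apply_merge <- function(table, map) {
  table <- fragment_table(table)
  if (inherits(map, "merge_map")) map <- map$map
  map <- as.data.table(map)
  if (nrow(map) == 0L || nrow(table) == 0L) return(table)
  out <- copy(table)
  out[map, barcode := i.merged, on = "barcode"]
  fragment_table(out)
}
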