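#' Correct one observed barcode against a whitelist
#'
#' Implements the Hamming-distance-1 whitelist rule used when processing raw
#' barcode reads: an exact whitelist match is kept as-is; otherwise, if
#' exactly one whitelist barcode lies at Hamming distance 1 from the observed
#' sequence it is substituted (status `corrected`); two or more such
#' neighbours make the observation `ambiguous` and zero make it
#' `uncorrectable` — in both cases no correction is applied.
#'
#' @param observed A single observed barcode string.
#' @param whitelist A whitelist as returned by [read_whitelist()] /
#'   [validate_whitelist()] (any character vector is validated on the fly).
#' @return A list with `observed`, `corrected` (the whitelist barcode or
#'   `NA`), and `status` in `exact`, `corrected`, `ambiguous`,
#'   `uncorrectable`.
#' @export
correct_barcode <- function(observed, whitelist) {
  res <- correct_barcodes(observed, whitelist)
  list(observed = observed, corrected = res$corrected[1],
       status = res$status[1])
}

#' Vectorised Hamming-1 whitelist correction
#'
#' @param observed Character vector of observed barcodes, all of the
#'   whitelist's length.
#' @param whitelist Whitelist character vector (validated).
#' @return A `data.table` with columns `observed`, `corrected` (NA where no
#'   unambiguous match exists) and `status`.
#' @export
correct_barcodes <- function(observed, whitelist) {
  whitelist <- validate_whitelist(whitelist)
  L <- attr(whitelist, "barcode_length")
  observed <- as.character(observed)
  if (any(nchar(observed) != L))
    stop("observed barcode length differs from whitelist length ", L)
  uo <- unique(observed)
  in_wl <- uo %chin% whitelist
  status <- ifelse(in_wl, "exact", NA_character_)
  corrected <- ifelse(in_wl, uo, NA_character_)
  todo <- which(!in_wl)
  if (length(todo)) {
    # enumerate the 3L single-base edits of each unmatched barcode and look
    # them up in the whitelist hash: O(L * |todo|), sub-linear in |whitelist|
    obs_todo <- uo[todo]
    bases <- c("A", "C", "G", "T")
    n_hit <- integer(length(todo))
    hit <- character(length(todo))
    for (pos in seq_len(L)) {
      orig <- substr(obs_todo, pos, pos)
      pre <- substr(obs_todo, 1L, pos - 1L)
      post <- substr(obs_todo, pos + 1L, L)
      for (b in bases) {
        sub <- which(orig != b)
        if (!length(sub)) next
        cand <- paste0(pre[sub], b, post[sub])
        ok <- cand %chin% whitelist
        n_hit[sub[ok]] <- n_hit[sub[ok]] + 1L
        hit[sub[ok]] <- cand[ok]
      }
    }
    status[todo] <- ifelse(n_hit == 1L, "corrected",
                           ifelse(n_hit >= 2L, "ambiguous", "uncorrectable"))
    corrected[todo] <- ifelse(n_hit == 1L, hit, NA_character_)
  }
  lut <- data.table(observed = uo, corrected = corrected, status = status)
  row_idx <- match(observed, uo)
  lut[row_idx]
}

#' Correct the barcodes of a raw read table
#'
#' Applies Hamming-1 whitelist correction to every read of a raw read table
#' (fragment coordinates plus *observed* barcode, one row per read or with a
#' `count` column), collapses the exact/corrected reads into a fragment table
#' under the corrected barcode, and reports how many reads fell into each
#' correction status. Ambiguous and uncorrectable reads are counted but
#' excluded from the returned table.
#'
#' @param reads A data.frame-like with columns `chrom`, `start`, `end`,
#'   `barcode` (observed) and optionally `count` (default 1 per row).
#' @param whitelist Whitelist character vector.
#' @return A list with `fragments` (a [fragment_table()] of valid-barcode
#'   fragments) and `summary` (a `data.table` of status → read count,
#'   all four statuses always present).
#' @export
correct_table <- function(reads, whitelist) {
  reads <- as.data.table(reads)
  if (!"count" %in% names(reads)) reads[, count := 1L]
  res <- correct_barcodes(reads$barcode, whitelist)
  res[, read_count := reads$count]
  statuses <- c("exact", "corrected", "ambiguous", "uncorrectable")
  tallies <- res[, .(reads = sum(read_count)), by = status]
  summary <- tallies[data.table(status = statuses), on = "status"]
  summary[is.na(reads), reads := 0L]
  keep <- res$status %chin% c("exact", "corrected")
  frag <- reads[keep][, barcode := res$corrected[keep]]
  list(fragments = fragment_table(frag), summary = summary[])
}
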