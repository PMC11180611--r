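#' @import data.table
#' @importFrom stats median rbinom rnorm runif setNames coef lm rpois rnbinom
#' @importFrom utils head tail packageVersion
NULL

FRAG_COLS <- c("chrom", "start", "end", "barcode", "count")

# fread wrapper handling gzip via a connection and zero-byte files
fread_flex <- function(path, ...) {
  if (endsWith(path, ".gz")) {
    lines <- readLines(con <- gzfile(path)); close(con)
    if (!length(lines)) return(data.table())
    fread(text = lines, ...)
  } else {
    if (file.size(path) == 0) return(data.table())
    fread(path, ...)
  }
}

#' Construct and validate a fragment table
#'
#' A fragment table is the package's central container: a `data.table` with
#' columns `chrom`, `start`, `end`, `barcode` and `count`, one row per unique
#' fragment per barcode. Coordinates follow the BED convention (0-based,
#' half-open), `barcode` is an opaque token (possibly an underscore-joined
#' merged identity), and `count` is the number of sequencing reads supporting
#' that fragment. Rows identical in `(chrom, start, end, barcode)` are
#' collapsed by summing counts, so collapsing is idempotent and conserves the
#' total read count.
#'
#' @param x A data.frame-like object with at least the five fragment columns,
#'   or a list of equal-length vectors.
#' @param collapse Collapse duplicate `(chrom, start, end, barcode)` rows by
#'   summing counts (default `TRUE`).
#' @param validate Check invariants (`start < end`, `count >= 1`,
#'   non-negative coordinates); default `TRUE`.
#' @return A `data.table` of class `fragment_table`, keyed by
#'   `(chrom, start, end, barcode)`.
#' @export
fragment_table <- function(x = NULL, collapse = TRUE, validate = TRUE) {
  if (is.null(x)) {
    dt <- data.table(chrom = character(), start = integer(), end = integer(),
                     barcode = character(), count = integer())
  } else {
    dt <- as.data.table(x)
    missing_cols <- setdiff(FRAG_COLS, names(dt))
    if (length(missing_cols))
      stop("fragment table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    dt <- dt[, ..FRAG_COLS]
    dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
              end = as.integer(end), barcode = as.character(barcode),
              count = as.integer(count))]
  }
  if (validate && nrow(dt)) {
    if (anyNA(dt))
      stop("fragment table contains missing values")
    if (any(dt$start >= dt$end))
      stop("fragment table violates start < end")
    if (any(dt$start < 0L))
      stop("fragment table contains negative coordinates")
    if (any(dt$count < 1L))
      stop("fragment table contains counts < 1")
  }
  if (collapse && nrow(dt)) {
    dt <- dt[, .(count = sum(count)), by = .(chrom, start, end, barcode)]
  }
  setkeyv(dt, c("chrom", "start", "end", "barcode"))
  setattr(dt, "class", c("fragment_table", class(dt)))
  dt[]
}

#' Read a fragments file
#'
#' Reads a bed-like fragments file (tab-separated: chromosome, start, end,
#' barcode, read count; optionally gzip-compressed; `#`-prefixed comment lines
#' permitted) into a collapsed [fragment_table()]. Both dialects of the format
#' are accepted: files carrying pre-collapsed counts and files with one line
#' per read (a missing fifth column is treated as count 1); duplicate
#' coordinate/barcode rows are collapsed by summing counts either way.
#'
#' @param path Path to the fragments file (`.tsv` or `.tsv.gz`).
#' @param min_count_filter Optional integer; rows whose *collapsed* count is
#'   below this value are dropped.
#' @return A [fragment_table()].
#' @export
read_fragments <- function(path, min_count_filter = NULL) {
  if (!file.exists(path))
    stop("fragments file not found: ", path)
  dt <- fread_flex(path, sep = "\t", header = FALSE, fill = TRUE,
                   colClasses = list(character = 1), showProgress = FALSE)
  # fread drops '#'-prefixed lines only when they lead; strip any remaining
  if (nrow(dt) && is.character(dt[[1]]))
    dt <- dt[!startsWith(dt[[1]], "#")]
  if (nrow(dt) == 0L) {
    out <- fragment_table()
  } else {
    if (ncol(dt) < 4L)
      stop("fragments file has fewer than 4 columns: ", path)
    if (ncol(dt) == 4L) dt[, V5 := 1L]
    dt <- dt[, 1:5]
    setnames(dt, FRAG_COLS)
    start_n <- suppressWarnings(as.integer(dt$start))
    end_n <- suppressWarnings(as.integer(dt$end))
    count_n <- suppressWarnings(as.integer(dt$count))
    bad <- which(is.na(start_n) | is.na(end_n) | is.na(count_n) |
                   start_n >= end_n | start_n < 0L | count_n < 1L)
    if (length(bad))
      stop("malformed fragment record at data line ", bad[1], " of ", path,
           ": '", paste(unlist(dt[bad[1]]), collapse = "\t"), "'")
    dt[, `:=`(start = start_n, end = end_n, count = count_n)]
    out <- fragment_table(dt, collapse = TRUE, validate = FALSE)
  }
  if (!is.null(min_count_filter))
    out <- out[count >= as.integer(min_count_filter)]
  setattr(out, "class", c("fragment_table", "data.table", "data.frame"))
  out[]
}

#' Write a fragments file
#'
#' Writes a fragment table in the tab-separated bed-like dialect, sorted by
#' `(chrom, start, end, barcode)`, gzip-compressed when the path ends in
#' `.gz`. No header line is written, so `read_fragments(write_fragments(t))`
#' is the identity on collapsed tables.
#'
#' @param table A [fragment_table()].
#' @param path Output path.
#' @param header Optional character vector of provenance lines to prepend,
#'   each written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(table, path, header = NULL) {
  table <- fragment_table(table)
  out <- table[order(chrom, start, end, barcode)]
  compress <- if (endsWith(path, ".gz")) "gzip" else "none"
  if (is.null(header)) {
    fwrite(out, path, sep = "\t", col.names = FALSE, compress = compress,
           showProgress = FALSE)
  } else {
    lines <- c(paste0("#", sub("^#", "", header)),
               if (nrow(out)) out[, paste(chrom, start, end, barcode, count,
                                          sep = "\t")])
    con <- if (compress == "gzip") gzfile(path, "wb") else file(path, "wb")
    writeLines(lines, con)
    close(con)
  }
  invisible(path)
}

#' Read a BED interval file
#'
#' Reads BED3+ intervals (0-based, half-open) such as a peak set. A fourth
#' column, when present, is kept as the interval name.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @return A `data.table` with columns `chrom`, `start`, `end` and `name`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path))
    stop("BED file not found: ", path)
  dt <- fread_flex(path, sep = "\t", header = FALSE, fill = TRUE,
                   showProgress = FALSE)
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  if (nrow(dt) && is.character(dt[[1]]))
    dt <- dt[!startsWith(dt[[1]], "#")]
  if (ncol(dt) < 3L)
    stop("BED file has fewer than 3 columns: ", path)
  out <- data.table(chrom = as.character(dt[[1]]),
                    start = suppressWarnings(as.integer(dt[[2]])),
                    end = suppressWarnings(as.integer(dt[[3]])),
                    name = if (ncol(dt) >= 4L) as.character(dt[[4]])
                           else NA_character_)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end)
  if (length(bad))
    stop("malformed BED record at line ", bad[1], " of ", path)
  out[]
}

#' Read a TSS annotation table
#'
#' Reads a tab-separated table of transcription start sites with columns
#' `chrom`, `position` (0-based) and `strand` (`+` or `-`). Duplicate rows
#' are removed.
#'
#' @param path Path to the TSS table; a header line is detected automatically.
#' @return A `data.table` with columns `chrom`, `position`, `strand`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path))
    stop("TSS table not found: ", path)
  dt <- fread_flex(path, sep = "\t", header = "auto", showProgress = FALSE)
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), position = integer(),
                      strand = character()))
  if (ncol(dt) < 3L)
    stop("TSS table has fewer than 3 columns: ", path)
  if (!all(c("chrom", "position", "strand") %in% names(dt)))
    setnames(dt, 1:3, c("chrom", "position", "strand"))
  out <- data.table(chrom = as.character(dt$chrom),
                    position = suppressWarnings(as.integer(dt$position)),
                    strand = as.character(dt$strand))
  if (anyNA(out$position))
    stop("non-integer TSS position in ", path)
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand '", out$strand[bad[1]], "' at line ", bad[1],
         " of ", path, " (must be + or -)")
  unique(out)[]
}

#' Read a barcode whitelist
#'
#' Reads a plain-text whitelist (one barcode per line) and validates that all
#' barcodes have the same length and use only A/C/G/T. Duplicates are removed.
#'
#' @param path Path to the whitelist file (optionally gzipped).
#' @return A character vector of unique barcodes with attribute
#'   `barcode_length`.
#' @export
read_whitelist <- function(path) {
  if (!file.exists(path))
    stop("whitelist file not found: ", path)
  bcs <- readLines(con <- gzfile(path)); close(con)
  bcs <- bcs[nzchar(bcs)]
  validate_whitelist(bcs)
}

#' Validate a barcode whitelist vector
#'
#' @param barcodes Character vector of barcodes.
#' @return The unique barcodes with attribute `barcode_length`.
#' @export
validate_whitelist <- function(barcodes) {
  barcodes <- unique(as.character(barcodes))
  if (length(barcodes) == 0L)
    return(structure(character(), barcode_length = NA_integer_))
  lens <- unique(nchar(barcodes))
  if (length(lens) != 1L)
    stop("whitelist barcodes have mixed lengths: ",
         paste(sort(lens), collapse = ", "))
  if (any(grepl("[^ACGT]", barcodes)))
    stop("whitelist contains non-ACGT characters")
  structure(barcodes, barcode_length = as.integer(lens))
}

#' Total read count of a fragment table
#' @param table A [fragment_table()].
#' @return Sum of the `count` column (0 for an empty table).
#' @export
total_reads <- function(table) {
  if (nrow(table) == 0L) return(0L)
  sum(table$count)
}
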