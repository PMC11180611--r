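library(data.table)

# small deterministic fragment table spread over two chromosomes
random_fragment_dt <- function(n, n_barcodes = 5, seed = 42,
                               max_count = 4) {
  withr::with_seed(seed, {
    start <- sample.int(10000L, n, replace = TRUE)
    data.table(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = start,
               end = start + sample.int(500L, n, replace = TRUE),
               barcode = paste0("BC", sample.int(n_barcodes, n,
                                                 replace = TRUE)),
               count = sample.int(max_count, n, replace = TRUE))
  })
}

write_tmp_fragments <- function(dt, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  fwrite(dt, path, sep = "\t", col.names = FALSE,
         compress = if (gz) "gzip" else "none")
  path
}

# exhaustive Otsu oracle: loop over every interior bin boundary, classify the
# raw values, maximize the between-class variance computed from bin midpoints
otsu_oracle <- function(values, n_bins = 100) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  n <- sum(counts)
  scores <- rep(-Inf, n_bins - 1)
  for (t in seq_len(n_bins - 1)) {
    w0 <- sum(counts[1:t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / w0
    mu1 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / w1
    scores[t] <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  }
  # lowest boundary within fp tolerance of the maximum (ties break low)
  best <- which(scores >= max(scores) * (1 - 1e-9))[1]
  list(threshold = breaks[best + 1], between_var = scores[best])
}

# brute-force Hamming-1 correction: scan the whole whitelist per query
hamming1_oracle <- function(observed, whitelist) {
  L <- nchar(whitelist[1])
  vapply(observed, function(o) {
    if (o %in% whitelist) return("exact")
    d <- vapply(whitelist, function(w) {
      sum(strsplit(o, "")[[1]] != strsplit(w, "")[[1]])
    }, integer(1))
    n1 <- sum(d == 1)
    if (n1 == 1) "corrected" else if (n1 >= 2) "ambiguous"
    else "uncorrectable"
  }, character(1), USE.NAMES = FALSE)
}

# brute-force any-overlap of half-open intervals
overlap_oracle <- function(frag, peaks) {
  vapply(seq_len(nrow(frag)), function(i) {
    any(peaks$chrom == frag$chrom[i] &
          peaks$start < frag$end[i] &
          peaks$end > frag$start[i])
  }, logical(1))
}
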