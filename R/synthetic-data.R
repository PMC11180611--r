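#' Simulation configuration
#'
#' Builds the configuration object for the fragment-level simulator. The
#' defaults describe a small but realistic droplet scATAC-seq experiment:
#' a two-chromosome 100-Mb genome, 200 cells with a library complexity of
#' 5,000 unique molecules each sequenced to ~10,000 reads (reads are drawn
#' with replacement from the molecule pool, so the expected number of unique
#' fragments per cell is `N * (1 - (1 - 1/N)^r)`), 2,000 ambient barcodes
#' carrying ~30 reads of pooled cell-derived chromatin, 5% bead multiplets
#' whose reads are split across 2 bead barcodes, a target FRIP of 0.6, and
#' a 1% per-base barcode substitution error rate.
#'
#' @param chrom_sizes Named numeric vector of chromosome sizes in bp.
#' @param n_tss Number of transcription start sites to place.
#' @param n_peaks Number of peaks; `peak_width` their width in bp.
#' @param frac_tss_peaks Fraction of peaks centred on a TSS.
#' @param n_cells Number of true cells.
#' @param n_noise_barcodes Number of ambient (background) barcodes.
#' @param barcode_length Barcode length L.
#' @param whitelist_size Whitelist size (must exceed the number of barcodes
#'   used).
#' @param mean_reads_per_cell Mean sequencing reads per cell.
#' @param reads_dispersion Negative-binomial size parameter for per-cell read
#'   budgets; `Inf` gives every cell exactly `mean_reads_per_cell` reads.
#' @param library_complexity Unique molecules available per cell (N).
#' @param target_frip Probability that a molecule falls in a peak.
#' @param tss_weight Among peak molecules, probability of drawing from a
#'   TSS-centred peak (drives TSS enrichment).
#' @param frac_short,len_short_mean,len_short_sd,len_long_mean,len_long_sd
#'   Fragment-length mixture: `frac_short` sub-nucleosomal fragments
#'   (mean 80 bp) and the rest mono-nucleosomal (mean 200 bp), truncated to
#'   `len_range`.
#' @param len_range Two-element vector of allowed fragment lengths, bp.
#' @param multiplet_rate Fraction of cells whose reads are split across
#'   `multiplet_k` bead barcodes.
#' @param multiplet_k Bead barcodes per multiplet cell.
#' @param mean_ambient_reads Mean reads per ambient barcode (Poisson).
#' @param error_rate Per-base barcode substitution error probability.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 5e7, chr2 = 5e7),
                       n_tss = 200,
                       n_peaks = 400,
                       peak_width = 500,
                       frac_tss_peaks = 0.5,
                       n_cells = 200,
                       n_noise_barcodes = 2000,
                       barcode_length = 16,
                       whitelist_size = 6000,
                       mean_reads_per_cell = 10000,
                       reads_dispersion = 10,
                       library_complexity = 5000,
                       target_frip = 0.6,
                       tss_weight = 0.5,
                       frac_short = 0.6,
                       len_short_mean = 80, len_short_sd = 20,
                       len_long_mean = 200, len_long_sd = 50,
                       len_range = c(20, 1000),
                       multiplet_rate = 0.05,
                       multiplet_k = 2,
                       mean_ambient_reads = 30,
                       error_rate = 0.01,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(frac_tss_peaks = frac_tss_peaks, target_frip = target_frip,
             tss_weight = tss_weight, frac_short = frac_short,
             multiplet_rate = multiplet_rate, error_rate = error_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  counts <- c(n_tss = n_tss, n_peaks = n_peaks, peak_width = peak_width,
              n_cells = n_cells, barcode_length = barcode_length,
              whitelist_size = whitelist_size,
              mean_reads_per_cell = mean_reads_per_cell,
              library_complexity = library_complexity,
              multiplet_k = multiplet_k)
  if (any(counts <= 0))
    stop("counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  n_beads <- n_cells + round(multiplet_rate * n_cells) * (multiplet_k - 1)
  if (whitelist_size < n_beads + n_noise_barcodes)
    stop("whitelist_size too small for ", n_beads, " bead + ",
         n_noise_barcodes, " ambient barcodes")
  structure(cfg, class = "sim_config")
}

# positions with pairwise separation >= min_gap on one chromosome
place_separated <- function(n, size, min_gap, margin = 0) {
  if (n == 0L) return(integer())
  lo <- margin; hi <- size - margin
  if (n * min_gap > (hi - lo) * 0.8)
    stop("requested features exceed genome capacity")
  kept <- integer()
  for (it in 1:50) {
    cand <- sort(unique(c(kept, as.integer(runif(3L * n, lo, hi)))))
    keep <- logical(length(cand))
    last <- -Inf
    for (i in seq_along(cand)) {
      if (cand[i] - last >= min_gap) { keep[i] <- TRUE; last <- cand[i] }
    }
    kept <- cand[keep]
    if (length(kept) >= n)
      return(sort(kept[sample.int(length(kept), n)]))
  }
  stop("requested features exceed genome capacity")
}

#' Simulate a reference annotation
#'
#' Places `n_tss` transcription start sites (random strand) and `n_peaks`
#' non-overlapping peaks on the configured genome. A fraction
#' `frac_tss_peaks` of peaks is centred on a TSS (these carry the
#' TSS-proximal signal); the rest are placed away from other peaks.
#'
#' @param config A [sim_config()].
#' @return A list with `tss` (data.table `chrom`, `position`, `strand`) and
#'   `peaks` (data.table `chrom`, `start`, `end`, `name`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(config) {
  cs <- config$chrom_sizes
  w <- config$peak_width
  # TSSs separated enough that TSS-centred peaks never overlap
  min_gap <- max(2L * w, 10000L)
  n_per_chrom <- diff(round(seq(0, config$n_tss,
                                length.out = length(cs) + 1L)))
  tss <- rbindlist(lapply(seq_along(cs), function(i) {
    data.table(chrom = names(cs)[i],
               position = place_separated(n_per_chrom[i], cs[i], min_gap,
                                          margin = 2L * w + 2000L),
               strand = sample(c("+", "-"), n_per_chrom[i], replace = TRUE))
  }))
  n_tss_peaks <- min(round(config$frac_tss_peaks * config$n_peaks),
                     nrow(tss))
  tss_idx <- if (n_tss_peaks > 0) sort(sample(nrow(tss), n_tss_peaks))
             else integer()
  tss_peaks <- if (length(tss_idx))
    tss[tss_idx, .(chrom, start = as.integer(position - w %/% 2L),
                   end = as.integer(position - w %/% 2L + w))]
  else data.table(chrom = character(), start = integer(), end = integer())
  n_bg <- config$n_peaks - nrow(tss_peaks)
  n_bg_per <- diff(round(seq(0, n_bg, length.out = length(cs) + 1L)))
  bg_peaks <- rbindlist(lapply(seq_along(cs), function(i) {
    existing <- tss_peaks[chrom == names(cs)[i]]
    # rejection-place background peaks clear of TSS peaks and each other
    got <- data.table(chrom = character(), start = integer(),
                      end = integer())
    need <- n_bg_per[i]
    for (it in 1:50) {
      if (nrow(got) >= need) break
      st <- as.integer(runif(3L * need, w, cs[i] - 2L * w))
      cand <- data.table(chrom = names(cs)[i], start = st,
                         end = st + as.integer(w))
      all_cur <- rbind(existing, got, cand)
      ok <- !overlaps_any(
        data.table(chrom = cand$chrom, start = cand$start, end = cand$end,
                   barcode = "x", count = 1L),
        rbind(existing, got))
      cand <- cand[ok]
      # drop mutual overlaps among the new candidates (greedy by start)
      setorder(cand, start)
      keep <- logical(nrow(cand)); last_end <- -1L
      for (j in seq_len(nrow(cand))) {
        if (cand$start[j] >= last_end) { keep[j] <- TRUE
          last_end <- cand$end[j] }
      }
      got <- rbind(got, cand[keep])
    }
    if (nrow(got) < need)
      stop("requested features exceed genome capacity")
    got[seq_len(need)]
  }))
  peaks <- rbind(tss_peaks, bg_peaks)
  setorder(peaks, chrom, start)
  peaks[, name := sprintf("peak_%05d", .I)]
  list(tss = tss[], peaks = peaks[])
}

# draw n fragment lengths from the truncated two-component normal mixture
draw_lengths <- function(n, config) {
  if (n == 0L) return(integer())
  short <- runif(n) < config$frac_short
  len <- ifelse(short,
                rnorm(n, config$len_short_mean, config$len_short_sd),
                rnorm(n, config$len_long_mean, config$len_long_sd))
  bad <- which(len < config$len_range[1] | len > config$len_range[2])
  while (length(bad)) {
    sh <- short[bad]
    len[bad] <- ifelse(sh,
                       rnorm(length(bad), config$len_short_mean,
                             config$len_short_sd),
                       rnorm(length(bad), config$len_long_mean,
                             config$len_long_sd))
    bad <- bad[len[bad] < config$len_range[1] |
                 len[bad] > config$len_range[2]]
  }
  as.integer(round(len))
}

# random unique barcodes over ACGT
draw_barcodes <- function(n, L) {
  out <- character(0)
  while (length(out) < n) {
    m <- matrix(sample(c("A", "C", "G", "T"), (n - length(out) + 16L) * L,
                       replace = TRUE), ncol = L)
    out <- unique(c(out, apply(m, 1, paste, collapse = "")))
  }
  out[seq_len(n)]
}

#' Simulate a full scATAC-seq experiment with known ground truth
#'
#' Generates a reference annotation, a whitelist, per-cell molecule pools and
#' the observed read table. Each cell owns `library_complexity` (N) unique
#' molecules: a molecule lands in a peak with probability `target_frip`
#' (an integer cut site near the peak centre plus an integer mixture length,
#' so exact coordinate collisions between unrelated barcodes are possible
#' but rare) and otherwise gets uniform background coordinates. Sequencing draws each cell's read
#' budget with replacement from its molecule pool — the duplication
#' mechanism, with expected unique fragments `N * (1 - (1 - 1/N)^r)`.
#' Multiplet cells split their reads uniformly across `multiplet_k` bead
#' barcodes sharing one molecule pool; ambient barcodes draw small Poisson
#' read counts from the pooled cell molecule distribution; observed barcodes
#' carry independent per-base substitution errors.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `config`, `tss`,
#'   `peaks`, `whitelist`, `reads` (observed-barcode fragment table, the
#'   simulator's primary output), `fragments` (error-free truth fragment
#'   table keyed by bead barcode), `cell_beads` (data.table `cell_id`,
#'   `barcode`, `is_multiplet`), `multiplet_groups` (data.table `cell_id`,
#'   `merged`), `ambient_barcodes`, and `per_cell` (data.table `cell_id`,
#'   `n_molecules`, `reads_budget`, `unique_fragments`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  ref <- simulate_reference_impl(config)
  cs <- config$chrom_sizes
  n_cells <- config$n_cells
  N <- config$library_complexity
  L <- config$barcode_length

  # ---- barcodes -----------------------------------------------------------
  whitelist <- validate_whitelist(draw_barcodes(config$whitelist_size, L))
  n_mult <- round(config$multiplet_rate * n_cells)
  k <- if (n_mult > 0) config$multiplet_k else 1L
  n_beads <- n_cells + n_mult * (k - 1L)
  picked <- sample(whitelist, n_beads + config$n_noise_barcodes)
  bead_bcs <- picked[seq_len(n_beads)]
  ambient_bcs <- picked[n_beads + seq_len(config$n_noise_barcodes)]
  mult_cells <- if (n_mult > 0) sort(sample(n_cells, n_mult)) else integer()
  beads_per_cell <- rep(1L, n_cells); beads_per_cell[mult_cells] <- k
  cell_beads <- data.table(
    cell_id = rep(seq_len(n_cells), beads_per_cell),
    barcode = bead_bcs[seq_len(sum(beads_per_cell))])
  cell_beads[, is_multiplet := cell_id %in% mult_cells]

  # ---- peak classes ---------------------------------------------------------
  peaks <- ref$peaks
  n_peaks <- nrow(peaks)
  # peaks were reordered by coordinate; recover TSS-centred ones by overlap
  is_tss_peak <- if (nrow(ref$tss) && n_peaks) {
    overlaps_any(
      data.table(chrom = peaks$chrom, start = peaks$start, end = peaks$end),
      data.table(chrom = ref$tss$chrom, start = ref$tss$position,
                 end = ref$tss$position + 1L))
  } else rep(FALSE, n_peaks)

  # ---- molecule pools per cell ----------------------------------------------
  # In-peak molecules get an integer cut site near the peak centre and an
  # integer length from the mixture; exact (start, end) collisions between
  # unrelated cells are therefore possible but rare, as in real Tn5 data.
  n_mol <- n_cells * N
  in_peak <- runif(n_mol) < config$target_frip
  tss_peak_ids <- which(is_tss_peak)
  bg_peak_ids <- which(!is_tss_peak)
  np <- sum(in_peak)
  use_tss <- runif(np) < config$tss_weight
  if (!length(tss_peak_ids)) use_tss[] <- FALSE
  if (!length(bg_peak_ids)) use_tss[] <- TRUE
  pk <- integer(np)
  if (any(use_tss))
    pk[use_tss] <- tss_peak_ids[sample.int(length(tss_peak_ids),
                                           sum(use_tss), replace = TRUE)]
  if (any(!use_tss))
    pk[!use_tss] <- bg_peak_ids[sample.int(length(bg_peak_ids),
                                           sum(!use_tss), replace = TRUE)]
  mol <- data.table(cell_id = rep(seq_len(n_cells), each = N),
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_)
  if (np > 0) {
    centers <- (peaks$start[pk] + peaks$end[pk]) %/% 2L
    cut1 <- as.integer(round(rnorm(np, centers, config$peak_width / 6)))
    plen <- draw_lengths(np, config)
    pstart <- pmax(cut1, 0L)
    pend <- pstart + plen
    pmaxend <- as.integer(cs[peaks$chrom[pk]])
    clip <- pend > pmaxend
    pstart[clip] <- pmax(0L, pmaxend[clip] - plen[clip])
    pend[clip] <- pmaxend[clip]
    mol[which(in_peak), `:=`(chrom = peaks$chrom[pk], start = pstart,
                             end = pend)]
  }
  nb <- n_mol - np
  if (nb > 0) {
    bg_chrom <- sample(names(cs), nb, replace = TRUE,
                       prob = cs / sum(cs))
    bg_len <- draw_lengths(nb, config)
    bg_start <- as.integer(floor(runif(nb) *
                                   (cs[bg_chrom] - bg_len)))
    mol[which(!in_peak), `:=`(chrom = bg_chrom, start = bg_start,
                              end = bg_start + bg_len)]
  }

  # ---- sequencing: draw reads with replacement from molecule pools --------
  budgets <- if (is.infinite(config$reads_dispersion))
    rep(as.integer(config$mean_reads_per_cell), n_cells)
  else
    pmax(1L, rnbinom(n_cells, mu = config$mean_reads_per_cell,
                     size = config$reads_dispersion))
  read_cell <- rep(seq_len(n_cells), budgets)
  total_reads_cells <- length(read_cell)
  mol_idx <- (read_cell - 1L) * N +
    sample.int(N, total_reads_cells, replace = TRUE)
  # bead barcode per read: singlets use their one bead, multiplets split
  n_beads_per <- beads_per_cell[read_cell]
  bead_pick <- as.integer(ceiling(runif(total_reads_cells) * n_beads_per))
  first_bead <- cumsum(c(0L, beads_per_cell))[read_cell] + bead_pick
  read_barcode <- cell_beads$barcode[first_bead]
  reads_cells <- data.table(chrom = mol$chrom[mol_idx],
                            start = mol$start[mol_idx],
                            end = mol$end[mol_idx],
                            barcode = read_barcode)

  # ---- ambient barcodes ----------------------------------------------------
  amb_n <- pmax(1L, rpois(config$n_noise_barcodes,
                          config$mean_ambient_reads))
  amb_mol <- sample.int(n_mol, sum(amb_n), replace = TRUE)
  reads_ambient <- data.table(chrom = mol$chrom[amb_mol],
                              start = mol$start[amb_mol],
                              end = mol$end[amb_mol],
                              barcode = rep(ambient_bcs, amb_n))
  reads_all <- rbind(reads_cells, reads_ambient)

  # ---- truth fragment table (error-free barcodes) --------------------------
  truth <- fragment_table(reads_all[, .(chrom, start, end, barcode,
                                        count = 1L)])

  # ---- barcode sequencing errors -------------------------------------------
  # independent per-base substitutions, applied position by position
  observed <- reads_all$barcode
  if (config$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    n_obs <- length(observed)
    for (p in seq_len(L)) {
      hit <- which(runif(n_obs) < config$error_rate)
      if (!length(hit)) next
      cur <- match(substr(observed[hit], p, p), bases)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      substr(observed[hit], p, p) <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  reads_obs <- fragment_table(data.table(chrom = reads_all$chrom,
                                         start = reads_all$start,
                                         end = reads_all$end,
                                         barcode = observed, count = 1L))

  # ---- bookkeeping ----------------------------------------------------------
  per_cell_unique <- truth[cell_beads, on = "barcode"][
    , .(unique_fragments = uniqueN(paste(chrom, start, end))), by = cell_id]
  per_cell <- data.table(cell_id = seq_len(n_cells),
                         n_molecules = N,
                         reads_budget = budgets)
  per_cell[per_cell_unique, unique_fragments := i.unique_fragments,
           on = "cell_id"]
  multiplet_groups <- cell_beads[is_multiplet == TRUE,
                                 .(merged = paste(sort(barcode),
                                                  collapse = "_")),
                                 by = cell_id]
  structure(list(config = config, tss = ref$tss, peaks = ref$peaks,
                 whitelist = whitelist, reads = reads_obs,
                 fragments = truth, cell_beads = cell_beads,
                 multiplet_groups = multiplet_groups,
                 ambient_barcodes = ambient_bcs, per_cell = per_cell),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("simulated scATAC experiment: ", x$config$n_cells, " cells (",
      nrow(x$multiplet_groups), " multiplets), ",
      length(x$ambient_barcodes), " ambient barcodes, ",
      total_reads(x$reads), " reads / ", nrow(x$fragments),
      " unique truth fragments\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the standard file set: `fragments.tsv.gz` (observed barcodes),
#' `peaks.bed`, `tss.tsv`, `whitelist.txt`, truth tables
#' (`truth_fragments.tsv.gz`, `cell_beads.tsv`, `multiplet_groups.tsv`,
#' `per_cell.tsv`, `ambient_barcodes.txt`) and the resolved configuration
#' (`config.yaml`).
#'
#' @param truth A `sim_truth` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fragments(truth$reads, file.path(dir, "fragments.tsv.gz"))
  write_fragments(truth$fragments, file.path(dir, "truth_fragments.tsv.gz"))
  fwrite(truth$peaks, file.path(dir, "peaks.bed"), sep = "\t",
         col.names = FALSE)
  fwrite(truth$tss, file.path(dir, "tss.tsv"), sep = "\t")
  writeLines(as.character(truth$whitelist),
             file.path(dir, "whitelist.txt"))
  writeLines(truth$ambient_barcodes,
             file.path(dir, "ambient_barcodes.txt"))
  fwrite(truth$cell_beads, file.path(dir, "cell_beads.tsv"), sep = "\t")
  fwrite(truth$multiplet_groups, file.path(dir, "multiplet_groups.tsv"),
         sep = "\t")
  fwrite(truth$per_cell, file.path(dir, "per_cell.tsv"), sep = "\t")
  cfg <- truth$config
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
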