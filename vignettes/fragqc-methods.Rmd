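---
title: "Methods: fragment-file QC, multiplet merging and saturation economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-file QC, multiplet merging and saturation economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragqc)
library(data.table)
```

# Scope

`fragqc` implements the computational core of a single-cell ATAC-seq
preprocessing and quality-control workflow that operates on the bed-like
*fragments file* (chromosome, 0-based half-open interval, cell barcode, read
count). Alignment, adapter trimming, peak calling and all downstream topic
modelling / annotation are out of scope: peaks and TSS annotations are
inputs. Everything here is testable without sequencing data because the
package ships a fragment-level simulator with complete ground truth.

Coordinates are 0-based half-open (BED) throughout. Any read-position
shifting conventions applied by upstream aligner pipelines are assumed
already applied in the input fragments; the package never re-shifts.

# Barcode error correction

Observed barcodes are corrected against a whitelist at Hamming distance at
most 1: an exact match stands; otherwise the 3L single-base edits of the
observed sequence are looked up in a whitelist hash (sub-linear in whitelist
size). Exactly one hit corrects the barcode; two or more hits are
*ambiguous* and zero hits *uncorrectable* — neither is corrected, and both
are excluded from the valid-barcode fragment table while still being
counted. Leaving ambiguous reads uncorrected is a deliberate, conservative
choice: without per-base quality scores (FASTQ processing is out of scope)
there is no principled way to rank equidistant candidates, and a
deterministic rule keeps runs reproducible.

# Bead multiplet detection and merging

Droplet platforms that overload beads produce *barcode multiplets*: several
bead barcodes attached to one nucleus, yielding distinct barcodes with
nearly identical fragment sets. Detection proceeds in two stages.

**Pair scoring.** Barcodes with at least `min_unique = 1000` unique
fragments are eligible. For every eligible pair sharing at least
`min_shared = 5` exact `(chrom, start, end)` coordinates, the Jaccard index
`shared / (uniqueA + uniqueB - shared)` is computed. Pairs are found by
inverting a coordinate-to-barcode index, so only coordinates observed in
two or more eligible barcodes generate work; the all-pairs intersection is
never formed. `min_shared` is a denoising pre-filter: chance exact
collisions between unrelated deep barcodes are rare but nonzero, and pairs
sharing fewer than a handful of coordinates carry no evidence either way.

**Thresholding and merging.** Genuine multiplet pairs have Jaccard scores
of roughly 0.1–1; chance-collision pairs sit around 10^-3. Because the two
populations are separated by orders of magnitude, Otsu's threshold is
computed on `log10(jaccard)`. Pairs above the threshold are edges of a
graph; connected components become merge groups (transitively, so a chain
A–B, B–C merges into `A_B_C`), named by the underscore-joined sorted member
barcodes. Merging rewrites the fragment table under the group identity and
re-collapses, so total reads are conserved and a group's unique count is
exactly the union of its members' fragment sets.

Otsu's criterion assumes both populations are present. In two regimes it
is not decidable: when every candidate pair is a true multiplet (no chance
collisions survived `min_shared`) the split would land *inside* the
multiplet mode and discard real multiplets, and when no multiplets exist it
would slice the background mode and merge unrelated cells. `detect_multiplets`
therefore accepts the Otsu split only if the two classes' mean Jaccard
differs by at least one order of magnitude (`min_mode_separation = 1` in
log10 units). Otherwise the candidate list is treated as unimodal and an
absolute floor `min_jaccard = 0.02` decides: it sits roughly an order of
magnitude above chance-collision scores and an order below genuine
multiplet scores, so it is insensitive to its exact value. The floor is
also applied on top of an accepted Otsu threshold. If all candidate scores
are exactly identical no threshold exists; the function warns and returns
an identity map.

# Per-barcode quality metrics

* `total_reads`, `unique_fragments`, and the duplicate rate
  `1 - unique/total`. (The duplicate *rate* is the complement of the
  unique fraction; a library sequenced to saturation has rate 0.5, i.e.
  half its reads are copies of already-seen fragments.)
* **TSS enrichment** follows the ENCODE-style recipe: each unique fragment
  contributes its two Tn5 insertion sites (`start` and `end - 1`); sites
  within `window = 2000` bp of a TSS are binned by signed offset (negated
  on minus-strand TSSs, counted once per overlapping window). The
  background is the mean insertion count over the outermost `flank = 100`
  bp at each window end plus `pseudocount = 0.1`; the score is the mean of
  count/background over the central ±`center = 50` bp. Only the 2,000-bp
  window is fixed by convention upstream; flank, centre and pseudocount
  follow common practice and are exposed as parameters. The score is
  depth-free in the dense regime; at very low depth the pseudocount
  (which prevents division by zero for sparse barcodes) biases scores
  downward — this is intentional, since a 10-fragment barcode cannot
  demonstrate enrichment.
* **FRIP**: the fraction of a barcode's unique fragments overlapping any
  peak by at least 1 bp (half-open on both sides; multi-peak overlaps count
  once). Any-overlap mirrors how fragments are counted into region
  matrices downstream.
* **Fragment length**: medians over unique fragments, not read-weighted.
* **Cross-file agreement** (`compare_fragment_files`): per-barcode Jaccard
  of coordinate sets between two tables, summarised as the mean weighted by
  the barcode's union fragment count, so deep barcodes dominate the way
  aligned fragments do in a whole-file comparison.

# Cell calling

Barcodes with fewer than `min_unique_floor = 10` unique fragments are
dropped outright. Among the rest, Otsu thresholds are derived separately on
`log10(unique_fragments)` — fragment counts are log-bimodal, as knee plots
show — and on TSS enrichment on the linear scale, where scores are already
normalized ratios. A barcode is a cell only if it passes *both*: high
count alone (e.g. an ambient-soup aggregate) or high enrichment alone
(a sparse but clean barcode) is insufficient. Both Otsu runs use
`n_bins = 100`; the two runs share binning by default but both are
parameters. No doublet detection is attempted here.

# Downsampling and the saturation model

`downsample_reads` thins reads by independent Bernoulli retention
(`Binomial(count, p)` per collapsed row), matching the behaviour of
seed-stable FASTQ subsamplers; it is order-independent, so downsampling
commutes with collapsing in distribution. Target mode derives one global
`p = target * |cells| / total_cell_reads` from the cell set's mean depth —
whole-file downsampling to a common reads-per-cell, not per-cell exact
subsampling. Upsampling is refused.

`saturation_curve` subsamples a cell-restricted table over a fraction grid
and records mean reads per cell, mean per-cell duplication rate and mean
unique fragments per cell; the fraction-1 point is computed on the full
data. `fit_saturation` then fits, independently:

* duplication: `dup(r) = r / (K_dup + r)` — a Michaelis–Menten curve with
  the asymptote pinned at 1, because duplication must approach 100% at
  infinite depth; this makes "50% duplicates at `r = K_dup`" exact, and
  `K_dup` *is* the saturation depth;
* unique yield: `U(r) = U_max * r / (K_L + r)` — a Langmuir curve whose
  plateau `U_max` estimates library complexity.

The two curves are deliberately not forced to share parameters: each is a
two- (or one-) parameter approximation to the exact sampling model
`E[unique] = N(1 - (1 - 1/N)^r)`, and tying them would degrade both fits.
Nonlinear least squares (`minpack.lm::nlsLM`, relative tolerance 1e-10,
up to 200 iterations) is initialised from the linearised double-reciprocal
estimates, which makes convergence a formality on saturating data. The
expected unique yield at saturation is `U(K_dup)`.

Under the exact sampling model, 50% duplication occurs at `r = xN` where
`(1 - e^(-x))/x = 1/2`, i.e. `x = 1.5936`. The fitted `K_dup` recovers
`1.5936 N` to within a few percent across `N` from 10^3 to 10^4 — the
hyperbolic approximation is biased slightly upward (about +2% in our
checks) because the true duplication curve is not exactly hyperbolic.

# Cost model

A hypothetical experiment is priced as
`sequencing_cost = n_cells_sequenced * saturation_depth * price / 1e6`
(default price $2.875 per million reads), rounded to the nearest dollar,
and `total_cost_per_cell = (assay_price + sequencing_cost) / n_cells`,
rounded to 3 decimals. Rounding is half-away-from-zero in both places
(977.5 → 978; 0.2746 → 0.275), which R's banker's rounding would not give.
The sequencing term prices a fixed 5,000-cell cohort — the standard
comparison unit — while the per-cell denominator uses the actually
recovered cell count, which may differ (plate-based assays recover
e.g. 5,760 cells from four 1,440-cell plates). Multiplying the expected
unique yield by a technique's median FRIP gives the expected *usable*
(in-peak) fragments per cell.

# Read-loss waterfall

`waterfall` decomposes total raw reads into five disjoint fractions:
lost upstream (barcode/mapping), in non-cell barcodes, duplicates within
cells (`count - 1` per unique fragment — the first read of each fragment is
the unique one, which keeps the categories disjoint), unique in cells
outside peaks, and unique in cells inside peaks. The last is the
*sequencing efficiency*. The five fractions sum to 1 exactly by
construction. The decomposition is per sample; per-technology summaries
should weight by total reads.

# The simulator

`simulate_experiment` generates data whose statistical structure matches
what the QC stack measures:

* a two-chromosome 100-Mb genome with 200 TSSs and 400 non-overlapping
  500-bp peaks, half centred on TSSs;
* 200 cells, each owning `N = 5000` unique molecules; a molecule falls in
  a peak with probability `target_frip = 0.6` (TSS-centred peaks taking
  `tss_weight = 0.5` of peak molecules, which is what creates TSS
  enrichment) and otherwise gets uniform background coordinates;
* fragment lengths from a truncated normal mixture — 60% sub-nucleosomal
  (mean 80 bp, sd 20) and 40% mono-nucleosomal (mean 200 bp, sd 50),
  truncated to 20–1000 bp — giving a realistic length profile and median;
* sequencing draws each cell's read budget (negative binomial, mean
  10,000, size 10; `Inf` gives fixed budgets) *with replacement* from its
  molecule pool. This is the duplication mechanism, chosen because it has
  the closed form `E[unique] = N(1 - (1 - 1/N)^r)` that the saturation
  module's tests check against;
* 5% of cells are bead multiplets whose reads are split uniformly across
  2 bead barcodes sharing one molecule pool;
* 2,000 ambient barcodes draw Poisson(30) reads from the pooled cell
  molecule distribution — ambient chromatin mirrors the cell population's
  composition (similar FRIP and per-fragment TSS behaviour) but at trace
  depth;
* observed barcodes carry independent per-base substitution errors at
  rate 0.01 against a 6,000-entry whitelist of random 16-mers.

In-peak cut sites are integer-rounded Gaussians around the peak centre
(sd = width/6), so exact coordinate collisions between unrelated cells
occur at a realistic low rate (of order one shared fragment per deep cell
pair) — enough to exercise the multiplet detector's background class
without swamping it.

What the simulator does **not** emulate: genome sequence and Tn5 sequence
bias, chromatin-state structure beyond a flat peak set, cell-type mixtures,
two-nucleus doublets (as opposed to bead multiplets), mappability losses,
and quality-score-dependent errors. Passing tests therefore demonstrate
the *estimators'* correctness against known generative truth, not
performance on any particular tissue or platform.

# Problem sizes and numerical choices

The test and acceptance runs use: 100 random instances of up to 10^4
values for the Otsu oracle; 200 cells (N = 5000, 10,000 reads/cell, fixed
budgets) for multiplet precision/recall and 300 cells for the
zero-multiplet control; 500 cells plus 5,000 ambient barcodes
(N = 10^4, 20,000 reads/cell) for cell calling; 100 cells at
N ∈ {10^3, 10^4} sequenced to 2.5N reads over an 8-point fraction grid for
saturation recovery; whitelists of 2,000–3,000 entries for the correction
oracle. These sizes put Monte-Carlo noise well inside the tolerances
asserted (3% for closed-form means, 10% for fitted saturation depth)
while keeping a full run to a few minutes on one CPU.

Ties in Otsu's criterion (including floating-point near-ties, compared at
relative tolerance 1e-9) break toward the lower bin boundary. Degenerate
inputs error early and explicitly: constant Otsu input, empty TSS
annotations, empty cell sets, upsampling requests, raw-read totals smaller
than the table they claim to contain.

# Known limitations

* The TSS enrichment score weights each unique fragment once; read counts
  are deliberately ignored, so PCR-duplicated fragments cannot inflate
  enrichment.
* `candidate_pairs` memory grows with the number of coordinate collisions;
  pathological inputs in which thousands of barcodes share one coordinate
  would expand quadratically in that coordinate's group.
* The cost model takes prices as given and models no doublet-rate
  dependence on loading.
* Saturation extrapolation inherits the Michaelis–Menten approximation
  bias noted above; depths far beyond the fitted range are extrapolations
  and should be read as such.
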