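---
title: "Models and methods: clonal confounding in EB CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: clonal confounding in EB CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebscreen)
```

This vignette explains the models behind `ebscreen`: what the synthetic
screen generator simulates and why, how each analysis step is defined, the
numerical conventions we fixed where the workflow left room, and what the
package's tests do and do not demonstrate about real data.

## 1. The clonal-dynamics generator

### Clone sizes and jackpotting

A mosaic EB is founded by `founders_per_eb` cells (default 500) drawn from
the guide library with probability proportional to each guide's library
frequency. We do not simulate growth kinetics; what we target
is the *end state*: final clone sizes are extremely skewed, with
2–10 clones covering 90% of an EB and exceeding the remaining clones by two
to three orders of magnitude. We model this end state directly as a
symmetric Dirichlet over founders with a single concentration knob
$\alpha$ (`clone_concentration`), realised multinomially over the EB's
final cell count (uniform on 10,000–30,000 cells). A birth–death simulation
would add parameters without adding testable structure, and whether the
skew arises from growth-rate variance or cell death is biologically
unresolved — the Dirichlet knob is agnostic.

$\alpha$ was calibrated once by Monte-Carlo: with 500 founders,
$\alpha = 0.005$ gives a median of 6 clones (IQR 4–7) covering 90% of an
EB's guide reads, a top-to-median clone ratio of roughly $10^2$, and about
20–30 clones with any cells at all — the jackpot regime. Dominance is
monotone in $1/\alpha$, which the test suite checks over a seed grid;
$\alpha \to \infty$ recovers the uniform limit where
$\lceil 0.9\,K \rceil$ of $K$ clones are needed.

### Library frequencies

Real guide libraries are not uniform: cloning bias plus fitness differences
during stem-cell culture spread guide abundances over two to three orders
of magnitude (complete dropout of essential-gene guides included). We give
each guide a log-normal relative frequency (`freq_sdlog = 1.5`, a ~400-fold
95% range). This spread is what makes *aggregate* guide frequencies highly
reproducible between replicate screens ($r > 0.9$) even while *per-EB*
dominant guides are essentially random — the signature separating a
bottlenecked readout from a bottlenecked library.

### Composition, effects, silencing, counts

Each EB draws its cell-type composition from
$\mathrm{Dirichlet}(\kappa \cdot \pi)$ around a ten-type baseline $\pi$
(`default_eb_composition()`), with `eb_heterogeneity` $\kappa = 30$: for a
type at 12% this gives a per-EB standard deviation of about 6 percentage
points, the "considerable variation" regime in which individual monoclonal
EBs of identical genotype still differ visibly in composition. A
perturbation effect is a vector of multiplicative factors on the per-EB
composition, renormalised — the simplest model producing both enrichment
and depletion.

Captured cells (default 300/EB for mosaic, a 10x-scale capture) are drawn
without replacement. Guide and barcode UMIs per expressing cell are
zero-truncated negative binomial (mean 12, size 2); reads per UMI are
geometric (mean 40), so reads ≥ UMIs entrywise by construction. Silencing
is all-or-none per cell with cell-type-dependent detection probability
(default 0.9 everywhere), matching reporter-negative/positive dichotomies
rather than partial expression. Ambient contamination adds a single
foreign-guide UMI per affected cell (rate 0.02) — the floating-cell
artefact that the 1%-prevalence guide filter is designed to remove.

The generator does **not** simulate transcriptomes. Cell-type labels (and
an optional Gaussian-blob embedding for neighbourhood tests) are the
outputs; gene-level count fixtures for the pseudobulk comparison are built
in test code. Consequently the simulator says nothing about
normalisation, clustering or annotation quality on real data — passing
tests demonstrate correctness of the *screen statistics and deconvolution
logic* given labels, not of upstream processing.

## 2. Guide assignment and quality control

The two assignment rules are implemented with the comparison directions
exactly as printed — `>=` inclusive for the UMI and read floors, `<`
strict for the read-dependent upper bound — and ties therefore resolve by
the printed inequality. The second `alltf` inequality makes high-UMI/
low-read cells unassignable; that is intentional (chimeric artefacts). We
apply the read thresholds to the read matrix as supplied, without asking
whether reads were deduplicated upstream.

QC consumes externally supplied metrics (doublet scores are inputs, never
computed). For the top-UMI rule, "exceeding the top 0.5%" is implemented
as strictly above the inverse-ECDF (type-1) quantile at $1 - q$, so that on
distinct values exactly $\lfloor nq \rfloor$ cells are removed — with 1,000
cells and $q = 0.005$, the five highest. Per-lane threshold adjustment is
left to the caller via arguments; the package does not automate it.

## 3. Clonotype deconvolution

The pipeline follows the organoid-barcode workflow step by step. Points we
had to pin down:

* **Hamming correction**: barcodes failing both count floors are removed;
  a surviving barcode with exactly one higher-abundance neighbour at
  Hamming distance 1 merges into it. A barcode equidistant from two
  parents stays unmerged and is reported — guessing would corrupt two
  clonotypes to rescue one barcode.
* **"Scaling the normalised counts"** before barcode–barcode correlation
  is read as per-column standardisation (zero mean, unit variance), the
  standard meaning in this workflow; since Pearson correlation is
  invariant to affine rescaling, this matters only for documentation of
  the zero-variance case, which is reported and never merged.
* **Correlations are computed over all barcode-assigned cells**, not only
  multi-barcode cells, matching the order of operations in which
  barcodeless cells are excluded first and multi-barcode cells are
  excluded *after* the correlation decides their fate.
* **Transitive closure**: the merge rule is stated pairwise; we close it
  transitively (union–find) so clonotypes form a partition.
* Cells are never silently dropped: every cell carries a status
  (`assigned`, `too_small`, `ambiguous_multi_bc`, `no_bc`).
* The barcode-universe floor `min_log2_reads` is a preset (15 for
  10x-depth data, 10 for shallower assays), not a constant.

## 4. Composition screening and its null

The screen statistic is the plain goodness-of-fit chi-square
$\sum (O - E)^2 / E$ of a unit's cell-type counts against the pooled-NTC
background proportions, with the full category set kept (zeros allowed in
observed; categories with zero background count are dropped with a warning,
fixing the degrees of freedom). Units are targets (three guides pooled) and
random NTC triplet groups built to mimic them; both are downsampled without
replacement to 100 cells; the empirical significance cutoff is the 0.05
quantile (type-7, fixed for reproducibility) of the NTC-group p-values.
NTC groups are fixed per seed and the seed is recorded. The background
includes a tested NTC group's own cells, as the pooled-background
definition implies.

### Why mosaic screens inflate

Under jackpotting a target's 100 downsampled cells descend from a handful
of EBs, so its composition is a mixture of a few heterogeneous per-EB
draws — wildly overdispersed relative to the multinomial sampling the
chi-square assumes. With *no* simulated effects, far more than $2q$ of
targets reach nominal $p < q$, and both targets and NTC groups rise far
off the QQ diagonal (`autoplot()` on a `screen_test` shows this). The
empirical NTC cutoff absorbs much of the inflation — NTC groups jackpot
too — so the *empirically* flagged set hovers near the $q$ fraction in a
null simulation; what betrays it is irreproducibility: empirically flagged
sets from two replicate simulations share almost nothing (Jaccard < 0.2)
even though aggregate guide frequencies correlate at $r > 0.9$. Both
readouts (nominal fraction and empirical flags) are reported; the
calibration statements in the test suite are made on the nominal rule,
whose null distribution is exact.

### The clonotype-aware rescue

With monoclonal EBs the clone is observable, and `screen_composition(...,
clonotype_aware = TRUE)` replaces the analytic chi-square null with an
NTC-clonotype resampling null: each unit's statistic is compared with
statistics of randomly drawn, clonotype-count-matched sets of NTC
clonotypes, processed identically (pooled, downsampled, tested against the
background). One subtlety is essential: a target is independent of the NTC
background, so its null draws must be compared against the background
*minus the drawn clonotypes* — otherwise the null statistics are shrunk by
self-inclusion and the test inflates for clonotype-rich targets (we
measured roughly a doubling of the nominal rate before this correction).
NTC-group units, which genuinely live inside the background, keep the full
background. With the exclusion in place the flagged fraction returns to
the binomial neighbourhood of $q$ across independent simulated cohorts.
Resampling p-values use the add-one estimator with 199 draws, so the
attainable floor is 1/200.

## 5. Other statistics

* **Fraction tests** across clonotypes use the two-sided Wilcoxon rank-sum
  test (exact for small untied samples, normal approximation with tie
  correction otherwise), verified against exhaustive enumeration of rank
  assignments at $n \le 8$.
* **Pseudobulk comparison**: the single-cell track rank-sum-tests each
  gene across cells on log1p counts-per-10k; the clonotype track sums
  counts per clonotype, normalises to counts-per-million, log1p-transforms
  and rank-sum-tests across clonotypes; both are BH-corrected at
  $\alpha = 0.05$. Rank-sum tests stand in for a negative-binomial GLM
  deliberately: the quantity of interest is the *fraction of single-cell
  calls unsupported at the clonotype level*, a replication question, not a
  model-fit question.
* **kNN enrichment** uses exact blockwise Euclidean neighbour search at
  every size (the contract is exact neighbours; at the scales used here,
  up to a few thousand retained cells, brute force is fastest and
  simplest), self excluded, with the random-label expectation reported
  alongside. Scores are invariant under rigid rotation of the embedding.
* **NNLS correspondence** augments the design with a sign-split intercept
  pair so the non-negativity constraint never binds the intercept — the
  model includes an unconstrained offset, and whether the published fits
  constrained it is unstated; this is the choice we document. "Most
  specific" is operationalised as expression minus the mean of the other
  types (an alternative ratio definition is a documented knob). The
  solver is `pracma::lsqnonneg`, cross-checked against exhaustive
  active-set enumeration.
* **Bottleneck metrics**: UMI deduplication counts distinct (UMI, guide)
  pairs with no birthday-collision correction (a documented limitation,
  negligible at the UMI lengths used); dominance counts break ties by
  guide id; log2 fold changes add a 0.5 pseudocount to raw counts before
  renormalisation, keeping dropouts finite; fold changes are
  anti-symmetric under swapping sample and reference.

## 6. Problem sizes and design constants in the test suite

The end-to-end properties run on simulated cohorts sized like the screens
they emulate: the mosaic confounding cohort uses 125 targets × 3 guides +
81 NTCs, 350 EBs, 500 founders/EB and 300 captured cells/EB (~600 cells
per target); the monoclonal rescue re-uses the same library with 350
single-founder EBs at 120 captured cells; recovery uses a 9-target
piggyBac-style library over 150 EBs; the power check uses an arrayed-style
design with 10 target and 12 NTC clonotypes and a 0.25× lateral-plate-
mesoderm effect, within the clonotype ranges of the experiments it
mirrors. Null calibration pools 20 label permutations of a synthetic
cohort with 45 NTC triplet groups. These constants were fixed from the
designs being emulated before the tests were written.

## 7. Known limitations

* The Dirichlet end-state model cannot say *why* jackpotting arises, and
  per-EB clone sizes are exchangeable — no spatial or temporal structure.
* No transcriptome simulation: annotation error, doublets and
  normalisation artefacts of real data are out of scope, as are read
  alignment, matrix generation and doublet-score computation.
* UMI deduplication ignores barcode-collision inflation.
* The empirical-null screen assumes enough NTC guides to form at least two
  triplet groups; with few groups the cutoff quantile is noisy, which is
  intrinsic to the design it implements.
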