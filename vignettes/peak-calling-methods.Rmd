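---
title: "Methods: signal decomposition and HMM segmentation of ATAC-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal decomposition and HMM segmentation of ATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `atachmm`, the
parameters that matter, the numerical choices made where behavior was
genuinely open, and what the synthetic validation does and does not
demonstrate.

## The model

### Fragment-length mixture

A properly-paired ATAC-seq read pair measures one Tn5-to-Tn5 insert. Its
length $x$ is modeled as a four-component mixture: an exponential with
fixed mean $\beta$ for nucleosome-free fragments, and Gaussians
$N(\mu_m,\sigma_m)$, $N(\mu_d,\sigma_d)$, $N(\mu_t,\sigma_t)$ for
fragments spanning one, two and three nucleosomes. Fragment lengths are
discrete, but with means well above 100 bp and large sample sizes the
Gaussian approximation is sound.

Only the Gaussian parameters are estimated. `fit_em()` runs standard
Gaussian-mixture EM restricted to *nucleosomal* fragments — those longer
than `nucleosomal_min_length` (100 bp) — on a 10% random subsample
(`subsample_frac`), iterating until the largest mean change drops below
`epsilon` (0.5 bp) or 50 iterations. $\beta$ is never updated: the
exponential is heavily contaminated by the Gaussian left tails and jointly
fitting it destabilizes the mixture; 100 bp is the canonical sub-nucleosomal
scale.

Initial means 200/400/600 bp match the fragment-length modes commonly
reported for ATAC-seq libraries; initial SDs 20/50/100 bp are wide enough
to avoid starving a component, and weights start equal. All are exposed as
options. A fitted SD is floored at 1 bp (with a warning) so a degenerate
length distribution cannot produce a singular component, and components are
sorted so $\mu_m < \mu_d < \mu_t$ always holds on return.

One point the mixture formulation leaves open is how the *final*
per-fragment responsibilities used for track building should treat the
exponential component. `responsibilities()` defaults to a full
four-component posterior, with the NFR prior weight set to the observed
fraction of fragments at or below 100 bp — a self-calibrating choice that
needs no user input. `hard_assign_nfr = TRUE` instead assigns every
fragment ≤ 100 bp wholly to the NFR track, for users who prefer the
cutoff-style behavior. On fragments far outside the support of every
component (where all densities underflow), the fragment is assigned to the
component with the nearest mean; this keeps the decomposition total-mass
preserving for arbitrary input.

### Signal tracks

`build_tracks()` adds, for every base pair a fragment covers, that
fragment's four responsibilities to the four signal layers, aggregated into
10-bp bins; a fragment overlapping only part of a bin contributes
fractionally (overlap bp / bin size). Because responsibilities sum to one,
raw tracks conserve mass exactly: summed track values × bin size equals
summed fragment lengths, which the test suite asserts to 1e-6 relative.
The per-bp-then-bin formulation and native fractional binning are
mass-equivalent, so the cheaper fractional binning is used.

Tracks are square-root transformed before modeling. The signal is
nonnegative and zero-rich, which rules out the log transform; the square
root stabilizes variance while keeping zeros at zero and preserving
ordering (argmax positions are unchanged). Transforming twice is an error
rather than a silent no-op.

### Training regions

The HMM is trained on up to 1000 regions where binned coverage fold change
over background falls within `[lower_fc, upper_fc]` (defaults 10–20),
each run extended ±5 kb so genuine background flanks every enriched seed.
"Background" is defined here as the genome-wide mean of binned coverage
over chromosomes that carry any signal — the defining quantity is
deliberately simple and is logged so users can audit it. When more than
1000 candidate regions qualify, the strongest seeds (by maximum seed
coverage, ties broken by genomic order) are kept; this makes the selection
invariant to chromosome ordering, unlike keeping the first 1000 scanned.
Extended regions that merge count as one region. Users can bypass selection
entirely with a BED of predefined regions (no extension applied).

If no bin falls in the band the run stops with an instruction to supply
training regions or adjust the band — on data without accessible-region
structure there is nothing to learn from, and proceeding would train the
model on noise.

### The hidden Markov model

Three states with 4-dimensional Gaussian emissions over the (sqrt) signal
vector: the open-chromatin **center** (high everything), flanking
**nucleosome** (low NFR, moderate nucleosomal), and **background** (low
everything). Emissions are initialized by k-means (`stats::kmeans`, random
initialization, seeded; an empty cluster triggers a bounded re-seeded
retry) over all training-region bins; initial and transition probabilities
start uniform at 1/3. Baum-Welch (scaled forward-backward) re-estimates
transitions and emissions until the log-likelihood gain drops below `tol`
(1e-3) — initial probabilities are never updated. Likelihood monotonicity
is asserted on every training run in the tests, and the implementation is
cross-checked step-for-step against an independent reference HMM library
on a fixed small instance.

Roles are assigned by ranking states on the sum of their emission means.
When the top state does not dominate *every* signal dimension the model is
suspect — typically the nucleosome state has captured the NFR signal — and
a warning advises re-training with a more stringent fold-change band
(raising `-u`/`-l`), which in practice resolves it. Models with a state
count other than 3 are accepted but warned against: only the top and bottom
states then get meaningful roles.

### Decoding, masking and peaks

Before Viterbi decoding, bins whose z-scored coverage exceeds
`zscore_cutoff` are masked, together with any user blacklist. The default
cutoff of 100 is intentionally extreme: only pathological pileups (the kind
that otherwise derail the state path for the rest of a chromosome) should
mask, and a constant-coverage genome (SD = 0) masks nothing. Masked bins
are *excised*, not zero-filled; decoding restarts after every mask and no
state run or peak ever spans one.

Chromosomes are decoded in windows of `window_bins` bins (default
2,500,000 bins = 25 Mb at 10-bp resolution — well beyond any desk-scale
test, so windowing only matters on real genomes). Each window restarts
from the initial probabilities; the only consistency loss is at window
boundaries, which is the standard memory/fidelity trade-off.

Center-state runs longer than `min_center_length` are merged with their
immediately adjacent nucleosome runs; center runs separated only by
nucleosome runs coalesce into one peak. The 200-bp default is roughly one
nucleosome footprint: shorter center runs are more often decoding noise
than regulatory structure. A qualifying center with no nucleosome neighbor
on one side still forms a peak from the blocks present, flagged `_noflank`
in its name. Scores are the maximum *raw* binned read coverage over the
center blocks (scores describe evidence, so they stay on the untransformed
scale, at bin rather than bp resolution). Summits maximize
Gaussian-smoothed coverage across the center blocks with a 120-bp window;
$\sigma$ = window/6 makes the window span ±3σ, the kernel is renormalized
at block edges so truncation cannot bias the argmax, and ties resolve to
the leftmost position, so a flat profile yields the block start.

### Evaluation

All benchmarking is at base-pair resolution: inputs are coalesced, TP/FP
are intersection widths against positive/negative interval sets, and
PPV = TP/(TP+FP), TPR = TP/RP, FPR = FP/RN. Conventions at degenerate
denominators: an empty prediction set has precision 1 and rates 0. ROC and
PR curves from a score-cutoff sweep are completed with extreme points —
ROC with (0,0) and (1,1); PR with (TPR 0, PPV 1) and (TPR 1,
PPV = $L_{true}/(L_{true}+L_{false})$), the precision of predicting
everything — then integrated with trapezoids after sorting by (x, y);
points sharing an x form a vertical segment and contribute no area, which
handles single-point and empty curves cleanly. A 2-kb proximity merge for
clustered gold-standard sites is available as `merge_nearby()` but never
applied implicitly.

## The synthetic generator

`simulate_dataset()` encodes the qualitative structure of an accessible
region: an NFR core (400 bp) flanked on each side by two phased nucleosomes
with 200-bp dyad spacing. NFR fragments fall uniformly across the core;
nucleosomal fragment midpoints are Gaussian (SD 20 bp) around the covered
dyad(s). Lengths are drawn from the canonical mixture — exponential mean
100 bp; Gaussians 195/396/693 bp with SDs 25/50/100 and weights
0.7/0.2/0.1 among nucleosomal fragments; half of all fragments
nucleosome-free — values chosen once to match well-characterized deeply
sequenced human ATAC-seq libraries. By default 75% of fragments are
uniform background; with 20 regions on 2 Mb at 30× depth this places
planted-region coverage at roughly 13-fold over the genome mean, inside
the default 10–20 training band, i.e. the generator's defaults *are* the
study conditions of the validation. Fragments can be written as a sorted,
indexed paired-end BAM (MAPQ 60, coordinates only, no base sequences).

What the generator does **not** emulate: Tn5 sequence bias and duplicated
transposition hotspots, mappability artifacts, chromatin-state
heterogeneity between regions, overdispersed background, and chromosome-
scale copy-number variation. Passing the planted-recovery tests therefore
demonstrates correctness of the algorithmic chain (decomposition →
training → decoding → assembly) under the model's own assumptions, not
peak-calling accuracy on real tissue data.

## Numerical choices

- Multivariate Gaussian log-densities via Cholesky; when a covariance is
  not positive definite its diagonal is inflated by 1e-4 (doubling on
  retry, bounded). Baum-Welch adds 1e-6 to covariance diagonals each
  M-step; k-means cluster covariances get +1e-4.
- Forward-backward uses per-step scaling plus a per-bin max-shift of the
  log emission densities, so extreme densities cannot overflow.
- Viterbi runs in log space; ties break to the lowest-numbered state,
  making decoding deterministic.
- `baum_welch(tol = Inf)` returns the input model with zero updates —
  every finite gain is below an infinite threshold.
- EM on a constant length vector converges with the affected SD floored;
  coincident component means are separated by 1e-6 bp to keep the
  mono < di < tri ordering strict.
- The weighted pileup can leave values around −1e-17 from floating-point
  cancellation; track bins are clamped at zero before the square root.
- All randomness (EM subsampling, k-means, the simulator) flows from
  explicit seeds; a pipeline run with the same configuration and seed is
  bit-reproducible.

## Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen to
exercise every code path with comfortable statistical margins: mixture
recovery on 50,000 fragment lengths; Viterbi against exhaustive path
enumeration on 500 random ≤ 8-bin instances; transition-matrix recovery on
100 segments × 200 bins; and end-to-end planted-region recovery on a 2-Mb
genome with 20 regions at 30× depth (~310,000 fragments), where called
peaks are required to cover ≥ 90% of planted center base pairs while
touching ≤ 5% of background. Full-genome human runs differ only in scale,
not code path; the windowed decoder and per-chromosome track layout exist
for that regime.

## Known limitations

- Single-end libraries carry no fragment-length information and are
  rejected; there is no fallback mode.
- The MAPQ filter requires both mates to pass; tools filtering one mate
  will retain slightly more pairs.
- Peak scores are raw maximum coverage, not calibrated significance; no
  FDR is attached.
- The decoder does not propagate state across window boundaries.
- With more or fewer than 3 states, role assignment is heuristic and peak
  assembly is not recommended.
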