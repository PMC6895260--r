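# atachmm

HMM-based peak calling for paired-end ATAC-seq in R.

ATAC-seq uses the Tn5 transposase to cut preferentially into open chromatin,
so the insertion length *x* of every sequenced read pair carries structural
information: short fragments come from nucleosome-free regions (NFRs),
longer ones span one, two or three nucleosomes. Instead of calling peaks on
a single pileup, `atachmm` exploits that structure. It models the fragment
length distribution as a mixture of four components,

```
P_s(x | β)        = (1/β) exp(−x/β)                      nucleosome-free
P_m(x | μ_m, σ_m) = N(μ_m, σ_m)                          mono-nucleosome
P_d(x | μ_d, σ_d) = N(μ_d, σ_d)                          di-nucleosome
P_t(x | μ_t, σ_t) = N(μ_t, σ_t)                          tri-nucleosome
```

with β fixed at runtime (default 100 bp) and the Gaussian parameters fitted
by expectation-maximization on the nucleosomal fragments (> 100 bp, 10%
random subsample). Every mapped fragment then contributes its posterior
component probabilities to four genome-wide signal tracks at 10-bp
resolution, which are square-root transformed and fed to a 3-state hidden
Markov model — **background**, **nucleosome**, and open-region **center** —
with 4-dimensional Gaussian emissions. Emissions are initialized by k-means
over automatically selected training regions (coverage fold change within
10–20 of background, extended ±5 kb, at most 1000 regions), transitions and
emissions are refined by Baum-Welch (initial probabilities stay fixed), and
the genome is decoded with the Viterbi algorithm after masking blacklisted
and extreme-coverage regions. Center-state runs longer than a minimum
length are merged with their flanking nucleosome runs and reported in
gappedPeak format, scored by maximum center-state read coverage, with
summits from a 120-bp Gaussian-smoothed coverage profile.

The package also ships a synthetic paired-end fragment simulator with known
truth labels (planted NFR cores flanked by phased nucleosomes) and a
base-pair-resolution evaluation module (precision / recall / FPR and
ROC/PR AUC with extreme-point completion) so that the whole pipeline can be
validated without external data.

## Worked example

Simulate a 500-kb genome with 5 planted accessible regions at 30× depth,
write it as a sorted indexed BAM, and call peaks:

```r
library(atachmm)

sim <- simulate_dataset(layout = c(chrSim = 500000), n_regions = 5,
                        depth = 30, seed = 42,
                        bam_path = file.path(tempdir(), "example.bam"))
res <- run_pipeline(config = pipeline_config(bam = sim$bam, seed = 7))

res$mixture
#> Fragment-length mixture
#>   NFR:  exponential, beta = 100.0 bp (fixed), prior = 0.316
#>   1Ns:  N(mu = 186.9, sigma = 36.9), weight = 0.734
#>   2Ns:  N(mu = 382.7, sigma = 53.6), weight = 0.181
#>   3Ns:  N(mu = 688.2, sigma = 107.6), weight = 0.085

as.data.frame(res$peaks)[, c("seqnames", "start", "end", "score", "summit")]
#>   seqnames  start    end score summit
#> 1   chrSim  96531  98140 735.2  97581
#> 2   chrSim 194631 196280 738.6 195691
#> 3   chrSim 228891 230530 711.6 229971
#> 4   chrSim 376511 378140 758.9 377581
#> 5   chrSim 454631 456240 734.6 455171
```

The fitted 1Ns mean (187 bp) sits a little below the generating 195 bp
because exponential-tail NFR fragments longer than 100 bp leak into the
mono-nucleosome component — expected behavior of the mixture on realistic
input. All five planted regions are recovered as single peaks whose summits
fall inside the planted NFR cores; against the planted truth this run
recovers 100% of center base pairs while calling 0.43% of background base
pairs:

```r
background <- GenomicRanges::setdiff(GRanges("chrSim", IRanges(1, 500000)),
                                     c(sim$centers, sim$nucleosomes))
cnt <- basepair_counts(res$peaks, sim$centers, background)
c(recall = cnt$TP / cnt$RP, fpr = cnt$FP / cnt$RN)
```

`res$model` holds the trained HMM (serializable with `write_model()`), and
`evaluate_peaks()` produces score-sweep ROC/PR curves for any peak set
against positive/negative interval sets.

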