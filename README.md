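# tadtriplex

Long noncoding RNAs can bind double-stranded DNA through RNA–DNA triplex
(Hoogsteen) base pairing, and genome-wide maps of such triplex-forming sites
raise a structural question: are these sites placed randomly, or do they
track features of 3D genome organization — topologically associated domains
(TADs), TAD boundaries, and A/B compartments — across cell differentiation?
`tadtriplex` implements the full statistical pipeline for answering that
question from interval data (BED), signal tracks (bedGraph), and per-stage
TAD/compartment calls, for anyone analysing capture-based or predicted
triplex sites (or any other point annotation) against Hi-C-derived genome
architecture.

## The statistics

**Shuffle-null coverage enrichment.** For sites *S* and regions of interest
*R* (TADs or boundary windows), the observed statistic is the base-pair
coverage `obs = |union(S) ∩ union(R)|`. The null repositions the sites
uniformly at random in the genome (preserving each site's length) *N* times,
giving null coverages `e_1 … e_N`. A normal distribution is fitted
(`μ̂ = mean(e)`, `σ̂ = sd(e)`, n−1), and the headline p-value is the
upper-tail probability of `z = (obs − μ̂)/σ̂`. The empirical rank p-value
`(1 + #{e_r ≥ obs})/(N + 1)` is always reported alongside and takes over
when the null is degenerate.

**Positional preference within TADs.** Each TAD is split into 10
equal-length bins; per bin, the fraction of bin length covered by sites is
averaged over TADs (mean ± SEM). Each site also contributes its midpoint's
relative position folded to distance-from-the-nearer-boundary in [0, 0.5];
the observed sample is compared by a two-sample Kolmogorov–Smirnov test to a
control in which boundary-overlapping sites are repositioned uniformly into
TAD interiors.

**Dynamic reorganization across four stages.** Over the ordered stages
ES → MES → CP → CM, each site gets a binary state per stage (overlaps that
stage's boundary set; or midpoint in compartment A). Non-constant
state tuples are the 2⁴ − 2 = 14 dynamic categories. Observed category
counts are compared to the mean counts of randomized site sets with a
chi-square test (expected rescaled to the observed total; bins with
expected < 5 pooled).

**Site profiling.** Per site: mean-per-bp ChIP signal and conservation
(uncovered bases count 0 over the full site length), repeat-class occupancy
fractions (LTR/SINE/LINE/DNA), and nearest-TSS target gene with signed
distance. Sites are grouped as {all, at boundary, non-boundary, random
control} and every pair (6 comparisons) is tested with Welch's t-test; raw
p-values are reported.

A seeded synthetic-data generator (`simulate_bundle`) produces a complete
input bundle — genome, four-stage TAD and compartment calls, sites with a
planted boundary-enrichment factor, CTCF-like and conservation tracks with
planted effects, repeats, TSS — so every stage of the pipeline can be
validated against known ground truth.

## Worked example

```r
library(tadtriplex)

cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 5e6, n_sites = 300)
bundle <- simulate_bundle(cfg, "bundle_dir")
report <- run_pipeline(bundle, out_dir = "results_dir",
                       n_shuffles = 200, n_randomizations = 50, rng_seed = 7)
report$enrichment_boundaries
```

```
Shuffle-null coverage enrichment (upper tail)
  observed coverage : 95383 bp
  null mean (sd)    : 26498.9 (4966.1) bp over 200 shuffles
  z = 13.871, normal-fit p = 4.76e-44, empirical p = 0.00498
```

The sites cover 95.4 kb of boundary windows, 3.6× the null mean of ~26 kb;
the empirical p is the smallest achievable at 200 shuffles (1/201),
consistent with the planted 5× boundary placement density. The report also
holds the 10-bin occupancy profile with its KS test, both dynamic-category
chi-square blocks, the signal/conservation/repeat group comparisons, and the
target-gene table; `write_report` lays them out as diffable TSV/JSON.

Real data run the same way: point `read_bundle` at a directory with
`genome.chrom.sizes`, per-stage `tads_*.bed` / `compartments_*.bed` (BED4,
A/B label), `sites.bed`, `ctcf.bedgraph`, `cons.bedgraph`, `repeats.bed`
(name = class), and `tss.bed`. All file coordinates are BED 0-based
half-open. A shell wrapper is provided at `inst/scripts/run_pipeline.R`.

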