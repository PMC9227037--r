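---
title: "Relating RNA–DNA triplex-forming sites to 3D genome organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating RNA-DNA triplex-forming sites to 3D genome organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadtriplex)
```

## The question and the data model

Some long noncoding RNAs bind genomic DNA as RNA–DNA triplexes, and a
genome-wide map of one lncRNA's triplex-forming sites (an interval set) can
be confronted with the architecture of the genome: topologically associated
domains (TADs) and their boundaries called per differentiation stage from
Hi-C, A/B compartment labels per stage, ChIP signal for boundary factors
such as CTCF, repeat annotations, and per-base conservation. `tadtriplex`
implements that confrontation as a deterministic, seeded pipeline.

Everything is an interval on a genome assembly. Files use BED conventions
(0-based half-open); in R the package uses `GRanges` (1-based closed) bound
to a `Seqinfo` assembly, and converts at I/O only. Intervals are validated
on read: a site extending past its chromosome end is an input error, not
silently clipped, because coordinates out of range usually signal an
assembly mismatch that should stop an analysis rather than bias it.

## The shuffle null

All null models derive from one primitive, `shuffle_intervals`: every site
is repositioned uniformly at random over the allowed space, preserving its
length. The allowed space is the assembly, minus an optional exclusion set,
intersected with an optional confinement set. Chromosome (more precisely,
allowed span) choice is proportional to the number of valid start positions
for the site's length, which makes placement uniform over all valid
positions genome-wide rather than per chromosome. Shuffled sites may
overlap one another — the null asks "where would this much sequence land at
random", not "construct a disjoint annotation" — and a
`non_overlapping = TRUE` mode (rejection sampling) exists for users who want
disjoint placements.

Seeding: replicate *r* of any replicated null uses `rng_seed + r`, so a
single replicate can be reproduced without regenerating the whole ensemble.
Replicated nulls (the enrichment test and the dynamic-category
randomizations) execute placement and coverage scoring on a plain-numeric
event-sweep over a global coordinate line (chromosomes laid end to end with
a 1 bp spacer); the test suite asserts this path reproduces the
`GRanges`-based route draw for draw.

## Coverage enrichment

`permutation_coverage_enrichment` scores observed coverage (base pairs of
the merged site union inside the merged region union) against the shuffle
null. Two p-values are always reported:

* the **normal-fit p** — fit `N(mean, sd)` (sample sd, n−1) to the null
  coverages and take the upper-tail probability of the observed value; this
  is the headline number and extrapolates below the 1/(N+1) resolution of
  the ensemble;
* the **empirical p** — `(1 + #{null ≥ obs})/(N + 1)`, which is
  distribution-free and authoritative whenever the normal fit is
  questionable, in particular when the null is degenerate (sd = 0), where
  the fit p is reported as 1 or 0 with a `degenerate_null` flag.

The default is 1000 shuffles and a one-sided upper tail (the question is
enrichment); `tail = "lower"`/`"two.sided"` are available for reuse.

One structural caveat, visible on synthetic data: if the TAD partition
tiles the genome completely, whole-TAD coverage equals the site union
length for every placement, and the sites-in-TADs test carries no
information (the only residual variation is site self-overlap, which can
only depress the observed union). The test is meaningful when TAD calls
leave unorganized gaps, as real ones do. Boundary windows never tile the
genome, so the boundary test is always informative.

## Boundary windows

TAD callers report domain intervals; boundary *width* is an analysis
choice, not a measurement. `tad_boundaries` emits a window of
`flank_bp` on each side of every TAD edge (deduplicating edges shared by
adjacent TADs, clipping at chromosome ends, merging the result). The
package default is `flank_bp = 40000`, a typical Hi-C bin scale; because
every boundary-dependent result changes with this value, it is a required,
echoed parameter in the pipeline provenance block rather than a hidden
constant.

## Positional preference within TADs

`bin_occupancy` divides each TAD into 10 contiguous bins of equal length
(integer remainders go one base each to the leading bins, so bins differ by
at most 1 bp and tile the TAD exactly — an asserted invariant). Occupancy
is the *fraction of bin length* covered by sites, which normalizes away the
TAD size distribution; mean and SEM are taken across TADs per bin index.
The profile is reported left-to-right by default; a `fold = TRUE` option
averages mirror bins onto a distance-from-boundary axis. Left-to-right is
the default because it is lossless (folding is a projection of it) and
symmetric in expectation.

The hypothesis test is per-site rather than per-bin: each site contributes
its midpoint's relative position in its host TAD folded to [0, 0.5], and
the observed sample is compared by a two-sample Kolmogorov–Smirnov test
(`stats::ks.test`, exact p for small n, asymptotic otherwise) to a control
built by `within_tad_randomization`: sites overlapping a boundary window
are repositioned uniformly into TAD interiors (TADs minus boundary
windows), everything else stays put. Per-base attribution drives the
profile; midpoints drive the KS sample — occupancy is defined as a length
fraction, while the KS test needs one number per site. TADs are used as
given here, not merged: adjacent TADs are distinct position scales.

## Dynamic reorganization across stages

Four ordered stages (ES, MES, CP, CM) give each site a binary state vector:
boundary presence (≥ 1 bp overlap with that stage's boundary windows —
boundaries are narrow targets) or compartment membership (midpoint inside
an A-labelled interval — compartments are broad partitions, and a midpoint
rule avoids ambiguity for straddling sites). The 2⁴ − 2 = 14 non-constant
vectors are the dynamic categories; constant vectors (never / always) are
pooled into a reported `static` bin that is excluded from the test by
default (`include_static = TRUE` includes it), since the question is about
sites that *experience* reorganization.

`category_chi_square` builds expected counts by annotating
`n_randomizations` shuffled site sets and averaging, rescales expected to
the observed total, pools bins with expected < 5 (the classical validity
rule; the pre-pooling table is always returned), and computes
`χ² = Σ(O−E)²/E` with `df = bins − 1`. The chi-square arithmetic is checked
against `stats::chisq.test` to 1e-10 in the tests. Estimating expected
counts from a finite randomization ensemble inflates the statistic by a
factor of about `(1 + 1/n_randomizations)`; with the default 100
randomizations the effect is ~1% and ignored.

## Site profiling

`aggregate_signal` summarizes a stepwise-constant track (bedGraph
semantics) per site as mean-per-bp over the full site extent — bases not
covered by a segment contribute 0 to the numerator and 1 to the
denominator, matching coverage-style averaging tools. No flanking window is
added by default (`flank_bp` extends sites symmetrically if desired);
conservation uses the identical contract. Repeat occupancy is the fraction
of site length covered by the merged repeats of each class.

`group_and_compare` partitions sites into {all, at boundary, non-boundary}
plus a length-matched random control, evaluates a caller-supplied
`value_fun` on each group, and runs Welch's t-test on every pair — 6
comparisons for 4 groups. Welch was chosen because group variances have no
reason to be equal; p-values are reported raw (no multiple-testing
correction) so downstream users can correct across whatever family they
assemble. The design takes a *function* rather than precomputed values
because the control group's values must be measured on the control's own
intervals from the same source. Pairs with a group under 2 values are
flagged untestable, never silently dropped.

`nearest_tss_targets` assigns each site the gene whose TSS minimizes the
distance to the site's closed coordinate span (0 if inside); ties break by
smaller TSS coordinate, then lexicographic gene name, and the signed
distance is negative when the TSS lies left of the site. The output gene
list is a TSV consumable by external GO-enrichment tools; GO analysis
itself is out of scope.

## The synthetic-data generator

`simulate_bundle` exists so that every statistic above can be exercised
against a known ground truth. Its defaults are the package's reference
conditions, chosen once at design time: 2 chromosomes × 10 Mb (large enough
for ~12 TADs and 1000 sites without crowding, small enough to simulate in
seconds), TAD lengths ~ truncated exponential with mean 1 Mb (floor at a
fifth of the mean), boundary flank 40 kb, boundary turnover 0.15 per
internal edge per transition (each removed edge is replaced by a uniform
new one, preserving TAD counts; Markov across stages, which gives every one
of the 14 patterns positive probability for any turnover in (0, 1)),
compartments as fixed 1 Mb alternating A/B blocks with a 0.2 per-transition
flip rate, 1000 sites of 1 kb with boundary enrichment 5, a CTCF-like track
of exponential(1) noise on 1 kb segments with a +5 peak over half the
sites, Beta(2, 6) conservation with +0.2 at boundary-overlapping sites, and
four repeat classes at 5% genome density each with LTR/SINE placed 4× and
LINE/DNA 0.25× as densely inside sites (mirroring the directionality such
analyses report on real repeat annotations).

Site planting follows a closed form: with boundary share *b* and
enrichment *E*, a site lands in boundary space with probability
`E·b/(E·b + (1 − b))`, uniformly within the chosen space — so `E = 1` is
exactly the uniform null, and the planted fraction is analytically
recoverable (a generator test checks the binomial CI). All randomness flows
from one seed with fixed offsets per component (stages +0, sites +1000,
tracks +2000), making each component independently reproducible and whole
bundles byte-identical across runs.

What the generator does *not* emulate — and therefore what green tests do
not show about real data: sequence content (no GC or mappability structure,
no assembly gaps), realistic TAD size and nesting distributions, correlated
boundary/compartment dynamics, ChIP peak shapes, or spatial autocorrelation
of conservation beyond the planted uplift. Passing tests demonstrate that
the statistics recover planted effects and stay calibrated under the
generator's null, not that real triplex sites behave any particular way.

## Numerical and degenerate-input choices

* Coverage, occupancy and signal arithmetic are integer-exact (base pairs);
  property tests compare them to a per-base bitmap oracle on small genomes.
* Degenerate enrichment nulls (sd = 0) switch to the empirical p with a
  flag; degenerate chi-square tables (all static, or fewer than 2 usable
  bins) return χ² = 0, p = 1 with a flag.
* TADs shorter than the bin count are skipped with a warning and counted;
  sites whose midpoint escapes all TADs or all compartment intervals are
  dropped and counted, never silently.
* Ties in nearest-TSS distances break deterministically (coordinate, then
  name), so outputs are stable across platforms.
* Reports exclude timestamps and hostnames; identical inputs, parameters
  and seed give byte-identical TSV/JSON.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on simulated data:
oracle-equivalence properties on ≤ 0.1 Mb genomes (hundreds of cases),
calibration ensembles of 60–200 replicates at 200 shuffles on 2 Mb
genomes, power checks at the reference conditions above, and the full
pipeline at 1000 shuffles / 100 randomizations on the default 2 × 10 Mb
bundle. These sizes were chosen as the smallest at which the planted
effects and calibration bands are comfortably resolved.

## Limitations

The pipeline treats TAD and compartment calls as given truth; uncertainty
in the calls does not propagate. The shuffle null is unmatched (no GC,
gap or chromatin-state matching) — exclusion sets are supported but not
derived. Boundary width is a free parameter with no in-package estimator.
The dynamic-category labels are presence/absence tuples; the isomorphic
"gain at stage k / loss at stage k" event labelling is not produced. And
the sites-in-TADs enrichment is uninformative when the TAD partition tiles
the genome (see above), which includes all bundles this generator produces.
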