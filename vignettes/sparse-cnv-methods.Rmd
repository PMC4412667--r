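---
title: "Methods: CNV, LOH and UPD calling from sparse targeted coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV, LOH and UPD calling from sparse targeted coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsecnv)
```

## The problem and the design premise

`sparsecnv` detects genome-wide copy-number variants (CNV), loss of
heterozygosity (LOH) and copy-neutral uniparental isodisomy (UPD) from a
sparse capture panel: short (~150 bp) probes placed roughly every 10 kb
across the genome, each carrying a common SNP where possible. Two
observations per probe drive everything downstream — the mean read depth
over the probe, and the reference/non-reference read counts at the
probe's SNP. Because the panel covers only ~1.5% of the genome, the
design buys genome-wide CNV/LOH sensitivity at a tiny fraction of
whole-genome sequencing cost; the price is resolution, which is bounded
below by the probe spacing (~10 kb) and in practice by the minimum event
filters.

There is no matched control. In its place, the method uses a
*multi-sample median baseline* (a panel of normals): at every probe, the
median normalized ratio over a collection of unrelated samples stands in
for the expected diploid signal. The median is robust as long as fewer
than half the panel carries an aberration at any one locus, which is why
the panel has a hard floor of 3 samples and a recommended minimum of 8.
When a sample in the panel is itself under test, its own values are
excluded from the medians (leave-one-out), so a large event cannot
suppress its own baseline.

## Depth normalization

Per-probe depth `TD_i` (reads per base; an aligned-base-count dialect
divides by probe length) passes through three transformations:

1. **Smoothing.** `TD_mi` is the mean of `TD` over probes `i..i+n` on the
   same chromosome (`n = 10`, i.e. 11-probe windows, per the printed
   summation bounds; windows truncate at the chromosome end with the
   divisor equal to the actual window size). Smoothing trades single-probe
   noise for an 11-probe correlation length — a trade the calling stage
   must account for (below).
2. **Autosomal scaling.** `R_i = TD_mi / mean(TD_mi over autosomal
   probes)`. Excluding X/Y from the divisor keeps male samples on the
   same scale as female ones; `R_i` is still defined on X/Y.
3. **Baseline division.** `R_mi = R_i / median_i(panel R_i)`. The shared
   per-probe capture efficiency cancels here, which is the step that
   makes a sparse capture panel workable without GC or mappability
   regressions. The panel median of the *unsmoothed* ratio is kept
   alongside for boundary work.

Probes with zero depth in more than half the panel, or a zero median,
are masked genome-wide. The naive ratio `preR_i = TD_i / mean(TD)` is
retained for diagnostics: on a heterogeneous-efficiency null panel,
`R_m` has visibly smaller dispersion and a mean within a few percent of
1, while `preR` does not — the test suite asserts both directions.

## CNV calling

At each probe the test sample is compared with the panel by a
one-vs-group t statistic

    t_i = (Rm_test,i - mean(Rm_panel,i)) / sqrt(S2_panel,i * (1 + 1/n)),

with `n - 1` degrees of freedom and a two-sided p-value; `Z_i` denotes
the numerator. Under a Gaussian panel this construction is exactly
calibrated (the suite checks uniformity of null p-values by a KS test);
on Poisson counts at ~30X it is mildly conservative because an
11-probe-smoothed Poisson ratio is slightly skewed for `df = n - 1` as
small as 6-9. That bias is in the safe direction and is left alone.

**Seeding.** Every window of 4 consecutive probes whose t scores share a
sign, with at least 3 p-values below `p_cnv` (default 0.05) and the
remaining one at most `p_seed2` (default 0.2), marks its probes with a
`+`/`-` pseudo-signal; windows slide by one and marks accumulate. A
probe only qualifies if its own rounded copy number differs from 2 in
the window's direction (`R_m < 0.75` for losses, `>= 1.25` for gains).
This absolute gate matters: smoothing gives neighboring probes a lag-1
autocorrelation near 0.9, so purely p-value-based seeds arise in long
correlated runs even in null data, while the CN gate sits several
standard deviations out at 30X and keeps them quiet.

**Merging.** Maximal same-sign marked runs merge across gaps of at most
`max_gap` unmarked probes (default 5), to a fixpoint; opposite signs
never merge.

**Region confirmation.** Each candidate interval must pass three checks
at the `p_cnv` level:

* the within-region one-sample t on `Z_i` (df `m - 1`) — the printed
  construction, reported as the call's statistic;
* a region-scale test between the test sample and the panel: the test
  sample's region mean of `R_m` against the panel samples' region means
  (same t form, df `n - 1`). The panel means carry the same smoothing
  autocorrelation as the test mean, so this re-test stays calibrated
  under the selection that produced the candidate, which the
  within-region t does not;
* a copy-number clearance: the region mean must clear the rounding
  boundary of the neutral state (0.75 for losses, 1.25 for gains) by
  more than the panel's region-mean dispersion allows (one-sided t). A
  "CNV" whose integer CN rounds back to 2 is not a call. This is what
  preserves zero false positives when depth drops toward 8X and the
  per-probe gate loses its margin.

**Boundaries.** The forward moving average delays a step's apparent
edges by up to the window length, so each confirmed interval's edges are
re-fitted at probe resolution with a two-segment least-squares step fit
on the *unsmoothed* baseline-normalized ratio, searching up to the
smoothing span around the candidate edge. Refinement is skipped at
chromosome ends where no outside segment exists. Sub-probe breakpoints
are out of scope by construction — a breakpoint cannot be located beyond
the two probes flanking it.

Filters: `min_probes` (default 45) AND `min_size` (default 1 Mb), both
configurable; the simulation benchmark runs at `min_probes = 10` with no
size floor. Copy number is `round_half_up(mean_ratio / 0.5)`, floored at
0 — so a continuous CN estimate of 3.497 reports as 3, reproducing the
method's known rounding behavior on low-density regions. When at least
90% of a chromosome's probes sit in same-direction calls the calls are
promoted to a whole-chromosome aneuploidy record. Sample sex is inferred
from chrX/chrY depth coefficients (XX above 0.85, XY below 0.65 with Y
coverage, an "other" review band between), and calls can be rendered as
ISCN-style karyotype strings (`"46,XY,del(5)(p14)"`) against a cytoband
table.

## LOH and UPD calling

At each usable SNP (total depth >= `min_depth`, default 10 reads — below
that a B-allele fraction is too noisy to interpret, so the site is
excluded rather than zeroed), the heterozygosity coefficient is

    R_Het = min(BAF / (1 - BAF), (1 - BAF) / BAF),

1 at perfect heterozygosity, 0 at homozygosity, symmetric in
`BAF <-> 1 - BAF`. The per-site median of `R_Het` across the panel forms
the baseline. A sliding window of `W = 25` consecutive usable sites
(step 1, anchored at its first site, never crossing a chromosome — the
window span is a design choice, as the source construction leaves it
open) compares the test window's variance with the baseline window's by
the two-sided F construction

    F_upper = S2_max / S2_min,  p = p_upper + (1 - p_under),

with `W - 1, W - 1` degrees of freedom, clipped to 1. The non-standard
additive form is kept deliberately (it evaluates to exactly 1 at equal
variances and is what the method defines); a zero minimum variance
flags the window and floors the p-value. By default a directional gate
additionally requires the test window's mean `R_Het` to lie below the
baseline window's before an anchor may seed LOH: variance can move for
reasons other than heterozygosity loss, but LOH always pulls `R_Het`
down. The gate can be disabled (`loh_directional = FALSE`) for the
agnostic reading.

Intervals initiate at 3 consecutive anchors with `p < 0.01` and extend
greedily; one above-threshold anchor may be absorbed per excursion
provided the running mean p stays below 0.1, and two consecutive
excursions stop the extension. An interval spans its first anchor
through its last anchor's window end, so boundary uncertainty is about
one window (~250 kb at default density) — small against the 5 Mb
reporting floor. Classification intersects LOH with CNV: majority
overlap with CN 2 is isodisomy (`UPD`), anything else is `LOH_nonUPD`
with the copy number recorded. A consistency check lists every
reportable CN = 1 call lacking a co-localizing LOH interval, since a
hemizygous deletion must lose heterozygosity.

## Probe design

The design module reproduces the four-stage selection against a genome
and SNP table: (1) keep SNPs with population allele frequency in the
closed interval [0.10, 0.90]; (2) drop a SNP within 100 bp of the
previously kept one; (3) require the 101-base flank (50 up, site, 50
down) to occur exactly once in the genome and to have no second locus
above 95% identity — implemented as an exact plus near-match string
search with a mismatch budget of `floor(0.05 * 101) = 5`, which makes
the screen deterministic and self-contained (the looser alternative
reading, keeping sites *with* a near-identical second hit, contradicts
the uniqueness goal and was rejected); (4) thin to one SNP per 10 kb
bin, keeping the site nearest the bin center (ties to the lower
position; the original selection rule within a bin is unstated).

Gaps of at least 1.5x the spacing then receive
`max(1, floor(gap / spacing) - 1)` evenly spaced filler anchors. The
trigger is deliberately not "any gap over the spacing": bisecting a
10-15 kb gap would move the grid *further* from the target spacing, and
a set built that way could not show the ~10 kb median inter-probe
distance the design aims for. Fillers must avoid homopolymer runs of 10+
bases and keep window GC within [0.3, 0.7] (the numeric bounds are this
package's choices for "simple repeats" and "extreme GC"), sliding up to
half the spacing to comply or skipping with the gap logged. Anchors
become 150 bp centered probes, clipped at contig edges; overlaps resolve
in favor of SNP-sourced probes.

## The simulator: what it emulates and what it does not

The count-level simulator generates exactly the quantities the method
consumes: a regular 10 kb probe grid, one common SNP per probe
(`pop_af ~ U[0.1, 0.9]`), shared per-probe capture efficiencies
`e_i ~ lognormal(0, 0.4)`, per-sample Poisson depths at
`mean_depth * e_i * CN/2`, Hardy-Weinberg genotypes, and binomial allele
counts at genotype-determined BAF targets (homozygous 0/1 pushed to a
0.002 sequencing-error floor; hemizygous deletions at 0/1; heterozygous
three-copy segments at 1/3 or 2/3). The benchmark preset implants 9 CNV
events (CN 1 or 3, 450 kb-3 Mb, drawn uniformly — the original mix is
unreported, so the draw is recorded in the truth table) across 3 of 8
samples on two ~60 Mb chromosomes at ~30X.

Deliberately absent: read-level artifacts (alignment error, duplicate
reads, insert-size structure), GC-dependent coverage curves, mappability
variation, batch effects between samples, and relatedness. Passing
tests therefore demonstrate the statistical machinery under the stated
noise model, not robustness to library-preparation pathologies; on real
data the multi-sample median absorbs shared capture structure but
nothing sample-specific.

Benchmark sizes used by the test suite: the full two-chromosome
8-sample simulation for sensitivity/specificity (at 30X and again at
8X); 50 null replicates on 20 Mb single-chromosome 10-sample panels for
false positives; 100 replicates of 30 Mb panels with one 6 Mb UPD and
one 6 Mb deletion for LOH/UPD recovery; 1,000 random fixtures per
statistic for oracle agreement at 1e-10.

## Numerical and degenerate-input choices

* Rounding is half-up everywhere CN is assigned (deterministic
  tie-break: ratio 0.75 gives CN 2).
* Zero panel variance masks a probe; zero `Z` dispersion or a flat test
  window floors the p-value at the smallest representable double with a
  flag, never silently.
* Rolling means and variances use cumulative sums (exact, O(n)).
* All intervals are 0-based half-open internally; tables render 1-based
  inclusive; sizes are always `end - start`.
* Every generator takes an explicit seed and is byte-reproducible;
  `threads` never affects results (the pipeline is single-threaded by
  construction).

## Known limitations

Resolution is bounded by probe spacing (~10 kb) and the event filters;
mosaic or fractional copy states are not modeled (integer CN only);
heterodisomy is undetectable without parental genotypes; sex-chromosome
baselines require sex-matched panel members (otherwise all samples are
used with a warning); and the multiple-testing posture is the method's
own — raw per-probe thresholds with run-length, merging, region-level
and CN-clearance rules as the effective error control, with per-run
probe-level hit rates recorded in the manifest for QC rather than any
FDR adjustment.
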