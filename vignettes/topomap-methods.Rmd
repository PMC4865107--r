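---
title: "Mapping topoisomerase IV binding and cleavage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping topoisomerase IV binding and cleavage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomap)
```

# The problem

Topoisomerase IV (Topo IV, the ParC~2~ParE~2~ heterotetramer) is the main
decatenase of the *E. coli* chromosome: it removes precatenanes behind
replication forks and the catenation links that remain between fully
replicated sister chromosomes, with a hotspot of activity at the
chromosome-dimer resolution site *dif*. Two genomic assays probe it:

* **ChIP-seq** maps where the protein *binds*: a symmetric enrichment of
  IP coverage over input, typically spanning ~200 bp.
* **NorflIP** maps where it *cleaves*: the quinolone norfloxacin traps the
  enzyme covalently on the 5′ ends of its cleavage site. Because the
  blocked 5′ ends ligate poorly during library preparation, the resulting
  signature is strand-asymmetric — a ~170 bp forward-strand enrichment
  block and a ~170 bp reverse-strand block separated by a ~130 bp
  non-enriched gap, with a ~100 bp central window where raw reads drop
  out entirely. The cleavage point sits at the center of that window,
  ~150 bp downstream of the forward-peak center.

topomap implements the full downstream analysis for both assays on
circular bacterial genomes, along with the replication analyses
(marker-frequency breakpoints, a replication-coupled occupancy null
model) and the genomic-context statistics used to interpret the site
catalogs. A synthetic-data generator with planted ground truth makes every
step testable end to end.

All coordinates are 0-based, half-open (BED convention) and wrap
circularly; window arithmetic wraps everywhere.

# Coverage processing

Tracks are processed the way the published pipeline describes: per-strand
read counts are smoothed with a **200 bp** centered circular moving
average, strands are summed, libraries are scaled to reads per million,
and the IP/input ratio is formed with a pseudocount.

Choices the published description leaves open, fixed here:

* **Pseudocount**: one read per smoothing window, in each track's own
  units, added to numerator and denominator. It stabilizes ratios where
  coverage is low without biasing well-covered bins.
* **Centering**: the ratio track is rescaled to genome-wide **median** 1
  (not mean): the handful of strong peaks barely move the median.
* **Artifact masking**: positions where the smoothed mock-IP/input ratio
  reaches 2 are masked — this captures the rRNA-, tRNA- and IS-like
  signal shared with mock immunoprecipitations. Masks propagate: scans,
  fold validation and context statistics ignore masked positions.
* **GC normalization** fits a least-squares *line* of the 60 kb-binned
  ratio against windowed GC fraction and divides it out, preserving the
  genome-wide mean; a linear fit (rather than lowess) keeps the
  correction deterministic and transparent.

# The cleavage-site caller

The caller reproduces the published template-matching procedure:

1. smooth forward and reverse IP signals (200 bp) and subtract
   (`differential_track()`); a cleavage site is a positive lobe followed
   by a negative lobe with the zero crossing at the cleavage point;
2. correlate a 600 bp template against the genome at 100 bp steps
   (`scan_cleavage()`); the published alternative of 2 kb probes is
   available through `cleavage_params(template_window = 2000)`;
3. keep regions whose best window reaches Pearson r ≥ 0.72;
4. validate candidates at IP/input fold ≥ 2 within the template window
   (`validate_sites()`), after artifact masking;
5. estimate each site's cleavage point and shape
   (`estimate_cleavage_point()`, `measure_shape()`).

**Template source.** By default the template is the differential signal
of a single noise-free canonical site (`canonical_cleavage_template()`),
so calling does not depend on the data containing strong sites. A
`template = "data"` mode reproduces the published bootstrap instead: the
two strongest enrichment regions (in the data, *dif* and the 1.9 Mb site)
are extracted and averaged.

**Sign convention.** The template is forward-lobe-first and negative
correlations are never calls. Implementing that naively — "call windows
with r ≥ 0.72" — turns out to be insufficient: a *mirrored*
(reverse-lobe-first) signature anti-correlates at its center but
windows offset by half a template still correlate positively at r ≈ 0.9
(one lobe aligned, the rest flat). A surviving candidate is therefore
discarded when a more strongly anti-correlated window lies within the
merge distance: that region is better explained by the mirrored shape.
True sites are unaffected — their center window (r ≈ +1) dominates their
own anti-correlated flanks.

**What the r threshold does and does not do.** Pearson correlation is
scale-free, and 200 bp smoothing leaves only ~3–4 effective degrees of
freedom per 600 bp window, so pure background coverage crosses r = 0.72
regularly (hundreds of windows per Mb at typical depth). The correlation
scan is a *shape* filter; the *amplitude* filter is the fold ≥ 2
validation, and only their combination has high precision. On planted
truth (fold ≥ 5, depth 5 reads/bp, 4.6 Mb genome) the combined caller
measures ≥ 95% recall and precision across 20 simulations; on
background-only genomes it validates zero sites.

**Cleavage point.** The primary estimator is the center of the raw-read
depleted gap between the forward and reverse read blocks (blocks are the
contiguous runs above half-maximum of each strand's raw signal). On
noiseless canonical input the estimate is exact and reproduces the 150 bp
offset from the forward-peak center, since
offset = (fwd_span + gap)/2 = (170 + 130)/2. When no strand-offset gap
exists (e.g. a symmetric binding peak) the estimator falls back to the
differential-signal zero crossing and flags the site. With Poisson noise
at depth 5 the median error is below 50 bp (light 40 bp smoothing of the
raw signal before block detection).

# The binding-site caller

ChIP peaks are symmetric, so the caller correlates the IP/input ratio
with a template extracted at a reference site (*dif* by default) at 100 bp
steps, keeps windows with r ≥ 0.7 and fold ≥ 2, and merges within 300 bp.
The published account does not print the window length for this filter;
600 bp (the cleavage caller's window) is the default and 2 kb the
alternative, both via `binding_params()`. Support across experiments
("site seen in ≥ 2 experiments") is computed by midpoint agreement within
250 bp in `cross_experiment_overlap()`.

`ori_ter_bias()` quantifies the non-specific binding bias: mean ratio
over a 3 Mb oriC-centered arc versus the complementary arc, and the
longest run of 60 kb bins below the genome-wide mean (the published
terminus-depleted span is ~1.6 Mb).

# Replication analyses

**Marker frequency** is the binned ratio of a replicating sample's input
coverage to a non-replicating reference, rescaled so the lowest-decile
bins average 1. In synchronized populations the replicated region sits at
2 and the unreplicated region at 1, with slope changes at the fork
positions.

**Breakpoint detection.** The published account reports "sharp changes of
the slope" without a method. We fit a segmented least-squares model — a
free line per segment, optimal breakpoints found by dynamic programming
over all bin-resolution segmentations — to the circular profile cut at
*dif* (far from the forks). We deliberately do *not* constrain the fit to
be continuous: the synthetic synchronized profile is an exact step
(values in {1, 2}), which a continuous piecewise-linear function cannot
represent, and the discontinuous fit localizes both the ideal step and
noisy ramped profiles correctly (breakpoints exact on the noiseless step;
median error ≤ 2 bins at Poisson depth 5 over 20 simulations). A profile
whose single-line fit is within 5% RSS of the segmented fit reports no
breakpoints. `fork_distances()` then converts two breakpoints into
per-replichore distances from oriC, assigning each breakpoint to the arm
along which it is nearer the origin.

**The comet null model.** To ask whether binding merely follows
replication, the null model places a "comet" of fixed genomic length
behind each replication fork, optionally letting occupancy persist for a
fixed time per locus. The implementation fixes what the sketch leaves
open: exponential steady-state age distribution (density ∝ 2^(−t/T)),
deterministic fork speed v = L/C, replication initiated so that a locus
at replichore coordinate s is replicated s/v minutes into the C period,
and the D period following termination within the same schedule
(overlapping rounds arise naturally when T < C + D). Under this model the
dosage is the Cooper–Helmstetter copy number D(s) = 2^((C+D−s/v)/T) and a
locus is bound for dur = comet_len/v + persistence minutes after its
replication (saturating at T, since each locus is re-replicated every
doubling time), giving

O(s) = 2 · D(s) · (1 − 2^(−min(dur, T)/T)).

Occupancy is therefore *exactly proportional to dosage for every
parameterization* — that is the model's testable content, verified
analytically (CV of O/D < 10⁻⁶) and against a 10⁵-cell Monte-Carlo
oracle (agreement within 3 standard errors). Consequently an occupancy
gap that survives dosage normalization — like the observed
terminus-proximal depletion — rejects the model; `flatness_stat()`
measures this as the coefficient of variation of O/D, and injecting a
halved-occupancy arc into the model output raises the CV above 0.1.

# Genomic-context statistics

* `gene_localization()` classifies site midpoints and reports positions
  within genes normalized to [0, 1], oriented 5′→3′ by strand.
* `tu_proximity()` measures circular distances to the nearest highly
  expressed transcription unit (expression ≥ 500 reads, approximately the
  top decile; a "top decile" selector can be emulated by choosing the
  threshold from the expression quantiles) and compares sites with a
  matched uniform control by a one-way ANOVA F-test. The F-test is kept
  because it is the published comparison, even though distances are
  skewed; its p-values are verified to be well calibrated under the null
  in the test suite.
* `overlap_fisher()` performs the gene-level 2×2 enrichment test
  (one-sided Fisher), matching the published "genes carrying both"
  phrasing; the tests verify it against brute-force hypergeometric
  enumeration on small universes.
* `dinucleotide_profile()` and `gatc_spacing()` compute the positional
  GC-dinucleotide frequency and the mean spacing of consecutive GATC
  motifs at ranks ±k around sites. One subtlety: for uniformly random
  sites the rank-0 gap (the gap *containing* the site) is length-biased
  (inspection paradox; ≈ 2/p − 1 ≈ 511 bp on an i.i.d. sequence where
  the unbiased geometric expectation is 4⁴ = 256 bp), so closed-form
  comparisons use the flanking ranks.
* `random_sites()` draws the uniform controls, excluding the artifact
  mask (or any interval set) when asked; controls default to the site-set
  size.

# The synthetic-data generator

The generator is the package's test bed and defines the simulated study
conditions:

* **Read model**: independent per-base Poisson rates (the analyses
  operate on coverage, not alignments), with a noise-free mode that
  returns the rate tracks so geometric assertions are exact. Input and
  mock are uniform at 5 reads/bp by default (IP background equal to input
  depth), which puts a planted fold-10 peak far above noise after 200 bp
  smoothing.
* **Fold semantics**: an enrichment block raises the combined strand rate
  to fold × background, so the noise-free unsmoothed IP/input ratio on a
  block equals the planted fold. Note that 200 bp smoothing of a 170 bp
  block attenuates the *measured* maximum ratio to ≈ (170·fold + 30)/200;
  published fold values carry the same attenuation.
* **Cleavage geometry**: blocks and gap as above; the central 100 bp
  read-depletion window drops the raw rate to zero (a
  `depletion_frac` parameter is available), reflecting the unligatable
  covalently blocked 5′ ends. The 130 bp gap and 100 bp depletion are
  independent parameters because their mechanistic relation
  (fragment-end geometry) is not specified by the data they summarize.
* **Artifacts** multiply IP *and* mock rates over a region, leaving input
  unchanged, so masking can be exercised.
* **Planted sites** default to ≥ 2 kb spacing; closer sites only warn,
  because real genomes do cluster sites.
* **Annotations**: non-overlapping genes with log-normal (heavy-tailed)
  expression, a configurable number of them forced above the 500-read
  threshold; Fis point sites and H-NS intervals placed uniformly.

What the generator does *not* emulate: mappability structure, GC-coupled
coverage bias at the read level (GC bias is exercised by constructing
ratio tracks against the genome's actual windowed GC), PCR duplicates,
fragment-level end geometry, and biological site clustering. Passing
tests therefore demonstrate correctness of the *procedures* under the
stated noise model, not performance on any particular real library.

# Problem sizes and numerical choices

The test suite runs the callers at full genome scale (4.639 Mb, the
*E. coli* convention with oriC at 3,926 kb and *dif* at 1,588 kb) across
20 simulation seeds for the recovery benchmarks, and smaller 0.1–1 Mb
genomes for unit-level properties. Scanning uses running sums (one pass
per template tap), smoothing uses circular cumulative sums, and the
segmented fit precomputes interval line fits from cumulative sums, so a
full-genome call takes seconds. Merging ties break to the smaller
coordinate; constant scan windows get r = 0 by convention; all
stochastic steps take explicit integer seeds and are reproducible
byte-for-byte.

# Limitations

* The "manual validation" step of the published catalog is modeled only
  by its two stated criteria (r ≥ 0.72, fold > 2).
* The comet model's D-period placement and initiation cadence for
  overlapping rounds are parameterized choices, not unique readings.
* The breakpoint fitter assumes exactly `n_breaks` slope changes; it
  reports none when a single line suffices but does not select the
  number of breaks automatically.
* Reproducing the published site catalogs (571 union sites, 88 common to
  three experiments, 19 binding sites) requires the deposited sequencing
  data; the package validates the machinery on synthetic constructions
  with that structure instead.
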