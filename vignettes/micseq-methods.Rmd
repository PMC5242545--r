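---
title: "Modeling micronuclear DNA representation with micseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling micronuclear DNA representation with micseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micseq)
```

## The measurement and the model

Micronucleus sequencing (Mic-Seq) reads out ongoing chromosome breakage
genome-wide. When a double-strand break is not repaired before anaphase, the
acentromeric fragment — everything from the breakpoint to the distal
telomere — has no kinetochore, missegregates, and can end up in a
micronucleus that is retained in an enucleated red blood cell. Sequencing
micronuclear DNA from the red-cell lysate fraction (MN) therefore
over-represents sequences distal to frequent breakpoints. Granulocyte DNA
(GRN) from the same blood provides a matched whole-genome control that
carries the same GC, library and strain-mapping biases but none of the
micronucleation biology.

Mouse chromosomes are telocentric, so a coordinate `x` on a chromosome of
length `L` is literally the distance from the centromere. The expected MN
coverage at `x` is decomposed into four components:

* `alpha` (per chromosome) — baseline representation: whole-chromosome
  loss into micronuclei plus contamination by nucleated-cell DNA;
* `beta x^2` — the genome-wide quadratic increase of coverage with
  centromere distance. If breaks occur roughly uniformly and every break at
  `p` contributes coverage on `[p, L]`, integrating a retention rate that
  grows linearly in `p` gives a quadratic in `x`;
* `rho (L - x)^2` — the converse, centromere-proximal gain, visible mainly
  on the longest chromosomes;
* `gamma` — localized, cumulative step increases distal to breakpoint hot
  spots, measured as the slope of a monotonically smoothed coverage profile.

The pipeline is: count fragment midpoints in overlapping windows →
normalize MN against GRN and rescale depth via `alpha` ratios → fit
`alpha + beta x^2 + rho (L - x)^2` on designated low-instability
chromosomes (chr7, chr11) → extract `gamma`, remove the fitted trend slope,
normalize by distance to the distal telomere, and call peaks against an
empirical null.

## Windowing and filters

Fragments are pair-bridged spans; records must be proper pairs, not PCR
duplicates, with mapping quality strictly above 20, and with span at most a
maximum insert chosen as the 0.999 quantile of the insert-size histogram. A
fragment is assigned to every window containing the midpoint of its
left-end read; with 40 kb windows stepped every 20 kb (20 kb/10 kb for
pooled data) an interior midpoint falls in exactly two windows. All
coordinates are 0-based half-open, matching BED/bedGraph conventions, with
the centromere at 0. A midpoint lying in `k` overlapping windows increments
all `k` — the only order-independent reading of overlapping-window
counting; the midpoint of the left read is `floor((start + end)/2)`.

## Normalization

Window-wise MN/GRN ratios cancel any bias shared by the fractions. Windows
whose GRN count is zero or departs from the genome-wide GRN mean by more
than 3 standard deviations are masked; the s.d. is computed genome-wide
because the bias being removed (GC, strain) is global. Ratios are rescaled
by the mean GRN count so normalized tracks stay on the MN count scale and
`alpha` remains interpretable.

`alpha` is estimated as the minimum over all runs of `m = 1000` consecutive
unmasked windows of the run median. Because `beta` and `rho` raise coverage
away from the profile minimum, this is a deliberate slight over-estimate;
tests assert the bias is bounded by the trend's rise. On chromosomes
shorter than `m` windows the run shrinks with a warning. Depth scaling then
multiplies each sample by the median, over chromosomes without strong
condition-specific `alpha` changes (the mouse default excludes chr6, 12,
15, 16, 18, 19 and X), of reference-to-sample `alpha` ratios.

## Trend fitting

`alpha_c + beta x^2 + rho (L - x)^2` is linear in its coefficients, so the
nonnegativity-constrained weighted least-squares fit is solved exactly:
the unconstrained solution is accepted when already nonnegative, otherwise
nonnegative least squares (Lawson–Hanson) is used. Positions are rescaled
internally from bp to 100 Mb units purely for conditioning; coefficients
are reported per bp². Weights default to uniform — the original
description says "weighted" without defining weights — with inverse-GRN
weights available. `alpha` is per chromosome in the joint fit (it differs
by chromosome by definition); `beta` and `rho` are shared across the
fitting chromosomes, chr7 and chr11 by default, chosen for their small
localized effects. Uncertainty comes from refitting on 50% subsamples
drawn without replacement, 1000 times by default, reporting the s.d. and
the 2.5/97.5 percentiles; the subsampling is seeded and reproducible.

## Gamma: smoothing, detrending, distance normalization

The cumulative-step signature of a hot spot is separated from
non-cumulative wiggles (GC and similar local biases) by fitting a monotone
curve: non-decreasing along the chromosome, or — on chromosomes with a
significant `rho` arm — non-increasing before the minimum-median point and
non-decreasing after it, continuous at the split. The split is located with
the same 1000-point running median used for `alpha`, refined to the
minimum value inside the minimizing run.

Two monotone engines are provided:

* **Penalized spline** (default): a cubic regression spline with knots
  every 2 Mb fitted under monotonicity constraints with `mgcv`
  (`smoothCon` + `mono.con` + `pcls`). Its slope field is continuous,
  which the 3 s.d. empirical-null calibration requires.
* **Isotonic regression** (`stats::isoreg`): the exact least-squares
  monotone projection. Its fit is piecewise constant: razor-sharp at step
  positions, but its slope distribution is spiky (mostly zero with sparse
  jumps), which breaks a standard-deviation-based cutoff.

Three numerical choices here were genuinely open and were settled by
simulation during development:

1. **Structural smoothing bandwidth.** The spline's penalty weight is set
   so the unconstrained smooth carries `6 + 0.05 L/Mb` effective degrees
   of freedom — a little above the quadratic trend's three. This choice
   depends only on the window grid, never on the data, so the bandwidth
   is identical across chromosomes (relative to length), samples, seeds
   and conditions. Data-driven selection (GCV or REML) was evaluated and
   rejected: a strong hot spot drags its own chromosome toward
   undersmoothing, inflating that chromosome's slope noise relative to
   the null chromosomes and producing broad spurious exceedances; REML
   estimates also vary between seeds, making the false-call rate
   unstable.
2. **Two-scale peak calling.** Peak significance and height are assessed
   on the smooth slope field; the apex position is then estimated within
   each called region as the least-squares change point of the detrended
   coverage — the maximum-likelihood estimate of a step location under
   Gaussian noise. The spline smears a step over its bandwidth (roughly
   megabases), so its own argmax can wander hundreds of kb; the change
   point recovers the breakpoint to within a couple of windows. (The
   sharp isotonic slope field is also carried in the gamma table; its
   largest jump is a noisier localizer and is kept as a fallback.)
3. **Edge masking.** Slope estimates within 20 windows of a chromosome end
   are one-sided and unstable, and the centromeric end is exactly where the
   `(L - x)` normalization is largest; those windows are masked. In real
   mouse data the pericentromeric satellite is unmappable, so coverage
   there does not exist in the first place — the simulator, which maps
   everything, is *harder* than real data in this respect.

`gamma_raw` is the per-window slope of the smoothed profile (value per bp).
Detrending subtracts the fitted trend slope `2 beta x - 2 rho (L - x)`,
clipped below at zero so the decreasing `rho` arm cannot manufacture
negative-gamma artifacts. The distance normalization multiplies by
`(L - x)`: a breakpoint at `x` spreads its extra representation over the
`(L - x)` distal bp, so equal-intensity hot spots otherwise look weaker
near the telomere. The positional cutoff mirrors this form:
`3 sigma_null (L - x)`, with `sigma_null` the larger (more conservative) of
the per-null-chromosome standard deviations of detrended gamma after
discarding values above the trim threshold (default 1e-7 on a per-bp
density scale; the trim is exposed because its unit follows the track's
own scale, and simulation-based tests on count-scale tracks disable it).

Supra-cutoff windows are merged into peaks with a gap tolerance of one
smoothing bandwidth (in windows), and peaks narrower than 1.2 bandwidths
are discarded. Both defaults are expressed in units of the smoother's
resolution: where a hot spot's declining flank crosses the cutoff, noise
wiggles produce repeated crossings over a bandwidth-scale region that
belongs to the same spot (hence the gap), and a genuine resolved spot must
elevate the slope over at least the bandwidth, while marginal null
exceedances span less than one (hence the width floor; at the default
settings true hot spots span roughly two bandwidths of supra-cutoff
signal and null artifacts at most one). A 1-window gap with no width
floor was evaluated and rejected: it fractures single hot spots into
several adjacent calls and admits narrow noise exceedances.

## The forward simulator

`simulate_mn()` draws fragment midpoints from the positional density the
model predicts: per-chromosome baseline `alpha0` (default 20 expected
counts per 20 kb window), `beta = 2e-15` and `rho = 5e-16` per bp² (putting
the distal gain on the order of the baseline over a 100 Mb chromosome, as
in wild-type MN fractions), step hot spots (`step` = added expected counts
per window distal to the break; default test hot spots use step 8, about
40% of baseline), a uniform GRN at 200 expected counts per window, and
Poisson counts (negative binomial with dispersion 0.05 available for
over-dispersion). A log-normal window bias with log-s.d. 0.15, normalized
to unit mean, multiplies both fractions; it is drawn from its own
`bias_seed` so all samples of a study share it — the premise of both GRN
normalization and replicate pooling. Ground truth (`alpha`, `beta`, `rho`,
expected normalized-gamma apex per hot spot) is recorded with the dataset.

What the simulator does *not* emulate: mappability holes and assembly gaps,
chromosome-specific GC composition, true over-dispersion structure of
biological replicates, satellite/rDNA sequence context (compartments are
drawn as a multinomial), or event-level correlation between windows sharing
one micronucleation event. Passing tests therefore demonstrate correctness
of the estimators under the model's own assumptions, not robustness to
every artifact of real libraries.

Desk-scale defaults are used throughout the test-suite studies: genomes of
three to fifteen chromosomes of 30–80 Mb and single-sample depths around
2–4 × 10^5 MN fragments, roughly two orders of magnitude below the real
study. Studies analyzed on the 20 kb / 10 kb grid pool two or three
simulated replicates per fraction first, since that grid is defined for
pooled data (the original protocol pooled replicates per condition
precisely to support the smaller windows). One visible consequence: inter-replicate Pearson correlations run
near 0.4 at this depth (the published 0.94–0.988 values reflect ~100-fold
more fragments per window), so pipeline tests set the QC floor accordingly
and check the identical-replicate case (`r = 1`) exactly.

## Sensitivity and resolution tradeoff

With the spiky isotonic slope field, detectability of a step scales with
the s.d. of single-window slope noise; with the calibrated spline field it
scales with `sigma_null` times the smoothing bandwidth. The package's
operating point favors calibration: hot spots at the default simulated
scale (~200 times the sharp-field slope s.d.) are detected with essentially
full recall and localized within two windows, while steps near the
single-window noise floor are traded away. Two hot spots closer than about
one smoothing bandwidth (a few Mb at default settings) merge into one call;
the test designs therefore place independent hot spots on separate
chromosomes.

## Repeat compartments

Reads from the 45S rDNA and the major/minor satellites multi-map within
concatenated repeat contigs, so a MAPQ floor of 20 would discard them;
compartment counting therefore applies no MAPQ filter to compartment
contigs (configurable) while genomic fragments keep the strict filter.
Enrichment across samples is assessed by regressing rDNA counts on MaSat
counts over the included samples and flagging points outside the pointwise
95% prediction band — the regression-line-plus-band construction used for
the published rDNA/MaSat scatter, with "95% confidence interval"
interpreted as the prediction band for a new sample.

## Known limitations

* The 3 s.d. cutoff is calibrated for the spline engine; calling peaks on
  the isotonic engine's gamma directly will over-call by design.
* `sigma_null` assumes chr7/chr11 carry no real signal; any true
  instability there inflates the cutoff (a conservative failure mode).
* Peak intervals are wide (the smoothing bandwidth), and closely spaced
  hot spots on one chromosome merge.
* The trend fit assumes shared `beta`, `rho` across the null chromosomes;
  per-chromosome trend coefficients are out of scope.
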