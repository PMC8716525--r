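---
title: "Methods: size-resolved mask passage evaluation and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-resolved mask passage evaluation and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskpassage)
```

## The measurement model

A mask test consists of two runs on the same rig: a *reference* run with an
empty mask mount, quantifying the unfiltered sodium-chloride challenge
aerosol, and a *sample* run with the mask sealed into the mount. A laser
aerosol spectrometer counts particles per one-minute interval in each of 99
geometric size classes spanning 90 nm to 7.5 µm (edge ratio
$(7500/90)^{1/99} \approx 1.0457$, i.e. ≈ 4.6 % class width). Because the
instrument's endpoints define the integration bounds, the grid constructor
treats the endpoints and class count as authoritative and derives the ratio;
a nominal "4.5 % width" is the rounded description of the same grid.

Each run lasts five minutes and the first two are discarded: the chamber and
the long tubing need that time to equilibrate, so counts in early minutes
under-represent the aerosol. Per-class counts are averaged over minutes 3–5
and converted to a detected mass concentration

$$m_i = \bar N_i \cdot \frac{\pi d_{\min,i}^3}{6} \cdot \rho \cdot
\frac{\mathrm{dilution}}{\dot V_\mathrm{sample}},$$

where $d_{\min,i}$ is the class's **lower edge**: a particle sorted into
class $i$ is at least that large, so the assigned sphere is its minimum
volume and $m_i$ is a conservative detected mass. The density $\rho$
(2165 kg m⁻³ for NaCl) and the window length scale all $m_i$ equally and
cancel in every passage ratio; they are kept so that mass spectra are
physically scaled (the chamber concentration check needs absolute units).
Passage per class is $P_i = m_{\mathrm{filter},i}/m_{\mathrm{reference},i}$
and the total passage is the ratio of the summed masses, identically the
reference-mass-weighted mean of the $P_i$. The test suite asserts both the
density cancellation and the weighted-mean identity to $10^{-12}$.

Classes in which the reference detected no mass are flagged *undefined*
rather than set to 0 or 1: at the sparse upper end of the grid a 0/0 would
otherwise masquerade as a measurement. Undefined classes contribute nothing
to $P_\mathrm{total}$ because it is formed from raw mass sums. A total
passage slightly above 1 is possible for a transparent mask through counting
noise and is tolerated; above 1.05 a warning points at pairing or counting
problems.

Each sample run is evaluated against the nearest *preceding* reference run
in file order. This matches lab practice — a reference is taken, then the
masks of a session — and makes pairing deterministic; sessions are simply
blocks in the metadata file.

## Quality control

A run is flagged (never silently dropped) when the rig leaves its operating
bands: chamber pressure outside −7…−3 mbar relative to ambient; a mounted
mask whose pressure drop is within 0.1 mbar of zero (air is bypassing the
mask; the threshold is configurable since "close to zero" is a judgement
call); reference aerosol count median diameter (CMD) outside 60–100 nm or
chamber mass concentration outside 4–12 mg m⁻³; relative humidity above
40 %. The CMD is computed as the count-weighted median over the grid's
geometric class midpoints with linear interpolation inside the median class.

One caveat is documented deliberately: the spectrometer only sees particles
above 90 nm, so the *detected* CMD of an aerosol whose true CMD is below the
grid (e.g. 80 nm) is pushed upward by truncation — analytically to ≈ 128 nm
for the default simulator aerosol — and the CMD band check then flags a
perfectly valid generator setting. The check is implemented exactly as
stated because it operates on what the instrument reports; labs using a
below-grid CMD should widen `cmd_range_nm` in the QC policy or validate the
CMD with an instrument that covers the sub-90-nm range. The package's
defaults keep the band at 60–100 nm and the batch reports in `run_campaign()`
therefore do not filter on QC by default.

## Detector equivalence

The spectrometer-derived total passage is validated against the flame
photometer with Lin's concordance correlation coefficient,

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

with population ($n$-denominator) moments. The squared location term is the
canonical definition; an audit option `form = "printed"` reproduces an
unsquared variant that circulates in print but can exceed 1 and breaks the
symmetry $\rho_c \le |r|$, so it is excluded from inference. Restricted-range
results (default: pairs with both readouts ≤ 10 %, the span containing all
certification limits) condition on **both** members of a pair — the
conservative reading, since conditioning on one detector only would admit
pairs the other detector disputes. Subsets with fewer than two pairs are
reported as not estimable rather than extrapolated.

## Batch statistics and categorisation

Per-mask headline passages aggregate into violin statistics: quartiles by
linear interpolation (type-7), whiskers at the most extreme observations
within $1.5\,\mathrm{IQR}$ of the quartiles, and a Gaussian KDE with
Scott's-rule bandwidth evaluated on 256 points (the exported KDE documents
its bandwidth instead of matching any plotting library's defaults; the test
suite checks it integrates to 1 within $10^{-3}$ on its grid). Two headline
weightings are provided because certification practice is ambiguous between
them: `mass_weighted` (the total-mass passage, default, matching the
photometer-based standards) and `unweighted` (the plain mean over defined
size classes, which weights small particles more heavily). Batch compliance
is *mean ≤ limit*, the framing used for batch-level quality monitoring; the
per-mask exceedance fraction is reported alongside because per-mask
certification judges individuals. Ties at the limit count as compliant:
the standards phrase limits as a *maximum* passage.

The size profile averages per-class passages over the batch's masks and
summarises classes whose lower edge lies in 90–500 nm by default — the
submicron span where counting statistics are strong; the range is
configurable up to the full grid. Since the profile is a per-class
construct, its median and maximum are unweighted across classes. The A/B/C
category uses the crisp rule — A: median and max ≤ limit; B: median ≤ limit
< max; C: median > limit — with ties resolving toward compliance. The
relative standard deviation across classes (population SD / mean) is
reported as a continuous uniformity measure; a default annotation threshold
of 0.5 is exposed purely as a heuristic and never enters the category.

## The simulator

The synthetic campaign generator exists so that every stage above is
testable against planted ground truth. It emulates:

* a lognormal number-size distribution (default CMD 80 nm, GSD 1.8 — a
  mid-band NaCl test aerosol) discretized over the grid; the default number
  concentration of $3.3\times10^6$ cm⁻³ was calibrated analytically, once,
  so the detected chamber mass concentration is ≈ 8 mg m⁻³, the midpoint of
  the 4–12 mg m⁻³ validity band;
* a start-up transient, ramp factors $(0.5, 0.8, 1, 1, 1)$ per minute, so
  that discarding the first two minutes is consequential in tests;
* per-minute, per-class independent Poisson counting at the LAS sample flow
  (default 0.1 L min⁻¹) with an optional dilution factor;
* size-dependent penetration as a Gaussian in log-diameter around an MPPS
  (defaults: peak 4 % at 200 nm, curvature 0.5) — the simplest unimodal
  shape consistent with depth filtration; mask-to-mask variability as one
  lognormal multiplier on the whole curve (default σ 0.25) plus a defect
  mixture (default 2 % of masks with flat 30 % penetration), the fewest
  parameters that reproduce bimodal batch spreads;
* a flame photometer reading the true stream mass concentration times
  $1+\varepsilon$, $\varepsilon \sim N(0, \mathrm{CV})$ truncated at −1
  (default CV 1 %).

It deliberately does **not** model single-fiber filtration physics,
electrostatic charge decay, filter loading, counter coincidence or dead
time, optical-vs-geometric diameter differences, or correlated drifts of the
aerosol generator. Passing tests therefore demonstrate that the evaluation
pipeline is correct and unbiased *given* Poisson counting and a stable
aerosol — not that any physical mask behaves like the planted curves.

## Numerical choices and problem sizes

All randomness flows from explicit integer seeds; fixed seeds reproduce
campaigns byte-for-byte through CSV export. Grid-equality checks use a
relative edge tolerance of $10^{-9}$; algebraic identities are asserted at
$10^{-12}$; estimator-recovery tests use 3-standard-error bands. The test
suite works at reduced aerosol concentration ($3.3\times10^4$ cm⁻³,
≈ $1.4\times10^6$ expected counts per minute) — far above the $10^5$ counts
where Poisson error is negligible for these checks, while keeping the full
suite under a minute: 200-seed recovery runs for planted flat penetrations,
100-seed runs per planted A/B/C category with 20-mask batches, and a
60-mask detector-equivalence campaign at full concentration. The acceptance
script recovers the FFP2/FFP3/KN95 limits by 14-step bisection of the
planted passage against the batch verdict, resolving the boundary to
≈ 0.001 %.

## Known limitations

* The count-to-mass conversion uses the lower-edge (minimum-volume) sphere;
  absolute mass concentrations are biased low relative to a mid-point
  convention, a constant factor per class that cancels in all passages.
* The CMD validity check inherits the instrument's 90-nm floor (see above).
* The concordance analysis provides no confidence intervals; the bootstrap
  hook is intentionally left out of the certified outputs.
* Production-date effects are tabulated, not modelled.
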