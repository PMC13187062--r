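---
title: "Methods: histomorphometric identification of burned bone fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histomorphometric identification of burned bone fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteohist)
```

## The measurement model

Cortical bone in most adult mammals is dominated by secondary osteons:
roughly cylindrical remodelling units with a central vascular (Haversian)
canal. On a transverse slice each complete osteon contributes two nested
closed contours, and the two quantities the pipeline works with are the
osteon cross-sectional area (On.Ar) and the Haversian canal
cross-sectional area (H.Ar), both in µm².

`polygon_area()` computes contour areas with the shoelace formula on the
traced vertex list and scales by the squared pixel pitch. This matches the
polygon-ROI semantics of interactive tracing tools: the contour is the
measurement, not a pixel mask. Pixel-mask counting appears in the test
suite only as an independent oracle on synthetic images, where the two
approaches must agree to within boundary-pixel error. Coordinates are
0-based pixel centres and may be fractional; vertex order, starting vertex
and orientation do not affect the result. Self-intersecting contours are
rejected with the offending edge pair named, because a figure-eight trace
has no well-defined enclosed area; repeated closing vertices are tolerated.

Specimen summaries use the arithmetic mean and the sample SD (n − 1
denominator) with SE = SD/√N. The n − 1 choice is stated prominently
because published summary tables in this field rarely say which
denominator they used; with the osteon counts involved (3–138) the
difference is within the rounding of the reported values. Nothing is
rounded internally; `round_report()` (half away from zero, one decimal)
exists only for formatting, mirroring how such tables are conventionally
printed.

## The burning-shrinkage interval

Gray (calcined) bone colour indicates burning at roughly 500–700 °C.
Experimental burning data show no shrinkage of osteons or canals at
500–600 °C, and shrinkage to about three-quarters of the original area at
700 °C (observed post/pre ratios: 76.6 % for osteons, 76.4 % for canals,
stored as provenance in the model object). The model therefore brackets
every measured area between:

* **lower bound** — the measured value (no shrinkage, 500–600 °C), and
* **upper bound** — the measured value / 0.75 (shrinkage at ~700 °C).

The operational factor is the single rounded 0.75 for both metrics; using
the metric-specific empirical ratios would change the upper bounds by
under 1 %, well inside the measurement SDs. SDs are divided by the same
factor as means: the model is a deterministic linear rescaling of areas,
and linear scaling scales every moment of the distribution identically.
Consequently `apply_shrinkage_bounds()` is homogeneous of order one, which
the property tests exercise directly. Temperatures above 700 °C are
rejected for quantitative use — above that, histological structure becomes
too indistinct for the measurement stage to be meaningful, so a scale
factor would convey false confidence. `color_to_temperature()` returns
coarse, flagged ranges for non-gray colours; only gray feeds the
quantitative model.

## Games–Howell from summary statistics

Osteon-area variances differ strongly across taxa (reference SDs span two
orders of magnitude), so pairwise comparisons use the Games–Howell test,
which assumes neither equal variances nor equal N:

$$t = \frac{|m_a - m_b|}{\sqrt{s_a^2/n_a + s_b^2/n_b}},\qquad
\nu = \frac{(s_a^2/n_a + s_b^2/n_b)^2}
{\frac{(s_a^2/n_a)^2}{n_a-1} + \frac{(s_b^2/n_b)^2}{n_b-1}},\qquad
p = 1 - F_{q}(t\sqrt{2};\, k, \nu)$$

where $F_q$ is the studentized-range CDF. The test operates purely on
(mean, SD, N) triples, so published summary tables are sufficient input;
reference rows reporting SE are converted by SD = SE·√N
(`dispersion_to_sd()`), with the dispersion kind kept as an explicit tag
in the database rather than silently normalised at load time.

`studentized_range_cdf()` validates its arguments and evaluates the CDF
through R's `ptukey()`, which integrates the range distribution against
the chi density. Correctness is established two independent ways in the
tests: a Monte-Carlo oracle (range of k standard normals over an
independent χ/√df scale estimate, 10⁶ replicates per (k, df) grid point,
agreement within 3 Monte-Carlo standard errors) and the closed-form
k = 2 reduction $F(q; 2, \nu) = 2T_\nu(q/\sqrt2) - 1$, which also makes
the k = 2 Games–Howell test numerically identical to `t.test()`'s Welch
test — a cross-check the suite performs on constructed samples with exact
moments. A type-I calibration (2000 seeded null replicates at k = 2,
n = 30) confirms the rejection rate sits inside the binomial 99 % band
around 0.05.

**Family size.** The studentized-range family size k is a genuine design
opening: when a published analysis delegates the test to closed-source
software, the family it used is not recoverable. The default is k = 48,
the number of groups compared per metric in the packaged analysis (3
fragments + 45 reference specimens), exposed as a configuration knob.
Sensitivity is documented rather than hidden: the elephant-scale
exclusions are untouched by any k in [10, 60], while the most marginal
headline comparison (the smallest fragment–giant-deer On.Ar contrast
under maximal shrinkage, p = 0.041 at k = 48) crosses 0.05 near k ≈ 55.
The acceptance suite asserts the full [10, 60] range and therefore
records that boundary case as a known failure rather than narrowing the
range after the fact.

p-values are clipped to [0, 1] and printed as "< 0.001" below that floor;
significance is the strict inequality p < α with α = 0.05 by default.
Exact reproduction of any previously printed p-value is deliberately not a
goal: such values depend on the unprinted family size and on raw data
behind the summaries. Classifications (significant / not) are the stable
output.

## Range rectangles and classification

For the bivariate screen, each taxon group is summarised as the axis-
aligned rectangle spanning the minimum-to-maximum *mean* On.Ar and *mean*
H.Ar across its member specimens — a deliberately conservative envelope of
central tendencies, not of within-specimen variation. Each fragment is the
rectangle from its no-shrinkage means (lower-left corner) to its 700 °C
means (upper-right corner). Overlap is tested on closed intervals: a
shared edge counts. This tie-break matters in exactly one place — a large
bovid mean sits 32 µm² below one fragment's upper bound — and the closed
convention keeps that genuinely marginal contact as an overlap instead of
manufacturing an exclusion from a boundary technicality.

The rectangle stage and the statistical stage intentionally use different
row sets: rectangles are built from **all** reference rows (including
literature-derived ones, which broaden the envelopes and so make
exclusion harder, the conservative direction), while Games–Howell uses
only the internally measured rows (`filter_statistical_set()`, 45 of 58),
whose SDs can be reconstructed reliably.

A group is **excluded** only when both lines of evidence agree: no
rectangle overlap *and* every member specimen with data differs
significantly from the fragment on at least one metric under *both*
shrinkage scenarios. Requiring unanimity across members and scenarios
makes exclusion a strong claim; groups failing the geometric test but not
the statistical unanimity are reported as *indeterminate*. A config flag
(`criterion = "either"`) relaxes this for exploratory use. Fragments
showing plexiform bone receive a qualitative note (plexiform bone is
typical of artiodactyls, some carnivores and perissodactyls, and absent
in adult humans) and no quantitative classification — plexiform tissue has
no osteons to measure.

Carnivore groups routinely overlap the fragment rectangles; they are
reported as candidates like any overlapping group, with no attempt to
rank candidates probabilistically. Species-level discrimination inside
the medium-artiodactyl group is out of scope: the member taxa's ranges
interleave too strongly for area statistics alone.

## Synthetic data: what it emulates and what it does not

`generate_population()` draws paired (On.Ar, H.Ar) values matching target
mean/SD/N. The default marginal is a normal truncated at zero with
parameters moment-matched *numerically on the truncated scale* — relevant
because one packaged fragment has an H.Ar SD of 0.74 × mean, where naive
parent-scale matching would miss the targets by several percent. A
lognormal alternative (closed-form matching) is provided since no
distributional form is established for osteon areas. Pairs couple through
a Gaussian copula with default correlation 0.3 — a plausible positive
value, flagged as an assumption, not an empirical estimate — and canal
draws are constrained below their paired osteon draw by bounded redraws.

`generate_slice()` renders non-overlapping circular osteons (bright
annulus, dark lumen, mid-gray matrix, additive Gaussian noise) with
ground-truth contours polygonised at 256 vertices, where the polygon-to-
circle area deficit is below 0.05 %. Circles keep ground truth analytic;
real osteons are irregular, but irregularity is irrelevant to an
area-based pipeline. The images emulate none of the physics of real CT —
no beam hardening, rings, phase contrast, or taphonomic blurring — so
passing the synthetic end-to-end test demonstrates that the *measurement
and inference chain* is correct, not that contour tracing on degraded
archaeological material is easy. Slice packing is rejection-sampled with
a 40 % area cap and bounded retries; failures suggest reducing the count.

All generators are deterministic under a fixed seed (seeds are recorded
in output attributes and file headers), and generation restores the
caller's RNG state.

## Numerical and interface choices

* Degenerate inputs fail loudly and early: zero-area contours, canal ≥
  osteon area (a mis-trace signature), canal vertices outside the
  outline, n = 1 where an SD is required, unknown taxa, unknown colours,
  missing scenario tables.
* Problem sizes in the routine test run are chosen to give stable
  verdicts at interactive cost: 10⁶ Monte-Carlo replicates per CDF grid
  point, 2000 type-I replicates, n = 5000 for generator moment recovery
  (2 % tolerance ≈ 2.7 standard errors for the dominant metric), n = 500
  for the 2-SE recovery check.
* `run_full_analysis()` writes CSV/JSON with fixed field order and fixed
  numeric formatting, so identical configurations give byte-identical
  outputs; the plot file is excluded from that guarantee.
* Stage failures abort with the stage name and remove partial outputs.

## Known limitations

* Osteon size varies within a single bone, and a sub-centimetre fragment
  need not represent its bone of origin; exclusions are therefore more
  robust than candidacies, and the strongest supported claim is at the
  body-size/order group level.
* The shrinkage interval treats temperature as bracketed, not estimated;
  no per-specimen temperature inference is attempted beyond the colour
  lookup.
* Reference coverage is uneven (one specimen for several taxa), making
  some group rectangles degenerate points; those groups can be excluded
  but their candidacy would be fragile.
* The summary-statistics route cannot recover decisions that depend on
  raw per-osteon data (e.g. exact historical p-values); it is designed
  for the common situation where only published tables survive.
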