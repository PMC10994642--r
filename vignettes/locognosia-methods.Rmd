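---
title: "Measuring touch localization after nerve injury: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring touch localization after nerve injury: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locognosia)
```

## The measurement problem

Locognosia — the ability to say *where* on the skin one was touched — is a
sensitive index of recovery after median or ulnar nerve transection and
repair. In the digital-photograph test implemented here, an experimenter
stimulates 18 marked points on the volar distal pads (two on the radial
thumb, four quadrants on each finger), over five randomized blocks, and the
participant clicks the felt position on a photograph of their own hand. The
raw data for one hand are therefore 90 target–response pairs in image
pixels, plus the hand's geometry: pixel-to-mm calibration factors, one axis
angle per digit, and region polygons for the five digits and the palm.

This package implements the full analysis chain for such sessions:
error metrics, misreferral structure, nerve-territory group statistics, the
modified Marsh zone score used for concurrent validity, and a synthetic
session generator with known ground truth so that every stage is testable
without clinical data.

## Error model

For a target–response pair, the signed pixel differences are converted to mm
with separate x and y factors, `Ex = fx * (x_r - x_t)`, `Ey = fy * (y_r - y_t)`,
and the absolute error (error of localization) is the Euclidean norm
`E_abs = sqrt(Ex^2 + Ey^2)`.

The directional decomposition resolves this error along each digit's axis.
The digit axis angle θ is measured in degrees from the image's lower edge to
the digit midline; in a fingertips-up photograph a vertical digit has
θ = 90°. Images use raster coordinates (y grows downward), so the unit
*distal* vector is `(cos θ, −sin θ)` and the decomposition in the default
`orthogonal` mode is

* `E_long = Ex·cos θ − Ey·sin θ` — positive distal, negative proximal;
* `E_trans = s·(Ex·sin θ + Ey·cos θ)` — positive ulnar, with `s = +1` for
  right hands and `s = −1` for left hands, because a palmar view of a right
  hand has the ulnar side at +x while a left hand has it at −x.

This is a proper rotation, so `E_long² + E_trans² = E_abs²` (asserted at
1e−9 relative tolerance throughout the suite), and the canonical signs make
a *proximal* response bias appear as a negative mean `E_long` and a *radial*
bias as a negative mean `E_trans` on either hand.

A second mode, `as_printed`, evaluates the legacy formulas
`E_long = Ex·sin θ + Ey·cos θ` and `E_trans = Ex·cos θ + Ey·sin θ`
verbatim. These two expressions are not orthogonal to each other — their
squares do not sum to `E_abs²` except at special angles — and they carry no
hand-side mirror. We expose the mode for literal reproduction of previously
computed values, but the orthogonal projection is the default because the
Pythagorean identity is the only reading under which "components of the
error" is coherent; the suite asserts that the two modes genuinely differ
away from θ ∈ {0°, 90°} so the distinction cannot silently vanish.

Angles are stored in degrees in session files and converted internally; all
aggregation is in double precision; geometric comparisons in the tests use
1e−9 relative tolerance.

## Misreferrals

A response on a different digit than the one stimulated, or on the palm, is
a *misreferral*. Error magnitudes are undefined across digits (straight-line
vs along-skin distance is ambiguous, and digit-to-digit distance depends on
posture), so misreferral trials are excluded from error means and analyzed
separately — `aggregate_errors()` reports them as `n_excluded`.

Region classification follows the crease rule: a response exactly on the
permanent crease separating digits from palm belongs to the adjoining
digit; strictly palm-side of the crease is the palm. Two boundary situations
the rule leaves open are resolved deterministically: a point on a boundary
shared by two digits goes to the digit whose midline (the axis line through
the digit polygon's centroid) is nearest, ties to the lower-indexed digit;
a point in no region and not palm-side of the crease is flagged
unclassifiable, warned about, and excluded from both error and misreferral
statistics. The interior test is `mgcv::in.out()`; boundary membership is an
exact point-to-segment distance test with a 1e−9 px tolerance, and the suite
checks the whole classifier against an independently written ray-casting
oracle on 10,000 random points.

Misreferral frequency per hand is the count divided by the number of
classifiable trials (90 in a complete session; incomplete sessions are
accepted with a warning and use their actual count). For group comparison
the proportions are arcsine square-root transformed, `asin(sqrt(p))`, which
stabilizes variance when many participants sit at or near zero.

Because the thumb carries 2 of the 18 targets and each finger 4, equal
per-stimulation misreferral risk predicts a per-digit share equal to the
digit's target share: 11.11% for the thumb and 22.22% for each finger.
Observed per-digit counts are tested against this with a plain chi-squared
goodness of fit, `X² = Σ(O−E)²/E`, df = 4, no continuity correction;
expected cells below 5 trigger a warning rather than an exact-test switch.
Directionality is summarized as a 5×6 confusion matrix (rows = stimulated
digit, columns = response digit or palm) of proportions of the hand's total
misreferrals; for controls the two hands' matrices are averaged, using only
hands that made at least one misreferral (a zero-misreferral hand has no
defined proportions). Participants with no misreferrals contribute a
proportion of 0 (arcsine 0) to group analyses rather than being dropped.

## Nerve territories and matched controls

Impairment is evaluated within the injured nerve's territory: all D1–D4
targets (14) for median injuries, all D4–D5 targets (8) for ulnar, all 18
for combined injuries. D4 belongs to *both* territories deliberately — the
anatomical border runs through D4 and varies between individuals. The
homologous targets (same digit and subzone) on the uninjured hand form the
Uninj condition; patients with partial lesions are grouped by their injured
nerve.

Control data are "formulated to match" the patient composition: with `n`
controls and patient counts (median, ulnar, both), the median and ulnar
shares are rounded to the nearest integer and the remainder is assigned to
the both-nerves condition — with 33 controls and a (5, 8, 5)/18 composition
this yields (9, 15, 9). The nearest-integer rule is inferred from those
printed counts; if a degenerate composition makes the remainder negative,
largest-remainder apportionment is used instead (and logged). Which control
lands in which condition is uniform at random under a recorded seed; counts
never depend on the seed. Before pooling, a paired t test across controls
compares dominant and nondominant hands; at p ≥ 0.05 each control
contributes the mean of its hands, otherwise hands are kept separate and
flagged.

## Gated statistical procedures

All group statistics run on participant-level means (trial-level modeling is
out of scope). The decision trees are pure functions of their gate p-values:

* **Paired** (Inj vs Uninj): Shapiro–Wilk on the paired differences at
  α = 0.05; normal → paired t, otherwise Wilcoxon matched-pairs signed-rank.
* **Unpaired** (patients vs controls): Levene's test (center = median,
  α = 0.05) chooses pooled vs Welch variance handling; Shapiro–Wilk on the
  internally studentized residuals (each group centered and scaled by its
  own spread) sends non-normal data to Mann–Whitney. Studentizing matters:
  raw pooled residuals of heteroscedastic normal groups look non-normal, and
  the gate would then answer the question Levene already answered.
* **One-sample bias tests**: directional error means against zero, run per
  digit (D2, D5), component, and group, with a Bonferroni-corrected
  threshold α/family. The family size is a parameter (default 6 = 3 groups ×
  2 components per digit analysis) because no canonical family is defined
  for this design.

Effect sizes: every t-based result carries partial eta squared,
`η_p² = t²/(t² + df)` (fractional df under Welch). For rank tests we report
`η² = Z²/N` with Z from the continuity-corrected normal approximation; this
is a documented package convention — there is no unique standard for rank
tests, and it will not reproduce effect sizes computed by other conventions.
Rank tests use the normal approximation with continuity correction
(`wilcox.test` defaults): at the n ≈ 18 typical of patient groups the
uncorrected approximation is measurably anticonservative. Degenerate inputs
(zero-variance differences) raise explicit errors rather than NaN; the one
exception is two identical samples, which return the trivial null result
(t = 0, p = 1, effect 0). Concurrent validity against external clinical
scores (sensory Rosen, Marsh) is a Pearson correlation on per-patient
difference scores, reported as r with df = n − 2 and r².

## Modified Marsh scoring

The Marsh test divides the distal pads into 20 quadrant zones; each of two
trials per zone is scored 2 (correct zone), 1 (edge-adjacent quadrant of the
same digit), 1 (same quadrant on a neighboring digit), or 0, and the sum is
expressed as a percent of the attainable maximum: median injuries test zones
1–14 (max 56), ulnar 15–20 (max 24), both 1–20 (max 80). The official zone
numbering and adjacency tables are distributed only on request, so the
default map numbers zones digit-by-digit from the D1 radial-distal quadrant,
takes edge-sharing quadrants as adjacent (diagonals are not), and same-digit
ordering forces the 14/6 split to divide D4 into radial (13–14) and ulnar
(15–16) halves — the only split consistent with the quadrant structure. All
three components are overridable via a JSON zone-map file for users holding
the official materials.

## The synthetic generator

`generate_session()` produces full sessions from known ground truth so the
pipeline's estimators can be checked for parameter recovery. What it
emulates: bivariate Gaussian response scatter expressed in the digit frame
(so planted biases live in the same coordinates the analysis measures, and
recovery is exact up to sampling noise); a proximal longitudinal bias
(−3 mm); a small radial transverse bias on D5 in healthy hands (−1.1 mm) that
grows to −7.05 mm under ulnar injury; multiplicative scatter inflation
(×2.5) on digits inside the injured territory; and a misreferral process
whose joint (from, to) distribution is a configurable kernel — healthy hands
concentrate 74% of misreferral mass on the D3↔D4 pair and never refer to
the palm, injured territories use a diffuse kernel that includes the palm.
Per-trial misreferral probability is shaped per digit as
`rate × J_d × N/n_d` (J_d the kernel's row mass, n_d the digit's target
count), which makes the expected overall rate equal the configured rate and
the joint distribution of events equal the kernel. Default rates are 0.02
per trial for healthy territory and 0.10 inside an injured territory.
The −1.1 mm, −7.05 mm and 74% anchors are published group-level values; the
scatter scale (4 mm), proximal bias, inflation factor and rates are chosen,
realistic values — absolute error magnitudes are reported only graphically
in the source literature.

The stylized hand is deliberately simple: rectangular digits above a
horizontal crease and a palm below it, near-vertical digit axes with ±3°
jitter, ≈0.25 mm/px calibration jittered per hand and axis, targets at
±5 mm transverse and 16/26 mm from the tip. Digits are generous — 40 mm wide
and 70–105 mm long — because non-misreferral responses are rejection-sampled
to stay on the stimulated digit (a response that left the digit would *be* a
misreferral, and a zero misreferral rate must yield zero detected
misreferrals). That rejection truncates the planted Gaussians at the digit
edge; at these dimensions the truncation shifts the recovered D5 bias by
under 0.1 mm and the recovered inflation ratio from 2.5 to ≈2.15, both well
inside the recovery tolerances the tests use (±0.3 mm; ±20%). Narrower,
more anatomical digits would push the inflation ratio out of its recovery
band — a real D5 is ~15 mm wide, which is exactly why severely inflated
real-world scatter manifests partly as misreferrals rather than on-digit
error. Misreferral responses are placed uniformly within the destination
region (no within-region distribution is published).

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: photograph distortion and calibration error
beyond axis-wise scale, curved or flexed digits and posture changes between
blocks, learning or fatigue across blocks, response-time structure, and any
correlation between a participant's error magnitude and misreferral rate.
Parameter-recovery results certify the estimators, not the realism of
clinical data.

## Problem sizes and determinism

Every random draw flows from explicit integer seeds (`withr::with_seed`);
the same seed reproduces sessions bit for bit, and `run_group()` is a pure
function of its inputs plus configuration, with a manifest recording seeds
and composition. The test suite sizes its simulations for tight but
practical runtimes: 10,000-point geometric oracles, 200 control sessions for
bias recovery, 50 patient sessions for inflation recovery, 2,000 replicates
per branch for the type-I calibration of the decision trees (each branch's
rejection rate is measured among the replicates its gates actually routed to
it), 500 replicates for gate-selection checks, and 20 small cohorts for the
end-to-end null calibration.

## Known limitations

* The `as_printed` mode reproduces the legacy directional formulas exactly
  as published, including their non-orthogonality; whether some unstated
  angle convention makes them correct in the original setting cannot be
  determined from the text, which is why both modes exist.
* The sign conventions behind published bias directions are not stated in
  the source literature; the canonical distal/ulnar-positive convention here
  is a package definition, chosen so the published proximal and radial
  biases come out negative.
* Rank-test effect sizes use the Z²/N convention and will not match values
  computed by other conventions.
* The inter-digit boundary tie-break (nearest midline, lower index on ties)
  is a package extension beyond the crease rule; it only matters for
  responses landing exactly on shared polygon edges.
* Group analyses operate on participant means and assume sessions are
  exchangeable across blocks; no trial-level or longitudinal modeling is
  provided.
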