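---
title: "A static biomechanical model of waist loading in manual lifting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A static biomechanical model of waist loading in manual lifting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waistload)
```

## The model

`waistload` implements a static sagittal-plane model of the load on the
lumbosacral (L5-S1) joint while a worker lifts an object in the stoop
posture — legs straight, trunk flexed forward, no torsion. The body above
L5-S1 is treated as a rigid lever pivoting at the disc; the erector spinae
muscle group, acting on a short moment arm of about 5 cm (2.98 % of
stature), balances the forward moments of the head and neck, the arms, the
upper trunk and the lifted object. Static equilibrium of moments gives the
muscle force

\[
F = (c_1 M + c_2 G)\,\sin\alpha ,
\]

where \(M\) is the worker's weight force, \(G\) the object's weight force,
and \(\alpha\) the trunk inclination from the horizontal. The coefficients
collapse the anthropometry:
\(c_1 = (j_1 k_1 + j_2 k_2 + j_3 k_3)/0.0298\) and
\(c_2 = k_2/0.0298\), where \(j_{1..3}\) are the weight fractions of the
head+neck, both arms, and the trunk above L5-S1, and \(k_{1..3}\,H\) the
distances of their centroids (and of the hands) from L5-S1. With the
standard Chinese male constants these round to \(c_1 = 3.42\),
\(c_2 = 9.06\), so \(F = (1976.76 + 9.06\,G)\sin\alpha\) for the 168 cm,
59 kg (578 N) reference worker.

The geometry ties \(\alpha\) to the height \(h\) of the object's centre of
gravity: with the arm hanging from the acromion,
\(\cos\alpha = (h/H + b - a)/k_2\), which for the standard constants is the
line \(3.70\,h/H - 0.63\). The admissible band
\(0 \le \cos\alpha < 1\) gives the valid lifting heights
\(28.6\ \mathrm{cm} \le h < 74.0\ \mathrm{cm}\).

Two model surfaces deserve explicit statement:

* **Rounded versus exact constants.** All published results of this model
  family are computed with the *rounded* two-decimal coefficients (3.42,
  9.06, cosine line 3.70/0.63). Near the upright end of the range the sine
  amplifies the third decimal of the cosine strongly (about 2 % in
  \(\sin\alpha\) at \(h = 72\)), so the rounded and exact forms genuinely
  differ there. The package therefore defaults to `mode = "paper_rounded"`
  and offers `mode = "derived"` (exact fractions) for sensitivity analysis;
  the two agree within 0.5 % for \(h \lesssim 64\) cm.
* **Intra-abdominal pressure.** The full moment balance includes a small
  relief term \(F_4 L_4\) (1 % of body weight on a 6.8 % of stature arm,
  about 13 N). The published closed form drops it; `erector_force()`
  follows that default and exposes `include_abdominal = TRUE` for the full
  balance.

## Recommended weight limit and comfort

The revised NIOSH lifting equation
\(RWL = LC \cdot HM \cdot VM \cdot DM \cdot FM \cdot AM \cdot CM\) is
adapted to Chinese male anthropometry: load constant 20 kg (the 23 kg
constant reduced 15 %), vertical reference 72 cm, horizontal distance
25 cm, sagittal lifting, single lifts (frequency 0.2/min, under an hour,
FM = 1), poor coupling (CM = 0.90), and travel distance \(D = 74 - h\) up
to the 50th-percentile functional hand height. That yields the closed form

\[
RWL(h) = 20\,(1 - 0.003\,|h - 72|)\,(0.82 + \tfrac{4.5}{74-h})\cdot 0.90 .
\]

No multiplier caps or distance clamps of the official applications manual
are applied: the short-travel limit \(D \to 0\) is precisely what makes the
adapted RWL grow without bound as \(h \to 74\), and only the unclamped form
reproduces the model's published values (34.80 kg at \(h = 70\)). Lifts
delivering at or above 74 cm are outside the model's scope — the geometry
anchors the travel distance to the standing hand height, a restriction
stated rather than resolved here.

Comfort is scored against the muscle force at the limit load:

\[
C = 1 - \mu_C = 1 - \frac{F}{F(RWL)},
\]

so \(C = 0\) exactly at the limit load (lifting index \(LI = 1\)),
\(0 < C < 1\) for acceptable loads, and \(C < 0\) for dangerous ones;
\(LI > 3\) is classified severely dangerous. Because \(F\) is linear in
\(G\), the force cost of one LI unit is exactly
\(c_2\,RWL\,g\,\sin\alpha\) — about 1300 N over mid-range heights
(`force_per_li()`).

The `limit` class is a measure-zero boundary, so `assess()` uses a tight
relative band (`tol = 1e-9`) around \(LI = 1\); `assess_batch()` defaults
to `tol = 1e-3` because batch inputs are typically recorded at two
decimals, and a mass entered as its own printed RWL should classify as
`limit`, not fall a rounding error to either side.

## Spinal stress validation

The L5-S1 load decomposes along and across the disc axis:

\[
\sigma = F + (0.47 M + G)\cos\alpha,\qquad
\tau = (0.47 M + G)\sin\alpha,\qquad
N = \sqrt{\sigma^2 + \tau^2},
\]

with 0.47 the upper-body weight fraction (the exact \(j\)-sum is 0.4726;
the published 0.47 is the default and the exact value is available via the
profile's `upper_body_weight_frac`). The model is accepted as usable if, at
the limit load \(G = RWL(h)\) (comfort 0), the resultant stays below the
3400 N NIOSH compression criterion across the working heights — the
criterion is a named, overridable constant, not hard-coded. On the integer
grid 34..72 cm the resultant bottoms out at \(h = 70\) cm (about 2653 N,
with an RWL of 34.80 kg) and peaks near \(h = 40\) cm at about 3377 N,
below the criterion everywhere:

```{r}
summary(waist_model())
```

## Numerical choices

* **g = 9.8 m/s²** exactly, everywhere: the published weight-force
  constants are built on it (59 kg → 578 N after the source's own integer
  rounding, which the standard profile preserves; exact conversion is used
  for any other body mass).
* The lifting index is computed as a mass ratio (kg/kg), not a force
  ratio; the two are identical since g is one constant, but the mass ratio
  avoids a needless kg→N→kg round trip.
* The valid height interval is closed at \(h_{\min}\), open at
  \(h_{\max}\) (upright, \(\alpha = 0\), is excluded). \(\cos\alpha\)
  evaluated at \(h_{\min}\) itself can land \(10^{-16}\) below zero in
  floating point; values within \(10^{-9}\) of zero are snapped to the
  boundary. Genuinely out-of-range heights are never clamped —
  `trunk_cosine()` flags them, and the force/RWL functions raise errors
  naming the valid interval, since silently clamping would fabricate
  forces outside the model's stated domain.
* The frequency-multiplier table is a discrete lookup; untabulated rates
  error by default, or round up to the next (more penalising) row with
  `conservative = TRUE`. The V < 75 cm column split is kept even in the
  Chinese adaptation (the source does not restate it for 72 cm); at the
  0.2/min default both columns agree anyway.
* In the bundled segment table the foot's centroid relative position is
  48.6 %; the source text's iliac-spine arithmetic prints 38.2 % for that
  term, but only 48.6 % reproduces the published 909 mm, so the table
  value is used.

## What the synthetic tasks emulate

`generate_fixture_tasks()` (also exposed as `simulate()` on the model
object) draws deterministic pseudo-random worker-task records: statures
uniform on 155–190 cm and body masses on 50–95 kg, spanning roughly the
5th–99th percentile band of adult male workers around the 50th-percentile
reference; object heights uniform over each worker's own valid range (with
a 2 % margin off the edges so records survive 0.1 cm rounding); and object
masses uniform on \([0, 2] \times RWL\), so lifting indices straddle the
limit line. These records exercise the model's domain logic and
classification, not real exposure data: they contain no measurement error,
no posture variation at fixed height, no correlation between stature and
mass, and only male anthropometry — passing tests on them shows internal
consistency of the model, not predictive validity for a real workforce.

## Problem sizes

The test suite and the reproduction script work at the model's natural
desk scale: the 39-point integer height grid 34..72 cm used for all sweep
extrema, oracle grids of at most a few hundred points, and synthetic
batches of up to 300 records. Everything is closed-form; no iteration or
simulation beyond these grids is involved.

## Known limitations

Static, sagittal, stoop-only: no dynamics (accelerations add to every
force here), no torsion or asymmetric postures (the AM factor is applied
but no asymmetric geometry is modelled), no squat technique, upward lifts
only. Only male 50th-percentile-anchored anthropometry is bundled — custom
profiles can represent any worker, but no female standard table exists in
the package. The comfort score models muscle stress only; psychological
and environmental components of perceived comfort are out of scope. The
L5-S1 standing height is proxied by the anterior superior iliac spine
height — an anthropometric approximation inherited from the source
standards, documented rather than corrected. And the LI→injury-risk
relation is known to be non-linear; the package classifies loads but does
not map LI to an injury probability.
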