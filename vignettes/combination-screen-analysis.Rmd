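---
title: "Scoring dose-matrix drug-combination screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dose-matrix drug-combination screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
```

comboscreen analyzes checkerboard (dose-matrix) drug-combination screens of
the kind used to find partners for an "anchor" drug: every library compound
is plated in a full factorial grid against the anchor, each axis a serial
dilution series plus a vehicle level, and the screen asks which pairs kill
cells beyond what the two single agents explain. This vignette lays out the
models the package implements, the parameters that matter, what the bundled
simulator does and does not emulate, and the numerical and design choices a
maintainer should know about.

## From raw signal to fraction affected

Each `(block, assay)` grid is normalized to its own vehicle-vehicle well:

$$v_{ijr} = \frac{y_{ijr}}{\overline{y}_{00\cdot}},$$

the fraction-of-control viability. Wells that outgrow the control keep
`v > 1` — clamping them would hide real (and sometimes diagnostic)
stimulation — but the derived fraction affected `fa = 1 - v` is clamped to
`[0, 1]`, because all downstream median-effect arithmetic works on
`log(fa/fu)` with `fu = 1 - fa`, which only exists inside the unit interval.
Replicates are aggregated by arithmetic mean with the standard error
reported. An activity readout (e.g. caspase luminescence) measured on a
congruent grid can be expressed per viable cell with
`normalize_activity_to_viability()`; wells below 1% viability are masked
rather than divided through, since a ratio of two near-zero luminescences
means nothing.

## Single-agent dose response

The median-effect model
$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m$$
describes a single agent by its median-effect dose `Dm` (the IC50) and
sigmoidicity `m`. The default fit is the classical linearization — least
squares of `log(fa/fu)` on `log D` — with a nonlinear refinement available.
Three censoring rules keep the linearization meaningful:

* **Boundary censoring.** `fa` is clamped to `[1e-4, 1 - 1e-4]` and dose
  levels at the clamp boundary are excluded: a well at 0% or 100% effect
  carries no slope information, only a bound.
* **Dose ceiling.** Doses above 10 µM (configurable) are excluded; at such
  concentrations off-target chemistry dominates and the values are not
  clinically translatable.
* **Plateau censoring** (`plateau_tol = 0.05` on the `fa` scale). Many drugs
  are partial-efficacy: viability floors at some `emax > 0` rather than
  zero. Once the observed response has plateaued, every higher dose repeats
  the drug's own ceiling; keeping those levels drags the fitted slope toward
  zero and inflates the effect-dose interpolation `Dx(fa)` by orders of
  magnitude, which in turn makes Bliss-null partners of such drugs read as
  strongly synergistic. Only the first level reaching within `plateau_tol`
  of the maximal observed `fa` is kept. The tolerance is set to about twice
  the per-well standard error under 10% replicate noise in triplicate, so a
  genuine slow approach to full effect is not mistaken for a plateau.

A four-parameter logistic (`fit_hill()`) is fitted alongside for curve QC;
the IC50s used by the combination-index machinery always come from the
median-effect fit, for internal consistency.

## Synergy surfaces and scalar scores

Two per-well reference models are computed on the replicate-mean viability:

* **Excess over highest single agent**: `v(i,j) - min(v(i,0), v(0,j))`.
* **Delta Bliss**: `v(i,j) - v(i,0)·v(0,j)`.

Negative values mean the combination kills more than the reference predicts.
Each surface is summarized by the sum of its negative wells, and both are
exported; neither gates hits.

The **combination index** at an interior well with observed effect `fa` is
$$CI = \frac{d_A}{D_{x,A}(f_a)} + \frac{d_B}{D_{x,B}(f_a)},$$
the two-term (mutually exclusive) form; `CI < 1` is synergy on the Loewe
scale, `CI = 1` additivity. A full matrix yields one CI per well and the
package must collapse them to one number per pair. Where the dilution factor
is shared between axes — true of both designs here — the matrix diagonal is
a constant-ratio ray, and for potency-shift (Loewe-type) synergy the
per-well CI is constant along it, so any location estimate over in-band
diagonal wells estimates the same quantity. Four policies are implemented:

* `diag_band_median` (default): median per-well CI over diagonal wells whose
  observed `fa` lies in the evaluation band `[0.25, 0.75]`. Pooling wells
  suppresses replicate noise; the median resists the occasional band-edge
  well where the fits interpolate poorly.
* `nearest_half`: the single in-band diagonal well nearest `fa = 0.5`.
  Unbiased but noisier (one well).
* `ray_fit`: the classical fixed-ratio evaluation — fit the median-effect
  model to the diagonal mixture and read CI at `fa = 0.5`, where slope error
  cancels (`Dx(0.5) = Dm`). Exact when the two agents share a slope, but the
  global line fit is biased when slopes differ strongly, because the mixture
  ray is then not itself median-effect shaped.
* `fa_band_min`: the minimum per-well CI over all in-band interior wells.
  As a minimum of many noisy values it is biased low under replicate noise
  and inflates false-positive calls; it is the right choice only for
  noise-free or heavily replicated data, where it reads the strongest signal
  on the surface.

The evaluation band is enforced for every policy: outside `fa` of roughly
25–75% the single-agent fits extrapolate, and a CI built on extrapolated
reference doses is reported as undefined (`no-effect-band`) rather than
guessed. The default band, thresholds and policy live in `screen_config()`.

The **beta ratio** is the maximal-efficacy co-filter:
$$\beta = \frac{v(\text{top}, \text{top})}{\min\big(v(\text{top}, 0),\, v(0, \text{top})\big)},$$
so `beta < 1` means the combination at top doses kills beyond the best
single agent's maximal effect. When the best single agent already drives
viability below 1% the ratio divides two near-zero numbers and is reported
undefined (`singles-saturating`). No standard closed form exists for this
quantity; the definition is isolated in `beta_parameter()` so it can be
swapped without touching anything else.

## Triage

A pair is a hit when both scores are defined and `CI < 0.5` **and**
`beta < 1`, with strict inequalities. Hits are ranked by CI, ties broken by
the Bliss negative sum and then pair id so exports are reproducible. Pairs
with undefined scores are never silently dropped: they are listed separately
and excluded from the scoreable denominator. `run_stage()` orchestrates a
stage end to end and pools the anchor's single-agent fit across all blocks —
the anchor is the same drug on every plate, and a per-block refit would
discard the vast majority of its measurements while injecting coherent
per-pair CI error. `aggregate_by_class()` then tabulates tested/hit counts
per mechanism-of-action class.

Note one degenerate point: a planted potency shift of exactly 2 puts the
true CI exactly on the 0.5 threshold, where the strict inequality makes the
call undecidable in principle and seed-dependent in practice.

## The simulator and its study conditions

`simulate_library()` builds the screen the pipeline is tested on. Single
agents follow a four-parameter logistic
`v(D) = emax + (1 - emax)/(1 + (D/ec50)^slope)`. Defaults emulate a
primary screen: 6×6 blocks (5 five-fold dilutions plus vehicle per axis),
triplicate, multiplicative lognormal noise with CV = 10% (lognormal keeps
signals positive), library top dose 10 µM, `ec50` log-uniform across the
nonzero dose range, slope uniform on [0.5, 3], viability floor `emax`
uniform on [0, 0.4]. The confirmatory design is 10×10 with
`sqrt(10)`-fold steps, so nine steps span the same four-log range. The
anchor drug is a full-kill curve (`ec50` 400 nM, slope 1.5, `emax` 0) plated
to 2.5 µM: the combination-index machinery presumes a
median-effect-describable anchor whose top-dose viability stays measurable
(a floored or fully saturating anchor would invalidate CI or beta for every
pair at once, nulls and synergists alike — a real screen anchors on a drug
for which the score is computable).

Interaction models: `bliss_independent` multiplies viabilities (the null),
`hsa_equal` takes the better single agent, and `potency_shift` plants
synergy as a symmetric Loewe-style shift — the well's effect solves
$$\psi\,\frac{d_A}{D_{x,A}(f_a)} + \psi\,\frac{d_B}{D_{x,B}(f_a)} = 1,$$
i.e. both agents' dose requirements drop ψ-fold at fixed ratio, which gives
the planted surface a closed-form per-well combination index of exactly
`1/ψ` — a brute-force-checkable target. ψ = 1 is exact Loewe additivity, the
sham surface a drug combined with itself must score CI = 1 on. Axis wells
always show the plain single-agent response. Synergists draw ψ uniform on
[2, 8] and mechanism-of-action labels from a synergy-enriched class pool, so
class-level aggregation has recoverable structure.

What the simulator does **not** emulate: plate-position and edge effects,
batch drift between plates, dispensing errors, dose-dependent assay
interference, cell-line panels, and any biology behind the interaction
(signaling feedback, sequence-of-addition effects). Passing tests therefore
demonstrate that the estimators recover known surface structure under
well-behaved noise — not that real screen data meet these assumptions.

## Numerical choices

* Loewe surface construction inverts the single-agent curves in closed form
  and solves for `fa` by bisection (`uniroot`, tolerance 1e-13); effects
  beyond a partial-efficacy agent's ceiling put its reference dose at
  infinity, which the solver handles naturally.
* The 4PL fit uses Levenberg–Marquardt with deterministic initialization
  (`e0 = 1`, `emax = min v`, `ec50` at the geometric mid-dose, slope 1);
  non-convergence is flagged, with the median-effect IC50 as fallback.
* Exported CSVs render doubles with 17 significant digits and are read back
  with a correctly-rounded parser, so write–read is bit-identical and seeded
  runs are byte-identical across repeats.
* Degenerate inputs are first-class: inactive compounds (< 2 usable dose
  levels, or non-positive slope) raise a classed fit error that the pipeline
  converts into flagged, non-hit report rows.

## Problem sizes

The bundled tests and the acceptance script exercise the pipeline at the
scale of a small primary screen: 200-compound libraries with 10% planted
synergists, triplicate 6×6 blocks at 10% noise, repeated over ten seeds for
the operating characteristics, plus 100-draw identity checks for the Bliss
and HSA references and 50-draw sham-CI checks. These sizes give the
stochastic quantities (sensitivity, false-positive rate, median parameter
recovery) stable two-digit estimates while a full run completes in minutes
on a laptop.

## Known limitations

* The combination index inherits the median-effect model's assumptions;
  for partial-efficacy agents it is meaningful only below the achievable
  effect ceiling, which is why plateau censoring and the evaluation band
  exist. Pairs whose informative wells all fall outside the band are
  reported undefined rather than scored.
* Bliss independence and Loewe additivity genuinely disagree for shallow
  dose-response slopes; a Bliss-null pair of shallow drugs *is* Loewe-
  synergistic, and no estimator choice removes that — it is a property of
  the references, visible in the simulator as a small residual
  false-positive floor.
* The beta definition is a pragmatic maximal-efficacy ratio, not a
  literature standard.
* No statistical null model is attached to the synergy scores (no
  resampling-based significance); the screen triage is a ranking-and-
  threshold procedure, and confirmatory designs exist precisely to re-test
  its calls.
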