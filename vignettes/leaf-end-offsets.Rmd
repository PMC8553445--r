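---
title: "Leaf-end offsets of a rectangular carbon-ion MLC: model and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf-end offsets of a rectangular carbon-ion MLC: model and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcoffset)
```

## The model

A diverging carbon-ion beam is collimated by an MLC with rectangular
leaf ends. Three axis positions are attached to one leaf setting: the
light-field edge `X_tang` (projection of the leaf-bottom inner corner,
equal to the nominal half-field by construction), the planning position
`X_mlc` (projection of the leaf-end midpoint), and the radiation edge
`X50` (the point receiving 50% of the central-axis dose).

Two ingredients determine `X50`:

1. **Attenuation.** Beam nuclei survive a material path `x` with
   probability `exp(-x / lambda)`. This single exponential is the whole
   physics model: no energy-loss, scatter, source-size or secondary
   particle terms. The half-value path is `d50 = lambda ln 2`.
2. **Projection geometry.** An effective point source on the axis at
   distance `sad` from the isocenter, with the leaf-bottom plane at
   `z_b`. A ray at angle `t` that clips the vertical end face (lateral
   position `x_leaf = h z_b / sad` for half-field `h`) enters at depth
   `x_leaf / tan t` and exits through the leaf bottom, cutting the
   slant chord

   `chord(t) = (z_b - x_leaf / tan t) / cos t`.

`X50` is `sad * tan(t*)` where `chord(t*) = d50`. The chord is measured
along the ray (the `1/cos t` obliquity); at the sub-2-degree divergence
angles of this beamline the correction is below 0.07%, smaller than the
4-decimal quantization of the reference tables, so whether the original
computation applied it is indistinguishable at print precision.

The planning offset is `(X50 - X_mlc) * 10` mm and the light-radiation
agreement `(X_tang - X50) * 10` mm. Because `d50` is strictly between 0
and the maximum chord for every shipped material, `t*` is bracketed by
the corner angles `theta` and `theta''`, which is exactly the statement
that `X50` always lies between `X_tang` and `X_mlc` — both corrections
are negative at positive half-fields.

### Numerical solution

`chord(t)` is strictly increasing on `(theta, theta'')`, so the solve is
recast as the fixed point `z_enter = z_b - d50 * cos(atan(x_leaf /
z_enter))`, a contraction that converges to machine precision in a
handful of iterations (the iteration stops at `|dz| < 1e-12` cm and the
result is verified to reproduce the chord within `1e-8` cm). It is
deterministic; no randomness enters anywhere in the solver. The
degenerate `half_field = 0` setting is handled as the exact-zero limit
(all projections 0), not an error, and mirrored leaves
(`direction_sign = -1`) are solved by symmetry with every projection and
angle negated.

## Parameters and conventions

| parameter | default | units | meaning |
|---|---|---|---|
| `sad` | 263.3 | cm | source-to-isocenter distance used for projections |
| `source_to_leaf_bottom` | 196.8 | cm | effective source to the leaf-bottom plane |
| `max_half_field` | 6 | cm | rated half-field (12 × 12 cm maximum field) |
| `lambda` (W100) | 2.7 | cm | attenuation length of tungsten at 400 MeV/n |
| `lambda` (others) | straggling range | cm | see below |
| `thickness` | per material | cm | leaf thickness along the beam |

**Effective geometry.** The measured virtual source sits 257.8 cm from
the isocenter with 191.3 cm to the MLC bottom. The planning system
projects from the nominal SAD of 263.3 cm, so the virtual-source shift
is folded into an effective source-to-leaf-bottom distance that
preserves the physical leaf-bottom-to-isocenter gap: 263.3 − (257.8 −
191.3) = 196.8 cm (`derive_projection_geometry()`). This pair — not the
raw virtual-source distances — reproduces the reference geometry
columns to all four printed decimals (e.g. `X_mlc` = 6.0967 cm at
half-field 6, 9.1450 cm at 9). Both constants are plain arguments of
`beamline_geometry()` and can be overridden.

**Attenuation lengths.** For tungsten, `lambda` = 2.7 cm is stated
directly and is the only value consistent with the tabulated half-value
path and the tungsten offset column; the tabulated tungsten straggling
range (2.62 cm) is retained as a separate field but not used as
`lambda`. For the other eight alloys no attenuation length is stated
anywhere, so the package adopts `lambda :=` tabulated straggling range;
that convention reproduces the published nine-material offsets within
about 0.5% at the largest field. It is an inference, not a measurement,
and the shipped CSV (`inst/extdata/mlc_materials.csv`) accepts an
explicit `lambda_cm` column for users who have better values.

**Half-value path.** The package uses exact `ln 2`, giving `d50` =
1.871497 cm for tungsten; the reference value 1.8711 cm reflects a
truncated `ln 2 ≈ 0.6930`. The 0.02% difference is far below every
tolerance used here.

**Units and signs.** All internal lengths are cm; the two clinical
corrections are reported in mm. Positive `direction_sign` means the
leaf travels away from the central axis; offsets keep the
`X50 − X_mlc` sign convention under mirroring, so a leaf over the axis
reports a positive offset of the same magnitude.

## Tolerances against the reference tables

The reference per-field tables were evidently computed through radians
rounded to 4 decimals, which injects position jitter of up to ±0.033 mm
into the dose-point columns (their offset column is visibly non-smooth:
consecutive steps range from −0.008 to −0.060 mm where the smooth model
steps by −0.0326 mm per half-centimetre). Regeneration tests therefore
compare:

- geometry columns (angles, `X_mlc`) exactly at print precision;
- offsets and light-radiation agreement within an absolute **0.04 mm**
  envelope at half-fields ≥ 2 cm;
- half-fields ≤ 1.5 cm for sign and monotone trend only, since ±0.033 mm
  of quantization noise dominates entries of magnitude ≤ 0.08 mm.

`generate_table2(paper_rounding = TRUE)` provides a forensic mode that
quantizes the 50%-ray angle to 4 decimals before projecting (geometry
columns, which the reference carries at full precision, stay exact).
It demonstrates the jitter mechanism — offset steps become strongly
non-uniform — but the original pipeline's exact rounding points are not
recoverable (the row-wise implied `d50` scatters between roughly 1.8
and 2.2 cm), so the mode reproduces the *character* of the noise, not
the row-by-row values.

## The ray-traced oracle and fixtures

`trace_profile()` recomputes the edge numerically: each axis position's
ray is classified as missing the leaf, clipping the end face, or
passing above the leaf-top corner (full slant thickness), and the dose
is the exponential survival of that chord with the open field
normalized to 1. Edge metrics extracted from traced profiles by linear
interpolation on a 0.001 cm grid agree with the analytic solver to
better than 1e-4 cm; this dual route (closed-form chord solve vs.
brute-force tracing) is the package's main self-check.

`generate_fixture_profiles()` writes seeded, byte-reproducible CSV
profiles with a JSON manifest of generator truth. Cases sample the nine
materials and half-fields uniformly in [1, 6] cm — the rated field
range — with optional additive Gaussian noise on relative dose
(`noise_sd`, default 0). What the fixtures emulate is only the
attenuation-model edge; they do **not** emulate effective source size,
in-leaf scatter, secondary particles or film-response blurring, all of
which widen a measured penumbra. Consequently the model 20–80% penumbra
(≈1.17 mm for tungsten at half-field 6) is a different, narrower
quantity than a measured film penumbra (≈2.7 mm at the same field,
growing linearly with field size), and passing the fixture tests says
nothing about those effects in real data.

## Calibration fit

`fit_calibration()` maps net optical density back to dose with a
monotone shape-preserving Hermite spline (Fritsch–Carlson slopes,
`stats::splinefun(method = "monoH.FC")`): it interpolates the knots
exactly, is monotone everywhere, is exactly linear on collinear data,
and recovers a saturating synthetic dose-response sampled at the nine
standard graded doses (5–200 cGy) to within 2% at mid-knot queries.
Extrapolation outside the calibrated response range is refused rather
than guessed. Film spatial response, scanner RGB handling and red-filter
physics are out of scope; the fit consumes (dose, net-OD) pairs only.

## Design choices made where the design was open

- **50% reference level**: the central-axis (open-field) dose, not the
  local plateau; fixtures normalize the open field to 1.
- **Combining multi-gap virtual-source estimates**: unweighted
  arithmetic mean, with the spread reported alongside — with only an
  upstream and a downstream gap there is no basis for weights.
- **Interpolation for edge metrics**: linear between samples; the
  first-order error at the 0.001 cm default grid is orders of magnitude
  below the 1e-4 cm agreement target.
- **Rated-field handling**: settings beyond the rated 6 cm half-field
  warn (a classed condition the table generators muffle, since the
  reference tables themselves extend to 9 cm); settings beyond twice
  the rated value error.
- **Problem sizes** in the test suite (60 half-fields for the
  betweenness sweep, 50 random oracle cases, 0.001 cm tracing grids)
  were chosen as the smallest sets that exercise every material and the
  full field range; the whole suite runs in a few seconds.

## Known limitations

- The single-exponential model has no energy dependence: `lambda` is
  valid for 400 MeV/n carbon ions only, and other energies need their
  own attenuation lengths.
- Non-tungsten attenuation lengths rest on the straggling-range
  convention described above.
- No 2-D leaf-bank effects: interleaf leakage, tongue-and-groove and
  rounded leaf sides are out of scope, as are Monte-Carlo secondary
  radiation doses.
- The measured 20–80% penumbra is not predicted, only the attenuation
  model's own edge width.
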