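# mlcoffset

Leaf-end offset corrections for carbon-ion multileaf collimators (MLCs).

## The problem

A passive-scattering carbon-ion beamline shapes its field with an MLC
whose leaves have *rectangular* (flat) ends, unlike the rounded leaf
ends of photon machines. Three positions on the isocenter axis then
disagree slightly for every leaf setting:

- **X_tang** — the visible light-field edge: the projection of the
  leaf-bottom inner corner. Equals the nominal half-field by
  construction.
- **X_mlc** — the planning-system leaf position: the projection of the
  leaf-end *midpoint*, which monitor-unit calculations reference.
- **X50** — the radiation field edge: the axis point receiving 50% of
  the central-axis dose.

For heavy charged particles the 50% point is set by nuclear attenuation
along the slant chord a diverging ray cuts through the leaf material.
Beam survival is single-exponential,

    N / N_B = exp(-x / lambda),

with attenuation length `lambda` (the interaction mean free path, a.k.a.
straggling range in the leaf; 2.7 cm for tungsten at 400 MeV/n, giving a
half-value path `d50 = lambda * ln 2 = 1.8715 cm`). The 50% ray is the
one whose chord through the rectangular leaf end equals `d50`: with the
leaf face at lateral position `x_leaf` and the leaf bottom at distance
`z_b` from the effective source, the chord of a ray at divergence angle
`t` is

    chord(t) = (z_b - x_leaf / tan t) / cos t,

and the package solves `chord(t*) = d50` by a fixed-point iteration,
projecting `X50 = SAD * tan(t*)`. Two clinical corrections follow:

- **planning offset** = `(X50 - X_mlc) * 10` mm — what the planning
  system must add to its stored leaf position;
- **light-radiation agreement** = `(X_tang - X50) * 10` mm.

Both are negative at every field size for all nine candidate leaf
materials shipped with the package: X50 always falls *between* the
light edge and the planning position.

The package also estimates the virtual source position from field-size
magnification at displaced planes (`f = g / (FS_gap/FS_iso - 1)`),
ray-traces numeric transmission profiles as an independent check and
fixture generator, extracts 20/50/80% edge metrics from measured
profiles, and fits a monotone film-calibration (H-D) curve.

Intended users: medical physicists commissioning or auditing a
carbon-ion treatment-planning system's MLC model.

## Worked example

```r
library(mlcoffset)
w <- mlc_materials()$W100        # pure tungsten: 6.24 cm thick, lambda 2.7 cm
solve_edge(leaf_setting(6), w)   # half-field 6 cm = the 12 x 12 cm maximum field
```

```
Leaf-end edge solution: W100, half-field 6 cm (direction +1)
  angles [rad]: theta 0.022784  theta' 0.023151  theta'' 0.023530  alpha 0.023002
  axis [cm]:    X_tang 6.0000  X50 6.0576  X_mlc 6.0967
  offset -0.3906 mm   light-radiation agreement -0.5759 mm   model penumbra 1.1702 mm
```

Reading it: the light field edge sits at 6 cm, the planning system
stores the leaf at 6.0967 cm, but the radiation edge is at 6.0576 cm —
so the planning system must correct its leaf position by −0.39 mm, and
the light field understates the radiation field by 0.58 mm. The model
penumbra (1.17 mm) is the 20–80% width of the attenuation model alone,
without source size or scatter.

The per-field tungsten table and the nine-material offset matrix:

```r
generate_table2(w, digits = 4)        # 18 half-fields, 0.5 .. 9 cm
generate_table3()                     # 9 materials x 9 half-fields, mm
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/mlcoffset offset -m W100 -f 9
Rscript inst/cli/mlcoffset table2 --out table2.csv
Rscript inst/cli/mlcoffset virtual-source --fs-iso 8 --fs-gap 8.46548 --gap 15
```

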