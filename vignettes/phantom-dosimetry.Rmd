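---
title: "Stylized phantom construction and photon Monte Carlo dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stylized phantom construction and photon Monte Carlo dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Internal dosimetry asks: when a radionuclide accumulates in one organ, how
much dose does each organ of the body receive? In the MIRD schema the answer
factorizes into biokinetics (cumulated activity per source organ, outside
the scope of this package) and geometry/physics, summarized by two
quantities:

* the **specific absorbed fraction** SAF(t ← s, E), the fraction of energy
  emitted in source region *s* at photon energy *E* that is absorbed in
  target *t*, divided by the target mass (kg⁻¹);
* the **S-value** S(t ← s), the mean absorbed dose rate to *t* per unit
  activity in *s* (here mGy per MBq·s), obtained by summing the nuclide's
  emission lines: photons weighted by yield, energy and SAF, plus the
  non-penetrating (electron) energy absorbed in the source organ itself.

Both depend on body size, organ masses and the geometric arrangement of
organs, which is why population-specific reference phantoms matter: the
package builds the Taiwanese adult reference man (TRM, 168.7 cm) and woman
(TRW, 156.2 cm) next to the classic ORNL stylized adult (178.6 cm) and
computes SAFs and S-values on all three with the same engine, so that
differences reflect anatomy rather than methodology.

# Phantom construction

## Body frame

Each phantom is a stack of quadric solids: an elliptic head cylinder
(semi-axes `A_H`, `B_H`, height `C_H`) on an elliptic trunk cylinder
(`A_T`, `B_T`, `C_T`, with z = 0 at the trunk base), and two mirror cone
legs of length `C_L` satisfying `x² + y² ≤ |x|·(A_T + (A_T/C_L)·z)` on
`−C_L ≤ z ≤ 0`. The head-region equations as printed are dimensionally
ambiguous about the head z-range; we adopt the stacked-segment reading
(head occupies `[C_T, C_T + C_H]`), which reproduces the printed total
heights exactly (168.7 / 156.2 / 178.6 cm). The `±` in the leg equation is
resolved as the standard mirror-cone convention (`+` branch for x > 0).

## Organ templates and calibration

Organs are instances of a built-in template registry
(`organ_templates()`): ellipsoids, clipped ellipsoids, cut elliptic
cylinders and concentric wall/content shells, anchored at the classic
stylized-adult positions (wedge-shaped liver cut by the plane
`x/35 + y/45 − z/43 ≤ −1`, paired posterior kidneys with a medial plane
cut, transverse half-ellipsoid pancreas, etc.). The baseline recipes were
chosen so their closed-form volumes reproduce the reference adult organ
volumes (kidneys 288 cm³, spleen 175.9, stomach 402, ovaries 8.38 ...),
which is the strongest check available that the shapes match the published
equations; the exact report equations can be substituted through the
`templates` argument if a user has them.

For a target phantom, each organ is transformed in two steps that mirror
the construction procedure of the reference phantoms:

1. **z-scaling** by the organ's segment height ratio (trunk organs by
   `C_T` ratio, head organs by `C_H` ratio, leg structures by `C_L`
   ratio), applied to both z extents and z anchors;
2. **lateral calibration**: x and y semi-axes are multiplied by a common
   factor *s* solved so the organ volume equals its reference target,
   preserving the x:y ratio. Because an affine scale multiplies any
   region's volume by exactly s², *s* has the closed form
   `sqrt(V_target / V_z)` whenever the z-scaled template volume `V_z` is
   known (analytically or by a single Monte Carlo integration); organs
   with carve-outs (lungs minus the heart and rib cage, skeleton minus
   the brain) are solved by bisection against Monte Carlo volume
   integration with common random numbers.

Anchor x/y positions are additionally scaled by the segment's lateral
semi-axis ratios. The construction procedure only prescribes z scaling;
lateral anchor scaling is our design choice so that organs stay inside the
thinner Taiwanese trunks and move proportionally closer together — the
mechanism the narrative invokes to explain the larger cross-organ SAFs of
the shorter phantoms.

Wall organs are concentric shells: the outer surface is calibrated to
wall + content volume, the content to its own row, and the wall is the
difference. Contents use the wall's tissue composition (no separate
content material is tabulated). The skeleton is a simplified axial model
(leg cones, arm bones, spine, rib-cage shell, pelvis half-ring, skull
shell) calibrated jointly to the tabulated bone volume; skin is a fixed
0.2 cm outer shell; everything else is residual soft tissue. Testes are
placed just above the trunk base because the three-segment envelope has no
genital region; female breasts have no tabulated volume and default to
350 cm³ total (configurable). Organ masses are volume × density by
definition.

Overlaps are resolved by a fixed classification precedence
(breasts > skin > skeleton > walls > contents > solid organs > residual);
the built-in layout keeps organs disjoint to well below 1% of their
volumes (verified by `validate_phantom()`), the only sizeable contact
being the rib cage grazing the anterior heart wall.

# Interaction data

No photon cross-section library is available to R in this toolchain, so the
package builds its own elemental tables (H, C, N, O, Na, P, S, Cl, K, Ca;
0.002–4 MeV) from a small set of bundled water anchor values plus analytic
physics:

* **incoherent**: free-electron Klein–Nishina (exact closed form), with an
  energy-dependent effective binding factor `r(E)` (see below);
* **coherent**: Thomson cross section weighted by the squared
  Thomas–Fermi–Molière atomic form factor (exact hydrogenic form factor
  for H), integrated numerically; the same cumulative `∫F² dq²` tables
  drive angular sampling in the kernel;
* **photoelectric**: derived from the bundled water mass energy-absorption
  coefficient as `pe ≈ μ_en − incoherent·t̄(E)` with `t̄(E)` the exact KN
  mean energy-transfer fraction, then scaled across elements as `Z^4.5/A`.
  Anchoring pe on μ_en rather than on the attenuation residual partitions
  the channels far more accurately in the 0.05–0.5 MeV range, where the
  photoelectric share of *deposition* is an order of magnitude larger than
  its share of attenuation;
* the incoherent channel is then set to the residual of the anchored water
  total, expressed as `r(E)` times KN, so water attenuation is exact at the
  anchors by construction (derived channel splits agree with the public
  compilation to a few percent, e.g. water pe 0.0027 vs 0.0028 cm²/g at
  0.1 MeV);
* **pair production**: `Z(Z+1)/A` scaling anchored on the water residual
  above 1.022 MeV (irrelevant for the bundled nuclides, retained for
  completeness).

Mixtures use the mass-fraction rule with log–log interpolation in energy.
The largest model uncertainty sits in the calcium photoelectric channel
(bone) below 0.1 MeV, where the `Z^4.5` scaling is an approximation.

# Transport

The engine is an analog photon Monte Carlo with **Woodcock (delta)
tracking**: flight lengths are sampled against a global majorant (the
maximum total attenuation over the phantom's materials at the current
energy), and collisions at points whose local attenuation is lower are
rejected as fictitious. This needs only point containment — which the
quadric CSG provides cheaply — and no ray–surface intersections. An
independent surface-to-surface **ray tracer** for sphere fixtures
(`ray_trace_spheres()`) provides a two-tracker equivalence oracle in the
test suite; the two agree within combined statistics on self and cross
tallies.

Collision physics: photoelectric events absorb the full photon energy at
the interaction point; incoherent events sample the free-electron
Klein–Nishina distribution by rejection (exact), deposit the transfer
locally, and continue the scattered photon; coherent events redirect using
the form-factor angular law without deposit; pair production deposits
`E − 1.022` MeV and emits two annihilation photons back-to-back. Secondary
electrons are not transported (**kerma approximation**) — organ dimensions
are large compared to electron ranges below ~1 MeV — and fluorescence after
photoelectric absorption is neglected (soft-tissue K-edges are below
4 keV). Photons at or below the 1 keV cutoff deposit locally. Energy
bookkeeping is exact: deposits plus escape equal emitted energy to
floating-point accuracy on every run.

Tallies are per-organ energy deposits accumulated in batches (default 20);
the reported CV is the relative standard error of the mean over batches,
and results with CV > 20% (strictly) are flagged excluded and rendered as
`"-"` in formatted tables. One seeded generator drives each simulation;
identical (configuration, seed) pairs give byte-identical outputs.

## Default problem sizes

The reference calculations were run at 10⁷ histories per point; the
package defaults to 10⁶, which gives self-SAF CVs of ~0.1–0.5% and
resolves the tabulated cross-organ S-values at a few percent — the
statistical error is then well below the organ-shape modeling error.
The test suite runs its physics property checks at 10⁴–10⁵ histories and
the table-reproduction checks at 10⁶; `scripts/acceptance.R` likewise uses
10⁶ histories per point. The paper-scale 10⁷ is one flag away
(`--histories 1e7`).

# Dosimetry conventions

S-values use the classic MIRD non-penetrating treatment: β spectra
(represented by their mean energy per decay), conversion and Auger
electrons are absorbed entirely in the source organ; only photons are
transported. Bundled emission schemes for ¹³¹I and ⁹⁹ᵐTc list photon lines
with yield ≥ 1% (X-ray lines merged at intensity-weighted energies) plus
one electron row carrying the total non-penetrating energy per decay
(0.192 and 0.0163 MeV respectively); the CSV format is documented so users
can supply other nuclides. Conversion: 1 MeV/(kg·decay) =
1.602 × 10⁻⁴ mGy/(MBq·s). Line CVs are propagated in quadrature.

A note on reciprocity: for detached regions in a quasi-uniform medium the
reciprocity theorem states SAF(t ← s) ≈ SAF(s ← t) — the *specific*
absorbed fractions are symmetric, not the absorbed fractions — and this is
the form verified on the two-sphere fixture.

# What the fixtures do and do not show

The analytic fixtures (`make_fixture()`) have exactly known masses and
closed-form expectations: the 1 kg sphere reproduces the 1/m self-SAF
limit under forced local deposition, the slab reproduces Beer–Lambert
transmission, and the two-sphere fixture exercises cross tallies,
reciprocity and CV scaling. Passing these shows the transport and tally
machinery is correct; it does not validate the anatomical layout, which is
tested separately against the printed reference tables. Conversely, the
stylized phantoms emulate organ masses and gross positions, not true
anatomy: lobed organ shapes, marrow, the gastrointestinal tract detail and
body curvature are simplified, so cross-organ SAFs carry a layout
uncertainty of tens of percent even when self-SAFs (which are mass- and
shape-dominated) agree within ~15%.

# Numerical choices

* Boundary convention: `≤` everywhere; a boundary point is inside.
* Calibration tolerance 0.2% of the target volume; bisection runs 45
  iterations on s ∈ [0.15, 3] with fixed-seed Monte Carlo overlap
  integration restricted to the intersection bounding box.
* Klein–Nishina sampling by rejection against the `x + 1/x` envelope
  (exact for all energies; efficiency ≥ ~50% below 2 MeV).
* Coherent angle sampling inverts the tabulated cumulative `∫F² dq²` and
  accepts on the Thomson factor, with a forward-scatter fallback after 500
  rejections (relevant only where coherent is already negligible).
* Majorant lookup interpolates the per-grid maximum of material totals in
  log–log; linear interpolation of log values is monotone in the node
  values, so the interpolated majorant bounds every interpolated material.
* Degenerate inputs: source sampling aborts below an acceptance rate of
  10⁻⁴; zero-mass targets are dropped from SAF tables; energies outside
  0.002–4 MeV are rejected.

# Known limitations

* The organ layout is ORNL-like, not the verbatim report equations; cross
  SAFs between near organs (e.g. liver → pancreas) inherit the anchor
  choices, documented and configurable above.
* Bound-Compton effects enter only through the effective `r(E)` factor on
  attenuation; scattered-energy sampling is free-electron. Below ~30 keV
  this and the `Z^4.5` photoelectric scaling are the dominant physics
  approximations (several percent on 30 keV self-SAFs).
* No electron transport, no bremsstrahlung, no fluorescence; S-values for
  nuclides whose dose is dominated by energetic β in *small* organs are
  only as good as the non-penetrating assumption.
* Marrow, the GI tract and effective-dose weighting are out of scope.
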