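---
title: "Multiscale modelling of NPWT wound mechanics and tissue oxygenation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale modelling of NPWT wound mechanics and tissue oxygenation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Negative pressure wound therapy (NPWT) dresses an open wound with an
open-cell polyurethane foam filler, seals it, and applies sub-atmospheric
pressure (typically 70--150 mmHg below atmosphere). The therapy contracts
the wound edges and perturbs perfusion and oxygenation of the tissue
around the wound bed. `npwtox` models both effects for a trans-femoral
residual limb with a circumferential distal wound, in four coupled
stages:

1. **Macro scale.** A nonlinear static finite-element solve of the limb
   (rigid femur core, hyperelastic muscle, hyperfoam filler) under the
   NPWT loads gives displacements and Cauchy stresses
   (`build_limb_geometry()`, `solve_macro()`).
2. **ROI statistics.** Within tissue layers at chosen distances from the
   wound-bed surface, the per-element maximum and minimum principal
   stresses are summarised as histograms; the highest-probability (modal)
   pair becomes the boundary condition of the capillary model
   (`define_roi_layers()`, `roi_modal_stresses()`).
3. **Meso scale.** A plane-strain Krogh-cylinder cross-section (lumen,
   wall, tissue sleeve) is loaded by the luminal blood pressure and the
   ROI modal stresses; its equivalent pressure stress field
   $p = -\operatorname{tr}\sigma/3$ feeds an oxygen diffusion solve whose
   flux is extended with a pressure-stress drift term
   (`solve_capillary()`, `solve_diffusion()`).
4. **Report.** The oxygenated tissue-area fraction (concentration at or
   above a 10 µM sufficiency threshold) of each coupled run is compared
   with the uncoupled Fickian baseline and mapped back to the ROI layers
   (`run_pipeline()`).

## Constitutive models

Muscle (and the capillary-surrounding tissue) is Mooney--Rivlin,
$W = C_1(\bar I_1 - 3) + C_2(\bar I_2 - 3) + U(J)$, with the
literature-derived constants $C_1 = 0.0094$ MPa, $C_2 = 0.082$ MPa and
incompressible behaviour ($D = 0$). Incompressibility is regularised by a
penalty bulk modulus $\kappa = 1000\,\mu_0$ with
$\mu_0 = 2(C_1 + C_2) = 0.1828$ MPa; a pure constraint is ill-posed in a
displacement formulation, and at this ratio the volumetric strain under
therapeutic loads is below $10^{-4}$. When a compressibility parameter is
given (capillary wall: $C_1 = 0.257$, $C_2 = 0.00257$ MPa,
$D = 10^{-6}$ MPa$^{-1}$), $U(J) = (1/D)(J-1)^2$ as in the source data.

The foam filler uses a single-term compressible Ogden (hyperfoam) energy
$$U = \frac{2\mu}{\alpha^2}\Big(\lambda_1^\alpha + \lambda_2^\alpha +
\lambda_3^\alpha - 3 + \frac{J^{-\alpha\beta}-1}{\beta}\Big),$$
with $\mu = 0.907\times10^{-2}$ MPa, $\alpha = 0.213\times10^{-2}$,
$\beta = 0.844\times10^{-2}$. The printed constants describe a second-order
fit in the source literature but only one $(\mu, \alpha, \beta)$ triple is
available, so one term is implemented. Because $\alpha$ is tiny, the
energy is numerically a Hencky-type law (effective Poisson ratio
$\beta/(1+2\beta) \approx 0.008$, initial $E \approx 0.018$ MPa); all
stretch powers are evaluated with `expm1` on log-stretches to avoid the
catastrophic cancellation that the naive form suffers at this $\alpha$.

## The synthetic limb geometry

No imaging data ship with the package; the limb is generated
parametrically as a 2D axisymmetric surrogate, a simplification that the
original 3D study itself validated against an axisymmetric twin. Defaults:

| parameter | default | basis |
|---|---|---|
| wound radius / depth | 3.6 / 0.8 cm | printed wound, opening $\approx 40.7$ cm² |
| limb length | 18 cm | resection 18 cm distal to the greater trochanter |
| muscle radius | 7 cm | not printed; a representative mid-thigh radius |
| bone radius | 1.5 cm | not printed; representative femur |
| distal soft-tissue cap | 4 cm | not printed; leaves 3.2 cm of muscle below the wound bed for the 0--17 mm ROI band |
| fillet radius (round edges) | 2 mm | not printed; configurable |

The mesh is a graded structured quadrilateral grid (1 mm target size near
the wound--filler interface, 5 mm far field, held fine over a 2 cm band
around the wound so 2 mm ROI layers stay resolved). "Round" wound edges
are produced by a corner map that carries the square corner of the cavity
onto a circular arc exactly, at any resolution: nodes in the
$L_\infty$-ball around each cavity corner are radially rescaled onto the
$L_2$-ball. Revolved region volumes match the closed-form solids of
revolution to machine precision (sharp) or to within the fillet-area
correction (round).

What the generator does *not* emulate: patient-specific anatomy, skin and
fascia layers, non-circular combat-wound shapes, and the adhesive drape.
Tests passing on this geometry therefore validate the mechanics and the
coupling machinery, not anatomical fidelity.

## Macro loads and boundary conditions

Suction is applied as follower pressure (traction on the deformed
surface) pulling the wound lateral wall and bottom towards the cavity;
the filler top carries a pushing load. The filler-top load is interpreted
in gauge terms: the net pressure on the foam is the difference between
atmosphere outside and the evacuated pore space inside, i.e. the suction
magnitude. Applying full absolute atmosphere (0.101 MPa) to a foam with
$E \approx 0.018$ MPa would flatten it to a few percent of its height,
which contradicts the moderate filler deformation the therapy produces;
the default is therefore `filler_top = suction`, overridable in
`npwt_load_case()`. Conversions use 1 mmHg = 133.322 Pa exactly; the
rounded literature MPa values are accepted via `units = "MPa"`.

The proximal end is encastre, the bone interface fixed (rigid femur), the
muscle--filler interface tied by shared nodes (no slippage), and the
symmetry axis carries a roller.

# Numerical methods

* **Elements.** Bilinear quadrilaterals, total-Lagrangian, axisymmetric
  (macro) or plane strain (capillary). Plane strain is chosen for the
  capillary because it is long and axially constrained.
* **Near-incompressibility.** Mean-dilatation (B-bar): deviatoric stress
  at the 2×2 Gauss rule, volumetric pressure from the element-averaged
  volume ratio, $\bar p = \kappa(\bar J - 1)$, with its rank-one tangent.
  A 1-point volumetric rule was rejected because it fails the
  axisymmetric patch test (the $\partial N/\partial z \cdot r$ integrand
  it drops is quadratic); the implemented scheme reproduces a hydrostatic
  state to machine precision on any mesh.
* **Tangents.** Analytic for Mooney--Rivlin; for the hyperfoam the
  principal-stretch stress is differentiated by central differences per
  quadrature point (verified against the analytic stress to $10^{-7}$).
  Internal forces are exact gradients of the discrete energy (checked in
  the test suite by finite differences).
* **Newton.** 10 uniform load increments with adaptive halving on
  divergence, relative residual tolerance $10^{-8}$, follower-load
  stiffness included. At very small loads the near-incompressibility
  penalty sets a rounding-noise floor on the attainable relative
  residual; an increment is accepted when the residual stagnates below
  $10^{-6}$.
* **Degenerate inputs.** Zero suction returns the zero solution exactly;
  a zero-radius wound builds a solid limb; inverted elements and
  non-convergence abort with the load level and last residual.
* **Diffusion.** P1-on-quads finite elements on the wall + tissue
  annulus, implicit Euler with dimensionless step
  $\Delta\tau = 10^{-3}$ ($\tau = D_t t / R_{out}^2$), Dirichlet 40.32 µM
  at the lumen surface, zero total flux at the Krogh radius, zero initial
  tissue concentration. Mass change equals lumen influx to round-off at
  every step. The element pressure field is projected to nodes
  (area-weighted) before its gradient enters the drift term.

## The drift term and its sign

The flux law is implemented as
$J = -D\nabla C - sK_P\nabla p$ with *signed* $K_P$, so that positive
$K_P$ drives oxygen from compressed towards unloaded tissue and the
steady state with an impermeable outer boundary obeys
$C = \text{const} - (sK_P/D)(p - p_{ref})$ (asserted on a radial-$p$
fixture). The published form of the extended Fick law carries the
opposite sign on the drift term; the two conventions differ only in the
sign of the constant, which is calibrated anyway. Empirically, the
oxygenation *decreases* reported around NPWT wounds require drift
*towards* high pressure stress, i.e. negative $K_P$ in this package's
convention (equivalently the printed form with positive $K_P$).

## Evaluation time $\tau$

With no tissue consumption and a zero-flux outer boundary, the true
steady state is uniform at the wall concentration, which makes the
oxygenated-area threshold degenerate. Area comparisons are therefore
made at the fixed developing-gradient time $\tau = 0.1$ (about 0.08 s of
physical time), where the baseline shows a clear radial gradient with an
oxygenated fraction of about 0.19; baseline and coupled runs always use
the same $\tau$, mesh and step. This is the largest interpretive decision
in the transport model and is exposed as `diffusion_params(tau_end =)`.

## Calibration of $K_P$

$K_P$ has no literature value. `calibrate_pressure_factor()` fixes it
once, by matching the oxygenated-area change of the beneath-wound 0 mm
layer at 125 mmHg to a target (the published decrease), then holds it
fixed for all other layers and pressures. Because the response is not
monotone in $K_P$ (strong drift both drains the threshold ring and
refills it from the lumen side), the search scans a signed log-spaced
grid, root-finds in the bracket nearest zero, and falls back with a
warning to the closest-attainable $K_P$ when the target is out of reach.
Under the default conditions the 0 mm layer saturates near a 34--44 %
decrease: its modal stress pair mixes tension and compression, and the
resulting quadrupolar pressure field partially cancels its own effect on
the threshold ring, while the purely compressive deeper layers respond
more strongly. This inverts the published depth ordering and is reported
as-is by the pipeline; see the repository notes on the acceptance
results.

## ROI layers and the heterogeneity label

`beneath_wound` layers are horizontal slabs below the cavity bottom
selected by centroid depth in $[\text{offset}, \text{offset} +
\text{thickness})$ (thickness default 2 mm, not printed in the source);
`beside_wound` layers are annular shells outside the cavity wall spanning
the wound depth. The modal stress uses Freedman--Diaconis bins (fallback
20 uniform bins), per-element counting (area weighting available), the
bin centre as the modal value, and ties broken towards smaller absolute
stress — all choices made for reproducibility where the source is
silent. A layer is labelled `heterogeneous` when re-running the capillary
chain at its quartile stress pairs yields area changes of both signs with
magnitude above 5 points, else `homogeneous`.

## Capillary far-field loading

The modal stresses are applied as normal tractions on a square frame of
side $2.2\,R_{out}$ circumscribing the annulus (maximum principal stress
on the x-face pair, minimum on the y-face pair), with the annulus
embedded in tissue filling the frame; loading the frame instead of the
annulus rim keeps load-edge artefacts away from the transport domain.
The luminal pressure is 0.5 kPa. Rigid-body modes are pinned at three
frame points whose reactions vanish by the loads' self-equilibrium. The
solve is verified against the Lamé thick-wall solution (≤ 5 % at small
load), the plane-strain hydrostatic limit under equibiaxial compression,
and 90° rotation symmetry.

# Problem sizes

The package defaults produce a 3219-element limb mesh and a 1056-element
capillary mesh (48 angular divisions); these are the sizes the
acceptance analysis runs at, and the macro quantities of interest change
by under 1 % upon refinement. The test suite exercises the same models
at a 978-element limb mesh (2 mm interface resolution), where the same
quantities differ from the refined values by well under the assertion
tolerances; the mesh-convergence property is itself asserted.

# Known limitations

* The limb is an axisymmetric surrogate: non-circular wounds, skin,
  fascia, drape and patient anatomy are out of scope.
* Quasi-static, immediate response only — no healing, no evolution of
  material properties, no exudate or interstitial fluid.
* The foam is a continuum; pore-scale microdeformation is not modelled.
* Oxygen consumption is excluded from the 2D diffusion solve (it enters
  only the axial Krogh balance that sets the wall concentration), hence
  the $\tau$-based evaluation described above.
* Capillary lumen collapse/contact under strong compression is not
  modelled; the structural solve assumes the lumen stays open.
* The edge-shape comparison is sensitive to the unprinted fillet radius;
  with the default 2 mm fillet the package predicts a substantially
  larger edge-shape effect than the published 4 %.
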