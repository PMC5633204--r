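---
title: "Model and methods: tumor growth, vascular normalization and liposome delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(angionorm)
```

## The scientific problem

Solid tumors recruit their blood supply by angiogenesis. The resulting
vessels are leaky (large inter-endothelial pores), and the tumor interior
lacks functional lymphatics. Fluid therefore pours out of the vasculature
until the interstitial fluid pressure (IFP) rises to the effective
microvascular pressure (MVP), at which point transvascular convection stops.
For small-molecule drugs this matters little — they cross vessel walls by
diffusion — but ~100 nm liposomal carriers are delivered almost entirely by
convective solvent drag, so an IFP plateau at MVP shuts their delivery off
in exactly the region where the drug is needed.

Antiangiogenic agents prune and "normalize" tumor vessels: wall conductivity
drops back toward normal-tissue values and vessel density falls. Both
changes *reduce* the delivery surface, but they also *lower IFP*, restoring
the transvascular pressure difference. `angionorm` simulates this
competition to ask when scheduling an antiangiogenic agent next to liposomal
chemotherapy improves delivery.

## Model structure

Five coupled fields on a uniform 2-D grid (cm units):

* tumor cell density `n(x, t)` — reaction–diffusion with logistic growth,
  vessel-assisted proliferation `alpha_mn n m` and a chemotherapy kill term
  `d_r n d`;
* vessel density `m(x, t)` — diffusion, a bistable cubic
  `m (alpha + beta m + gamma m^2)` with stable states `m = 0` and `m = 1`,
  tumor-driven angiogenesis `alpha_nm n (1 - n/n_lim) m`, a
  gradient-following redistribution term `beta_nm div(m grad n)`, and an
  antiangiogenic kill term `A_r m A`;
* IFP `P(x, t)` — quasi-static Darcy/Starling balance
  `-K lap(P) = lambda_b m (P_v - P - sigma_v(pi_c - pi_i)) - lambda_l P`;
* antiangiogenic agent `A` and liposomal drug `d` — steady-state transport
  (diffusive for the agent; convection-dominated with upwinded retarded
  Darcy velocity, solvent-drag source `Gamma_b (1 - sigma_d) d_v`, lymphatic
  drainage, cellular consumption and decay for the liposome), driven by
  exponentially decaying plasma boluses.

Growth runs on a day clock with explicit forward-Euler steps; pressure and
drug fields are elliptic solves refreshed at the pharmacokinetic sampling
cadence (0.05 day while any drug is in plasma, 0.25 day otherwise). The
quasi-steady treatment of `P`, `A`, `d` is justified by scale separation:
transport equilibrates in minutes–hours, growth changes over days.

### The normalization switch

Vessel density up to 1 represents inherent, mature vasculature; density
above 1 exists only where angiogenesis created it, and those vessels are
leaky. The wall conductivity (and the agent's transvascular permeability)
therefore switches from normal- to tumor-column values on a linear ramp
`m` in `(1, 1.1)` — the ramp keeps the elliptic coefficients continuous and
the solver well conditioned; a hard threshold is recovered as the ramp width
goes to zero.

Two parameters follow the *tissue* rather than the wall state:

* lymphatic conductivity fades with tumor density and is zero for
  `n > 0.1` — tumors destroy their lymphatics, and killing vessels does not
  resurrect them;
* the Starling osmotic term `sigma_v (pi_c - pi_i)` (9.1 mmHg in normal
  tissue, ~0 in tumor) also ramps with `n`, not `m`. This is a deliberate
  design choice where the design was genuinely open. The near-zero oncotic
  gradient of tumor tissue reflects plasma protein that has already leaked
  into the interstitium; a normalization pulse tightens the walls but cannot
  clear that protein (there are no lymphatics to do it). The alternative —
  switching the osmotic term with `m` — has a structural consequence worth
  recording: normalized walls would then pull toward
  `P_eff = 5.9` mmHg while interior IFP, having no interior sink, can never
  fall below 5.9 mmHg, so post-normalization extravasation would be
  identically zero everywhere inside the tumor and no schedule could ever
  improve delivery. The tissue-tied reading keeps the driving force
  `P_v - P - sigma_v(pi_c - pi_i) = 15 - P` inside the tumor, which is what
  lets an IFP reduction translate into restored convective delivery.

### Transvascular drug flux

Liposome extravasation is `Gamma_b (1 - sigma_d) d_v` with
`sigma_d = (1 - (1 - a)^2)^2 = 0.1296` from the pore-exclusion model at
`a` = 100 nm / 500 nm (transmitted fraction 0.87). Where `Gamma_b < 0`
(fluid resorption, `P > P_eff`) the drug source is clamped to zero: pores
large enough to pass a 100 nm particle outward would also pass it inward,
but the intravascular concentration gradient at the wall makes re-entry
second-order, and an unclamped source would act as an unphysical negative
concentration source. Transvascular *diffusion* of liposomes is neglected
(the tabulated diffusional permeability is recorded but unused).

## Parameters

Transport parameters are the tabulated tumor/normal reference values
(wall conductivity, surface density, lymphatic conductivity, osmotic terms,
`K = 2.5e-7 cm^2/mmHg s`, drug diffusivities, plasma time constants 20 h
and 45.2 h, kill rates 1/h). Derived quantities are always computed:
`lambda_b = L_p * SV` (3.72e-4 / 2.52e-6 1/mmHg s),
`P_eff = P_v - sigma_v(pi_c - pi_i)` (15.0 / 5.9 mmHg), `sigma_d` from the
pore model.

The growth-side constants are *not* published with the transport tables
(they come from an earlier model generation), so this package fixes its own
defaults once and flags them as such:

* `D_n = 1.6e-3 cm^2/day`, `r = 0.3/day`. The observable the model must hit
  is the growth trajectory: 0.2 mm to ~13.5 mm in 30 days, an average front
  speed of 0.44 mm/day. The tumor front is a pulled (Fisher) wave with
  speed `2 sqrt(r D_n)` and width `sqrt(D_n/r)`; demanding the printed
  speed with a cell-scale diffusivity (1e-5 cm^2/day) would force
  `r ≈ 49/day` and a 5 µm front that no affordable grid resolves (discrete
  fronts pin at that ratio). The chosen pair gives the right speed, a
  0.7 mm front (~4 cells at the default resolution), and a biologically
  sane doubling time. `calibrate_growth()` trims `r` by bisection to meet
  the day-30 radius exactly.
* vessel cubic `(-0.0375, 0.15, -0.1125)/day` — roots 0, 1/3, 1 with both
  outer roots stable. The magnitude sets how stiffly vessel density is
  pinned to 1; it must be weak enough that the printed angiogenesis
  strength (`alpha_nm = 0.25`) can push the rim to `m* ≈ 1.5`. A 4x
  stiffer cubic caps angiogenic density at `m* ≈ 1.17`, and then any dose
  achieving the calibrated 50% density reduction drives every vessel below
  the leakiness switch, collapsing delivery entirely — contradicting the
  phenomenon under study.
* `alpha_mn = 0.02/day` — sets the interior overdensity
  `n/n_lim = 1 + alpha_mn m / r ≈ 1.04` and with it the interior
  vessel-regression rate `alpha_nm n (n/n_lim - 1) ≈ 0.01/day`. The tumor
  core then keeps a patchy leaky vasculature for weeks, which is what pins
  interior IFP at MVP in untreated tumors; a five-fold larger coupling
  fully normalizes the core within days and the control IFP plateau is
  lost.
* `beta_nm` is stored as the printed dimensionless 0.5 times the square of
  a reference front width `sqrt(D_n/r) = 0.073 cm` (a fixed constant, not
  recomputed when `r` is calibrated). Read literally in cm^2/day, 0.5 makes
  the redistribution term ~±90/day at the front, which strips all vessels
  behind the advancing rim and leaves the tumor avascular at zero IFP.
* `D_m = 1e-5 cm^2/day` keeps the vessel-island interface narrower than a
  grid cell, so the bistable relaxation in `init_vessel_islands()` settles
  nodes crisply onto {0, 1}.

Dose peaks are dimensionless. The chemotherapy peak defaults to 0.01,
chosen once so that chemotherapy alone reduces the interior cell density
noticeably without eradicating the tumor; the antiangiogenic peak is never
chosen by hand — `calibrate_aa_dose()` bisects it until microvascular
density inside the tumor (masked mean of `m`) falls 50 ± 2% by the end of
the administrations. The reduction is measured on the tumor mask frozen at
the first administration: with a moving mask the freshly vascularized rim
of the still-growing tumor dilutes the kill signal and the dose response is
no longer monotone. Antiangiogenic pulse peaks taper by 0.8 per pulse
(tapering is part of the protocol; the factor itself is a package default,
exposed in the config).

## Numerics

* 5-point Laplacian and flux-form `div(coef grad .)` with arithmetic-mean
  face coefficients (the coefficient fields are smooth densities, not
  material jumps — harmonic averaging would be wrong here); ghost-node
  boundary closure (mirror for no-flux, fixed ghost for Dirichlet).
* IFP: sparse direct solve of the 5-point system; Dirichlet boundary at the
  *computed* healthy-tissue equilibrium
  `lambda_b,n P_eff,n / (lambda_b,n + lambda_l,n) ≈ 0.022 mmHg`. The
  literature phrase "pressure reduces to the normal value" is ambiguous
  (the vascular pressure is 15 mmHg, but normal-tissue IFP under the same
  Starling balance is ~0.02 mmHg); the equilibrium reading is the
  physically consistent one and matches the near-zero IFP outside the rim.
  `boundary_literal = TRUE` restores the literal 15 mmHg reading.
* Liposome convection: first-order upwinding of the retarded Darcy flux on
  cell faces. Together with the clamped source this gives an M-matrix, so
  the discrete drug concentration is provably nonnegative.
* Forward Euler for growth with the diffusive bound
  `dt <= h^2 / 4 max(D_n, D_m)` enforced; the default `dt = 0.025 day` is
  also comfortably below the reaction stiffness of the kill terms at
  calibrated doses. Negative densities produced by a step are clamped to
  zero (and counted when `options(angionorm.verbose = TRUE)`).
* Plasma decay is implemented exactly as the printed `exp(-t/t_half)` — the
  tabulated "half-life" acts as an e-folding time constant. A config flag
  (`halflife_ln2`) switches to `exp(-t ln 2 / t_half)` for users who read
  the constants as true half-lives.
* The analytic oracle for the pressure solver is the piecewise-uniform
  radial problem solved with modified Bessel functions (`I0` inside,
  `K0` outside, continuity of `P` and flux at the interface), evaluated
  with exponentially scaled Bessel ratios for stability. When this sharp
  interface is posed on the Cartesian grid, the *product*
  `lambda_b (P_v - osmotic)` is cell-averaged across the interface (16-point
  subsampling) rather than averaging the factors separately; homogenizing
  the source itself keeps the interface error at ~O(h^2) (measured
  rel. L2 4e-4 at 301x301) where factor averaging plateaus near 3e-3.

## What the synthetic world does and does not establish

The initial vasculature is an i.i.d. uniform field relaxed under the
bistable cubic. With the default (weak) cubic and vessel diffusivity, the
healthy tissue relaxes to the homogeneous vascularized state `m ≈ 1`;
heterogeneous islands, sparse cores and leaky rims then *emerge* from the
tumor coupling, which is the regime the underlying model describes
("a homogeneous distribution of vessels is altered by the addition of new
leaky vessels"). A green directional test therefore establishes that the
mechanism — normalization lowering IFP and restoring convective delivery —
operates in the model; it does not establish quantitative agreement with
any particular animal system, intravascular flow heterogeneity (perfusion
is uniform here), functional normalization, 3-D effects, or liposome
payload release kinetics (the tabulated release rate appears in no
equation and is not implemented).

Desk-scale checks run at 64x64 over a 2.4 cm domain: at 64x64 over 3 cm
the grid spacing is twice the front width and the discrete front pins. The
treatment comparisons there use a 1.5 mm seed tumor so the interior region
(`n > 1` mask) is populated through the treatment window. At desk scale the
chemotherapy-alone interior baseline extravasation is essentially zero
(interior IFP sits at MVP), so improvement ratios of the combination cases
are numerically enormous rather than the published ~2x; the directional
assertions are the meaningful content at this scale.

## Known limitations

* Uniform intravascular pressure and perfusion; no blood-flow network.
* 2-D; radially grown tumors under-represent lobed morphologies.
* Explicit growth stepping wastes time far from the front; no adaptivity.
* The interior mask `n > 1` sits just a few percent above carrying
  capacity at the default coupling, so it is sensitive to the
  `alpha_mn / r` ratio.
* Repeat dosing superposes bolus decays (linear PK); saturable clearance
  is out of scope.
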