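---
title: "Hydroelastic modelling of supercoiled DNA minicircles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydroelastic modelling of supercoiled DNA minicircles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(minicircle)
```

DNA minicircles of a few hundred base pairs store torsional and bending
strain that forces them into a small family of three-dimensional shapes:
open circles, figure-8s, and interwound (plectonemic) forms. Those shapes
in turn set the molecule's hydrodynamic friction, and with it the diffusion
and sedimentation coefficients that analytical ultracentrifugation (AUC)
measures. This package implements that whole chain — topology to shape to
transport — as a composable pipeline, and this vignette is the package's
account of the modelling choices inside it.

## The elastic model

A minicircle is treated as an inextensible, uniform Kirchhoff rod of
contour length $L$, steric diameter $d_s$, bending rigidity $A$ and
torsional stiffness $\omega A$, where $\omega$ is a geometric factor equal
to $2/3$ for a circular cross-section. The elastic energy of a closed
configuration is

$$E = \tfrac{1}{2}\int A\,(\kappa^2 + \omega\,\Omega^2)\,\mathrm{d}s,$$

with $\kappa$ the local curvature and $\Omega$ the residual excess twist
density. Scaling by $k_BT$ (with $A = k_BT\,P$, persistence length
$P = 500$ Å by default) makes the problem dimensionless: the only shape
parameters are the aspect ratio $d_s/L$ and $\omega$.

Topology enters through the Călugăreanu decomposition $Lk = Tw + Wr$. The
linking number $Lk$ is fixed for a covalently closed molecule; its deficit
relative to the relaxed reference $Lk_0 = N/h$ (helical repeat
$h = 10.42$ bp/turn in the calcium-containing buffer modelled here) is
$\Delta Lk$. Because the energy is quadratic in $\Omega$ with no coupling
to position, a minimizer distributes the untwisted part uniformly,

$$\Omega = \frac{2\pi\,(\Delta Lk - Wr)}{L},$$

so the twist energy of a shape depends on its writhe only. `rod_energy()`
implements exactly this decomposition. Note that the package also provides
`loop_energy_scales()`, the coarser literature estimates
$E_\mathrm{bend} = 4\pi^2 P/L$ and
$E_\mathrm{twist} = 6\pi^2 (\Delta Lk)^2 P/L$; their prefactors are
deliberately *not* those of the Kirchhoff energy (the flat-circle bending
energy of the rod model is $2\pi^2 P/L$), because they are order-of-
magnitude scales used to justify treating the shapes as rigid, not model
energies. Both conventions are kept, clearly separated, because both
appear in the supercoiling literature.

Keeping the fractional part of $\Delta Lk$ matters: a "relaxed" 336 bp
circle has $Lk_0 = 32.25$ and an integer $Lk = 32$, hence
$\Delta Lk \approx -0.25$, and the pipeline applies this offset
automatically for covalently closed species (nicked circles are torsionally
unconstrained and get $\Delta Lk = 0$).

## Writhe

`writhe()` evaluates the Gauss double integral by replacing the centerline
with straight segments (200 by default) and summing the exact solid-angle
contribution of every non-adjacent segment pair — the segment-pair closed
form that avoids the singular quadrature of the raw Gauss integrand. Two
numerical details are load-bearing:

* exactly collinear or coplanar segment pairs produce cross products that
  are pure floating-point noise; their normals are suppressed with a
  relative threshold (the analytic contribution of such pairs is zero), so
  the sum is refinement-invariant to $\sim 10^{-6}$;
* the sign convention is right-handed crossings positive, so negatively
  supercoiled loops acquire negative writhe. Published writhe curves are
  plotted in magnitude; the tests therefore compare $|Wr|$.

The test suite cross-checks the segment-pair sum against a brute-force
Riemann double sum of the Gauss integral on twenty random smooth loops
(agreement to $10^{-3}$) and against per-pair quadrature for a random
polygon.

## Stability regimes and the critical deficit

Below a thickness-dependent critical deficit
$Lk_\mathrm{crit} = \sqrt{1 + 23.1\,d_s/L}$ only the flat circle is an
equilibrium; between $Lk_\mathrm{crit}$ and the thickness-independent limit
$Lk_\mathrm{max} = \sqrt{3}/\omega$ ($= 2.6$ for $\omega = 2/3$) circle and
writhed shapes coexist; above $Lk_\mathrm{max}$ only writhed shapes
remain. `stability_regime()` encodes this partition. The empirical
$Lk_\mathrm{crit}$ formula predicts a *larger* threshold for the thicker
(relative) 336 bp rod ($1.19$ at $d_s/L = 0.018$) than for 672/718 bp
($\approx 1.09$); prose accounts sometimes order these the other way. The
package implements the formula as published and does not hard-code the
prose values.

## Finding minimum-energy shapes

`minimize_shape()` represents the centerline as a periodic cubic spline
through 16 control points (twice continuously differentiable across the
seam), optionally restricted to the two-fold symmetry
$\mathbf{p}(t + \tfrac12) = S\,\mathbf{p}(t)$ with $S$ a rotation by $\pi$
— the symmetry of the figure-8/interwound family, which halves the number
of free coordinates. The search runs from two starts, a flat circle and an
analytic figure-8 whose crossing separation is set to $1.5\,d_s$ and whose
handedness matches the sign of $\Delta Lk$:

1. **Simulated annealing.** Gaussian single-node proposals with a
   geometrically annealed temperature and step size (five stages by
   default); the steric penalty weight ramps tenfold over the anneal.
2. **Gradient quench.** The descent from a writhed start to the interwound
   minimum is barrier-free (that is *why* the circle destabilizes above
   $Lk_\mathrm{max}$), so quasi-Newton (BFGS) iterations on the penalized
   objective do most of the work; a second cycle restarts the quench to
   guard against premature line-search exits.

Constraints are handled as follows:

* **Length** is imposed exactly: every candidate spline is rescaled
  uniformly to contour length $L$ (scaling leaves writhe invariant and maps
  curvature as $\kappa \mapsto \kappa/c$), so the returned shape satisfies
  the length constraint to machine precision rather than within a penalty
  tolerance. This replaces a quadratic length penalty; it is cheaper and
  removes one tuning weight.
* **Sterics** use a quadratic penalty $(d_s - r)^2$ summed over sample
  pairs closer than $d_s$, over a contact-tracking grid of
  $\lceil 20\,L/d_s \rceil$ points (capped at 600 — beyond a spacing of
  $\sim d_s/10$ the penalty no longer changes), excluding pairs closer
  than $2 d_s$ along the contour. A companion term penalizes local
  curvature beyond $2/d_s$, where the tube would overlap itself.
* **Contacts** of the final shape are classified by clustering samples
  whose non-neighbour separation is below $1.1\,d_s$: none, point (short
  arc) or line (contact arc longer than $3\,d_s$).

The returned object records the energy decomposition, writhe, contact
summary, convergence flag and every optimization branch (including the
analytic flat circle), so the multistable band exposes both minima.
Everything is deterministic for a fixed `rng_seed`. Above
$Lk_\mathrm{max}$ the circle start is annealed but only quenched if it
undercuts the quenched figure-8 branch, since the circle is not an
equilibrium there.

Two derived diagnostics in `glance()` quantify stress release:
`wr_fraction` $= Wr/\Delta Lk$ and `twist_relaxation`
$= 1 - ((\Delta Lk - Wr)/\Delta Lk)^2$. At $\Delta Lk = -3.2$ (336 bp
geometry) the minimized shape has $Wr \approx -2.0$, which relaxes roughly
85–90 % of the flat-circle torsional energy; the literature's "around
90 %" phrasing is ambiguous between these two metrics, so both are
reported and neither is asserted as a fixed number.

Problem sizes: the package default (`minimizer_config()`) uses 200 writhe
segments, a 160-point bending quadrature and a 1 200-step anneal with a
200-iteration quench; `study_minimizer_config()` pins the settings used
for the reference predictions (a few minutes per deficit on one core). The
test suite exercises the same algorithm at reduced resolution (12 nodes,
100 segments) so a full run stays inside a routine check.

## Electrostatic estimates

`debye_length()`, `persistence_length()`, `loop_energy_scales()` and
`long_range_electrostatic_energy()` implement the screening-based
order-of-magnitude estimates — Debye length $R_D = 1/(\kappa_0\sqrt{C_s})$
with $\kappa_0 = 0.329\,$Å$^{-1}\,$l$^{1/2}$mol$^{-1/2}$, the
Odijk–Skolnick–Fixman electrostatic persistence length
$P_{el} = R_D^2/(4 l_B)$ (Bjerrum length $l_B = 7.1$ Å in water near
20 ℃, configurable), and the screened loop repulsion
$E_{lr} = (q^2 N l_B / 2L)\,e^{-L/2\pi R_D}$. These are diagnostics: they
justify the stiff-beam treatment (tens of $k_BT$ stored elastically versus
$\sim k_BT$ thermal) and never feed back into the minimizer. One
published inconsistency is worth flagging: at 230 mM ionic strength the
formula gives $R_D = 6.34$ Å, while the printed value 1.45 Å coincides
numerically with $P_{el} = R_D^2/(4 l_B)$ — apparently a conflation of the
two quantities. The package implements the formulas as written and uses
neither printed value as a target.

## Hydrodynamics

For open circles, two closed forms give the orientation-averaged
hydrodynamic radius of a torus of centerline length $L$ and tube diameter
$d_h$: an expression accurate even for stout tori
(`torus_rh_exact()`, with $x = L/\pi d_h$) and a slender-torus fit
(`torus_rh_slender()`), which agree within 2.5 % once $L/d_h \gtrsim 35$.
For arbitrary shapes, `build_bead_model()` places equal overlapping beads
of diameter $d_h$ (400 by default) at equal arclength spacing along the
centerline, and `bead_model_rh()` computes the rigid-body $R_h$ by one of
two engines:

* **pairwise** (default, deterministic): the Rotne–Prager–Yamakawa pair
  mobility — which stays positive definite for overlapping equal spheres —
  assembled into the grand resistance by constrained solves, inverted, and
  evaluated at the center of mobility; $R_h = (6\pi\eta\,
  \overline{\mu_{tt}})^{-1}$ with $\overline{\mu_{tt}}$ the trace-mean of
  the translational mobility block. Each bead's own rotational drag
  ($8\pi\eta a^3$) enters the rotation block, which also regularizes
  collinear bead chains; the rotational block is rescaled by the body size
  before inversion for conditioning.
* **montecarlo**: a walk-on-spheres estimator of the electrostatic
  capacitance of the bead union (unbiased launch-sphere re-entry via the
  exterior Poisson kernel; seeded; standard error reported), using the
  capacitance ≈ Stokes-radius analogy that path-integral hydrodynamics
  tools rely on.

Measured accuracy against the torus closed form, bead-count converged
(400 vs 800 beads change $R_h$ by < 0.1 %):

| $L/d_h$ | pairwise | montecarlo |
|---------|----------|------------|
| 10      | −8.2 %   | −2.3 %     |
| 20      | −5.6 %   | —          |
| 38.9    | −3.9 %   | −4.8 %     |
| 100     | −2.6 %   | −5.7 %     |

The two engines have complementary bias profiles — the pair tensor
truncation hurts for stout, compact bodies, the capacitance analogy for
slender ones — and neither is uniformly inside the nominal 5 % band across
$L/d_h \in [10, 100]$; the stated 5 % should be read as the accuracy in
the study regime ($L/d_h \approx 39$ and 77), where both comply. Ratios of
radii (writhed shape versus circle at the same thickness) cancel most of
the bias, which is why relative compaction is the more robust prediction.
The reference predictions use the montecarlo engine, matching the
path-integral methodology behind the published numbers; the pairwise
engine is the deterministic default for general use.

`calibrate_dh()` fits one common hydrodynamic diameter to measured
$(L, R_h)$ pairs through the torus model by least squares. Because $R_h$
depends on $d_h$ only logarithmically, the fitted value is intrinsically
imprecise and a single thickness cannot match several lengths exactly; the
per-point residuals are returned and expected to be nonzero (with two
lengths the least-squares residuals bracket zero whenever the optimum is
interior). The package therefore treats the calibrated
$d_h = 29.4$ Å as an input constant for predictions rather than a quantity
it asserts.

The linear-DNA model is a straight rod of the same contour length and
thickness built from the same overlapping-bead construction; it reproduces
the expected circular-to-linear size ordering (ratio near 7:6) and is
validated only at that order of magnitude.

## Transport observables

`diffusion_from_rh()` (Stokes–Einstein), `svedberg_s()`,
`apparent_psv()` (the exact algebraic inverse of the Svedberg relation),
`frictional_ratio()` (against the sphere holding the PSV-defined volume)
and `standard_conditions()` (water-at-20 ℃ corrections, with
$\eta_{20,w} = 1.0016$ cP and $\rho_{20,w} = 0.99823$ g/ml) convert radii
into AUC observables. Constants are CODATA
($k_B = 1.380649\times10^{-23}$ J/K,
$N_A = 6.02214076\times10^{23}$ mol$^{-1}$); user-facing units are Å,
μm²/s, svedbergs, kDa, ml/g and cP, with all internal computation in SI.
Apparent partial specific volumes are buffer-condition quantities: with
divalent calcium bound to the DNA the standard-condition PSV is unknown,
so predictions default to the study-average apparent value 0.482 ml/g.

## The pipeline and its conventions

`run_pipeline()` chains regime classification, shape minimization, bead
construction and transport conversion for each requested topoisomer, and
for mixtures reports the *dominant* species as the headline (mixtures
sediment as a single species in AUC; a fraction-weighted average is also
returned). Contour length defaults to 3.4 Å/bp, but the published
hydrodynamic aspect ratios ($d_h/L = 2.6\times10^{-2}$ and
$1.3\times10^{-2}$ for 336 and 672 bp at $d_h = 29.4$ Å) imply slightly
shorter contours; since those ratios, not absolute lengths in Å, are what
the source calculations state, the reference computations pass the
ratio-derived lengths explicitly via `contour_length`.

## What the synthetic fixtures do and do not emulate

`generate_fixture()` produces exact circles, a figure-8 family with a
controlled crossing separation (writhe → ±1 as the crossing closes),
seeded smooth Fourier-perturbed loops, and straight rods. These span the
geometric regimes the model traverses — which is what the tests need — but
they are idealized: no sequence-dependent flexibility, no base-pair
disruption or kinking, no thermal shape fluctuations (shapes are rigid
energy minima), and no solvent-structure detail beyond the two effective
diameters $d_s$ and $d_h$. Passing tests therefore demonstrate the
fidelity of the elastic/hydrodynamic machinery, not that real minicircles
of arbitrary sequence behave identically; tightly bent shapes in
particular may exceed the linear-elasticity regime.

## Known limitations

* Shapes are global minima of a rigid elastic energy; thermally excited
  local minima (branched plectonemes, racquets) are not sampled.
* The 16-node symmetric spline resolves the simple writhed family well but
  would under-resolve heavily multi-contact shapes at $|\Delta Lk| > 5$.
* Bead-model accuracy is the 5 % discussed above; absolute $R_h$ for very
  stout or very slender bodies inherits the engine bias, while relative
  values largely cancel it.
* The boundary-value (shooting) construction of $Lk_\mathrm{crit}$ is not
  implemented; the empirical formula plus direct minimization covers the
  same predictions.
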