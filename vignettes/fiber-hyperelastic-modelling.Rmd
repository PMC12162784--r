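---
title: "Fiber-based hyperelastic modelling of uniaxial tensile data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber-based hyperelastic modelling of uniaxial tensile data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrelast)
library(dplyr)
```

## The problem

Tubular soft tissues such as the urethra are fiber-reinforced composites: a
compliant ground matrix interspersed with stiff collagen fibers that, in the
distal urethra, run predominantly along the longitudinal axis. Uniaxial
tensile tests of strips cut circumferentially and longitudinally therefore
show a markedly anisotropic response — similar initial slopes, then a much
steeper stiffening of the longitudinal strips once the fibers engage.
Classical isotropic hyperelastic models (Neo-Hookean, Yeoh, Ogden) can fit
either orientation on its own but not both with one parameter set; that is
the gap transversely isotropic models (Gasser–Ogden–Holzapfel, and the
fiber-matrix composite implemented here) close.

`fibrelast` implements the whole workflow on tabular stress–strain records:
kinematics, five constitutive models with analytic nominal stresses, a
two-stage calibration protocol, percent-RMSE model comparison, and a
synthetic-curve generator so that every stage can be validated against known
ground truth.

## Kinematics

All models operate on incompressible uniaxial extension. With nominal
(engineering) strain $\varepsilon$ and loading stretch
$\lambda = 1 + \varepsilon$, incompressibility ($\det F = 1$, traction-free
lateral faces) fixes the lateral stretches at $\lambda^{-1/2}$, so the
deformation is one-dimensional and the pressure-like Lagrange multiplier of
the general incompressible stress relation is eliminated by substitution.
The invariants reduce to

$$I_1 = \lambda^2 + 2\lambda^{-1}, \qquad
  I_4 = \lambda^2\cos^2\theta + \lambda^{-1}\sin^2\theta,$$

where $\theta$ is the angle between the fiber direction and the loading
axis; $I_4$ is the squared stretch along the fiber. The nominal stress is
then simply $\sigma_n = \partial W/\partial\lambda$ of the substituted
strain-energy density $W$.

The definition of $I_4(\theta)$ off the two operating points deserves a
note: for a 1-D reduction only $\theta = 0$ (loading along the fibers,
longitudinal strips) and $\theta = \pi/2$ (loading across them,
circumferential strips) are ever exercised by the fitting protocol, and
there the standard $A \cdot C A$ contraction above is unambiguous. For
exploratory off-axis evaluation a config switch (`i4_mode`) can replace it
with the loading-axis convention $I_4 = \lambda^2$.

## The models

With $x = I_1 - 3$:

* **Neo-Hookean** $W = C_1 x$ — one constant, small-to-moderate strains.
* **Yeoh** $W = C_1 x + C_2 x^2 + C_3 x^3$ — captures stiffening;
  fitted soft-tissue sets commonly have $C_3 < 0$, which is admitted
  (validation restricts only $C_1 > 0$ by default).
* **Ogden** $W = \sum_n \frac{\mu_n}{\alpha_n}
  (\lambda^{\alpha_n} + 2\lambda^{-\alpha_n/2} - 3)$ — principal-stretch
  form; one term by default, arbitrary $N$ supported.
* **GOH** $W = C\,x + \frac{k_1}{2k_2}\,
  (e^{k_2 E^2} - 1)$ with fiber argument
  $E = \kappa x + (1 - 3\kappa)(I_4 - 1)$ — exponential fiber stiffening
  with dispersion $\kappa \in [0, 1/3]$.
* **Fiber-matrix composite**
  $W = (1-\phi)\,W_{\mathrm{Yeoh}} + \phi\cos\theta\,
  \frac{E_f}{2}\left(e^{k(I_4-1)} - 1\right)$ — the matrix is Yeoh-like,
  the fiber term carries physically interpretable constants: fiber modulus
  $E_f$, volume fraction $\phi$, stiffening exponent $k$, orientation
  $\theta$.

Two deliberate design choices:

* **GOH variant.** A variant of the GOH fiber argument that subtracts an
  extra 1 inside the squared bracket circulates in print; it is not
  stress-free at $\lambda = 1$, which a reference configuration physically
  requires. The default is the standard Gasser–Ogden–Holzapfel form; the
  literal variant is retained as `variant = "as_printed"` for audit, and its
  derivative is still oracle-checked.
* **Fiber residual stress.** The composite's fiber term as defined has
  $\mathrm{d}W_{\mathrm{fibers}}/\mathrm{d}\lambda \ne 0$ at $\lambda = 1$
  for $\theta < \pi/2$ (the derivative of $e^{k(I_4-1)}$ at $I_4 = 1$ is
  $k$), i.e. a small residual stress at zero strain along the fiber
  direction. The model is implemented exactly as defined and the residual is
  documented rather than patched away; across the fibers
  ($\theta = \pi/2$) the term vanishes identically.

A second documented inconsistency concerns magnitudes: with a literature
collagen modulus ($E_f \approx 230$ MPa) and $\phi = 0.2$, the fiber term
predicts stresses orders of magnitude above the tens-of-kPa scale of whole
urethral tissue. The package does not guess a correction — constants and
units are explicit everywhere ($E_f$ is accepted in MPa at the interface and
stored in kPa), and the synthetic generator (below) uses an effective
curve-scale modulus instead.

Every analytic stress is verified against a central finite difference of the
energy ($h = 10^{-6}$ on the stretch), the package's independent oracle;
the test suite requires relative agreement below $10^{-6}$ on a 50-point
stretch grid for all five models at both operating angles, plus exact
reduction identities ($C_2 = C_3 = 0 \to$ Neo-Hookean, $\phi = 0 \to$ Yeoh,
$\theta = \pi/2$ kills the fiber term, $k_1 \to 0$ GOH $\to$ Neo-Hookean).

## Calibration

**Pooling.** Specimen curves are resampled onto a common strain grid
(default 51 points on $[0, 0.5]$, linear interpolation) and averaged within
orientation; fits run against the mean curve per orientation. The 0.5 upper
bound reflects the usual conservative analysis window for clamped strips,
beyond which cross-section changes make nominal quantities unreliable.

**Two-stage protocol** (fiber-matrix composite). Circumferential loading
runs across the fibers, so the composite's circumferential prediction is the
matrix alone, weighted $(1-\phi)$: stage one fits $C_1, C_2, C_3$ there.
Stage two freezes the matrix and fits the fiber constants — by default only
$k$ — on the longitudinal mean curve. $E_f$ and $\phi$ default to being held
at externally supplied (e.g. histological) values, and $\theta$ is an
operating condition fixed per orientation, never a fitted constant. The free
set is configurable.

**Single-set protocol.** For model comparison, each model gets one parameter
vector minimising the pooled squared residual over both orientation means.
Isotropic models then necessarily predict one curve for both orientations —
the comparison is designed to expose exactly that limitation.

**Optimizer.** Bounded quasi-Newton (L-BFGS-B) with numerical gradients and
a seeded multi-start (8 starts: the supplied init plus uniform draws within
the bounds), because the exponential stiffening terms create local minima.
Internally the optimizer minimises $\log(1 + \mathrm{SSR})$ — the same
minimiser as the raw sum of squared residuals, but numerically stable when a
random start lands in the steep exponential regime where the raw objective
exceeds $10^{20}$; reported objective values are raw SSR. Default bounds
and starts: $C$'s in $[-10^3, 10^3]$ kPa (init 1, $C_1 > 0$), $\mu \in
(0, 10^3]$ (init 5), $\alpha \in [1, 20]$ (init 8), $k_1 \in (0, 10^4]$
(init 100), $k_2 \in (0, 10^2]$ (init 1), $\kappa \in [0, 1/3]$ (init 0.3),
$k \in (0, 10^2]$ (init 2). Results carry convergence and boundary-hit
flags; a parameter whose perturbation leaves the objective flat (e.g. $k$
when $\phi = 0$) triggers an identifiability warning instead of a spurious
estimate. Identical inputs and seed give identical results.

**Percent RMSE.** $100\sqrt{\overline{(\hat\sigma - \sigma)^2}}/N$ with
normaliser $N$ equal to the mean absolute observed stress by default
(`range` and `max` are selectable, and every report records which was used).
Mean-normalisation is the most common convention and is well behaved on
monotone curves.

## The synthetic generator

`synthetic_spec()`/`generate_curves()` evaluate any ground-truth model on a
strain grid for both orientations and add per-point noise (additive Gaussian
with sd a fraction of the maximum stress, default 2%, or multiplicative),
independently per specimen, deterministically under a seed.

`calibrate_emulation()` produces a fiber-model ground truth whose mean
curves reproduce the tissue-scale anisotropy of distal porcine urethra:
33.01 kPa circumferential and 59.4 kPa longitudinal at 0.5 strain, with the
longitudinal excess concentrated above ~0.25 strain. The matrix keeps a
fixed Yeoh shape (ratios of the reference set 3.54 : 38.21 : −14.6 kPa) and
is scaled to the circumferential anchor; with $\phi = 0.2$ and $k = 3$
(chosen to place the stiffening onset near 0.25 strain) the fiber modulus
follows in closed form from the longitudinal anchor, landing at an
*effective* $E_f$ of order 1 kPa. This is intentional: the generator's job
is the statistical structure of the curves (anisotropy, stiffening,
scatter), not histological fidelity — see the magnitude note above. The
default 2% additive noise keeps replicate scatter below per-subject
standard-deviation ceilings of 6.9% (circumferential) and 8.7%
(longitudinal) of the signal.

What passing tests on these synthetic curves shows: that the estimator
recovers known parameters, that the protocol's stages are consistent, and
that anisotropic models dominate isotropic ones on anisotropic data. What it
does not show: fidelity to any particular experimental data set —
real curves carry toe-region artefacts, slippage, rate effects and
between-subject variation the generator deliberately omits.

```{r example, fig.width = 6, fig.height = 3.5}
truth <- calibrate_emulation()
curves <- generate_curves(synthetic_spec(
  truth, noise = "gaussian_additive", sigma_frac = 0.02,
  n_specimens = 2, seed = 1))
plot_curves(curves)
```

```{r fit}
fit <- fit_two_stage(curves, e_f_kpa = truth$e_f_kpa, phi = 0.2, seed = 1)
glance(fit)
tidy(fit)
```

## Numerical choices and degenerate inputs

* Strains are dimensionless engineering strains; stresses kPa throughout;
  moduli quoted in MPa are converted on ingestion.
* Strain grids for pooling use linear interpolation with no extrapolation
  (grid points outside a specimen's support are dropped from its
  contribution).
* The finite-difference oracle uses a central difference with
  $h \le 10^{-3}$ (default $10^{-6}$), which for these smooth energies gives
  $\sim 10^{-9}$ relative error.
* Degenerate fits are surfaced, not silenced: non-convergence warns and is
  flagged, a bound-constrained optimum sets `boundary_hit`, and a flat
  objective raises an identifiability warning.
* Problem sizes in the shipped tests (51–101-point grids, up to 20 noisy
  replicates, 8 optimizer starts) were chosen as the smallest at which the
  recovery tolerances below are meaningful: noise-free Yeoh constants to
  $10^{-3}$ relative, exponential-family constants to $10^{-2}$ (they are
  weakly identified), noisy medians to 10%.

## Known limitations

* Uniaxial incompressible extension only — no shear, biaxial or 3-D modes,
  no compressible or viscoelastic extensions.
* The fiber composite's residual reference stress (above) makes it
  formally inconsistent at $\lambda = 1$ for $\theta < \pi/2$; at
  tissue-calibrated constants the residual is small but nonzero.
* Percent-RMSE values depend on the normaliser; comparisons across
  publications that do not state theirs are indicative only.
* The two-stage protocol assumes the circumferential response is
  fiber-free; tissues with dispersed or crossed fiber families violate this
  and should use the GOH route with $\kappa > 0$.
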