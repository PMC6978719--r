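---
title: "Methods: steady hemodynamics of stenosed intracranial arteries at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady hemodynamics of stenosed intracranial arteries at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`icasflow` reproduces, at desk scale, the measurement logic of
image-based computational hemodynamics studies of intracranial
atherosclerosis (ICAS): solve the flow through a stenosed middle cerebral
artery (MCA), read wall shear stress (WSS) and wall pressure along the
lesion, condense them into translesional indices at five defined points,
and relate the indices to percent stenosis across a cohort. This vignette
is the package's own account of the model, its assumptions, the numerical
choices, and the known limitations.

## 1. The flow model and its assumptions

Blood is treated as a viscous, incompressible, Newtonian fluid with
constant density $\rho = 1060\ \mathrm{kg\,m^{-3}}$ (1.06 g/cm³, standard
whole blood) and constant dynamic viscosity
$\mu = 3.5\times10^{-3}\ \mathrm{Pa\,s}$. The governing equations are the
steady incompressible Navier–Stokes equations. Three deliberate reductions
make the problem desk-sized:

* **Dimensional reduction.** Instead of a 3-D tetrahedral mesh of a
  patient-specific artery, the lumen is an axisymmetric body of revolution
  (or, for eccentric single-wall plaques, a planar two-wall channel). Every
  quantity the measurement scheme needs — WSS magnitude and wall pressure
  along one longitudinal wall section — survives this reduction.
* **Steady flow at the time-averaged rate.** Pulsatility is dropped; the
  inlet carries the duplex-derived time-averaged flow rate
  $Q = \bar v \cdot A$ with $\bar v = \mathrm{PSV}/3 + 2\,\mathrm{EDV}/3$
  (the same 1/3–2/3 weighting used for mean arterial pressure). The
  reported indices are single-valued, consistent with a steady analysis.
* **Laminar regime only.** A throat-jet Reynolds number
  $Re_{jet} = \rho\,u_{jet}\,D_{throat}/\mu$ (jet velocity = mean velocity
  through the narrowest section) above a configurable cap (default 2000)
  causes a *refusal*, recorded per case, rather than an unconverged or
  silently under-resolved solution. Near and beyond that cap the
  post-stenotic jet is physically unsteady, and a steady solution would be
  fiction.

Boundary conditions: fully developed (parabolic) inflow carrying exactly
$Q$; no-slip rigid walls; zero-gradient outflow. The absolute pressure
level is anchored so that the inlet-plane pressure equals the mean
arterial pressure $\mathrm{MAP} = \mathrm{DBP} + (\mathrm{SBP} -
\mathrm{DBP})/3$ (converted at 133.322 Pa/mmHg). With that anchoring the
terminal/origin pressure ratio is an absolute, FFR-like index. An optional
linear-resistance outlet ($P_{out} = P_d + R_d\,Q$) is available when a
distal-vasculature model is preferred; the constants of the original
multi-branch lumped-parameter outlet are not recoverable, so a
reference-pressure anchor is the default.

### Numerical scheme

The solver (compiled core) uses the streamfunction–vorticity form on a
body-fitted structured grid: $\xi$ along the axis, $\eta \in [0,1]$
spanning the local lumen. In axisymmetric mode the unknown is the reduced
azimuthal vorticity $\Omega = \omega/r$, which is regular on the axis.
Convection is discretised with second-order upwind-biased differences,
diffusion centrally; the nonlinear system is relaxed by under-relaxed
pointwise Gauss–Seidel (alternating sweep direction, so information also
propagates upstream through recirculation zones), interleaved with SOR
sweeps of the streamfunction Poisson equation and a second-order
(three-point) wall-vorticity condition. Convergence is declared when the
RMS steady-state residuals of both equations, normalised by the current
solution magnitude (floored at inlet reference scales), fall below the
tolerance (default $10^{-6}$).

Convectively stiff cases ($Re_{jet} > 700$) are solved by flow-rate
continuation: intermediate solves at a fraction of $Q$, on a
half-resolution grid and a relaxed tolerance ($10^{-4}$), warm-start the
next stage after scaling with the flow-rate ratio and bilinear
interpolation to the full grid. A stage that diverges (detected early by
residual growth) is retried with halved, then quartered, relaxation
factors. All of this only affects *how fast* the fixed-point is reached;
the converged solution is defined by the discretisation, not the path, and
the test suite checks that solver settings do not change the answers.

Mass conservation is exact by construction of the streamfunction
($2\pi\,\psi_{wall} = Q$); the package still *measures* the discrete
station fluxes by Simpson quadrature of the axial velocity and reports the
worst relative deviation, which stays below 0.5% at the default grid.

**Wall quantities.** WSS is $\mu$ times the wall-normal gradient of the
wall-tangential velocity, evaluated at the wall — at a no-slip rigid wall
this equals $\mu\,|\omega_{wall}|$. Wall pressure is obtained by
integrating the tangential wall momentum balance
($\nabla p = -\mu\,\nabla\times\boldsymbol\omega$ at a stationary no-slip
wall) along the wall from the inlet anchor; this is exact for Poiseuille
flow and second-order accurate generally. The volumetric pressure field
offered for VTK export integrates the axial momentum balance along grid
lines and is a visualisation diagnostic; all indices use the wall-line
integration.

**Defaults and units.** Grid 256 × 48 cells; tolerance $10^{-6}$;
relaxation factors 1.0 (interior vorticity) and 0.6 (wall vorticity); 8
streamfunction SOR sweeps (factor 1.8) per outer iteration; Reynolds cap
2000. The relaxation defaults were selected for convergence speed on the
package's own benchmark cases; the converged solution is grid- and
tolerance-defined, independent of these factors, and a case that fails at
the defaults is automatically retried with smaller factors. Lengths in metres, velocities in m/s, pressures in Pa (blood
pressures entered in mmHg), WSS in Pa.

### Validation

The closed-form Poiseuille solution ($\Delta P = 8\mu L Q/\pi R^4$,
$\tau_w = 4\mu Q/\pi R^3$; plane-channel analogues for the planar mode) is
the analytic oracle: at the default grid the solver reproduces both within
0.4%, at doubled grid within 0.1%. For a 50% stenosis, pressure drop and
WSS$_{max}$ change by under 3% when both grid dimensions are doubled
(second-order discretisation). These checks run in the test suite and in
`scripts/acceptance.R`.

## 2. Lesion geometry and the synthetic cohort

A lesion is a cosine bump — smooth ($C^1$ at the edges), standard in
stenosis CFD benchmarks, and exactly consistent with the WASID diameter
definition of percent stenosis,
$s = (1 - D_{stenosed}/D_{reference})\times100$, with the unstenosed
proximal diameter as reference. Real plaques are irregular; without
patient imaging, shape realism is out of reach, and the cosine bump is the
disciplined choice. Eccentric lesions carve the whole diameter deficit out
of one wall of a planar channel; a single-sided plaque deeper than 50%
would cross the centreline and is refused (use the two-sided or
axisymmetric mode for severe lesions). The main pipeline defaults to the
axisymmetric realisation of each lesion's total stenosis, keeping the
plaque-side label for subgroup reporting.

The vessel extends five reference diameters upstream and downstream of the
lesion, so the inflow is fully developed at the lesion entrance and the
outflow condition does not contaminate the measurement window.

**Lesion extent.** The entrance/exit (origin/terminal) are the first/last
axial samples whose relative diameter deficit exceeds a threshold (default
2%) — an operationalisation of "entrance and exit of the stenosis" that is
robust to grid resolution (the detected extent moves by at most one cell
under refinement). The apex is the narrowest sample, ties broken to the
most upstream position.

**The synthetic cohort** stands in for patient TOF-MRA and carotid
ultrasonography. Defaults: percent stenosis $\sim N(43.2, 17.3^2)$ clipped
to [10, 85]%; reference radius $\sim N(1.5, 0.15^2)$ mm; lesion length
$\sim N(8, 1.5^2)$ mm in [4, 14] mm; PSV $\sim N(0.9, 0.2^2)$ m/s with
EDV = PSV·U(0.3, 0.6); blood pressure 130/80 ± (15/10) mmHg; age
$\sim N(65.5, 8^2)$ years; male with p = 0.545; tandem-lesion and
bifurcation flags Bernoulli(0.1) each (tandem cases get a neighbour
distance below 2 cm, others either a distant neighbour or none). The
stenosis mean/SD, age mean and sex ratio are anchored to the symptomatic
MCA-ICAS population the generator emulates; the remaining values are
physiological defaults for that territory, chosen once, and all
config-overridable. The lesion-length distribution is the package's own
choice (MCA M1 plaques of a few millimetres to ~1 cm).

What the generator does **not** emulate: irregular plaque morphology,
imaging segmentation error, severity-dependent measurement noise,
within-patient correlation of multiple lesions, or circle-of-Willis
collateral topology. Passing cohort-level tests therefore demonstrates
that the *pipeline* recovers the hemodynamic structure its physics
implies — not that real patient data would show identical coefficients
(see §5).

**Exclusion rules.** Tandem lesions closer than 2 cm (hemodynamic
interference) and lesions at a bifurcation or branch opening are excluded
before solving, with machine-readable reasons, and logged in the cohort
table rather than dropped.

## 3. The measurement scheme

Five points on the prominent side — origin, M$_{up}$ (midpoint of
origin→apex), apex, M$_{down}$ (midpoint of apex→terminal), terminal.
Point values are linearly interpolated between profile samples; extrema
are searched over the samples inside [origin, terminal] with no
sub-sample optimisation (resolution-controlled, and checked against a
brute-force scan). Ties break to the most upstream position, making
output deterministic. An extremum within 2% of lesion length of a named
point takes that point's label; otherwise it takes the enclosing open
section (Origin-to-M$_{up}$, M$_{up}$-to-apex, Apex-to-M$_{down}$,
M$_{down}$-to-terminal); coarse aliases Upstream/Apex/Downstream map from
the fine labels. Both the snap tolerance and the tie rule are package
conventions — the underlying clinical protocol does not specify them.

Derived indices: WSS and pressure at the five points; WSS$_{max}$,
WSS$_{min}$, pressure$_{max}$, pressure$_{min}$ with locations; WSS
ratio (max/origin) and (min/origin); pressure ratio (terminal/origin);
pressure drop (origin-to-terminal); and the four segmental drops, which
sum to the total drop to rounding (asserted at $10^{-10}$ relative
tolerance). When the origin WSS or pressure is zero the ratios are
returned as undefined while the absolute indices remain valid.

## 4. Statistics

Implemented from their defining formulas (average ranks for ties
throughout; two-sided p-values; α = 0.05):

* **Spearman** $r_s$: Pearson correlation of midranks; p from the t
  approximation with $n-2$ df.
* **Age/sex-adjusted Spearman**: ranks of every variable (sex coded 0/1),
  least-squares residualisation of the x- and y-ranks on the covariate
  ranks, correlation of residuals; $n-2-k$ df. The adjustment mechanism is
  not dictated by the underlying protocol; rank residualisation is the
  package's choice and collapses to plain Spearman when covariates carry
  no information.
* **Friedman** with the tie-corrected statistic
  $Q = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$,
  $A=\sum r_{ij}^2$, $C=nk(k+1)^2/4$; p from $\chi^2_{k-1}$.
* **Post-hoc**: pairwise Wilcoxon signed-rank (zeros dropped — Wilcoxon's
  original convention; exact enumeration of the tied-rank null by dynamic
  programming for ≤ 25 non-zero pairs, tie-corrected normal approximation
  beyond) with Bonferroni correction across pairs; Conover's rank-sum
  post-hoc behind a config switch.
* **Chi-square** (Pearson, no continuity correction) and **Cohen's kappa**
  (marginal-product chance agreement, large-sample z test).

No clustering adjustment is made for multiple lesions per patient: lesions
are treated as independent units, a simplification inherited from the
study design the package replicates, and a documented caveat.

A note on p-value accuracy at very small n: the prescribed reference
distributions (χ² for Friedman, t for Spearman) are asymptotic, while the
exact permutation nulls at n ≤ 8 are discrete; differences of order
10⁻²–10⁻³ in tail probabilities are inherent to the approximation, not an
implementation defect. The test suite therefore pins the *statistics* to
independent brute-force oracles at 10⁻¹² and checks the exact Wilcoxon p
against full enumeration, while the asymptotic-vs-permutation comparison
for Friedman is reported with its actual gap.

## 5. What the pipeline recovers — and what it cannot

On the default synthetic cohort (n = 55) the pipeline reproduces the
qualitative hemodynamic structure expected of ICAS: WSS$_{max}$
concentrates between M$_{up}$ and M$_{down}$ (overwhelmingly at or just
upstream of the apex), pressure$_{max}$ sits in the origin-to-M$_{up}$
segment, pressure$_{min}$ beyond the apex; pressure drop and WSS$_{max}$
grow superlinearly with percent stenosis (positive second differences of
the WSS ratio above 40%, an inflection-like acceleration around 50%); and
WSS$_{max}$ correlates tightly with the translesional pressure drop
(positively) and pressure ratio (negatively), with adjusted $|r_s|$ near
0.99.

One cohort-level pattern from patient data does **not** reproduce under
these clean conditions: the severity-subgroup ordering of the
stenosis–WSS-ratio correlation. In real cohorts the association is
reported as tighter in the ≥ 50% subgroup; in the synthetic cohort the
< 50% subgroup correlates more tightly (≈ 0.96 vs ≈ 0.83 at the default
seed), because the index is a clean convex function of stenosis and the
milder subgroup is both larger and spans a wider severity range, while
the severe subgroup is truncated from above by the laminar-regime cap.
The real-data ordering is plausibly driven by severity-dependent imaging
and measurement noise — exactly the feature of patient data the generator
does not emulate. The package reports both subgroup coefficients and
leaves the interpretation to the user.

A second departure from in-vivo behaviour is deliberate: with a fixed
inflow, a severe stenosis can produce a translesional drop exceeding MAP
(pressure ratio < 0); in vivo, autoregulation and collaterals would reduce
the flow instead. The fixed-flow assumption isolates the geometric effect
and matches the steady single-pass design.

## 6. Problem sizes and runtimes

Defaults were chosen so a full study replica is a coffee-break
computation on one core: a single mild lesion solves in seconds, stiff
cases (Re$_{jet}$ ≳ 1500) in about a minute, the seven-level severity
sweep in ~1.5 minutes, and the n = 55 cohort pipeline in several minutes.
The unit-test suite runs coarse grids (96–128 axial cells) for plumbing
tests and reserves the default grid for the validation and acceptance
checks.

## 7. Known limitations

* Idealised smooth cosine lesions; no plaque-composition or out-of-plane
  morphology.
* Steady laminar flow at the time-averaged rate; no pulsatility,
  turbulence, non-Newtonian rheology, or fluid–structure interaction.
* Single straight vessel; no bifurcations or circle-of-Willis networks
  (cases at bifurcations are excluded, as in the replicated design).
* Reference-pressure outlet by default; the original study's
  lumped-parameter outlet constants are unrecoverable.
* The planar eccentric mode restricts single-sided plaques to < 50%
  stenosis (centreline crossing).
* Statistics treat lesions as independent even when a cohort row set
  contains multiple lesions per notional patient.
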