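---
title: "Multiscale models of quorum-suppressed motility and stripe formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale models of quorum-suppressed motility and stripe formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripesim)
```

## The system

Engineered *E. coli* couple their chemotaxis pathway to a quorum-sensing
module: every cell secretes the diffusible signal AHL, and when the local
AHL level $h$ exceeds a threshold $h_0$ the transcription of *cheZ* shuts
off. CheZ is the phosphatase of CheY-P, the response regulator whose binding
to the flagellar motor promotes clockwise rotation and hence tumbling. A
cell caught in a high-AHL region therefore dilutes its CheZ as it grows,
accumulates CheY-P, tumbles persistently, and effectively stops moving.
Growing colonies of such cells deposit concentric high-density rings behind
an expanding front. `stripesim` implements the three scales of this process
and the metrics used to quantify the resulting pattern.

## Single-cell layer

**CheZ turnover.** Total CheZ $z$ relaxes toward the wild-type level $Z_w$
at the growth rate $k_V = r\,n$ while AHL is below threshold, and is diluted
at the same rate when AHL is above it:
$z' = g(z,h) = k_V (Z_w - z)$ for $h < h_0$ and $z' = -k_V z$ for
$h \ge h_0$. The boundary case $h = h_0$ is assigned to the suppressed
branch, matching the inequality in the model definition. A logistic blend of
the two branches is available (`chez_rhs(..., smooth=)`) for sensitivity
checks, but the default keeps the sharp switch: the published observation is
that the transition must be sharp for stripes to form, and the blended form
here is a convenience, not a reproduction of any published variant.

**Receptor activity and methylation.** Receptor-kinase activity is a
logistic in the mean methylation level $m$,
$A(m) = 1/(1+\exp[N_r \alpha_0 (m_0 - m)])$, and free CheR is
$R(m) = R_t/(1 + K_R T_t (1-A))$. Methylation evolves as
$m' = f(m,z) = k_R R (1-A) - k_{Bp} B_p A$, with $B_p$ taken from the
phospho-protein quasi-steady state.

**Phospho-protein system.** The CheA/CheY/CheB phosphotransfer balances with
their conservation relations form a nonlinear algebraic system for
$(T_p, Y_p, B_p)$. `solve_phospho()` reduces it to a scalar root problem in
$Y_p$: given a trial $Y_p$, the CheY balance yields $T_p$ in closed form and
the CheB balance then yields $B_p$, leaving a single residual (the CheA
balance) that changes sign exactly once on the physical branch
$Y_p \in [0, Y_t)$. Bracketed root finding on that interval is guaranteed to
converge to the unique nonnegative root, which matters because the map from
$(m, z)$ to $Y_p$ is ultrasensitive and Newton-type iterations are fragile
near the transition. The test suite cross-checks the solver against an
independent relaxation oracle that integrates the three balance ODEs to
steady state.

**A numerical-precision note.** With the default parameters the pipeline
gives, at $z = Z_w = 1.23\,\mu M$ and $m = m^*(z)$ (solved to
$|f| < 10^{-12}$), whole-cell rates $\lambda = 0.5858$, $\mu = 6.1426$
s$^{-1}$. The reference values $0.594$ and $6.1143$ s$^{-1}$ are both
reproduced exactly by a single CheY-P value only $0.16\%$ away from ours,
reachable by perturbing $m^*$ in its fifth decimal — i.e. they correspond to
a slightly looser stationary-methylation solve. We keep the tight root; the
$\sim 1.4\%$ residual on $\lambda$ (and $0.5\%$ on $\mu$) is the amplified
image of that fifth-decimal difference through the exponential/quartic motor
laws. The alternative reading of "basal" as $m = m_0$ exactly is excluded:
it yields $\lambda \sim 10^8$ s$^{-1}$.

**Flagellar voting.** Single-motor switching rates are empirical functions
of $Y_p$: $\lambda_f = a_1 e^{b_1 Y_p}$ and
$\mu_f = a_2 e^{-(b_2-Y_p)^4/c}$. Since $b_2 < 0$, the argument
$(b_2 - Y_p)^4$ needs no clamping for physical $Y_p \ge 0$. A cell with
$n_f = 8$ independent flagella runs when at least $w = 6$ rotate CCW; the
binomial voting probabilities give the whole-cell rates
$\lambda = w \lambda_f P^{(w)}_{CCW}/P_{run}$ and
$\mu = (n_f - w + 1)\mu_f P^{(w-1)}_{CCW}/P_{tumble}$, and the effective
diffusivity of the velocity-jump process is
$D(z) = s_0^2 \mu_0 / (d \lambda_0 (\mu_0 + \lambda_0))$ in $d$ dimensions,
evaluated at the quasi-steady methylation level.

Because every cell's rates depend on $z$ alone once methylation is slaved to
its quasi-steady state, `motility_table()` precomputes $m^*(z)$, $Y_p^*(z)$,
$\lambda_0(z)$, $\mu_0(z)$ and $D(z)$ on a uniform grid (spacing
$0.005\,\mu M$) and the simulators interpolate linearly; all of these are
smooth in $z$, and the tabulation error is far below the statistical and
discretization errors that matter downstream.

## Hybrid agent-based model

Cells are particles with position, heading, a run/tumble flag and internal
state $(z, m)$, coupled to AHL and nutrient fields on a node-centred
finite-volume grid. The loop advances, per field step
(`dt_field` = 1 s): internal states, then `dt_field/dt_motion` = 20
velocity-jump substeps (`dt_motion` = 0.05 s), then division, then the
fields. Choices worth stating:

* **Quasi-steady methylation.** The methylation time scale (seconds) is far
  below the CheZ time scale (tens of minutes), so population runs slave $m$
  to $m^*(z)$; `step_internal()` also offers an explicit $m$ step (used in
  tests of the relaxation property). The CheZ branch ODE is linear with
  frozen coefficients over a step and is integrated with its exact
  exponential factor.
* **Switching** uses per-substep Bernoulli draws with
  $p = 1 - e^{-\text{rate}\,dt}$, the exact first-event probability for
  frozen rates; rates refresh every field step.
* **Division** is a per-cell Bernoulli with $p = 1 - e^{-k_V dt}$, exact for
  a Poisson process at any step. Daughters sit at the mother's position,
  copy $(z, m)$ and the movement flag, and draw a fresh heading; the model
  definition is silent on daughter state, and copying preserves the
  population-level $(x, z)$ density structure the mean-field derivation
  assumes.
* **Fields.** Per-cell delta sources deposit on the nearest node
  ($\alpha_d/\Delta x$ per unit time); AHL decay uses its exact exponential
  factor; diffusion is backward-Euler with no-flux boundaries
  (unconditionally stable, mass-conservative). Nutrient consumption is
  multiplicative, $n \mapsto n\,e^{-\gamma_d c\, dt/\Delta x}$ with $c$ the
  local cell count, which keeps $n \ge 0$ exactly.
* **Boundaries** reflect: a cell crossing a wall is mirrored back with the
  normal velocity component reversed (in 1D the direction simply reverses).
* **Determinism.** One seeded generator drives a realization; ensemble
  member $k$ uses `seed + k - 1`. Identical seeds give bit-identical runs.

The 1D engine is compiled; a 2D square-domain variant can be composed from
the exported step functions and is test-grade only — all population-level 2D
results use the radially symmetric PDE.

## Mean-field PDE

The density $\rho^z(x, z, t)$ of cells at position $x$ with total CheZ $z$
obeys
$$\partial_t \rho^z = \nabla_x\!\cdot\!\big(D(z)\nabla_x \rho^z\big)
 - \kappa\,\partial_z\big(g(z,h)\rho^z\big) + r n \rho^z,$$
coupled to reaction-diffusion equations for $h$ and $n$ with
$\alpha = \alpha_d \rho_s$, $\gamma = \gamma_d \rho_s$ and the density scale
$\rho_s = 1000$ cells/mm (the same conversion is used in radial geometry — a
bookkeeping convention, not physics). $\kappa$ scales the CheZ turnover
speed; $\kappa = 1$ is the baseline.

Numerics (one IMEX operator-split step, default `dt` = 2 s, auto-reduced to
keep the $z$-advection CFL number below 0.4):

1. implicit (backward-Euler) spatial diffusion, one tridiagonal solve per
   $z$-level with a precomputed factorization ($D$ is constant in time);
2. conservative first-order upwind advection in $z$ with velocity
   $\kappa g(z, h)$ and zero flux at both $z$ ends — $g$ changes sign at the
   sharp AHL switch, where monotone first-order upwinding is the safe
   choice;
3. growth by the exact factor $e^{r n\, dt}$;
4. field update (explicit source, exact decay factor, implicit diffusion).

Mass is conserved by construction (telescoping fluxes plus direct
tridiagonal solves); the suite verifies $10^{-10}$ relative drift over
$10^4$ steps, nonnegativity, and agreement with heat-kernel and
$z$-moment closed forms.

Two discretization choices deserve emphasis:

* **$z$-grid alignment.** The inoculum is a $\delta$-layer at $z = Z_w$,
  represented as all mass in one $z$-cell. Since $D(z)$ varies steeply near
  $Z_w$, the effective front diffusivity would otherwise depend on where the
  containing cell's centre happens to fall. The grid spacing is therefore
  chosen so that $Z_w$ lies exactly on a cell centre at any resolution
  (`Nz` = 60 over $[0, 1.05 Z_w]$ by default); with this alignment, halving
  the grid moves the 10-h front position by well under 2%.
* **Radial axis.** Cell centres sit at $\xi_i = (i-\tfrac12)\Delta\xi$, so
  the innermost face lies at $\xi = 0$ with zero area: the coordinate
  singularity and the symmetry condition are handled by the face-area
  weighting with no special-cased stencil.

The reduced model $\partial_t\rho = \Delta(\bar D(h)\rho) + rn\rho$, with
$\bar D$ a step function of $h$ (equal to $D(Z_w)$ below threshold, $D(0)$
above), follows from slaving $z$ to its steady state. It is included as the
comparison limit: during actual stripe formation CheZ is far from
steady-state across the population, which is the point of carrying $z$ as an
internal coordinate. Note the flux form $\nabla(\bar D \rho)$, not
$\bar D \nabla \rho$; its tridiagonal system is rebuilt every step because
$\bar D$ follows $h$.

## Pattern metrics

* **Front position**: outermost crossing of a density threshold (default
  0.1 in $\rho_s$ units), linearly interpolated; **front speed** is the
  least-squares slope over 10–20 h.
* **Stripes**: interior local maxima with topographic prominence at least
  10% of the profile maximum, excluding the outermost (front) peak. Both the
  prominence cutoff and the front exclusion are operational choices of this
  package — the pattern definition in the source material is graphical — and
  they are exposed as arguments.
* **Wavelength**: mean spacing of successive stripe maxima.
* **Height ratio**: following minimum over peak within a stripe. **Density
  ratio**: $\int_B^C \xi\rho\,d\xi / (h_1 \int_B^C \xi\,d\xi)$ with
  $[B, C]$ the pair of minima bracketing a peak (one full wavelength). The
  graphical definition does not pin down the window or the normalizing
  denominator; bracketing minima and the $h_1$-weighted window integral are
  this package's stated convention (they reproduce the flat-profile limit 1
  and the thin-annulus square-wave limit $\varphi$, the occupied fraction).
* **Formation interval**: mean difference between the first times at which
  the $k$-th interior stripe appears in a snapshot series.

## Study conditions and problem sizes

The baseline scenarios are: 500 cells (1D) inoculated as a centred Gaussian
with $\sigma = 2$ mm, internal states at equilibrium ($z = Z_w$, $m = m_0$),
$n \equiv 1$, $h \equiv 0$; the radial inoculum uses the same Gaussian line
profile with $\rho_0 = 0.5$. Default domains are chosen so fronts never
reach the wall: $[-25, 25]$ mm for 1D runs to 10 h, radius 40 mm for radial
runs to 12.5 h ($N_x = 500$, $N_z = 60$), radius 75 mm at $N_x = 300$ for
the 20-h parameter sweeps. The hybrid/PDE cross-validation runs the 1D
scenario to 5 h.

Two measurement choices in the cross-validation deserve a note. First, the
ensemble mean of the agent model is estimated from 12 realizations: with
$10^4$ cells in 0.1-mm bins, the Monte-Carlo error of a 6-run mean is itself
comparable to the model discrepancy being measured, and 12 runs bring the
estimator error safely below it. Second, a residual systematic gap of order
10% in L1 remains at any ensemble size and is concentrated at the colony
edge: discrete-particle fronts propagate slightly slower than their
mean-field limit (the well-known finite-population cutoff correction to
pulled fronts). This is a real property of the agent model, not a solver
artifact; the mean-field model remains quantitatively faithful in the bulk.

## What the simulations do and do not emulate

The generator reproduces the idealized study conditions: point-like cells,
constant speed, uncrowded motion (no steric or hydrodynamic interactions),
nutrient-independent speed, Poisson division without a cell-cycle variable,
and noise-free intracellular dynamics. Passing tests therefore demonstrate
internal consistency of the multiscale chain (signaling to motility to
population) and semi-quantitative agreement of emergent pattern scales; they
do not certify quantitative accuracy for real plates, where agar mechanics,
cell shape, metabolic heterogeneity and gene-expression noise all enter.
Known limitations: first-order splitting and upwinding (sharpening the
stripes slightly diffuses $z$-structure), nearest-node source deposition
(grid-convergent but first-order), and the front-cutoff discrepancy between
the agent and mean-field models discussed above.

## A worked single-cell example

```{r single-cell}
sp <- signaling_params()
ms <- steady_methylation(sp$Zw, sp)
rt <- cell_rates(ms, sp$Zw)
c(m_star = ms, lambda = rt$lambda, mu = rt$mu,
  run_frac = rt$mu / (rt$lambda + rt$mu))
run_fraction(c(1.23, 1.11))
effective_diffusion(1.23, d = 1)
```

## A scaled-down pattern run

```{r pattern, fig.width = 6, fig.height = 4}
cfg <- scenario_preset("radial_baseline", T_end = 9 * 3600, snap_dt = 1800)
run <- run_pde(cfg)
plot(run, times = c(5, 7, 9) * 3600)
pattern_metrics(run, t_window = c(5, 9) * 3600)
```
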