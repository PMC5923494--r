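---
title: "Quantifying cell-to-cell viral spread among stationary cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-to-cell viral spread among stationary cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexspread)
```

## The problem

Viruses spread through a cell population by two routes: cell-free (CF)
transmission, in which exported virions diffuse and infect distant cells,
and direct cell-to-cell (CC) transmission between an infected cell and an
adjacent uninfected one. Standard virus-dynamics ODE models describe both
routes by mass-action kinetics,

$$
\dot T = -\beta_f V T - \beta_c I T, \qquad
\dot I = +\beta_f V T + \beta_c I T, \qquad
\dot V = \rho I - c V,
$$

which implicitly assumes every infected cell can transmit. For stationary
cells in a monolayer or solid tissue this is wrong: CC spread produces
compact foci, and cells in the interior of a focus — surrounded entirely by
other infected cells — contribute nothing. Mass-action fits to such data
then misattribute the decelerating growth to a small transmission rate,
systematically underestimating $\beta_c$.

`hexspread` provides (i) an agent-based model (ABM) of viral spread on a
hexagonal monolayer that generates realistic population-level time series
with known ground truth, (ii) a perimeter-fraction correction $f_c(I)$ that
restores a valid population-level description of CC spread, and (iii) the
likelihood machinery (replicate-variance Gaussian likelihood, AICc, profile
intervals) to fit and compare the model family on such data.

## The adjustment term

For a single focus growing radially on a lattice with $k$ neighbours per
cell, after $n$ complete rings the focus holds $I(n,k) = \tfrac k2 n^2 +
\tfrac k2 n + 1$ cells of which $kn$ lie on the perimeter. The contributing
fraction after ring $n$ is therefore $f_c(n,k) = 2kn/(kn^2+kn+2)$.
Inverting $I(n,k)$ for $n$ gives the continuous form

$$
f_c(I) = \frac{\sqrt{k^2 + 8kI - 8k} - k}{2I}, \qquad I \ge k .
$$

For $I \le k$ every infected cell still borders uninfected cells, so
$f_c = 1$; a cubic connection polynomial on $k < I < k+z$ joins the two
branches with matching value and slope at both ends (coefficients from the
2×2 linear system in `solve_connection()`). The window width $z$ is a
fittable shape parameter. Cultures with $\psi$ initial foci growing
irregularly (irregularity $\theta \ge 1$, with $\theta = 1$ perfect circular
growth) are mapped onto the single-focus curve by evaluating at
$I/(\psi\theta)$. The adjusted models multiply the CC term by $f_c(I)$:
`aCC`, `aCC-dI` (with an infectivity delay), `aCCF` (both routes).

```{r fc-curve}
ap <- adjustment_params(k = 6, z = 10)
round(fc_full(c(1, 6, 16, 100, 1000), ap), 4)
```

## The agent-based simulator

Cells occupy a hexagon-shaped patch of a hexagonal lattice (`hex_lattice()`;
side 90 gives the 24,031-cell culture, reduced scales shrink it). Each
infected cell carries an intracellular RNA load $R$ following logistic
replication with degradation and export,
$\dot R = \alpha R (1 - R/R_{cap}) - \gamma R - \rho R$, feeding local
extracellular virus $\dot V = f_{inf}\rho R - cV$ which diffuses by a
conservative neighbour-exchange rule (fraction $m/k$ of each pairwise
concentration difference per step; the exchange form keeps total virus
conserved and uniform fields stationary, which the printed sign of the
source scheme would violate). Uninfected cells are infected per time step
with probability $\min(1, s_f V \, dt)$ (CF) and, per infected neighbour,
$\min(1, s_c f_{inf} R \, dt)$ (CC, donors tried in random order, donor
loses one RNA copy, recipient starts at $R = 1$). Experiments are seeded
either with one central cell or by Poisson inoculation over a 17-h window
with density $\hat I_0 \lambda e^{-\lambda t}/(1 - e^{-17\lambda})$, whose
integral is exactly $\hat I_0$ regardless of lattice size; at 17 h the
medium is changed ($V \to 0$) and CF infection can be blocked (antibody
wash), leaving pure CC spread.

### Generator defaults

The intracellular parameters are a documented fixture (the data they were
originally estimated from are not shipped): $\alpha = 4\times10^{-3}$,
$\gamma = 10^{-3}$, $\rho = 10^{-3}$, $c = 10^{-3}$ min⁻¹,
$R_{cap} = 1000$, $f_{inf} = 0.01$. These give an effective replication
rate of $2\times10^{-3}$ min⁻¹: a newly infected cell's RNA rises over
roughly two days to a plateau of 500 copies, the qualitative single-cell
behaviour the simulator is meant to emulate. The CC scaling
$s_c = 3\times10^{-4}$ min⁻¹RNA⁻¹ is chosen so that, with this fixture, a
focus advances one ring per ≈24–28 h — the regime implied by the
population-level transmission-rate estimates the method is designed to
recover. $s_f = 5\times10^{-4}$ min⁻¹virus⁻¹ makes CF and CC per-step
hazards comparable near a producing focus; slow diffusion uses $m = 0.005$
and the fast-diffusion scenarios scale it 165-fold. $\hat I_0 = 10$,
$\lambda = 0.1$ h⁻¹. What passing tests show is therefore that the
*method* recovers the kinetics of data generated under these conditions;
they do not validate any particular virus's parameter values, and features
of real data such as cell death, proliferation, motility or measurement
artefacts are outside the generator by design.

## Fitting and model comparison

Replicate runs are aggregated into per-time means $\bar x(t)$ and
empirical SDs $\sigma_t$; the likelihood of a model prediction $f(\theta,t)$
is Gaussian with combined variance $\sigma^2(t) = \sigma_t^2/n +
\sigma_{me}^2$, where the measurement error $\sigma_{me}$ is estimated. We
use the per-time-point variance inside both the residual and the
normalisation term — the only reading that keeps the likelihood proper when
$\sigma_t$ varies over time. When viral load is co-fitted with cell counts,
both channels switch to a relative error model (residuals and replicate SDs
divided by the model prediction). Optimisation is Nelder–Mead in a
transformed (log-scaled, box-squashed) parameter space from Latin-hypercube
restarts; models are ranked by AICc, and confidence intervals come from
profile likelihood (re-optimising all other parameters on a geometric grid
with warm starts and bisection refinement of the 1.92-drop crossing). A
parameter whose profile never reaches the drop on either side within its
bounds is flagged non-identifiable.

Single-focus fits use the ten daily means from day 1 to day 10 with
$I_0 = 1$ at $t_0 = 0$; multifocus fits start from the mean infected-cell
count at the 17-h media change, with $\psi$ fixed to the expected (or,
optionally, realized) inoculum size. CC-only fits drop the virus equation
entirely (viral turnover is then irrelevant to the cell counts). In the
mixed-transmission fits to cell counts alone, clearance $c$ is fixed at its
known value and production $\rho$ is free; this is what makes $\beta_f$
structurally non-identifiable there ($\beta_f$ and $\rho$ compensate), the
pattern the joint fit with a CF-only calibration dataset resolves.

## Numerical choices

Trajectories are integrated by a fixed-step RK4 method-of-steps scheme
(step 0.01 h in tests, 0.02 h in the scripted scenarios; halving the step
changes undelayed trajectories by $<10^{-6}$ relative). The delay models
store the infected-cell history on the integration grid and interpolate the
lagged value linearly. Two pre-histories are supported: the default
`"zero"` treats cells infected at time $s$ as infectious from $s+\tau$
(eclipse reading — nothing is infectious before $t_0+\tau$), while
`"constant"` holds $I(s) = I_0$ for $s < t_0$. We made `"zero"` the
default after finding that a constant pre-history makes the delay unable to
express the initial infectivity lag it is meant to represent: the founder
is then already infectious at $t_0$ and the fitted $\tau$ collapses to the
boundary. Infection probabilities are capped at 1; per-step hazards at the
default $dt = 1$ min are far below the cap in all shipped scenarios. The
ABM uses explicit Euler for the intracellular ODE, validated by
$\alpha\,dt \ll 1$ at construction.

## Known limitations and open choices

* The delay signal on single-focus data is fixture-dependent: under the
  shipped generator the aCC model (with $\theta$, $z$ free) already absorbs
  the early lag and the fitted $\tau$ goes to zero at every scale we
  simulated, under either pre-history. The multifocus behaviour
  ($\tau \approx 0$) is robust.
* $\varphi = \psi\theta$ is implemented as a product: both the number of
  initial foci and their irregularity shrink the effective focus size that
  enters $f_c$; $\psi = \theta = 1$ recovers the single-focus term.
* The perimeter correction assumes foci far from the culture boundary;
  saturating runs emit a warning, and late saturated time points carry
  boundary effects the correction does not model.
* Profile likelihood is the only CI method implemented; restart-cloud
  intervals are approximated by it.
* Scripted scenarios default to reduced problem sizes (side-40 lattice with
  20 replicates for the CC-only scenarios, side-30 with 10 replicates for
  the mixed ones) so a full scenario completes in minutes on one CPU;
  `full_scale = TRUE` restores the side-90 / 100-replicate setting.

## A complete run

```{r example, eval = FALSE}
rep <- run_multifocus(side = 40, n_reps = 20, base_seed = 1, n_restarts = 8)
rep$delta_aicc   # CC is decisively outranked by aCC
rep$beta_ratio   # ~1.5-fold larger adjusted estimate
rep$contributors # observed vs fc(I) * T/T0 contributor fractions
```
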