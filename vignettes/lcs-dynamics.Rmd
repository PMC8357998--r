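---
title: "Latent change score models: dynamics, simulation and estimation with lcsdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent change score models: dynamics, simulation and estimation with lcsdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsdyn)
```

## The model family

A latent change score (LCS) model describes a repeated-measures panel through
occasion-to-occasion changes in a latent process. The observed score of
individual $i$ at occasion $t$ is the latent initial level plus the
accumulated changes plus measurement error,

$$Y_{i[t]} = y_{i,0} + \sum_{k=1}^{t} \Delta y_{i[k]} + \varepsilon_{i[t]},$$

and the *dual* change specification makes each change a sum of a constant
individual additive component and a proportional self-feedback on the
previous level,

$$\Delta y_{i[t]} = y_{a,i} + \beta \, y_{i[t-1]}.$$

The loading of the additive component is fixed to 1 throughout and is never
counted as a parameter. Individuals differ in their initial level and
additive component, which follow a bivariate (in general, $2p$-variate)
normal distribution with means $\mu_{y0}, \mu_{ya}$ and covariance matrix
$\Phi$. With a single measurement-error variance $\sigma^2_e$ this is the
seven-parameter univariate dual model: two means, three variances, one
covariance, one self-feedback. `count_free_parameters()` reproduces this
accounting for every structural variant and is independent of the number of
occasions.

The bivariate model couples two processes $x$ and $y$ through cross-lagged
coupling parameters,

$$\Delta x_{i[t]} = x_{a,i} + \beta_x x_{i[t-1]} + \gamma_x y_{i[t-1]}, \qquad
  \Delta y_{i[t]} = y_{a,i} + \beta_y y_{i[t-1]} + \gamma_y x_{i[t-1]},$$

and the *stochastic* variant adds latent innovations $d_{i[t]} \sim
N(0, \Psi)$ to every change. Innovations are not measurement error: their
effect is carried forward through the dynamics to all later occasions. The
full stochastic bivariate model as specified here has 24 free parameters:
4 means, 10 distinct entries of $\Phi$, 4 dynamic coefficients, 3 entries of
the measurement-error covariance $\Theta$ (including a within-occasion
covariance, toggled by `error_covariance`) and 3 entries of $\Psi$. The
published path diagram for this model states the total of 24 without
enumerating the blocks; the composition above is this package's reading of
it, and each block can be switched off (`free_couplings`,
`error_covariance`, `innovation_covariance`) when a sparser structure is
wanted.

Standing assumptions, enforced at validation: one indicator per process;
occasions $0, \dots, T-1$ equally spaced with spacing `time_lag`; all
parameters time-invariant; Gaussian random effects, innovations and errors;
$\Phi, \Theta, \Psi$ symmetric PSD (eigenvalues above $-10^{-10}$).

## Trajectory algebra and the continuous-time view

With $M = I + A$ ($A$ the dynamics matrix: self-feedbacks on the diagonal,
couplings off it), the mean recursion is $\mu_{t} = M\mu_{t-1} + \mu_a$. In
the univariate case this is the discretization of the linear-affine ODE
$dy/dt = y_a + \beta_{CT}\, y$, whose solution is the exponential curve

$$y(t) = y_{As} - (y_{As} - y(t_0))\, e^{-r t}$$

with rate $r = -\beta_{CT}$ and asymptote $y_{As} = y_a / (-\beta)$
(`exponential_level()`, `additive_from_asymptote()`,
`asymptote_from_additive()`). The discrete- and continuous-time
parameterizations are linked by the matrix exponential:

* `ct_to_dt()`: $A_{\Delta t} = e^{B\,\Delta t} - I$ and
  $a_{\Delta t} = \int_0^{\Delta t} e^{Bs}\,ds \; a$;
* `dt_to_ct()`: $B = \log(I + A_{\Delta t})/\Delta t$, defined only when
  $I + A_{\Delta t}$ has no eigenvalue on the closed negative real axis
  (univariate: $1 + \beta > 0$).

Numerical choices. The matrix exponential uses `Matrix::expm()`
(scaling-and-squaring Padé; accurate to machine precision, including
defective matrices). The matrix logarithm is computed in closed form for the
$1 \times 1$ and $2 \times 2$ cases via eigenvalue interpolation
($\log M = aI + bM$), with the repeated-eigenvalue limit
$\log\lambda \cdot I + (M - \lambda I)/\lambda$; a closed form was chosen
because general-purpose eigendecomposition-based logarithms break down on
defective and near-defective blocks. The additive integral uses the
augmented-matrix identity, so a singular drift (the linear regime,
$\beta = 0$) needs no special-casing. Iterating the discrete recursion on
converted parameters reproduces the continuous solution at multiples of the
lag to $10^{-10}$; this round trip is property-tested over randomized stable
configurations.

## Shape classification

`classify_shape()` gives one qualitative label per model.

*Univariate*: the sign of $\beta$ decides decelerated ($\beta < 0$) versus
accelerated ($\beta > 0$) change, and the position of the asymptote relative
to the initial mean decides growth versus decline. $\beta = 0$ gives linear
growth/decline by the sign of $\mu_a$, and `constant` covers both the
degenerate linear case and trajectories starting on their asymptote. A point
worth emphasizing because it is often gotten wrong in applied work: the
*sign of the additive component does not determine* growth versus decline —
two configurations with identical $\mu_a$ and $\beta$ grow or decline
depending only on which side of the asymptote the initial level lies.

*Bivariate*: the eigenvalues of $M = I + A$ decide. A complex pair yields
oscillatory trajectories — damped, sustained or explosive as the modulus is
below, at, or above 1; real eigenvalues yield monotone-type trajectories,
convergent when the spectral radius is below 1 and divergent otherwise.
When both couplings are zero the two processes are dynamically independent
and the per-process univariate labels are attached. All boundary decisions
("zero", "modulus one") use a tolerance `tol`, default `1e-8`,
overridable per call.

Two caveats are documented deliberately. First, oscillation is defined here
as a complex eigenvalue pair; a negative real eigenvalue of $M$ (possible
for $\beta < -1$) produces period-two sign alternation that this taxonomy
still labels non-oscillatory. Second, among the six catalogued bivariate
coupling regimes (`table1_A` … `table1_F` in the fixture registry), regime C
has eigenvalues $0.8 \pm 0.22i$: its trajectories look like decelerated
monotone change over short horizons (the oscillation period is roughly 23
occasions and the modulus 0.83), but the classifier reports it — correctly,
under the eigenvalue definition — as weakly damped-oscillatory, and regime B
(eigenvalues 0.7 and 1.3) as divergent. Verbal descriptions of such
catalogues as "decelerated A–C" describe the plotted window, not the
spectrum; the package follows the spectrum.

The bivariate fixed point solves $A y^* + \mu_a = 0$ (`fixed_point()`). In
coupled systems the univariate identity $y_{As} = y_a/(-\beta)$ does *not*
hold process-by-process; the equilibrium mixes both additive components
through $A^{-1}$.

## The simulator

`simulate_panel()` composes three steps, each with its own substream derived
from one master seed so that, e.g., changing the error covariance never
perturbs the latent draws:

1. `draw_between_effects()`: multivariate-normal random effects
   (`MASS::mvrnorm`, eigen-based, so genuinely singular $\Phi$ is allowed);
2. `simulate_latent()`: the change recursion, with i.i.d. $N(0, \Psi)$
   innovations on each of the $T-1$ changes when stochastic;
3. `observe()`: additive Gaussian measurement error, independent across
   individuals and occasions.

The fixture registry (`lcs_fixture()`) freezes the illustrative scenarios
used throughout the documentation and tests: the four exponential
configurations (rates $4$ and $-0.4$, initial levels $0$ and $10$, common
asymptote $5$, converted to the discrete metric at lag 1), the decelerated
self-feedback contrast ($\beta = -0.2, -0.5, -1$) and its accelerated decay
mirror ($\beta = 0.2, 0.5, 1$), the additive-variance contrasts
($\sigma^2_{y0} = 10$ with $\sigma^2_{ya} = 0$ or $12$), and the six
bivariate coupling regimes. Where the source material prints no value
(means, error variances, occasion counts) the registry fixes documented
constants — univariate scenarios use $T = 5$, $\sigma^2_e = 0.25$ and a
modest random-effect covariance; bivariate scenarios use $T = 10$,
$\mu_0 = (0,0)$, $\mu_a = (1,1)$ — chosen once to give visually sensible
panels at the catalogued dynamics, and never adjusted afterwards.

What the generator emulates is exactly the model: Gaussian effects,
innovations and errors, equal spacing, time-invariant parameters, and
missingness only if the user masks cells. Real panels violate several of
these (non-normality, attrition that depends on the outcome, drifting
measurement properties), so passing tests here demonstrate correctness of
the machinery under the model's own assumptions, not robustness to their
violation.

## Likelihood: two independent routes

`implied_moments()` builds the mean and covariance of the stacked observed
vector in closed form from the loading matrix
$L_t = [M^t, \; \sum_{k=0}^{t-1} M^k]$: mean $L(\mu_0, \mu_a)'$, covariance
$L \Phi L' + Q + R$ with the innovation accumulation
$Q_{t,s} = \sum_{k=1}^{\min(t,s)} M^{t-k}\Psi (M^{s-k})'$ and $R$ the
per-occasion error blocks. `minus_two_loglik()` is the casewise
(full-information) Gaussian likelihood: rows are grouped by missingness
pattern, each pattern is reduced to its count, mean and scatter, and each
pattern's marginal covariance is factorized once — evaluation cost is then
independent of the number of individuals. Missing data are marginalized, not
imputed; all-missing rows are dropped with a warning. Covariance solves use
the Cholesky factor; a diagonal jitter of $10^{-10}$ is added only when
factorization fails, with a warning.

`kalman_loglik()` evaluates the same quantity through a linear state-space
filter (state = latent levels and additive components; innovations as
process noise, measurement error as observation noise, missing rows dropped
from the observation equation step by step). It exists as an independent
cross-check — the two routes share no moment code and agree to $10^{-6}$ on
every tested panel — and as an $O(T)$ alternative for long panels.

## Estimation

`lcs_fit()` minimizes the full-information $-2\log L$ over an unconstrained
coordinate system: means and dynamic coefficients untransformed, covariance
blocks through Cholesky factors with logged diagonals (single variances as
log-variances), so every point of the search space is a valid parameter set
and no explicit constraints are needed. Couplings fixed by the specification
are pinned to zero, never estimated.

Starting values are data-driven: initial-level means from the first
occasion, $\beta$ from the log-ratio of successive occasion-mean changes
(clipped to $(-1.9, 0.9)$, falling back to $-0.3$ when the ratios are
unusable), the additive mean from the average change residual, and variance
blocks from first/last-occasion sample moments. Additional starts jitter the
unconstrained vector by $\pm 20\%$; the default is 5 starts and the best
converged solution wins. Optimization uses `nlminb` with a relative
function tolerance of $10^{-10}$. A solution is declared converged when the
optimizer reports convergence within its iteration budget and the central
finite-difference gradient of $-\log L$ satisfies
$\|g\|_\infty < 10^{-5} \max(1, |\!-\!2LL|/2)$ — the relative scaling exists
because an absolute $10^{-5}$ is below finite-difference precision once the
log-likelihood is of order $10^3$–$10^4$. No bounds are placed on the
dynamics: explosive solutions are legal and flagged
(`explosive = TRUE` when the spectral radius of $I+A$ exceeds 1). Fits on
variance boundaries (e.g. data generated with $\Phi = 0$) converge in
location but may fail the gradient criterion; the estimates are still
returned with `converged = FALSE`.

Standard errors are delta-method: the numeric Hessian of $-2LL/2$ in
unconstrained coordinates is inverted and pushed through the Jacobian of the
natural-scale map; a non-positive-definite Hessian withholds SEs with a
warning rather than reporting nonsense. AIC and BIC satisfy
$\mathrm{AIC} = -2LL + 2k$, $\mathrm{BIC} = -2LL + k\log N$ with
$k$ = `count_free_parameters()` exactly. Three occasions is accepted with an
identification warning — the dual model is at the edge of identification
there and no hard minimum beyond $T \ge 3$ is imposed.

`recovery_study()` wraps the simulate–fit loop and reports per-parameter
bias, RMSE, 95% Wald coverage and the convergence rate. The shipped
acceptance checks run the deterministic univariate design at $N = 500$,
$T = 5$ with 50 replications and the stochastic univariate design at
$N = 1000$ with 50 replications, each with 2 starts per fit; all parameters
recover within 3 Monte-Carlo standard errors at these sizes. Monte-Carlo
moment checks use $2\times 10^5$ simulated individuals, at which the
analytic and empirical moments agree within 3 elementwise Monte-Carlo
standard errors.

## Known limitations

* One indicator per process; no measurement model or longitudinal
  invariance testing.
* Equal occasion spacing only; continuous-time *estimation* from
  irregularly spaced data is out of scope (conversion of parameters is not).
* At most two processes; no higher-order change specifications
  (change-to-change couplings, quadratic additive components, acceleration
  models), no time-varying parameters or regime switching, no random
  self-feedbacks.
* Gaussian likelihood only; no robust or least-squares estimators, no
  Bayesian machinery.
* Missingness is handled by marginalization under an ignorable-missingness
  assumption; no dropout models.
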