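---
title: "Models and methods in yeastcolony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in yeastcolony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The microenvironment model

Budding yeast in glucose-rich medium grows fermentatively, excretes
ethanol, and after glucose is exhausted undergoes the diauxic shift to
respiratory growth on the accumulated ethanol; nutrient-starved cells
drop into a quiescent state. `yeastcolony` models a locally homogeneous
population by five ODE states: cell mass in the glucose (`m_g`),
ethanol (`m_e`) and quiescent (`m_q`) metabolic states, and the
glucose (`g`) and ethanol (`e`) levels:

$$
\begin{aligned}
\dot m_g &= \mu_1 m_g g - \beta_1 \frac{m_g}{g + K} - \beta_2 m_g, &
\dot g &= -\frac{\mu_1}{\gamma_1} m_g g,\\
\dot m_e &= \mu_2 m_e e + \beta_1 \frac{m_g}{g + K} - \beta_3 m_e, &
\dot e &= \frac{\mu_1}{\gamma_2} m_g g - \frac{\mu_2}{\gamma_3} m_e e,\\
\dot m_q &= \beta_2 m_g + \beta_3 m_e. &&
\end{aligned}
$$

The switching term $\beta_1 m_g/(g+K)$ is deliberately not
Monod-style: it is small while glucose is abundant and saturates at
rate $\beta_1/K$ once $g \to 0$, which is what makes the model
diauxic. The observable is the total mass $m = m_g + m_e + m_q$,
matching optical-density readings one-to-one (no calibration curve is
applied). Three structural hypotheses differ in the admissible routes
into quiescence: `H1` keeps both $\beta_2$ (directly from the glucose
state) and $\beta_3$ (via the ethanol state); `H2` sets
$\beta_2 = 0$; `H3` sets $\beta_3 = 0$. A petite
(respiratory-deficient) strain is the same model with $\mu_2 = 0$
(`as_petite()`).

**Parameterization.** Cultures start in glucose-rich medium, so only
$m_g(0)$ and $g(0)$ are non-zero, and $g(0)$ is normalised to 1. The
free parameters are the logarithms of $m_g(0), \mu_1, \beta_1, K,
\mu_2, \gamma_1, \gamma_2, \gamma_3$ plus $\log\beta_2$ and/or
$\log\beta_3$ as the hypothesis allows (10 parameters under `H1`, 9
under `H2`/`H3`). Log coordinates match the standard-normal priors and
enforce positivity as a soft bound: a rate that is present cannot be
arbitrarily close to zero under the prior.

**A known degeneracy.** The transformation
$(e, \mu_2, \gamma_2, \gamma_3) \to (c e, \mu_2/c, \gamma_2/c,
\gamma_3/c)$ leaves every observable invariant, because ethanol is
never measured directly. These three parameters are therefore
identified only through the prior. The ridge is common to all three
hypotheses, so evidence comparisons are essentially unaffected, but
individual estimates of $\mu_2, \gamma_2, \gamma_3$ should be read as
one identified combination.

**Integration.** The system is integrated by an adaptive embedded
Dormand–Prince 5(4) scheme in compiled code at `rtol = 1e-8`,
`atol = 1e-10`. On the support of the prior the system is at most
mildly stiff (the fastest rate is $\beta_1/K$), and the adaptive step
resolves the thin switching layer around glucose depletion; the
implementation is cross-checked in the tests against an independent
stiff solver (`deSolve::lsoda`) and a fixed-step RK4 oracle.
Negative undershoots smaller than $10^{-9}$ of the initial content are
clamped to zero; anything larger aborts. During sampling and
optimization, a 20,000-step budget per solve bounds the cost of
pathological corners (the data-supported region needs a few hundred
steps); a failed or over-budget solve scores a $-10^{10}$
log-likelihood sentinel instead of raising, which keeps chains alive.

# The synthetic data generator

No experimental data ship with the package; the generators reproduce
the sampling designs the inference assumes.

* **Growth curves** (`generate_growth_curves()`): total mass on a
  15-minute grid to 88 h, six replicates, additive i.i.d. Gaussian
  noise per replicate with `noise_sd = 0.01` OD-equivalent units (a
  typical plate-reader noise floor); the averaged curve `D_k` and the
  per-timepoint sample variances `v_k` are what the likelihood
  consumes, with a `1e-8` variance floor so the likelihood is always
  evaluable. Composition observations at `t_N = 80` h are the true
  trajectory fractions perturbed by Gaussian noise with sd 0.02,
  truncated to valid fractions by rejection.
* **Footprints** (`generate_footprint()`): the lattice simulator's
  footprint-area series, sampled every 20 minutes in the full design,
  with zero-truncated Gaussian noise.

The default ground truth (`default_truth_theta()`) is an `H2`
parameterization tuned once so that the 80 h composition is exactly
29% ethanol-state and 62% quiescent-state mass — the published
steady-state composition of wild-type colonies — with
$\mu_1 = 0.6\,\mathrm{h^{-1}}$ and unit yields as realistic OD-scale
values; the curve is cleanly diauxic (glucose phase to ~12 h, a
pronounced ethanol growth phase to ~30 h) and saturates at total mass
2.05 well before the composition readout. Because the composition
constraints leave two free directions among the switching rates, those
were resolved by two further design requirements, fixed once: the
routing must be structurally identifiable (the best `H3` fit to
noiseless data trails the generating model by ~60 log-likelihood
units), and the parameters sit as close to the prior bulk as the data
allow (`K = 1`, `beta1 = 0.0235`, `beta3 = 0.0216`; rates slower than
the 88 h observation window are unavoidable prior-tail events).

What the generator does *not* emulate: plate-to-plate systematic
effects, OD nonlinearity at high density, heteroscedastic measurement
error, image-segmentation artefacts in footprint extraction, or any
misspecification between model and data. Passing recovery tests on
these data therefore demonstrates the correctness and calibration of
the machinery, not robustness of the model on real measurements.

# Likelihood, priors, and evidence

The likelihood multiplies independent Gaussians for every averaged
curve point ($D_k$ with variance $v_k$) and two Gaussians for the
composition fractions at $t_N$. Priors are independent standard
normals in log space. Marginal likelihoods
$\pi(D\mid H_i)$ are estimated by population MCMC over the
fifth-power temperature ladder
$\beta_i = ((i-1)/(N_\beta-1))^5$ and thermodynamic integration
(trapezoidal quadrature of the per-temperature mean log likelihood,
with a right-endpoint rule on the panel touching $\beta = 0$; see
the limitations section); hypothesis posteriors follow by log-sum-exp
normalisation under a uniform hypothesis prior.

**Sampler.** Within each temperature, adaptive random-walk Metropolis
with proposal covariance $(2.38^2/d)\,\hat C + 10^{-8} I$ estimated
from the trailing window (recomputed every 25 sweeps during burn-in,
frozen afterwards), plus a Robbins–Monro scale factor tuned towards
0.234 acceptance during burn-in, which rescues temperatures whose
covariance estimate is poor. One Metropolis swap attempt between a
uniformly chosen adjacent temperature pair per sweep (configurable;
more swaps were found to transport diffuse near-prior states up the
ladder faster than local moves can relax them, biasing evidence for
narrow-mode models low). The $\beta = 0$ chain is advanced by
independent draws from the prior — its marginal target *is* the prior
— which keeps its log-likelihood trace free of the long excursions a
random walk makes into regions where the solver fails.

**Initialization.** The growth-curve posterior is multimodal: a
"fast-switching" local mode traps most naive optimizer starts.
`fit_map()` therefore starts from a moment-matched heuristic (initial
mass from the first reading, yield from the plateau, growth rate from
the early log-slope, switching rates on the observation timescale
$1/T$), plus randomized perturbations of it and the origin, screens
all starts cheaply and refines the best. `init_by_multistart()` runs
this search at $\beta = 1$ and carries the optimum down the ladder by
warm-started local optimizations, attaching Laplace (inverse-Hessian)
proposal covariances per temperature so chains start essentially
converged.

**Why 30 temperatures.** With six replicates of 0.01 noise the
variances $v_k \sim 10^{-4}$ make prior-draw log likelihoods of order
$-10^7$. The trapezoid panel adjacent to $\beta = 0$ has weight
$\beta_2/2$; at $N_\beta = 10$ that weight is $8.5\times10^{-6}$ and
the panel contributes an $O(100)$-nat error, at $N_\beta = 30$ it is
$2.5\times10^{-8}$ and the error is $O(1)$. Hypothesis comparisons
therefore always use the full 30-rung ladder (chain lengths, not the
ladder, are what we scale down for testing); the 10-rung ladder is
reserved for the benign conjugate-toy validation, where the
closed-form evidence is reproduced to better than 0.1.

**Diagnostics.** `psrf()` implements the classic Gelman–Rubin
between/within form, $\sqrt{((n-1)/n\,W + B/n)/W}$, with 1.1 as the
conventional convergence threshold.

# The spatial framework

Space is discretized into cubes of edge $h = 0.1$ mm. Each cube holds
the five microenvironment quantities; agar cubes (a disc of thickness
0.2 mm, diameter 1 cm in the full configuration) hold glucose only.
The dynamics per Euler step (`dt = 0.0025` h) are the cube-local
reactions plus two flux couplings between the six face neighbours:

* **Cell-mass movement** moves only the thresholded excess
  $\max(m - th, 0)$ ("pressure", threshold $th = 1$) from high to
  low, at rate $\lambda_{mass} = 20\,\mathrm{h^{-1}}$, carrying the
  donor cube's state composition along. Movement into agar is
  forbidden; domain boundaries are zero-flux (a sealed dish). The
  pairwise flux is antisymmetric, so transport conserves total mass
  to machine precision.
* **Nutrient transfer** is plain flux coupling without thresholding.
  Glucose lives on the union of agar and cell-occupied cubes; its
  per-edge rate is $\lambda_{col}$ above the agar–colony interface
  (layers $k > h_{agar}+1$, or the upward edge out of layer
  $h_{agar}+1$) and $\lambda_{agar}$ otherwise, read literally from
  the layer rule — including its ambiguity at the interface, where
  lateral edges in the first colony layer take the agar rate; this is
  flagged as a sensitivity, not resolved. Ethanol diffuses only over
  cell-occupied cubes and always at $\lambda_{col}$, and never enters
  the agar.

Initialization seeds one centre cube above the agar with glucose-state
mass equal to $th$ and local glucose 1; agar cubes start at
$g_0^{agar} = 1$. The footprint area is the number of columns with
above-agar cell mass times $h^2$.

Per-cube quantities are treated as amounts with unit cube volume, so
microenvironment concentrations and amounts coincide (the per-cube
normalisation $g_0 = 1$).

**Numerics.** Neighbour contributions are accumulated as
(x-pair + y-pair) + z-pair; because floating-point addition is
commutative within pairs, a 4-fold rotationally symmetric state stays
*bitwise* symmetric for the whole run, which the tests exploit. The
same scheme is implemented twice: a vectorised R reference
(`euler_step()` and the `*_rhs()` functions) used by the tests, and a
compiled core used by `simulate_colony()`; both are compared directly.
Values in $(-10^{-9}, 0)$ are clamped to zero each step, larger
negatives abort with a step-size error.

**Problem sizes.** The tests and examples run a reduced lattice,
21×21×(2+10) cubes with a 1.9 mm agar disc (and smaller still for
per-operation checks), chosen so the colony's behaviour — spreading,
nutrient depletion from the agar, petite/wild-type ordering — is fully
expressed at interactive runtimes; the full plate (101×101 footprint,
1 cm disc, 7.5-day horizon) is a configuration change, not a code
path.

# Calibration of the transfer rates

The two free spatial parameters $(\lambda_{agar}, \lambda_{col})$ are
fitted to footprint-area series by minimizing
$\xi = \log \sum_i (A^{sim}_{t_i} - A^{meas}_{t_i})^2$ (sum floored at
$10^{-300}$ so a perfect fit stays finite) with GP-based Bayesian
optimization: a 20-point Latin hypercube initial design inside the
bounds $[5, 75] \times [0.005, 1]$, a zero-mean GP with squared
exponential kernel on costs standardized to zero mean and unit sd
(sd floor $10^{-12}$), hyperparameters (two length-scales, signal
variance, error variance) fitted by maximizing the exact log marginal
likelihood in log space from $\theta = (1,1,1)$,
$\sigma_{error} = 0.1$, with a $10^{-10}$ diagonal jitter; expected
improvement maximized by multistart L-BFGS-B from a 50-point LHS; the
loop stops below an EI threshold of $10^{-46}$ or at the iteration
cap. Failed cost evaluations are recorded as a large sentinel rather
than aborting the loop.

# Limitations

* Total-mass curves plus a single composition timepoint identify the
  quiescence routing only weakly against the *nested* alternative:
  `H3` (direct glucose-to-quiescence only) is rejected by ~60 nats
  under the default truth, but `H1`, which contains the generating
  `H2` as a special case, trails it by only ~3 nats of evidence — its
  extra switching route's complexity penalty is largely recovered by
  parameter compensation. Long-chain thermodynamic integration
  (cross-checked by importance sampling) resolves this margin; at the
  short chain lengths the test suite can afford, the `H1` evidence
  retains a positive transient bias of comparable size (chains started
  at the per-temperature optima of a 10-dimensional ridge posterior
  relax slowly), so the posterior probability of `H2` then fluctuates
  around the conventional 0.9 reporting threshold instead of clearing
  it reliably. Decisive route selection from data of this design
  therefore requires production-scale chains (order 10^4 sweeps per
  temperature), not the scaled-down test settings.
* The trapezoid panel touching `beta = 0` is replaced by a
  right-endpoint rule (see above); absolute evidence values therefore
  inherit an `O(1)`-nat quadrature convention near the prior end that
  is common to all hypotheses and cancels from comparisons.
* With standard-normal log-space priors, evidence comparisons are
  trustworthy only when the generating parameters are not extreme
  prior-tail events; rates much slower than ~e^-4 per hour sit many
  prior standard deviations out and distort nested-model comparisons.
* No cell death, agar invasion, extracellular-matrix structure, or
  aromatic-alcohol signalling; quiescent and dead cells are not
  distinguished.
* The simulated footprint saturates once the agar's glucose is
  consumed, so very long horizons add little information about the
  transfer rates.
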