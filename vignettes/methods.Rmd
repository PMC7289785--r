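---
title: "Models and methods: population PK/PD of pulsatile GH and circadian PRL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pulsepkpd)
```

## The problem

Growth hormone (GH) and prolactin (PRL) are pituitary hormones whose
secretion a somatostatin–dopamine chimeric agonist suppresses. Quantifying
that concentration–effect relationship from a phase-1 ascending-dose study
is hard for two reasons: endogenous GH is secreted in irregular bursts whose
timing differs between individuals and between days, and PRL follows a
circadian rhythm and declines slowly under repeated dosing. `pulsepkpd`
implements a deconvolution-informed population PK/PD workflow for this
setting: individual GH profiles are first decomposed into Gaussian secretion
events, the event locations are then carried into a nonlinear mixed-effects
(NLME) model where the drug inhibits pulse mass, and PRL is modelled as a
precursor pool with circadian release under direct drug inhibition. Because
the original clinical data are available only on request, the package also
contains a virtual-trial generator with the same statistical structure, so
every stage can be exercised and tested end-to-end.

## Structural models

### Growth hormone

Secretion is a basal rate plus a train of Gaussian bursts,

$$ S(t) \;=\; \mathrm{baseline}\cdot k_{el}
   \;+\; \sum_j m_j \, f_j \, \varphi(t;\,T_j,\,w), $$

where $\varphi$ is a unit-mass Gaussian density, $T_j$ the pulse centre
(from the deconvolution), $w$ the common secretion width (h), and $m_j$
the pulse mass (ng/mL, the time-integral of the secretion bump). Plasma GH
obeys $dC/dt = S(t) - k_{el}\,C$. The system is linear, so the model is
evaluated with the exact Gaussian-convolved-exponential form

$$ C(t) = \mathrm{baseline} + \sum_j m_j f_j\,
   e^{k_{el}^2 w^2/2 - k_{el}(t-T_j)}\,
   \Phi\!\left(\tfrac{t-T_j}{w} - k_{el} w\right), $$

with an adaptive Runge–Kutta route retained purely as a numerical
cross-check (they agree to < 1e-6 ng/mL; see the acceptance tests).
The drug factor is
$f_j = 1 + E_{max}\, C_e(T_j)/(EC_{50} + C_e(T_j))$ with
$E_{max} \in [-1, 0]$: the effect-site concentration $C_e$ (first-order
equilibration with plasma at rate $k_{e0}$) is sampled at the pulse centre
and scales the whole pulse mass — a pulse is treated as a single secretion
decision. Pointwise scaling of the secretion rate is available through
`gh_concentration(effect = "rate")` but is not the default; with 20-min
sampling and ~11-min pulse SD the two are practically indistinguishable.

Interpretation of the parameter table: "baseline" is the steady-state
baseline concentration (ng/mL), so the basal secretion rate is
`baseline * kel`; "amplitude" is the typical pulse mass, so the Gaussian
height is `mass/(width * sqrt(2*pi))` — both choices keep the printed units
and make the mass invariant to the width.

### Prolactin

A precursor pool $P$ is filled at synthesis rate $k_s$ and releases into
plasma at rate $k_r$, modulated by two cosines (24 h and 12 h periods) and
directly inhibited by the drug plasma concentration:

$$ \frac{dP}{dt} = k_s\,(1 - I(t)) - k_r^{\mathrm{eff}}(t)\,P,\qquad
   \frac{dC}{dt} = k_r^{\mathrm{eff}}(t)\,P - k_{el}\,C, $$

$$ k_r^{\mathrm{eff}}(t) = k_r\,\bigl(1 + A_{24}\cos\tfrac{2\pi(t-\phi_{24})}{24}
   + A_{12}\cos\tfrac{2\pi(t-\phi_{12})}{12}\bigr)\,
   \bigl(1 + E_{max}\tfrac{C_p(t)}{EC_{50}+C_p(t)}\bigr), $$

with the additive-cosine parameterisation requiring
$|A_{24}| + |A_{12}| < 1$ so the release rate stays positive. The synthesis
decline under repeated dosing is driven by cumulative exposure
$x(t)$ (the running AUC of plasma drug concentration, mg·h/L):
$I(t) = x\,s/(1 + x\,s)$, which is 0 with no exposure and saturates at 1.
Note the deliberate asymmetry: the GH effect is driven from an effect
compartment, the PRL effect directly from plasma — both as reported.

All clock times are normalised so 0 = 6 a.m.; the simulation includes a
24 h initialisation period, and the state at its start is placed on the
drug-free periodic orbit. Because the system is linear in $(P, C)$, one
period of the drug-free dynamics is an affine map $x \mapsto Ax + c$; the
periodic state $(I-A)^{-1}c$ is computed exactly from three short
integrations, which makes the drug-free solution 24 h-periodic to machine
precision (no run-in transient leaks into the fit).

### Numerics

No general ODE solver is assumed in the environment, so the package ships
its own: a Dormand–Prince 5(4) adaptive integrator (`ode_rk45`) used for
the two-compartment Michaelis–Menten PK model and for cross-checks, and a
second-order exponential-midpoint integrator for the PRL pool system. The
latter freezes the coefficients at each step midpoint and propagates the
two linear sub-problems exactly; it is unconditionally stable and preserves
constant steady states exactly (the drug-free, circadian-free solution is
flat to machine precision). Inside the estimation hot loop the recurrence
runs in compiled code with all transcendentals precomputed as vectors and
cached across optimiser iterations; the default fitting step is 0.1 h
(simulation default 0.05 h) — at rates of at most 1.25/h the local error of
the midpoint scheme is far below the 4.9% proportional assay noise.

## The virtual-trial generator

The generator emulates the published design: cohorts of 8 (6 active, 2
placebo), single doses of 0.1–1.5 mg or 1.2 mg q.d. / 0.8 and 1.0 mg
b.i.d. at 8 h/16 h intervals over 13 days, 20-min hormone sampling from
−2 h to +12 h (single dose, with 15/30/60-min points in the first hour) or
−1 h to +11 h on days 7 and 12 (multiple dose). GH observations below the
0.05 ng/mL assay limit are substituted by the limit and flagged — not
censored — exactly as the source analysis handled them; PRL is never
censored.

Choices that the source does not pin down, decided once:

* **Pulse timing.** The inter-pulse interval law is a log-normal renewal
  process. Its two parameters (meanlog 4.3661, sdlog 0.8387 on the
  log-minute scale) were fitted by least squares on the normal-quantile
  scale to the four reported placebo interval statistics (median 74 min,
  quartiles 44 and 160 min, 95th percentile 293 min) before any test was
  run; the fitted law reproduces all four within 14%.
* **Drug PK.** The two-compartment PK parameters were published separately
  and are consumed as configuration. The shipped default (`pk_config()`:
  ka 1 /h, Vc 8 L, Vp 20 L, Q 5 L/h, CL 20 L/h, Vmax 50 µg/h, Km 1 µg/L)
  is illustrative: therapeutic doses cross both reported EC50s for several
  hours and decline toward baseline within ~8 h. Any quantitative PK claim
  requires an explicit configuration.
* **Covariates.** Age, weight and height are independent truncated
  normals; BMI and lean body mass are derived. No covariate affects any
  model parameter (the source analysis found none), so their joint
  structure is irrelevant to the recovery experiments.
* **Seeding.** One master seed; per-subject substreams are derived
  deterministically, so subject $k$'s data do not depend on how many
  subjects follow.

What a green recovery test does establish: that the estimator identifies
the published parameter vector from data with the assumed statistical
structure at the published design and noise levels. What it does not: that
real GH/PRL data follow that structure. Known differences include
homogeneous pulse timing (real nocturnal pulsing is denser — one visible
consequence is that the generator produces ~10% of placebo GH samples below
the assay limit where the source reports 20%), log-normal amplitude
variation without within-day structure, and noise-free drug concentration
records standing in for the individual post-hoc PK curves of the original
analysis.

## Deconvolution

`deconvolve()` decomposes one uniformly sampled profile into basal
secretion, an elimination rate, a common pulse SD, and Gaussian secretion
events, by weighted least squares on the closed-form convolution model
(proportional-error weights, one fixed weight set per profile so that RSS
values of nested fits are comparable). The iteration is insert–test–remove:

1. **Insert (triage).** A candidate is placed at the peak of the 3-point
   moving average of the positive *proportional* residuals (raw residuals
   are dominated by assay noise around the tallest pulses) and kept if the
   weighted RSS drop is significant at a deliberately liberal
   `alpha_insert = 0.2`, with the noise scale estimated robustly (MAD of
   weighted residuals — a mean square would be inflated by pulses not yet
   in the model and would veto everything on pulse-dense profiles). Each
   insertion is refitted from two starts (warm and reset kinetics), because
   a basal-only fit of a pulsatile profile can park the elimination rate at
   a bound.
2. **Test/remove.** Within each cycle, events whose mass fails a one-sided
   t-test at `alpha = 0.05` against its asymptotic standard error are
   removed (never the last event — single-event decisions belong to the
   final prune).
3. **Final prune.** At the converged event set, the model is refitted
   without each event in turn; an event is kept only if its removal
   significantly worsens the fit. The retention threshold is
   Bonferroni-adjusted for the location search (about n/3 effectively
   independent candidate positions after smoothing), and the noise scale is
   the residual MAD inflated by n/df — a heavily parameterised fit
   understates its own noise. The drop-one form is immune both to the
   variance-inflation cascade of sequential t-tests and to the covariance
   blow-up of near-collinear event pairs.

Kinetic parameters are box-constrained to physiological ranges (half-life
2.8 min–2.3 h, pulse SD 3–60 min): letting them escape makes the location
columns of the Jacobian degenerate and every significance test
uninformative. Pulses located before the first sample are absorbed by the
initial-condition parameter and are unidentifiable in principle; operating
characteristics are therefore scored on pulses inside the observed window
(and, following the published sensitivity claim, with mass at least ten
times the basal per-interval secretion). On 100 synthetic placebo profiles
at the published parameters and 15% noise the suite requires sensitivity
≥ 90%, at most one spurious event per profile, and an elimination-rate
recovery within ±15%.

After deconvolution, `augment_gaps()` applies the reported rule: whenever
two adjacent identified pulses are more than 300 min apart, one pulse
location is inserted at the midpoint (once per gap, never recursively,
identically for placebo and treated profiles). Augmented events carry a
location only; their mass is estimated downstream by the population model,
which is how they inform the maximal-effect end of the concentration–effect
curve.

## Estimation

`pkpd_fit()` maximises a first-order-conditional (FOCE) approximate
marginal likelihood with interaction: per subject the random effects are
optimised to the posterior mode (damped Gauss–Newton with analytic or
cheap hybrid Jacobians, a log-scale trust region, and warm starts across
optimiser iterations), the model is linearised there, and the subject's
contribution is the matching multivariate-normal deviance
$\log|V| + e^\top V^{-1} e + n\log 2\pi$ with
$V = J\Omega J^\top + \sigma^2\,\mathrm{diag}(f^2)$. For a model linear in
the random effects this is exact, which the test suite exploits as an
oracle. The outer problem is quasi-Newton over transformed parameters (log
for positive quantities, logit for the bounded $|E_{max}|$, identity for
phases, log for variances) with an explicit forward-difference gradient at
step 1e-3 — large enough to dominate the inner problems' convergence noise,
which machine-epsilon differencing does not — and automatic restarts when
the optimiser reports false convergence; an objective stable across
restarts is accepted as converged.

Random effects follow the reported structure: log-normal IIV on GH
baseline/width/k_el and a log-normal per-pulse amplitude deviation;
between-occasion variability on width and k_el (one draw per sampling day);
log-normal IIV on PRL k_s and both cosine amplitudes (phases would be
additive-normal, but carry no random effects in the final model). Residual
error is proportional for both hormones, with the variance floored at 1e-6
and predictions floored at 1e-10 ng/mL inside the residual model. GH
values at the assay limit enter the likelihood as ordinary observations —
the substituted-value approach of the source analysis; a censored
likelihood is deliberately not the default.

The GH fit follows the sequential protocol: system parameters and all
variance components are estimated on placebo subjects only, then fixed,
and the drug parameters ($k_{e0}$, $E_{max}$, $EC_{50}$) are estimated on
the full dataset. The Hill coefficient is fixed to 1 and IIV on $EC_{50}$
is excluded, both mirroring the final published model. Default starting
values are neutral (e.g. GH k_el at the deconvolution's initial 15-min
half-life, Emax at −50%) and deliberately not the published estimates.

`covariance_step()` inverts a Richardson-extrapolated finite-difference
Hessian of OFV/2 and reports delta-method standard errors, RSEs and the
eigenvalue condition number of the estimate correlation matrix, flagging
failure when the Hessian is not positive definite. `bootstrap()` resamples
subjects with replacement stratified by cohort and reports medians, 95%
percentile intervals and minimisation/covariance success rates. `lrt()`
applies the 6.63-point (printed as 6.64) chi-square criterion for one added
parameter at p < 0.01.

## Diagnostics

* `cwresi()` — conditional weighted residuals with interaction, whitened by
  the Cholesky factor of the linearised marginal covariance at the
  empirical Bayes mode. Under the true model the fraction with magnitude
  above 2 approaches the 4.6% two-sided normal tail; the acceptance suite
  checks that at over 2000 observations. Because the residual variance is
  floored, the zero-residual-error degenerate case cannot arise.
* `npde()` — Monte-Carlo normalised prediction distribution errors with
  per-subject empirical decorrelation, mid-rank ties and a 1/(2·n_sim)
  boundary clamp, summarised per treatment day (placebo subjects pooled by
  day). 1000 simulations by default; with the 74-observation multiple-dose
  subjects, fewer than ~300 leaves visible decorrelation noise in the
  per-day variance.
* `pcvpc()` — prediction-corrected visual predictive check over clock time
  (12 equal-count bins by default). Coverage is scored per (bin,
  percentile) pair, since each simulated band is a 95% interval for one
  percentile — requiring all three percentiles of a bin to be covered
  jointly would fail ~14% of bins even under a perfect model. GH requests
  are refused with an explicit error: percentile bands over clock time are
  meaningless when the timing of pulses differs between individuals.
* `shrinkage()` — 100·(1 − SD(EBE)/ω) per random-effect component.
* `covariate_screen()` — r² of every subject-level EBE against every
  mean-centred covariate, candidates at r² > 0.5, with optional
  forward-inclusion (p < 0.05) / backward-deletion (p < 0.01) stepping via
  a user-supplied refit closure.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `deconvolve(alpha)` | 0.05 | — | event-mass significance, as reported |
| `deconvolve(alpha_insert)` | 0.2 | — | liberal triage; final prune is the gate |
| `augment_gaps(threshold)` | 300 | min | the reported 95th-percentile rule |
| `prl dt` (fit / simulate) | 0.1 / 0.05 | h | midpoint-scheme error ≪ assay noise |
| `fit_foce control$grad_step` | 1e-3 | — | FD step above inner-noise floor |
| `npde(n_sim)` | 1000 | — | decorrelation noise at 74-obs subjects |
| `pcvpc(bins)` | 12 | — | equal-count clock-time bins |

## Known limitations

* The estimator's contract is parameter recovery, not objective-function
  parity with any specific NLME implementation; OFV values are comparable
  only within this package.
* The GH placebo stage estimates eleven parameters from sparse placebo
  arms; with only ~10 placebo subjects the variance components (especially
  between-occasion terms) are noisy, which is why the elimination-rate and
  width recovery targets use a dedicated 20-subject placebo design.
* Deconvolution sensitivity is defined on identifiable pulses (inside the
  sampled window, mass above ten times basal per-interval secretion);
  pulses closer than one sampling interval to a larger neighbour are
  frequently merged — a resolution limit of 20-min sampling, not of the
  implementation. At the published parameters this caps the measured
  sensitivity near 87% over 100 profiles (the shortfall concentrates in
  subjects whose individual half-life drifts long, ~27 min, while pulsing
  densely), with ~0.7 spurious events per profile and an unbiased
  elimination rate.
* With ~20 placebo subjects and 50% between-subject variability in the
  elimination rate, the realized sample mean of k_el drifts by ±10%
  between seeds; recovery experiments at that size test the estimator
  against the realized sample more than against the population value.
* The GH potency (EC50) is only weakly identified at desk scale: the
  per-pulse amplitude variability (CV 555%) dwarfs the at-most 2.8-fold
  Emax modulation, so the profile objective is flat within about one point
  over a several-fold EC50 range and the recovered value scatters
  correspondingly (its maximal inhibition Emax, by contrast, recovers to a
  few percent, as does the directly plasma-driven PRL potency).
* The virtual world is stationary within a day; real GH secretion is not,
  and the below-limit fraction of placebo samples is correspondingly lower
  in simulation (~10%) than reported (20%).
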