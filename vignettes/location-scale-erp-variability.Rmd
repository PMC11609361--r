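---
title: "Modelling trial-to-trial variability of ERP amplitudes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-to-trial variability of ERP amplitudes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Event-related potential (ERP) research in clinical populations has mostly
compared *average* amplitudes between groups, treating the trial-to-trial
spread of a person's single-trial scores as noise. That spread —
intraindividual (within-person) variability — is itself a candidate marker
of unstable information processing, and theories of psychosis predict it
should be elevated in patients. Testing that prediction needs a model in
which each person's residual variability is a first-class quantity, not a
nuisance constant.

`trialvar` implements the full analysis chain for this question: a
synthetic-data generator with the exact trial-level structure the model
assumes, single-trial scoring of epoched waveforms, a Bayesian mixed-effects
location-scale model (MELSM), a predictive-accuracy manipulation check,
registered credible-interval decision rules, and generalizability-theory
reliability summaries.

## The model

For trial $j$ of participant $i$, the single-trial amplitude (in microvolts)
is modelled as

$$y_{ij} \sim \mathrm{Normal}\!\left(\mu_{ij},\ \sigma_{ij}^2\right), \qquad
\mu_{ij} = x_{ij}'\beta + z_{ij}' u_i, \qquad
\log \sigma_{ij} = w_{ij}'\eta + z_{ij}' v_i ,$$

with treatment-coded fixed effects for event type, diagnostic group and
their interaction on both portions ($x_{ij} = w_{ij}$ in the default
design; a continuous, standardized symptom covariate can replace the group
factor in exploratory models). The random effects — location intercept and
event slope $u_i$, scale intercept and event slope $v_i$ — are jointly
multivariate normal with SD vector $\tau$ and correlation matrix $\Omega$:
$(u_i, v_i) \sim \mathrm{MVN}(0, \mathrm{diag}(\tau)\,\Omega\,\mathrm{diag}(\tau))$.

The scale portion is the scientific payload. A coefficient $\eta_k$ on the
log-SD scale back-transforms to a percent change in within-person SD,
$100(e^{\eta_k}-1)$, so $\eta = -0.02$ reads "about 2% less variable". The
reference level ("never-psychotic" group, first-listed event) defines the
intercepts; every other coefficient is a deviation from it.

The *location-only* model used by the manipulation check is the same model
with a constant residual SD (`scale = ~1`, no scale random effects) — the
ordinary multilevel model.

## Priors and their defaults

* location fixed effects: Normal(0, 10) in microvolts — vague relative to
  single-trial ERP scores, which rarely exceed tens of microvolts;
* scale fixed effects: Normal(0, 1) on the log-SD scale — a one-unit log-SD
  change is almost a tripling of variability, so this is weakly
  informative while keeping the sampler away from absurd scales;
* random-effect SDs: half-Student-t(3, 2.5) — the usual heavy-tailed
  weakly-informative choice that admits both near-zero and large components;
* random-effect correlations: LKJ with concentration 1 (uniform over
  correlation matrices). All are configurable via `melsm_priors()`.

The interval type everywhere is the equal-tailed 95% credible interval and
the point estimate is the posterior median; equal-tailed percentiles were
chosen over highest-density intervals because they are exactly reproducible
from order statistics.

## Posterior computation

Sampling uses an adaptive Markov chain Monte Carlo scheme written for this
model's structure:

* $\beta$ and the location random effects $u_i$ have Gaussian full
  conditionals given the scale portion and are updated by exact Gibbs
  steps;
* $\eta$ uses a joint random-walk Metropolis step whose proposal
  covariance is adapted from the warmup history; the scale random effects
  $v_i$ use vectorized per-participant random-walk updates whose proposal
  SD is scaled per column by the current $\tau$, so small variance
  components still mix;
* $\tau$ and the correlation angles are updated element-wise on the
  multivariate-normal level (cheap, repeated twice per iteration), with
  $\Omega$ parameterized through the spherical Cholesky angles and the
  LKJ prior imposed through a numerically computed Jacobian;
* two classes of *exact auxiliary moves* remove the posterior correlations
  that make naive samplers crawl on hierarchical models: likelihood-invariant
  "translation" Gibbs updates that trade an intercept-like fixed effect
  against the mean of its random-effect column, and interweaved rescaling
  moves for each $\tau_k$ that pass through the non-centered
  parameterization (the multivariate-normal and proposal-Jacobian terms
  cancel, leaving only the data likelihood and the $\tau$ prior). The
  interweaving strategy achieves what a non-centered parameterization
  would, while keeping the conjugate location updates that a non-centered
  model would forfeit.

Adaptation (Robbins–Monro step-size tuning and proposal-covariance
estimation) runs during warmup only, so the post-warmup chain is a fixed
Markov kernel. Convergence is assessed by rank-normalized split R-hat and
bulk effective sample size on every reported parameter; fits flag
themselves with a warning when any parameter has R-hat > 1.01 or bulk
ESS < 400. Fits are exactly reproducible given `seed`. Random-effect
correlations are the slowest-mixing parameters in small samples (they are
weakly identified there); production analyses should use longer chains
than the package's test settings.

The fit stores a thinned pointwise log-likelihood matrix (default 1000
draws x observations) for cross-validation, running posterior means of
$\mu_{ij}$ and $\sigma_{ij}$ for residuals and predictions, and a thinned
set of joint random-effect draws for posterior-predictive simulation.

## Manipulation check

Pareto-smoothed importance-sampling leave-one-out cross-validation
(PSIS-LOO) is implemented from first principles: importance ratios
$1/p(y_n \mid \theta_s)$; the largest $M = \min(0.2S, 3\sqrt{S})$ weights
replaced by expected order statistics of a generalized Pareto distribution
fitted to the exceedances with the Zhang–Stephens profile-posterior
estimator (shape regularized toward 0.5 with prior weight 10); smoothed
weights truncated at the raw maximum and self-normalized. Observations
with tail shape $\hat k > 0.7$ are flagged unreliable. The decision rule
is the registered one: a model fits better only when the elpd difference
exceeds 4 **and** twice its paired standard error; otherwise the fits are
comparable. Degenerate tails (constant weights, too few tail points) skip
smoothing and report $\hat k = 0$, which is treated as reliable.

## Decision rules

`decide_hypothesis()` applies the registered rules per component. For the
components predicted to show higher patient variability, support requires
the group parameter on the scale portion to exclude zero with patients
higher, and/or the event-by-group parameter to exclude zero with patients
higher for one event and comparable for the other. A scale contrast that
excludes zero only in the "patients less variable" direction yields the
explicit verdict `opposite-direction`. For the reward positivity the
prediction is a null: support requires both CrIs to *contain* zero.

## The synthetic-data generator

`simulate_trial_table()` draws from exactly the generative process the
model assumes, so parameter recovery is a meaningful end-to-end check. Its
defaults are the duration-deviant mismatch-negativity study conditions:
location effects (1.63, -2.61, 0.02, 0.46) microvolts, scale effects
(2.49, 0.01, 0.04, -0.02) log-SD units (within-person SD
$e^{2.49} \approx 12$ microvolts at the reference cell — single-trial EEG
is noisy), random-effect SDs 1.34/1.39 microvolts (mean structure) and
0.27/0.02 (variance structure), zero random-effect correlations (none are
reported for the original fits; correlations are configurable), 100
participants per group, 40 trials per condition. Trial dropout is i.i.d.
Bernoulli with rate 0.10 — a typical artifact-rejection loss; real
rejection is structured (bursts of bad trials, participant-specific
rates), but independent deletion is enough to exercise unbalanced cells.
One trial per cell is always retained so tables remain valid.

What the generator does **not** emulate: multichannel data, ocular
artifacts, autocorrelated trial sequences, non-Gaussian residuals,
paired deviant/standard trials. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to their violation.

`simulate_epochs()` wraps each generated amplitude in a toy waveform
(baseline level + component bump + white noise) so the scoring stage —
200-ms baseline adjustment, half-open time-window mean amplitude,
collapsed-localizer window selection, the 5-trials-per-condition inclusion
rule — can be tested round-trip.

## Scoring conventions

Windows are half-open `[start, end)` on the sample grid, avoiding
double-counting of shared endpoints and making scores bit-reproducible.
The collapsed localizer grand-averages the condition-difference wave with
equal weight per participant (pooling groups), picks the extremum of the
requested polarity, breaks ties toward the earliest latency, and returns a
window of plus/minus 25 ms (both published mismatch-negativity windows are
50 ms wide) snapped to the grid. Whether the original localizer weighted
participants or trials equally is not stated; equal participant weighting
was chosen for order-independence.

## Reliability

Dependability is the generalizability-theory reliability of an average of
$n$ trials, $\sigma^2_p / (\sigma^2_p + \sigma^2_e/n)$, with variance
components from a one-way random-effects decomposition per group and
event. Estimation is restricted maximum likelihood (with a
method-of-moments fallback using the unbalanced-design correction);
negative components truncate to zero with a warning. The default
dependability threshold is 0.70, a conventional acceptability floor —
configurable. The standardized measurement error of a cell is the trial SD
over the square root of the trial count. Difference-score reliability is
approximated from the two cells' components under independence, because
trials are unpaired across events in this design.

## Problem sizes used by the test suite

The package's own test suite runs every check end to end but at reduced
sizes chosen to keep a full run within ordinary test runtimes: the
manipulation-check suite uses 40 participants x 30 trials per condition
(one heteroscedastic run; ten homoscedastic replicates), parameter
recovery uses 12 replicates of 40 participants per group x 25 trials, and
the small-effect power suite uses 12 replicates of 100 participants per
group x 5 trials. At 12 replicates the Monte-Carlo error of the *location*
bias estimate is comparable to the bias band itself (person-level means
are noisy when the mean-structure random-effect SDs are 1.3-1.4
microvolts), so the location-bias check adds three Monte-Carlo standard
errors to the band; the scale-portion bias — the quantity of scientific
interest — is checked against the plain band. Larger replicate counts
tighten these checks without changing the machinery.

## Known limitations

* The sampler is a random-walk/Gibbs hybrid: robust and dependency-free,
  but less efficient than gradient-based samplers on large models; budget
  longer chains for full-size analyses (the defaults suit hundreds of
  participants and tens of trials).
* Random-effect correlations mix slowly when variance components are near
  zero; their posteriors are honest but need more iterations than fixed
  effects.
* The exact priors and interval conventions of the original analysis are
  not public; the defaults here are standard weakly-informative practice
  and are configurable.
* No frequentist MELSM, autoregressive trial effects, or non-Gaussian
  likelihoods; vendor EEG formats are out of scope (CSV trial tables and
  the toy epoch format are the supported I/O).
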