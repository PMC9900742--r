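---
title: "Adaptive Bayesian assessment of lower-limb position sense: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Bayesian assessment of lower-limb position sense: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(propsi)
library(dplyr)
```

propsi implements a standing, whole-limb assessment of static position
sense. A participant stands on a dual-belt treadmill with vision and
hearing of the legs occluded; the left (test) foot is passively moved to a
stimulus position while the right foot stays put, and the participant
answers a two-alternative forced choice: *"Do you feel your right or left
foot is more forward?"*. The stimulus variable is the foot-position
difference in millimetres (left minus right ankle marker along the
walking axis; positive = left foot forward). This vignette explains the
model, the adaptive algorithm, the protocol simulation, and the Bayesian
agreement suite, together with the numerical and design choices a user
should know about.

## The psychometric model

The probability of judging the left foot as more forward at stimulus $s$
is modelled as a cumulative Gaussian

$$\psi(s) = \Phi\!\left(\frac{s - \alpha}{\beta}\right),$$

with two parameters, both in millimetres:

* $\alpha$ — the **point of subjective equality (PSE)**: the
  foot-position difference the participant perceives as "feet aligned"
  ($\psi(\alpha) = 0.5$). Healthy adults typically show a positive bias
  around 10–15 mm.
* $\beta$ — the **uncertainty**: the SD of the cdf, inversely related to
  its slope; it reflects noise in the proprioceptive estimate and is
  typically just under 20 mm.

No lapse or guess parameters are included in the assessment model:
pilot observations show responses at $\pm 100$ mm are essentially
deterministic. The simulated [`observer()`] nevertheless accepts optional
lapse/guess rates (clamping $\psi$ to $[\text{guess}, 1-\text{lapse}]$)
so robustness studies remain possible; their defaults of 0 reproduce the
assessment model exactly.

```{r}
plot_psychometric(psychometric_params(12, 18))
```

## The Psi algorithm

The Psi procedure maintains a joint posterior $p(\alpha, \beta)$ over a
discrete grid and, before each trial, asks which of the 21 candidate
stimulus positions ($-100$ to $+100$ mm in 10 mm steps) is expected to
shrink that posterior's Shannon entropy the most. For each candidate $s$
and each possible response $r$, the one-step-ahead posterior
$p(\alpha,\beta \mid s, r)$ and its entropy $H(s, r)$ are computed, and
the expected entropy
$E[H_s] = \sum_r H(s, r)\, p(r \mid s)$ is minimised over $s$; the
predictive probability $p(r \mid s)$ is the posterior-weighted average of
the per-cell response probabilities (the marginal-likelihood normaliser
of Bayes' rule). After the response, the posterior is updated by
product-and-normalise with likelihoods read from precomputed lookup
tables ($\psi$ for "left", $1-\psi$ for "right"), and the posterior of
trial $t$ becomes the prior of trial $t+1$. Point estimates are the means
of the two marginal posteriors.

Priors are wide, maximum-entropy-style choices evaluated on the grid:
$\alpha \sim \mathcal N(0, 20\,\text{mm})$ (no prior bias) and
$\beta \sim \text{Exponential}(\text{mean } 20\,\text{mm})$. Because the
$\beta$ prior is discretized and truncated at the grid boundary, its
discrete mean sits slightly below 20 mm; the gap shrinks with grid
refinement and is irrelevant after a handful of trials.

Numerical choices:

* **Grid.** Default $\alpha$: $-100\ldots100$ mm in 1 mm steps (the PSE
  grid must span the stimulus range); default $\beta$: $1\ldots60$ mm in
  0.5 mm steps (generously above observed human values of ~18 mm). Both
  are configurable. The simulation studies in the test-suite and the
  acceptance script use a 2 mm / 1 mm grid for the cohort-scale studies —
  its recovery error is statistically indistinguishable from the fine
  grid's — and the fine default grid for the recovery study itself; the
  vignette states these sizes as the package's own study choices.
* **Entropy convention.** $0\log 0 = 0$ everywhere, so sharply peaked
  posteriors never produce NaN.
* **Tie-breaking.** Expected entropies tie exactly under symmetric
  posteriors (mirror stimulus pairs). Ties within a $10^{-12}$ relative
  tolerance are broken deterministically: smallest $|s|$ first, then the
  negative member. Determinism is required for exact session replay.
* **Entropy kernel.** The per-trial scan over 21 stimuli × grid cells is
  implemented in C++; grid cells carrying less than $10^{-18}$ posterior
  mass are skipped, which perturbs expected entropies by $<10^{-13}$
  bits — below the tie tolerance.
* **Degenerate updates.** A response whose marginal likelihood is zero on
  the grid raises an explicit error rather than silently renormalising
  NaNs.

```{r}
state <- psi_new(psi_grid(alpha = seq(-60, 60, 2), beta = seq(2, 40, 1)))
obs <- observer(alpha = 12, beta = 18, seed = 8)
for (t in 1:40) {
  s <- select_next_stimulus(state)
  state <- psi_update(state, s, simulate_response(obs, s))
}
psi_estimate(state)
```

## The testing protocol

`run_session()` reproduces the full 75-trial test around the Psi core:

* **Movement directions.** The test foot starts in front of the stimulus
  (then moves backward to it) on exactly 38 trials and behind it on 37,
  in pseudorandom order, so direction-linked response biases wash out.
* **Start positions** (mm) are drawn from $\mathcal N(+100, 5)$ for
  in-front starts and $\mathcal N(-100, 5)$ for behind starts, redrawing
  from the same distribution until the start lies on the correct side of
  the stimulus.
* **Speeds.** Travel to the start at Uniform(40, 50) mm/s and to the
  stimulus at Uniform(10, 30) mm/s, plus a logged Uniform(0, 2) s pause,
  remove duration cues.
* **Engagement stimuli.** One *far* stimulus (uniform over ±90/±100 mm)
  per complete 10-trial block and one *near* stimulus (current PSE
  estimate ± 10/20/30 mm, snapped to the stimulus set) per complete
  5-trial block keep the task from dwelling at maximally ambiguous
  positions; none may occur in the first 5 trials. When the far and near
  draws collide, the far insertion wins and the near slot is redrawn
  within its block — this preserves the "once per 10 trials" guarantee of
  the rarer class. Responses on preselected trials update the posterior
  like any other data; there is no principled reason to discard ~30% of
  the trials. Near-stimulus snapping rounds midpoints away from zero and
  clamps to the stimulus range.
* **Breaks** after trials 25 and 50 are logged metadata; the posterior
  depends only on the stimulus/response history, so a break provably
  cannot alter it (the replay test asserts this).
* **Baseline correction.** Hardware logs are imported after subtracting
  the residual ankle-marker baseline difference rounded to the nearest
  millimetre; the package operates in corrected coordinates throughout,
  including the running PSE used for near stimuli.
* **Block reading.** "Once every $N$ trials" is read as fixed consecutive
  blocks (1–10, 11–20, …) restricted to complete blocks, giving 7 far and
  (excluding the warmup-blocked first block) 14 near insertions per
  75-trial session.

Every source of randomness is an explicit stream: the protocol stream is
seeded from the session config and the observer's responses from its own
seed, so a (config seed, observer seed) pair determines the session byte
for byte, and replaying a logged session through `replay_session()`
reproduces every running estimate exactly.

```{r}
cfg <- session_config(grid = psi_grid(seq(-60, 60, 4), seq(4, 34, 2)),
                      n_trials = 25, seed = 3)
sess <- run_session(cfg, observer(12, 18, seed = 4))
glance(sess)
```

## What the simulated data do and do not show

The synthetic cohort generator draws true PSEs from
$\mathcal N(12, 15)$ mm and true uncertainties from a positive-truncated
$\mathcal N(18.2, 5)$ mm — population means matching healthy adults on
this assessment, with SDs wide enough to span the plausible range — and
runs two complete simulated sessions per participant. Between-test
variability then arises from the Psi procedure's own estimation noise
(plus optional truth jitter and injected mean/proportional biases for
calibration studies). A faster estimate-level generator
(`simulate_estimates()`) skips the sessions and adds per-test Gaussian
estimation noise whose defaults (6.8 mm PSE, 3.9 mm uncertainty) are
back-computed from the limits of agreement observed with human cohorts.

Simulated observers are stationary cumulative-Gaussian responders. Real
participants drift, fatigue, occasionally lapse, and may weight
directional cues; none of that is emulated. Passing recovery and
calibration tests therefore demonstrates that the *algorithmic pipeline*
is correct and well calibrated under the model's own assumptions — not
that human test-retest agreement will match the simulated rates.

The package's recovery study (200 pure Psi sessions, true
$\alpha \in [-40, 40]$, $\beta \in [10, 30]$) finds median absolute
errors of roughly 2–2.5 mm for both parameters after 75 trials,
with $\alpha$ bias within ±2 mm and errors shrinking monotonically from
trial 25 to 50 to 75. This ~2 mm floor is not a grid artefact: the
Fisher information of 75 Bernoulli responses bounds the attainable
standard error near $\beta/\sqrt{0.64 \times 75} \approx 2.3$ mm at
$\beta \approx 20$, so refining the 1 mm / 0.5 mm grid cannot push the
median error below it.

## The agreement suite

Two administrations of the test yield per-participant (Test 1, Test 2)
pairs for both measures. The suite mirrors a Bayesian re-casting of the
Bland-Altman workflow:

* **Limits of agreement** — closed form,
  $\overline{d} \pm 1.96\, \mathrm{SD}(d)$ with $d = $ Test1 − Test2.
* **Mean bias** — $d_i \sim \mathcal N(\mu, \sigma)$; posterior of $\mu$
  with ROPE ±5 mm.
* **Bias across true scores** — regression of $d_i$ on the
  per-participant mean of the two tests; ROPEs ±0.1 (slope) and ±5 mm
  (intercept).
* **Test-retest regression** — Test 2 on Test 1; perfect agreement is
  slope 1, intercept 0.
* **ICC(2,1)** — two-way random-effects, absolute-agreement,
  single-measure ICC from the ANOVA decomposition with the conventional
  F-based CI.

Posteriors are summarised by the mean, the 95% highest-density interval
(narrowest contiguous window containing 95% of the draws — for
multimodal posteriors this is wider than the union of HPD regions, a
documented limitation), and the percentage of draws inside the ROPE.
The **good-agreement decision rule** declares agreement unless at least
90% of the mass of any Bland-Altman posterior falls outside its ROPE,
i.e. unless some posterior is decisive evidence of bias; posteriors that
merely straddle a ROPE do not count against agreement.

Design choices that were genuinely open:

* The normal-mean and regression models have 2–3 parameters, so instead
  of MCMC they are sampled *exactly* under the reference prior
  $p(\theta, \sigma^2) \propto 1/\sigma^2$ (scaled-inverse-$\chi^2$ /
  normal conjugate draws). This is the wide-prior limit of the
  maximum-entropy priors used elsewhere, is seed-deterministic, and makes
  the mean-bias posterior mean converge to the sample mean difference by
  construction. Degenerate inputs (zero-variance differences, constant
  predictors) collapse to flagged point masses instead of failing.
* The movement-direction model is hierarchically structured
  (per-participant intercepts and per-direction coefficients as indexing
  variables, stimulus in mm as a continuous covariate) and genuinely
  needs MCMC; it is fitted with JAGS behind a sampler-config contract
  (10,000 draws × 4 chains, 2,000 tuning by default; per-chain seeds
  derived from the sampler seed). Intercept-scale terms get
  $\mathcal N(0, 1.5)$ priors — weakly informative on the logit scale,
  and regularising the additive aliasing between participant and
  direction intercepts, which leaves the backward-minus-forward
  *contrast* identified. The contrast is reported on the coefficient
  scale with ROPE ±0.5 (consistent with the magnitudes this analysis
  produces), alongside a secondary probability-scale contrast evaluated
  for an average participant at the mean delivered stimulus. Split-chain
  $\hat R$ and effective sample size are attached to every fit and warn
  rather than fail.

```{r}
est <- simulate_estimates(cohort_spec(seed = 42))
ba <- bland_altman(est, "pse", sampler_config(4000, 2, seed = 1))
tidy(ba)
good_agreement(ba)
icc_2_1(est, "pse")
```

## Known limitations

* Only the sagittal-plane, two-response task is modelled; non-Gaussian
  psychometric forms and lapse-aware adaptive variants are out of scope.
* The HDI is constrained to a single contiguous interval.
* The ICC confidence interval uses the classical F construction; small
  samples (n = 13) make it wide, as expected.
* Simulation studies in the tests and acceptance script are sized to
  run comfortably on one CPU (e.g. 100–200 recovery sessions, 12–50
  calibration cohorts, reduced MCMC draw counts); all sizes are stated
  where they are used and scale up by changing one argument.
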