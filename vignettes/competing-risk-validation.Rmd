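---
title: "Validating time-to-event risk models when competing events occur"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r}
library(crvalidate)
```

## The problem

A prognostic model predicts the risk that a patient experiences some event —
say kidney failure in advanced chronic kidney disease — within a fixed
horizon. External validation asks how well those predictions hold up in a new
cohort. When a *competing event* (death without kidney failure) can preclude
the event of interest, the validation itself must decide which risk it is
checking:

* **the hypothetical (net) risk**, "assuming nobody can die first", which is
  what a conventional Cox-type analysis that censors competing events
  estimates; or
* **the absolute (real-world) risk**, in which a patient who dies first can
  never experience the event, estimated by the cumulative incidence function
  (CIF, the Aalen–Johansen estimator).

`crvalidate` computes every calibration and discrimination measure in both
arms so the contrast is explicit: the "naive" arm censors competing events
(Kaplan–Meier observed probabilities, Harrell's C, Cox-based D statistic),
the "competing-risk" arm accounts for them (Aalen–Johansen observed
probabilities, Wolbers-adapted or IPCW C, Fine–Gray-based D statistic).

## Nonparametric estimands

With distinct event times $t_1 < t_2 < \dots$, $n_j$ at risk and $d_{kj}$
cause-$k$ events at $t_j$:

* Kaplan–Meier: $\hat S(t) = \prod_{t_j \le t} (1 - d_j / n_j)$ with
  Greenwood variance;
* Aalen–Johansen: $\hat F_k(t) = \sum_{t_j \le t} \hat S(t_j^-)\, d_{kj} /
  n_j$, with a one-pass delta-method (Aalen-type) pointwise variance;
* censoring survival $\hat G(t)$: the same product-limit construction with
  the roles of events and censorings reversed, used for inverse-censoring
  weights.

$\hat F_1 + \hat F_2 + \hat S = 1$ holds at every grid point by construction
and is asserted to $10^{-12}$ in the tests; $1 - \hat S_{\text{cause-1 KM}}
\ge \hat F_1$ pointwise, with equality exactly when no competing events
precede cause-1 events. Confidence intervals for probabilities use the
complementary log(–log) transform so bounds stay inside $[0, 1]$; the
literature reports intervals without naming a method, and this choice is a
package default, not a claim of equivalence.

Tie and boundary conventions (the data sources are silent on all of them):

* at tied times, events are processed before censorings — this affects both
  the ordinary at-risk counts and the left limits $\hat G(T^-)$;
* an event exactly at the horizon counts as within the horizon (closed
  interval, matching "within 2 or 5 years");
* beyond the last observed time every curve is extrapolated as constant, and
  asking for an estimate past the maximum follow-up raises a warning rather
  than an error, because a 5-year horizon against, say, 6.5 years of maximum
  follow-up is routine while truly extrapolated requests deserve scrutiny.

## Calibration

**Calibration-in-the-large.** The average predicted risk $E$ is compared with
the observed probability $O$ at the horizon; `oe_ratio()` reports $O/E$ with
a log-scale Wald interval built from the standard error of $O$ alone,
treating $E$ as fixed (it is a known average of given predictions). A seeded
nonparametric bootstrap (`boot = 500`) is available where the Wald
approximation is in doubt.

**Grouped calibration.** `calibration_groups()` splits the cohort into
`n_groups = 10` groups (deciles are the convention in this literature) by
*rank* of predicted risk with stable ordering, so group sizes differ by at
most one even when many predictions tie exactly.

**Smoothed curves via pseudo-values.** Each subject receives a jackknife
pseudo-observation of the CIF at the horizon,
$PV_i = n\hat F_1(\tau) - (n-1)\hat F_1^{(-i)}(\tau)$.
With no censoring $PV_i$ is exactly the subject's event indicator; under
censoring pseudo-values spread the estimator's information over all subjects
and may legitimately fall outside $[0,1]$, so the smoothed curve is never
clamped. Two implementations coexist deliberately: a naive jackknife that
refits the estimator $n$ times (default up to $n = 2000$) and a one-pass
algorithm that updates the product-limit prefix sums in $O(n + \#\text{times})$
(default above). They are required to agree to $10^{-10}$ in the tests; the
redundancy is a correctness gate for the algebraically intricate fast path.

The smoother is local-linear regression (`KernSmooth::locpoly`) with a
direct plug-in bandwidth (`KernSmooth::dpill`), evaluated on 100 equally
spaced points across the observed predicted-risk range, with a
normal-reference fallback bandwidth when the plug-in pilot fails. No source
we follow names a smoother or bandwidth; any reasonable scatterplot smoother
is interchangeable here, which is why the choice is isolated behind
`calibration_curve()`.

## Discrimination

`harrell_c()` scores all pairs where the smaller follow-up time belongs to an
event; ties in predicted risk credit 0.5; tied event times between two
events are not examinable (the standard convention). Competing events enter
three ways:

* `wolbers_c(..., "infinity")` keeps competing-event subjects in the risk set
  forever ("they will never experience the event"); infinity is a flag, not
  a sentinel value, so no arithmetic ever sees `Inf`. Appropriate when
  follow-up is complete apart from administrative censoring.
* `wolbers_c(..., "censoring_complete")` instead censors them at the
  administrative censoring date they would have had — the right variant when
  every censoring is administrative, and therefore the report default
  whenever the cohort carries `admin_censor_time`.
* `ipcw_c()` truncates at the horizon and reweights each examinable pair by
  $1/\hat G(T_i^-)^2$, the inverse censoring survival at the left limit of
  the anchor's event time for both pair members. Several published weighting
  schemes exist; this one is fixed and documented rather than guessed per
  dataset, and with no random censoring it reduces exactly to the truncated
  Wolbers estimate.

Direction of the naive-vs-competing contrast: retaining competing-event
subjects adds pairs anchored by cause-1 events. When high predicted risk
*also* predicts early competing death, the added pairs are mostly discordant
and the competing-risk C drops below Harrell's C; when competing deaths
concentrate among low-risk subjects the added pairs are mostly concordant
and the adjustment can raise C. The package makes no directional promise —
the tests construct both regimes.

Confidence intervals for C use a seeded nonparametric bootstrap
(percentile, `boot = 500` suggested). The suite checks coverage with a
scaled-down design — 60 replicates of $n = 600$ with 200 bootstrap
resamples against the concordance of a 30,000-subject cohort from the same
generator, gate at 88% — sized so the whole suite stays fast; the estimator
itself is unchanged by these sizes.

## Prognostic separation: D and $R^2_D$

The model's linear predictors are ranked, turned into Blom normal scores
$\Phi^{-1}\{(r_i - 3/8)/(n + 1/4)\}$, divided by $\kappa = \sqrt{8/\pi}$, and
entered as the single covariate of a new regression on the validation data;
the fitted coefficient is the D statistic — interpretable as the log hazard
ratio between the upper and lower prognostic halves. Blom's offsets are one
standard choice for "ranked and scaled"; any monotone transform of the
linear predictor (including using the predicted risks themselves when no
linear predictor is supplied) leaves the ranks, hence D, unchanged.
Explained variation is
$R^2_D = (D^2/\kappa^2) / (\pi^2/6 + D^2/\kappa^2)$,
strictly increasing in $|D|$ and bounded in $[0, 1)$.

The regressions are fitted by self-contained single-covariate engines:

* `cox_fit()`: Newton–Raphson on the Cox partial likelihood, Breslow tie
  handling, starting at 0 with step-halving, converged when the step or the
  score drops below $10^{-10}$; monotone-likelihood separation and
  zero-information covariates raise errors rather than wandering off.
* `fine_gray_fit()`: the weighted partial likelihood of the subdistribution
  hazard. Subjects with competing events stay in the risk set after their
  event with weight $\hat G(t^-)/\hat G(T_i^-)$; all risk-set sums reduce to
  prefix/suffix cumulative sums, so each iteration is $O(n \log n)$. With no
  random censoring all weights are 1 and the fit coincides with `cox_fit()`
  on data where competing-event subjects are kept event-free forever (a
  tested identity at $10^{-8}$). The reported standard error is the
  model-based one from the observed information; because the weights make it
  approximate, `d_statistic(boot = ...)` offers a seeded bootstrap
  alternative.

Breslow tie handling is sufficient (rather than Efron/exact) because the
D-statistic covariate is tie-free after rankit scaling; the engines are
single-covariate by design — the package validates existing models and never
re-develops them.

## Synthetic cohorts

Two generators exist because no single mechanism tests everything cleanly:

* `simulate_cause_specific()` draws latent times from exponential
  cause-specific hazards $\lambda_k e^{\beta_k x}$, so the true CIF is
  available in closed form (`true_cif_cause_specific()`). Attaching that
  true CIF as each subject's predicted risk yields a *perfectly calibrated
  model by construction* — the anchor for every end-to-end calibration test:
  the competing-risk arm must find $O/E \approx 1$ while the naive arm
  overshoots whenever $\lambda_2 > 0$. A `risk = "net"` option instead
  attaches $1 - \exp(-\lambda_1 e^{\beta_1 x} t)$, the quantity a
  competing-events-censored development pipeline would (mis)label an
  absolute risk. `risk_scale` emulates a uniformly over-predicting model.
* `simulate_fine_gray()` draws cause-1 times by inverting
  $F_1(t;x) = 1 - [1 - p(1 - e^{-t})]^{\exp(\beta x)}$, so the
  subdistribution coefficient $\beta$ is the directly recoverable truth for
  the Fine–Gray engine.

`emulate_registry()` shapes the cause-specific generator like a nephrology
referral registry: ~13,500 patients entering uniformly over a 6.5-year
accrual window with a single administrative cutoff (so censoring is purely
administrative and `admin_censor_time` is known for everyone); covariates
age (74 ± 11, truncated 18–95), sex, eGFR (19 ± 5.5, truncated 8–30) and
log-albuminuria; kidney-failure hazard decreasing in age and eGFR, death
hazard dominated by age; and lognormal frailties (SD 1.4 and 1.2) carrying
the unmeasured heterogeneity without which exponential hazards cannot
produce the fast-then-flattening incidence a referral cohort shows. The two
baseline hazards were calibrated once by coarse search so the marginal
cumulative incidences land near 13%/20% (cause 1, 2/5 years) and 16%/25%
(cause 2), with the 70+ subgroup near 12%/33% at 5 years, and then frozen.
Predicted risks are each subject's true *net* risk, so the emulation
reproduces the characteristic finding: a naive validation that looks
excellent while the competing-risk arm reveals over-prediction that grows
with horizon and age. The emulation targets only the structure the metrics
need — it does not attempt realistic joint covariate distributions, secular
trends, loss to follow-up, or measurement error, so passing tests on it says
nothing about those aspects of real registry data.

No published risk-equation coefficients ship with the package: a risk
equation of the usual form $1 - S_0(\tau)^{\exp(lp)}$ is supplied through
`risk_config()` / `read_risk_config()`, keeping transcription of published
formulae an explicit, auditable user step.

## Numerical and design notes

* Event coding is fixed internally to 0/1/2; `as_cohort(event_codes = ...)`
  maps arbitrary labels onto it.
* Validation rejects offending rows with their row numbers and never drops
  or imputes anything; handling missing predictors is explicitly out of
  scope.
* Times are continuous; exact ties are preserved and resolved by each
  estimator's convention, never perturbed.
* `oe_stat()` requires $E > 0$; $\hat G = 0$ while weights are still needed
  raises an error that suggests truncating earlier.
* Test and simulation sizes (e.g. $n = 20{,}000$ for end-to-end calibration,
  $n = 5{,}000$ for coefficient recovery, 10,000 random instances for the
  pair-enumeration oracle, the scaled bootstrap coverage design above) are
  the package's own trade-off between Monte-Carlo resolution and a suite
  that runs in about a minute.

## Known limitations

The IPCW censoring model is marginal only — no covariate-dependent
censoring. The regression engines are single-covariate on purpose.
Calibration slope, integrated calibration index, time-dependent AUC and net
benefit are out of scope. Pseudo-value smoothing assumes completely random
censoring for its exactness guarantees; under covariate-dependent censoring
the curves are approximations.
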