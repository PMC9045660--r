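# barrettjm

Dynamic, personalized risk estimation for Barrett's esophagus (BE)
surveillance.

Patients with BE are followed by periodic endoscopy; current practice
shortens the surveillance interval based only on the *last* histology
call, even though low-grade dysplasia (LGD) and the
immunohistochemical markers p53 and SOX2 flip between endoscopies.
`barrettjm` implements the longitudinal alternative: the full marker
trajectories of each patient are modelled and linked to the hazard of
high-grade dysplasia / esophageal adenocarcinoma (HGD/EAC) in a
Bayesian multivariate joint model, so the progression risk over a
future window can be re-estimated at every new endoscopy from the
whole history.

## The model

Each dichotomized marker `k` (LGD, p53, SOX2) follows a random-intercept
logistic submodel on time, standardized age, gender, BE length (>= 3 cm)
and esophagitis:

    logit pi_ik(t) = beta_k' x_i(t) + b_ik,   (b_i1, b_i2, b_i3) ~ N3(0, D)

and the HGD/EAC hazard loads on each marker's current aberrancy
probability (*value* association) and its running integral
(*accumulated effect*), on top of a piecewise-constant baseline and the
same covariates, with delayed entry at the 0.5-year run-in:

    h_i(t) = exp( log lambda(t) + gamma' w_i(t)
                  + sum_k [ alpha_v_k pi_ik(t) + alpha_c_k Int_0^t pi_ik(s) ds ] )

Marker hazard ratios are reported per 10% change in the aberrancy
probability, `HR = exp(0.1 alpha)`. Fitting is by adaptive
Metropolis-within-Gibbs (split R-hat / ESS diagnostics, deterministic
under a seed). Individualized prediction conditions a new patient's
random intercepts on their observed history and survival to the
landmark, and returns `P(T <= t + 3 | T > t, history)` with a credible
interval. Internal validation computes landmark window AUCs (years
1–6, 3-year window) with Harrell bootstrap optimism correction and a
static baseline-marker Cox comparator. A synthetic surveillance-cohort
generator with known ground truth (631 patients, ~8% progressors,
outcome-dependent staining design) makes every stage testable without
patient data.

## Worked example

```r
library(barrettjm)

truth  <- default_truth(n_patients = 300)          # known ground truth
sim    <- simulate_cohort(truth, seed = 42)
cohort <- apply_ihc_sampling_design(sim$cohort, mode = "study", seed = 43)
flt    <- apply_eligibility_filters(cohort)        # 6-month run-in etc.
cohort <- standardize_age(flt$cohort)
cohort
#> Barrett's surveillance cohort: 290 patients, 2337 visits, 21 events
#>   age standardized against mean 59.94, sd 10.85

inc <- compute_incidence(cohort)
sprintf("%.1f per 100 person-years (95%% CI %.1f-%.1f)", inc$rate, inc$lower, inc$upper)
#> "1.0 per 100 person-years (95% CI 0.6-1.6)"

fit_mixed_logistic(cohort, "p53")                  # Table-2-style submodel
#> Random-intercept logistic fit for p53 (408 obs, 290 patients)
#>     covariate   or lower upper
#>          time 1.17  1.04  1.32
#>       age_std 3.01  1.60  5.65
#>        female 0.16  0.04  0.69
#>  long_segment 2.46  0.71  8.53
#>   esophagitis 0.37  0.08  1.77
#> random-intercept sd 2.262, logLik -183.00
```

Ten simulated patients progressed before 0.5 years and were excluded;
the crude incidence and the p53 odds ratios (odds of an aberrant call
rising ~17%/year, higher with age, lower in women) come out at the
plausible orders of magnitude for this setting. Dynamic prediction for
a patient whose p53 turns aberrant at year 1 and SOX2 at year 2 (here
scored at known parameters via `as_joint_fit`; after a real
`fit_joint_model()` the same call averages over the posterior):

```r
pat <- patient_history(64, 0, data.frame(
  time_years = c(0, 1, 2), lgd = c(0, 0, 0), p53 = c(0, 1, 1),
  sox2 = c(0, 0, 1), esophagitis = 0, long_segment = 1))
pf <- as_joint_fit(truth$longitudinal, truth$survival,
                   age_scaler = cohort$age_scaler, n_draws = 200)
risk_trajectory(pat, pf, landmarks = c(1, 2, 3), horizon = 3, seed = 7)
#>   landmark horizon       risk       lower     upper n_draws
#> 1        1       3 0.02270962 0.005704311 0.1154875     500
#> 2        2       3 0.07155995 0.010297641 0.3078076     500
#> 3        3       3 0.08874988 0.010954915 0.3943407     500
```

The 3-year risk rises from 2.3% to 8.9% as the aberrant p53 and SOX2
findings accrue — the per-endoscopy updating that fixed-interval
surveillance ignores.

## The analysis workflow

The `analysis/` scripts run the full pipeline at study scale and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # 631-patient cohort + ground truth
Rscript analysis/02_longitudinal.R      # three marker submodels, OR table
Rscript analysis/03_fit_joint.R [--fast]# joint model, per-10% HR table
Rscript analysis/04_predict.R           # example risk trajectories
Rscript analysis/05_validate.R [--fast] # landmark AUC table, optimism-corrected
```

Stages 3 and 5 are MCMC-heavy at full scale (about an hour each);
`--fast` gives a reduced-settings pass in minutes.

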