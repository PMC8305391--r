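# trajclass

Latent-class stratification of long-term functional recovery after
pediatric acquired brain injury (ABI), and single-subject prediction of
the recovery trajectory from first-discharge data.

Rehabilitation cohorts are heterogeneous: patients with similar
admission status follow very different seven-year courses of the
(Wee)FIM functional score. `trajclass` is for biostatisticians and
rehabilitation researchers who want to (i) cluster bounded functional
trajectories under heavy, informative attrition, (ii) validate the
cluster solution, and (iii) predict the long-term trajectory type of a
new patient at the moment of first discharge.

## The model

For subject $i$ with baseline covariates $x_i$, scores $y_{ij}$ at times
$t_{ij}$ (years since admission) and an exit record, the K-class joint
latent-class growth model combines three equations:

$$\Pr(c_i = k \mid x_i) = \frac{e^{\gamma_k^\top x_i}}{\sum_l e^{\gamma_l^\top x_i}}, \qquad
y_{ij} \mid c_i = k \sim N\!\big(\beta_k^\top (1, t_{ij}, t_{ij}^2),\ \sigma^2\big),$$

plus a class-specific discrete-time exit hazard $h_{kj}$ over the seven
follow-up intervals (survival terms for completed intervals, an event
term when the subject exits for death/recovery/opt-out). Missing visits
are skipped — never imputed — and informative dropout contributes to
classification through the hazard. Estimation is multi-start EM;
classes are relabeled by ascending year-7 endpoint so class 1 is always
the non-responder reference; K is chosen by BIC together with the
per-class posterior-sharpness diagnostic. The workflow adds split-half
likelihood-ratio stability tests, cross-design (held-out) class labels,
and a ridge-penalized multinomial logistic classifier evaluated with a
two-half, k-consecutive-fold scheme. A synthetic-cohort generator with
ground-truth labels makes the whole pipeline testable offline.

## Worked example

```r
library(trajclass)

sim <- generate_cohort(generator_config(seed = 42))  # 600 subjects
cohort <- sim$cohort
cohort
#> <abi_cohort> 600 subjects, 3043 functional assessments
#> exit reasons: in_service=109 death=17 recovery=105 opt_out=185 censored=184

fit <- fit_lcgmm(cohort, lcgmm_config(n_classes = 4, seed = 7, n_starts = 10))
fit
#> <lcgmm_fit> K=4 classes, N=600, loglik=-10899.25, BIC=22252.7 (converged in 15 iterations)
#> class sizes (posterior-max): 228/114/168/90
#> marginal probabilities: 0.378 0.197 0.275 0.150
```

The four classes are the canonical archetypes — non-responders, slow,
low-start fast and high-start fast responders; the marginal
probabilities recover the generating 35/22/28/15 mixture. Their mean
trajectories (clamped to the 18–126 scale for display):

```r
round(predicted_trajectories(fit, times = c(0, 1, 3, 7)), 1)
#>   time class1 class2 class3 class4
#> 1    0   20.0   24.9   30.1   89.6
#> 2    1   23.2   45.1   63.6  103.3
#> 3    3   27.5   73.8  108.4  121.3
#> 4    7   28.2   84.4  109.2  118.9
```

Held-out class labels and discharge-based prediction:

```r
cfg <- lcgmm_config(n_classes = 4, seed = 7, n_starts = 5)
labels <- cross_design_labels(cohort, 4, cfg, seed = 11)  # every label from a model that never saw the subject
preds <- nested_cv_predict(build_features(cohort),
                           setNames(labels$label, labels$subject_id),
                           cv_plan(k = 5, seed = 3), n_classes = 4)
evaluate_predictions(preds$true, preds$pred, preds[, paste0("p_class", 1:4)], 4)
#> <eval_report> 4 classes, n=600: accuracy=0.878 precision=0.872 kappa=0.830
#> per-class AUC: 0.985 0.912 0.979 1.000
#> share of errors between neighboring classes: 1.00
```

Out-of-fold accuracy 0.88 against the held-out cluster labels, with the
slow responders hardest to separate (AUC 0.91) and *every*
misclassification falling between neighboring trajectory types. Class
characteristics reproduce the clinical pattern — fast responders had
shorter comas and, for the high-start class, shorter stays:

```r
class_characteristics(fit, cohort)
#> <class_characteristics>
#> sizes: class1=228 class2=114 class3=168 class4=90
#> strongest membership effects (vs class 1):
#>  contrast covariate estimate    se     z        p
#>    class3 coma_days   -2.381 0.287 -8.30 1.02e-16
#>    class4 coma_days   -8.334 1.066 -7.82 5.32e-15
#>    class4  los_days   -1.968 0.309 -6.38 1.78e-10
#>    ...
```

`run_pipeline(pipeline_config(...))` chains all stages — simulate/read,
covariate screening, BIC scan, stability tests, cross-design labels,
class characteristics, prediction — deterministically under one master
seed and writes a JSON/CSV/text report bundle.

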