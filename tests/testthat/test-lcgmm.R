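# the brute-force likelihood oracle lives in helper-oracles.R; the config
# below matches its fixed membership covariates (coma_days, epilepsy)
oracle_config <- function(K) {
  lcgmm_config(n_classes = K, membership_covariates = c("coma_days",
                                                        "epilepsy"),
               standardize_covariates = FALSE, seed = 1, n_starts = 2)
}

hand_params <- function(K, degree = 2) {
  lcgmm_params(
    gamma = matrix(seq(-0.4, 0.4, length.out = (K - 1) * 3), K - 1, 3),
    beta = matrix(c(20, 3, -0.2, 35, 12, -1, 60, 20, -2)[1:((degree + 1) *
                                                              K)],
                  K, degree + 1, byrow = TRUE),
    sigma = 5,
    hazard = matrix(seq(0.05, 0.3, length.out = K * 7), K, 7))
}

# --- unit behaviour -------------------------------------------------------

test_that("the time basis maps the visit grid to years since admission", {
  expect_equal(time_basis("admission", 112, 2), c(1, 0, 0))
  expect_equal(time_basis("Y2", 500, 2), c(1, 2, 4))
  expect_equal(time_basis("discharge", 365, 1), c(1, 365 / 365.25))
  expect_equal(time_basis("Y7", 10, 3), c(1, 7, 49, 343))
  expect_error(time_basis("Y9", 10, 2), "unknown timepoint")
})

test_that("membership probabilities are a reference-class softmax", {
  expect_equal(membership_probs(matrix(0, 3, 1), 1), rep(0.25, 4))
  p <- membership_probs(matrix(1, 1, 1), 1)
  expect_equal(p, c(1, exp(1)) / (1 + exp(1)), tolerance = 1e-6)
  expect_equal(p[2], 0.73106, tolerance = 1e-4)
  # saturation
  p3 <- membership_probs(matrix(c(50, 0), 2, 1), 1)
  expect_equal(p3, c(0, 1, 0), tolerance = 1e-12)
  expect_error(membership_probs(matrix(0, 1, 2), 1),
               "dimension mismatch")
})

test_that("subject-level joint log-likelihood assembles the three parts", {
  # one observation at the class mean, sigma 1, no follow-up intervals
  ll <- subject_class_loglik(y = 20, timepoints = "admission",
                             last_timepoint = "discharge",
                             reason = "censored",
                             beta_k = c(20, 0, 0), sigma = 1,
                             hazard_k = rep(0.1, 7), los_days = 100)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)

  # censored after Y2 adds two survival terms
  ll2 <- subject_class_loglik(y = 20, timepoints = "admission",
                              last_timepoint = "Y2", reason = "censored",
                              beta_k = c(20, 0, 0), sigma = 1,
                              hazard_k = rep(0.1, 7), los_days = 100)
  expect_equal(ll2 - ll, 2 * log(0.9), tolerance = 1e-12)

  # opting out in the first interval adds log(h_1)
  ll3 <- subject_class_loglik(y = 20, timepoints = "admission",
                              last_timepoint = "discharge",
                              reason = "opt_out",
                              beta_k = c(20, 0, 0), sigma = 1,
                              hazard_k = rep(0.5, 7), los_days = 100)
  expect_equal(ll3, -0.5 * log(2 * pi) + log(0.5), tolerance = 1e-12)
})

test_that("mixture log-likelihood matches the brute-force oracle", {
  cohort <- toy_cohort_small()
  for (K in 2:3) {
    params <- hand_params(K)
    cfg <- oracle_config(K)
    expect_equal(mixture_loglik(cohort, params, cfg),
                 brute_force_mixture_loglik(cohort, params, cfg),
                 tolerance = 1e-10)
  }
  # and on a larger random cohort with 5 subjects
  sim <- generate_cohort(generator_config(n_subjects = 5, seed = 3))
  params <- hand_params(3)
  cfg <- oracle_config(3)
  expect_equal(mixture_loglik(sim$cohort, params, cfg),
               brute_force_mixture_loglik(sim$cohort, params, cfg),
               tolerance = 1e-10)
})

test_that("a two-component mixture of identical densities collapses", {
  cohort <- toy_cohort_small()
  cfg <- oracle_config(2)
  p2 <- lcgmm_params(gamma = matrix(0, 1, 3),
                     beta = matrix(c(20, 3, -0.2), 2, 3, byrow = TRUE),
                     sigma = 5, hazard = matrix(0.1, 2, 7))
  cfg1 <- oracle_config(1)
  p1 <- lcgmm_params(gamma = matrix(0, 0, 3),
                     beta = matrix(c(20, 3, -0.2), 1, 3), sigma = 5,
                     hazard = matrix(0.1, 1, 7))
  expect_equal(mixture_loglik(cohort, p2, cfg),
               mixture_loglik(cohort, p1, cfg1), tolerance = 1e-12)
})

test_that("the E-step is Bayes' rule", {
  cohort <- toy_cohort_small()
  cfg <- oracle_config(2)
  # identical components: posterior equals the membership prior
  p_same <- lcgmm_params(gamma = matrix(c(0.3, -0.01, 0.2), 1, 3),
                         beta = matrix(c(20, 3, -0.2), 2, 3,
                                       byrow = TRUE),
                         sigma = 5, hazard = matrix(0.1, 2, 7))
  post <- e_step(cohort, p_same, cfg)
  design <- trajclass:::build_design(cohort, cfg)
  prior <- membership_probs(p_same$gamma, design$Xcov)
  expect_equal(unname(post[, ]), unname(prior), tolerance = 1e-12)
  expect_equal(rowSums(post), setNames(rep(1, 3), rownames(post)),
               tolerance = 1e-9)

  # hand Bayes computation for distinct components
  params <- hand_params(2)
  post2 <- e_step(cohort, params, cfg)
  for (i in 1:3) {
    id <- subject_ids(cohort)[i]
    sub <- cohort$series[cohort$series$subject_id == id, ]
    ex <- cohort$exits[cohort$exits$subject_id == id, ]
    cov <- cohort$covariates[cohort$covariates$subject_id == id, ]
    lik <- sapply(1:2, function(k) {
      exp(subject_class_loglik(sub$total, sub$timepoint,
                               ex$last_timepoint, ex$reason,
                               params$beta[k, ], params$sigma,
                               params$hazard[k, ], cov$los_days))
    })
    pri <- membership_probs(params$gamma,
                            c(1, cov$coma_days, cov$epilepsy))
    expect_equal(unname(post2[id, ]), pri * lik / sum(pri * lik),
                 tolerance = 1e-9)
  }

  # a dominating component saturates the posterior
  p_dom <- hand_params(2)
  p_dom$beta[2, ] <- c(120, 0, 0)
  post3 <- e_step(cohort, p_dom, cfg)
  expect_equal(unname(post3[, 1]), rep(1, 3), tolerance = 1e-10)
})

test_that("the M-step solves the weighted subproblems", {
  cohort <- toy_cohort_small()
  cfg1 <- oracle_config(1)
  # all mass on one class reduces to ordinary least squares
  post1 <- matrix(1, 3, 1)
  par1 <- m_step(cohort, post1, cfg1)
  design <- trajclass:::build_design(cohort, cfg1)
  ls <- lm.fit(design$Xtime, design$y)
  expect_equal(unname(par1$beta[1, ]), unname(coef(ls)),
               tolerance = 1e-6)

  # symmetric half-half posterior gives identical class trajectories
  cfg2 <- oracle_config(2)
  post2 <- matrix(0.5, 3, 2)
  par2 <- m_step(cohort, post2, cfg2)
  expect_equal(par2$beta[1, ], par2$beta[2, ], tolerance = 1e-8)
  expect_equal(par2$hazard[1, ], par2$hazard[2, ], tolerance = 1e-12)

  # hazard estimates are weighted occurrence/exposure ratios:
  # S1 opts out in interval 3, S2 dies in interval 2, S3 censored at Y2
  h <- unname(par2$hazard[1, ])
  expect_equal(h[1], 1e-6)     # 3 at risk, no exits: clipped floor
  expect_equal(h[2], 1 / 3, tolerance = 1e-9)   # S2 exits, 3 at risk
  expect_equal(h[3], 1 - 1e-6)  # S1 exits as the only subject at risk
  expect_equal(h[4:7], rep(1e-6, 4))            # nobody at risk

  # noiseless single-class data pins beta and floors sigma
  flat <- new_cohort(
    toy_covariate_row("F1"),
    rbind(toy_series_row("F1", "admission", 30),
          toy_series_row("F1", "discharge", 30),
          toy_series_row("F1", "Y1", 30)),
    data.frame(subject_id = "F1", last_timepoint = "Y1",
               reason = "censored"))
  parf <- m_step(flat, matrix(1, 1, 1), cfg1)
  expect_equal(unname(parf$beta[1, ]), c(30, 0, 0), tolerance = 1e-4)
  expect_equal(parf$sigma, 1e-3)
})

test_that("degenerate classes are reported by index", {
  cohort <- toy_cohort_small()
  post <- cbind(rep(1, 3), rep(0, 3))
  expect_error(m_step(cohort, post, oracle_config(2)),
               "degenerate class 2")
})

test_that("EM is monotone and deterministic, and labels recover a
           well-separated noiseless design", {
  cfg_gen <- two_class_config(n = 80, seed = 21, sigma_obs = 0)
  sim <- generate_cohort(cfg_gen)
  cfg <- lcgmm_config(n_classes = 2, seed = 5, n_starts = 4)
  fit <- fit_lcgmm(sim$cohort, cfg)

  # monotone likelihood trace in every non-failed start
  for (tr in fit$diagnostics$traces) {
    if (!is.null(tr)) expect_true(all(diff(tr) >= -1e-8))
  }
  # exact label recovery in the noiseless limit
  lab <- max.col(fit$posterior, ties.method = "first")
  expect_equal(lab, sim$truth$labels$true_class)

  # refitting bit-identically
  fit2 <- fit_lcgmm(sim$cohort, cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$posterior, fit2$posterior)
})

test_that("posterior rows sum to one and BIC follows its definition", {
  fit <- default_fit_k4()
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
  expect_equal(sum(fit$marginal_probs), 1, tolerance = 1e-9)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(600))
  expect_equal(fit$n_params, 3 * 10 + 4 * 3 + 1 + 4 * 7)
})

test_that("the model is invariant under class-label permutation", {
  cohort <- toy_cohort_small()
  cfg <- oracle_config(3)
  params <- hand_params(3)
  # permute classes and re-reference gamma accordingly
  perm <- c(3, 1, 2)
  gfull <- rbind(0, params$gamma)[perm, ]
  gfull <- sweep(gfull, 2, gfull[1, ])
  params_p <- lcgmm_params(gamma = gfull[-1, ],
                           beta = params$beta[perm, ],
                           sigma = params$sigma,
                           hazard = params$hazard[perm, ])
  expect_equal(mixture_loglik(cohort, params_p, cfg),
               mixture_loglik(cohort, params, cfg), tolerance = 1e-12)
  expect_equal(unname(e_step(cohort, params_p, cfg)[, ]),
               unname(e_step(cohort, params, cfg)[, perm]),
               tolerance = 1e-10)
})

test_that("canonical ordering sorts classes by the year-7 endpoint", {
  fit <- default_fit_k4()
  endpoint <- fit$params$beta %*% c(1, 7, 49)
  expect_true(all(diff(endpoint) > 0))
})

test_that("assigning the training cohort reproduces the fitted posterior", {
  sim <- generate_cohort(two_class_config(n = 60, seed = 31))
  fit <- fit_lcgmm(sim$cohort, lcgmm_config(n_classes = 2, seed = 5,
                                            n_starts = 3))
  asg <- assign_classes(fit, sim$cohort)
  expect_equal(asg$posterior, fit$posterior, tolerance = 1e-9)
  # a held-out cohort from the same process is labelled accurately
  sim2 <- generate_cohort(two_class_config(n = 60, seed = 32))
  asg2 <- assign_classes(fit, sim2$cohort)
  expect_gte(mean(asg2$label == sim2$truth$labels$true_class), 0.9)
})

test_that("parameters of the generating process are recovered", {
  # interior (non-saturating) classes: trajectory anchors within 5 points;
  # mixing proportions within 0.05; membership coefficient signs correct
  ok_signs <- 0
  for (s in 1:3) {
    sim <- generate_cohort(generator_config(n_subjects = 600, seed = s))
    fit <- fit_lcgmm(sim$cohort, lcgmm_config(n_classes = 4, seed = 7,
                                              n_starts = 6))
    realized <- tabulate(sim$truth$labels$true_class, 4) / 600
    expect_true(all(abs(fit$marginal_probs - realized) < 0.05))
    for (k in 1:4) {
      est <- fit$params$beta[k, ] %*% rbind(1, c(0, 1, 7),
                                            c(0, 1, 49))
      truth <- sim$truth$config$anchors[k, ]
      expect_true(all(abs(est - truth) < 5))
    }
    g <- fit$params$gamma
    age_eff <- g[, "age_at_event"] + g[, "age_at_admission"]
    signs_ok <- all(g[c("class3", "class4"), "coma_days"] < 0) &&
      all(g[c("class3", "class4"), "anoxic"] < 0) &&
      g["class2", "epilepsy"] < 0 && all(age_eff[c(2, 3)] > 0)
    ok_signs <- ok_signs + signs_ok
  }
  expect_gte(ok_signs, 2)
})

test_that("the BIC scan tabulates fits and the posterior diagnostic", {
  sim <- generate_cohort(two_class_config(n = 120, seed = 13))
  scan <- bic_scan(sim$cohort, 2:3,
                   lcgmm_config(n_classes = 2, seed = 5, n_starts = 3))
  expect_equal(scan$table$K, 2:3)
  expect_true(all(diff(scan$table$n_params) > 0))
  expect_equal(scan$table$bic,
               -2 * scan$table$loglik + scan$table$n_params * log(120))
  expect_true(all(scan$table$min_class_post <= 1))
  # the generating two-class structure wins
  expect_equal(scan$table$K[which.min(scan$table$bic)], 2L)
})

test_that("reported trajectories clamp to the scale only for display", {
  fit <- default_fit_k4()
  tr <- predicted_trajectories(fit, times = 0:7)
  expect_true(all(as.matrix(tr[, -1]) >= 18 &
                    as.matrix(tr[, -1]) <= 126))
  raw <- predicted_trajectories(fit, times = 0:7, clamp = FALSE)
  expect_true(any(as.matrix(raw[, -1]) > 126))  # the fast classes overshoot
})
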