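test_that("class draws follow the mixing proportions", {
  sim <- default_sim()
  counts <- tabulate(sim$truth$labels$true_class, 4L)
  expect_equal(sum(counts), 600L)
  probs <- c(0.35, 0.22, 0.28, 0.15)
  for (k in 1:4) {
    sd_k <- sqrt(600 * probs[k] * (1 - probs[k]))
    expect_lt(abs(counts[k] - 600 * probs[k]), 4 * sd_k)
  }
})

test_that("generated scores satisfy every scale invariant exactly", {
  ser <- default_sim()$cohort$series
  expect_true(all(ser$total >= 18 & ser$total <= 126))
  expect_true(all(ser$selfcare >= 8 & ser$selfcare <= 56))
  expect_true(all(ser$mobility >= 5 & ser$mobility <= 35))
  expect_true(all(ser$cognition >= 5 & ser$cognition <= 35))
  expect_true(all(ser$total == ser$selfcare + ser$mobility +
                    ser$cognition))
})

test_that("the noiseless single-class limit reproduces the polynomial", {
  cfg <- generator_config(
    n_subjects = 20, class_probs = 1, class_names = "non_responder",
    anchors = rbind(non_responder = c(18, 22, 28)), sigma_obs = 0,
    age_mean = 70, coma_mean = 60, los_mean = 160,
    epilepsy_prob = 0.35, anoxic_prob = 0.45, other_prob = 0.2,
    dcn_prob = 0.55,
    hazard = matrix(0, 1, 7),
    reason_probs = matrix(c(0.1, 0.02, 0.43, 0.45), 1),
    visit_skip_prob = 0, seed = 4)
  sim <- generate_cohort(cfg)
  beta <- anchors_to_beta(c(18, 22, 28))
  ser <- sim$cohort$series
  los <- sim$cohort$covariates$los_days[match(ser$subject_id,
                                              sim$cohort$covariates$subject_id)]
  yr <- as.numeric(ifelse(grepl("^Y", ser$timepoint),
                          sub("Y", "", ser$timepoint), NA))
  t <- ifelse(ser$timepoint == "admission", 0,
              ifelse(ser$timepoint == "discharge", los / 365.25, yr))
  mu <- beta[1] + beta[2] * t + beta[3] * t^2
  expect_identical(ser$total,
                   as.integer(round(pmin(126, pmax(18, mu)))))
  # no dropout: everyone observed through Y7
  expect_true(all(sim$cohort$exits$last_timepoint == "Y7"))
})

test_that("certain exit at year one truncates every series", {
  cfg <- two_class_config(n = 30, seed = 9)
  cfg$hazard[] <- 1
  sim <- generate_cohort(cfg)
  expect_true(all(sim$cohort$exits$last_timepoint == "discharge"))
  expect_true(all(sim$cohort$series$timepoint %in%
                    c("admission", "discharge")))
})

test_that("generation is deterministic per seed and differs across seeds", {
  a <- generate_cohort(generator_config(n_subjects = 50, seed = 8))
  b <- generate_cohort(generator_config(n_subjects = 50, seed = 8))
  c <- generate_cohort(generator_config(n_subjects = 50, seed = 9))
  expect_identical(a$cohort$series, b$cohort$series)
  expect_identical(a$cohort$covariates, b$cohort$covariates)
  expect_false(identical(a$cohort$series, c$cohort$series))
})

test_that("attrition is monotone apart from interior visit skips", {
  sim <- default_sim()
  ser <- sim$cohort$series
  ex <- sim$cohort$exits
  last_idx <- match(ex$last_timepoint,
                    c("admission", "discharge", paste0("Y", 1:7)))
  names(last_idx) <- ex$subject_id
  obs_idx <- match(ser$timepoint,
                   c("admission", "discharge", paste0("Y", 1:7)))
  # no observation beyond the declared last attended visit
  expect_true(all(obs_idx <= last_idx[ser$subject_id]))
  # the set of subjects observed at the final attended year shrinks over time
  at_year <- sapply(1:7, function(j) sum(last_idx - 2L >= j))
  expect_true(all(diff(at_year) <= 0))
})

test_that("class-conditional covariates reproduce the clinical sign pattern", {
  sim <- default_sim()
  cls <- sim$truth$labels$true_class
  cov <- sim$cohort$covariates
  mean_by <- function(v, k) mean(v[cls == k])
  # fast responders (classes 3, 4) are older than non-responders (class 1)
  expect_gt(mean_by(cov$age_at_event_months, 3),
            mean_by(cov$age_at_event_months, 1))
  expect_gt(mean_by(cov$age_at_event_months, 4),
            mean_by(cov$age_at_event_months, 1))
  # and suffered shorter coma
  expect_lt(mean_by(cov$coma_days, 3), mean_by(cov$coma_days, 1))
  expect_lt(mean_by(cov$coma_days, 4), mean_by(cov$coma_days, 1))
  # high-start fast responders have shorter stays
  expect_lt(mean_by(cov$los_days, 4), mean_by(cov$los_days, 1))
  # slow responders show less epilepsy
  expect_lt(mean_by(cov$epilepsy, 2), mean_by(cov$epilepsy, 1))
  # responders are less often anoxic
  anox <- as.integer(cov$etiology == "anoxic")
  expect_lt(mean_by(anox, 3), mean_by(anox, 1))
  expect_lt(mean_by(anox, 4), mean_by(anox, 1))
})

test_that("cohort summary matches hand computation on a small cohort", {
  s <- summarize_cohort(toy_cohort_small())
  adm <- s[s$timepoint == "admission", ]
  # totals at admission: 18, 20, 40
  expect_equal(adm$total_median, 20)
  expect_equal(adm$total_q1, 19)
  expect_equal(adm$total_q3, 30)
  expect_equal(adm$n_missing, 0L)
  y1 <- s[s$timepoint == "Y1", ]
  expect_equal(y1$n_observed, 2L)  # S3 skipped Y1
  y2 <- s[s$timepoint == "Y2", ]
  expect_equal(y2$deaths, 1L)      # S2 died after Y1
  y7 <- s[s$timepoint == "Y7", ]
  expect_equal(y7$opt_out, 1L)
  expect_equal(y7$censored, 1L)
})

test_that("cumulative missingness never decreases over the follow-ups", {
  s <- summarize_cohort(default_sim()$cohort)
  miss <- s$n_missing[s$timepoint %in% paste0("Y", 1:7)]
  expect_true(all(diff(miss) >= 0))
})

test_that("degenerate generator configurations are rejected", {
  expect_error(generator_config(sigma_obs = -1), "sigma_obs")
  expect_error(generator_config(class_probs = c(0.5, 0.5, 0, 0)),
               "empty class")
  expect_error(generator_config(class_probs = c(0.6, 0.2, 0.1, 0.2)),
               "sum to 1")
  expect_error(generator_config(hazard = matrix(2, 4, 7)),
               "hazards")
})

test_that("a YAML document reproduces an explicit configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 25",
               "class_probs: [0.5, 0.5]",
               "class_names: [non_responder, slow]",
               "anchors:", "  - [18, 22, 28]", "  - [25, 45, 85]",
               "sigma_obs: 3",
               "age_mean: [70, 95]", "coma_mean: [60, 35]",
               "los_mean: [160, 140]",
               "epilepsy_prob: [0.35, 0.16]",
               "anoxic_prob: [0.45, 0.25]", "other_prob: [0.2, 0.2]",
               "dcn_prob: [0.55, 0.5]",
               "hazard:",
               "  - [0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1]",
               "  - [0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2]",
               "reason_probs:",
               "  - [0.1, 0.02, 0.43, 0.45]",
               "  - [0.02, 0.08, 0.55, 0.35]",
               "seed: 12"), path)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_subjects, 25L)
  expect_equal(cfg$sigma_obs, 3)
  sim <- generate_cohort(cfg)
  expect_equal(n_subjects(sim$cohort), 25L)
})
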