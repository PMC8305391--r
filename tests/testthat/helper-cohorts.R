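# hand-built fixtures and lazily cached expensive fits shared across files

toy_covariate_row <- function(id, age = 60, coma = 10, los = 100,
                              delay = 40, etiology = "traumatic",
                              gender = "M", dcn = 0, epilepsy = 0) {
  data.frame(subject_id = id, gender = gender, age_at_event_months = age,
             etiology = etiology, age_at_admission_months = age + 2,
             los_days = los, coma_days = coma,
             event_to_discharge_days = delay + los, dcn = dcn,
             epilepsy = epilepsy, stringsAsFactors = FALSE)
}

# series row with a consistent domain split (selfcare soaks the remainder)
toy_series_row <- function(id, timepoint, total) {
  mobility <- min(35L, max(5L, as.integer(round((total - 18) * 30 / 108)) + 5L))
  cognition <- min(35L, max(5L, as.integer(round((total - 18) * 30 / 108)) + 5L))
  selfcare <- total - mobility - cognition
  data.frame(subject_id = id, timepoint = timepoint,
             total = as.integer(total), selfcare = as.integer(selfcare),
             mobility = mobility, cognition = cognition,
             stringsAsFactors = FALSE)
}

# two subjects, all nine timepoints observed, one improver one flat
toy_cohort_full <- function() {
  tps <- c("admission", "discharge", paste0("Y", 1:7))
  ser <- rbind(
    do.call(rbind, lapply(seq_along(tps), function(i) {
      toy_series_row("A01", tps[i], 20 + 10 * (i - 1))
    })),
    do.call(rbind, lapply(tps, function(tp) toy_series_row("B02", tp, 19)))
  )
  cov <- rbind(toy_covariate_row("A01", age = 120, coma = 3),
               toy_covariate_row("B02", age = 40, coma = 90,
                                 etiology = "anoxic", epilepsy = 1))
  ex <- data.frame(subject_id = c("A01", "B02"),
                   last_timepoint = "Y7", reason = "in_service",
                   stringsAsFactors = FALSE)
  new_cohort(cov, ser, ex)
}

# three subjects with attrition and an intermittent gap
toy_cohort_small <- function() {
  ser <- rbind(
    toy_series_row("S1", "admission", 20),
    toy_series_row("S1", "discharge", 30),
    toy_series_row("S1", "Y1", 50),
    toy_series_row("S1", "Y2", 70),
    toy_series_row("S2", "admission", 18),
    toy_series_row("S2", "discharge", 19),
    toy_series_row("S2", "Y1", 20),
    toy_series_row("S3", "admission", 40),
    toy_series_row("S3", "discharge", 60),
    toy_series_row("S3", "Y2", 90)   # Y1 skipped, still in service later
  )
  cov <- rbind(toy_covariate_row("S1", los = 120),
               toy_covariate_row("S2", coma = 60, los = 150),
               toy_covariate_row("S3", age = 100, los = 90))
  ex <- data.frame(subject_id = c("S1", "S2", "S3"),
                   last_timepoint = c("Y2", "Y1", "Y2"),
                   reason = c("opt_out", "death", "censored"),
                   stringsAsFactors = FALSE)
  new_cohort(cov, ser, ex)
}

# two-class generating condition: non-responders + slow responders
two_class_config <- function(n = 300L, seed = 1L, sigma_obs = 6) {
  generator_config(
    n_subjects = n,
    class_probs = c(0.5, 0.5),
    class_names = c("non_responder", "slow"),
    anchors = rbind(non_responder = c(18, 22, 28), slow = c(25, 45, 85)),
    sigma_obs = sigma_obs,
    age_mean = c(70, 95), coma_mean = c(60, 35), los_mean = c(160, 140),
    epilepsy_prob = c(0.35, 0.16), anoxic_prob = c(0.45, 0.25),
    other_prob = c(0.20, 0.20), dcn_prob = c(0.55, 0.50),
    hazard = outer(c(0.8, 1.0), c(0.15, 0.19, 0.21, 0.22, 0.24, 0.27,
                                  0.28)),
    reason_probs = rbind(c(0.10, 0.02, 0.43, 0.45),
                         c(0.02, 0.08, 0.55, 0.35)),
    seed = seed)
}

# shared expensive artifacts, computed at most once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_sim <- function() cached("default_sim", {
  generate_cohort(generator_config(seed = 42))
})

default_fit_k4 <- function() cached("fit_k4", {
  fit_lcgmm(default_sim()$cohort,
            lcgmm_config(n_classes = 4, seed = 7, n_starts = 10))
})

default_fit_k2 <- function() cached("fit_k2", {
  fit_lcgmm(default_sim()$cohort,
            lcgmm_config(n_classes = 2, seed = 7, n_starts = 10))
})

default_crossfit <- function() cached("crossfit", {
  cross_design_labels(default_sim()$cohort, 4,
                      lcgmm_config(n_classes = 4, seed = 7, n_starts = 5),
                      seed = 11)
})

default_predictions <- function() cached("predictions", {
  lab <- default_crossfit()
  feats <- build_features(default_sim()$cohort)
  nested_cv_predict(feats, setNames(lab$label, lab$subject_id),
                    cv_plan(k = 5, seed = 3), n_classes = 4)
})
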