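#' Configuration of the synthetic-cohort generator
#'
#' Defines a four-class (by default) population of functional-recovery
#' trajectories. Classes are stored in canonical order of ascending
#' year-7 endpoint: non-responders, slow responders, low-start fast
#' responders, high-start fast responders, with mixing proportions
#' 35/22/28/15 percent. Each class has a quadratic mean trajectory for the
#' total FIM score specified through three anchors (value at admission,
#' year 1, year 7); covariate distributions differ by class (fast
#' responders older with shorter coma, high-start fast with shorter stays,
#' slow responders with less epilepsy, responders less often anoxic); and
#' attrition follows class-specific discrete-time exit hazards with a
#' class-specific mixture of exit reasons.
#'
#' @param n_subjects cohort size (default 600).
#' @param class_probs mixing proportions, canonical class order; must sum
#'   to 1 within 1e-12.
#' @param class_names labels, canonical order.
#' @param anchors K x 3 matrix of total-FIM mean values at admission,
#'   year 1 and year 7; the quadratic trajectory coefficients are derived
#'   from these anchors. The defaults are chosen so that every class
#'   quadratic stays (within a few points) inside the 18-126 scale over
#'   the seven-year window: trajectories that overshoot the ceiling by
#'   tens of points would be pegged at 126 for years, i.e. the generated
#'   data would no longer follow the polynomial-plus-noise model family
#'   the package fits. The two fast-responder endpoints are kept ten
#'   points apart so that the canonical year-7 ordering of estimated
#'   classes is stable under sampling noise.
#' @param sigma_obs residual standard deviation of the observed scores
#'   (FIM points, default 6); 0 gives the noiseless limit.
#' @param age_mean,age_sd class means (canonical order) and common SD of
#'   age at event, months; truncated to 3-215.
#' @param coma_mean class means of days of coma (gamma-distributed).
#' @param coma_shape gamma shape of the coma-day distribution.
#' @param los_mean class means of length of stay, days (gamma, floor 7).
#' @param los_shape gamma shape of the LOS distribution.
#' @param delay_mean,delay_shape event-to-admission delay, days (gamma,
#'   class-independent).
#' @param epilepsy_prob,anoxic_prob,other_prob,dcn_prob per-class
#'   probabilities of in-stay epilepsy, anoxic etiology, other
#'   non-traumatic etiology, acute decompressive craniotomy/neurosurgery.
#' @param male_prob probability of male gender (class-independent).
#' @param hazard K x 7 matrix of per-interval exit probabilities
#'   (interval j = year j-1 to year j of follow-up).
#' @param reason_probs K x 4 matrix of exit-reason probabilities
#'   (death, recovery, opt_out, censored) given an exit.
#' @param visit_skip_prob missing-at-random skip probability for interior
#'   follow-up visits (default 0.05); never removes the last attended
#'   visit, so attrition stays monotone up to these skips.
#' @param seed integer RNG seed.
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(
    n_subjects = 600L,
    class_probs = c(0.35, 0.22, 0.28, 0.15),
    class_names = c("non_responder", "slow", "low_start_fast",
                    "high_start_fast"),
    anchors = rbind(non_responder   = c(18, 22, 28),
                    slow            = c(25, 45, 85),
                    low_start_fast  = c(30, 64, 110),
                    high_start_fast = c(90, 104, 120)),
    sigma_obs = 6,
    age_mean = c(70, 95, 100, 110), age_sd = 50,
    coma_mean = c(60, 35, 18, 6), coma_shape = 1.3,
    los_mean = c(160, 140, 115, 75), los_shape = 4,
    delay_mean = 50, delay_shape = 3,
    epilepsy_prob = c(0.35, 0.16, 0.26, 0.26),
    anoxic_prob = c(0.45, 0.25, 0.15, 0.10),
    other_prob = c(0.20, 0.20, 0.20, 0.20),
    dcn_prob = c(0.55, 0.50, 0.45, 0.40),
    male_prob = 0.61,
    hazard = outer(c(0.8, 1.0, 1.1, 1.3),
                   c(0.15, 0.19, 0.21, 0.22, 0.24, 0.27, 0.28)),
    reason_probs = rbind(c(0.10, 0.02, 0.43, 0.45),
                         c(0.02, 0.08, 0.55, 0.35),
                         c(0.02, 0.40, 0.28, 0.30),
                         c(0.01, 0.55, 0.19, 0.25)),
    visit_skip_prob = 0.05,
    seed = 1L) {
  K <- length(class_probs)
  cfg <- list(n_subjects = as.integer(n_subjects),
              class_probs = class_probs, class_names = class_names,
              anchors = anchors, sigma_obs = sigma_obs,
              age_mean = age_mean, age_sd = age_sd,
              coma_mean = coma_mean, coma_shape = coma_shape,
              los_mean = los_mean, los_shape = los_shape,
              delay_mean = delay_mean, delay_shape = delay_shape,
              epilepsy_prob = epilepsy_prob, anoxic_prob = anoxic_prob,
              other_prob = other_prob, dcn_prob = dcn_prob,
              male_prob = male_prob, hazard = hazard,
              reason_probs = reason_probs,
              visit_skip_prob = visit_skip_prob, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  K <- length(cfg$class_probs)
  if (cfg$n_subjects < 1L) stop("config error: n_subjects must be >= 1",
                                call. = FALSE)
  if (K < 1L) stop("config error: at least one class required",
                   call. = FALSE)
  if (abs(sum(cfg$class_probs) - 1) > 1e-12) {
    stop("config error: class_probs must sum to 1 within 1e-12",
         call. = FALSE)
  }
  if (any(cfg$class_probs <= 0)) {
    stop("config error: empty class in class_probs", call. = FALSE)
  }
  if (cfg$sigma_obs < 0) {
    stop("config error: sigma_obs must be non-negative", call. = FALSE)
  }
  if (!is.matrix(cfg$hazard) || nrow(cfg$hazard) != K ||
      ncol(cfg$hazard) != N_INTERVALS) {
    stop("config error: hazard must be a K x 7 matrix", call. = FALSE)
  }
  if (any(cfg$hazard < 0) || any(cfg$hazard > 1)) {
    stop("config error: hazards must lie in [0, 1]", call. = FALSE)
  }
  per_class_len <- c("class_names", "age_mean", "coma_mean", "los_mean",
                     "epilepsy_prob", "anoxic_prob", "other_prob",
                     "dcn_prob")
  for (f in per_class_len) {
    if (length(cfg[[f]]) != K) {
      stop("config error: ", f, " must have one entry per class",
           call. = FALSE)
    }
  }
  if (!is.matrix(cfg$anchors) || nrow(cfg$anchors) != K ||
      ncol(cfg$anchors) != 3L) {
    stop("config error: anchors must be a K x 3 matrix", call. = FALSE)
  }
  invisible(cfg)
}

#' Quadratic trajectory coefficients from (admission, year-1, year-7) anchors
#'
#' Solves for `(b0, b1, b2)` of `b0 + b1 t + b2 t^2` passing through the
#' three anchor values at t = 0, 1, 7 years.
#'
#' @param anchors length-3 vector or K x 3 matrix of anchor values.
#' @return matrix (or vector) of polynomial coefficients.
#' @export
anchors_to_beta <- function(anchors) {
  if (is.null(dim(anchors))) anchors <- matrix(anchors, nrow = 1L)
  b0 <- anchors[, 1L]
  d1 <- anchors[, 2L] - b0
  d7 <- anchors[, 3L] - b0
  b2 <- (d7 - 7 * d1) / 42
  b1 <- d1 - b2
  out <- cbind(b0 = b0, b1 = b1, b2 = b2)
  rownames(out) <- rownames(anchors)
  out
}

#' Read a generator configuration from a YAML file
#'
#' Flat key/value document mirroring the [generator_config()] arguments;
#' matrix fields (`anchors`, `hazard`, `reason_probs`) are given as lists
#' of per-class rows. Absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `"generator_config"`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("anchors", "hazard", "reason_probs")) {
    if (!is.null(raw[[f]])) raw[[f]] <- do.call(rbind, raw[[f]])
  }
  do.call(generator_config, raw)
}

# split a total score into (selfcare, mobility, cognition) respecting the
# subscale floors (8, 5, 5) and ceilings (56, 35, 35) with an exact sum:
# the excess over the floor is shared proportionally to subscale capacity
# (48, 30, 30) with largest-remainder rounding, ties to the earlier domain
split_total <- function(total) {
  floors <- c(8L, 5L, 5L)
  caps <- c(48L, 30L, 30L)
  t(vapply(total, function(tt) {
    extra <- tt - 18L
    raw <- extra * caps / 108
    fl <- floor(raw)
    rem <- extra - sum(fl)
    if (rem > 0L) {
      give <- order(-(raw - fl), seq_along(raw))[seq_len(rem)]
      fl[give] <- fl[give] + 1L
    }
    as.integer(floors + fl)
  }, integer(3L)))
}

#' Generate a synthetic cohort with ground-truth class labels
#'
#' Draws each subject's latent class from the mixing proportions, baseline
#' covariates from class-conditional distributions, bounded noisy FIM
#' observations around the class quadratic (clamped to 18-126 and rounded,
#' with domain scores splitting the total exactly), and monotone attrition
#' from class-specific discrete-time exit hazards with class-specific exit
#' reasons. Admission and discharge are always observed; interior follow-up
#' visits may additionally be skipped at random.
#'
#' @param config a [generator_config()].
#' @return list with elements `cohort` (an `"abi_cohort"`) and `truth`
#'   (class `"ground_truth"`: data.frame `labels` with `subject_id`,
#'   `true_class`, `class_name`, plus the generating `config`).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  K <- length(config$class_probs)
  beta <- anchors_to_beta(config$anchors)

  ids <- sprintf("S%0*d", max(4L, nchar(n)), seq_len(n))
  cls <- sample.int(K, n, replace = TRUE, prob = config$class_probs)

  age <- round(pmin(215, pmax(3, rnorm(n, config$age_mean[cls],
                                       config$age_sd))))
  coma <- round(rgamma(n, shape = config$coma_shape,
                       scale = config$coma_mean[cls] / config$coma_shape))
  los <- pmax(7, round(rgamma(n, shape = config$los_shape,
                              scale = config$los_mean[cls] /
                                config$los_shape)))
  delay <- pmax(1, round(rgamma(n, shape = config$delay_shape,
                                scale = config$delay_mean /
                                  config$delay_shape)))
  age_adm <- age + round(delay / 30.4375 * 10) / 10
  e2d <- delay + los
  gender <- ifelse(runif(n) < config$male_prob, "M", "F")
  u_et <- runif(n)
  etiology <- ifelse(u_et < config$anoxic_prob[cls], "anoxic",
                     ifelse(u_et < config$anoxic_prob[cls] +
                              config$other_prob[cls],
                            "other_nontraumatic", "traumatic"))
  dcn <- as.integer(runif(n) < config$dcn_prob[cls])
  epilepsy <- as.integer(runif(n) < config$epilepsy_prob[cls])

  covariates <- data.frame(subject_id = ids, gender = gender,
                           age_at_event_months = age, etiology = etiology,
                           age_at_admission_months = age_adm,
                           los_days = as.integer(los),
                           coma_days = as.integer(coma),
                           event_to_discharge_days = as.integer(e2d),
                           dcn = dcn, epilepsy = epilepsy,
                           stringsAsFactors = FALSE)

  # attrition: first interval whose exit draw fires; reason drawn from the
  # class-specific mixture ("censored" yields survival-only likelihood terms)
  u_exit <- matrix(runif(n * N_INTERVALS), n, N_INTERVALS)
  fires <- u_exit < config$hazard[cls, , drop = FALSE]
  exit_interval <- apply(fires, 1L, function(r) {
    w <- which(r)
    if (length(w) > 0L) w[1L] else 0L
  })
  m_completed <- ifelse(exit_interval > 0L, exit_interval - 1L,
                        N_INTERVALS)
  reason <- rep("in_service", n)
  has_exit <- exit_interval > 0L
  if (any(has_exit)) {
    reason[has_exit] <- vapply(which(has_exit), function(i) {
      sample(c("death", "recovery", "opt_out", "censored"), 1L,
             prob = config$reason_probs[cls[i], ])
    }, character(1L))
  }
  last_tp <- TIMEPOINTS[m_completed + 2L]
  exits <- data.frame(subject_id = ids, last_timepoint = last_tp,
                      reason = reason, stringsAsFactors = FALSE)

  # observed visit grid: admission + discharge always; follow-ups up to the
  # last attended year, interior visits skipped at the MAR rate
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    yrs <- seq_len(m_completed[i])
    if (length(yrs) > 1L && config$visit_skip_prob > 0) {
      interior <- yrs[-length(yrs)]
      keep <- runif(length(interior)) >= config$visit_skip_prob
      yrs <- c(interior[keep], yrs[length(yrs)])
    }
    tp <- c("admission", "discharge",
            paste0("Y", yrs, recycle0 = TRUE))
    t_years <- c(0, los[i] / 365.25, yrs)
    mu <- beta[cls[i], 1L] + beta[cls[i], 2L] * t_years +
      beta[cls[i], 3L] * t_years^2
    noise <- if (config$sigma_obs > 0) {
      rnorm(length(mu), 0, config$sigma_obs)
    } else 0
    total <- as.integer(round(pmin(126, pmax(18, mu + noise))))
    rows[[i]] <- data.frame(subject_id = ids[i], timepoint = tp,
                            total = total, stringsAsFactors = FALSE)
  }
  series <- do.call(rbind, rows)
  dom <- split_total(series$total)
  series$selfcare <- dom[, 1L]
  series$mobility <- dom[, 2L]
  series$cognition <- dom[, 3L]

  cohort <- new_cohort(covariates, series, exits)
  truth <- structure(list(labels = data.frame(subject_id = ids,
                                              true_class = cls,
                                              class_name =
                                                config$class_names[cls],
                                              stringsAsFactors = FALSE),
                          config = config),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Per-timepoint descriptive summary of a cohort
#'
#' Median and interquartile range of the total score and each domain at
#' every timepoint, together with cumulative counts of missing assessments
#' and of exits by reason (deaths, recovery, opt-out, censored) up to each
#' follow-up year.
#'
#' @param cohort an `"abi_cohort"`.
#' @return a data.frame with one row per timepoint, class
#'   `"cohort_summary"`.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  n <- n_subjects(cohort)
  ser <- cohort$series
  ex <- cohort$exits
  m_exit <- completed_intervals(ex$last_timepoint)

  rows <- lapply(seq_along(TIMEPOINTS), function(ti) {
    tp <- TIMEPOINTS[ti]
    sub <- ser[ser$timepoint == tp, , drop = FALSE]
    qs <- lapply(names(FIM_BOUNDS), function(d) {
      if (nrow(sub) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      quantile(sub[[d]], c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    })
    names(qs) <- names(FIM_BOUNDS)
    j <- ti - 2L  # follow-up year (0 for admission/discharge)
    exited_by_j <- if (j >= 1L) m_exit < j else rep(FALSE, n)
    data.frame(
      timepoint = tp,
      n_observed = nrow(sub),
      n_missing = if (j >= 1L) n - nrow(sub) else 0L,
      total_median = qs$total[1L], total_q1 = qs$total[2L],
      total_q3 = qs$total[3L],
      selfcare_median = qs$selfcare[1L], selfcare_q1 = qs$selfcare[2L],
      selfcare_q3 = qs$selfcare[3L],
      mobility_median = qs$mobility[1L], mobility_q1 = qs$mobility[2L],
      mobility_q3 = qs$mobility[3L],
      cognition_median = qs$cognition[1L], cognition_q1 = qs$cognition[2L],
      cognition_q3 = qs$cognition[3L],
      deaths = sum(exited_by_j & ex$reason == "death"),
      recovery = sum(exited_by_j & ex$reason == "recovery"),
      opt_out = sum(exited_by_j & ex$reason == "opt_out"),
      censored = sum(exited_by_j & ex$reason == "censored"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}
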