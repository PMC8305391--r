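#' Model configuration for the latent-class trajectory mixture
#'
#' @param n_classes number of latent classes K (2-5 in the intended use;
#'   K = 1 is accepted as a degenerate reference model).
#' @param degree polynomial degree of the class trajectories (default 2:
#'   intercept, tangent at admission, curvature).
#' @param membership_covariates names of baseline covariates entering the
#'   multinomial membership submodel; `"etiology"` expands to the
#'   `anoxic` and `other_nontraumatic` dummies (traumatic reference).
#' @param em_tol relative log-likelihood change declaring EM convergence.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of randomized EM starts.
#' @param seed integer; start s uses seed `seed + s`.
#' @param outcome which score to model: `total` (default) or one domain.
#' @param standardize_covariates z-standardize continuous covariates before
#'   the membership submodel (default TRUE; membership coefficients are
#'   then on the standardized scale).
#' @param class_specific_sigma estimate one residual SD per class instead
#'   of a shared SD (default FALSE).
#' @return an object of class `"lcgmm_config"`.
#' @export
lcgmm_config <- function(n_classes,
                         degree = 2L,
                         membership_covariates = c("gender",
                                                   "age_at_event",
                                                   "etiology",
                                                   "age_at_admission",
                                                   "los_days", "coma_days",
                                                   "dcn", "epilepsy"),
                         em_tol = 1e-6,
                         max_iter = 500L,
                         n_starts = 10L,
                         seed = 1L,
                         outcome = c("total", "selfcare", "mobility",
                                     "cognition"),
                         standardize_covariates = TRUE,
                         class_specific_sigma = FALSE) {
  outcome <- match.arg(outcome)
  if (n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  if (n_starts < 1L) stop("n_starts must be >= 1", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 degree = as.integer(degree),
                 membership_covariates = membership_covariates,
                 em_tol = em_tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 outcome = outcome,
                 standardize_covariates = standardize_covariates,
                 class_specific_sigma = class_specific_sigma),
            class = "lcgmm_config")
}

#' Parameters of the joint latent-class model
#'
#' @param gamma (K-1) x (p+1) matrix of membership log-odds coefficients
#'   against the reference class (class 1), first column the intercept.
#' @param beta K x (degree+1) matrix of trajectory coefficients on the time
#'   basis `(1, t, ..., t^degree)`, t in years since admission.
#' @param sigma residual standard deviation (> 0); length 1 (shared) or K.
#' @param hazard K x 7 matrix of per-interval exit probabilities in (0, 1).
#' @return an object of class `"lcgmm_params"`.
#' @export
lcgmm_params <- function(gamma, beta, sigma, hazard) {
  gamma <- as.matrix(gamma)
  beta <- as.matrix(beta)
  hazard <- as.matrix(hazard)
  K <- nrow(beta)
  if (nrow(gamma) != K - 1L) {
    stop("gamma must have K-1 rows (reference class 1 fixed at zero)",
         call. = FALSE)
  }
  if (!length(sigma) %in% c(1L, K) || any(sigma <= 0)) {
    stop("sigma must be positive, length 1 or K", call. = FALSE)
  }
  if (nrow(hazard) != K || ncol(hazard) != N_INTERVALS ||
      any(hazard <= 0) || any(hazard >= 1)) {
    stop("hazard must be K x 7 with entries in (0, 1)", call. = FALSE)
  }
  structure(list(gamma = gamma, beta = beta, sigma = sigma,
                 hazard = hazard),
            class = "lcgmm_params")
}

#' Time basis of the trajectory submodel
#'
#' Maps a timepoint to the polynomial time basis `(1, t, ..., t^degree)`
#' with t the time since admission in years: admission is t = 0, discharge
#' t = `los_days`/365.25, and follow-up `Yk` is t = k.
#'
#' @param timepoint one of `admission`, `discharge`, `Y1`..`Y7`.
#' @param los_days length of stay in days (used for the discharge time).
#' @param degree polynomial degree.
#' @return numeric vector of length `degree + 1`.
#' @export
time_basis <- function(timepoint, los_days, degree = 2L) {
  t <- timepoint_years(timepoint, los_days)
  t^(0:degree)
}

timepoint_years <- function(timepoint, los_days) {
  idx <- match(timepoint, TIMEPOINTS)
  if (anyNA(idx)) {
    stop("unknown timepoint: ",
         paste(unique(timepoint[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(idx == 1L, 0, ifelse(idx == 2L, los_days / 365.25, idx - 2L))
}

#' Class-membership probabilities from the multinomial submodel
#'
#' Softmax over the linear predictors with the reference class (class 1)
#' fixed at zero.
#'
#' @param gamma (K-1) x (p+1) coefficient matrix.
#' @param x covariate vector of length p+1 including the leading intercept
#'   term, or an N x (p+1) matrix.
#' @return length-K probability vector (or N x K matrix), rows sum to 1.
#' @export
membership_probs <- function(gamma, x) {
  gamma <- as.matrix(gamma)
  if (is.null(dim(x))) {
    if (length(x) != ncol(gamma)) {
      stop("dimension mismatch between gamma and x", call. = FALSE)
    }
    eta <- c(0, gamma %*% x)
    eta <- eta - max(eta)
    p <- exp(eta)
    return(p / sum(p))
  }
  x <- as.matrix(x)
  if (ncol(x) != ncol(gamma)) {
    stop("dimension mismatch between gamma and x", call. = FALSE)
  }
  eta <- cbind(0, x %*% t(gamma))
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Joint log-likelihood of one subject under one class
#'
#' Sum of (a) Gaussian log-densities of the observed scores around the
#' class mean trajectory and (b) the exit-process terms: `log(1 - h_kj)`
#' for every completed follow-up interval up to the last attended
#' timepoint, plus `log(h_kj)` at the exit interval when the exit reason is
#' an event (`death`, `recovery`, `opt_out`); `censored` and `in_service`
#' subjects contribute survival terms only. Missing visits are skipped.
#'
#' @param y observed scores (one per attended timepoint).
#' @param timepoints matching timepoint labels.
#' @param last_timepoint,reason the subject's exit record.
#' @param beta_k trajectory coefficients of the class (length degree+1).
#' @param sigma residual SD of the class.
#' @param hazard_k per-interval exit probabilities of the class (length 7).
#' @param los_days the subject's length of stay, days.
#' @return scalar log-likelihood.
#' @export
subject_class_loglik <- function(y, timepoints, last_timepoint, reason,
                                 beta_k, sigma, hazard_k, los_days) {
  degree <- length(beta_k) - 1L
  t <- timepoint_years(timepoints, los_days)
  mu <- drop(outer(t, 0:degree, `^`) %*% beta_k)
  ll <- sum(dnorm(y, mu, sigma, log = TRUE))
  m <- completed_intervals(last_timepoint)
  if (m > 0L) ll <- ll + sum(log1p(-hazard_k[seq_len(m)]))
  if (reason %in% c("death", "recovery", "opt_out")) {
    ll <- ll + log(hazard_k[m + 1L])
  }
  ll
}

# ---------------------------------------------------------------------------
# internal design: everything the EM engine needs, precomputed once
# ---------------------------------------------------------------------------

CONTINUOUS_COVARIATES <- c("age_at_event", "age_at_admission", "los_days",
                           "coma_days")

expand_membership_covariates <- function(names) {
  out <- unlist(lapply(names, function(nm) {
    if (nm == "etiology") c("anoxic", "other_nontraumatic") else nm
  }))
  unique(out)
}

build_design <- function(cohort, config, center = NULL, scale = NULL) {
  cov <- cohort$covariates
  ids <- cov$subject_id
  enc <- encode_covariates(cov)
  covnames <- expand_membership_covariates(config$membership_covariates)
  missing <- setdiff(covnames, names(enc))
  if (length(missing) > 0L) {
    stop("missing required covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(enc[, covnames, drop = FALSE])
  if (isTRUE(config$standardize_covariates)) {
    cont <- intersect(covnames, CONTINUOUS_COVARIATES)
    if (is.null(center)) {
      center <- setNames(numeric(length(covnames)), covnames)
      scale <- setNames(rep(1, length(covnames)), covnames)
      for (v in cont) {
        center[v] <- mean(X[, v])
        s <- sd(X[, v])
        scale[v] <- if (is.na(s) || s < 1e-12) 1 else s
      }
    }
    X <- sweep(sweep(X, 2L, center[covnames]), 2L, scale[covnames], "/")
  } else {
    center <- setNames(numeric(length(covnames)), covnames)
    scale <- setNames(rep(1, length(covnames)), covnames)
  }
  Xcov <- cbind("(Intercept)" = 1, X)

  ser <- cohort$series
  subj <- match(ser$subject_id, ids)
  los <- cov$los_days[subj]
  t <- timepoint_years(ser$timepoint, los)
  Xtime <- outer(t, 0:config$degree, `^`)
  y <- as.numeric(ser[[config$outcome]])

  ex <- cohort$exits[match(ids, cohort$exits$subject_id), , drop = FALSE]
  m <- completed_intervals(ex$last_timepoint)
  e <- ifelse(ex$reason %in% c("death", "recovery", "opt_out"), m + 1L, 0L)

  list(ids = ids, N = length(ids), Xcov = Xcov, Xtime = Xtime, y = y,
       subj = subj, m = m, e = e, center = center, scale = scale,
       covnames = covnames)
}

# N x K matrix of per-subject, per-class joint log-likelihood contributions
# (trajectory + exit process), excluding the membership prior
class_loglik_matrix <- function(design, params) {
  K <- nrow(params$beta)
  sigma <- if (length(params$sigma) == 1L) {
    rep(params$sigma, K)
  } else params$sigma
  mu <- design$Xtime %*% t(params$beta)                       # M x K
  obs_ll <- vapply(seq_len(K), function(k) {
    dnorm(design$y, mu[, k], sigma[k], log = TRUE)
  }, numeric(length(design$y)))
  if (is.null(dim(obs_ll))) obs_ll <- matrix(obs_ll, nrow = 1L)
  L <- rowsum(obs_ll, design$subj, reorder = TRUE)            # N x K

  logS <- apply(log1p(-params$hazard), 1L, cumsum)            # J x K
  if (is.null(dim(logS))) logS <- matrix(logS, nrow = 1L)
  cumS <- rbind(0, logS)                                      # (J+1) x K
  L <- L + cumS[design$m + 1L, , drop = FALSE]
  has_e <- which(design$e > 0L)
  if (length(has_e) > 0L) {
    logh <- log(params$hazard)                                # K x J
    L[has_e, ] <- L[has_e, ] + t(logh[, design$e[has_e], drop = FALSE])
  }
  L
}

e_step_internal <- function(design, params) {
  P <- membership_probs(params$gamma, design$Xcov)
  A <- log(P) + class_loglik_matrix(design, params)
  mx <- apply(A, 1L, max)
  if (any(!is.finite(mx))) {
    stop("non-finite subject log-likelihood in E-step", call. = FALSE)
  }
  w <- exp(A - mx)
  s <- rowSums(w)
  list(posterior = w / s, loglik = sum(mx + log(s)), prior = P)
}

# weighted multinomial-logit maximization (damped Newton with ascent
# guarantee); W has fractional rows summing to 1, columns = classes
fit_weighted_multinomial <- function(X, W, gamma_init = NULL,
                                     tol = 1e-8, max_iter = 100L) {
  K <- ncol(W)
  p1 <- ncol(X)
  gamma <- if (is.null(gamma_init)) {
    matrix(0, K - 1L, p1)
  } else gamma_init
  if (K == 1L) return(matrix(0, 0L, p1))
  obj <- function(g) {
    # weighted log-softmax, safe under saturation
    eta <- cbind(0, X %*% t(g))
    mx <- apply(eta, 1L, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    sum(W * (eta - lse))
  }
  f_cur <- obj(gamma)
  damp <- 1e-8
  for (it in seq_len(max_iter)) {
    P <- membership_probs(gamma, X)
    G <- t(X) %*% (W[, -1L, drop = FALSE] - P[, -1L, drop = FALSE])
    gvec <- as.vector(G)
    if (max(abs(gvec)) < tol) break
    nb <- (K - 1L) * p1
    H <- matrix(0, nb, nb)
    for (a in seq_len(K - 1L)) {
      for (b in a:(K - 1L)) {
        wab <- P[, a + 1L] * ((a == b) - P[, b + 1L])
        blk <- crossprod(X * wab, X)
        ra <- (a - 1L) * p1 + seq_len(p1)
        rb <- (b - 1L) * p1 + seq_len(p1)
        H[ra, rb] <- blk
        H[rb, ra] <- t(blk)
      }
    }
    step <- NULL
    for (try in 1:8) {
      Hd <- H + diag(damp * (1 + max(abs(diag(H)))), nb)
      step <- tryCatch(solve(Hd, gvec), error = function(e) NULL)
      if (!is.null(step)) break
      damp <- damp * 100
    }
    if (is.null(step)) break
    # backtracking line search preserving ascent
    alpha <- 1
    improved <- FALSE
    for (ls in 1:30) {
      cand <- gamma + alpha * matrix(step, K - 1L, p1, byrow = TRUE)
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new >= f_cur - 1e-12) {
        if (f_new > f_cur || max(abs(gvec)) < tol) {
          gamma <- cand
          f_cur <- f_new
          improved <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    damp <- max(damp / 10, 1e-10)
  }
  dimnames(gamma) <- list(NULL, colnames(X))
  gamma
}

SIGMA_FLOOR <- 1e-3
HAZARD_CLIP <- c(1e-6, 1 - 1e-6)

m_step_internal <- function(design, posterior, config,
                            gamma_init = NULL) {
  K <- ncol(posterior)
  d1 <- ncol(design$Xtime)
  Wobs <- posterior[design$subj, , drop = FALSE]               # M x K

  total_mass <- colSums(posterior)
  if (any(total_mass < 1e-8)) {
    stop(sprintf("degenerate class %d: total posterior mass below 1e-8",
                 which(total_mass < 1e-8)[1L]), call. = FALSE)
  }

  beta <- matrix(0, K, d1)
  ss <- numeric(K)
  wsum <- numeric(K)
  for (k in seq_len(K)) {
    w <- Wobs[, k]
    XtW <- crossprod(design$Xtime * w, design$Xtime)
    beta[k, ] <- solve(XtW + diag(1e-10, d1),
                       crossprod(design$Xtime * w, design$y))
    resid <- design$y - drop(design$Xtime %*% beta[k, ])
    ss[k] <- sum(w * resid^2)
    wsum[k] <- sum(w)
  }
  sigma <- if (isTRUE(config$class_specific_sigma)) {
    pmax(SIGMA_FLOOR, sqrt(ss / wsum))
  } else {
    max(SIGMA_FLOOR, sqrt(sum(ss) / sum(wsum)))
  }

  hazard <- matrix(HAZARD_CLIP[1L], K, N_INTERVALS)
  for (j in seq_len(N_INTERVALS)) {
    atrisk <- design$m >= j | design$e == j
    exited <- design$e == j
    num <- colSums(posterior * exited)
    den <- colSums(posterior * atrisk)
    h <- ifelse(den > 0, num / pmax(den, 1e-12), HAZARD_CLIP[1L])
    hazard[, j] <- pmin(HAZARD_CLIP[2L], pmax(HAZARD_CLIP[1L], h))
  }

  gamma <- fit_weighted_multinomial(design$Xcov, posterior,
                                    gamma_init = gamma_init)
  lcgmm_params(gamma = gamma, beta = beta, sigma = sigma, hazard = hazard)
}

#' Posterior class probabilities (E-step)
#'
#' Bayes' rule in log space: `posterior_ik` proportional to
#' `pi_k(x_i) * L_ik` where `L_ik` is the subject's joint
#' trajectory-and-exit likelihood under class k.
#'
#' @param cohort an `"abi_cohort"`.
#' @param params an [lcgmm_params()] object.
#' @param config an [lcgmm_config()].
#' @return N x K matrix of posterior probabilities, rows summing to 1,
#'   rownames the subject ids; attribute `"loglik"` carries the observed
#'   mixture log-likelihood.
#' @export
e_step <- function(cohort, params, config) {
  design <- build_design(cohort, config)
  es <- e_step_internal(design, params)
  out <- es$posterior
  rownames(out) <- design$ids
  attr(out, "loglik") <- es$loglik
  out
}

#' Maximization step of the EM algorithm
#'
#' Given posterior class weights: trajectory coefficients and residual SD
#' by posterior-weighted least squares over all observations, exit hazards
#' by posterior-weighted occurrence/exposure ratios (clipped to
#' (1e-6, 1-1e-6)), and membership coefficients by posterior-weighted
#' multinomial-logit maximization (damped Newton with an ascent guarantee,
#' gradient tolerance 1e-8).
#'
#' @param cohort an `"abi_cohort"`.
#' @param posterior N x K weight matrix (rows sum to 1), subject order as
#'   in `subject_ids(cohort)`.
#' @param config an [lcgmm_config()].
#' @return an [lcgmm_params()] object.
#' @export
m_step <- function(cohort, posterior, config) {
  design <- build_design(cohort, config)
  m_step_internal(design, posterior, config)
}

#' Observed-data mixture log-likelihood
#'
#' `sum_i log sum_k pi_k(x_i) exp(L_ik)`, evaluated stably via
#' log-sum-exp.
#'
#' @inheritParams e_step
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(cohort, params, config) {
  if (any(!is.finite(unlist(params[c("gamma", "beta", "sigma",
                                     "hazard")])))) {
    stop("non-finite parameter", call. = FALSE)
  }
  design <- build_design(cohort, config)
  e_step_internal(design, params)$loglik
}

lcgmm_n_params <- function(K, p1, degree, class_specific_sigma = FALSE) {
  (K - 1L) * p1 + K * (degree + 1L) +
    (if (class_specific_sigma) K else 1L) + K * N_INTERVALS
}

# canonical relabeling: ascending model-implied mean outcome at year 7,
# class 1 (lowest endpoint, the non-responders) is the reference
canonical_order <- function(beta) {
  degree <- ncol(beta) - 1L
  endpoint <- drop(beta %*% 7^(0:degree))
  order(endpoint)
}

apply_class_order <- function(params, posterior, perm) {
  K <- nrow(params$beta)
  gfull <- rbind(0, params$gamma)[perm, , drop = FALSE]
  gfull <- sweep(gfull, 2L, gfull[1L, ])
  params$gamma <- gfull[-1L, , drop = FALSE]
  params$beta <- params$beta[perm, , drop = FALSE]
  if (length(params$sigma) > 1L) params$sigma <- params$sigma[perm]
  params$hazard <- params$hazard[perm, , drop = FALSE]
  posterior <- posterior[, perm, drop = FALSE]
  list(params = params, posterior = posterior)
}

run_em <- function(design, params, config) {
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  posterior <- NULL
  for (it in seq_len(config$max_iter)) {
    es <- e_step_internal(design, params)
    posterior <- es$posterior
    trace <- c(trace, es$loglik)
    if (is.finite(ll_prev) &&
        abs(es$loglik - ll_prev) <= config$em_tol *
        (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
    params <- m_step_internal(design, posterior, config,
                              gamma_init = params$gamma)
  }
  list(params = params, posterior = posterior,
       loglik = trace[length(trace)], trace = trace,
       converged = converged, n_iter = length(trace))
}

#' Fit the joint latent-class trajectory model by multi-start EM
#'
#' Runs `n_starts` EM runs from randomized initializations (per-subject
#' Dirichlet(1, ..., 1) posterior draws, seed = `config$seed` + start
#' index), optionally plus user-supplied warm starts, and keeps the run
#' with the highest converged log-likelihood. Classes are relabeled
#' canonically by ascending model-implied mean outcome at year 7, so class
#' 1 (lowest endpoint, the non-responders) is the reference class of the
#' membership coefficients. Starts that collapse a class (posterior mass
#' below 1e-8) are abandoned, not fatal, as long as one start converges.
#'
#' @param cohort an `"abi_cohort"`.
#' @param config an [lcgmm_config()].
#' @param init_params optional list of [lcgmm_params()] used as additional
#'   deterministic warm starts.
#' @return an object of class `"lcgmm_fit"` with elements `params`,
#'   `loglik`, `n_params`, `bic` (`-2 loglik + n_params log N`),
#'   `posterior` (N x K), `marginal_probs` (column means of the
#'   membership-submodel probabilities), `class_order`, `converged`,
#'   `n_iter`, `start_index`, `diagnostics` (per-start traces and status),
#'   standardization constants and the config.
#' @export
fit_lcgmm <- function(cohort, config, init_params = NULL) {
  validate_cohort(cohort)
  design <- build_design(cohort, config)
  K <- config$n_classes
  N <- design$N
  p1 <- ncol(design$Xcov)

  starts <- list()
  for (s in seq_len(config$n_starts)) {
    set.seed(config$seed + s)
    w <- matrix(rexp(N * K), N, K)
    starts[[s]] <- list(kind = "random", posterior = w / rowSums(w))
  }
  if (!is.null(init_params)) {
    for (ip in init_params) {
      starts[[length(starts) + 1L]] <- list(kind = "warm", params = ip)
    }
  }

  runs <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    runs[[s]] <- tryCatch({
      params0 <- if (starts[[s]]$kind == "random") {
        m_step_internal(design, starts[[s]]$posterior, config)
      } else starts[[s]]$params
      run_em(design, params0, config)
    }, error = function(err) list(failed = TRUE,
                                  message = conditionMessage(err)))
  }

  ok <- which(vapply(runs, function(r) is.null(r$failed) && r$converged,
                     logical(1L)))
  if (length(ok) == 0L) {
    # fall back to non-converged runs before declaring failure
    ok <- which(vapply(runs, function(r) is.null(r$failed), logical(1L)))
    if (length(ok) == 0L) {
      stop("no EM start converged; all starts degenerate or failed: ",
           runs[[1L]]$message, call. = FALSE)
    }
    warning("no EM start reached the tolerance within max_iter; ",
            "returning the best available run", call. = FALSE)
  }
  best <- ok[which.max(vapply(runs[ok], `[[`, numeric(1L), "loglik"))]
  run <- runs[[best]]

  perm <- canonical_order(run$params$beta)
  canon <- apply_class_order(run$params, run$posterior, perm)
  params <- canon$params
  posterior <- canon$posterior
  rownames(posterior) <- design$ids
  colnames(posterior) <- paste0("class", seq_len(K))
  rownames(params$beta) <- paste0("class", seq_len(K))
  colnames(params$beta) <- paste0("t^", 0:config$degree)
  rownames(params$hazard) <- paste0("class", seq_len(K))
  colnames(params$hazard) <- paste0("interval", seq_len(N_INTERVALS))
  if (K > 1L) {
    rownames(params$gamma) <- paste0("class", 2:K)
    colnames(params$gamma) <- colnames(design$Xcov)
  }

  P <- membership_probs(params$gamma, design$Xcov)
  marginal <- colMeans(P)
  n_params <- lcgmm_n_params(K, p1, config$degree,
                             config$class_specific_sigma)

  structure(list(
    params = params,
    loglik = run$loglik,
    n_params = n_params,
    bic = -2 * run$loglik + n_params * log(N),
    posterior = posterior,
    marginal_probs = marginal,
    class_order = perm,
    converged = run$converged,
    n_iter = run$n_iter,
    start_index = best,
    diagnostics = list(
      traces = lapply(runs, function(r) if (is.null(r$failed)) r$trace),
      failed = vapply(runs, function(r) !is.null(r$failed), logical(1L)),
      messages = lapply(runs, function(r) r$message)
    ),
    center = design$center, scale = design$scale,
    covnames = design$covnames,
    config = config, n = N
  ), class = "lcgmm_fit")
}

#' @export
print.lcgmm_fit <- function(x, ...) {
  K <- nrow(x$params$beta)
  cat(sprintf(
    "<lcgmm_fit> K=%d classes, N=%d, loglik=%.2f, BIC=%.1f (%s)\n",
    K, x$n, x$loglik, x$bic,
    if (x$converged) sprintf("converged in %d iterations", x$n_iter)
    else "not converged"))
  lab <- max.col(x$posterior, ties.method = "first")
  sizes <- tabulate(lab, K)
  cat("class sizes (posterior-max):",
      paste(sizes, collapse = "/"), "\n")
  cat("marginal probabilities:",
      paste(sprintf("%.3f", x$marginal_probs), collapse = " "), "\n")
  invisible(x)
}

#' Predicted mean trajectory of each class
#'
#' Model-implied mean outcome of each class on a time grid, clamped to the
#' scale bounds for reporting (the clamp never enters the likelihood).
#'
#' @param fitted an `"lcgmm_fit"`.
#' @param times numeric vector of years since admission.
#' @param clamp clamp to the outcome's scale bounds (default TRUE).
#' @return data.frame with columns `time`, one column per class.
#' @export
predicted_trajectories <- function(fitted, times = seq(0, 7, by = 0.25),
                                   clamp = TRUE) {
  degree <- ncol(fitted$params$beta) - 1L
  B <- outer(times, 0:degree, `^`)
  mu <- B %*% t(fitted$params$beta)
  if (clamp) {
    b <- FIM_BOUNDS[[fitted$config$outcome]]
    mu[] <- pmin(b[2L], pmax(b[1L], mu))
  }
  out <- data.frame(time = times)
  out[colnames(fitted$posterior)] <- as.data.frame(mu)
  out
}

#' Assign classes to (possibly unseen) subjects with frozen parameters
#'
#' Computes posterior class probabilities for every subject of `cohort`
#' under the fitted parameters (covariates standardized with the training
#' constants) and labels each subject by maximal posterior, ties broken
#' toward the lower canonical class index.
#'
#' @param fitted an `"lcgmm_fit"`.
#' @param cohort an `"abi_cohort"`; subjects need not have been seen in
#'   fitting but must carry the model covariates and at least the
#'   admission and discharge assessments.
#' @return list with `label` (named integer vector) and `posterior`
#'   (N x K matrix).
#' @export
assign_classes <- function(fitted, cohort) {
  validate_cohort(cohort)
  design <- build_design(cohort, fitted$config, center = fitted$center,
                         scale = fitted$scale)
  es <- e_step_internal(design, fitted$params)
  post <- es$posterior
  rownames(post) <- design$ids
  colnames(post) <- colnames(fitted$posterior)
  label <- max.col(post, ties.method = "first")
  names(label) <- design$ids
  list(label = label, posterior = post)
}

#' BIC scan over the number of classes
#'
#' Fits the model once per K under a common seed policy and tabulates
#' log-likelihood, parameter count, BIC, and the posterior-sharpness
#' diagnostic: the mean maximal posterior probability within each class
#' (reported as its minimum over classes, plus per-class values).
#'
#' @param cohort an `"abi_cohort"`.
#' @param K_range integers to scan (default 2:5).
#' @param base_config an [lcgmm_config()] whose `n_classes` is replaced by
#'   each K in turn.
#' @return an object of class `"bic_scan"`: list with `table` (data.frame
#'   K, loglik, n_params, bic, min_class_post), `class_post` (list of
#'   per-class mean max-posterior vectors) and `fits` (list of
#'   `"lcgmm_fit"`, NULL where a fit failed with a warning).
#' @export
bic_scan <- function(cohort, K_range = 2:5, base_config) {
  fits <- vector("list", length(K_range))
  rows <- vector("list", length(K_range))
  class_post <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    cfg <- base_config
    cfg$n_classes <- as.integer(K_range[i])
    fit <- tryCatch(fit_lcgmm(cohort, cfg), error = function(e) {
      warning(sprintf("K=%d fit failed: %s", K_range[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    fits[[i]] <- fit
    if (!is.null(fit)) {
      cp <- class_mean_max_posterior(fit$posterior)
      class_post[[i]] <- cp
      rows[[i]] <- data.frame(K = K_range[i], loglik = fit$loglik,
                              n_params = fit$n_params, bic = fit$bic,
                              min_class_post = min(cp, na.rm = TRUE))
    }
  }
  structure(list(table = do.call(rbind, rows), class_post = class_post,
                 K_range = K_range, fits = fits),
            class = "bic_scan")
}

#' @export
print.bic_scan <- function(x, ...) {
  cat("<bic_scan>\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$table) && nrow(x$table) > 0L) {
    cat("BIC-selected K:", x$table$K[which.min(x$table$bic)], "\n")
  }
  invisible(x)
}

# per-class mean of the maximal posterior probability among subjects
# assigned to that class (NA for empty classes)
class_mean_max_posterior <- function(posterior) {
  lab <- max.col(posterior, ties.method = "first")
  K <- ncol(posterior)
  vapply(seq_len(K), function(k) {
    members <- lab == k
    if (!any(members)) return(NA_real_)
    mean(posterior[members, k])
  }, numeric(1L))
}
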