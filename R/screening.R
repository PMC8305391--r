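#' Numerically encode the covariate table
#'
#' Encodes the baseline covariate table for correlation screening and
#' modelling: gender M=0/F=1, etiology as one-hot dummies with traumatic as
#' the reference level (`anoxic`, `other_nontraumatic`), booleans as 0/1,
#' durations and ages unchanged.
#'
#' @param covariates the `covariates` table of an `"abi_cohort"`.
#' @param etiology_dummies expand etiology into the two dummies (default)
#'   instead of a single integer code 0/1/2.
#' @return data.frame of numeric columns plus `subject_id`.
#' @export
encode_covariates <- function(covariates, etiology_dummies = TRUE) {
  out <- data.frame(
    subject_id = covariates$subject_id,
    gender = as.integer(covariates$gender == "F"),
    age_at_event = covariates$age_at_event_months,
    age_at_admission = covariates$age_at_admission_months,
    los_days = covariates$los_days,
    coma_days = covariates$coma_days,
    dcn = as.integer(covariates$dcn),
    epilepsy = as.integer(covariates$epilepsy),
    stringsAsFactors = FALSE
  )
  if (etiology_dummies) {
    out$anoxic <- as.integer(covariates$etiology == "anoxic")
    out$other_nontraumatic <-
      as.integer(covariates$etiology == "other_nontraumatic")
  } else {
    out$etiology <- match(covariates$etiology, ETIOLOGIES) - 1L
  }
  out
}

# Spearman rho with two-sided p-value from the t approximation
spearman_test <- function(x, y) {
  n <- length(x)
  r <- cor(rank(x), rank(y))
  if (is.na(r)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(r) >= 1) return(c(rho = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(rho = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Correlation-based covariate screening
#'
#' Retains a subset of covariates such that no retained pair is strongly
#' monotonically associated: a pair conflicts when `|Spearman rho| >=
#' rho_max` and the Bonferroni-corrected p-value (t approximation,
#' correction over all tested pairs) is below `alpha`. Conflicts are
#' resolved deterministically: covariates are considered in `keep_priority`
#' order (then alphabetically) and a candidate is dropped when it conflicts
#' with an already retained covariate. Constant (zero-variance) covariates
#' are excluded with a warning.
#'
#' @param covariates data.frame of numerically encoded covariates
#'   (categories as integer codes, booleans 0/1); a `subject_id` column is
#'   ignored. At least 3 rows.
#' @param rho_max absolute Spearman correlation threshold (default 0.5).
#' @param alpha significance level after Bonferroni correction
#'   (default 0.01).
#' @param keep_priority character vector; earlier names win conflicts.
#'   Defaults to the clinically established ordering: gender, age at event,
#'   etiology dummies, age at admission, length of stay, days of coma,
#'   decompressive craniotomy/neurosurgery, epilepsy.
#' @return an object of class `"covariate_screen"`: list with `selected`
#'   (character vector), `dropped`, `report` (data.frame of all pairwise
#'   rho, raw and corrected p, and the conflict flag).
#' @export
screen_covariates <- function(covariates,
                              rho_max = 0.5,
                              alpha = 0.01,
                              keep_priority = c("gender", "age_at_event",
                                                "anoxic",
                                                "other_nontraumatic",
                                                "etiology",
                                                "age_at_admission",
                                                "los_days", "coma_days",
                                                "dcn", "epilepsy")) {
  covariates <- as.data.frame(covariates)
  covariates$subject_id <- NULL
  if (nrow(covariates) < 3L) {
    stop("screening needs at least 3 subjects", call. = FALSE)
  }
  vars <- names(covariates)
  const <- vars[vapply(covariates, function(v) length(unique(v)) < 2L,
                       logical(1L))]
  if (length(const) > 0L) {
    warning("excluding constant covariate(s): ",
            paste(const, collapse = ", "), call. = FALSE)
    vars <- setdiff(vars, const)
  }
  ord <- c(intersect(keep_priority, vars),
           sort(setdiff(vars, keep_priority)))

  pairs <- if (length(ord) >= 2L) utils::combn(ord, 2L) else
    matrix(character(0), nrow = 2L)
  n_tests <- ncol(pairs)
  report <- data.frame(var1 = character(0), var2 = character(0),
                       rho = numeric(0), p = numeric(0),
                       p_bonferroni = numeric(0), conflict = logical(0))
  if (n_tests > 0L) {
    stats <- apply(pairs, 2L, function(p) {
      spearman_test(covariates[[p[1L]]], covariates[[p[2L]]])
    })
    p_bonf <- pmin(1, stats["p", ] * n_tests)
    report <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                         rho = stats["rho", ], p = stats["p", ],
                         p_bonferroni = p_bonf,
                         conflict = abs(stats["rho", ]) >= rho_max &
                           p_bonf < alpha,
                         stringsAsFactors = FALSE)
  }

  selected <- character(0)
  dropped <- character(0)
  for (v in ord) {
    hit <- report$conflict &
      ((report$var1 == v & report$var2 %in% selected) |
         (report$var2 == v & report$var1 %in% selected))
    if (any(hit)) dropped <- c(dropped, v) else selected <- c(selected, v)
  }
  structure(list(selected = selected,
                 dropped = c(dropped, const),
                 rho_max = rho_max, alpha = alpha,
                 n_tests = n_tests, report = report),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat(sprintf(
    "<covariate_screen> |rho| >= %.2f at Bonferroni alpha = %g (%d tests)\n",
    x$rho_max, x$alpha, x$n_tests))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  if (length(x$dropped) > 0L) {
    cat("dropped: ", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
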