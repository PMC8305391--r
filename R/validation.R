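#' Randomized split of a cohort into two halves
#'
#' Deterministic given the seed: a seeded permutation of the subjects is
#' cut into halves of sizes ceiling(N/2) and floor(N/2).
#'
#' @param cohort an `"abi_cohort"` with at least 4 subjects.
#' @param seed integer seed.
#' @return list with `A` and `B` (disjoint `"abi_cohort"` halves) and
#'   `ids_A`, `ids_B`.
#' @export
split_half <- function(cohort, seed) {
  N <- n_subjects(cohort)
  if (N < 4L) stop("split_half needs at least 4 subjects", call. = FALSE)
  set.seed(seed)
  perm <- sample(subject_ids(cohort))
  nA <- ceiling(N / 2)
  ids_A <- sort(perm[seq_len(nA)])
  ids_B <- sort(perm[(nA + 1L):N])
  list(A = subset_cohort(cohort, ids_A), B = subset_cohort(cohort, ids_B),
       ids_A = ids_A, ids_B = ids_B)
}

#' Split-half stability test of the class solution
#'
#' Compares a constrained multi-group fit (one parameter set shared by the
#' two randomized halves, i.e. the ordinary pooled fit) against an
#' unconstrained fit (separate parameter sets per half, log-likelihoods
#' summed) with a likelihood-ratio test on `df` = the parameter-count
#' difference. Each half fit includes the pooled solution as a warm start,
#' which guarantees the nesting inequality
#' `loglik_unconstrained >= loglik_constrained`. A non-significant test
#' indicates that the class structure is stable across halves.
#'
#' @param cohort an `"abi_cohort"`.
#' @param K number of classes.
#' @param config an [lcgmm_config()]; its `n_classes` is overridden by
#'   `K`.
#' @param seed seed of the randomized split.
#' @param halves optional list with character vectors `ids_A`, `ids_B`
#'   giving a fixed split (then `seed` is ignored for splitting).
#' @return an object of class `"stability_result"`: `K`,
#'   `loglik_constrained`, `loglik_unconstrained`, `lr_stat`, `df`,
#'   `p_value`, plus the three fits.
#' @export
stability_test <- function(cohort, K, config, seed = 1L, halves = NULL) {
  cfg <- config
  cfg$n_classes <- as.integer(K)
  if (is.null(halves)) {
    sp <- split_half(cohort, seed)
  } else {
    sp <- list(A = subset_cohort(cohort, halves$ids_A),
               B = subset_cohort(cohort, halves$ids_B))
  }
  pooled <- fit_lcgmm(cohort, cfg)
  fit_A <- fit_lcgmm(sp$A, cfg, init_params = list(pooled$params))
  fit_B <- fit_lcgmm(sp$B, cfg, init_params = list(pooled$params))

  # the pooled likelihood splits additively over the halves, so the
  # constrained log-likelihood is the pooled maximum
  ll_con <- pooled$loglik
  ll_unc <- fit_A$loglik + fit_B$loglik
  if (ll_unc < ll_con - 1e-6) {
    warning("unconstrained log-likelihood below constrained one ",
            "(local optimum); statistic truncated at 0", call. = FALSE)
  }
  lr <- max(0, 2 * (ll_unc - ll_con))
  df <- pooled$n_params
  structure(list(K = as.integer(K),
                 loglik_constrained = ll_con,
                 loglik_unconstrained = ll_unc,
                 lr_stat = lr, df = df,
                 p_value = pchisq(lr, df, lower.tail = FALSE),
                 fit_pooled = pooled, fit_A = fit_A, fit_B = fit_B),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> K=%d LR=%.2f on df=%d, p=%.4g (%s)\n",
    x$K, x$lr_stat, x$df, x$p_value,
    if (x$p_value > 0.05) "stable" else "halves differ"))
  invisible(x)
}

#' Cross-design class labels (every label from a held-out model)
#'
#' Fits the model on each randomized half and assigns classes to the other
#' half, so every subject's label comes from a model that never saw that
#' subject. Both half-models are relabeled canonically by ascending year-7
#' endpoint before the labels are pooled, harmonizing the class meaning
#' across halves.
#'
#' @inheritParams stability_test
#' @return an object of class `"cross_design_labels"`: a data.frame with
#'   columns `subject_id`, `half` (the half the subject belongs to),
#'   `label`, `p_class1`..`p_classK`; attributes `fit_A`, `fit_B` hold the
#'   two half-models.
#' @export
cross_design_labels <- function(cohort, K, config, seed = 1L,
                                halves = NULL) {
  cfg <- config
  cfg$n_classes <- as.integer(K)
  if (is.null(halves)) {
    sp <- split_half(cohort, seed)
  } else {
    sp <- list(A = subset_cohort(cohort, halves$ids_A),
               B = subset_cohort(cohort, halves$ids_B),
               ids_A = halves$ids_A, ids_B = halves$ids_B)
  }
  fit_A <- fit_lcgmm(sp$A, cfg)
  fit_B <- fit_lcgmm(sp$B, cfg)
  asg_B <- assign_classes(fit_A, sp$B)  # A's model labels B's subjects
  asg_A <- assign_classes(fit_B, sp$A)

  mk <- function(asg, half) {
    df <- data.frame(subject_id = names(asg$label), half = half,
                     label = as.integer(asg$label),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(asg$posterior,
                            col.names = paste0("p_class", seq_len(K))))
  }
  post_names <- paste0("p_class", seq_len(K))
  dfA <- mk(asg_A, "A"); names(dfA)[-(1:3)] <- post_names
  dfB <- mk(asg_B, "B"); names(dfB)[-(1:3)] <- post_names
  out <- rbind(dfA, dfB)
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fit_A") <- fit_A
  attr(out, "fit_B") <- fit_B
  class(out) <- c("cross_design_labels", "data.frame")
  out
}
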