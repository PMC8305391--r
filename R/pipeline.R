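#' Configuration of the full stratification pipeline
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"read"`
#'   (load CSVs from `cohort_path`).
#' @param generator a [generator_config()] (simulate mode).
#' @param cohort_path directory with the cohort CSVs (read mode).
#' @param class_range class counts for the BIC scan and stability tests.
#' @param prediction_classes class counts for which cross-design labels
#'   and discharge prediction are produced.
#' @param outcome score to model (`total` or one domain).
#' @param master_seed single seed; all stage seeds are derived from it by
#'   fixed offsets.
#' @param k_folds folds per half in the prediction stage.
#' @param n_starts EM starts per fit.
#' @param out_dir optional output directory for the report bundle
#'   artifacts (JSON summary, labels CSV, text report).
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("simulate", "read"),
                            generator = generator_config(),
                            cohort_path = NULL,
                            class_range = 2:5,
                            prediction_classes = c(2L, 3L, 4L),
                            outcome = "total",
                            master_seed = 42L,
                            k_folds = 5L,
                            n_starts = 5L,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "read" && is.null(cohort_path)) {
    stop("read mode requires cohort_path", call. = FALSE)
  }
  structure(list(mode = mode, generator = generator,
                 cohort_path = cohort_path,
                 class_range = as.integer(class_range),
                 prediction_classes = as.integer(prediction_classes),
                 outcome = outcome, master_seed = as.integer(master_seed),
                 k_folds = as.integer(k_folds),
                 n_starts = as.integer(n_starts), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  config$out_dir <- NULL  # volatile: not part of the scientific identity
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf, version = 2)
  unname(tools::md5sum(tf))
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Per-class characteristics and membership coefficients
#'
#' Class sizes, mean baseline covariates per class (raw scale), and the
#' membership-submodel coefficients against canonical class 1 (the
#' non-responders) with Wald standard errors from the observed information
#' of the posterior-weighted multinomial submodel. The Wald p-values are
#' descriptive (no multiplicity correction).
#'
#' @param fitted an `"lcgmm_fit"`.
#' @param cohort the cohort the model was fitted to.
#' @param labels optional integer labels (default: posterior-max labels
#'   from `fitted`).
#' @return an object of class `"class_characteristics"`: list with
#'   `sizes`, `covariate_means` (classes x covariates), `gamma_table`
#'   (coefficient, SE, z, p per contrast and covariate).
#' @export
class_characteristics <- function(fitted, cohort, labels = NULL) {
  K <- nrow(fitted$params$beta)
  if (is.null(labels)) {
    labels <- max.col(fitted$posterior, ties.method = "first")
    names(labels) <- rownames(fitted$posterior)
  }
  ids <- subject_ids(cohort)
  labels <- labels[ids]
  sizes <- tabulate(labels, K)
  names(sizes) <- paste0("class", seq_len(K))

  enc <- encode_covariates(cohort$covariates)
  enc$subject_id <- NULL
  covariate_means <- t(vapply(seq_len(K), function(k) {
    colMeans(enc[labels == k, , drop = FALSE])
  }, numeric(ncol(enc))))
  rownames(covariate_means) <- names(sizes)

  # observed information of the membership submodel at the fitted gamma,
  # with the posterior weights as fractional class indicators
  design <- build_design(cohort, fitted$config, center = fitted$center,
                         scale = fitted$scale)
  X <- design$Xcov
  P <- membership_probs(fitted$params$gamma, X)
  p1 <- ncol(X)
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
  V <- tryCatch(solve(H + diag(1e-10, nb)), error = function(e) {
    matrix(NA_real_, nb, nb)
  })
  se <- matrix(sqrt(pmax(diag(V), 0)), K - 1L, p1, byrow = TRUE)
  est <- fitted$params$gamma
  z <- est / se
  gamma_table <- data.frame(
    contrast = rep(rownames(est), each = p1),
    covariate = rep(colnames(est), K - 1L),
    estimate = as.vector(t(est)),
    se = as.vector(t(se)),
    z = as.vector(t(z)),
    p = 2 * pnorm(-abs(as.vector(t(z)))),
    stringsAsFactors = FALSE
  )
  structure(list(sizes = sizes, covariate_means = covariate_means,
                 gamma_table = gamma_table),
            class = "class_characteristics")
}

#' @export
print.class_characteristics <- function(x, ...) {
  cat("<class_characteristics>\n")
  cat("sizes:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                      collapse = " "), "\n")
  top <- x$gamma_table[order(x$gamma_table$p), ]
  cat("strongest membership effects (vs class 1):\n")
  print(head(top[top$covariate != "(Intercept)", ], 6L),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full trajectory-stratification pipeline
#'
#' Orchestrates the analysis end to end under one master seed:
#' simulate or read the cohort, screen covariates, scan the number of
#' classes by BIC, test split-half stability for every K in the range,
#' produce cross-design (held-out) labels, summarize class
#' characteristics at the BIC-selected K, and run the discharge-based
#' prediction with nested cross-validation for each requested number of
#' classes. All stage seeds derive deterministically from the master
#' seed, so two runs with the same configuration produce identical
#' bundles.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `"report_bundle"`: list with `cohort_summary`,
#'   `screening`, `bic` (scan table), `stability` (data.frame over K),
#'   `labels` (cross-design labels at each prediction K), `selected_K`,
#'   `characteristics`, `prediction` (named list of `"eval_report"`),
#'   `truth_agreement` (simulate mode only), `config`, `config_hash`,
#'   `seeds`.
#' @export
run_pipeline <- function(config) {
  hash <- config_hash(config)
  seeds <- list(generator = config$master_seed + 101L,
                fit = config$master_seed + 202L,
                split = config$master_seed + 303L,
                cv = config$master_seed + 404L)

  truth <- NULL
  if (config$mode == "simulate") {
    pipeline_log("simulate", "generating synthetic cohort (seed %d)",
                 seeds$generator)
    gen <- config$generator
    gen$seed <- seeds$generator
    sim <- generate_cohort(gen)
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    pipeline_log("read", "reading cohort from %s", config$cohort_path)
    cohort <- read_cohort(config$cohort_path)
  }

  screening <- screen_covariates(encode_covariates(cohort$covariates))
  pipeline_log("screen", "retained: %s",
               paste(screening$selected, collapse = ", "))

  base_cfg <- lcgmm_config(n_classes = 2L, outcome = config$outcome,
                           seed = seeds$fit, n_starts = config$n_starts)
  scan <- bic_scan(cohort, config$class_range, base_cfg)
  pipeline_log("scan", "BIC over K: %s",
               paste(sprintf("K=%d:%.0f", scan$table$K, scan$table$bic),
                     collapse = " "))
  selected_K <- scan$table$K[which.min(scan$table$bic)]

  stability <- do.call(rbind, lapply(config$class_range, function(K) {
    st <- stability_test(cohort, K, base_cfg, seed = seeds$split)
    pipeline_log("stability", "K=%d LR=%.1f df=%d p=%.3g", K, st$lr_stat,
                 st$df, st$p_value)
    data.frame(K = K, lr_stat = st$lr_stat, df = st$df,
               p_value = st$p_value)
  }))

  labels_by_K <- list()
  prediction <- list()
  features <- build_features(cohort, outcome = config$outcome)
  for (K in config$prediction_classes) {
    lab <- cross_design_labels(cohort, K, base_cfg, seed = seeds$split)
    labels_by_K[[as.character(K)]] <- lab
    plan <- cv_plan(k = config$k_folds, seed = seeds$cv + K)
    preds <- nested_cv_predict(features,
                               setNames(lab$label, lab$subject_id),
                               plan, n_classes = K)
    rep_k <- evaluate_predictions(preds$true, preds$pred,
                                  preds[, paste0("p_class", seq_len(K))],
                                  n_classes = K)
    pipeline_log("predict", "K=%d accuracy=%.3f kappa=%.3f", K,
                 rep_k$accuracy, rep_k$kappa)
    prediction[[as.character(K)]] <- rep_k
  }

  sel_fit <- scan$fits[[match(selected_K, scan$K_range)]]
  characteristics <- class_characteristics(sel_fit, cohort)

  truth_agreement <- NULL
  if (!is.null(truth) &&
      as.character(length(truth$config$class_probs)) %in%
      names(labels_by_K)) {
    K_true <- length(truth$config$class_probs)
    lab <- labels_by_K[[as.character(K_true)]]
    agree <- mean(lab$label ==
                    truth$labels$true_class[match(lab$subject_id,
                                                  truth$labels$subject_id)])
    truth_agreement <- data.frame(K = K_true, label_accuracy = agree)
    pipeline_log("truth", "held-out label agreement with ground truth: %.3f",
                 agree)
  }

  bundle <- structure(list(
    cohort_summary = summarize_cohort(cohort),
    screening = screening,
    bic = scan$table,
    stability = stability,
    labels = labels_by_K,
    selected_K = selected_K,
    characteristics = characteristics,
    prediction = prediction,
    truth_agreement = truth_agreement,
    config = config, config_hash = hash, seeds = seeds
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# machine-readable summary (JSON), labels CSV, and a short text report
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary <- list(
    config_hash = bundle$config_hash,
    seeds = bundle$seeds,
    selected_K = bundle$selected_K,
    bic = bundle$bic,
    stability = bundle$stability,
    prediction = lapply(bundle$prediction, function(r) {
      list(accuracy = r$accuracy, precision = r$precision,
           kappa = r$kappa, auc = r$auc,
           confusion = unclass(r$confusion),
           adjacency_error_share = r$adjacency_error_share)
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (K in names(bundle$labels)) {
    write.csv(as.data.frame(bundle$labels[[K]]),
              file.path(out_dir, sprintf("labels_K%s.csv", K)),
              row.names = FALSE)
  }
  txt <- c(
    sprintf("trajectory stratification report (config %s)",
            bundle$config_hash),
    sprintf("BIC-selected number of classes: %d", bundle$selected_K),
    capture.output(print(bundle$bic, row.names = FALSE)),
    "split-half stability (LR tests):",
    capture.output(print(bundle$stability, row.names = FALSE)),
    "prediction from first-discharge data:",
    unlist(lapply(names(bundle$prediction), function(K) {
      r <- bundle$prediction[[K]]
      sprintf("  K=%s: accuracy=%.3f precision=%.3f kappa=%.3f", K,
              r$accuracy, r$precision, r$kappa)
    }))
  )
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("BIC-selected K:", x$selected_K, "\n")
  print(x$bic, row.names = FALSE)
  for (K in names(x$prediction)) {
    r <- x$prediction[[K]]
    cat(sprintf("prediction K=%s: accuracy=%.3f kappa=%.3f\n", K,
                r$accuracy, r$kappa))
  }
  invisible(x)
}
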