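# Independent brute-force oracles, coded with explicit loops and no code
# shared with the package internals. They define the expected values for
# the likelihood and the evaluation metrics.

# joint mixture log-likelihood, enumerating classes per subject; assumes
# the model config uses membership covariates (coma_days, epilepsy),
# unstandardized
brute_force_mixture_loglik <- function(cohort, params, config) {
  tps <- c("admission", "discharge", paste0("Y", 1:7))
  gfull <- rbind(0, params$gamma)
  K <- nrow(params$beta)
  total <- 0
  for (id in cohort$covariates$subject_id) {
    cov <- cohort$covariates[cohort$covariates$subject_id == id, ]
    x <- c(1, cov$coma_days, cov$epilepsy)
    sub <- cohort$series[cohort$series$subject_id == id, ]
    ex <- cohort$exits[cohort$exits$subject_id == id, ]
    m <- max(0L, match(ex$last_timepoint, tps) - 2L)
    lik <- 0
    for (k in seq_len(K)) {
      eta_num <- exp(sum(gfull[k, ] * x))
      eta_den <- 0
      for (kk in seq_len(K)) eta_den <- eta_den + exp(sum(gfull[kk, ] * x))
      pi_k <- eta_num / eta_den
      ll <- 0
      for (r in seq_len(nrow(sub))) {
        tp <- sub$timepoint[r]
        t <- if (tp == "admission") 0 else if (tp == "discharge") {
          cov$los_days / 365.25
        } else as.numeric(sub("Y", "", tp))
        mu <- 0
        for (d in seq_len(ncol(params$beta))) {
          mu <- mu + params$beta[k, d] * t^(d - 1)
        }
        s <- if (length(params$sigma) == 1) params$sigma else
          params$sigma[k]
        ll <- ll - 0.5 * log(2 * pi) - log(s) -
          (sub$total[r] - mu)^2 / (2 * s^2)
      }
      if (m > 0) for (j in 1:m) ll <- ll + log(1 - params$hazard[k, j])
      if (ex$reason %in% c("death", "recovery", "opt_out")) {
        ll <- ll + log(params$hazard[k, m + 1])
      }
      lik <- lik + pi_k * exp(ll)
    }
    total <- total + log(lik)
  }
  total
}

brute_accuracy <- function(truth, pred) {
  hits <- 0
  for (i in seq_along(truth)) if (truth[i] == pred[i]) hits <- hits + 1
  hits / length(truth)
}

brute_kappa <- function(truth, pred, K) {
  n <- length(truth)
  po <- brute_accuracy(truth, pred)
  pe <- 0
  for (k in 1:K) {
    row_k <- 0
    col_k <- 0
    for (i in 1:n) {
      if (truth[i] == k) row_k <- row_k + 1
      if (pred[i] == k) col_k <- col_k + 1
    }
    pe <- pe + (row_k / n) * (col_k / n)
  }
  (po - pe) / (1 - pe)
}

brute_precision_macro <- function(truth, pred, K) {
  vals <- c()
  for (k in 1:K) {
    tp <- 0
    fp <- 0
    for (i in seq_along(truth)) {
      if (pred[i] == k && truth[i] == k) tp <- tp + 1
      if (pred[i] == k && truth[i] != k) fp <- fp + 1
    }
    if (tp + fp > 0) vals <- c(vals, tp / (tp + fp))
  }
  mean(vals)
}

brute_auc <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  s <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) s <- s + 1
      if (scores[i] == scores[j]) s <- s + 0.5
    }
  }
  s / (length(pos) * length(neg))
}
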