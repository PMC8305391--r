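#' First-discharge prediction features
#'
#' One feature row per subject using only information available by the day
#' of first discharge: the chosen score at admission, its
#' discharge-minus-admission change, days of coma capped by the
#' event-to-discharge interval (the shorter of the two is used), age at
#' event, gender, etiology dummies, length of stay, acute neurosurgery and
#' in-stay epilepsy. Follow-up assessments never enter; deleting all
#' `Y1`..`Y7` rows leaves the output unchanged. Features are returned on
#' their raw scale; standardization happens inside [fit_classifier()] with
#' training-fold statistics only.
#'
#' @param cohort an `"abi_cohort"`.
#' @param outcome which score feeds the admission level and delta
#'   (default `total`).
#' @return data.frame with `subject_id` and the feature columns.
#' @export
build_features <- function(cohort, outcome = c("total", "selfcare",
                                               "mobility", "cognition")) {
  outcome <- match.arg(outcome)
  validate_cohort(cohort)
  cov <- cohort$covariates
  ser <- cohort$series
  adm <- ser[ser$timepoint == "admission", c("subject_id", outcome)]
  dis <- ser[ser$timepoint == "discharge", c("subject_id", outcome)]
  i_adm <- match(cov$subject_id, adm$subject_id)
  i_dis <- match(cov$subject_id, dis$subject_id)
  if (anyNA(i_adm) || anyNA(i_dis)) {
    stop("missing admission/discharge assessment for subject ",
         cov$subject_id[which(is.na(i_adm) | is.na(i_dis))[1L]],
         call. = FALSE)
  }
  data.frame(
    subject_id = cov$subject_id,
    fim_admission = adm[[outcome]][i_adm],
    fim_delta = dis[[outcome]][i_dis] - adm[[outcome]][i_adm],
    coma_capped = pmin(cov$coma_days, cov$event_to_discharge_days),
    age_at_event = cov$age_at_event_months,
    gender = as.integer(cov$gender == "F"),
    anoxic = as.integer(cov$etiology == "anoxic"),
    other_nontraumatic = as.integer(cov$etiology == "other_nontraumatic"),
    los_days = cov$los_days,
    dcn = as.integer(cov$dcn),
    epilepsy = as.integer(cov$epilepsy),
    stringsAsFactors = FALSE
  )
}

#' Cross-validation plan for the prediction stage
#'
#' The cohort is randomized into two halves; each half is divided into `k`
#' consecutive folds after a seeded shuffle. Every fold is used once as a
#' held-out validation set while the remaining k-1 folds of the same half
#' form the training set.
#'
#' @param k folds per half (default 5).
#' @param seed integer seed.
#' @param stratified stratify the fold assignment by class label
#'   (default FALSE: plain consecutive blocks after the shuffle).
#' @return an object of class `"cv_plan"`.
#' @export
cv_plan <- function(k = 5L, seed = 1L, stratified = FALSE) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = stratified),
            class = "cv_plan")
}

# damped Newton polish of the ridge-penalized softmax likelihood; BFGS
# stops in the flat tail, which matters when near-duplicate features make
# the optimum a narrow ridge
newton_refine_softmax <- function(par, Xs, Ymat, ki, lambda, nll) {
  Kp <- ncol(Ymat)
  p1 <- ncol(Xs)
  f_cur <- nll(par)
  for (it in 1:50) {
    th <- matrix(par, Kp - 1L, p1)
    P <- membership_probs(th, Xs)
    G <- t(P[, -1L, drop = FALSE] - Ymat[, -1L, drop = FALSE]) %*% Xs
    G[, -1L] <- G[, -1L] + lambda * th[, -1L]
    # gradient is laid out like par: (K-1) x p1, column-major
    gvec <- as.vector(G)
    if (max(abs(gvec)) < 1e-10) break
    nb <- (Kp - 1L) * p1
    H <- matrix(0, nb, nb)
    for (a in seq_len(Kp - 1L)) {
      for (b in a:(Kp - 1L)) {
        wab <- P[, a + 1L] * ((a == b) - P[, b + 1L])
        blk <- crossprod(Xs * wab, Xs)
        # par is column-major over the (K-1) x p1 matrix: coefficient
        # (a, j) sits at index (j-1)*(K-1) + a
        ia <- a + (seq_len(p1) - 1L) * (Kp - 1L)
        ib <- b + (seq_len(p1) - 1L) * (Kp - 1L)
        H[ia, ib] <- blk
        H[ib, ia] <- t(blk)
      }
    }
    pen <- rep(c(0, rep(lambda, p1 - 1L)), each = Kp - 1L)
    H <- H + diag(pen + 1e-12, nb)
    step <- tryCatch(solve(H, gvec), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    done <- FALSE
    for (ls in 1:30) {
      cand <- par - alpha * step
      f_new <- nll(cand)
      if (is.finite(f_new) && f_new <= f_cur) {
        par <- cand
        f_cur <- f_new
        done <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!done) break
  }
  par
}

# consecutive-block fold ids for n items (sizes differ by at most 1)
consecutive_folds <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Fit the multinomial logistic trajectory-class classifier
#'
#' Multinomial (softmax) logistic regression with reference class 1,
#' maximized by penalized likelihood with a small ridge term on the
#' standardized, non-intercept coefficients (guaranteeing existence under
#' separation). Continuous features are z-standardized internally; the
#' standardization constants are part of the trained model.
#'
#' @param X data.frame of features (a `subject_id` column is ignored).
#' @param y integer class labels 1..K; at least two classes present.
#' @param lambda ridge penalty on standardized coefficients
#'   (default 1e-4, intercept unpenalized).
#' @param n_classes total number of classes K (defaults to `max(y)`);
#'   classes absent from `y` get zero predicted probability.
#' @return an object of class `"discharge_classifier"`.
#' @export
fit_classifier <- function(X, y, lambda = 1e-4, n_classes = max(y)) {
  X <- as.data.frame(X)
  X$subject_id <- NULL
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("fit_classifier needs at least 2 classes in y", call. = FALSE)
  }
  feature_names <- names(X)
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"

  continuous <- vapply(seq_len(ncol(Xm)),
                       function(j) length(unique(Xm[, j])) > 2L,
                       logical(1L))
  center <- setNames(numeric(ncol(Xm)), feature_names)
  scl <- setNames(rep(1, ncol(Xm)), feature_names)
  for (j in which(continuous)) {
    center[j] <- mean(Xm[, j])
    s <- sd(Xm[, j])
    scl[j] <- if (is.na(s) || s < 1e-12) 1 else s
  }
  Xs <- cbind("(Intercept)" = 1,
              sweep(sweep(Xm, 2L, center), 2L, scl, "/"))

  ki <- match(y, classes)                       # 1..Kp (present classes)
  Kp <- length(classes)
  p1 <- ncol(Xs)
  Ymat <- matrix(0, nrow(Xs), Kp)
  Ymat[cbind(seq_len(nrow(Xs)), ki)] <- 1

  nll <- function(par) {
    th <- matrix(par, Kp - 1L, p1)
    eta <- cbind(0, Xs %*% t(th))
    mx <- apply(eta, 1L, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    -sum(eta[cbind(seq_len(nrow(Xs)), ki)] - lse) +
      lambda / 2 * sum(th[, -1L]^2)
  }
  grad <- function(par) {
    th <- matrix(par, Kp - 1L, p1)
    P <- membership_probs(th, Xs)
    G <- t(P[, -1L, drop = FALSE] - Ymat[, -1L, drop = FALSE]) %*% Xs
    G[, -1L] <- G[, -1L] + lambda * th[, -1L]
    as.vector(G)
  }
  opt <- optim(rep(0, (Kp - 1L) * p1), nll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  if (opt$convergence != 0 && opt$convergence != 1) {
    stop("classifier optimization failed to converge (code ",
         opt$convergence, ")", call. = FALSE)
  }
  par <- newton_refine_softmax(opt$par, Xs, Ymat, ki, lambda, nll)
  theta <- matrix(par, Kp - 1L, p1,
                  dimnames = list(paste0("class", classes[-1L]),
                                  colnames(Xs)))
  structure(list(theta = theta, classes = classes,
                 n_classes = as.integer(n_classes),
                 feature_names = feature_names,
                 center = center, scale = scl, lambda = lambda,
                 nll = opt$value, convergence = opt$convergence),
            class = "discharge_classifier")
}

#' Predict class probabilities and labels
#'
#' Features are bound by name, standardized with the training constants
#' and pushed through the softmax. Classes unseen during training receive
#' probability zero; the label is the class of maximal probability, ties
#' broken toward the lower class index.
#'
#' @param object a `"discharge_classifier"`.
#' @param newdata data.frame containing the training feature columns.
#' @param ... unused.
#' @return list with `probs` (N x K matrix over all `n_classes`) and
#'   `label` (integer vector).
#' @export
predict.discharge_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0L) {
    stop("feature schema mismatch; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Xm <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(Xm) <- "double"
  Xs <- cbind(1, sweep(sweep(Xm, 2L, object$center), 2L, object$scale,
                       "/"))
  Pp <- membership_probs(object$theta, Xs)
  probs <- matrix(0, nrow(Pp), object$n_classes,
                  dimnames = list(NULL,
                                  paste0("p_class",
                                         seq_len(object$n_classes))))
  probs[, object$classes] <- Pp
  list(probs = probs, label = max.col(probs, ties.method = "first"))
}

#' Nested cross-validated out-of-fold predictions
#'
#' Implements the two-half, k-consecutive-fold scheme: subjects are
#' randomized into two halves; within each half every fold is predicted
#' once by a classifier trained on the remaining k-1 folds of that half,
#' with parameters retrained at each iteration and no transfer; the
#' out-of-fold predictions of the two halves are then joined, so
#' evaluation covers the whole dataset with every subject predicted by a
#' model that never saw it.
#'
#' @param features data.frame from [build_features()] (must contain
#'   `subject_id`).
#' @param labels integer class labels 1..K, either named by subject id or
#'   in `features` row order; typically the cross-design clustering labels
#'   used as ground truth.
#' @param plan a [cv_plan()].
#' @param n_classes total number of classes (defaults to `max(labels)`).
#' @param lambda ridge penalty passed to [fit_classifier()].
#' @return data.frame with `subject_id`, `true`, `pred`,
#'   `p_class1`..`p_classK`, `half`, `fold`; one row per subject.
#' @export
nested_cv_predict <- function(features, labels, plan = cv_plan(),
                              n_classes = NULL, lambda = 1e-4) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (!is.null(names(labels))) {
    labels <- labels[features$subject_id]
  }
  labels <- as.integer(labels)
  if (length(labels) != n || anyNA(labels)) {
    stop("labels must cover every subject in features", call. = FALSE)
  }
  if (is.null(n_classes)) n_classes <- max(labels)

  set.seed(plan$seed)
  perm <- sample.int(n)
  nA <- ceiling(n / 2)
  half_of <- integer(n)
  half_of[perm[seq_len(nA)]] <- 1L
  half_of[perm[(nA + 1L):n]] <- 2L

  out <- vector("list", 2L * plan$k)
  oi <- 0L
  for (h in 1:2) {
    idx <- which(half_of == h)
    ord <- sample(idx)                       # seeded shuffle within half
    if (plan$stratified) {
      # interleave classes so consecutive blocks stay balanced
      ord <- ord[order(stats::ave(seq_along(ord), labels[ord],
                                  FUN = seq_along))]
    }
    fold_of <- consecutive_folds(length(ord), plan$k)
    for (f in seq_len(plan$k)) {
      test_idx <- ord[fold_of == f]
      train_idx <- ord[fold_of != f]
      train_classes <- unique(labels[train_idx])
      if (length(setdiff(seq_len(n_classes), train_classes)) > 0L) {
        warning(sprintf(
          "half %d fold %d: class(es) %s absent from training set",
          h, f, paste(setdiff(seq_len(n_classes), train_classes),
                      collapse = ",")), call. = FALSE)
      }
      clf <- fit_classifier(features[train_idx, , drop = FALSE],
                            labels[train_idx], lambda = lambda,
                            n_classes = n_classes)
      pr <- predict(clf, features[test_idx, , drop = FALSE])
      oi <- oi + 1L
      out[[oi]] <- data.frame(subject_id = features$subject_id[test_idx],
                              true = labels[test_idx],
                              pred = pr$label,
                              half = c("A", "B")[h], fold = f,
                              stringsAsFactors = FALSE)
      out[[oi]] <- cbind(out[[oi]], as.data.frame(pr$probs))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$subject_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank features by their contribution to the trained classifier
#'
#' Features are ranked by the maximum absolute standardized coefficient
#' across classes (intercept excluded); ties are broken alphabetically.
#'
#' @param classifier a `"discharge_classifier"`.
#' @return data.frame with `feature`, `importance`, `rank`.
#' @export
feature_importance <- function(classifier) {
  coefs <- classifier$theta[, -1L, drop = FALSE]
  imp <- apply(abs(coefs), 2L, max)
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}
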