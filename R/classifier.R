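## Case-level classification: featurization of latency profiles, four
## classifier families under leave-one-out cross-validation, ROC diagnostics
## and confusion-matrix metrics. MCI is the positive class throughout.

#' Feature vector of a case latency profile
#'
#' Deterministic featurization: the profile's PDF bin densities plus four
#' summary statistics of the window maxima (median, min, max, fraction of
#' negative maxima). All cases in a cohort share the same length because the
#' histogram grid is fixed.
#'
#' @param profile an `smrr_profile` from [case_profile()].
#' @return named numeric vector; attribute `low_coverage` carries the flag.
#' @export
features_from_profile <- function(profile) {
  stopifnot(inherits(profile, "smrr_profile"))
  m <- profile$maxima_ms
  if (length(m) == 0L) stop("features_from_profile: empty profile")
  v <- c(profile$density,
         median = stats::median(m), min = min(m), max = max(m),
         frac_negative = mean(m < 0))
  names(v)[seq_along(profile$density)] <-
    paste0("bin", seq_along(profile$density))
  attr(v, "low_coverage") <- profile$low_coverage
  v
}

#' Classify one case by the plain 70 ms latency-threshold rule
#'
#' Predicts MCI when the median window-maximum latency is at or below
#' `threshold_ms`: short or negative latencies (respiration change leading
#' movement) are the MCI-like pattern. The boundary value itself is assigned
#' to MCI.
#'
#' @param profile an `smrr_profile`.
#' @param threshold_ms decision threshold in ms.
#' @return `"MCI"` or `"NC"`.
#' @export
#' @examples
#' p <- case_profile(c(150, 160, 140))
#' latency_threshold_classify(p)  # "NC"
latency_threshold_classify <- function(profile, threshold_ms = 70) {
  stopifnot(inherits(profile, "smrr_profile"))
  if (length(profile$maxima_ms) == 0L)
    stop("latency_threshold_classify: empty profile")
  if (stats::median(profile$maxima_ms) <= threshold_ms) "MCI" else "NC"
}

#' Classifier specification
#'
#' @param family one of `"neural_network"`, `"gaussian"`, `"kernel"`,
#'   `"latency_threshold"`.
#' @param seed integer seed (mandatory for the neural network, which has
#'   random weight initialization; harmless elsewhere).
#' @param hidden hidden units (neural network).
#' @param decay L2 weight penalty (neural network).
#' @param iters full-batch training iterations (neural network).
#' @param shrinkage covariance shrinkage toward a scaled identity in `[0,1]`
#'   (Gaussian discriminant).
#' @param lambda ridge penalty (kernel method).
#' @param threshold_ms decision threshold (latency-threshold family).
#' @return an `smrr_classifier_spec`.
#' @export
classifier_spec <- function(family = c("neural_network", "gaussian", "kernel",
                                       "latency_threshold"),
                            seed = NULL, hidden = 8L, decay = 1e-2,
                            iters = 400L, shrinkage = 0.5, lambda = 1,
                            threshold_ms = 70) {
  family <- match.arg(family)
  if (family == "neural_network" && is.null(seed))
    stop("classifier_spec: seed is mandatory for the neural network")
  structure(list(family = family, seed = seed, hidden = as.integer(hidden),
                 decay = decay, iters = as.integer(iters),
                 shrinkage = shrinkage, lambda = lambda,
                 threshold_ms = threshold_ms),
            class = "smrr_classifier_spec")
}

## ---- single-hidden-layer tanh network, deterministic full-batch training --
## Smallest architecture that can reproduce the published score separation;
## trained by gradient descent with momentum, no early stopping, weights
## initialized from the spec seed so every fold is reproducible.
nn_train <- function(X, y, spec) {
  n <- nrow(X); p <- ncol(X); h <- spec$hidden
  set.seed(spec$seed)
  W1 <- matrix(stats::rnorm(p * h, 0, 1 / sqrt(p)), p, h)
  b1 <- numeric(h)
  W2 <- stats::rnorm(h, 0, 1 / sqrt(h))
  b2 <- 0
  lr <- 0.05; mom <- 0.9
  vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- 0
  for (it in seq_len(spec$iters)) {
    A <- tanh(sweep(X %*% W1, 2, b1, `+`))
    z <- as.numeric(A %*% W2) + b2
    pr <- 1 / (1 + exp(-z))
    d2 <- (pr - y) / n
    gW2 <- as.numeric(crossprod(A, d2)) + spec$decay * W2
    gb2 <- sum(d2)
    dA <- outer(d2, W2) * (1 - A^2)
    gW1 <- crossprod(X, dA) + spec$decay * W1
    gb1 <- colSums(dA)
    vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
    vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

nn_score <- function(model, X) {
  A <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
  as.numeric(A %*% model$W2) + model$b2
}

## ---- Gaussian discriminant with shared, shrunk covariance ----------------
gda_train <- function(X, y, spec) {
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  Xc <- rbind(sweep(X[y == 1, , drop = FALSE], 2, mu1),
              sweep(X[y == 0, , drop = FALSE], 2, mu0))
  S <- crossprod(Xc) / max(nrow(X) - 2, 1)
  g <- spec$shrinkage
  S <- (1 - g) * S + g * mean(diag(S)) * diag(ncol(X))
  w <- tryCatch(solve(S, mu1 - mu0),
                error = function(e) (mu1 - mu0) / mean(diag(S)))
  list(w = w, c = sum(w * (mu1 + mu0)) / 2)
}

gda_score <- function(model, X) as.numeric(X %*% model$w) - model$c

## ---- RBF-kernel ridge regression on +/-1 labels ---------------------------
## Bandwidth: median pairwise distance among training cases.
rbf_kernel <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

kernel_train <- function(X, y, spec) {
  D <- as.matrix(stats::dist(X))
  sigma <- stats::median(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  K <- rbf_kernel(X, X, sigma)
  alpha <- solve(K + spec$lambda * diag(nrow(X)), 2 * y - 1)
  list(Xtr = X, alpha = alpha, sigma = sigma)
}

kernel_score <- function(model, X)
  as.numeric(rbf_kernel(X, model$Xtr, model$sigma) %*% model$alpha)

## standardization fitted on the training fold only (no leakage); constant
## columns get unit scale
fold_standardizer <- function(Xtr) {
  mu <- colMeans(Xtr)
  sd_ <- apply(Xtr, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, sd_, `/`)
}

#' Leave-one-out cross-validated case scores
#'
#' Each case is scored by a model trained on all other cases; feature
#' standardization is fitted inside each fold. Higher scores mean more
#' MCI-like. Fully deterministic given `spec$seed`.
#'
#' @param features numeric matrix, one row per case (rows named by case).
#' @param labels factor or character vector in `{"MCI", "NC"}`.
#' @param spec an [classifier_spec()].
#' @return data frame with `case_id`, `label`, `score`, `fold`.
#' @export
loocv_scores <- function(features, labels, spec) {
  stopifnot(inherits(spec, "smrr_classifier_spec"))
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (!all(labels %in% c("MCI", "NC")))
    stop("loocv_scores: labels must be MCI or NC")
  if (length(unique(labels)) < 2L)
    stop("loocv_scores: both classes must be present")
  if (min(table(labels)) < 2L)
    stop("loocv_scores: need at least 2 cases per class")
  if (any(!is.finite(X))) stop("loocv_scores: non-finite features")
  y <- as.numeric(labels == "MCI")
  n <- nrow(X)
  train_fun <- switch(spec$family,
    neural_network = nn_train, gaussian = gda_train, kernel = kernel_train,
    latency_threshold = NULL)
  score_fun <- switch(spec$family,
    neural_network = nn_score, gaussian = gda_score, kernel = kernel_score,
    latency_threshold = NULL)
  scores <- numeric(n)
  if (spec$family == "latency_threshold") {
    ## no training: score is the negated median window-maximum latency,
    ## shifted so that score 0 corresponds to the threshold
    if (!"median" %in% colnames(X))
      stop("loocv_scores: latency_threshold needs a 'median' feature")
    scores <- spec$threshold_ms - X[, "median"]
  } else {
    for (i in seq_len(n)) {
      std <- fold_standardizer(X[-i, , drop = FALSE])
      model <- train_fun(std(X[-i, , drop = FALSE]), y[-i], spec)
      scores[i] <- score_fun(model, std(X[i, , drop = FALSE]))
    }
  }
  data.frame(case_id = if (!is.null(rownames(X))) rownames(X) else
               sprintf("case%02d", seq_len(n)),
             label = labels, score = scores, fold = seq_len(n))
}

#' Empirical ROC curve, AUC and operating-point metrics
#'
#' ROC over all score thresholds (predict MCI when `score >= threshold`);
#' AUC by the trapezoid rule; operating threshold maximizing Youden's J
#' (sensitivity + specificity - 1), ties broken toward higher specificity.
#' Sensitivity, specificity, PPV and NPV are reported at that threshold,
#' together with the confusion matrix they derive from.
#'
#' @param scores numeric case scores (higher = more MCI-like).
#' @param labels vector in `{"MCI", "NC"}`.
#' @param operating_rule only `"youden"` is implemented.
#' @return an `smrr_roc`: `curve` (data frame `threshold`, `fpr`, `tpr`),
#'   `auc`, `threshold`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `confusion` (an `smrr_confusion`), `degenerate` flag.
#' @export
roc_metrics <- function(scores, labels, operating_rule = "youden") {
  stopifnot(operating_rule == "youden")
  labels <- as.character(labels)
  if (!all(labels %in% c("MCI", "NC"))) stop("roc_metrics: bad labels")
  pos <- labels == "MCI"
  if (!any(pos) || all(pos)) stop("roc_metrics: both classes must be present")
  degenerate <- length(unique(scores)) == 1L
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) mean(scores[pos] >= th), 0)
  fpr <- vapply(thr, function(th) mean(scores[!pos] >= th), 0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]  # ties -> higher specificity
  th <- thr[best]
  pred <- ifelse(scores >= th, "MCI", "NC")
  cm <- confusion(pred, labels)
  structure(list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, threshold = th,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 ppv = cm$ppv, npv = cm$npv, confusion = cm,
                 degenerate = degenerate),
            class = "smrr_roc")
}

#' @export
print.smrr_roc <- function(x, ...) {
  cat(sprintf("<smrr_roc> AUC %.3f | thr %.3g | sens %.2f spec %.2f ppv %s npv %s%s\n",
              x$auc, x$threshold, x$sensitivity, x$specificity,
              format(x$ppv, digits = 2), format(x$npv, digits = 2),
              if (x$degenerate) " (degenerate scores)" else ""))
  invisible(x)
}

#' Confusion matrix and derived metrics (MCI = positive class)
#'
#' Ratios with a zero denominator are reported as `NA` (undefined), never
#' as 0.
#'
#' @param predicted,truth aligned label vectors in `{"MCI", "NC"}`.
#' @return an `smrr_confusion`: `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
#' @examples
#' confusion(c("MCI", "NC", "NC", "MCI"), c("MCI", "MCI", "NC", "NC"))
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("confusion: length mismatch")
  if (!all(c(predicted, truth) %in% c("MCI", "NC")))
    stop("confusion: labels must be MCI or NC")
  tp <- sum(predicted == "MCI" & truth == "MCI")
  tn <- sum(predicted == "NC" & truth == "NC")
  fp <- sum(predicted == "MCI" & truth == "NC")
  fn <- sum(predicted == "NC" & truth == "MCI")
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn)),
            class = "smrr_confusion")
}

#' @export
print.smrr_confusion <- function(x, ...) {
  cat(sprintf("<smrr_confusion> tp %d fp %d / fn %d tn %d | sens %s spec %s ppv %s npv %s\n",
              x$tp, x$fp, x$fn, x$tn,
              format(x$sensitivity, digits = 3), format(x$specificity, digits = 3),
              format(x$ppv, digits = 3), format(x$npv, digits = 3)))
  invisible(x)
}
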