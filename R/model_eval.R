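#' Train an RBF-kernel support vector machine
#'
#' Features are z-scored with statistics learned from the training data
#' (stored in the model so prediction applies the same transform), then a
#' soft-margin SVM with Gaussian kernel
#' \eqn{K(x, x') = \exp(-\gamma \|x - x'\|^2)} is fitted via the libsvm
#' solver in \pkg{e1071}. The returned model carries the support vectors,
#' the signed dual weights \eqn{\alpha_i y_i} and the bias, oriented so a
#' positive decision value means "malignant".
#'
#' @param X Numeric feature matrix (n x d).
#' @param y Labels, `"benign"` / `"malignant"`, both present.
#' @param C Box constraint, > 0.
#' @param gamma Kernel width, > 0; default `1 / d` on the z-scored features.
#' @param seed Integer seed (libsvm's shrinking heuristics are deterministic,
#'   but the seed also fixes any internal sampling).
#' @return Object of class `svm_model`: `support_vectors` (in z-scored
#'   space), `alphas`, `bias`, `gamma`, `C`, `scaling` (`center`, `scale`),
#'   `levels`.
#' @export
train_svm <- function(X, y, C = 1, gamma = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) {
    stop_invalid("training data must contain both classes")
  }
  if (C <= 0) stop_invalid("C must be > 0")
  ctr <- colMeans(X)
  # population (1/n) sd so that duplicating every row leaves the learned
  # transform, and hence the decision function, unchanged
  scl <- sqrt(colMeans(X^2) - ctr^2)
  scl[scl <= 0 | !is.finite(scl)] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (gamma <= 0) stop_invalid("gamma must be > 0")
  yf <- factor(y, levels = c("malignant", "benign"))
  fit <- with_seed(seed, e1071::svm(Z, yf, type = "C-classification",
                                    kernel = "radial", cost = C,
                                    gamma = gamma, scale = FALSE,
                                    tolerance = 1e-7))
  alphas <- as.numeric(fit$coefs)   # already alpha_i * y_i w.r.t. libsvm's + class
  bias <- -fit$rho
  # libsvm orients decision values so positive means the class named first
  # in the "A/B" column name of its decision values; flip the stored
  # weights if needed so positive always means "malignant".
  dv <- stats::predict(fit, Z[1, , drop = FALSE], decision.values = TRUE)
  orient <- strsplit(colnames(attr(dv, "decision.values"))[1], "/")[[1]][1]
  if (orient != "malignant") {
    alphas <- -alphas
    bias <- -bias
  }
  structure(
    list(support_vectors = as.matrix(fit$SV), alphas = alphas, bias = bias,
         gamma = gamma, C = C,
         scaling = list(center = ctr, scale = scl),
         levels = c("benign", "malignant")),
    class = "svm_model"
  )
}

#' SVM decision value
#'
#' Evaluates the kernel-expansion decision function
#' \eqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b} directly from the stored
#' support vectors; the predicted label is the sign of \eqn{f}
#' (positive = malignant).
#'
#' @param model An `svm_model`.
#' @param x A feature vector of length d, or an n x d matrix.
#' @return Numeric decision value(s).
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  d <- ncol(model$support_vectors)
  if (ncol(x) != d) {
    stop_invalid("feature dimension mismatch: model expects %d, got %d", d, ncol(x))
  }
  Z <- scale(x, center = model$scaling$center, scale = model$scaling$scale)
  SV <- model$support_vectors
  # squared distances n x s
  D2 <- outer(rowSums(Z^2), rowSums(SV^2), `+`) - 2 * Z %*% t(SV)
  D2[D2 < 0] <- 0
  as.numeric(exp(-model$gamma * D2) %*% model$alphas + model$bias)
}

#' Save / load an SVM model as portable JSON
#'
#' Serializes the complete kernel expansion (support vectors, signed dual
#' weights, bias, gamma, C, and the z-scoring parameters), so a model can
#' be reloaded and evaluated elsewhere without the training data.
#'
#' @param model An `svm_model`.
#' @param path JSON file path.
#' @return `write_svm_model`: `path`, invisibly. `read_svm_model`: the
#'   restored `svm_model`.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  jsonlite::write_json(
    list(support_vectors = model$support_vectors, alphas = model$alphas,
         bias = model$bias, gamma = model$gamma, C = model$C,
         scaling = model$scaling, levels = model$levels),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(support_vectors = as.matrix(raw$support_vectors),
         alphas = as.numeric(raw$alphas), bias = raw$bias,
         gamma = raw$gamma, C = raw$C,
         scaling = list(center = as.numeric(raw$scaling$center),
                        scale = as.numeric(raw$scaling$scale)),
         levels = raw$levels),
    class = "svm_model"
  )
}

#' Predict class labels from an SVM model
#' @param model An `svm_model`.
#' @param x Feature vector or matrix.
#' @return Character vector of `"benign"` / `"malignant"`.
#' @export
predict_label <- function(model, x) {
  ifelse(decision_value(model, x) > 0, "malignant", "benign")
}

# Stratified fold assignment. grouping = "roi": each row assigned
# independently, class proportions preserved within one row per fold.
# grouping = "patient": all rows of a patient share a fold; patients are
# stratified by class.
assign_folds <- function(y, k, grouping = c("patient", "roi"),
                         patient_id = NULL, seed = 1L) {
  grouping <- match.arg(grouping)
  n <- length(y)
  if (k < 2L) stop_invalid("k must be >= 2")
  fold <- integer(n)
  with_seed(seed, {
    if (grouping == "roi") {
      if (k > n) stop_invalid("k = %d exceeds the %d rows", k, n)
      # strata fill folds through one global rotating counter, so k up to
      # n (leave-one-out) still yields k non-empty folds
      start <- 0L
      for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
        start <- start + length(idx)
      }
    } else {
      if (is.null(patient_id)) stop_invalid("patient grouping needs patient_id")
      pts <- unique(data.frame(patient_id = patient_id, y = y,
                               stringsAsFactors = FALSE))
      if (anyDuplicated(pts$patient_id)) {
        stop_invalid("a patient appears with more than one class label")
      }
      if (k > nrow(pts)) stop_invalid("k = %d exceeds the %d patients", k, nrow(pts))
      pfold <- stats::setNames(integer(nrow(pts)), pts$patient_id)
      start <- 0L
      for (cls in unique(pts$y)) {
        idx <- which(pts$y == cls)
        idx <- idx[sample.int(length(idx))]
        pfold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
        start <- start + length(idx)
      }
      fold <- pfold[as.character(patient_id)]
    }
  })
  as.integer(fold)
}

#' Stratified k-fold cross-validation of the RBF-SVM
#'
#' Splits rows into `k` stratified folds (with `grouping = "patient"`, the
#' default, all ROIs of a patient stay in one fold, so patient-level
#' leakage across folds is impossible), trains on k-1 folds and predicts
#' the held-out fold, cycling through all folds. Fold assignment and
#' training are deterministic under the seed.
#'
#' @param X Feature matrix; `y` labels; `patient_id` required for patient
#'   grouping.
#' @param k Number of folds (default 10).
#' @param grouping `"patient"` or `"roi"`.
#' @param C,gamma SVM hyperparameters (see [train_svm()]).
#' @param seed Integer seed.
#' @return List of class `cv_result`: `fold_accuracies`, `mean_accuracy`,
#'   `fold` (per-row assignment), `predicted` (held-out label per row),
#'   `decision` (held-out decision value per row).
#' @export
kfold_cv <- function(X, y, k = 10L, grouping = c("patient", "roi"),
                     patient_id = NULL, C = 1, gamma = NULL, seed = 1L) {
  grouping <- match.arg(grouping)
  X <- as.matrix(X)
  y <- as.character(y)
  fold <- assign_folds(y, k, grouping, patient_id,
                       seed = derive_seed(seed, "folds"))
  predicted <- character(length(y))
  decision <- numeric(length(y))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    if (!any(te)) { acc[f] <- NA_real_; next }
    m <- train_svm(X[!te, , drop = FALSE], y[!te], C = C, gamma = gamma,
                   seed = derive_seed(seed, sprintf("fit%d", f)))
    dv <- decision_value(m, X[te, , drop = FALSE])
    predicted[te] <- ifelse(dv > 0, "malignant", "benign")
    decision[te] <- dv
    acc[f] <- mean(predicted[te] == y[te])
  }
  structure(
    list(fold_accuracies = acc, mean_accuracy = mean(acc, na.rm = TRUE),
         fold = fold, predicted = predicted, decision = decision),
    class = "cv_result"
  )
}

#' Patient-level malignance rate
#'
#' The fraction of a patient's ROIs that the classifier calls malignant;
#' the continuous per-patient score used for the ROC analysis.
#'
#' @param predictions Character vector of per-ROI predicted labels for one
#'   patient.
#' @return A number in \[0, 1\].
#' @export
malignance_rate <- function(predictions) {
  if (length(predictions) == 0L) {
    stop_invalid("malignance rate needs at least one ROI prediction")
  }
  mean(predictions == "malignant")
}

#' ROC curve, AUC and Mann-Whitney p-value
#'
#' Sweeps a threshold over the unique scores (predicting positive when
#' `score >= threshold`), traces the ROC curve, and integrates it by the
#' trapezoid rule. With ties this equals the Mann-Whitney statistic
#' \eqn{U / (n_+ n_-)} with half credit for tied pairs. `auc_p` is the
#' two-sided normal-approximation Mann-Whitney p-value (tie-corrected
#' variance) for the null AUC = 0.5.
#'
#' @param scores Numeric scores (higher = more malignant).
#' @param labels `"benign"` / `"malignant"` per score; both present.
#' @return List of class `roc_result`: `roc` (data.frame `threshold`,
#'   `fpr`, `tpr`), `auc`, `auc_p`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "malignant"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_invalid("both classes must be present for a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)

  # normal-approximation Mann-Whitney test with tie correction
  N <- n1 + n0
  U <- auc * n1 * n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- n1 * n0 / 12 * ((N + 1) - tie_term)
  p <- if (varU <= 0) 1 else 2 * stats::pnorm(-abs(U - n1 * n0 / 2) / sqrt(varU))
  structure(list(roc = roc, auc = auc, auc_p = p), class = "roc_result")
}

#' Pearson chi-square test for a 2 x 2 contingency table
#'
#' Pearson's statistic without continuity correction (the convention that
#' reproduces the study-style demographic comparisons), df = 1.
#'
#' @param tab 2 x 2 matrix of non-negative counts with positive margins.
#' @return List: `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop_invalid("a 2 x 2 table is required")
  if (any(tab < 0)) stop_invalid("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_invalid("all margins must be positive")
  }
  # small-expected-count warnings are suppressed: the Pearson statistic is
  # the deliberate convention here regardless of cell size
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Longitudinal change of a texture feature
#'
#' For every patient with at least two scans, averages the feature over
#' each scan's ROIs and reports `delta = last - first`; patients with a
#' single scan are excluded with a warning. The default feature is the
#' mean co-occurrence standard deviation over the 32 detail sub-bands,
#' the statistic whose benign-vs-malignant drift the longitudinal
#' analysis is designed to detect.
#'
#' @param features Data frame with columns `patient_id`, `scan_index`,
#'   `label`, and feature columns.
#' @param feature_name Either the name of one feature column or
#'   `"detail_std_dev"` (default): the row mean of all `s2_*_std_dev`
#'   columns.
#' @return List of class `feature_change`: `per_patient` (data.frame
#'   `patient_id`, `label`, `first_value`, `last_value`, `delta`) and
#'   `by_class` (data.frame `label`, `mean_delta`, `ci_lo`, `ci_hi`, `n`).
#' @export
feature_change <- function(features, feature_name = "detail_std_dev") {
  stopifnot(all(c("patient_id", "scan_index", "label") %in% names(features)))
  if (feature_name == "detail_std_dev") {
    cols <- grep("^s2_w[0-9]+_std_dev$", names(features), value = TRUE)
    if (length(cols) == 0L) stop_invalid("no detail-band std_dev columns found")
    val <- rowMeans(features[, cols, drop = FALSE])
  } else {
    if (!feature_name %in% names(features)) {
      stop_invalid("feature column '%s' not found", feature_name)
    }
    val <- features[[feature_name]]
  }
  df <- data.frame(patient_id = features$patient_id,
                   scan_index = features$scan_index,
                   label = features$label, value = val,
                   stringsAsFactors = FALSE)
  per_scan <- stats::aggregate(value ~ patient_id + scan_index + label,
                               data = df, FUN = mean)
  rows <- list()
  for (pid in unique(per_scan$patient_id)) {
    sub <- per_scan[per_scan$patient_id == pid, ]
    sub <- sub[order(sub$scan_index), ]
    if (nrow(sub) < 2L) {
      warning(sprintf("patient %s has a single scan; excluded from the change analysis", pid),
              call. = FALSE)
      next
    }
    rows[[pid]] <- data.frame(
      patient_id = pid, label = sub$label[1],
      first_value = sub$value[1], last_value = sub$value[nrow(sub)],
      delta = sub$value[nrow(sub)] - sub$value[1],
      stringsAsFactors = FALSE
    )
  }
  per_patient <- do.call(rbind, rows)
  if (is.null(per_patient)) stop_invalid("no patient has two or more scans")
  by_class <- do.call(rbind, lapply(split(per_patient, per_patient$label), function(g) {
    n <- nrow(g)
    mu <- mean(g$delta)
    se <- if (n > 1) stats::sd(g$delta) / sqrt(n) else 0
    tq <- if (n > 1) stats::qt(0.975, n - 1) else 0
    data.frame(label = g$label[1], mean_delta = mu,
               ci_lo = mu - tq * se, ci_hi = mu + tq * se, n = n,
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  structure(list(per_patient = per_patient, by_class = by_class,
                 feature_name = feature_name),
            class = "feature_change")
}
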