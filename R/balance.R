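# k nearest neighbours by Euclidean distance, self excluded, computed in
# row blocks so the full distance matrix is never materialized for large m.
# Ties broken by row index (stable), so results are deterministic.
knn_indices <- function(X, k, block = 512L) {
  m <- nrow(X)
  k <- min(k, m - 1L)
  sq <- rowSums(X^2)
  out <- matrix(0L, m, k)
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(start + block - 1L, m)
    # squared distances block x m via the expansion ||a-b||^2
    D <- outer(sq[idx], sq, `+`) - 2 * X[idx, , drop = FALSE] %*% t(X)
    for (ii in seq_along(idx)) {
      d <- D[ii, ]
      d[idx[ii]] <- Inf
      out[idx[ii], ] <- order(d)[seq_len(k)]
    }
  }
  out
}

#' SMOTE synthetic over-sampling of a minority class
#'
#' For every minority row, generates `rate_percent / 100` synthetic rows:
#' one of its `k` Euclidean nearest minority neighbours is chosen at
#' random and the synthetic point is placed uniformly at random on the
#' segment between the row and that neighbour
#' (`x + u * (neighbour - x)`, `u ~ U(0, 1)`).
#'
#' @param X_min Numeric matrix of minority-class rows (m x d), m >= 2.
#' @param rate_percent Over-sampling rate, a positive multiple of 100.
#' @param k Number of nearest neighbours (default 5; capped at m - 1).
#' @param seed Integer seed; the output is deterministic given it.
#' @return Matrix of `(rate_percent / 100) * m` synthetic rows, with the
#'   same columns as `X_min`.
#' @export
smote <- function(X_min, rate_percent, k = 5L, seed = 1L) {
  X_min <- as.matrix(X_min)
  m <- nrow(X_min)
  if (m < 2L) stop_invalid("cannot interpolate: need at least 2 minority rows, got %d", m)
  if (k < 1L) stop_invalid("k must be >= 1")
  if (length(rate_percent) != 1L || is.na(rate_percent) ||
      rate_percent <= 0 || rate_percent %% 100 != 0) {
    stop_invalid("rate_percent must be a positive multiple of 100")
  }
  reps <- as.integer(rate_percent / 100)
  nn <- knn_indices(X_min, k)
  kk <- ncol(nn)
  with_seed(seed, {
    n_syn <- m * reps
    base_idx <- rep(seq_len(m), each = reps)
    pick <- sample.int(kk, n_syn, replace = TRUE)
    nbr_idx <- nn[cbind(base_idx, pick)]
    u <- stats::runif(n_syn)
    syn <- X_min[base_idx, , drop = FALSE] +
      u * (X_min[nbr_idx, , drop = FALSE] - X_min[base_idx, , drop = FALSE])
    dimnames(syn) <- list(NULL, colnames(X_min))
    syn
  })
}

#' Balance a labelled feature table by SMOTE over-sampling
#'
#' Augments one or both classes with synthetic rows until the requested
#' per-class count is reached. For each class needing `n_extra` rows the
#' smallest sufficient rate (a multiple of 100%) is used and the surplus
#' synthetic rows are dropped by seeded uniform subsampling. Original rows
#' are never modified or removed; synthetic rows are flagged in the
#' `provenance` field.
#'
#' @param X Numeric feature matrix (n x d).
#' @param y Character/factor labels, `"benign"` / `"malignant"`, both present.
#' @param target `"match_majority"` (default: bring the minority up to the
#'   majority count) or a single number: the target count for **both**
#'   classes (each class below it is over-sampled).
#' @param k SMOTE neighbourhood size.
#' @param seed Integer seed.
#' @return List of class `labeled_table`: `X`, `y`, `provenance`
#'   (`"original"` / `"synthetic"` per row).
#' @export
balance_dataset <- function(X, y, target = "match_majority", k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  counts <- table(y)
  if (length(counts) < 2L) {
    stop_invalid("both classes must be present, got only: %s",
                 paste(names(counts), collapse = ", "))
  }
  targets <- if (identical(target, "match_majority")) {
    stats::setNames(rep(max(counts), length(counts)), names(counts))
  } else {
    if (!is.numeric(target) || length(target) != 1L || is.na(target) || target < 1) {
      stop_invalid("target must be 'match_majority' or a single positive count")
    }
    stats::setNames(rep(as.numeric(target), length(counts)), names(counts))
  }
  X_out <- X
  y_out <- y
  prov <- rep("original", nrow(X))
  for (cls in names(counts)) {
    n_have <- as.integer(counts[[cls]])
    n_extra <- as.integer(targets[[cls]]) - n_have
    if (n_extra <= 0L) next
    rate <- 100L * as.integer(ceiling(n_extra / n_have))
    syn <- smote(X[y == cls, , drop = FALSE], rate, k = k,
                 seed = derive_seed(seed, paste0("smote_", cls)))
    if (nrow(syn) > n_extra) {
      keep <- with_seed(derive_seed(seed, paste0("subsample_", cls)),
                        sample.int(nrow(syn), n_extra))
      syn <- syn[sort(keep), , drop = FALSE]
    }
    X_out <- rbind(X_out, syn)
    y_out <- c(y_out, rep(cls, nrow(syn)))
    prov <- c(prov, rep("synthetic", nrow(syn)))
  }
  structure(list(X = X_out, y = y_out, provenance = prov),
            class = "labeled_table")
}
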