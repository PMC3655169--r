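#' Quantize a coefficient grid to discrete gray levels
#'
#' Two binning modes. With `bin_width = NULL` (relative mode): equal-width
#' bins between the grid's minimum and maximum (computed within `mask`
#' when one is given); a constant grid maps every pixel to level 1. With a
#' numeric `bin_width` (absolute mode): bins of that fixed width centred
#' on the (masked) median, clipped to `1..Ng`; this mode preserves the
#' grid's amplitude in the level distribution, which relative binning
#' normalizes away.
#'
#' @param coeffs Numeric matrix.
#' @param Ng Number of gray levels, >= 2.
#' @param mask Optional 0/1 matrix; when given, bin placement is computed
#'   from masked pixels only (all pixels are still assigned a level).
#' @param bin_width Optional positive bin width for absolute-mode binning.
#' @return Integer matrix with values in `1..Ng`.
#' @export
quantize <- function(coeffs, Ng = 64L, mask = NULL, bin_width = NULL) {
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop_invalid("Ng must be >= 2, got %d", Ng)
  stopifnot(is.matrix(coeffs), is.numeric(coeffs))
  vals <- if (is.null(mask)) coeffs else coeffs[mask != 0]
  if (!is.null(bin_width)) {
    if (bin_width <= 0) stop_invalid("bin_width must be > 0")
    ctr <- stats::median(vals)
    lv <- floor((coeffs - ctr) / bin_width) + Ng %/% 2L + 1L
    lv <- pmin(pmax(lv, 1L), Ng)
    return(matrix(as.integer(lv), nrow(coeffs), ncol(coeffs)))
  }
  mn <- min(vals); mx <- max(vals)
  if (mx <= mn) {
    lv <- matrix(1L, nrow(coeffs), ncol(coeffs))
    return(lv)
  }
  edges <- seq(mn, mx, length.out = Ng + 1L)
  lv <- findInterval(coeffs, edges, all.inside = TRUE)
  matrix(as.integer(lv), nrow(coeffs), ncol(coeffs))
}

# Morphological erosion of a binary mask (4-neighbour structuring element,
# `iterations` passes). Used to keep co-occurrence pairs away from the
# nodule boundary, whose step response otherwise dominates the band
# statistics.
erode_mask <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    m <- mask
    m[-1, ] <- m[-1, ] * mask[-nrow(mask), ]
    m[-nrow(m), ] <- m[-nrow(m), ] * mask[-1, ]
    m[, -1] <- m[, -1] * mask[, -ncol(mask)]
    m[, -ncol(m)] <- m[, -ncol(m)] * mask[, -1]
    mask <- m
  }
  mask
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered level pairs at each offset and its reverse (so the matrix
#' is symmetric), pooled over all offsets, normalized to sum to 1.
#'
#' @param levels Integer matrix with values in `1..Ng`.
#' @param Ng Number of gray levels.
#' @param offsets List of integer pairs `c(dr, dc)`; default the single
#'   horizontal offset `(0, 1)`.
#' @param mask Optional 0/1 matrix: only pairs whose two pixels both lie
#'   inside the mask are counted.
#' @return An object of class `cooccurrence_matrix`: list with `p`
#'   (Ng x Ng probability matrix), `Ng`, `offsets`.
#' @export
cooccurrence <- function(levels, Ng, offsets = list(c(0L, 1L)), mask = NULL) {
  stopifnot(is.matrix(levels), length(levels) > 0L)
  Ng <- as.integer(Ng)
  if (length(levels) == 0L) stop_invalid("empty level grid")
  if (min(levels) < 1L || max(levels) > Ng) {
    stop_invalid("levels must lie in 1..Ng")
  }
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- numeric(Ng * Ng)
  npairs <- 0L
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(nr - abs(dr)); cols <- seq_len(nc - abs(dc))
    if (length(rows) == 0L || length(cols) == 0L) next
    r1 <- if (dr >= 0) rows else rows + abs(dr)
    c1 <- if (dc >= 0) cols else cols + abs(dc)
    a <- levels[r1, c1, drop = FALSE]
    b <- levels[r1 + dr, c1 + dc, drop = FALSE]
    if (!is.null(mask)) {
      keep <- mask[r1, c1, drop = FALSE] != 0 &
        mask[r1 + dr, c1 + dc, drop = FALSE] != 0
      a <- a[keep]; b <- b[keep]
      if (length(a) == 0L) next
    }
    idx <- (a - 1L) * Ng + b
    tb <- tabulate(idx, nbins = Ng * Ng)
    counts <- counts + tb
    # reverse direction: count (b, a) as well -> symmetric matrix
    counts <- counts + tabulate((b - 1L) * Ng + a, nbins = Ng * Ng)
    npairs <- npairs + 2L * length(a)
  }
  if (npairs == 0L) {
    stop_invalid("no co-occurring pairs exist at any offset (grid too small)")
  }
  p <- matrix(counts / npairs, Ng, Ng, byrow = TRUE)  # counts indexed (a-1)*Ng+b row-major
  structure(list(p = p, Ng = Ng, offsets = offsets), class = "cooccurrence_matrix")
}

#' Names of the 14 co-occurrence texture statistics, in canonical order
#' @return Character vector of length 14.
#' @export
texture_feature_names <- function() {
  c("entropy", "mean", "correlation", "energy", "homogeneity",
    "std_dev", "max_prob", "idm", "cluster_tendency", "inertia",
    "sum_mean", "diff_mean", "sum_entropy", "diff_entropy")
}

# cached per-Ng index structures for the feature formulas
.texture_cache <- new.env(parent = emptyenv())

texture_indices <- function(Ng) {
  key <- sprintf("i_%d", Ng)
  got <- .texture_cache[[key]]
  if (!is.null(got)) return(got)
  I <- matrix(rep(seq_len(Ng), Ng), Ng, Ng)       # row index i
  J <- t(I)                                        # column index j
  out <- list(
    I = I, J = J,
    absdiff = abs(I - J), diff2 = (I - J)^2,
    sumg = as.vector(I + J),                       # groups for p_{x+y}
    diffg = as.vector(abs(I - J)) + 1L             # groups for p_{x-y}
  )
  assign(key, out, envir = .texture_cache)
  out
}

#' The 14 co-occurrence texture statistics
#'
#' Computes, from a symmetric normalized co-occurrence matrix `P` with
#' marginal mean/sd `mu`, `sigma` (symmetry implies the row and column
#' marginals agree): entropy (bits), mean, correlation (0 by convention
#' when sigma is 0), energy, homogeneity, standard deviation, maximum
#' probability, inverse difference moment, cluster tendency, inertia,
#' sum-mean, difference-mean, sum-entropy, and difference-entropy.
#' Logarithms are base 2 with the 0 log 0 = 0 convention.
#'
#' @param P A `cooccurrence_matrix` or a plain Ng x Ng probability matrix.
#' @return Named numeric vector of length 14 (see [texture_feature_names()]).
#' @export
texture_features_14 <- function(P) {
  p <- if (inherits(P, "cooccurrence_matrix")) P$p else P
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  Ng <- nrow(p)
  ix <- texture_indices(Ng)
  px <- rowSums(p)
  mu <- sum(seq_len(Ng) * px)
  sig2 <- sum((seq_len(Ng) - mu)^2 * px)
  sig <- sqrt(sig2)

  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  corr <- if (sig2 > 0) sum((ix$I - mu) * (ix$J - mu) * p) / sig2 else 0
  energy <- sum(p * p)
  homog <- sum(p / (1 + ix$absdiff))
  idm <- sum(p / (1 + ix$diff2))
  cluster <- sum((ix$I + ix$J - 2 * mu)^2 * p)
  inertia <- sum(ix$diff2 * p)
  sum_mean <- sum((ix$I + ix$J) * p)
  diff_mean <- sum(ix$absdiff * p)
  pv <- as.vector(p)
  psum <- unname(rowsum(pv, ix$sumg, reorder = FALSE))
  pdiff <- unname(rowsum(pv, ix$diffg, reorder = FALSE))
  sum_entropy <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  diff_entropy <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))

  c(entropy = entropy, mean = mu, correlation = corr, energy = energy,
    homogeneity = homog, std_dev = sig, max_prob = max(p), idm = idm,
    cluster_tendency = cluster, inertia = inertia, sum_mean = sum_mean,
    diff_mean = diff_mean, sum_entropy = sum_entropy,
    diff_entropy = diff_entropy)
}

# the four standard offsets (0 deg, 90 deg, 45 deg, 135 deg)
default_offsets <- function() {
  list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
}

# TRUE iff at least one pixel pair at one of the standard offsets lies
# entirely inside the mask
has_offset_pairs <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (off in default_offsets()) {
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(nr - abs(dr)); cols <- seq_len(nc - abs(dc))
    if (length(rows) == 0L || length(cols) == 0L) next
    r1 <- if (dr >= 0) rows else rows + abs(dr)
    c1 <- if (dc >= 0) cols else cols + abs(dc)
    if (any(mask[r1, c1] != 0 & mask[r1 + dr, c1 + dc] != 0)) return(TRUE)
  }
  FALSE
}

# stable sub-band name prefixes: s1_w01 (coarse), s2_w01..s2_w32 (detail
# wedges CCW from angle 0), s3_w01 (fine)
subband_name_prefixes <- function(cfg = curvelet_config()) {
  n_w <- cfg$n_detail_wedges
  c("s1_w01", sprintf("s2_w%02d", seq_len(n_w)), "s3_w01")
}

#' Default quantization bin widths per scale
#'
#' Absolute bin widths (intensity units) used when quantizing sub-band
#' coefficients, sized so that 64 levels cover the within-nodule
#' coefficient spread each scale exhibits under the synthetic-cohort
#' intensity scale (nodule base intensity of order 100).
#'
#' @return Named numeric vector with entries `coarse`, `detail`, `fine`.
#' @export
default_bin_widths <- function() {
  c(coarse = 2.5, detail = 0.2, fine = 1.25)
}

#' Curvelet texture vector for one ROI
#'
#' Decomposes a (masked) ROI image into its 34 sub-bands, and for each
#' sub-band quantizes the real coefficients to `Ng` levels, builds a
#' symmetric co-occurrence matrix at each of the four standard offsets
#' ((0,1), (1,0), (1,1), (1,-1)), computes the 14 texture statistics per
#' offset, and averages them over the offsets. The 34 x 14 = 476 values
#' are concatenated in sub-band order (coarse, detail wedges 1..32, fine)
#' with stable names `s{scale}_w{wedge}_{feature}`.
#'
#' When the input is a [roi_image()], quantization is centred on the
#' within-mask coefficient distribution and only pixel pairs lying inside
#' the mask (eroded by `mask_erosion` pixels, so the nodule boundary's
#' step response does not dominate) are counted; by default bins have the
#' fixed per-scale widths of [default_bin_widths()], so a band's overall
#' coefficient amplitude — the quantity that grows with nodule texture
#' heterogeneity — is reflected in the features rather than normalized
#' away. Pass `bin_widths = NULL` for amplitude-invariant per-band
#' min-max binning.
#'
#' @param image A `roi_image` (see [roi_image()]) or a plain numeric matrix
#'   (no mask: whole-grid statistics).
#' @param cfg A [curvelet_config()].
#' @param Ng Gray levels for quantization (default 64).
#' @param magnitude If TRUE, features are computed on absolute coefficient
#'   values instead of the raw real coefficients.
#' @param bin_widths Named per-scale bin widths (`coarse`, `detail`,
#'   `fine`), or `NULL` for per-band min-max binning.
#' @param mask_erosion Erosion radius (pixels) applied to the mask before
#'   pair counting; ignored for plain-matrix input. If erosion empties the
#'   mask, the un-eroded mask is used.
#' @return Named numeric vector of length `subband_count(cfg) * 14`
#'   (476 under the default configuration).
#' @export
roi_texture_vector <- function(image, cfg = curvelet_config(), Ng = 64L,
                               magnitude = FALSE,
                               bin_widths = default_bin_widths(),
                               mask_erosion = 3L) {
  is_roi <- inherits(image, "roi_image")
  px <- if (is_roi) image$pixels else image
  mask <- NULL
  if (is_roi) {
    mask <- erode_mask(image$mask, mask_erosion)
    # a ragged mask can erode into isolated pixels with no co-occurring
    # pairs left; fall back to the un-eroded mask in that case
    if (!has_offset_pairs(mask)) mask <- image$mask
    mask <- pad_image(mask, cfg$pad_to)
  }
  d <- fdct_forward(px, cfg)
  offs <- default_offsets()
  fnames <- texture_feature_names()
  prefixes <- subband_name_prefixes(cfg)
  out <- numeric(0)
  for (j in seq_along(d$subbands)) {
    co <- d$subbands[[j]]$coeff
    if (magnitude) co <- abs(co)
    bw <- if (is.null(bin_widths)) NULL else {
      unname(bin_widths[[d$subbands[[j]]$scale_id]])
    }
    lv <- quantize(co, Ng, mask = mask, bin_width = bw)
    acc <- numeric(length(fnames))
    for (off in offs) {
      acc <- acc + texture_features_14(cooccurrence(lv, Ng, list(off), mask = mask))
    }
    feats <- acc / length(offs)
    names(feats) <- paste(prefixes[j], fnames, sep = "_")
    out <- c(out, feats)
  }
  out
}

#' Names of the 12 clinical covariates appended to the texture block
#' @return Character vector: age, sex, smoking, then the 9 morphology names.
#' @export
clinical_feature_names <- function() {
  c("age", "sex", "smoking",
    "substantial_change", "density", "spicule", "cavern", "vacuole",
    "lobulation", "calcification", "ground_glass", "area_class")
}

#' Assemble the full 488-dimensional model input
#'
#' Appends the three demographic covariates (age in years, sex and smoking
#' coded 0/1) and the nine morphological covariates to a 476-entry texture
#' vector, giving the 488 model inputs.
#'
#' @param texture Named numeric vector of length 476 (34 sub-bands x 14).
#' @param demographics Numeric vector or list with elements `age`, `sex`,
#'   `smoking`.
#' @param morphology Numeric vector of the 9 morphology values, in the order
#'   of `clinical_feature_names()[-(1:3)]`.
#' @return Named numeric vector of length 488.
#' @export
full_feature_vector <- function(texture, demographics, morphology) {
  if (length(texture) != 476L) {
    stop_invalid("texture block must have length 476, got %d", length(texture))
  }
  demographics <- unlist(demographics)
  if (!all(c("age", "sex", "smoking") %in% names(demographics))) {
    stop_invalid("demographics must provide age, sex, smoking")
  }
  morphology <- unlist(morphology)
  if (length(morphology) != 9L) {
    stop_invalid("exactly 9 morphology values required, got %d", length(morphology))
  }
  cn <- clinical_feature_names()
  clin <- c(demographics[["age"]], demographics[["sex"]], demographics[["smoking"]],
            as.numeric(morphology))
  names(clin) <- cn
  out <- c(texture, clin)
  stopifnot(length(out) == 488L, !anyDuplicated(names(out)))
  out
}
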