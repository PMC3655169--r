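# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (explicit loops, direct enumeration).

# Double-loop evaluation of the 14 co-occurrence statistics.
oracle_glcm_features <- function(p) {
  Ng <- nrow(p)
  px <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) px[i] <- px[i] + p[i, j]
  mu <- 0
  for (i in 1:Ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:Ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  sig <- sqrt(sig2)

  entropy <- 0; energy <- 0; homog <- 0; idm <- 0; cluster <- 0
  inertia <- 0; sum_mean <- 0; diff_mean <- 0; corr_num <- 0; mx <- 0
  psum <- numeric(2 * Ng); pdiff <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    v <- p[i, j]
    if (v > 0) entropy <- entropy - v * log2(v)
    energy <- energy + v^2
    homog <- homog + v / (1 + abs(i - j))
    idm <- idm + v / (1 + (i - j)^2)
    cluster <- cluster + (i + j - 2 * mu)^2 * v
    inertia <- inertia + (i - j)^2 * v
    sum_mean <- sum_mean + (i + j) * v
    diff_mean <- diff_mean + abs(i - j) * v
    corr_num <- corr_num + (i - mu) * (j - mu) * v
    if (v > mx) mx <- v
    psum[i + j] <- psum[i + j] + v
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + v
  }
  sum_entropy <- 0
  for (k in seq_along(psum)) if (psum[k] > 0) sum_entropy <- sum_entropy - psum[k] * log2(psum[k])
  diff_entropy <- 0
  for (k in seq_along(pdiff)) if (pdiff[k] > 0) diff_entropy <- diff_entropy - pdiff[k] * log2(pdiff[k])

  c(entropy = entropy, mean = mu,
    correlation = if (sig2 > 0) corr_num / sig2 else 0,
    energy = energy, homogeneity = homog, std_dev = sig, max_prob = mx,
    idm = idm, cluster_tendency = cluster, inertia = inertia,
    sum_mean = sum_mean, diff_mean = diff_mean, sum_entropy = sum_entropy,
    diff_entropy = diff_entropy)
}

# Random symmetric normalized co-occurrence matrix.
random_glcm <- function(Ng) {
  a <- matrix(stats::rexp(Ng * Ng), Ng, Ng)
  p <- a + t(a)
  p / sum(p)
}

# Exhaustive BFS flood fill: connected component (4-neighbour) of pixels
# whose value is within tol of the seed pixel's value.
oracle_flood_fill <- function(pixels, seed_point, tol) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  ref <- pixels[seed_point[1], seed_point[2]]
  mask <- matrix(0, nr, nc)
  frontier <- list(seed_point)
  mask[seed_point[1], seed_point[2]] <- 1
  while (length(frontier) > 0) {
    pt <- frontier[[1]]; frontier <- frontier[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- pt[1] + d[1]; c <- pt[2] + d[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] == 0 &&
          abs(pixels[r, c] - ref) <= tol) {
        mask[r, c] <- 1
        frontier[[length(frontier) + 1]] <- c(r, c)
      }
    }
  }
  mask
}

# TRUE iff the 1-pixels of a mask form one 4-connected component.
mask_is_connected <- function(mask) {
  on <- which(mask == 1, arr.ind = TRUE)
  if (nrow(on) == 0) return(FALSE)
  comp <- oracle_flood_fill(mask, c(on[1, 1], on[1, 2]), 0.5)
  sum(comp * mask) == sum(mask)
}

# AUC by direct enumeration of all positive/negative pairs (half credit
# for ties) -- the Mann-Whitney U / (n1 n0) definition.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == "malignant"]
  sn <- scores[labels == "benign"]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# Within-mask standard deviation of an ROI image, computed directly.
mask_sd <- function(im) stats::sd(im$pixels[im$mask == 1])

rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
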