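test_that("quantization matches an explicit bin-edge oracle", {
  expect_true(all(quantize(matrix(3.7, 5, 5), 8) == 1L))
  two <- quantize(matrix(c(0, 10, 0, 10), 2, 2), 2)
  expect_equal(sort(unique(as.vector(two))), c(1L, 2L))
  expect_error(quantize(matrix(1:4, 2), 1), "Ng")

  set.seed(12)
  x <- matrix(rnorm(30 * 20), 30, 20)
  Ng <- 7
  got <- quantize(x, Ng)
  edges <- seq(min(x), max(x), length.out = Ng + 1)
  for (i in seq_along(x)) {
    lv <- 1L
    while (lv < Ng && x[i] > edges[lv + 1]) lv <- lv + 1L
    expect_identical(got[i], lv)
  }
})

test_that("co-occurrence counting is symmetric, normalized, and matches hand enumeration", {
  lv <- matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE)
  P <- cooccurrence(lv, 2, list(c(0L, 1L)))
  expect_equal(P$p[1, 2], 0.5)
  expect_equal(P$p[2, 1], 0.5)
  expect_equal(P$p[1, 1], 0)
  expect_equal(sum(P$p), 1)

  const <- cooccurrence(matrix(1L, 4, 4), 3)
  expect_equal(const$p[1, 1], 1)

  set.seed(3)
  for (i in 1:5) {
    lv <- matrix(sample.int(5, 100, replace = TRUE), 10, 10)
    for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
      P <- cooccurrence(lv, 5, list(off))
      expect_equal(sum(P$p), 1, tolerance = 1e-12)
      expect_equal(P$p, t(P$p))
      # hand count of the forward pairs
      cnt <- matrix(0, 5, 5)
      for (r in 1:10) for (c in 1:10) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= 10 && c2 >= 1 && c2 <= 10) {
          a <- lv[r, c]; b <- lv[r2, c2]
          cnt[a, b] <- cnt[a, b] + 1
          cnt[b, a] <- cnt[b, a] + 1
        }
      }
      expect_equal(P$p, cnt / sum(cnt), tolerance = 1e-12)
    }
  }
})

test_that("the 14 statistics match the brute-force double-loop oracle", {
  set.seed(9)
  for (i in 1:15) {
    Ng <- sample(3:12, 1)
    p <- random_glcm(Ng)
    expect_equal(texture_features_14(p), oracle_glcm_features(p),
                 tolerance = 1e-12)
  }
})

test_that("point-mass and two-level matrices give the hand-computed feature values", {
  g <- 4L; Ng <- 6L
  p <- matrix(0, Ng, Ng); p[g, g] <- 1
  f <- texture_features_14(p)
  expect_equal(unname(f[c("entropy", "energy", "max_prob", "homogeneity",
                          "idm", "inertia", "std_dev", "cluster_tendency",
                          "diff_mean", "correlation")]),
               c(0, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(f["sum_mean"]), 2 * g)
  expect_equal(unname(f["mean"]), g)

  q <- matrix(0, 2, 2); q[1, 2] <- 0.5; q[2, 1] <- 0.5
  f2 <- texture_features_14(q)
  expect_equal(unname(f2["inertia"]), 1)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["max_prob"]), 0.5)
  expect_equal(unname(f2["entropy"]), 1)
})

test_that("correlation stays in [-1, 1] on random symmetric matrices", {
  set.seed(14)
  for (i in 1:30) {
    p <- random_glcm(sample(2:10, 1))
    corr <- texture_features_14(p)[["correlation"]]
    expect_gte(corr, -1 - 1e-12)
    expect_lte(corr, 1 + 1e-12)
  }
})

test_that("offset-averaged inertia and energy are invariant under 90-degree rotation", {
  set.seed(22)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  avg_feats <- function(lv, Ng) {
    acc <- 0
    for (off in offs) acc <- acc + texture_features_14(cooccurrence(lv, Ng, list(off)))
    acc / 4
  }
  for (i in 1:5) {
    lv <- matrix(sample.int(6, 144, replace = TRUE), 12, 12)
    a <- avg_feats(lv, 6)
    b <- avg_feats(rot90(lv), 6)
    expect_equal(a[["inertia"]], b[["inertia"]], tolerance = 1e-8)
    expect_equal(a[["energy"]], b[["energy"]], tolerance = 1e-8)
  }
})

test_that("an ROI yields 476 deterministic, stably named texture features", {
  im <- gen_roi_image(texture_params("malignant"), 64, seed = 3)
  v1 <- roi_texture_vector(im)
  v2 <- roi_texture_vector(im)
  expect_length(v1, 476L)
  expect_identical(v1, v2)
  expect_false(anyDuplicated(names(v1)) > 0)
  expect_true(all(grepl("^s[123]_w[0-9]{2}_", names(v1))))
  expect_equal(sum(grepl("^s2_", names(v1))), 32 * 14)
})

test_that("the zero image gives zero-entropy, unit-energy features in every sub-band", {
  v <- roi_texture_vector(matrix(0, 64, 64))
  expect_true(all(v[grepl("_entropy$", names(v)) & !grepl("sum_|diff_", names(v))] == 0))
  expect_true(all(v[grepl("_energy$", names(v))] == 1))
})

test_that("higher generator noise raises the mean detail-band std_dev feature", {
  sds <- seq(2, 30, length.out = 10)
  feat <- vapply(seq_along(sds), function(i) {
    p <- texture_params("benign", noise_sd = sds[i], spicule_count = 0)
    v <- roi_texture_vector(gen_roi_image(p, 64, seed = 500 + i))
    mean(v[grepl("^s2_w[0-9]+_std_dev$", names(v))])
  }, 0)
  expect_gt(cor(sds, feat, method = "spearman"), 0)
})

test_that("the full feature vector is 488-dimensional with unique names", {
  im <- gen_roi_image(texture_params("benign"), 64, seed = 2)
  tex <- roi_texture_vector(im)
  fv <- full_feature_vector(tex, c(age = 55, sex = 1, smoking = 0), rep(0, 9))
  expect_length(fv, 488L)
  expect_equal(length(unique(names(fv))), 488L)
  expect_equal(unname(fv["age"]), 55)
  expect_error(full_feature_vector(tex[1:400], c(age = 1, sex = 0, smoking = 0), rep(0, 9)),
               "476")
  expect_error(full_feature_vector(tex, c(age = 1, sex = 0, smoking = 0), rep(0, 8)),
               "9 morphology")
})
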