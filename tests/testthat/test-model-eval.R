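make_clouds <- function(n, d = 2, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d), ncol = d),
             matrix(rnorm(n * d, mean = sep), ncol = d))
  list(X = X, y = rep(c("benign", "malignant"), each = n))
}

test_that("well-separated clouds are fit to near-perfect training accuracy", {
  dat <- make_clouds(100, sep = 10)
  m <- train_svm(dat$X, dat$y, C = 1)
  expect_gte(mean(predict_label(m, dat$X) == dat$y), 0.99)
  expect_error(train_svm(dat$X, rep("benign", 200)), "both classes")
  expect_error(train_svm(dat$X, dat$y, C = -1), "C must be")
})

test_that("the decision function matches an explicit kernel-sum oracle", {
  dat <- make_clouds(40, d = 3, sep = 3, seed = 7)
  m <- train_svm(dat$X, dat$y, C = 2, gamma = 0.5)
  probe <- matrix(rnorm(10 * 3), 10, 3)
  got <- decision_value(m, probe)
  for (i in 1:10) {
    z <- (probe[i, ] - m$scaling$center) / m$scaling$scale
    f <- m$bias
    for (s in seq_len(nrow(m$support_vectors))) {
      f <- f + m$alphas[s] * exp(-m$gamma * sum((m$support_vectors[s, ] - z)^2))
    }
    expect_equal(got[i], f, tolerance = 1e-10)
  }
  expect_error(decision_value(m, matrix(0, 1, 5)), "dimension")
})

test_that("duplicating every row leaves the decision function unchanged", {
  dat <- make_clouds(50, sep = 6, seed = 3)
  m1 <- train_svm(dat$X, dat$y, C = 1, gamma = 0.5)
  m2 <- train_svm(rbind(dat$X, dat$X), c(dat$y, dat$y), C = 0.5, gamma = 0.5)
  probe <- as.matrix(expand.grid(seq(-2, 8, length.out = 8),
                                 seq(-2, 8, length.out = 8)))
  expect_lt(max(abs(decision_value(m1, probe) - decision_value(m2, probe))), 1e-6)
})

test_that("flipping the labels negates the decision values", {
  dat <- make_clouds(40, sep = 5, seed = 11)
  yf <- ifelse(dat$y == "benign", "malignant", "benign")
  m1 <- train_svm(dat$X, dat$y, C = 1, gamma = 0.3)
  m2 <- train_svm(dat$X, yf, C = 1, gamma = 0.3)
  probe <- matrix(rnorm(40), 20, 2) * 3 + 4
  expect_lt(max(abs(decision_value(m1, probe) + decision_value(m2, probe))), 1e-6)
})

test_that("a symmetric two-point problem has zero bias; hard-margin SVs sit on the margin", {
  X <- rbind(c(1, 2), c(-1, -2))
  m <- train_svm(X, c("malignant", "benign"), C = 1e3, gamma = 0.5)
  expect_lt(abs(decision_value(m, matrix(0, 1, 2))), 1e-9)

  # separable 4-point problem, near-hard margin: |f| >= 1 at support vectors
  X4 <- rbind(c(0, 0), c(1, 0), c(4, 0), c(5, 0))
  y4 <- c("benign", "benign", "malignant", "malignant")
  m4 <- train_svm(X4, y4, C = 1e6, gamma = 0.1)
  sv_f <- decision_value(m4, m4$support_vectors *
                           matrix(m4$scaling$scale, nrow(m4$support_vectors), 2, byrow = TRUE) +
                           matrix(m4$scaling$center, nrow(m4$support_vectors), 2, byrow = TRUE))
  expect_true(all(abs(sv_f) >= 1 - 1e-6))
})

test_that("stratified cross-validation is deterministic, accurate on separable data, and leak-free", {
  dat <- make_clouds(30, sep = 8, seed = 5)
  pid <- paste0("P", rep(1:20, each = 3))
  cv1 <- kfold_cv(dat$X, dat$y, k = 5, grouping = "patient", patient_id = pid, seed = 2)
  cv2 <- kfold_cv(dat$X, dat$y, k = 5, grouping = "patient", patient_id = pid, seed = 2)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$predicted, cv2$predicted)
  expect_gte(cv1$mean_accuracy, 0.95)
  # all rows of one patient share a fold
  expect_true(all(tapply(cv1$fold, pid, function(f) length(unique(f))) == 1))

  # roi grouping: stratified within class, proportions preserved within 1
  cvr <- kfold_cv(dat$X, dat$y, k = 5, grouping = "roi", seed = 4)
  per_fold <- table(cvr$fold, dat$y)
  expect_true(all(abs(per_fold[, 1] - mean(per_fold[, 1])) <= 1))

  # leave-one-out fold arithmetic on 10 rows
  d10 <- make_clouds(5, sep = 8, seed = 9)
  cvl <- kfold_cv(d10$X, d10$y, k = 10, grouping = "roi", seed = 1)
  expect_equal(sort(unique(cvl$fold)), 1:10)
  expect_true(all(table(cvl$fold) == 1))
  expect_error(kfold_cv(d10$X, d10$y, k = 11, grouping = "roi", seed = 1), "exceeds")
})

test_that("malignance rate is the malignant fraction of ROI calls", {
  expect_equal(malignance_rate(rep(c("malignant", "benign"), c(7, 3))), 0.7)
  expect_equal(malignance_rate(rep("benign", 5)), 0)
  expect_equal(malignance_rate(rep("malignant", 4)), 1)
  expect_error(malignance_rate(character(0)), "at least one")
})

test_that("ROC examples: perfect separation, hand-counted pairs, and full ties", {
  r1 <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
                c("malignant", "malignant", "benign", "benign"))
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(c(0.8, 0.4, 0.6, 0.2),
                c("malignant", "malignant", "benign", "benign"))
  expect_equal(r2$auc, 0.75)
  r3 <- roc_auc(c(0.5, 0.5, 0.5, 0.5),
                c("malignant", "malignant", "benign", "benign"))
  expect_equal(r3$auc, 0.5)
  expect_gt(r3$auc_p, 0.99)
  expect_error(roc_auc(1:3, rep("benign", 3)), "both classes")
})

test_that("trapezoid AUC equals the enumerated Mann-Whitney statistic, and the curve is monotone", {
  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- c(round(runif(n1), 1), round(runif(n0), 1))  # rounding forces ties
    labels <- rep(c("malignant", "benign"), c(n1, n0))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  }
})

test_that("AUC p-value matches the Wilcoxon normal approximation", {
  set.seed(23)
  for (i in 1:5) {
    s <- c(rnorm(12, i / 4), round(rnorm(15), 1))
    lab <- rep(c("malignant", "benign"), c(12, 15))
    r <- roc_auc(s, lab)
    w <- wilcox.test(s[lab == "malignant"], s[lab == "benign"],
                     exact = FALSE, correct = FALSE)
    expect_equal(r$auc_p, w$p.value, tolerance = 1e-8)
  }
})

test_that("chi-square reproduces the printed demographic statistics and handles degenerate tables", {
  smoking <- matrix(c(64, 42, 107, 105), 2, 2)
  sex <- matrix(c(48, 58, 85, 127), 2, 2)
  expect_equal(chi_square_2x2(smoking)$statistic, 2.79, tolerance = 0.01 / 2.79)
  expect_equal(chi_square_2x2(sex)$statistic, 0.78, tolerance = 0.01 / 0.78)
  expect_equal(chi_square_2x2(smoking)$df, 1)
  expect_equal(chi_square_2x2(matrix(c(50, 50, 50, 50), 2, 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margins")
  expect_error(chi_square_2x2(matrix(1:6, 2, 3)), "2 x 2")
})

test_that("chi-square p agrees with a fixed-margin permutation null", {
  set.seed(41)
  for (i in 1:3) {
    tab <- matrix(sample(20:80, 4), 2, 2)
    got <- chi_square_2x2(tab)
    B <- 4000
    perm <- r2dtable(B, rowSums(tab), colSums(tab))
    stats_perm <- vapply(perm, function(tt) {
      suppressWarnings(chisq.test(tt, correct = FALSE)$statistic)
    }, 0)
    p_mc <- mean(stats_perm >= got$statistic - 1e-9)
    mc_err <- 3 * sqrt(p_mc * (1 - p_mc) / B) + 0.01
    expect_lt(abs(p_mc - got$p), mc_err + 0.03)
  }
})

test_that("feature change summarizes per-patient first-to-last deltas and flags single scans", {
  df <- data.frame(
    patient_id = c("A", "A", "B", "B", "C"),
    scan_index = c(0, 1, 0, 2, 0),
    label = c("benign", "benign", "malignant", "malignant", "benign"),
    s2_w01_std_dev = c(1, 3, 2, 2.5, 9),
    s2_w02_std_dev = c(1, 3, 2, 1.5, 9)
  )
  expect_warning(fc <- feature_change(df), "single scan")
  expect_equal(nrow(fc$per_patient), 2)
  a <- fc$per_patient[fc$per_patient$patient_id == "A", ]
  expect_equal(a$delta, 2)                    # mean(3,3) - mean(1,1)
  b <- fc$per_patient[fc$per_patient$patient_id == "B", ]
  expect_equal(b$delta, 0)                    # mean(2.5,1.5) - mean(2,2)
  # identical first and last scans give exactly zero delta
  df2 <- df[df$patient_id == "A", ]
  df2$s2_w01_std_dev <- 5; df2$s2_w02_std_dev <- 7
  expect_equal(feature_change(df2)$per_patient$delta, 0)
})

test_that("an SVM model round-trips through portable JSON", {
  dat <- make_clouds(30, d = 3, sep = 4, seed = 13)
  m <- train_svm(dat$X, dat$y, C = 2, gamma = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_svm_model(m, path)
  m2 <- read_svm_model(path)
  probe <- matrix(rnorm(30), 10, 3)
  expect_equal(decision_value(m2, probe), decision_value(m, probe),
               tolerance = 1e-12)
})
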