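test_that("zero-noise, zero-spicule nodule is constant inside its mask and 0 outside", {
  p <- texture_params("benign", noise_sd = 0, spicule_count = 0,
                      base_intensity = 120)
  im <- gen_roi_image(p, side = 64, seed = 11)
  expect_gt(sum(im$mask), 0)
  expect_true(all(im$pixels[im$mask == 1] == 120))
  expect_true(all(im$pixels[im$mask == 0] == 0))
})

test_that("image generation is bit-identical under a fixed seed and side < 32 errors", {
  p <- texture_params("malignant")
  a <- gen_roi_image(p, side = 64, seed = 42)
  b <- gen_roi_image(p, side = 64, seed = 42)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
  c <- gen_roi_image(p, side = 64, seed = 43)
  expect_false(identical(a$pixels, c$pixels))
  expect_error(gen_roi_image(p, side = 31, seed = 1), "side")
})

test_that("benign and malignant defaults separate in within-mask standard deviation", {
  pb <- texture_params("benign")
  pm <- texture_params("malignant")
  sd_b <- vapply(1:50, function(s) mask_sd(gen_roi_image(pb, 64, seed = s)), 0)
  sd_m <- vapply(1:50, function(s) mask_sd(gen_roi_image(pm, 64, seed = 1000 + s)), 0)
  expect_lt(t.test(sd_b, sd_m)$p.value, 0.01)
})

test_that("minimal cohort has the requested patients and ROIs; bad ranges error", {
  co <- gen_cohort(1, 1, rois_per_patient = c(1, 1), seed = 5)
  expect_equal(nrow(co$patients), 2L)
  expect_equal(nrow(co$rois), 2L)
  expect_length(co$images, 2L)
  expect_false(anyDuplicated(co$patients$patient_id) > 0)
  expect_error(gen_cohort(1, 1, rois_per_patient = c(3, 2)), "range")
  expect_error(gen_cohort(0, 1), "at least one")
})

test_that("cohort covariate marginals converge to the study's class-conditional values", {
  co <- gen_cohort(1000, 2000, rois_per_patient = c(1, 1), seed = 7,
                   generate_images = FALSE)
  pts <- co$patients
  ben <- pts[pts$label == "benign", ]
  mal <- pts[pts$label == "malignant", ]
  expect_equal(mean(ben$age), 50.8, tolerance = 1.5 / 50.8)
  expect_equal(mean(mal$smoking), 0.4953, tolerance = 0.04 / 0.4953)
  # three-standard-error convergence checks
  expect_lt(abs(mean(mal$age) - 62), 3 * 11.54 / sqrt(2000))
  expect_lt(abs(mean(ben$smoking) - 0.3962), 3 * sqrt(0.3962 * 0.6038 / 1000))
  expect_lt(abs(mean(ben$sex) - 0.5472), 3 * sqrt(0.5472 * 0.4528 / 1000))
  expect_lt(abs(mean(mal$sex) - 0.5991), 3 * sqrt(0.5991 * 0.4009 / 2000))
  # covariate tables are identical with and without image generation
  co2 <- gen_cohort(1000, 2000, rois_per_patient = c(1, 1), seed = 7,
                    generate_images = FALSE)
  expect_identical(co$patients, co2$patients)
})

test_that("ages are clamped to [18, 95]", {
  co <- gen_cohort(300, 300, rois_per_patient = c(1, 1), seed = 3,
                   generate_images = FALSE)
  expect_true(all(co$patients$age >= 18 & co$patients$age <= 95))
})

test_that("longitudinal drift raises benign within-mask sd but not malignant", {
  co <- gen_longitudinal_cohort(20, scans_per_patient = 2, seed = 21)
  sds <- vapply(co$rois$roi_id, function(id) mask_sd(co$images[[id]]), 0)
  df <- data.frame(patient_id = co$rois$patient_id, scan = co$rois$scan_index,
                   label = co$rois$label, sd = sds)
  per <- aggregate(sd ~ patient_id + scan + label, df, mean)
  first <- per[per$scan == 0, ]
  last <- per[per$scan == max(per$scan), ]
  m <- merge(first, last, by = c("patient_id", "label"))
  delta <- tapply(m$sd.y - m$sd.x, m$label, mean)
  expect_gt(delta[["benign"]], 0)
  expect_lt(abs(delta[["malignant"]]), 0.1 * delta[["benign"]])
})

test_that("months are zero at the first scan, non-decreasing, and drift-free classes stay flat", {
  p0 <- texture_params("benign", drift_per_month = 0)
  m0 <- texture_params("malignant", drift_per_month = 0)
  co <- gen_longitudinal_cohort(6, scans_per_patient = 3, seed = 9,
                                params_benign = p0, params_malignant = m0)
  for (pid in unique(co$rois$patient_id)) {
    sub <- co$rois[co$rois$patient_id == pid, ]
    sub <- sub[order(sub$scan_index), ]
    expect_equal(sub$months_from_first[sub$scan_index == 0], rep(0, sum(sub$scan_index == 0)))
    expect_true(all(diff(sub$months_from_first) >= 0))
  }
  sds <- vapply(co$rois$roi_id, function(id) mask_sd(co$images[[id]]), 0)
  df <- data.frame(patient_id = co$rois$patient_id, scan = co$rois$scan_index,
                   label = co$rois$label, sd = sds)
  per <- aggregate(sd ~ patient_id + scan + label, df, mean)
  first <- per[per$scan == 0, ]
  last <- per[per$scan == max(per$scan), ]
  m <- merge(first, last, by = c("patient_id", "label"))
  delta <- tapply(m$sd.y - m$sd.x, m$label, mean)
  expect_lt(abs(delta[["benign"]]), 1.5)
  expect_lt(abs(delta[["malignant"]]), 1.5)
  expect_error(gen_longitudinal_cohort(5, scans_per_patient = 1), "scans_per_patient")
})

test_that("cohort generators are deterministic end to end", {
  a <- gen_longitudinal_cohort(3, 2, seed = 77)
  b <- gen_longitudinal_cohort(3, 2, seed = 77)
  expect_identical(a$patients, b$patients)
  expect_identical(a$rois, b$rois)
  expect_identical(lapply(a$images, `[[`, "pixels"),
                   lapply(b$images, `[[`, "pixels"))
})
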