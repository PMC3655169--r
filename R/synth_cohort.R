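#' Per-class texture generator parameters
#'
#' Controls the synthetic nodule texture: a base intensity plus a
#' Gaussian-smoothed noise field (rescaled so its standard deviation is
#' `noise_sd`), and `spicule_count` radial ridges. The two class defaults
#' differ in noise level, smoothing and spiculation, giving texture
#' statistics that separate the classes; `drift_per_month` raises
#' `noise_sd` over follow-up time, which is how the benign class's
#' standard-deviation feature is made to rise between first and last scan.
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param base_intensity Mean nodule intensity (arbitrary CT-like units).
#' @param noise_sd Standard deviation of the texture field, >= 0.
#' @param smoothing_sigma Gaussian smoothing bandwidth in pixels, >= 0.
#' @param spicule_count Number of radial ridges, >= 0.
#' @param drift_per_month Additive change in `noise_sd` per month of
#'   follow-up (benign default positive, malignant 0).
#' @return Object of class `texture_params`.
#' @export
texture_params <- function(class_label = c("benign", "malignant"),
                           base_intensity = NULL, noise_sd = NULL,
                           smoothing_sigma = NULL, spicule_count = NULL,
                           drift_per_month = NULL) {
  class_label <- match.arg(class_label)
  def <- if (class_label == "benign") {
    list(base_intensity = 100, noise_sd = 8, smoothing_sigma = 1.8,
         spicule_count = 1L, drift_per_month = 2.5)
  } else {
    list(base_intensity = 110, noise_sd = 18, smoothing_sigma = 0.8,
         spicule_count = 8L, drift_per_month = 0)
  }
  p <- list(
    class_label = class_label,
    base_intensity = if (is.null(base_intensity)) def$base_intensity else base_intensity,
    noise_sd = if (is.null(noise_sd)) def$noise_sd else noise_sd,
    smoothing_sigma = if (is.null(smoothing_sigma)) def$smoothing_sigma else smoothing_sigma,
    spicule_count = if (is.null(spicule_count)) def$spicule_count else as.integer(spicule_count),
    drift_per_month = if (is.null(drift_per_month)) def$drift_per_month else drift_per_month
  )
  if (p$noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (p$smoothing_sigma < 0) stop_invalid("smoothing_sigma must be >= 0")
  if (p$spicule_count < 0) stop_invalid("spicule_count must be >= 0")
  structure(p, class = "texture_params")
}

# FFT Gaussian blur (periodic boundary); sigma in pixels
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- nrow(x); m <- ncol(x)
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fc <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
  G <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(x) * G, inverse = TRUE)) / (n * m)
}

#' Generate one synthetic nodule ROI image
#'
#' Places an elliptical nodule at the image centre (randomized semi-axes
#' and orientation), fills it with `base_intensity` plus a smoothed noise
#' texture of standard deviation `noise_sd`, and overlays `spicule_count`
#' radial ridges. Pixels outside the nodule are 0 and the returned mask is
#' 1 exactly inside the ellipse. Fully deterministic for a given seed.
#'
#' @param params A [texture_params()].
#' @param side Image side in pixels, >= 32.
#' @param seed Integer seed.
#' @param patient_id,scan_index,roi_id Identifiers passed through.
#' @return A [roi_image()].
#' @export
gen_roi_image <- function(params, side = 64L, seed = 1L,
                          patient_id = NA_character_, scan_index = 0L,
                          roi_id = NA_character_) {
  stopifnot(inherits(params, "texture_params"))
  side <- as.integer(side)
  if (side < 32L) {
    stop_invalid("side must be >= 32 (too small for a 3-scale decomposition), got %d", side)
  }
  with_seed(seed, {
    ctr <- (side + 1) / 2
    a <- stats::runif(1, 0.26, 0.38) * side / 2   # semi-axes
    b <- stats::runif(1, 0.26, 0.38) * side / 2
    phi <- stats::runif(1, 0, pi)
    rr <- matrix(seq_len(side) - ctr, side, side)
    cc <- t(rr)
    u <- cos(phi) * cc + sin(phi) * rr
    v <- -sin(phi) * cc + cos(phi) * rr
    mask <- ifelse((u / a)^2 + (v / b)^2 <= 1, 1, 0)

    img <- matrix(0, side, side)
    tex <- matrix(params$base_intensity, side, side)
    if (params$noise_sd > 0) {
      z <- matrix(stats::rnorm(side * side), side, side)
      z <- gaussian_blur(z, params$smoothing_sigma)
      z <- z / stats::sd(z) * params$noise_sd
      tex <- tex + z
    }
    if (params$spicule_count > 0) {
      theta <- atan2(rr, cc)
      r <- sqrt(rr^2 + cc^2)
      amp <- 0.35 * params$base_intensity
      jit <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(params$spicule_count)) {
        ang <- jit + 2 * pi * (s - 1) / params$spicule_count
        # angular distance to the ray, converted to a perpendicular
        # pixel distance so ridges have constant width ~1.5 px
        dang <- abs(((theta - ang + pi) %% (2 * pi)) - pi)
        perp <- dang * pmax(r, 1)
        tex <- tex + amp * exp(-(perp / 1.5)^2) * (r > 2)
      }
    }
    img[mask == 1] <- tex[mask == 1]
    roi_image(img, mask, patient_id = patient_id,
              scan_index = scan_index, roi_id = roi_id)
  })
}

# Table-3-style class-conditional demographics
demographic_defaults <- function() {
  list(
    benign = list(age_mean = 50.8, age_sd = 13.26, p_smoking = 0.3962, p_male = 0.5472),
    malignant = list(age_mean = 62, age_sd = 11.54, p_smoking = 0.4953, p_male = 0.5991)
  )
}

morphology_defaults <- function() {
  nm <- clinical_feature_names()[-(1:3)]
  benign <- stats::setNames(rep(0.5, 9), nm)
  malignant <- stats::setNames(rep(0.5, 9), nm)
  for (f in c("spicule", "lobulation", "vacuole")) {
    benign[f] <- 0.2
    malignant[f] <- 0.6
  }
  list(benign = benign, malignant = malignant)
}

draw_patients <- function(n, label, start_id, morph_probs) {
  dg <- demographic_defaults()[[label]]
  age <- stats::rnorm(n, dg$age_mean, dg$age_sd)
  clamped <- sum(age < 18 | age > 95)
  if (clamped > 0) {
    message(sprintf("gen_cohort: clamped %d %s age(s) to [18, 95]", clamped, label))
  }
  age <- pmin(pmax(age, 18), 95)
  sex <- stats::rbinom(n, 1, dg$p_male)          # 1 = male
  smoking <- stats::rbinom(n, 1, dg$p_smoking)   # 1 = yes
  morph <- vapply(morph_probs[[label]],
                  function(p) stats::rbinom(n, 1, p), integer(n))
  if (n == 1L) morph <- matrix(morph, nrow = 1, dimnames = list(NULL, names(morph_probs[[label]])))
  df <- data.frame(
    patient_id = sprintf("P%04d", start_id + seq_len(n) - 1L),
    age = age, sex = sex, smoking = smoking,
    label = label, stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(morph))
}

#' Generate a synthetic single-scan cohort with ROI images
#'
#' Draws per-class demographics matching the study's marginals — benign
#' ages N(50.8, 13.26), malignant N(62, 11.54), clamped to 18–95 years;
#' smoking probability 0.3962 / 0.4953; male probability 0.5472 / 0.5991 —
#' binary morphology covariates with class-conditional probabilities, and
#' a uniformly drawn number of ROI images per patient, all from one seed.
#'
#' @param n_benign,n_malignant Patients per class, >= 1.
#' @param rois_per_patient Integer range `c(lo, hi)`, lo >= 1.
#' @param seed Integer seed.
#' @param side ROI image side in pixels.
#' @param params_benign,params_malignant [texture_params()] per class.
#' @param morph_probs Optional list with `benign`/`malignant` named
#'   probability vectors for the 9 morphology covariates.
#' @param generate_images If FALSE, only the covariate and ROI tables are
#'   built (useful for large marginal-convergence checks); the tables are
#'   identical either way for a given seed.
#' @return A list of class `cohort`: `patients` (one row per patient),
#'   `rois` (one row per ROI: roi_id, patient_id, scan_index,
#'   months_from_first), and `images` (named list of [roi_image()]).
#' @export
gen_cohort <- function(n_benign, n_malignant, rois_per_patient = c(2L, 5L),
                       seed = 1L, side = 64L,
                       params_benign = texture_params("benign"),
                       params_malignant = texture_params("malignant"),
                       morph_probs = morphology_defaults(),
                       generate_images = TRUE) {
  if (n_benign < 1L || n_malignant < 1L) {
    stop_invalid("both classes need at least one patient")
  }
  rois_per_patient <- as.integer(rois_per_patient)
  if (length(rois_per_patient) != 2L || any(is.na(rois_per_patient)) ||
      rois_per_patient[1] > rois_per_patient[2] || rois_per_patient[1] < 1L) {
    stop_invalid("rois_per_patient must be a non-empty range c(lo, hi) with lo >= 1")
  }
  with_seed(seed, {
    pts <- rbind(
      draw_patients(n_benign, "benign", 1L, morph_probs),
      draw_patients(n_malignant, "malignant", n_benign + 1L, morph_probs)
    )
    n_rois <- sample(rois_per_patient[1]:rois_per_patient[2],
                     nrow(pts), replace = TRUE)
    img_seeds <- sample.int(2147483646L, sum(n_rois))
    rois <- data.frame(
      roi_id = sprintf("R%05d", seq_len(sum(n_rois))),
      patient_id = rep(pts$patient_id, n_rois),
      scan_index = 0L, months_from_first = 0,
      label = rep(pts$label, n_rois),
      stringsAsFactors = FALSE
    )
    images <- list()
    if (generate_images) {
      images <- vector("list", nrow(rois))
      for (i in seq_len(nrow(rois))) {
        par <- if (rois$label[i] == "benign") params_benign else params_malignant
        images[[i]] <- gen_roi_image(par, side = side, seed = img_seeds[i],
                                     patient_id = rois$patient_id[i],
                                     scan_index = 0L, roi_id = rois$roi_id[i])
      }
      names(images) <- rois$roi_id
    }
    structure(list(patients = pts, rois = rois, images = images, seed = seed),
              class = "cohort")
  })
}

#' Generate a longitudinal cohort with texture drift
#'
#' Every patient receives `scans_per_patient` scans. Total follow-up time
#' is drawn per patient from a lognormal distribution with median 2.0 and
#' mean `follow_up_mean_months` (default 6.9) months; intermediate scans
#' fall at sorted uniform fractions of it. At each scan the class's
#' `noise_sd` is increased by `drift_per_month * months_from_first`, so
#' with the default parameters the benign class's within-nodule standard
#' deviation rises over follow-up while the malignant class's stays flat.
#'
#' @param n_per_class Patients per class.
#' @param scans_per_patient Scans per patient, >= 2.
#' @param seed Integer seed.
#' @param rois_per_scan Integer range of ROIs per scan.
#' @param follow_up_mean_months Mean total follow-up (months).
#' @param side,params_benign,params_malignant,morph_probs As [gen_cohort()].
#' @return A `cohort` list (see [gen_cohort()]); `rois` carries one row per
#'   ROI per scan with its `months_from_first`.
#' @export
gen_longitudinal_cohort <- function(n_per_class, scans_per_patient = 2L,
                                    seed = 1L, rois_per_scan = c(1L, 3L),
                                    follow_up_mean_months = 6.9, side = 64L,
                                    params_benign = texture_params("benign"),
                                    params_malignant = texture_params("malignant"),
                                    morph_probs = morphology_defaults()) {
  scans_per_patient <- as.integer(scans_per_patient)
  if (scans_per_patient < 2L) stop_invalid("scans_per_patient must be >= 2")
  if (n_per_class < 1L) stop_invalid("n_per_class must be >= 1")
  # lognormal with median 2.0 months; sdlog set so the mean matches
  meanlog <- log(2)
  sdlog <- sqrt(2 * (log(follow_up_mean_months) - meanlog))
  if (is.nan(sdlog)) stop_invalid("follow_up_mean_months must exceed the 2.0-month median")

  with_seed(seed, {
    pts <- rbind(
      draw_patients(n_per_class, "benign", 1L, morph_probs),
      draw_patients(n_per_class, "malignant", n_per_class + 1L, morph_probs)
    )
    roi_rows <- list()
    images <- list()
    rid <- 0L
    for (i in seq_len(nrow(pts))) {
      par0 <- if (pts$label[i] == "benign") params_benign else params_malignant
      total <- stats::rlnorm(1, meanlog, sdlog)
      months <- c(0, sort(stats::runif(scans_per_patient - 2L, 0, total)), total)
      n_r <- sample(rois_per_scan[1]:rois_per_scan[2], scans_per_patient,
                    replace = TRUE)
      for (s in seq_len(scans_per_patient)) {
        par_s <- par0
        par_s$noise_sd <- par0$noise_sd + par0$drift_per_month * months[s]
        for (r in seq_len(n_r[s])) {
          rid <- rid + 1L
          id <- sprintf("R%05d", rid)
          roi_rows[[rid]] <- data.frame(
            roi_id = id, patient_id = pts$patient_id[i],
            scan_index = s - 1L, months_from_first = months[s],
            label = pts$label[i], stringsAsFactors = FALSE
          )
          images[[id]] <- gen_roi_image(par_s, side = side,
                                        seed = sample.int(2147483646L, 1),
                                        patient_id = pts$patient_id[i],
                                        scan_index = s - 1L, roi_id = id)
        }
      }
    }
    rois <- do.call(rbind, roi_rows)
    structure(list(patients = pts, rois = rois, images = images, seed = seed),
              class = "cohort")
  })
}

#' Write cohort images and metadata to disk
#'
#' Writes each ROI as a 16-bit grayscale TIFF plus a same-name `_mask.tif`,
#' the patient and ROI tables as CSV, and a JSON manifest recording the
#' seed and intensity scaling used, so a run can be reloaded exactly.
#'
#' @param cohort A `cohort` from [gen_cohort()] or [gen_longitudinal_cohort()].
#' @param dir Output directory (created if needed).
#' @param intensity_max Intensities are stored as `pixels / intensity_max`
#'   (clipped to \[0, 1\]) at 16-bit depth.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, intensity_max = 512) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_invalid("the 'tiff' package is required to write images")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  for (id in names(cohort$images)) {
    im <- cohort$images[[id]]
    px <- pmin(pmax(im$pixels / intensity_max, 0), 1)
    tiff::writeTIFF(px, file.path(img_dir, paste0(id, ".tif")),
                    bits.per.sample = 16L)
    tiff::writeTIFF(im$mask, file.path(img_dir, paste0(id, "_mask.tif")),
                    bits.per.sample = 16L)
  }
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed, intensity_max = intensity_max,
         n_images = length(cohort$images)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}
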