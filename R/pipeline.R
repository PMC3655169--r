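#' Configuration for a full pipeline run
#'
#' Collects every tunable of the simulate -> segment -> extract ->
#' balance -> train/evaluate -> longitudinal chain. All randomness flows
#' from the single `seed` via documented per-stage derivation, so a run
#' is reproducible from its config alone. The config round-trips through
#' YAML ([read_run_config()] / [write_run_config()]).
#'
#' @param seed Root seed.
#' @param n_benign,n_malignant Patients per class in the training cohort.
#' @param rois_per_patient Integer range of ROIs per patient.
#' @param side ROI side in pixels.
#' @param segment_tol Region-growing tolerance (intensity units).
#' @param Ng Gray levels for co-occurrence quantization.
#' @param balance_target `"match_majority"`, a count, or `NA` to skip
#'   balancing.
#' @param smote_k SMOTE neighbourhood size.
#' @param svm_C,svm_gamma SVM hyperparameters (`NULL` gamma = 1/d).
#' @param cv_k,cv_grouping Cross-validation folds and grouping.
#' @param longitudinal_n Patients per class in the longitudinal cohort
#'   (0 disables the stage).
#' @param scans_per_patient Scans per longitudinal patient.
#' @param out_dir Output directory (`NULL`: results kept in memory only).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_benign = 14L, n_malignant = 26L,
                       rois_per_patient = c(3L, 5L), side = 64L,
                       segment_tol = 60, Ng = 64L,
                       balance_target = "match_majority", smote_k = 5L,
                       svm_C = 1, svm_gamma = NULL,
                       cv_k = 10L, cv_grouping = "patient",
                       longitudinal_n = 20L, scans_per_patient = 2L,
                       out_dir = NULL) {
  structure(
    list(schema_version = 1L, seed = as.integer(seed),
         n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
         rois_per_patient = as.integer(rois_per_patient), side = as.integer(side),
         segment_tol = segment_tol, Ng = as.integer(Ng),
         balance_target = balance_target, smote_k = as.integer(smote_k),
         svm_C = svm_C, svm_gamma = svm_gamma,
         cv_k = as.integer(cv_k), cv_grouping = cv_grouping,
         longitudinal_n = as.integer(longitudinal_n),
         scans_per_patient = as.integer(scans_per_patient),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[setdiff(names(raw), "schema_version")]
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}

# Segment every cohort image (region growing from the centre seed, then
# background zeroing) and extract the full 488-entry feature vector per ROI.
extract_cohort_features <- function(cohort, segment_tol = 60,
                                    cfg = curvelet_config(), Ng = 64L) {
  pts <- cohort$patients
  rows <- vector("list", nrow(cohort$rois))
  for (i in seq_len(nrow(cohort$rois))) {
    rid <- cohort$rois$roi_id[i]
    im <- cohort$images[[rid]]
    # refine the delineated mask by region growing from the centre; accept
    # the refinement only if it retains most of the delineation (very
    # heterogeneous nodules can stall the growth near the seed)
    grown <- region_grow(im$pixels, tol = segment_tol)
    refined <- grown * im$mask
    if (sum(refined) >= 0.5 * sum(im$mask)) im$mask <- refined
    im <- apply_mask(im)
    tex <- roi_texture_vector(im, cfg = cfg, Ng = Ng)
    p <- pts[pts$patient_id == im$patient_id, ]
    morph <- as.numeric(p[1, clinical_feature_names()[-(1:3)]])
    fv <- full_feature_vector(tex,
                              c(age = p$age[1], sex = p$sex[1], smoking = p$smoking[1]),
                              morph)
    rows[[i]] <- fv
  }
  feat <- as.data.frame(do.call(rbind, rows))
  cbind(
    data.frame(roi_id = cohort$rois$roi_id,
               patient_id = cohort$rois$patient_id,
               scan_index = cohort$rois$scan_index,
               label = cohort$rois$label,
               stringsAsFactors = FALSE),
    feat
  )
}

feature_matrix <- function(features) {
  meta <- c("roi_id", "patient_id", "scan_index", "label", "provenance")
  as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
}

# Patient-level evaluation: held-out ROI predictions from CV -> per-patient
# malignance rate -> ROC/AUC against the true patient label.
patient_level_eval <- function(cv, features) {
  pred <- data.frame(patient_id = features$patient_id,
                     label = features$label,
                     predicted = cv$predicted,
                     stringsAsFactors = FALSE)
  per_patient <- do.call(rbind, lapply(split(pred, pred$patient_id), function(g) {
    data.frame(patient_id = g$patient_id[1], label = g$label[1],
               malignance_rate = malignance_rate(g$predicted),
               n_rois = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(per_patient) <- NULL
  roc <- roc_auc(per_patient$malignance_rate, per_patient$label)
  list(per_patient = per_patient, roc = roc$roc, auc = roc$auc,
       auc_p = roc$auc_p)
}

write_with_checksum <- function(obj, path, manifest) {
  if (is.data.frame(obj)) {
    utils::write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest[[basename(path)]] <- unname(tools::md5sum(path))
  manifest
}

#' Run the full diagnosis pipeline on synthetic data
#'
#' Simulates a cohort, removes ROI background by seeded region growing,
#' extracts the 488 model inputs per ROI (476 curvelet co-occurrence
#' textures + 12 clinical covariates), balances the classes by SMOTE,
#' cross-validates the RBF-SVM, aggregates held-out ROI predictions into
#' per-patient malignance rates and a patient-level ROC, compares the
#' cohort demographics between classes by chi-square, and (when
#' configured) runs the longitudinal texture-change analysis on a
#' separate multi-scan cohort. With `out_dir` set, every table is written
#' as CSV/JSON along with a manifest of MD5 checksums.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_result`: `features`, `balanced_counts`,
#'   `cv`, `patient_eval`, `demographics`, `longitudinal` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  stage <- function(name) {
    message(sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"), name))
  }

  stage("simulate cohort")
  cohort <- gen_cohort(cfg$n_benign, cfg$n_malignant,
                       rois_per_patient = cfg$rois_per_patient,
                       seed = derive_seed(cfg$seed, "simulate"),
                       side = cfg$side)

  stage("segment + extract features")
  features <- extract_cohort_features(cohort, segment_tol = cfg$segment_tol,
                                      Ng = cfg$Ng)

  X <- feature_matrix(features)
  y <- features$label

  balanced_counts <- table(y)
  bal <- NULL
  if (!identical(cfg$balance_target, NA) && !is.null(cfg$balance_target)) {
    stage("balance (SMOTE)")
    bal <- balance_dataset(X, y, target = cfg$balance_target, k = cfg$smote_k,
                           seed = derive_seed(cfg$seed, "balance"))
    balanced_counts <- table(bal$y)
  }

  stage("cross-validate")
  cv <- kfold_cv(X, y, k = cfg$cv_k, grouping = cfg$cv_grouping,
                 patient_id = features$patient_id,
                 C = cfg$svm_C, gamma = cfg$svm_gamma,
                 seed = derive_seed(cfg$seed, "cv"))

  stage("patient-level ROC")
  pe <- patient_level_eval(cv, features)

  stage("demographics")
  pts <- cohort$patients
  smoking_tab <- table(factor(pts$smoking, levels = c(0, 1)),
                       factor(pts$label, levels = c("benign", "malignant")))
  sex_tab <- table(factor(pts$sex, levels = c(0, 1)),
                   factor(pts$label, levels = c("benign", "malignant")))
  demographics <- list(
    smoking = chi_square_2x2(smoking_tab),
    sex = chi_square_2x2(sex_tab)
  )

  longitudinal <- NULL
  if (cfg$longitudinal_n > 0L) {
    stage("longitudinal cohort")
    lcoh <- gen_longitudinal_cohort(cfg$longitudinal_n, cfg$scans_per_patient,
                                    seed = derive_seed(cfg$seed, "longitudinal"),
                                    side = cfg$side)
    lfeat <- extract_cohort_features(lcoh, segment_tol = cfg$segment_tol,
                                     Ng = cfg$Ng)
    longitudinal <- feature_change(lfeat)
  }

  result <- structure(
    list(features = features, balanced_counts = balanced_counts,
         balanced = bal, cv = cv, patient_eval = pe,
         demographics = demographics, longitudinal = longitudinal,
         config = cfg),
    class = "pipeline_result"
  )

  if (!is.null(cfg$out_dir)) {
    stage("write outputs")
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    man <- list()
    man <- write_with_checksum(features, file.path(cfg$out_dir, "features.csv"), man)
    man <- write_with_checksum(pe$per_patient,
                               file.path(cfg$out_dir, "patient_rates.csv"), man)
    man <- write_with_checksum(pe$roc, file.path(cfg$out_dir, "roc.csv"), man)
    ev <- list(fold_accuracies = cv$fold_accuracies,
               mean_accuracy = cv$mean_accuracy, auc = pe$auc,
               auc_p = pe$auc_p,
               balanced_counts = as.list(balanced_counts),
               demographics = demographics)
    man <- write_with_checksum(ev, file.path(cfg$out_dir, "eval.json"), man)
    if (!is.null(longitudinal)) {
      man <- write_with_checksum(longitudinal$per_patient,
                                 file.path(cfg$out_dir, "longitudinal.csv"), man)
    }
    jsonlite::write_json(list(seed = cfg$seed, checksums = man),
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage("done")
  result
}
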