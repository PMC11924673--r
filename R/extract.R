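# Per-case feature extraction: preprocessing, filter bank, and the full
# seven-family catalog on every image variant.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with its default:
#' resampling spacing 1.17 mm, 32 gray levels, the nine-variant filter
#' bank, GLCM distance 1, reproducibility gate thresholds (ICC >= 0.75,
#' CV <= 10%), 67/33 train/test split, 5-fold LASSO CV, 10-fold model CV,
#' and the selection settings. Every stochastic stage draws from `seed`.
#'
#' @param synthetic a [synthetic_config()] describing the cohort generator
#' @param target_spacing_mm resampling target (mm)
#' @param n_bins gray levels for discretization
#' @param filters image variants to extract
#' @param glcm_distance GLCM offset distance (pixels)
#' @param icc_threshold,cv_threshold reproducibility gate thresholds
#' @param train_frac training fraction of the cohort split
#' @param lasso_folds,cv_folds cross-validation folds (LASSO / model CV)
#' @param corr_threshold hierarchical-clustering cut on |Spearman rho|
#' @param boruta_max_iter Boruta iteration cap
#' @param n_gate_cases reader-study cases for the reproducibility gate
#' @param jitter_px reader contour jitter (pixels)
#' @param glmm_patients,glmm_years,glmm_effect longitudinal design
#' @param seed master seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            target_spacing_mm = 1.17,
                            n_bins = 32L,
                            filters = FILTER_NAMES,
                            glcm_distance = 1L,
                            icc_threshold = 0.75,
                            cv_threshold = 0.10,
                            train_frac = 0.67,
                            lasso_folds = 5L,
                            cv_folds = 10L,
                            corr_threshold = 0.75,
                            boruta_max_iter = 50L,
                            n_gate_cases = 15L,
                            jitter_px = 0.8,
                            glmm_patients = 15L,
                            glmm_years = 3L,
                            glmm_effect = 2,
                            seed = 1L) {
  cfg <- list(synthetic = synthetic, target_spacing_mm = target_spacing_mm,
              n_bins = as.integer(n_bins), filters = filters,
              glcm_distance = as.integer(glcm_distance),
              icc_threshold = icc_threshold, cv_threshold = cv_threshold,
              train_frac = train_frac, lasso_folds = as.integer(lasso_folds),
              cv_folds = as.integer(cv_folds),
              corr_threshold = corr_threshold,
              boruta_max_iter = as.integer(boruta_max_iter),
              n_gate_cases = as.integer(n_gate_cases), jitter_px = jitter_px,
              glmm_patients = as.integer(glmm_patients),
              glmm_years = as.integer(glmm_years), glmm_effect = glmm_effect,
              seed = as.integer(seed))
  if (cfg$target_spacing_mm <= 0) stopf("target spacing must be positive")
  if (cfg$n_bins < 2) stopf("n_bins must be >= 2")
  if (!all(cfg$filters %in% FILTER_NAMES)) stopf("unknown filter name")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) stopf("train_frac in (0,1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Preprocess a case: rasterize, resample, crop, normalize
#'
#' Runs the fixed preprocessing order (rasterize -> resample to the
#' target spacing -> crop to the mask bounding box with a filter-support
#' margin -> mu +/- 3 sigma normalization).
#'
#' @param case a `synthetic_case`, or a list with `t1_map` and `contours`
#' @param config a [pipeline_config()]
#' @return list(image, mask, spacing, norm_params)
#' @export
preprocess_case <- function(case, config = pipeline_config()) {
  map <- case$t1_map
  mask <- rasterize_ring_mask(case$contours, dim(map$pixels), map$spacing)
  rs <- resample_to_spacing(map, mask, config$target_spacing_mm)
  map <- rs$map; mask <- rs$mask
  if (!any(mask)) stopf("mask empty after resampling")
  margin <- 8L
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - margin); r1 <- min(nrow(mask), max(idx[, 1]) + margin)
  c0 <- max(1L, min(idx[, 2]) - margin); c1 <- min(ncol(mask), max(idx[, 2]) + margin)
  map <- new_t1_map(map$pixels[r0:r1, c0:c1, drop = FALSE], map$spacing,
                    map$case_id)
  mask <- mask[r0:r1, c0:c1, drop = FALSE]
  norm <- normalize_mu3sigma(map, mask)
  list(image = norm$map$pixels, mask = mask, spacing = map$spacing,
       norm_params = norm$params)
}

# all 102 features of one image variant, named "<family>__<feature>"
variant_features <- function(image, mask, spacing, n_bins, glcm_distance,
                             shape = NULL) {
  disc <- discretize(image, mask, n_bins)
  if (is.null(shape)) shape <- shape_features(mask, spacing)
  fams <- list(
    shape2d = shape,
    firstorder = firstorder_features(image, mask, disc,
                                     pixel_area_mm2 = prod(spacing)),
    glcm = glcm_features(compute_glcm(disc, glcm_distance)),
    gldm = gldm_features(compute_gldm(disc)),
    glrlm = glrlm_features(compute_glrlm(disc)),
    glszm = glszm_features(compute_glszm(disc)),
    ngtdm = ngtdm_features(compute_ngtdm(disc))
  )
  out <- unlist(fams, use.names = FALSE)
  names(out) <- unlist(lapply(names(fams), function(fam) {
    paste(fam, names(fams[[fam]]), sep = "__")
  }))
  out
}

#' Extract the full feature vector for one case
#'
#' Computes all seven feature families on every configured image variant.
#' With the default nine-variant bank this yields exactly 918 named
#' values (names "<filter>__<family>__<feature>"). Shape features depend
#' only on the mask and are therefore identical across variants; they are
#' reported per variant to keep the catalog rectangular.
#'
#' @param case a `synthetic_case` (or list with `t1_map` and `contours`)
#' @param config a [pipeline_config()]
#' @param contours optional replacement contours (reader variants)
#' @return named numeric vector, one element per catalog feature
#' @export
extract_features <- function(case, config = pipeline_config(),
                             contours = NULL) {
  if (!is.null(contours)) case$contours <- contours
  prep <- preprocess_case(case, config)
  variants <- filter_bank(prep$image, prep$spacing, prep$mask, config$filters)
  shape <- shape_features(prep$mask, prep$spacing)
  out <- numeric(0)
  for (f in names(variants)) {
    fv <- variant_features(variants[[f]], prep$mask, prep$spacing,
                           config$n_bins, config$glcm_distance, shape = shape)
    names(fv) <- paste(f, names(fv), sep = "__")
    out <- c(out, fv)
  }
  out
}

#' Extract a feature table for a cohort
#'
#' @param cases list of `synthetic_case`s
#' @param config a [pipeline_config()]
#' @param verbose log per-case timing to stderr
#' @return data.frame with metadata columns (case_id, lge_status, age,
#'   exam_year, patient_id) followed by the feature columns
#' @export
extract_cohort <- function(cases, config = pipeline_config(),
                           verbose = FALSE) {
  rows <- lapply(cases, function(cs) {
    t0 <- proc.time()[["elapsed"]]
    fv <- extract_features(cs, config)
    if (verbose) {
      message(sprintf("extracted %s: %d features in %.2f s", cs$case_id,
                      length(fv), proc.time()[["elapsed"]] - t0))
    }
    fv
  })
  feat <- do.call(rbind, rows)
  meta <- data.frame(
    case_id = vapply(cases, function(cs) cs$case_id, character(1)),
    lge_status = vapply(cases, function(cs) as.integer(cs$lge_status), integer(1)),
    age = vapply(cases, function(cs) cs$age, numeric(1)),
    exam_year = vapply(cases, function(cs) as.integer(cs$exam_year), integer(1)),
    patient_id = vapply(cases, function(cs) {
      if (is.null(cs$patient_id)) NA_character_ else cs$patient_id
    }, character(1)),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(feat, check.names = FALSE))
}

#' Names of the feature columns of a feature table
#' @param table a feature table from [extract_cohort()]
#' @return character vector
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table),
          c("case_id", "lge_status", "age", "exam_year", "patient_id",
            "reader", "repeat"))
}
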