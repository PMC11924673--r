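# Feature catalog: the single source of truth for family membership and
# the name schema "<filter>__<family>__<feature>". Seven families per
# image variant (9 shape, 18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM,
# 16 GLSZM, 5 NGTDM = 102), times nine variants = 918 features.

FAMILY_FEATURES <- list(
  shape2d = c("mesh_surface", "pixel_surface", "perimeter",
              "perimeter_surface_ratio", "sphericity", "major_axis_length",
              "minor_axis_length", "elongation", "maximum_diameter"),
  firstorder = c("energy", "total_energy", "entropy", "minimum", "p10",
                 "p90", "maximum", "mean", "median", "iqr", "range", "mad",
                 "rmad", "rms", "skewness", "kurtosis", "variance",
                 "uniformity"),
  glcm = c("autocorrelation", "joint_average", "cluster_prominence",
           "cluster_shade", "cluster_tendency", "contrast", "correlation",
           "difference_average", "difference_entropy", "difference_variance",
           "joint_energy", "joint_entropy", "imc1", "imc2", "idm", "idmn",
           "id", "idn", "inverse_variance", "maximum_probability",
           "sum_average", "sum_entropy", "sum_squares", "mcc"),
  gldm = c("small_dependence_emphasis", "large_dependence_emphasis",
           "gray_level_nonuniformity", "dependence_nonuniformity",
           "dependence_nonuniformity_normalized", "gray_level_variance",
           "dependence_variance", "dependence_entropy",
           "low_gray_level_emphasis", "high_gray_level_emphasis",
           "small_dependence_low_gray_level_emphasis",
           "small_dependence_high_gray_level_emphasis",
           "large_dependence_low_gray_level_emphasis",
           "large_dependence_high_gray_level_emphasis"),
  glrlm = c("short_run_emphasis", "long_run_emphasis",
            "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
            "run_length_nonuniformity", "run_length_nonuniformity_normalized",
            "run_percentage", "gray_level_variance", "run_variance",
            "run_entropy", "low_gray_level_run_emphasis",
            "high_gray_level_run_emphasis", "short_run_low_gray_level_emphasis",
            "short_run_high_gray_level_emphasis",
            "long_run_low_gray_level_emphasis",
            "long_run_high_gray_level_emphasis"),
  glszm = c("small_area_emphasis", "large_area_emphasis",
            "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
            "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
            "zone_percentage", "gray_level_variance", "zone_variance",
            "zone_entropy", "low_gray_level_zone_emphasis",
            "high_gray_level_zone_emphasis",
            "small_area_low_gray_level_emphasis",
            "small_area_high_gray_level_emphasis",
            "large_area_low_gray_level_emphasis",
            "large_area_high_gray_level_emphasis"),
  ngtdm = c("coarseness", "contrast", "busyness", "complexity", "strength")
)

#' Feature catalog manifest
#'
#' Enumerates every feature the extractor produces, one row per feature,
#' with its image-variant (filter), family, and short feature name. With
#' the full nine-variant filter bank the catalog has 918 rows.
#'
#' @param filters image variants to include (default all nine)
#' @return data.frame(name, filter, family, feature)
#' @export
feature_catalog <- function(filters = FILTER_NAMES) {
  rows <- do.call(rbind, lapply(filters, function(f) {
    do.call(rbind, lapply(names(FAMILY_FEATURES), function(fam) {
      data.frame(filter = f, family = fam, feature = FAMILY_FEATURES[[fam]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$name <- paste(rows$filter, rows$family, rows$feature, sep = "__")
  rows[, c("name", "filter", "family", "feature")]
}

#' Write the catalog manifest as JSON
#' @param path output path
#' @param filters image variants to include
#' @return the path, invisibly
#' @export
write_catalog_manifest <- function(path, filters = FILTER_NAMES) {
  cat_df <- feature_catalog(filters)
  jsonlite::write_json(list(
    n_features = nrow(cat_df),
    filters = filters,
    family_sizes = vapply(FAMILY_FEATURES, length, integer(1)),
    features = cat_df
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
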