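# File interchange: NIfTI images/masks, contour CSVs, cohort manifests,
# feature tables. Contour coordinates are in mm; pixel (r, c) (1-based,
# row-major) has its centre at x_mm = (c - 0.5) * col_spacing,
# y_mm = (r - 0.5) * row_spacing.

#' Write a T1 map (or mask) as NIfTI
#'
#' Pixel spacing is recorded in the NIfTI header. Masks are written as
#' 0/1 voxels.
#' @param map a `t1_map`, or a numeric/logical matrix
#' @param path output path (.nii or .nii.gz)
#' @param spacing (row_mm, col_mm), required when `map` is a bare matrix
#' @return the path, invisibly
#' @export
write_t1_nifti <- function(map, path, spacing = NULL) {
  if (inherits(map, "t1_map")) {
    pix <- map$pixels
    spacing <- map$spacing
  } else {
    pix <- map
    if (is.logical(pix)) pix <- pix * 1
    if (is.null(spacing)) stopf("spacing required for bare matrices")
  }
  img <- RNifti::asNifti(pix)
  RNifti::pixdim(img) <- c(spacing[1], spacing[2])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a T1 map from NIfTI
#'
#' Accepts 2D or single-slice 3D images; spacing is taken from the header.
#' @param path NIfTI file
#' @param case_id identifier to attach
#' @return a `t1_map`
#' @export
read_t1_nifti <- function(path, case_id = basename(path)) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] != 1L) stopf("only 2D or single-slice 3D images are supported")
    arr <- arr[, , 1]
  }
  if (length(dim(arr)) != 2L) stopf("expected a 2D image")
  new_t1_map(arr, c(pd[1], pd[2]), case_id)
}

#' Write contours as CSV
#'
#' Columns: case_id, contour (endo/epi), vertex_index, x_mm, y_mm.
#' @param contours a `contour_set`
#' @param case_id case identifier
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_contours_csv <- function(contours, case_id, path) {
  rows <- do.call(rbind, lapply(c("endo", "epi"), function(w) {
    poly <- contours[[w]]
    data.frame(case_id = case_id, contour = w,
               vertex_index = seq_len(nrow(poly)) - 1L,
               x_mm = poly[, 1], y_mm = poly[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read contours from CSV
#' @param path CSV written by [write_contours_csv()]
#' @return a `contour_set`
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  poly_of <- function(w) {
    sub <- df[df$contour == w, ]
    sub <- sub[order(sub$vertex_index), ]
    cbind(x_mm = sub$x_mm, y_mm = sub$y_mm)
  }
  new_contour_set(poly_of("endo"), poly_of("epi"))
}

#' Write a cohort manifest CSV
#'
#' Columns: case_id, lge_status, age, exam_year, reader, repeat.
#' @param cases list of `synthetic_case`s
#' @param path output CSV
#' @param reader,rep reader/repeat labels (recycled)
#' @return the path, invisibly
#' @export
write_cohort_manifest <- function(cases, path, reader = 1L, rep = 1L) {
  df <- data.frame(
    case_id = vapply(cases, function(cs) cs$case_id, character(1)),
    lge_status = vapply(cases, function(cs) cs$lge_status, integer(1)),
    age = vapply(cases, function(cs) cs$age, numeric(1)),
    exam_year = vapply(cases, function(cs) as.integer(cs$exam_year), integer(1)),
    reader = reader, repeat_idx = rep
  )
  names(df)[names(df) == "repeat_idx"] <- "repeat"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature table CSV
#'
#' Rows are cases (or case x reader x repeat), columns are metadata plus
#' the named texture features.
#' @param table data.frame feature table
#' @param path CSV path
#' @return the path (write) or the data.frame (read)
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
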