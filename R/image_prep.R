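# Image preparation: contour rasterization, spacing resampling,
# mu +/- 3 sigma intensity normalization, and gray-level discretization.
#
# Conventions: images are numeric matrices indexed [row, col]; the centre
# of pixel (r, c) lies at ((c - 0.5) * col_mm, (r - 0.5) * row_mm) in the
# contour coordinate frame.

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting (even-odd rule) for a set of query points.
#' @param px,py query point coordinates
#' @param poly polygon vertex matrix (x, y), implicitly closed
#' @return logical vector
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Rasterize endo/epi contours into an annular myocardial mask
#'
#' A pixel belongs to the mask iff its centre is inside the epicardial
#' polygon and not inside the endocardial polygon (even-odd rule).
#'
#' @param contours a `contour_set` (mm coordinates)
#' @param grid_shape (n_rows, n_cols)
#' @param spacing (row_mm, col_mm)
#' @return logical matrix of `grid_shape`
#' @export
rasterize_ring_mask <- function(contours, grid_shape, spacing) {
  endo <- contours$endo
  epi <- contours$epi
  if (nrow(endo) < 3L || nrow(epi) < 3L) stopf("polygons need >= 3 vertices")
  if (!all(point_in_polygon(endo[, 1], endo[, 2], epi))) {
    stopf("endocardial contour is not inside the epicardial contour")
  }
  nr <- grid_shape[1]; nc <- grid_shape[2]
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * spacing[2]
  cy <- (rep(seq_len(nr), times = nc) - 0.5) * spacing[1]
  # restrict the test to the epi bounding box
  keep <- cx >= min(epi[, 1]) - spacing[2] & cx <= max(epi[, 1]) + spacing[2] &
    cy >= min(epi[, 2]) - spacing[1] & cy <= max(epi[, 2]) + spacing[1]
  in_epi <- logical(nr * nc)
  in_epi[keep] <- point_in_polygon(cx[keep], cy[keep], epi)
  in_endo <- logical(nr * nc)
  in_endo[keep] <- point_in_polygon(cx[keep], cy[keep], endo)
  mask <- matrix(in_epi & !in_endo, nr, nc)
  if (!any(mask)) stopf("rasterized myocardial mask is empty")
  mask
}

bilinear_sample <- function(pix, r, c) {
  nr <- nrow(pix); nc <- ncol(pix)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c), nc - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1L, c0)
  i01 <- cbind(r0, c0 + 1L); i11 <- cbind(r0 + 1L, c0 + 1L)
  (1 - fr) * (1 - fc) * pix[i00] + fr * (1 - fc) * pix[i10] +
    (1 - fr) * fc * pix[i01] + fr * fc * pix[i11]
}

#' Resample an image and mask to a target pixel spacing
#'
#' The image is resampled by bilinear interpolation and the mask by
#' nearest-neighbour lookup, both onto a grid whose pixel centres are at
#' (i - 0.5) * target_spacing in the same mm frame. A map already at the
#' target spacing is returned unchanged.
#'
#' @param map a `t1_map`
#' @param mask logical matrix aligned to `map`
#' @param target_spacing target in-plane spacing (mm), default 1.17
#' @return list(map, mask) at the new spacing
#' @export
resample_to_spacing <- function(map, mask, target_spacing = 1.17) {
  if (target_spacing <= 0) stopf("target spacing must be positive")
  sp <- map$spacing
  if (abs(sp[1] - target_spacing) < 1e-9 && abs(sp[2] - target_spacing) < 1e-9) {
    return(list(map = map, mask = mask))
  }
  nr <- nrow(map$pixels); nc <- ncol(map$pixels)
  nr2 <- max(1L, as.integer(round(nr * sp[1] / target_spacing)))
  nc2 <- max(1L, as.integer(round(nc * sp[2] / target_spacing)))
  # source fractional pixel index of each new pixel centre
  rr <- ((seq_len(nr2) - 0.5) * target_spacing) / sp[1] + 0.5
  cc <- ((seq_len(nc2) - 0.5) * target_spacing) / sp[2] + 0.5
  R <- matrix(rr, nr2, nc2)
  C <- matrix(cc, nr2, nc2, byrow = TRUE)
  pix2 <- matrix(bilinear_sample(map$pixels, as.vector(R), as.vector(C)), nr2, nc2)
  rn <- pmin(pmax(as.integer(round(rr)), 1L), nr)
  cn <- pmin(pmax(as.integer(round(cc)), 1L), nc)
  mask2 <- mask[rn, cn, drop = FALSE]
  list(map = new_t1_map(pix2, c(target_spacing, target_spacing), map$case_id),
       mask = mask2)
}

#' Normalize in-mask intensities to the mu +/- 3 sigma band
#'
#' Computes the mean and standard deviation of the in-mask gray levels and
#' clips in-mask intensities to [mu - 3 sigma, mu + 3 sigma]. Clipping
#' (rather than rescaling) follows the outlier-removal reading of the
#' band and leaves in-band images untouched. A constant in-mask image
#' (sigma = 0) is flagged and passed through unchanged.
#'
#' @param map a `t1_map`
#' @param mask logical matrix
#' @return list(map, params = list(mu, sigma, degenerate))
#' @export
normalize_mu3sigma <- function(map, mask) {
  v <- map$pixels[mask]
  if (length(v) == 0L) stopf("empty mask")
  mu <- mean(v)
  sigma <- stats::sd(v)
  if (!is.finite(sigma) || sigma == 0) {
    return(list(map = map, params = list(mu = mu, sigma = 0, degenerate = TRUE)))
  }
  lo <- mu - 3 * sigma
  hi <- mu + 3 * sigma
  pix <- map$pixels
  inm <- which(mask)
  pix[inm] <- pmin(pmax(pix[inm], lo), hi)
  list(map = new_t1_map(pix, map$spacing, map$case_id),
       params = list(mu = mu, sigma = sigma, degenerate = FALSE))
}

#' Discretize in-mask intensities into equal-width gray-level bins
#'
#' The in-mask range [min, max] is split into `n_bins` equal-width bins;
#' level(x) = min(floor((x - min) / width) + 1, n_bins). A constant image
#' yields a single level (Ng = 1). Off-mask pixels are NA.
#'
#' @param map a `t1_map` or numeric matrix
#' @param mask logical matrix
#' @param n_bins number of gray levels (>= 2)
#' @return list(levels = integer matrix with NA off-mask, n_levels)
#' @export
discretize <- function(map, mask, n_bins = 32L) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  pix <- if (inherits(map, "t1_map")) map$pixels else map
  v <- pix[mask]
  if (length(v) == 0L) stopf("empty mask")
  lo <- min(v); hi <- max(v)
  lev <- matrix(NA_integer_, nrow(pix), ncol(pix))
  if (hi == lo) {
    lev[mask] <- 1L
    return(list(levels = lev, n_levels = 1L))
  }
  width <- (hi - lo) / n_bins
  lev[mask] <- pmin(as.integer(floor((v - lo) / width)) + 1L, as.integer(n_bins))
  list(levels = lev, n_levels = as.integer(n_bins))
}
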