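# First-order intensity statistics and 2D shape descriptors.

#' First-order feature panel (18 features)
#'
#' Intensity statistics over the in-mask pixels of one image variant.
#' Entropy and uniformity are computed from the discretized in-mask
#' histogram (entropy in bits, so entropy <= log2(Ng)); all other
#' statistics use the raw (continuous) in-mask intensities. Variance,
#' skewness and kurtosis use the population (1/N) moments and kurtosis is
#' not excess-corrected. RMS is sqrt(mean(x^2)).
#'
#' @param image numeric matrix (one filtered variant)
#' @param mask logical matrix
#' @param disc the discretized variant from [discretize()]
#' @param pixel_area_mm2 pixel area (mm^2), used by total energy
#' @return named numeric vector of the 18 first-order features
#' @export
firstorder_features <- function(image, mask, disc, pixel_area_mm2 = 1) {
  x <- image[mask]
  if (length(x) == 0L) stopf("empty mask")
  n <- length(x)
  counts <- table(factor(disc$levels[mask], levels = seq_len(disc$n_levels)))
  p <- as.vector(counts) / n
  m <- mean(x)
  cm <- x - m
  m2 <- mean(cm^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  inner <- x[x >= q[1] & x <= q[5]]
  c(
    energy = sum(x^2),
    total_energy = pixel_area_mm2 * sum(x^2),
    entropy = entropy_bits(p),
    minimum = min(x),
    p10 = q[1],
    p90 = q[5],
    maximum = max(x),
    mean = m,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(cm)),
    rmad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) mean(cm^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(cm^4) / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2)
  )
}

# marching-squares area fractions and boundary lengths per 2x2 cell,
# with mid-edge vertices (iso-level halfway between pixel centres)
ms_cell_tables <- function(sx, sy) {
  h <- sqrt((sx / 2)^2 + (sy / 2)^2)
  area <- numeric(16)
  per <- numeric(16)
  cell <- sx * sy
  for (code in 0:15) {
    tl <- bitwAnd(code, 1L) > 0
    tr <- bitwAnd(code, 2L) > 0
    bl <- bitwAnd(code, 4L) > 0
    br <- bitwAnd(code, 8L) > 0
    k <- sum(tl, tr, bl, br)
    if (k == 0) {
      a <- 0; p <- 0
    } else if (k == 4) {
      a <- 1; p <- 0
    } else if (k == 1) {
      a <- 1 / 8; p <- h
    } else if (k == 3) {
      a <- 7 / 8; p <- h
    } else {
      # two corners: adjacent -> half cell and a straight cut; diagonal ->
      # two opposite corner triangles (the disconnected resolution)
      horiz <- (tl && tr) || (bl && br)
      vert <- (tl && bl) || (tr && br)
      if (horiz) {
        a <- 1 / 2; p <- sx
      } else if (vert) {
        a <- 1 / 2; p <- sy
      } else {
        a <- 1 / 4; p <- 2 * h
      }
    }
    area[code + 1L] <- a * cell
    per[code + 1L] <- p
  }
  list(area = area, per = per)
}

#' Shape feature panel (9 features) from the mask alone
#'
#' Mesh surface (area) and perimeter come from a marching-squares contour
#' at the half-level between pixel centres; pixel surface is the pixel
#' count times the pixel area; the axis lengths are 4 sqrt(lambda) from a
#' PCA of the in-mask pixel-centre coordinates; the maximum diameter is
#' the largest pairwise distance between boundary pixel centres; the
#' sphericity analogue is 2 sqrt(pi A) / P.
#'
#' @param mask logical matrix
#' @param spacing (row_mm, col_mm)
#' @return named numeric vector of the 9 shape features
#' @export
shape_features <- function(mask, spacing = c(1, 1)) {
  if (!any(mask)) stopf("empty mask")
  sy <- spacing[1]; sx <- spacing[2]
  padded <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(padded); nc <- ncol(padded)
  tl <- padded[-nr, -nc]; tr <- padded[-nr, -1]
  bl <- padded[-1, -nc]; br <- padded[-1, -1]
  code <- tl * 1L + tr * 2L + bl * 4L + br * 8L
  tabs <- ms_cell_tables(sx, sy)
  mesh_surface <- sum(tabs$area[code + 1L])
  perimeter <- sum(tabs$per[code + 1L])
  n <- sum(mask)
  pixel_surface <- n * sx * sy

  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind((idx[, 2] - 0.5) * sx, (idx[, 1] - 0.5) * sy)
  if (n > 1L) {
    ev <- sort(eigen(stats::cov(xy), only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
  } else {
    ev <- c(0, 0)
  }
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1

  # boundary pixels: in-mask with at least one off-mask 8-neighbour
  interior <- mask
  for (sh in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L),
                  c(0L, -1L), c(-1L, 0L), c(-1L, -1L), c(-1L, 1L))) {
    interior <- interior & shift_matrix(mask, sh[1], sh[2], fill = FALSE)
  }
  bidx <- which(mask & !interior, arr.ind = TRUE)
  if (nrow(bidx) == 0L) bidx <- idx
  bxy <- cbind((bidx[, 2] - 0.5) * sx, (bidx[, 1] - 0.5) * sy)
  hull <- if (nrow(bxy) > 2L) bxy[grDevices::chull(bxy), , drop = FALSE] else bxy
  maxd <- if (nrow(hull) > 1L) max(stats::dist(hull)) else 0

  c(
    mesh_surface = mesh_surface,
    pixel_surface = pixel_surface,
    perimeter = perimeter,
    perimeter_surface_ratio = perimeter / mesh_surface,
    sphericity = 2 * sqrt(pi * mesh_surface) / perimeter,
    major_axis_length = major,
    minor_axis_length = minor,
    elongation = elong,
    maximum_diameter = maxd
  )
}
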