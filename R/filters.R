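# Filter bank: the eight filtered variants of the normalized image on
# which texture families are recomputed (plus the original): gradient
# magnitude, square, LBP(8,1), LBP(8,2), and the four single-level
# stationary wavelet sub-bands LL/LH/HL/HH.

FILTER_NAMES <- c("original", "gradient", "square", "lbp_8_1", "lbp_8_2",
                  "wavelet_LL", "wavelet_LH", "wavelet_HL", "wavelet_HH")

# Coiflet-1 analysis filter bank (orthonormal; sum(lo) = sqrt(2), sum(hi) = 0)
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

#' Gradient-magnitude filter
#'
#' Spacing-aware per-pixel gradient magnitude using central differences in
#' the interior and one-sided differences at the borders.
#' @param image numeric matrix
#' @param spacing (row_mm, col_mm)
#' @return numeric matrix of the same shape
#' @export
gradient_filter <- function(image, spacing = c(1, 1)) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 2L || nc < 2L) stopf("gradient filter needs at least a 2x2 image")
  gr <- matrix(0, nr, nc)
  gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / (2 * spacing[1])
  gr[1, ] <- (image[2, ] - image[1, ]) / spacing[1]
  gr[nr, ] <- (image[nr, ] - image[nr - 1, ]) / spacing[1]
  gc[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / (2 * spacing[2])
  gc[, 1] <- (image[, 2] - image[, 1]) / spacing[2]
  gc[, nc] <- (image[, nc] - image[, nc - 1]) / spacing[2]
  sqrt(gr^2 + gc^2)
}

#' Square filter
#'
#' Pixel-wise square, linearly rescaled so the (in-mask) maximum absolute
#' value equals the pre-filter maximum absolute value. An all-zero image
#' maps to itself.
#' @param image numeric matrix
#' @param mask optional logical matrix restricting the rescaling reference
#' @return numeric matrix
#' @export
square_filter <- function(image, mask = NULL) {
  ref <- if (is.null(mask)) image else image[mask]
  m0 <- max(abs(ref))
  sq <- image^2
  ms <- if (is.null(mask)) max(sq) else max(sq[mask])
  if (ms == 0) return(sq)
  sq * (m0 / ms)
}

#' Rotation-invariant uniform local binary pattern filter
#'
#' For each pixel, `points` circularly interpolated neighbours at the given
#' radius are thresholded at the centre value (neighbour >= centre). Uniform
#' patterns (at most two 0/1 transitions around the circle) are coded by
#' their number of set bits (0..points); non-uniform patterns get code
#' points + 1 (riu2 coding). The image border is reflected.
#'
#' @param image numeric matrix
#' @param points sampling points on the circle
#' @param radius circle radius in pixels (1 or 2 in this pipeline)
#' @return numeric matrix of LBP codes
#' @export
lbp_filter <- function(image, points = 8L, radius = 1) {
  nr <- nrow(image); nc <- ncol(image)
  if (radius >= min(nr, nc) / 2) stopf("radius too large for the image")
  pad <- as.integer(ceiling(radius)) + 1L
  padded <- pad_reflect(image, pad)
  # tolerance so exact ties survive interpolation round-off
  tol <- 1e-9 * (max(abs(image)) + 1)
  bits <- vector("list", points)
  for (k in seq_len(points)) {
    th <- 2 * pi * (k - 1) / points
    dr <- -radius * sin(th)
    dc <- radius * cos(th)
    rr <- matrix(seq_len(nr) + pad + dr, nr, nc)
    cc <- matrix(seq_len(nc) + pad + dc, nr, nc, byrow = TRUE)
    nb <- matrix(bilinear_sample(padded, as.vector(rr), as.vector(cc)), nr, nc)
    bits[[k]] <- (nb - image >= -tol) * 1L
  }
  ones <- Reduce(`+`, bits)
  trans <- matrix(0L, nr, nc)
  for (k in seq_len(points)) {
    nxt <- if (k == points) 1L else k + 1L
    trans <- trans + (bits[[k]] != bits[[nxt]])
  }
  code <- ones
  code[trans > 2L] <- points + 1L
  code
}

pad_reflect <- function(image, pad) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- c(rev(seq_len(pad)), seq_len(nr), nr - seq_len(pad) + 1L)
  ci <- c(rev(seq_len(pad)), seq_len(nc), nc - seq_len(pad) + 1L)
  image[ri, ci, drop = FALSE]
}

# 1D filtering along matrix columns with whole-sample symmetric extension;
# output is centre-aligned and shape-preserving.
filter_cols_sym <- function(m, h) {
  L <- length(h)
  nr <- nrow(m)
  if (nr < L) stopf("image smaller than the wavelet filter support")
  top <- m[rev(seq_len(L)), , drop = FALSE]
  bot <- m[nr - seq_len(L) + 1L, , drop = FALSE]
  ext <- rbind(top, m, bot)
  out <- matrix(0, nr, ncol(m))
  off <- L - floor(L / 2)  # centre alignment within the extension
  for (k in seq_len(L)) {
    out <- out + h[k] * ext[(off + k - 1L) + seq_len(nr), , drop = FALSE]
  }
  out
}

#' Single-level stationary 2D wavelet sub-bands
#'
#' Undecimated (shape-preserving) single-level 2D discrete wavelet
#' transform with the Coiflet-1 filter pair and symmetric boundary
#' extension. Sub-band names: first letter = filter along rows, second =
#' along columns (LL = low/low approximation, HH = diagonal detail).
#'
#' @param image numeric matrix (at least 6x6)
#' @return named list of matrices LL, LH, HL, HH, each the input's shape
#' @export
wavelet_subbands <- function(image) {
  lo_c <- filter_cols_sym(image, COIF1_LO)
  hi_c <- filter_cols_sym(image, COIF1_HI)
  tlo <- function(m) t(filter_cols_sym(t(m), COIF1_LO))
  thi <- function(m) t(filter_cols_sym(t(m), COIF1_HI))
  list(LL = tlo(lo_c), LH = thi(lo_c), HL = tlo(hi_c), HH = thi(hi_c))
}

#' Apply the full filter bank to a normalized image
#'
#' Produces the named set of image variants (original plus eight filtered
#' versions), all the same shape as the input so the myocardial mask
#' applies unchanged.
#'
#' @param image numeric matrix (normalized intensities)
#' @param spacing (row_mm, col_mm), used by the gradient filter
#' @param mask optional logical matrix (square-filter rescaling reference)
#' @param filters subset of the nine variant names to compute
#' @return named list of matrices
#' @export
filter_bank <- function(image, spacing = c(1, 1), mask = NULL,
                        filters = FILTER_NAMES) {
  bad <- setdiff(filters, FILTER_NAMES)
  if (length(bad)) stopf("unknown filters: %s", paste(bad, collapse = ", "))
  out <- list()
  wav <- NULL
  for (f in filters) {
    out[[f]] <- switch(f,
      original = image,
      gradient = gradient_filter(image, spacing),
      square = square_filter(image, mask),
      lbp_8_1 = lbp_filter(image, 8L, 1),
      lbp_8_2 = lbp_filter(image, 8L, 2),
      {
        if (is.null(wav)) wav <- wavelet_subbands(image)
        wav[[sub("wavelet_", "", f)]]
      })
  }
  out
}
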