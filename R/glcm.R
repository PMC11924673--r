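# Gray-level co-occurrence matrix (GLCM) and its 24 features.
#
# Construction: distance-1 offsets along the four 2D angles (0,1), (1,1),
# (1,0), (1,-1); ordered in-mask level pairs are counted per angle,
# symmetrized, and normalized to sum 1. Features are computed per angle
# and averaged over the angles with at least one valid pair.

GLCM_ANGLES <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

#' Compute the gray-level co-occurrence matrix
#'
#' @param disc a discretized image as returned by [discretize()]
#' @param distance pixel offset distance (default 1)
#' @return a `glcm` object: list of per-angle Ng x Ng probability
#'   matrices (symmetric, summing to 1) plus `n_levels`
#' @export
compute_glcm <- function(disc, distance = 1L) {
  lev <- disc$levels
  ng <- disc$n_levels
  mats <- list()
  for (a in seq_along(GLCM_ANGLES)) {
    dr <- GLCM_ANGLES[[a]][1] * distance
    dc <- GLCM_ANGLES[[a]][2] * distance
    nb <- shift_matrix(lev, dr, dc)
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) next
    l1 <- factor(lev[ok], levels = seq_len(ng))
    l2 <- factor(nb[ok], levels = seq_len(ng))
    counts <- unname(unclass(table(l1, l2)))
    dimnames(counts) <- NULL
    P <- counts + t(counts)
    mats[[length(mats) + 1L]] <- P / sum(P)
  }
  if (length(mats) == 0L) stopf("no valid pixel pair at any GLCM angle")
  structure(list(p = mats, n_levels = ng), class = "glcm")
}

# Full 24-feature panel from one per-angle probability matrix
glcm_features_single <- function(p, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- matrix(seq_len(ng), ng, ng, byrow = TRUE)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px)
  mu_y <- sum(seq_len(ng) * py)
  sig_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sig_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))

  # distributions of i+j and |i-j|
  sums <- as.vector(i + j)
  diffs <- as.vector(abs(i - j))
  pxy_sum <- tapply(as.vector(p), sums, sum)
  k_sum <- as.numeric(names(pxy_sum))
  pxy_diff <- tapply(as.vector(p), diffs, sum)
  k_diff <- as.numeric(names(pxy_diff))

  joint_entropy <- entropy_bits(as.vector(p))
  hx <- entropy_bits(px)
  hy <- entropy_bits(py)
  pxpy <- outer(px, py)
  pos <- pxpy > 0
  hxy1 <- -sum(p[pos] * log2(pxpy[pos]))
  hxy2 <- -sum(xlog2x(pxpy[pos]))
  imc1 <- if (max(hx, hy) > 0) (joint_entropy - hxy1) / max(hx, hy) else 0
  imc2_arg <- 1 - exp(-2 * (hxy2 - joint_entropy))
  imc2 <- sqrt(max(0, imc2_arg))

  autoc <- sum(i * j * p)
  correlation <- if (sig_x > 0 && sig_y > 0) {
    (autoc - mu_x * mu_y) / (sig_x * sig_y)
  } else 1

  da <- sum(k_diff * pxy_diff)

  # MCC: second-largest eigenvalue of Q over levels with positive marginals
  nz <- which(px > 0)
  mcc <- if (length(nz) < 2L) 1 else {
    psub <- p[nz, nz, drop = FALSE]
    Q <- diag(1 / px[nz], nrow = length(nz)) %*% psub %*%
      diag(1 / py[nz], nrow = length(nz)) %*% t(psub)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }

  iv_mask <- i != j
  c(
    autocorrelation = autoc,
    joint_average = mu_x,
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = correlation,
    difference_average = da,
    difference_entropy = entropy_bits(pxy_diff),
    difference_variance = sum((k_diff - da)^2 * pxy_diff),
    joint_energy = sum(p^2),
    joint_entropy = joint_entropy,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    id = sum(p / (1 + abs(i - j))),
    idn = sum(p / (1 + abs(i - j) / ng)),
    inverse_variance = sum(p[iv_mask] / (i[iv_mask] - j[iv_mask])^2),
    maximum_probability = max(p),
    sum_average = sum(k_sum * pxy_sum),
    sum_entropy = entropy_bits(pxy_sum),
    sum_squares = sig_x^2,
    mcc = mcc
  )
}

#' GLCM feature panel (angle-averaged)
#' @param glcm a `glcm` object
#' @return named numeric vector of the 24 GLCM features
#' @export
glcm_features <- function(glcm) {
  per_angle <- vapply(glcm$p, glcm_features_single, numeric(24),
                      ng = glcm$n_levels)
  rowMeans(per_angle)
}

#' Inverse difference moment normalized
#'
#' IDMN = sum_ij p(i, j) / (1 + (i - j)^2 / Ng^2); lies in (0, 1] and
#' equals 1 iff all co-occurrence mass is on the diagonal.
#' @param glcm a `glcm` object
#' @return scalar
#' @export
glcm_idmn <- function(glcm) {
  unname(glcm_features(glcm)["idmn"])
}

#' GLCM sum entropy
#'
#' Entropy (bits) of the distribution of gray-level sums of co-occurring
#' pixel pairs: with p_(x+y)(k) = sum_{i+j=k} p(i, j), sum entropy =
#' -sum_k p_(x+y)(k) log2 p_(x+y)(k).
#' @param glcm a `glcm` object
#' @return scalar >= 0
#' @export
glcm_sum_entropy <- function(glcm) {
  unname(glcm_features(glcm)["sum_entropy"])
}
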