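# Run-length, size-zone, dependence, and neighbouring gray-tone
# difference matrix families.
#
# Conventions: gray levels are the 1..Ng discretized values; GLRLM uses
# the same four angles as the GLCM with features averaged over angles;
# GLSZM zones and GLDM neighbourhoods use full 8-connectivity; the GLDM
# dependence threshold is alpha = 0 (equal levels) at Chebyshev distance
# 1, with the dependence index j = (number of dependent neighbours) + 1.

# --- GLRLM ------------------------------------------------------------------

# split the level matrix into directed scan lines
glrlm_lines <- function(lev, angle) {
  switch(angle,
    h = lapply(seq_len(nrow(lev)), function(r) lev[r, ]),
    v = lapply(seq_len(ncol(lev)), function(c) lev[, c]),
    d = split(lev, row(lev) - col(lev)),   # down-right diagonals
    a = split(lev, row(lev) + col(lev))    # down-left anti-diagonals
  )
}

#' Compute gray-level run-length matrices (one per angle)
#'
#' Runs are maximal same-level in-mask segments along each of the four
#' scan directions; off-mask pixels break runs.
#' @param disc a discretized image from [discretize()]
#' @return a `glrlm` object: per-angle count matrices (Ng x max run
#'   length), `n_levels`, and `n_pixels`
#' @export
compute_glrlm <- function(disc) {
  lev <- disc$levels
  ng <- disc$n_levels
  np <- sum(!is.na(lev))
  if (np == 0L) stopf("empty mask")
  mats <- lapply(c("h", "v", "d", "a"), function(a) {
    runs_i <- integer(0)
    runs_l <- integer(0)
    for (line in glrlm_lines(lev, a)) {
      r <- rle(as.vector(line))
      keep <- !is.na(r$values)
      runs_i <- c(runs_i, r$values[keep])
      runs_l <- c(runs_l, r$lengths[keep])
    }
    maxlen <- max(runs_l)
    R <- matrix(0, ng, maxlen)
    for (k in seq_along(runs_i)) {
      R[runs_i[k], runs_l[k]] <- R[runs_i[k], runs_l[k]] + 1
    }
    R
  })
  structure(list(R = mats, n_levels = ng, n_pixels = np), class = "glrlm")
}

glrlm_features_single <- function(R, np) {
  nr_runs <- sum(R)
  iv <- seq_len(nrow(R))
  jv <- seq_len(ncol(R))
  ri <- rowSums(R)
  rj <- colSums(R)
  p <- R / nr_runs
  pi_m <- ri / nr_runs
  pj_m <- rj / nr_runs
  mu_i <- sum(iv * pi_m)
  mu_j <- sum(jv * pj_m)
  c(
    short_run_emphasis = sum(rj / jv^2) / nr_runs,
    long_run_emphasis = sum(rj * jv^2) / nr_runs,
    gray_level_nonuniformity = sum(ri^2) / nr_runs,
    gray_level_nonuniformity_normalized = sum(ri^2) / nr_runs^2,
    run_length_nonuniformity = sum(rj^2) / nr_runs,
    run_length_nonuniformity_normalized = sum(rj^2) / nr_runs^2,
    run_percentage = nr_runs / np,
    gray_level_variance = sum((iv - mu_i)^2 * pi_m),
    run_variance = sum((jv - mu_j)^2 * pj_m),
    run_entropy = entropy_bits(as.vector(p)),
    low_gray_level_run_emphasis = sum(ri / iv^2) / nr_runs,
    high_gray_level_run_emphasis = sum(ri * iv^2) / nr_runs,
    short_run_low_gray_level_emphasis = sum(R / outer(iv^2, jv^2)) / nr_runs,
    short_run_high_gray_level_emphasis = sum(R * outer(iv^2, 1 / jv^2)) / nr_runs,
    long_run_low_gray_level_emphasis = sum(R * outer(1 / iv^2, jv^2)) / nr_runs,
    long_run_high_gray_level_emphasis = sum(R * outer(iv^2, jv^2)) / nr_runs
  )
}

#' GLRLM feature panel (angle-averaged)
#' @param glrlm a `glrlm` object
#' @return named numeric vector of the 16 GLRLM features
#' @export
glrlm_features <- function(glrlm) {
  per_angle <- vapply(glrlm$R, glrlm_features_single, numeric(16),
                      np = glrlm$n_pixels)
  rowMeans(per_angle)
}

# --- GLSZM ------------------------------------------------------------------

# 8-connected same-level zone labelling by iterative minimum-label
# propagation (all gray levels at once)
label_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  lab <- matrix(as.integer(seq_len(nr * nc)), nr, nc)
  lab[is.na(levels)] <- NA_integer_
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L),
                 c(0L, -1L), c(-1L, 0L), c(-1L, -1L), c(-1L, 1L))
  repeat {
    changed <- FALSE
    for (sh in shifts) {
      nb_lab <- shift_matrix(lab, sh[1], sh[2])
      nb_lev <- shift_matrix(levels, sh[1], sh[2])
      upd <- which(levels == nb_lev & nb_lab < lab)
      if (length(upd)) {
        lab[upd] <- nb_lab[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Compute the gray-level size-zone matrix
#'
#' Zones are maximal 8-connected in-mask components of equal gray level;
#' every in-mask pixel belongs to exactly one zone.
#' @param disc a discretized image from [discretize()]
#' @return a `glszm` object: per-zone levels and sizes, `n_zones`,
#'   `n_pixels`, `n_levels`
#' @export
compute_glszm <- function(disc) {
  lev <- disc$levels
  np <- sum(!is.na(lev))
  if (np == 0L) stopf("empty mask")
  lab <- label_zones(lev)
  inm <- !is.na(lab)
  ids <- lab[inm]
  zone_size <- as.vector(table(ids))
  # table() orders by sorted unique id; align the level lookup with it
  ord_ids <- sort(unique(ids))
  lvl_by_id <- lev[inm][match(ord_ids, ids)]
  structure(list(zone_level = lvl_by_id, zone_size = zone_size,
                 n_zones = length(ord_ids), n_pixels = np,
                 n_levels = disc$n_levels), class = "glszm")
}

#' GLSZM feature panel
#' @param glszm a `glszm` object
#' @return named numeric vector of the 16 GLSZM features
#' @export
glszm_features <- function(glszm) {
  i <- glszm$zone_level
  s <- glszm$zone_size
  nz <- glszm$n_zones
  np <- glszm$n_pixels
  ni <- table(i)
  ns <- table(s)
  cell <- table(interaction(i, s, drop = TRUE))
  mu_i <- mean(i)
  mu_s <- mean(s)
  c(
    small_area_emphasis = mean(1 / s^2),
    large_area_emphasis = mean(s^2),
    gray_level_nonuniformity = sum(ni^2) / nz,
    gray_level_nonuniformity_normalized = sum(ni^2) / nz^2,
    size_zone_nonuniformity = sum(ns^2) / nz,
    size_zone_nonuniformity_normalized = sum(ns^2) / nz^2,
    zone_percentage = nz / np,
    gray_level_variance = mean((i - mu_i)^2),
    zone_variance = mean((s - mu_s)^2),
    zone_entropy = entropy_bits(as.vector(cell) / nz),
    low_gray_level_zone_emphasis = mean(1 / i^2),
    high_gray_level_zone_emphasis = mean(i^2),
    small_area_low_gray_level_emphasis = mean(1 / (i^2 * s^2)),
    small_area_high_gray_level_emphasis = mean(i^2 / s^2),
    large_area_low_gray_level_emphasis = mean(s^2 / i^2),
    large_area_high_gray_level_emphasis = mean(i^2 * s^2)
  )
}

#' GLSZM zone percentage
#'
#' Number of zones divided by the in-mask pixel count; in (0, 1], equal
#' to 1 iff every pixel is its own zone (maximally rough texture).
#' @param glszm a `glszm` object
#' @return scalar
#' @export
glszm_zone_percentage <- function(glszm) {
  glszm$n_zones / glszm$n_pixels
}

# --- GLDM -------------------------------------------------------------------

#' Compute the gray-level dependence matrix
#'
#' A Chebyshev-distance-1 neighbour is dependent on the centre pixel when
#' their levels differ by at most `alpha`. Each in-mask pixel contributes
#' one entry at (its level, number of dependent neighbours + 1).
#' @param disc a discretized image from [discretize()]
#' @param alpha dependence threshold on the level difference (default 0)
#' @return a `gldm` object: per-pixel levels and dependence indices
#' @export
compute_gldm <- function(disc, alpha = 0L) {
  lev <- disc$levels
  np <- sum(!is.na(lev))
  if (np == 0L) stopf("empty mask")
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L),
                 c(0L, -1L), c(-1L, 0L), c(-1L, -1L), c(-1L, 1L))
  dep <- matrix(0L, nrow(lev), ncol(lev))
  for (sh in shifts) {
    nb <- shift_matrix(lev, sh[1], sh[2])
    hit <- !is.na(lev) & !is.na(nb) & abs(lev - nb) <= alpha
    dep <- dep + hit
  }
  inm <- !is.na(lev)
  structure(list(pixel_level = lev[inm], pixel_dep = dep[inm] + 1L,
                 n_pixels = np, n_levels = disc$n_levels), class = "gldm")
}

#' GLDM feature panel
#' @param gldm a `gldm` object
#' @return named numeric vector of the 14 GLDM features
#' @export
gldm_features <- function(gldm) {
  i <- gldm$pixel_level
  j <- gldm$pixel_dep
  nd <- gldm$n_pixels
  ni <- table(i)
  nj <- table(j)
  cell <- table(interaction(i, j, drop = TRUE))
  mu_i <- mean(i)
  mu_j <- mean(j)
  c(
    small_dependence_emphasis = mean(1 / j^2),
    large_dependence_emphasis = mean(j^2),
    gray_level_nonuniformity = sum(ni^2) / nd,
    dependence_nonuniformity = sum(nj^2) / nd,
    dependence_nonuniformity_normalized = sum(nj^2) / nd^2,
    gray_level_variance = mean((i - mu_i)^2),
    dependence_variance = mean((j - mu_j)^2),
    dependence_entropy = entropy_bits(as.vector(cell) / nd),
    low_gray_level_emphasis = mean(1 / i^2),
    high_gray_level_emphasis = mean(i^2),
    small_dependence_low_gray_level_emphasis = mean(1 / (i^2 * j^2)),
    small_dependence_high_gray_level_emphasis = mean(i^2 / j^2),
    large_dependence_low_gray_level_emphasis = mean(j^2 / i^2),
    large_dependence_high_gray_level_emphasis = mean(i^2 * j^2)
  )
}

# --- NGTDM ------------------------------------------------------------------

#' Compute the neighbouring gray-tone difference matrix
#'
#' For each in-mask pixel with at least one in-mask 8-neighbour, the
#' absolute difference between its level and the mean level of those
#' neighbours is accumulated per gray level.
#' @param disc a discretized image from [discretize()]
#' @return a `ngtdm` object: per-level counts n_i, sums s_i, and the
#'   valid-pixel count
#' @export
compute_ngtdm <- function(disc) {
  lev <- disc$levels
  ng <- disc$n_levels
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L),
                 c(0L, -1L), c(-1L, 0L), c(-1L, -1L), c(-1L, 1L))
  nb_sum <- matrix(0, nrow(lev), ncol(lev))
  nb_cnt <- matrix(0L, nrow(lev), ncol(lev))
  for (sh in shifts) {
    nb <- shift_matrix(lev, sh[1], sh[2])
    ok <- !is.na(nb)
    nb_sum[ok] <- nb_sum[ok] + nb[ok]
    nb_cnt <- nb_cnt + ok
  }
  valid <- !is.na(lev) & nb_cnt > 0L
  if (!any(valid)) stopf("no pixel with a valid neighbourhood")
  A <- nb_sum[valid] / nb_cnt[valid]
  li <- lev[valid]
  n_i <- numeric(ng)
  s_i <- numeric(ng)
  for (g in seq_len(ng)) {
    sel <- li == g
    n_i[g] <- sum(sel)
    s_i[g] <- sum(abs(g - A[sel]))
  }
  structure(list(n = n_i, s = s_i, n_valid = sum(n_i), n_levels = ng),
            class = "ngtdm")
}

#' NGTDM feature panel
#' @param ngtdm a `ngtdm` object
#' @return named numeric vector of the 5 NGTDM features
#' @export
ngtdm_features <- function(ngtdm) {
  present <- which(ngtdm$n > 0)
  nvp <- ngtdm$n_valid
  p <- ngtdm$n / nvp
  s <- ngtdm$s
  ngp <- length(present)
  i <- present
  pi_ <- p[present]
  si <- s[present]

  coars_den <- sum(pi_ * si)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6

  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * outer(i, i, "-")^2) / (ngp * (ngp - 1))) *
      (sum(si) / nvp)
  } else 0

  # denominator sums |i p_i - j p_j| over all ordered (i, j) pairs
  busy_den <- sum(abs(outer(i * pi_, i * pi_, "-")))
  busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0

  complexity <- if (nvp > 0) {
    num <- outer(i, i, function(a, b) abs(a - b)) *
      (outer(pi_ * si, rep(1, ngp)) + outer(rep(1, ngp), pi_ * si)) /
      (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))
    sum(num) / nvp
  } else 0

  strength <- if (sum(si) > 0) {
    sum((outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_)) *
          outer(i, i, "-")^2) / sum(si)
  } else 0

  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
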