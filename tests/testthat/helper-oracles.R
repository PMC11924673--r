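# Independent brute-force oracles used to validate the fast
# implementations. Everything here is written as plain double loops or
# direct textbook formulas, deliberately avoiding the package's own code
# paths.

# random discretized image (levels 1..ng with NA holes) for matrix oracles
random_disc_image <- function(nr, nc, ng, mask_prob = 0.85) {
  lev <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  holes <- matrix(runif(nr * nc) > mask_prob, nr, nc)
  lev[holes] <- NA_integer_
  if (all(is.na(lev))) lev[1, 1] <- 1L
  list(levels = lev, n_levels = as.integer(ng))
}

# --- GLCM oracle: double loop over pixels and one offset -------------------
oracle_glcm_angle <- function(lev, ng, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  C <- matrix(0, ng, ng)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- lev[r, c]; b <- lev[r2, c2]
      if (is.na(a) || is.na(b)) next
      C[a, b] <- C[a, b] + 1
    }
  }
  P <- C + t(C)
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# --- GLRLM oracle: walk each line pixel by pixel ---------------------------
oracle_glrlm_angle <- function(lev, ng, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  # line starting points: cells with no predecessor along (dr, dc)
  runs <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      pr <- r - dr; pc <- c - dc
      if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next  # not a line start
      rr <- r; cc <- c
      cur <- NA; len <- 0
      while (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        v <- lev[rr, cc]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1
        } else {
          if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
          cur <- v; len <- if (is.na(v)) 0 else 1
        }
        rr <- rr + dr; cc <- cc + dc
      }
      if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
    }
  }
  if (!length(runs)) return(NULL)
  maxlen <- max(vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, ng, maxlen)
  for (rn in runs) R[rn[1], rn[2]] <- R[rn[1], rn[2]] + 1
  R
}

# --- zone oracle: recursive flood fill (8-connected, equal level) ----------
oracle_zones <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (seen[r0, c0] || is.na(lev[r0, c0])) next
      g <- lev[r0, c0]
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      size <- 0
      while (length(stack)) {
        pt <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- pt[1] + dr; c <- pt[2] + dc
          if (r < 1 || r > nr || c < 1 || c > nc) next
          if (seen[r, c] || is.na(lev[r, c]) || lev[r, c] != g) next
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
      zones[[length(zones) + 1]] <- c(level = g, size = size)
    }
  }
  do.call(rbind, zones)
}

# --- GLDM oracle: per-pixel neighbour count --------------------------------
oracle_gldm <- function(lev, alpha = 0) {
  nr <- nrow(lev); nc <- ncol(lev)
  out <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(lev[r, c])) next
      dep <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!is.na(lev[r2, c2]) && abs(lev[r2, c2] - lev[r, c]) <= alpha) {
          dep <- dep + 1
        }
      }
      out[[length(out) + 1]] <- c(level = lev[r, c], j = dep + 1)
    }
  }
  do.call(rbind, out)
}

# --- NGTDM oracle ----------------------------------------------------------
oracle_ngtdm <- function(lev, ng) {
  nr <- nrow(lev); nc <- ncol(lev)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(lev[r, c])) next
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!is.na(lev[r2, c2])) nb <- c(nb, lev[r2, c2])
      }
      if (!length(nb)) next
      g <- lev[r, c]
      n_i[g] <- n_i[g] + 1
      s_i[g] <- s_i[g] + abs(g - mean(nb))
    }
  }
  list(n = n_i, s = s_i)
}

# --- ICC oracle from a textbook two-way ANOVA decomposition via aov() ------
oracle_icc_aov <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(aov(y ~ subject + rater, data = df))[[1]]
  msr <- av["subject", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse)
}

# --- adaptive 15-node Gauss-Hermite marginal log-likelihood ----------------
# Gauss-Hermite nodes/weights by Golub-Welsch on the Jacobi matrix
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    J[i, i + 1] <- sqrt(i / 2)
    J[i + 1, i] <- sqrt(i / 2)
  }
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

oracle_glmm_agq_loglik <- function(b0, b1, sigma, records, n_nodes = 15) {
  gh <- gauss_hermite(n_nodes)
  total <- 0
  for (pid in unique(records$patient_id)) {
    sub <- records[records$patient_id == pid, ]
    x <- sub$feature_value; y <- sub$lge_status
    cond <- function(u) {
      eta <- b0 + b1 * x + u
      sum(y * eta - log(1 + exp(eta))) + dnorm(u, 0, sigma, log = TRUE)
    }
    # adaptive centering at the posterior mode
    op <- optimize(function(u) -cond(u), c(-30, 30))
    mode <- op$minimum
    h <- -(cond(mode + 1e-4) - 2 * cond(mode) + cond(mode - 1e-4)) / 1e-8
    tau <- 1 / sqrt(max(h, 1e-10))
    z <- mode + sqrt(2) * tau * gh$nodes
    vals <- vapply(z, cond, numeric(1))
    integrand <- exp(vals + gh$nodes^2) * gh$weights * sqrt(2) * tau
    total <- total + log(sum(integrand))
  }
  total
}

# --- naive average-linkage agglomeration on a distance matrix --------------
oracle_average_linkage_cut <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- c(NA, NA); bd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    if (bd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

# small, fast generator configuration for structural tests whose
# properties do not depend on the grid scale
small_config <- function(...) {
  synthetic_config(grid_size = 72L, endo_radius_px = 10, epi_radius_px = 16,
                   ...)
}

# feature shortcut: preprocessing + the named families on the original
# image only (used by simulation-heavy tests)
quick_features <- function(case, config = pipeline_config(filters = "original")) {
  extract_features(case, config)
}
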