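# Random-intercept logistic mixed model fitted by maximum likelihood
# with the Laplace approximation, for the longitudinal analysis of a
# texture feature's effect on the log odds of LGE.
#
# Model: logit P(y_it = 1) = b0 + b1 x_it + u_i, u_i ~ N(0, sigma^2).
# The marginal likelihood integrates u_i per patient; Laplace
# approximates each integral around the posterior mode:
#   log L_i ~ l_i(u_hat) - u_hat^2 / (2 sigma^2) - 0.5 log(sigma^2 H_i),
# where H_i = sum_t p(1-p) + 1/sigma^2 is the negative curvature at the
# mode. The outer optimization is quasi-Newton (BFGS) over
# (b0, b1, log sigma); the inner per-patient modes are found by Newton
# steps vectorized across patients.

# inner step: per-patient posterior modes and curvatures
glmm_inner_modes <- function(b0, b1, sigma2, x, y, gid, u0, max_iter = 50L,
                             tol = 1e-10) {
  u <- u0
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * x + u[gid]
    p <- stats::plogis(eta)
    g <- as.vector(rowsum(y - p, gid)) - u / sigma2
    H <- as.vector(rowsum(p * (1 - p), gid)) + 1 / sigma2
    step <- g / H
    # dampen huge steps for stability in near-separated groups
    step <- pmin(pmax(step, -5), 5)
    u <- u + step
    if (max(abs(step)) < tol) break
  }
  eta <- b0 + b1 * x + u[gid]
  p <- stats::plogis(eta)
  H <- as.vector(rowsum(p * (1 - p), gid)) + 1 / sigma2
  list(u = u, H = H)
}

glmm_laplace_negll <- function(par, x, y, gid, env) {
  b0 <- par[1]; b1 <- par[2]
  sigma2 <- exp(2 * par[3])
  inner <- glmm_inner_modes(b0, b1, sigma2, x, y, gid, env$u)
  env$u <- inner$u  # warm start the next evaluation
  u <- inner$u
  eta <- b0 + b1 * x + u[gid]
  ll_cond <- sum(y * eta - log1p(exp(eta)))
  ll <- ll_cond - sum(u^2) / (2 * sigma2) - 0.5 * sum(log(sigma2 * inner$H))
  -ll
}

#' Fit the random-intercept logistic mixed model (Laplace approximation)
#'
#' @param records data.frame with columns `patient_id`, `feature_value`,
#'   `lge_status` (and optionally `exam_year`, unused by the likelihood)
#' @param z_score z-score the feature across all records before fitting
#'   (default TRUE, matching the cross-sectional convention); the
#'   reported slope is then per SD of the feature
#' @param fix_sigma optional fixed value for the random-intercept SD; the
#'   variance is then not estimated (k = 2). A value near zero reduces
#'   the model to plain pooled logistic regression
#' @return a `glmm_fit`: beta (slope), se, p (Wald, or a likelihood-ratio
#'   test of the slope when separation degenerates the Wald SE; see
#'   `p_method`), intercept,
#'   sigma_u (random-intercept SD), loglik, aic, bic, convergence,
#'   boundary and separation flags, and the fitted random effects.
#'   Separated datasets (likelihood unbounded in the slope) return the
#'   flagged box-constrained optimum
#' @export
fit_glmm_logistic <- function(records, z_score = TRUE, fix_sigma = NULL) {
  need <- c("patient_id", "feature_value", "lge_status")
  if (!all(need %in% names(records))) {
    stopf("records must contain %s", paste(need, collapse = ", "))
  }
  y <- as.integer(records$lge_status)
  if (length(unique(y)) < 2L) stopf("both outcome classes must be present")
  gid <- factor(records$patient_id)
  if (nlevels(gid) < 2L) stopf("need at least 2 patients")
  x <- records$feature_value
  if (z_score) {
    s <- stats::sd(x)
    x <- (x - mean(x)) / if (is.finite(s) && s > 0) s else 1
  }
  gi <- as.integer(gid)

  env <- new.env()
  env$u <- numeric(nlevels(gid))
  fixed <- !is.null(fix_sigma)
  negll <- if (fixed) {
    function(par2, x, y, gid, env) {
      glmm_laplace_negll(c(par2, log(fix_sigma)), x, y, gid, env)
    }
  } else {
    glmm_laplace_negll
  }
  start <- c(stats::qlogis(max(0.05, min(0.95, mean(y)))), 0)
  lower <- c(-30, -30)
  upper <- c(30, 30)
  if (!fixed) {
    start <- c(start, 0)
    lower <- c(lower, log(1e-4))
    upper <- c(upper, log(15))
  }
  # box constraints keep separated datasets (likelihood unbounded in the
  # slope) at a finite, flagged optimum
  opt <- stats::optim(start, negll, x = x, y = y, gid = gi,
                      env = env, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52) {
    stopf("GLMM optimizer did not converge (code %d): %s", opt$convergence,
          paste(opt$message, collapse = " "))
  }
  separated <- any(abs(opt$par[1:2] - lower[1:2]) < 1e-6) ||
    any(abs(opt$par[1:2] - upper[1:2]) < 1e-6)
  # Hessian at the optimum for Wald inference
  hess <- stats::optimHess(opt$par, negll, x = x, y = y, gid = gi, env = env)
  vc <- tryCatch(solve(hess), error = function(e) {
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  se <- sqrt(pmax(diag(vc), 0))
  ll <- -opt$value
  k <- if (fixed) 2 else 3
  n_obs <- length(y)
  sigma_u <- if (fixed) fix_sigma else exp(opt$par[3])
  se_beta <- se[2]
  if (separated || !is.finite(se_beta) || se_beta < 1e-8) se_beta <- NA_real_
  boundary <- !fixed && sigma_u < 1e-3
  beta <- opt$par[2]
  if (is.finite(se_beta)) {
    p <- 2 * stats::pnorm(-abs(beta / se_beta))
    p_method <- "wald"
  } else {
    # Wald inference degenerates under separation; use the likelihood
    # ratio against the no-slope model instead
    null_negll <- function(par2, x, y, gid, env) {
      negll(if (fixed) c(par2[1], 0) else c(par2[1], 0, par2[2]),
            x, y, gid, env)
    }
    env0 <- new.env()
    env0$u <- numeric(nlevels(gid))
    st0 <- if (fixed) start[1] else start[c(1, 3)]
    lo0 <- if (fixed) lower[1] else lower[c(1, 3)]
    up0 <- if (fixed) upper[1] else upper[c(1, 3)]
    opt0 <- stats::optim(st0, null_negll, x = x, y = y, gid = gi, env = env0,
                         method = "L-BFGS-B", lower = lo0, upper = up0,
                         control = list(maxit = 500, factr = 1e4))
    lr <- max(0, 2 * (ll - (-opt0$value)))
    p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
    p_method <- "lr"
  }
  structure(list(
    beta = beta, se = se_beta, p = p, p_method = p_method,
    intercept = opt$par[1], intercept_se = se[1], sigma_u = sigma_u,
    loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n_obs) - 2 * ll,
    n_patients = nlevels(gid), n_obs = n_obs, converged = TRUE,
    boundary = boundary, separated = separated, z_scored = z_score,
    ranef = stats::setNames(env$u, levels(gid))
  ), class = "glmm_fit")
}

#' Summarize a longitudinal mixed-model fit
#'
#' Produces the reporting record (estimate (SE), p, AIC, BIC, logLik) in
#' the "23.35 (8.7)" formatting convention, plus a JSON-ready list.
#'
#' @param fit a `glmm_fit`
#' @param feature_name name of the analyzed feature
#' @return list(feature, estimate, se, estimate_label, p, aic, bic,
#'   loglik, sigma_u)
#' @export
longitudinal_report <- function(fit, feature_name) {
  if (!isTRUE(fit$converged)) stopf("fit did not converge")
  list(feature = feature_name,
       estimate = fit$beta, se = fit$se,
       estimate_label = sprintf("%.2f (%.1f)", fit$beta, fit$se),
       p = fit$p, aic = fit$aic, bic = fit$bic, loglik = fit$loglik,
       sigma_u = fit$sigma_u, separated = isTRUE(fit$separated))
}

#' Write / read a longitudinal report as JSON
#' @param report list from [longitudinal_report()]
#' @param path JSON path
#' @return the path (write) or the report list (read)
#' @export
write_longitudinal_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_longitudinal_report
#' @export
read_longitudinal_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
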