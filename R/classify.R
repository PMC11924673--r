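# Per-feature logistic models, cross-validation, the evaluation metric
# panel (exact binomial CI, kappa, F1, DeLong AUC CI), AIC ranking, and
# the single-split decision-stump threshold.

#' Z-score a training vector and apply the same scaling to a test vector
#'
#' Scaling statistics come from the training data only, so no test
#' information leaks into the model.
#' @param x_train,x_test numeric vectors
#' @return list(train, test, center, scale)
#' @export
zscore_train_test <- function(x_train, x_test = NULL) {
  m <- mean(x_train)
  s <- stats::sd(x_train)
  if (!is.finite(s) || s == 0) s <- 1
  list(train = (x_train - m) / s,
       test = if (is.null(x_test)) NULL else (x_test - m) / s,
       center = m, scale = s)
}

# Firth bias-reduced logistic regression (Jeffreys-prior score
# adjustment), used when ML fitting separates.
firth_logistic <- function(x, y, max_iter = 200L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(stats::qlogis(max(0.05, min(0.95, mean(y)))), 0)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    h <- rowSums((X %*% solve(info)) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(info, U)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  list(coefficients = stats::setNames(as.vector(beta), c("(Intercept)", "x")),
       loglik = ll)
}

#' Univariate logistic regression with AIC
#'
#' Maximum-likelihood intercept + slope fit; AIC = 2k - 2 logL with
#' k = 2. Complete separation triggers a Firth bias-reduced fallback,
#' flagged in the result.
#'
#' @param x predictor (z-scored on the training data)
#' @param y 0/1 outcome
#' @return a `logistic_fit`: coefficients, loglik, aic, separation flag
#' @export
fit_logistic_univariate <- function(x, y) {
  y <- as.integer(y)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || any(abs(stats::coef(fit)) > 15)) {
    fr <- firth_logistic(x, y)
    out <- list(coefficients = fr$coefficients, loglik = fr$loglik,
                aic = 2 * 2 - 2 * fr$loglik, separated = TRUE)
  } else {
    ll <- as.numeric(stats::logLik(fit))
    out <- list(coefficients = stats::setNames(stats::coef(fit),
                                               c("(Intercept)", "x")),
                loglik = ll, aic = stats::AIC(fit), separated = FALSE)
  }
  class(out) <- "logistic_fit"
  out
}

#' Predicted probabilities from a `logistic_fit`
#' @param fit a `logistic_fit`
#' @param x predictor values (on the training scale)
#' @return probabilities
#' @export
predict_logistic <- function(fit, x) {
  stats::plogis(fit$coefficients[1] + fit$coefficients[2] * x)
}

#' Seeded stratified k-fold cross-validation of the univariate model
#'
#' Folds are assigned per class so every fold keeps the class mix; the
#' per-fold held-out accuracy (probability cut 0.5) is reported as
#' mean +/- sd, and the final model is refit on all training cases.
#'
#' @param x,y training predictor and 0/1 outcome
#' @param folds number of folds (default 10)
#' @param seed integer seed
#' @return list(fold_accuracy, mean_accuracy, sd_accuracy, final_fit,
#'   fold_assignment)
#' @export
cross_validate <- function(x, y, folds = 10L, seed = 1L) {
  y <- as.integer(y)
  if (min(table(y)) < folds) {
    # every fold must see both classes in training; with fewer members
    # than folds a class would vanish from some training split
    if (min(table(y)) < 2L) stopf("stratified %d-fold CV infeasible", folds)
  }
  assign_folds <- function(n) sample(rep_len(seq_len(folds), n))
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) fold[y == cls] <- assign_folds(sum(y == cls))
    acc <- vapply(seq_len(folds), function(k) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2L) stopf("fold %d lost a class", k)
      fit <- fit_logistic_univariate(x[tr], y[tr])
      pred <- predict_logistic(fit, x[!tr]) >= 0.5
      mean(pred == (y[!tr] == 1L))
    }, numeric(1))
    list(fold_accuracy = acc, mean_accuracy = mean(acc),
         sd_accuracy = stats::sd(acc),
         final_fit = fit_logistic_univariate(x, y), fold_assignment = fold)
  })
}

#' Metric panel from confusion counts
#'
#' Accuracy with exact Clopper-Pearson 95% CI, balanced accuracy
#' (mean of sensitivity and specificity), Cohen's kappa, and F1
#' (positive class).
#'
#' @param tp,fp,fn,tn confusion counts (positive class = LGE+)
#' @return list of metrics plus the counts
#' @export
evaluate_confusion <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  acc <- (tp + tn) / n
  ci <- stats::binom.test(tp + tn, n)$conf.int
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = acc, accuracy_ci = c(ci[1], ci[2]),
       balanced_accuracy = mean(c(sens, spec)),
       sensitivity = sens, specificity = spec, kappa = kappa, f1 = f1)
}

#' Evaluate a fitted model on held-out data
#'
#' Class assignment at probability 0.5; the panel of
#' [evaluate_confusion()] plus rank-statistic AUC with a DeLong 95% CI.
#' A single-class test set leaves the AUC NA with a flag.
#'
#' @param fit a `logistic_fit`
#' @param x_test,y_test held-out predictor (training scale) and labels
#' @return a `model_metrics` list
#' @export
evaluate_model <- function(fit, x_test, y_test) {
  y_test <- as.integer(y_test)
  prob <- predict_logistic(fit, x_test)
  pred <- as.integer(prob >= 0.5)
  m <- evaluate_confusion(tp = sum(pred == 1 & y_test == 1),
                          fp = sum(pred == 1 & y_test == 0),
                          fn = sum(pred == 0 & y_test == 1),
                          tn = sum(pred == 0 & y_test == 0))
  if (length(unique(y_test)) < 2L) {
    m$auc <- NA_real_
    m$auc_ci <- c(NA_real_, NA_real_)
    m$auc_flag <- "single-class test set"
  } else {
    roc <- pROC::roc(response = y_test, predictor = as.numeric(prob),
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))
    m$auc <- as.numeric(pROC::auc(roc))
    m$auc_ci <- c(as.numeric(ci[1]), as.numeric(ci[3]))
    m$auc_flag <- NA_character_
  }
  m$aic <- fit$aic
  class(m) <- "model_metrics"
  m
}

#' Rank models by AIC
#'
#' Ascending AIC with a stable alphabetical tie-break on the feature
#' name.
#' @param metrics named list of `model_metrics` (names = feature names)
#' @return character vector of feature names, best first
#' @export
rank_models <- function(metrics) {
  if (!length(metrics)) stopf("no models to rank")
  aics <- vapply(metrics, function(m) m$aic, numeric(1))
  names(metrics)[order(aics, names(metrics))]
}

#' Single-split decision-stump threshold
#'
#' Candidate cuts are the midpoints of sorted unique predictor values;
#' the cut minimizing the weighted Gini impurity wins, ties resolved
#' toward the maximal-margin midpoint. The predicted class on each side
#' is the side's majority class.
#'
#' @param x continuous predictor
#' @param y 0/1 labels
#' @return list(threshold, upper_class, gini, predict)
#' @export
stump_threshold <- function(x, y) {
  y <- as.integer(y)
  ux <- sort(unique(x))
  if (length(ux) < 2L) stopf("constant predictor: no split exists")
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  gaps <- diff(ux)
  gini_side <- function(lab) {
    if (!length(lab)) return(0)
    p <- mean(lab)
    1 - p^2 - (1 - p)^2
  }
  imp <- vapply(cuts, function(ct) {
    left <- y[x <= ct]
    right <- y[x > ct]
    (length(left) * gini_side(left) + length(right) * gini_side(right)) /
      length(y)
  }, numeric(1))
  best <- which(imp <= min(imp) + 1e-12)
  pick <- best[order(-gaps[best], cuts[best])][1]
  thr <- cuts[pick]
  upper <- as.integer(mean(y[x > thr]) >= mean(y[x <= thr]))
  list(threshold = thr, upper_class = upper, gini = imp[pick],
       predict = function(newx) {
         ifelse(newx > thr, upper, 1L - upper)
       })
}
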