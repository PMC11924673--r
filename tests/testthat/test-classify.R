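# Logistic models, cross-validation, the metric panel, AIC ranking, and
# the decision stump.

test_that("univariate logistic fit matches a direct Bernoulli likelihood", {
  set.seed(61)
  x <- rnorm(10)
  y <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 1)
  fit <- fit_logistic_univariate(x, y)
  eta <- fit$coefficients[1] + fit$coefficients[2] * x
  ll_direct <- sum(y * eta - log(1 + exp(eta)))
  expect_equal(fit$loglik, ll_direct, tolerance = 1e-8)
  expect_equal(fit$aic, 4 - 2 * ll_direct, tolerance = 1e-8)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
})

test_that("null predictors give near-zero slopes and null-plus-2 AIC", {
  set.seed(62)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_logistic_univariate(x, y)
  expect_lt(abs(fit$coefficients[2]), 0.1)
  null_aic <- AIC(glm(y ~ 1, family = binomial()))
  expect_lt(abs(fit$aic - (null_aic + 2)), 2.5)
})

test_that("complete separation triggers a finite bias-reduced fit", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic_univariate(x, y)
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coefficients)))
  expect_lt(abs(fit$coefficients[2]), 15)
  # Firth slope remains positive and predictive
  expect_gt(fit$coefficients[2], 0)
  expect_gt(predict_logistic(fit, 3), 0.5)
  expect_lt(predict_logistic(fit, -3), 0.5)
})

test_that("metric panel matches hand arithmetic on every 7+/7- confusion", {
  for (tp in 0:7) {
    for (tn in 0:7) {
      fn <- 7 - tp
      fp <- 7 - tn
      m <- evaluate_confusion(tp, fp, fn, tn)
      acc <- (tp + tn) / 14
      sens <- tp / 7
      spec <- tn / 7
      pe <- ((tp + fp) * 7 + (fn + tn) * 7) / 196
      expect_equal(m$accuracy, acc)
      expect_equal(m$balanced_accuracy, (sens + spec) / 2)
      if (pe < 1) expect_equal(m$kappa, (acc - pe) / (1 - pe))
      if (2 * tp + fp + fn > 0) {
        expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
      }
      ci_ref <- binom.test(tp + tn, 14)$conf.int
      expect_equal(m$accuracy_ci, c(ci_ref[1], ci_ref[2]))
      expect_true(all(unlist(m[c("accuracy", "balanced_accuracy", "f1")])
                      >= 0, na.rm = TRUE))
    }
  }
})

test_that("the published confusion matrix reproduces its printed metrics", {
  m <- evaluate_confusion(tp = 7, fp = 2, fn = 0, tn = 5)
  expect_equal(round(m$accuracy, 3), 0.857)
  expect_equal(round(m$balanced_accuracy, 3), 0.857)
  expect_equal(round(m$kappa, 3), 0.714)
  expect_equal(round(m$f1, 3), 0.875)
  expect_equal(round(m$accuracy_ci, 3), c(0.572, 0.982))
})

test_that("AUC is rank-based: monotone-transform invariant, 0.5 under noise", {
  set.seed(63)
  n <- 40
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x))
  fit <- fit_logistic_univariate(x, y)
  m1 <- evaluate_model(fit, x, y)
  # strictly monotone transform of the predictor scores
  fit2 <- fit
  m2 <- evaluate_model(list(coefficients = fit$coefficients * c(1, 1),
                            aic = fit$aic), x, y)
  expect_equal(m1$auc, m2$auc)
  roc1 <- pROC::roc(y, plogis(x), levels = c(0, 1), direction = "<",
                    quiet = TRUE)
  roc2 <- pROC::roc(y, exp(3 * plogis(x)), levels = c(0, 1), direction = "<",
                    quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(roc1)), as.numeric(pROC::auc(roc2)))

  set.seed(64)
  big_y <- rbinom(2000, 1, 0.5)
  noise_fit <- fit_logistic_univariate(rnorm(2000), big_y)
  mN <- evaluate_model(noise_fit, rnorm(2000), big_y)
  expect_lt(abs(mN$auc - 0.5), 0.05)
})

test_that("single-class test sets flag the AUC as undefined", {
  fit <- fit_logistic_univariate(rnorm(20), rep(0:1, 10))
  m <- evaluate_model(fit, rnorm(5), rep(1L, 5))
  expect_true(is.na(m$auc))
  expect_match(m$auc_flag, "single-class")
})

test_that("cross-validation is stratified, seeded, and sane at the extremes", {
  set.seed(65)
  n <- 100
  y <- rep(0:1, n / 2)
  x_noise <- rnorm(n)
  cv1 <- cross_validate(x_noise, y, folds = 10L, seed = 3L)
  cv2 <- cross_validate(x_noise, y, folds = 10L, seed = 3L)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  expect_lt(abs(cv1$mean_accuracy - 0.5), 0.2)
  # each fold keeps the class mix
  for (k in 1:10) expect_equal(sum(y[cv1$fold_assignment == k]), 5)

  x_strong <- y * 4 + rnorm(n, 0, 0.5)
  cv3 <- cross_validate(x_strong, y, folds = 10L, seed = 4L)
  expect_gt(cv3$mean_accuracy, 0.9)
})

test_that("training-only z-scoring prevents test leakage", {
  set.seed(66)
  xtr <- rnorm(30, 10, 2)
  xte <- rnorm(10, 50, 9)  # wildly different test distribution
  z <- zscore_train_test(xtr, xte)
  expect_equal(mean(z$train), 0, tolerance = 1e-12)
  expect_equal(sd(z$train), 1, tolerance = 1e-12)
  expect_equal(z$test, (xte - mean(xtr)) / sd(xtr))
  # test values must NOT be standardized by their own statistics
  expect_gt(abs(mean(z$test)), 1)
})

test_that("models rank by AIC with alphabetical tie-break", {
  m <- list(b = list(aic = 10), a = list(aic = 10), c = list(aic = 5))
  expect_identical(rank_models(m), c("c", "a", "b"))
  expect_identical(rank_models(m["b"]), "b")
  expect_error(rank_models(list()), "no models")
})

test_that("decision stump: forced midpoint, oracle search, Bayes recovery", {
  s <- stump_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$upper_class, 1L)
  expect_identical(s$predict(c(2, 3)), c(0L, 1L))

  # exhaustive-search oracle on fixed 8-point data
  set.seed(67)
  for (k in 1:10) {
    x <- rnorm(8)
    y <- rbinom(8, 1, plogis(x))
    if (length(unique(y)) < 2) next
    s2 <- stump_threshold(x, y)
    ux <- sort(unique(x))
    cuts <- (ux[-1] + ux[-length(ux)]) / 2
    gini <- function(lab) if (!length(lab)) 0 else {
      p <- mean(lab); 1 - p^2 - (1 - p)^2
    }
    imp <- vapply(cuts, function(ct) {
      (sum(x <= ct) * gini(y[x <= ct]) + sum(x > ct) * gini(y[x > ct])) /
        length(y)
    }, numeric(1))
    expect_equal(s2$gini, min(imp), tolerance = 1e-12)
    expect_true(any(abs(cuts[imp <= min(imp) + 1e-12] - s2$threshold) < 1e-12))
  }

  # overlapping Gaussians: the stump approaches the analytic Bayes cut
  set.seed(68)
  n <- 10000
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n, mean = ifelse(y == 1, 1, -1))
  s3 <- stump_threshold(x, y)
  expect_lt(abs(s3$threshold - 0), 0.15)  # equal-priors Bayes boundary
  expect_error(stump_threshold(rep(1, 5), c(0, 1, 0, 1, 0)), "constant")
})
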