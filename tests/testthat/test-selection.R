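# Split/balance, Boruta shadow search, LASSO, clustering, VIF.

test_that("splitting 23+/19- at 67% reproduces the published cohort sizes", {
  ids <- sprintf("c%02d", 1:42)
  status <- c(rep(1L, 23), rep(0L, 19))
  sp <- split_and_balance(ids, status, train_frac = 0.67, seed = 99L)
  expect_length(sp$train_ids, 24L)
  expect_length(sp$test_ids, 14L)
  st <- setNames(status, ids)
  expect_equal(sum(st[sp$train_ids]), 12L)  # balanced 12+/12-
  expect_equal(sum(st[sp$test_ids]), 7L)    # balanced 7+/7-
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
})

test_that("already balanced cohorts lose no cases and splits are seeded", {
  ids <- sprintf("c%02d", 1:30)
  status <- rep(c(0L, 1L), 15)
  sp <- split_and_balance(ids, status, train_frac = 0.67, seed = 1L)
  expect_length(c(sp$train_ids, sp$test_ids), 30L)
  sp2 <- split_and_balance(ids, status, train_frac = 0.67, seed = 1L)
  expect_identical(sp, sp2)
  sp3 <- split_and_balance(ids, status, train_frac = 0.67, seed = 2L)
  expect_false(identical(sp$train_ids, sp3$train_ids))
  expect_error(split_and_balance(ids, rep(1L, 30)), "classes")
})

test_that("Boruta confirms a planted label-like feature and drops noise", {
  set.seed(41)
  n <- 100
  y <- rep(0:1, each = n / 2)
  X <- cbind(signal = y + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 9), n, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  out <- boruta_select(scale(X), y, seed = 5L, max_iter = 30L)
  expect_true("signal" %in% out$confirmed)
  expect_false(any(paste0("noise", 1:9) %in% out$confirmed))

  # duplicated informative feature: the all-relevant search keeps both
  X2 <- cbind(X[, "signal", drop = FALSE],
              signal_copy = X[, "signal"] + rnorm(n, 0, 0.01),
              X[, paste0("noise", 1:4)])
  out2 <- boruta_select(scale(X2), y, seed = 6L, max_iter = 30L)
  expect_true(all(c("signal", "signal_copy") %in% out2$confirmed))
})

test_that("Boruta on pure noise rarely confirms anything", {
  # n large enough that chance feature-outcome correlations are
  # negligible; at small n such correlations are real in-sample signal
  # and an all-relevant search legitimately flags them
  set.seed(42)
  n_confirmed <- vapply(1:5, function(s) {
    X <- matrix(rnorm(1000 * 8), 1000, 8,
                dimnames = list(NULL, paste0("n", 1:8)))
    y <- rep(0:1, each = 500)
    length(boruta_select(X, y, seed = s, max_iter = 20L)$confirmed)
  }, numeric(1))
  expect_gte(mean(n_confirmed == 0), 0.8)
  expect_error(boruta_select(matrix(c(1, NA, 2, 3), 2, 2), c(0, 1)),
               "non-finite")
})

test_that("LASSO keeps the informative feature and behaves at the penalty limit", {
  set.seed(43)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- cbind(signal = y * 2 + rnorm(n),
             matrix(rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("noise", 1:10))))
  out <- lasso_select(X, y, seed = 7L)
  expect_true("signal" %in% out$selected)
  expect_gt(out$lambda, 0)

  # at a huge penalty every coefficient vanishes (direct glmnet check of
  # the path limit the selector relies on)
  fit <- glmnet::glmnet(scale(X), y, family = "binomial", lambda = 10)
  expect_true(all(abs(as.matrix(coef(fit))[-1, 1]) < 1e-12))

  # duplicated columns: selection stays non-empty
  X2 <- cbind(s1 = X[, "signal"], s2 = X[, "signal"],
              X[, paste0("noise", 1:3)])
  out2 <- lasso_select(X2, y, seed = 8L)
  expect_gt(length(out2$selected), 0L)
  expect_true(any(c("s1", "s2") %in% out2$selected))
})

test_that("hierarchical decorrelation: copies collapse, orthogonals persist", {
  set.seed(44)
  n <- 60
  a <- rnorm(n)
  X <- data.frame(a = a, a_copy = a, b = rnorm(n), c = rnorm(n))
  out <- hierarchical_decorrelate(X, c("a", "a_copy"))
  expect_length(out$independent, 1L)
  out2 <- hierarchical_decorrelate(X, c("a", "b", "c"))
  expect_length(out2$independent, 3L)
  # passthrough below two candidates
  expect_identical(hierarchical_decorrelate(X, "a")$independent, "a")
})

test_that("cluster cut matches a naive average-linkage oracle", {
  set.seed(45)
  n <- 80
  u <- rnorm(n); v <- rnorm(n)
  X <- data.frame(f1 = u, f2 = u + rnorm(n, 0, 0.1), f3 = u + rnorm(n, 0, 0.15),
                  f4 = v, f5 = v + rnorm(n, 0, 0.1), f6 = rnorm(n))
  feats <- names(X)
  rho <- abs(cor(X, method = "spearman"))
  memb_oracle <- oracle_average_linkage_cut(1 - rho, h = 0.25)
  out <- hierarchical_decorrelate(X, feats, corr_threshold = 0.75)
  # same partition up to label names
  got <- out$clusters[feats]
  expect_equal(length(unique(got)), length(unique(memb_oracle)))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(got[feats[i]] == got[feats[j]],
                 memb_oracle[i] == memb_oracle[j], ignore_attr = TRUE)
  }
  # representatives are members of their clusters
  expect_true(all(out$independent %in% feats))
})

test_that("VIF matches the direct least-squares oracle", {
  set.seed(46)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.8 * x1 + 0.3 * rnorm(n)
  X <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- vif_check(X, c("x1", "x2", "x3"))
  for (f in names(v)) {
    r2 <- summary(lm(X[[f]] ~ ., data = X[setdiff(names(X), f)]))$r.squared
    expect_equal(unname(v[f]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # the independent feature has VIF near 1; the collinear pair is inflated
  expect_lt(v[["x2"]], 1.5)
  expect_gt(v[["x3"]], 2)
  Xc <- data.frame(a = x1, b = x1 + rnorm(n, 0, 1e-4), c = x2)
  expect_gt(max(vif_check(Xc, c("a", "b", "c"))), 5)
  expect_error(vif_check(X, "x1"), "at least 2")
})

test_that("the full cascade recovers a planted texture driver", {
  # cohort with one continuous texture driver: driver shifts the GRF
  # correlation length, outcome depends on the driver
  cfg <- pipeline_config(synthetic = small_config(), filters = "original",
                         seed = 50L)
  set.seed(51)
  n <- 44
  driver <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.6 * driver))
  cases <- lapply(seq_len(n), function(i) {
    sc <- cfg$synthetic
    sc$texture_corr_len_neg <- max(0.6, 2.2 + 0.6 * driver[i])
    sc$texture_corr_len_pos <- sc$texture_corr_len_neg
    generate_case(sc, y[i], seed = 7000L + i,
                  case_id = sprintf("d%03d", i))
  })
  tab <- extract_cohort(cases, cfg)
  sel <- select_features(tab, feature_columns(tab), cfg)
  expect_true(length(sel$independent) >= 1L)
  cors <- vapply(sel$independent, function(f) {
    abs(cor(tab[[f]], driver, method = "spearman"))
  }, numeric(1))
  expect_gte(max(cors), 0.7)
  expect_true(all(sel$independent %in% sel$union))
  # determinism of the cascade
  sel2 <- select_features(tab, feature_columns(tab), cfg)
  expect_identical(sel$independent, sel2$independent)
})
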