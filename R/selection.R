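# Feature selection cascade: stratified balanced split, Boruta shadow
# search, LASSO with cross-validation, hierarchical decorrelation, and
# the VIF multicollinearity check.

#' Stratified train/test split with class balancing
#'
#' Cases are split class-by-class (floor(train_frac * n) per class into
#' training), then within each split the majority class is randomly
#' undersampled to the minority count. 23+/19- at the default fractions
#' gives a balanced training cohort of 24 and a testing cohort of 14.
#'
#' @param ids case identifiers
#' @param status 0/1 class labels aligned with `ids`
#' @param train_frac training fraction (default 0.67)
#' @param seed integer seed
#' @return list(train_ids, test_ids)
#' @export
split_and_balance <- function(ids, status, train_frac = 0.67, seed = 1L) {
  status <- as.integer(status)
  if (length(unique(status)) < 2L) stopf("both classes must be present")
  with_seed(seed, {
    pos <- ids[status == 1L]
    neg <- ids[status == 0L]
    n_tr_pos <- floor(train_frac * length(pos))
    n_tr_neg <- floor(train_frac * length(neg))
    tr_pos <- sample(pos, n_tr_pos)
    tr_neg <- sample(neg, n_tr_neg)
    te_pos <- setdiff(pos, tr_pos)
    te_neg <- setdiff(neg, tr_neg)
    if (!length(tr_pos) || !length(tr_neg) || !length(te_pos) || !length(te_neg)) {
      stopf("a class is absent from one of the splits")
    }
    balance <- function(a, b) {
      m <- min(length(a), length(b))
      c(if (length(a) > m) sample(a, m) else a,
        if (length(b) > m) sample(b, m) else b)
    }
    list(train_ids = sort(balance(tr_pos, tr_neg)),
         test_ids = sort(balance(te_pos, te_neg)))
  })
}

#' Boruta all-relevant feature selection
#'
#' Shadow-feature search on a random-forest importance model: each
#' iteration appends a column-permuted shadow copy of every live feature,
#' fits a forest, and scores a "hit" for features whose importance beats
#' the best shadow. Two-sided binomial tests (Bonferroni-corrected at
#' `alpha`) promote features to confirmed or demote them to rejected;
#' undecided features at `max_iter` remain tentative. Predictors should
#' be scaled beforehand.
#'
#' @param X numeric matrix/data.frame (cases x features), scaled
#' @param y 0/1 outcome
#' @param seed integer seed
#' @param max_iter iteration cap (default 100)
#' @param ntree forest size per iteration (default 500)
#' @param alpha significance level of the promotion tests (default 0.01)
#' @return list(confirmed, tentative, rejected, hits, n_iter)
#' @export
boruta_select <- function(X, y, seed = 1L, max_iter = 100L, ntree = 500L,
                          alpha = 0.01) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stopf("non-finite values in X")
  y <- factor(y)
  p <- ncol(X)
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(p))
  colnames(X) <- feats
  with_seed(seed, {
    status <- rep("live", p)
    names(status) <- feats
    hits <- integer(p)
    names(hits) <- feats
    iters <- 0L
    while (iters < max_iter && any(status == "live")) {
      iters <- iters + 1L
      live <- names(status)[status != "rejected"]
      Xl <- X[, live, drop = FALSE]
      shadow <- apply(Xl, 2, sample)
      colnames(shadow) <- paste0(".shadow_", seq_len(ncol(shadow)))
      rf <- randomForest::randomForest(cbind(Xl, shadow), y, ntree = ntree,
                                       importance = FALSE)
      imp <- rf$importance[, "MeanDecreaseGini"]
      max_shadow <- max(imp[colnames(shadow)])
      hit_now <- imp[live] > max_shadow
      hits[live] <- hits[live] + hit_now
      # decision tests after a burn-in, Bonferroni over the initial set
      if (iters >= 5L) {
        thr <- alpha / (2 * p)
        for (f in names(status)[status == "live"]) {
          p_up <- stats::pbinom(hits[f] - 1L, iters, 0.5, lower.tail = FALSE)
          p_dn <- stats::pbinom(hits[f], iters, 0.5)
          if (p_up < thr) status[f] <- "confirmed"
          else if (p_dn < thr) status[f] <- "rejected"
        }
      }
    }
    status[status == "live"] <- "tentative"
    list(confirmed = names(status)[status == "confirmed"],
         tentative = names(status)[status == "tentative"],
         rejected = names(status)[status == "rejected"],
         hits = hits, n_iter = iters)
  })
}

#' LASSO feature selection with cross-validated penalty
#'
#' L1-penalized logistic regression over the glmnet lambda path; lambda
#' is the 5-fold cross-validated deviance minimizer (lambda.min), and the
#' selection is the set of features with nonzero coefficients there.
#'
#' @param X numeric matrix (cases x features); standardized internally
#' @param y 0/1 outcome
#' @param folds CV folds (default 5)
#' @param seed integer seed
#' @return list(selected, lambda, coefficients)
#' @export
lasso_select <- function(X, y, folds = 5L, seed = 1L) {
  X <- scale(as.matrix(X))
  X[!is.finite(X)] <- 0  # constant columns scale to NaN; they carry no signal
  y <- as.integer(y)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(folds), length(y)))
    # small-cohort folds routinely trip glmnet's class-size caution;
    # expected at this study scale
    cvfit <- withCallingHandlers(
      glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                        type.measure = "deviance"),
      warning = function(w) {
        if (grepl("fewer than 8|grouped=FALSE enforced",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, , drop = FALSE]
    sel <- rownames(cf)[cf[, 1] != 0]
    list(selected = sel, lambda = cvfit$lambda.min,
         coefficients = stats::setNames(cf[, 1], rownames(cf)))
  })
}

#' Hierarchical decorrelation of candidate features
#'
#' Average-linkage clustering on the distance 1 - |Spearman rho|, cut at
#' height 1 - corr_threshold (so clusters hold features with average
#' absolute correlation above the threshold). One representative per
#' cluster: the medoid maximizing mean |rho| to its cluster members, ties
#' broken alphabetically. Fewer than two candidates pass through.
#'
#' @param X feature matrix/data.frame (training cases)
#' @param candidates candidate feature names (union of Boruta and LASSO)
#' @param corr_threshold |rho| threshold (default 0.75)
#' @return list(independent, clusters)
#' @export
hierarchical_decorrelate <- function(X, candidates, corr_threshold = 0.75) {
  candidates <- sort(unique(candidates))
  if (length(candidates) < 2L) {
    return(list(independent = candidates,
                clusters = stats::setNames(rep(1L, length(candidates)),
                                           candidates)))
  }
  M <- as.matrix(X[, candidates, drop = FALSE])
  rho <- abs(stats::cor(M, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  d <- stats::as.dist(1 - rho)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, h = 1 - corr_threshold)
  reps <- vapply(split(names(cl), cl), function(members) {
    if (length(members) == 1L) return(members)
    score <- rowMeans(rho[members, members, drop = FALSE])
    members[order(-score, members)][1]
  }, character(1))
  list(independent = sort(unname(reps)), clusters = cl)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing feature j on the remaining
#' features; a singular fit reports Inf.
#'
#' @param X feature matrix/data.frame
#' @param features feature names to assess (>= 2)
#' @return named numeric vector of VIFs
#' @export
vif_check <- function(X, features) {
  if (length(features) < 2L) stopf("need at least 2 features for VIF")
  M <- as.data.frame(X[, features, drop = FALSE])
  if (nrow(M) <= length(features)) stopf("need more cases than features")
  vapply(features, function(f) {
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", setdiff(features, f)),
                                        response = sprintf("`%s`", f)),
                     data = M)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Run the full selection cascade on a gated feature table
#'
#' Split and balance, z-score the training block, run Boruta and LASSO
#' independently, cluster the union of their selections, and report the
#' independent representatives with their VIFs.
#'
#' @param table feature table (must contain `case_id`, `lge_status`)
#' @param gated_features feature names surviving the reproducibility gate
#' @param config a [pipeline_config()]
#' @return a `selection_result` list with the split, the per-stage
#'   survivors, the cluster map, and the VIFs
#' @export
select_features <- function(table, gated_features,
                            config = pipeline_config()) {
  split <- split_and_balance(table$case_id, table$lge_status,
                             train_frac = config$train_frac,
                             seed = config$seed + 1L)
  train <- table[table$case_id %in% split$train_ids, ]
  Xtr <- as.matrix(train[, gated_features, drop = FALSE])
  Xs <- scale(Xtr)
  Xs[!is.finite(Xs)] <- 0
  ytr <- train$lge_status
  bor <- boruta_select(Xs, ytr, seed = config$seed + 2L,
                       max_iter = config$boruta_max_iter)
  las <- lasso_select(Xtr, ytr, folds = config$lasso_folds,
                      seed = config$seed + 3L)
  union_sel <- sort(union(bor$confirmed, las$selected))
  dec <- hierarchical_decorrelate(train, union_sel,
                                  corr_threshold = config$corr_threshold)
  vifs <- if (length(dec$independent) >= 2L &&
              nrow(train) > length(dec$independent)) {
    vif_check(train, dec$independent)
  } else {
    stats::setNames(rep(1, length(dec$independent)), dec$independent)
  }
  structure(list(split_seed = config$seed + 1L,
                 train_ids = split$train_ids, test_ids = split$test_ids,
                 boruta_selected = bor$confirmed,
                 boruta_tentative = bor$tentative,
                 lasso_selected = las$selected, lambda = las$lambda,
                 union = union_sel, clusters = dec$clusters,
                 independent = dec$independent, vif = vifs),
            class = "selection_result")
}
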