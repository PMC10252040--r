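#' SMOTE minority over-sampling
#'
#' Rebalances a binary-labelled feature matrix by synthesizing minority-class
#' rows: each synthetic row is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`
#' and `x_nn` one of the `k` nearest minority neighbors of the seed row `x`
#' (Euclidean distance within the minority class). Original rows are kept
#' unchanged and classes are balanced to equal counts. Apply to learning
#' rows only; synthetic rows must never reach a validation or test fold, and
#' the returned `synthetic` flags make that auditable.
#'
#' @param X numeric feature matrix.
#' @param y binary label vector, length `nrow(X)`.
#' @param k number of nearest minority neighbors (default 5); reduced with a
#'   warning when the minority class has fewer than `k + 1` rows.
#' @param seed optional integer seed for the interpolation draws.
#' @return list with the rebalanced `X`, `y`, a logical `synthetic` flag per
#'   row, and for synthetic rows the minority-row indices `seed_row` and
#'   `neighbor_row` they interpolate between.
#' @export
smote_oversample <- function(X, y, k = 5L, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  tab <- table(y)
  if (length(tab) != 2) stop("y must contain exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min == n_maj) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X)),
                seed_row = integer(0), neighbor_row = integer(0)))
  }
  if (n_min < 2) stop("minority class has a single sample; SMOTE needs a neighbor")
  if (n_min <= k) {
    warning("reducing k from ", k, " to ", n_min - 1,
            " (minority class has ", n_min, " samples)")
    k <- n_min - 1L
  }
  min_idx <- which(y == minority)
  Xm <- X[min_idx, , drop = FALSE]
  d <- as.matrix(dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  n_new <- n_maj - n_min
  draw <- function() {
    seed_i <- sample.int(n_min, n_new, replace = TRUE)
    pick <- sample.int(k, n_new, replace = TRUE)
    u <- runif(n_new)
    list(seed_i = seed_i, nb_i = nn[cbind(seed_i, pick)], u = u)
  }
  dr <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  Xs <- Xm[dr$seed_i, , drop = FALSE] +
    dr$u * (Xm[dr$nb_i, , drop = FALSE] - Xm[dr$seed_i, , drop = FALSE])
  list(X = rbind(X, Xs),
       y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)),
       seed_row = min_idx[dr$seed_i],
       neighbor_row = min_idx[dr$nb_i])
}

#' Fit an L2-regularized logistic regression
#'
#' Minimizes the penalized negative log-likelihood
#' `-loglik + (1 / (2C)) * ||w||^2` (intercept unpenalized). The fit is
#' delegated to ridge-penalized `glmnet` with `lambda = 1 / (n * C)`, which
#' has the same minimizer, at tight tolerance so the solution is
#' deterministic for the convex problem.
#'
#' @param X numeric feature matrix (standardized features expected).
#' @param y binary labels; with `pre`/`post` labels the positive (modelled)
#'   class is `post`, otherwise the second sorted level.
#' @param C regularization strength, > 0 (larger C = weaker penalty).
#' @param positive optional explicit positive-class label.
#' @return a `voc_logreg` fit with `weights` (named per feature),
#'   `intercept`, `C`, `descriptors`, `positive`/`negative` labels.
#' @export
fit_logreg <- function(X, y, C, positive = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), C > 0)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  labs <- sort(unique(as.character(y)))
  if (length(labs) != 2) stop("y must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if (setequal(labs, .voc_statuses)) "post" else labs[2]
  }
  negative <- setdiff(labs, positive)
  y01 <- as.integer(as.character(y) == positive)
  Xfit <- X
  padded <- FALSE
  if (ncol(Xfit) < 2) {  # glmnet requires >= 2 columns; pad with a constant
    Xfit <- cbind(Xfit, `.pad.` = 0)
    padded <- TRUE
  }
  fit <- withCallingHandlers(
    glmnet::glmnet(Xfit, y01, family = "binomial", alpha = 0,
                   lambda = 1 / (nrow(Xfit) * C), standardize = FALSE,
                   thresh = 1e-12, maxit = 1e6),
    warning = function(w) {
      # small-cohort fits are the normal regime here; the ridge objective is
      # strictly convex, so tiny class counts are not a numerical hazard
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  w <- as.numeric(fit$beta)
  if (padded) w <- w[seq_len(ncol(X))]
  names(w) <- colnames(X)
  structure(list(weights = w, intercept = as.numeric(fit$a0), C = C,
                 descriptors = colnames(X), positive = positive,
                 negative = negative, n_train = nrow(X)),
            class = "voc_logreg")
}

#' Predict from a fitted logistic regression
#'
#' @param object a `voc_logreg` fit.
#' @param newdata feature matrix over the fit's descriptors.
#' @param type `"link"` (linear decision value), `"response"` (probability of
#'   the positive class), or `"class"`.
#' @param ... ignored.
#' @return numeric vector, or character labels for `type = "class"`.
#' @export
predict.voc_logreg <- function(object, newdata,
                               type = c("class", "response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    if (!all(object$descriptors %in% colnames(newdata))) {
      stop("newdata lacks fitted descriptors")
    }
    newdata <- newdata[, object$descriptors, drop = FALSE]
  }
  eta <- drop(object$intercept + newdata %*% object$weights)
  switch(type,
         link = eta,
         response = 1 / (1 + exp(-eta)),
         class = ifelse(eta > 0, object$positive, object$negative))
}

#' Support-weighted F1 score
#'
#' Mean of per-class F1 scores weighted by true-class support. A class whose
#' precision and recall are both zero contributes F1 = 0.
#'
#' @param y_true,y_pred equal-length binary label vectors.
#' @return score in \[0, 1\].
#' @export
f1_weighted <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  labs <- sort(unique(c(y_true, y_pred)))
  f1 <- vapply(labs, function(l) {
    tp <- sum(y_true == l & y_pred == l)
    fp <- sum(y_true != l & y_pred == l)
    fn <- sum(y_true == l & y_pred != l)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- vapply(labs, function(l) sum(y_true == l), numeric(1))
  sum(f1 * support) / sum(support)
}

#' Sensitivity and specificity
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)` for the
#' given positive label. An undefined ratio (zero denominator) is reported
#' as `NA`, not 0.
#'
#' @param y_true,y_pred label vectors.
#' @param positive the positive-class label.
#' @return named numeric vector `c(sensitivity =, specificity =)`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  c(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

# ---- group-aware cross-validation machinery ----------------------------

# Folds are built over sampling groups (subject, status): all technical
# replicates of one sampling stay together, so near-duplicate rows never
# leak across a split.
make_group_folds <- function(dataset, rows, scheme = c("loo", "stratified"),
                             k = 5L, seed = NULL) {
  scheme <- match.arg(scheme)
  meta <- dataset$meta[rows, , drop = FALSE]
  grp <- sampling_group(meta)
  groups <- unique(grp)
  if (scheme == "loo") {
    folds <- lapply(groups, function(g) rows[grp == g])
  } else {
    g_status <- vapply(groups, function(g) meta$status[grp == g][1], character(1))
    assign_fold <- function() {
      fold_of <- integer(length(groups))
      for (st in unique(g_status)) {
        ids <- which(g_status == st)
        ids <- ids[sample.int(length(ids))]
        fold_of[ids] <- rep_len(seq_len(k), length(ids))
      }
      fold_of
    }
    fold_of <- if (is.null(seed)) assign_fold()
               else withr::with_seed(as.integer(seed), assign_fold())
    folds <- lapply(seq_len(k), function(f) {
      rows[grp %in% groups[fold_of == f]]
    })
    folds <- folds[lengths(folds) > 0]
  }
  folds
}

# One CV pass at fixed (n_top, C) over prebuilt folds with per-fold
# train-set rankings (cached so a grid reuses them across cells).
cv_eval <- function(dataset, rows, folds, fold_ranks, n_top, C,
                    smote_k = 5L, seed = NULL) {
  truth <- character(0); pred <- character(0)
  for (i in seq_along(folds)) {
    test <- folds[[i]]
    train <- setdiff(rows, test)
    y_train <- dataset$meta$status[train]
    if (length(unique(y_train)) < 2) {
      warning("fold ", i, " skipped: single class in training rows")
      next
    }
    sel <- select_top(fold_ranks[[i]], n_top)$descriptor_id
    scaler <- fit_scaler(dataset, train)
    std <- apply_scaler(dataset, scaler)
    Xtr <- std$areas[train, sel, drop = FALSE]
    Xte <- std$areas[test, sel, drop = FALSE]
    fold_seed <- if (is.null(seed)) NULL else (as.integer(seed) + 7L * i) %% .Machine$integer.max
    bal <- smote_oversample(Xtr, y_train, k = smote_k, seed = fold_seed)
    fit <- fit_logreg(bal$X, bal$y, C)
    pred <- c(pred, predict(fit, Xte, type = "class"))
    truth <- c(truth, dataset$meta$status[test])
  }
  if (length(truth) == 0) stop("all folds skipped")
  f1_weighted(truth, pred)
}

#' Cross-validated F1-weighted score at fixed (C, N)
#'
#' For each fold: descriptors are ranked and the scaler fitted on the
#' training rows only, the training rows are SMOTE-rebalanced (never the
#' held-out rows), a logistic regression is fitted at `C` on the top-`n_top`
#' descriptors, and the held-out rows are predicted. Returns the
#' F1-weighted score of the pooled held-out predictions. Folds hold out
#' whole (subject, status) sampling groups.
#'
#' @param dataset a logged [voc_dataset].
#' @param rows learning-set row indices.
#' @param n_top number of top-ranked descriptors to use.
#' @param C regularization strength.
#' @param scheme `"loo"` (leave-one-group-out) or `"stratified"` k-fold.
#' @param k fold count for the stratified scheme (default 5).
#' @param smote_k SMOTE neighbor count.
#' @param seed integer seed driving fold assignment and SMOTE draws.
#' @return the pooled F1-weighted score, with the fold row sets in
#'   `attr(, "folds")`.
#' @export
cv_score <- function(dataset, rows, n_top, C, scheme = c("loo", "stratified"),
                     k = 5L, smote_k = 5L, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "voc_dataset"))
  if (dataset$transform_state != "logged") {
    stop("cv_score expects a logged dataset")
  }
  folds <- make_group_folds(dataset, rows, scheme, k, seed)
  fold_ranks <- lapply(folds, function(te) {
    mannwhitney_rank(dataset, setdiff(rows, te))
  })
  score <- cv_eval(dataset, rows, folds, fold_ranks, n_top, C, smote_k, seed)
  attr(score, "folds") <- folds
  score
}

#' (C, N) grid search with complexity tie-breaking
#'
#' Evaluates [cv_score] for every combination of `c_grid` (regularization)
#' and `n_grid` (descriptor count) and selects the cell with the maximal
#' score; among tied maxima the least complex model wins: smallest `N`
#' first, then smallest `C`. The full score surface is retained. Selection
#' is invariant to the enumeration order of the grids, and per-fold
#' rankings are computed once and shared across cells.
#'
#' @param dataset a logged [voc_dataset].
#' @param rows learning-set row indices.
#' @param c_grid positive regularization values.
#' @param n_grid positive descriptor counts (each <= library size).
#' @param scheme,k,smote_k,seed as in [cv_score].
#' @return a `grid_result` with `surface` (data frame of `C`, `N`, `score`),
#'   `best_C`, `best_N`, `best_score`, and `ties` (all cells attaining the
#'   maximum).
#' @export
grid_search <- function(dataset, rows, c_grid, n_grid,
                        scheme = c("loo", "stratified"), k = 5L,
                        smote_k = 5L, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(c_grid) >= 1, length(n_grid) >= 1, all(c_grid > 0),
            all(n_grid >= 1))
  if (max(n_grid) > ncol(dataset$areas)) {
    stop("n_grid value ", max(n_grid), " exceeds library size ",
         ncol(dataset$areas))
  }
  folds <- make_group_folds(dataset, rows, scheme, k, seed)
  fold_ranks <- lapply(folds, function(te) {
    mannwhitney_rank(dataset, setdiff(rows, te))
  })
  cells <- expand.grid(C = sort(as.numeric(c_grid)),
                       N = sort(as.integer(n_grid)),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$N, cells$C), ]  # canonical order: grid-order invariant
  cells$score <- vapply(seq_len(nrow(cells)), function(i) {
    cv_eval(dataset, rows, folds, fold_ranks, cells$N[i], cells$C[i],
            smote_k, seed)
  }, numeric(1))
  rownames(cells) <- NULL
  best_score <- max(cells$score)
  ties <- cells[cells$score >= best_score - 1e-12, ]
  best <- ties[order(ties$N, ties$C)[1], ]
  structure(list(surface = cells, best_C = best$C, best_N = best$N,
                 best_score = best$score, ties = ties),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result> ", nrow(x$surface), " cells; best score ",
      signif(x$best_score, 4), " at C = ", signif(x$best_C, 4),
      ", N = ", x$best_N, "\n", sep = "")
  invisible(x)
}

#' Final fit on the learning set and evaluation on a held-out test set
#'
#' Ranks descriptors and fits the scaler on the training rows, rebalances
#' the training rows with SMOTE, fits a logistic regression at `(C, n_top)`,
#' and evaluates on the untouched test rows. Training and test rows must not
#' share any (subject, status) sampling group; an overlap is a leakage
#' error. Sensitivity/specificity use `pre` (the disease state) as the
#' positive class.
#'
#' @param dataset a logged [voc_dataset].
#' @param train_rows,test_rows disjoint (at group level) row index sets.
#' @param C regularization strength.
#' @param n_top number of top-ranked descriptors.
#' @param smote_k SMOTE neighbor count.
#' @param seed integer seed for the SMOTE draws.
#' @return a `voc_holdout` list: `fit`, `metrics` (f1_weighted, sensitivity,
#'   specificity), `predictions`, `ranked`, `selected`, `scaler`, the
#'   SMOTE-rebalanced training matrices `X_train`/`y_train` with their
#'   `synthetic` flags, and the standardized original training/test
#'   matrices.
#' @export
evaluate_holdout <- function(dataset, train_rows, test_rows, C, n_top,
                             smote_k = 5L, seed = NULL) {
  stopifnot(inherits(dataset, "voc_dataset"))
  if (dataset$transform_state != "logged") {
    stop("evaluate_holdout expects a logged dataset")
  }
  g_train <- unique(sampling_group(dataset$meta[train_rows, , drop = FALSE]))
  g_test <- unique(sampling_group(dataset$meta[test_rows, , drop = FALSE]))
  overlap <- intersect(g_train, g_test)
  if (length(overlap)) {
    stop("leakage: sampling group(s) in both train and test: ",
         paste(overlap, collapse = ", "))
  }
  ranked <- mannwhitney_rank(dataset, train_rows)
  sel <- select_top(ranked, n_top)$descriptor_id
  scaler <- fit_scaler(dataset, train_rows)
  std <- apply_scaler(dataset, scaler)
  Xtr <- std$areas[train_rows, sel, drop = FALSE]
  Xte <- std$areas[test_rows, sel, drop = FALSE]
  y_train <- dataset$meta$status[train_rows]
  bal <- smote_oversample(Xtr, y_train, k = smote_k, seed = seed)
  fit <- fit_logreg(bal$X, bal$y, C)
  y_test <- dataset$meta$status[test_rows]
  pred <- predict(fit, Xte, type = "class")
  cm <- confusion_metrics(y_test, pred, positive = "pre")
  structure(list(
    fit = fit,
    metrics = c(f1_weighted = f1_weighted(y_test, pred), cm),
    predictions = data.frame(row = test_rows, truth = y_test, pred = pred,
                             stringsAsFactors = FALSE),
    ranked = ranked, selected = sel, scaler = scaler,
    X_train = bal$X, y_train = bal$y, synthetic = bal$synthetic,
    X_train_orig = Xtr, X_test = Xte), class = "voc_holdout")
}
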