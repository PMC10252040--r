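test_that("SMOTE balances classes with convex synthetic minority points", {
  set.seed(1)
  X <- rbind(matrix(rnorm(74 * 3, 0), 74, 3), matrix(rnorm(43 * 3, 4), 43, 3))
  y <- rep(c("pre", "post"), c(74, 43))
  out <- smote_oversample(X, y, k = 5, seed = 99)
  expect_equal(unname(table(out$y)["pre"]), 74)
  expect_equal(unname(table(out$y)["post"]), 74)
  expect_equal(sum(out$synthetic), 74 - 43)
  expect_identical(out$X[seq_len(117), ], X)  # originals untouched
  # every synthetic point lies on its seed-neighbor segment
  syn <- which(out$synthetic)
  for (i in seq_along(syn)) {
    s <- out$X[117 + i, ] - X[out$seed_row[i], ]
    v <- X[out$neighbor_row[i], ] - X[out$seed_row[i], ]
    t_hat <- sum(s * v) / sum(v * v)
    expect_gte(t_hat, 0); expect_lte(t_hat, 1)
    expect_lt(max(abs(s - t_hat * v)), 1e-10)
  }
  # reproducible under a fixed seed
  out2 <- smote_oversample(X, y, k = 5, seed = 99)
  expect_identical(out$X, out2$X)
})

test_that("SMOTE degenerate cases error or degrade gracefully", {
  X <- rbind(c(0, 0), c(2, 2), c(5, 5), c(6, 6), c(7, 7))
  y <- c("a", "a", "b", "b", "b")
  expect_warning(out <- smote_oversample(X, y, k = 5, seed = 1), "reducing k")
  expect_equal(sum(out$synthetic), 1)
  # with k = 1 the only neighbor is the other minority point: midpoint logic
  out1 <- smote_oversample(X, y, k = 1, seed = 2)
  s <- out1$X[6, ]
  expect_lt(max(abs((s - c(0, 0)) - (s[1] / 2) * c(2, 2) / 1)), 1e-10)
  expect_error(smote_oversample(X[2:5, ], y[2:5], k = 1), "single sample")
  bal <- smote_oversample(X[2:5, ], c("a", "a", "b", "b"), k = 1)
  expect_false(any(bal$synthetic))
})

test_that("penalized logistic fit matches an independent Newton solver", {
  withr::with_seed(4, {
    for (i in 1:5) {
      n <- 30; p <- sample(1:4, 1)
      X <- matrix(rnorm(n * p), n, p)
      y01 <- rbinom(n, 1, 0.5)
      if (length(unique(y01)) < 2) y01[1:2] <- c(0, 1)
      C <- 10^runif(1, -2, 1)
      fit <- fit_logreg(X, ifelse(y01 == 1, "post", "pre"), C)
      o <- logreg_newton_oracle(X, y01, C)
      expect_equal(unname(fit$weights), o$weights, tolerance = 1e-5)
      expect_equal(fit$intercept, o$intercept, tolerance = 1e-5)
    }
  })
})

test_that("regularization behaves as penalty theory predicts", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] > 0, "post", "pre")  # separable
  fit_hi <- fit_logreg(X, y, C = 1e6)
  expect_equal(mean(predict(fit_hi, X, type = "class") == y), 1)
  fit_lo <- fit_logreg(X, y, C = 1e-6)
  expect_lt(sqrt(sum(fit_lo$weights^2)), 1e-3)
  expect_equal(mean(predict(fit_lo, X, type = "response")), mean(y == "post"),
               tolerance = 0.02)
  norms <- vapply(10^seq(-3, 2, 1), function(C) {
    sqrt(sum(fit_logreg(X, y, C)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-8))
  expect_error(fit_logreg(X, rep("pre", 30), 1), "two classes")
})

test_that("weighted F1 and confusion metrics follow their definitions", {
  expect_equal(f1_weighted(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 1)), 82 / 105)
  expect_equal(f1_weighted(c("a", "b"), c("a", "b")), 1)
  expect_equal(f1_weighted(c("a", "a", "b"), c("b", "b", "a")), 0)
  expect_error(f1_weighted(character(0), character(0)), "empty")
  m <- confusion_metrics(c(rep("pre", 3), rep("post", 3)),
                         c("pre", "pre", "pre", "pre", "post", "post"),
                         positive = "pre")
  expect_equal(unname(m), c(1, 2 / 3))
  expect_true(is.na(confusion_metrics(rep("post", 3), rep("post", 3),
                                      positive = "pre")[["sensitivity"]]))
  expect_equal(unname(confusion_metrics(c("pre", "post"), c("pre", "post"),
                                        "pre")), c(1, 1))
})

test_that("leave-one-out CV holds out whole sampling groups, one fold each", {
  d <- separable_cohort(n_subjects = 6, replicates = 2, seed = 2)
  lg <- log_transform(d)
  sc <- cv_score(lg, seq_len(n_measurements(lg)), n_top = 3, C = 1,
                 scheme = "loo", seed = 1)
  folds <- attr(sc, "folds")
  expect_length(folds, 6 * 2)           # one fold per (subject, status)
  expect_true(all(lengths(folds) == 2)) # replicates stay together
  expect_setequal(unlist(folds), seq_len(n_measurements(lg)))
  grp <- paste(lg$meta$subject_id, lg$meta$status)
  for (f in folds) expect_length(unique(grp[f]), 1)
})

test_that("CV separates strong cohorts and stays at chance on shuffled labels", {
  scores <- vapply(1:3, function(s) {
    d <- separable_cohort(n_subjects = 8, p = 12, effect = 6, seed = s,
                          replicates = 2)
    lg <- log_transform(d)
    cv_score(lg, seq_len(n_measurements(lg)), n_top = 5, C = 1,
             scheme = "loo", seed = s)
  }, numeric(1))
  expect_gte(median(scores), 0.9)

  null_scores <- vapply(1:5, function(s) {
    d <- separable_cohort(n_subjects = 8, p = 12, effect = 6, seed = 3,
                          replicates = 2)
    # shuffle labels at the sampling-group level
    d$meta$status <- withr::with_seed(s, {
      grp <- paste(d$meta$subject_id, d$meta$status)
      new_lab <- sample(rep(c("pre", "post"), length.out = length(unique(grp))))
      new_lab[match(grp, unique(grp))]
    })
    lg <- log_transform(d)
    cv_score(lg, seq_len(n_measurements(lg)), n_top = 5, C = 1,
             scheme = "loo", seed = s)
  }, numeric(1))
  expect_lt(abs(median(null_scores) - 0.5), 0.15)
})

test_that("grid search breaks ties toward low complexity, independent of order", {
  d <- separable_cohort(n_subjects = 8, p = 12, effect = 8, seed = 5,
                        replicates = 2)
  lg <- log_transform(d)
  rows <- seq_len(n_measurements(lg))
  g <- grid_search(lg, rows, c_grid = c(10, 0.1), n_grid = c(8, 3),
                   scheme = "loo", seed = 11)
  expect_equal(g$best_score, max(g$surface$score))
  expect_gt(nrow(g$ties), 1)           # separable: several cells at the top
  expect_equal(g$best_N, min(g$ties$N))
  expect_equal(g$best_C, min(g$ties$C[g$ties$N == g$best_N]))
  # permuted grid enumeration gives the identical result
  g2 <- grid_search(lg, rows, c_grid = c(0.1, 10), n_grid = c(3, 8),
                    scheme = "loo", seed = 11)
  expect_equal(g2$surface, g$surface)
  expect_equal(c(g2$best_C, g2$best_N), c(g$best_C, g$best_N))
  g1 <- grid_search(lg, rows, c_grid = 1, n_grid = 4, scheme = "loo", seed = 1)
  expect_equal(nrow(g1$surface), 1)
  expect_equal(c(g1$best_C, g1$best_N), c(1, 4))
  expect_error(grid_search(lg, rows, 1, n_grid = 50, seed = 1),
               "exceeds library size")
})

test_that("holdout evaluation refuses train/test sampling-group overlap", {
  d <- separable_cohort(n_subjects = 6, replicates = 2, seed = 7)
  lg <- log_transform(d)
  grp <- paste(lg$meta$subject_id, lg$meta$status)
  test_rows <- which(grp %in% unique(grp)[1:3])
  expect_error(evaluate_holdout(lg, seq_len(n_measurements(lg)), test_rows,
                                C = 1, n_top = 3),
               "leakage")
  train_rows <- setdiff(seq_len(n_measurements(lg)), test_rows)
  h <- evaluate_holdout(lg, train_rows, test_rows, C = 1, n_top = 3, seed = 1)
  expect_named(h$metrics, c("f1_weighted", "sensitivity", "specificity"))
  expect_false(any(h$predictions$row %in% train_rows))
})
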