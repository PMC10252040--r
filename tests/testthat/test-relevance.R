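fake_fit <- function(w, b = 0) {
  structure(list(weights = setNames(w, paste0("V", seq_along(w))),
                 intercept = b, C = 1,
                 descriptors = paste0("V", seq_along(w)),
                 positive = "post", negative = "pre", n_train = 2),
            class = "voc_logreg")
}

test_that("linear SHAP is the exact closed-form attribution", {
  fit <- fake_fit(c(2, -1))
  X <- rbind(c(1, 1))
  bg <- rbind(c(0, 0), c(0, 0))
  s <- linear_shap(fit, X, bg)
  expect_equal(unname(s$phi[1, ]), c(2, -1))
  f <- predict(fit, X, type = "link")
  expect_equal(sum(s$phi[1, ]), unname(f) - s$baseline)
  # a zero-weight descriptor gets zero attribution everywhere
  fit0 <- fake_fit(c(0, 3))
  s0 <- linear_shap(fit0, matrix(rnorm(10), 5, 2))
  expect_equal(unname(s0$phi[, 1]), rep(0, 5))
  expect_error(linear_shap(fit, X, X[0, , drop = FALSE]), "background")
})

test_that("SHAP additivity identity holds across random fits", {
  withr::with_seed(10, {
    for (i in 1:10) {
      n <- 20; p <- sample(2:6, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- sample(c("pre", "post"), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c("pre", "post")
      fit <- fit_logreg(X, y, C = 10^runif(1, -2, 2))
      bg <- X[sample(n, 10), , drop = FALSE]
      s <- linear_shap(fit, X, bg)
      gap <- rowSums(s$phi) - (predict(fit, X, type = "link") - s$baseline)
      expect_lt(max(abs(gap)), 1e-10)
    }
  })
})

test_that("importance ranks order by mean |phi| with library-order ties", {
  fit <- fake_fit(c(1, 1))
  X <- rbind(c(2, -1), c(0, 1))
  s <- linear_shap(fit, X, background = matrix(0, 1, 2))
  expect_equal(unname(s$importance), c(1, 1))
  expect_equal(unname(s$rank), c(1, 2))
  tab <- shap_importance(s)
  expect_equal(tab$descriptor_id, c("V1", "V2"))
  # boosting one descriptor's weight cannot worsen its rank
  s10 <- linear_shap(fake_fit(c(10, 1)), X, background = matrix(0, 1, 2))
  expect_lte(s10$rank[["V1"]], s$rank[["V1"]])
  s1 <- linear_shap(fake_fit(1), matrix(1:3, 3, 1))
  expect_equal(unname(s1$rank), 1L)
})

test_that("probe rank cutoff implements max{r : F(r) <= delta}", {
  cdf <- c(0.01, 0.02, 0.04, 0.07, 0.2, 1)
  expect_equal(probe_rank_cutoff(cdf, 0.05), 3L)
  expect_equal(probe_rank_cutoff(cdf, 0.10), 4L)
  expect_equal(probe_rank_cutoff(c(0.3, 0.6, 1), 0.05), 0L)
  expect_equal(probe_rank_cutoff(cdf, 0.999), 5L)  # F(6) = 1 > delta
})

test_that("probe relevance retains a dominant feature and nests across deltas", {
  withr::with_seed(21, {
    hits <- vapply(1:5, function(s) {
      n <- 40
      X <- cbind(sig = rep(c(-2, 2), each = n / 2), std_noise_matrix(n, 9, s))
      colnames(X) <- c("sig", paste0("n", 1:9))
      y <- rep(c("pre", "post"), each = n / 2)
      pr <- probe_relevance(X, y, C = 1, R = 200, seed = s,
                            deltas = c(0.05, 0.10, 0.20))
      expect_true(all(pr$retained[["0.05"]] %in% pr$retained[["0.10"]]))
      expect_true(all(pr$retained[["0.10"]] %in% pr$retained[["0.20"]]))
      "sig" %in% pr$retained[["0.05"]]
    }, logical(1))
    expect_true(all(hits))
  })
  expect_error(probe_relevance(matrix(rnorm(20), 10, 2),
                               rep(c("a", "b"), 5), C = 1, R = 50),
               ">= 100")
})

test_that("Jaccard index and curves match closed forms", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(1:3, 1:3), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_warning(j <- jaccard(character(0), character(0)), "empty")
  expect_equal(j, 1)
  ranks <- letters[1:6]
  expect_true(all(jaccard_curve(ranks, ranks)$jaccard == 1))
  cv <- jaccard_curve(ranks, rev(ranks))
  expect_equal(cv$jaccard[6], 1)   # full sets coincide
  expect_equal(cv$jaccard[3], 0)   # top-3 vs bottom-3 are disjoint
  expect_error(jaccard_curve(ranks, ranks[1:3], sizes = 5), "exceeds")
})

test_that("relevance report counts occurrence fractions per status", {
  areas <- matrix(0, 20, 3, dimnames = list(NULL, NULL))
  areas[1:8, 1] <- 5    # pre rows 1:10, post rows 11:20
  areas[11:12, 1] <- 5
  areas[, 3] <- 1
  d <- build_dataset(areas, status = rep(c("pre", "post"), each = 10))
  probe <- structure(list(
    deltas = c(0.05, 0.2),
    retained = list("0.05" = c("d001", "d003"),
                    "0.2" = c("d001", "d002", "d003")),
    reference = data.frame(descriptor_id = c("d001", "d002", "d003"),
                           importance = c(3, 2, 1), rank = 1:3)),
    class = "probe_result")
  shap <- structure(list(importance = c(d001 = 3, d002 = 2, d003 = 1)),
                    class = "shap_summary")
  rep05 <- relevance_report(probe, shap, d, delta = 0.05)
  expect_equal(nrow(rep05), 2)
  r1 <- rep05[rep05$descriptor_id == "d001", ]
  expect_equal(r1$occurrence_pre, 0.8)
  expect_equal(r1$occurrence_post, 0.2)
  expect_equal(r1$occurrence_diff, 0.6)
  never <- relevance_report(probe, shap, d, delta = 0.2)
  r2 <- never[never$descriptor_id == "d002", ]
  expect_equal(r2$occurrence_pre, 0)
  expect_equal(r2$occurrence_diff, 0)
  expect_error(relevance_report(probe, shap, d, delta = 0.5), "not among")
})
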