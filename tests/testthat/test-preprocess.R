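test_that("log transform maps ln(1 + a), keeps zeros, preserves order", {
  a <- rbind(c(0, exp(1) - 1, 5), c(2, 0, 7))
  d <- build_dataset(a, status = c("pre", "post"))
  lg <- log_transform(d)
  expect_identical(lg$transform_state, "logged")
  expect_equal(unname(lg$areas[1, 1]), 0)
  expect_equal(unname(lg$areas[1, 2]), 1)
  expect_equal(lg$areas, log1p(a), ignore_attr = TRUE)
  expect_true(all(sign(diff(a[, 3])) == sign(diff(lg$areas[, 3]))))
  expect_error(log_transform(lg), "raw")
})

test_that("scaler standardizes fitting rows with population sd and flags constants", {
  a <- cbind(c(1, 2, 3), c(5, 5, 5))
  d <- build_dataset(a, status = c("pre", "pre", "post"))
  lg <- build_dataset(a, status = c("pre", "pre", "post"), state = "logged")
  st <- fit_scaler(lg)
  std <- apply_scaler(lg, st)
  expect_equal(std$areas[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(st$constant[2])
  expect_equal(std$areas[, 2], rep(0, 3))
  expect_identical(std$transform_state, "standardized")
  expect_error(fit_scaler(lg, integer(0)), "empty")
  expect_error(fit_scaler(d), "logged")
})

test_that("scaler applied to held-out rows does not refit", {
  set.seed(2)
  a <- matrix(rnorm(40, mean = 5), 10, 4)
  d <- build_dataset(abs(a), status = rep(c("pre", "post"), 5))
  lg <- log_transform(d)
  st <- fit_scaler(lg, rows = 1:5)
  std <- apply_scaler(lg, st)
  expect_equal(colMeans(std$areas[1:5, ]), rep(0, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(max(abs(colMeans(std$areas[6:10, ]))), 1e-6)
})

test_that("Mann-Whitney test matches closed-form and enumeration cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(mann_whitney_u(c(1, 4), c(2, 3))$p_value, 1.0)
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2, 2))$p_value, 1.0)
  # spot-check against the exhaustive oracle on random no-tie instances
  withr::with_seed(5, {
    for (i in 1:20) {
      n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
      v <- sample(100, n1 + n2)
      x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
      o <- mw_enum_oracle(x, y)
      got <- mann_whitney_u(x, y)
      expect_equal(got$U, o$U)
      expect_equal(got$p_value, o$p_value, tolerance = 1e-12)
    }
  })
})

test_that("descriptor ranking is sorted by p with library-order tie-breaks", {
  set.seed(3)
  base <- c(rnorm(4, 0), rnorm(4, 3))
  a <- cbind(rnorm(8), base, base, rnorm(8))
  d <- build_dataset(abs(a) + 1, status = rep(c("pre", "post"), each = 4))
  r <- mannwhitney_rank(d)
  expect_true(!is.unsorted(r$p_value))
  expect_equal(r$rank, seq_len(4))
  tied <- r[r$descriptor_id %in% c("d002", "d003"), ]
  expect_equal(tied$p_value[1], tied$p_value[2])
  expect_lt(tied$lib_index[1], tied$lib_index[2])  # library order decides
  single <- build_dataset(matrix(1, 2, 2), status = c("pre", "pre"))
  expect_error(mannwhitney_rank(single), "both statuses")
})

test_that("significance and top-n selection honor thresholds and bounds", {
  d <- build_dataset(matrix(runif(40, 1, 2), 10, 4),
                     status = rep(c("pre", "post"), 5))
  r <- mannwhitney_rank(d)
  r$p_value <- c(0.01, 0.04, 0.2, 0.6)  # deterministic p landscape
  r$rank <- 1:4
  kept <- select_significant(r, 0.05)
  expect_equal(kept$rank, 1:2)
  expect_warning(select_significant(r, 0.001), "no descriptor")
  expect_equal(nrow(select_significant(r, 1)), 4)
  expect_equal(nrow(select_top(r, 1)), 1)
  expect_equal(select_top(r, 4)$rank, 1:4)
  expect_error(select_top(r, 5), "1..4")
  expect_error(select_top(r, 0), "1..4")
})

test_that("PCA projects onto principal axes with complete reconstruction", {
  d <- build_dataset(rbind(c(-1, -1), c(1, 1)), status = c("pre", "post"),
                     state = "standardized")
  pc <- pca_project(d, c("d001", "d002"), k = 1)
  expect_equal(pc$explained[1], 1)
  expect_equal(abs(pc$rotation[, 1]), rep(1 / sqrt(2), 2), ignore_attr = TRUE)

  set.seed(8)
  x <- matrix(rnorm(40), 10, 4)
  ds <- build_dataset(x, status = rep(c("pre", "post"), 5),
                      state = "standardized")
  pc4 <- pca_project(ds, ds$library$descriptor_id, k = 4)
  expect_true(all(diff(pc4$explained) <= 1e-12))
  expect_lte(sum(pc4$explained), 1 + 1e-12)
  recon <- pc4$scores %*% t(pc4$rotation)
  centered <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(recon - centered)), 1e-9)

  raw <- build_dataset(abs(x), status = rep(c("pre", "post"), 5))
  expect_error(pca_project(raw, raw$library$descriptor_id, 2), "standardized")
  one <- ds[1]
  expect_error(pca_project(one, ds$library$descriptor_id, 2), "at least 2")
})
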