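# Independent oracles and fixture builders shared across the suite.

# Exhaustive label-assignment oracle for the two-sided Mann-Whitney test:
# enumerate every way of assigning the pooled values to the two groups,
# compute the U distribution, and form the two-sided tail probability.
mw_enum_oracle <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  combs <- utils::combn(length(vals), nx)
  Us <- apply(combs, 2, function(ix) sum(outer(vals[ix], vals[-ix], ">")))
  U_obs <- sum(outer(x, y, ">"))
  p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
  list(U = U_obs, p_value = min(1, p))
}

# Newton-Raphson minimizer of the penalized logistic negative log-likelihood
# -loglik + (1/(2C)) * ||w||^2 (intercept unpenalized); independent of the
# glmnet route used by the package.
logreg_newton_oracle <- function(X, y01, C, maxit = 100) {
  X1 <- cbind(1, as.matrix(X))
  p <- ncol(X1)
  pen <- diag(c(0, rep(1 / C, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X1, mu - y01)) + drop(pen %*% beta)
    H <- crossprod(X1, X1 * (mu * (1 - mu))) + pen
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  list(intercept = beta[1], weights = beta[-1])
}

tiny_library <- function(p) voc_library(sprintf("d%03d", seq_len(p)))

# Dataset builder: one measurement per row of `areas`.
build_dataset <- function(areas, status, subject = NULL, site = "breast",
                          batch = "column1", replicate = NULL, state = "raw") {
  areas <- as.matrix(areas)
  dimnames(areas) <- NULL
  n <- nrow(areas)
  if (is.null(subject)) subject <- sprintf("S%02d", seq_len(n))
  if (is.null(replicate)) replicate <- rep(1L, n)
  meta <- data.frame(subject_id = subject, site = rep_len(site, n),
                     status = status, batch = rep_len(batch, n),
                     replicate = replicate, stringsAsFactors = FALSE)
  voc_dataset(areas, meta, tiny_library(ncol(areas)), state)
}

# Population-standardized pure-noise feature matrix (columns exchangeable
# with the standardized probe).
std_noise_matrix <- function(n, p, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    X <- sweep(X, 2, colMeans(X))
    sweep(X, 2, sqrt(colMeans(X^2)), "/")
  })
}

# A small two-class cohort with a planted separation, used by modeling tests.
separable_cohort <- function(n_subjects = 8, p = 10, effect = 6, seed = 1,
                             replicates = 1) {
  cfg <- generator_config(
    n_subjects = n_subjects, n_descriptors = p,
    replicates_per_sampling = replicates,
    occurrence_profile = rep(1, p),
    nonzero_range = c(p, p),
    planted_descriptors = seq_len(max(2L, round(p / 3))),
    area_scale_spread = 0.5,
    effect_size = effect, dropout_shift = 0, seed = seed)
  generate_cohort(cfg)
}
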