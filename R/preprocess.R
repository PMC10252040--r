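#' Natural-log transform of peak areas
#'
#' Replaces each area `a` by `ln(1 + a)`, so absent descriptors (area 0) stay
#' exactly 0 and the transform is strictly monotone. Only a raw dataset may
#' be logged; re-logging is a state error.
#'
#' @param dataset a raw [voc_dataset].
#' @return the dataset with `transform_state = "logged"`.
#' @export
log_transform <- function(dataset) {
  stopifnot(inherits(dataset, "voc_dataset"))
  if (dataset$transform_state != "raw") {
    stop("log_transform requires a raw dataset (got '",
         dataset$transform_state, "')")
  }
  voc_dataset(log1p(dataset$areas), dataset$meta, dataset$library, "logged")
}

#' Fit / apply a standardizing scaler
#'
#' `fit_scaler` learns per-descriptor mean and population standard deviation
#' on a fitting row subset of a logged dataset; `apply_scaler` centers and
#' scales any rows with the learned state (no refit, so held-out rows need
#' not have mean 0). Descriptors constant on the fitting rows are flagged
#' and map to exactly 0.
#'
#' @param dataset a logged [voc_dataset].
#' @param rows integer row subset to fit on (default: all rows).
#' @return `fit_scaler`: a `scaler_state` with `mean`, `sd` (population),
#'   `constant` flags; `apply_scaler`: the standardized dataset.
#' @export
fit_scaler <- function(dataset, rows = seq_len(n_measurements(dataset))) {
  stopifnot(inherits(dataset, "voc_dataset"))
  if (dataset$transform_state != "logged") {
    stop("fit_scaler requires a logged dataset (got '",
         dataset$transform_state, "')")
  }
  if (length(rows) == 0) stop("empty fitting subset")
  x <- dataset$areas[rows, , drop = FALSE]
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))  # population sd
  constant <- s < 1e-12
  structure(list(mean = m, sd = s, constant = constant,
                 descriptor_id = colnames(dataset$areas)),
            class = "scaler_state")
}

#' @rdname fit_scaler
#' @param state a `scaler_state` from [fit_scaler].
#' @export
apply_scaler <- function(dataset, state) {
  stopifnot(inherits(dataset, "voc_dataset"), inherits(state, "scaler_state"))
  if (dataset$transform_state != "logged") {
    stop("apply_scaler requires a logged dataset (got '",
         dataset$transform_state, "')")
  }
  if (!identical(state$descriptor_id, colnames(dataset$areas))) {
    stop("scaler was fitted on a different descriptor set")
  }
  s <- ifelse(state$constant, 1, state$sd)
  z <- sweep(sweep(dataset$areas, 2, state$mean), 2, s, "/")
  z[, state$constant] <- 0
  voc_dataset(z, dataset$meta, dataset$library, "standardized")
}

#' Two-sided Mann-Whitney U test for one descriptor
#'
#' Exact null distribution when both groups have at most 8 observations and
#' there are no ties; tie-corrected normal approximation with continuity
#' correction otherwise. When every value is tied the statistic is
#' degenerate and the p-value is 1.
#'
#' @param x,y numeric value vectors for the two groups.
#' @return list with `U` (statistic for `x` relative to `y`) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE))
  p <- res$p.value
  if (!is.finite(p)) p <- 1  # all values tied: zero-variance rank sum
  list(U = unname(res$statistic), p_value = min(1, p))
}

#' Rank descriptors by Mann-Whitney p-value
#'
#' For each descriptor, compares its values between the `pre` and `post`
#' measurements among `rows` with a two-sided Mann-Whitney U test and ranks
#' descriptors from smallest to largest p-value (rank 1 = smallest; ties
#' broken by library order). The test is rank-based, so ranking on raw,
#' logged, or standardized areas is equivalent; restrict `rows` to the
#' learning set to keep the ranking leakage-free (passing all rows is the
#' full-data mode and leaks test information into descriptor selection).
#'
#' @param dataset a [voc_dataset].
#' @param rows integer row subset (default: all rows); must contain both
#'   statuses.
#' @return a `ranked_descriptors` data frame with columns `descriptor_id`,
#'   `U`, `p_value`, `rank`, `lib_index`, sorted by rank.
#' @export
mannwhitney_rank <- function(dataset, rows = seq_len(n_measurements(dataset))) {
  stopifnot(inherits(dataset, "voc_dataset"))
  status <- dataset$meta$status[rows]
  if (!all(.voc_statuses %in% status)) {
    stop("both statuses (pre, post) must be present among rows")
  }
  x <- dataset$areas[rows, , drop = FALSE]
  pre <- status == "pre"
  res <- lapply(seq_len(ncol(x)), function(j) mann_whitney_u(x[pre, j], x[!pre, j]))
  out <- data.frame(
    descriptor_id = colnames(x),
    U = vapply(res, `[[`, numeric(1), "U"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    lib_index = seq_len(ncol(x)),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$lib_index), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("descriptor_id", "U", "p_value", "rank", "lib_index")]
  class(out) <- c("ranked_descriptors", "data.frame")
  out
}

#' Select significant descriptors
#'
#' Keeps descriptors with `p < alpha`, preserving rank order. No multiplicity
#' correction is applied (the screening is deliberately permissive; the
#' probe-variable stage controls relevance downstream).
#'
#' @param ranked a `ranked_descriptors` from [mannwhitney_rank].
#' @param alpha significance level (default 0.05).
#' @return the subset of `ranked` with `p_value < alpha`; empty with a
#'   warning if nothing passes.
#' @export
select_significant <- function(ranked, alpha = 0.05) {
  stopifnot(inherits(ranked, "ranked_descriptors"))
  out <- ranked[ranked$p_value < alpha, , drop = FALSE]
  if (nrow(out) == 0) warning("no descriptor significant at alpha = ", alpha)
  rownames(out) <- NULL
  out
}

#' Select the top-n ranked descriptors
#'
#' @param ranked a `ranked_descriptors` from [mannwhitney_rank].
#' @param n number of descriptors to keep, 1 <= n <= library size.
#' @return the first `n` entries by rank.
#' @export
select_top <- function(ranked, n) {
  stopifnot(inherits(ranked, "ranked_descriptors"))
  if (n < 1 || n > nrow(ranked)) {
    stop("n must be in 1..", nrow(ranked), " (got ", n, ")")
  }
  out <- ranked[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project measurements onto principal components
#'
#' PCA of the standardized area matrix restricted to a descriptor subset.
#' Scores are projections onto the top-k principal axes of the (column-
#' centered) subset matrix; explained-variance fractions are non-increasing.
#'
#' @param dataset a standardized [voc_dataset].
#' @param subset descriptor ids (character) or column indices.
#' @param k number of components, `k <= length(subset)`.
#' @return a `voc_pca` list with `scores` (n x k), `explained` (length-k
#'   variance fractions), `rotation`, and `center`.
#' @export
pca_project <- function(dataset, subset, k = 2L) {
  stopifnot(inherits(dataset, "voc_dataset"))
  if (dataset$transform_state != "standardized") {
    stop("pca_project requires a standardized dataset (got '",
         dataset$transform_state, "')")
  }
  if (n_measurements(dataset) < 2) stop("need at least 2 measurements for PCA")
  x <- dataset$areas[, subset, drop = FALSE]
  if (ncol(x) < k) stop("subset smaller than k")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained = ev[seq_len(k)],
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center),
            class = "voc_pca")
}
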