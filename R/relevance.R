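#' Exact SHAP attributions for a linear classifier
#'
#' For a linear decision function `f(x) = b + w'x`, the SHAP attribution of
#' feature `j` on row `i` is exactly `phi_ij = w_j * (x_ij - mean_bg_j)`,
#' where `mean_bg_j` is the background mean. Attributions are additive:
#' `sum_j phi_ij = f(x_i) - f(x_bar)`. Negative values push the prediction
#' toward the negative class (`pre`-surgery), positive toward the positive
#' class (`post`-surgery). Per-descriptor importance is the mean absolute
#' attribution; importance ranks break ties by library (column) order.
#'
#' @param fit a `voc_logreg` from [fit_logreg].
#' @param X rows to attribute (matrix over the fit's descriptors).
#' @param background background rows defining the reference expectation;
#'   defaults to `X`.
#' @return a `shap_summary` with `phi` (attribution matrix), `importance`
#'   (mean |phi| per descriptor), `rank`, `descriptors`, and `baseline`
#'   (`f(x_bar)`).
#' @export
linear_shap <- function(fit, X, background = X) {
  stopifnot(inherits(fit, "voc_logreg"))
  X <- as.matrix(X); background <- as.matrix(background)
  if (nrow(background) == 0) stop("background must contain at least one row")
  if (!is.null(colnames(X))) X <- X[, fit$descriptors, drop = FALSE]
  if (!is.null(colnames(background))) {
    background <- background[, fit$descriptors, drop = FALSE]
  }
  stopifnot(ncol(X) == length(fit$weights))
  mu <- colMeans(background)
  phi <- sweep(X, 2, mu) %*% diag(fit$weights, nrow = length(fit$weights))
  colnames(phi) <- fit$descriptors
  importance <- colMeans(abs(phi))
  ord <- order(-importance, seq_along(importance))
  rank <- integer(length(importance)); rank[ord] <- seq_along(ord)
  names(rank) <- fit$descriptors
  structure(list(phi = phi, importance = importance, rank = rank,
                 descriptors = fit$descriptors,
                 baseline = as.numeric(fit$intercept + mu %*% fit$weights)),
            class = "shap_summary")
}

#' Descriptor importance ranking from SHAP attributions
#'
#' @param summary a `shap_summary` from [linear_shap].
#' @return data frame `descriptor_id`, `importance` (mean |phi|), `rank`,
#'   sorted by rank (1 = largest importance; ties broken by library order).
#' @export
shap_importance <- function(summary) {
  stopifnot(inherits(summary, "shap_summary"))
  out <- data.frame(descriptor_id = summary$descriptors,
                    importance = unname(summary$importance),
                    rank = unname(summary$rank), stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}

#' Rank cutoff from a probe-rank CDF at risk delta
#'
#' The retained-rank cutoff is `r_delta = max(r : F(r) <= delta)`, the
#' deepest rank at which the probability that the probe ranks at least that
#' well stays within the accepted risk; 0 when even rank 1 exceeds the risk
#' (`F(1) > delta`).
#'
#' @param cdf non-decreasing CDF vector, `cdf[r] = P(probe rank <= r)`.
#' @param delta risk threshold in (0, 1).
#' @return integer cutoff rank (0 = nothing retained).
#' @export
probe_rank_cutoff <- function(cdf, delta) {
  stopifnot(delta > 0, delta < 1)
  ok <- which(cdf <= delta)
  if (length(ok) == 0) 0L else max(ok)
}

#' Probe-variable relevance selection
#'
#' Adds a label-independent random probe feature to the model input, refits
#' the logistic regression at the same `C`, recomputes SHAP importances over
#' the augmented feature set, and records the probe's importance rank. Over
#' `R` such realizations the empirical cumulative distribution of the probe
#' rank is accumulated; at each risk `delta`, descriptors whose rank in the
#' probe-free reference fit is at most [probe_rank_cutoff] are retained —
#' i.e. descriptors unlikely (risk <= delta) to be out-ranked by a feature
#' that carries no information. The probe is drawn i.i.d. standard normal
#' and then standardized (mean 0, population sd 1), matching the scaling of
#' the real features so its importance is directly comparable.
#'
#' @param X standardized feature matrix the final model was trained on
#'   (typically the SMOTE-rebalanced learning matrix).
#' @param y training labels matching `X`.
#' @param C regularization strength of the reference model.
#' @param R number of probe realizations (>= 100; the rank CDF is too coarse
#'   below that).
#' @param seed integer seed.
#' @param deltas risk thresholds in (0, 1).
#' @return a `probe_result` with `R`, `N` (feature count), `rank_counts`
#'   (histogram over ranks 1..N+1), `cdf`, `thresholds` (`r_delta` per
#'   delta), `retained` (descriptor-id sets per delta, nested across
#'   increasing delta), `min_rank`/`max_rank` observed, and `reference`
#'   (the probe-free SHAP importance table).
#' @export
probe_relevance <- function(X, y, C, R = 1000L, seed = 1L,
                            deltas = c(0.05, 0.10, 0.20)) {
  X <- as.matrix(X)
  N <- ncol(X)
  if (N == 0) stop("no descriptors (N = 0)")
  if (R < 100) stop("R must be >= 100 for a usable rank CDF")
  stopifnot(all(deltas > 0), all(deltas < 1))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(N))
  ref_fit <- fit_logreg(X, y, C)
  ref <- shap_importance(linear_shap(ref_fit, X))
  counts <- integer(N + 1)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(R)) {
      z <- rnorm(nrow(X))
      z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
      Xp <- cbind(X, .probe. = z)
      fit <- fit_logreg(Xp, y, C)
      s <- linear_shap(fit, Xp)
      pr <- s$rank[[".probe."]]
      counts[pr] <- counts[pr] + 1L
    }
  })
  cdf <- cumsum(counts) / R
  thresholds <- vapply(deltas, function(d) probe_rank_cutoff(cdf, d), integer(1))
  names(thresholds) <- format(deltas)
  retained <- lapply(thresholds, function(rd) {
    ref$descriptor_id[ref$rank <= rd]
  })
  obs <- which(counts > 0)
  structure(list(R = as.integer(R), N = N, rank_counts = counts, cdf = cdf,
                 deltas = deltas, thresholds = thresholds, retained = retained,
                 min_rank = min(obs), max_rank = max(obs), reference = ref,
                 C = C),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat("<probe_result> R = ", x$R, ", N = ", x$N,
      "; probe rank in [", x$min_rank, ", ", x$max_rank, "]\n", sep = "")
  for (i in seq_along(x$deltas)) {
    cat(sprintf("  delta = %s: cutoff %d, %d descriptors retained\n",
                format(x$deltas[i]), x$thresholds[i],
                length(x$retained[[i]])))
  }
  invisible(x)
}

#' Jaccard index of two descriptor sets
#'
#' `|A intersect B| / |A union B|`. Two empty sets are defined as identical
#' (index 1) with a warning.
#'
#' @param setA,setB vectors (duplicates ignored).
#' @return value in \[0, 1\].
#' @export
jaccard <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  if (length(a) == 0 && length(b) == 0) {
    warning("both sets empty; Jaccard defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Jaccard curve over nested top-m sets of two rankings
#'
#' For each size `m`, the Jaccard index of the top-`m` entries of the two
#' rankings; used to compare retained-descriptor rankings across datasets
#' (e.g. body sites or instrument columns).
#'
#' @param rankedA,rankedB character vectors in rank order (best first).
#' @param sizes set sizes to evaluate; each must not exceed either ranking
#'   length.
#' @return a `voc_jaccard_curve` data frame with columns `size`, `jaccard`.
#' @export
jaccard_curve <- function(rankedA, rankedB,
                          sizes = seq_len(min(length(rankedA), length(rankedB)))) {
  if (any(sizes > length(rankedA)) || any(sizes > length(rankedB))) {
    stop("size exceeds a ranking length")
  }
  stopifnot(all(sizes >= 1))
  out <- data.frame(size = as.integer(sizes),
                    jaccard = vapply(sizes, function(m) {
                      jaccard(rankedA[seq_len(m)], rankedB[seq_len(m)])
                    }, numeric(1)))
  class(out) <- c("voc_jaccard_curve", "data.frame")
  out
}

#' Per-descriptor relevance report
#'
#' For every descriptor retained at risk `delta`: its reference importance
#' rank, mean absolute SHAP attribution, fraction of `pre` (sick-status) and
#' `post` (healthy-status) measurements in which it occurs (raw area > 0),
#' and the absolute difference of those occurrence fractions.
#'
#' @param probe a `probe_result` from [probe_relevance].
#' @param shap a `shap_summary` covering the retained descriptors.
#' @param dataset a raw or logged [voc_dataset] (occurrence = area > 0).
#' @param rows measurement rows over which occurrence fractions are counted
#'   (default: all).
#' @param delta which risk threshold's retained set to report (must be one
#'   of the probe result's deltas; default the smallest).
#' @return data frame with one row per retained descriptor.
#' @export
relevance_report <- function(probe, shap, dataset,
                             rows = seq_len(n_measurements(dataset)),
                             delta = min(probe$deltas)) {
  stopifnot(inherits(probe, "probe_result"), inherits(shap, "shap_summary"),
            inherits(dataset, "voc_dataset"))
  if (dataset$transform_state == "standardized") {
    stop("occurrence fractions need a raw or logged dataset")
  }
  di <- which(abs(probe$deltas - delta) < 1e-12)
  if (length(di) != 1) {
    stop("delta ", delta, " not among probe deltas: ",
         paste(format(probe$deltas), collapse = ", "))
  }
  ids <- probe$retained[[di]]
  status <- dataset$meta$status[rows]
  occ <- function(id, st) {
    sel <- rows[status == st]
    if (length(sel) == 0) return(NA_real_)
    mean(dataset$areas[sel, id] > 0)
  }
  ref <- probe$reference
  out <- data.frame(
    descriptor_id = ids,
    rank = ref$rank[match(ids, ref$descriptor_id)],
    mean_abs_shap = unname(shap$importance[ids]),
    occurrence_pre = vapply(ids, occ, numeric(1), st = "pre"),
    occurrence_post = vapply(ids, occ, numeric(1), st = "post"),
    stringsAsFactors = FALSE)
  out$occurrence_diff <- abs(out$occurrence_pre - out$occurrence_post)
  rownames(out) <- NULL
  out[order(out$rank), ]
}
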