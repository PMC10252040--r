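#' Pipeline run configuration
#'
#' Defaults: significance level 0.05; a C ladder of half-decade steps from
#' 1e-4 to 10; descriptor counts 5-250; SMOTE with 5 neighbors; 100,000
#' probe realizations at risks 5/10/20%; leave-one-group-out CV scoring;
#' a quarter of the sampling groups (stratified by status) held out for
#' testing. Every field can be overridden by argument or by a YAML config
#' file ([read_run_config]).
#'
#' @param alpha univariate significance level.
#' @param c_grid positive regularization values for the grid search.
#' @param n_grid descriptor counts for the grid search (validated against
#'   the library size before any compute).
#' @param smote_k SMOTE neighbor count.
#' @param probe_realizations probe realizations R (>= 100).
#' @param delta_grid probe risk thresholds, each in (0, 1).
#' @param cv_scheme `"loo"` or `"stratified"`.
#' @param cv_folds fold count for the stratified scheme.
#' @param test_fraction fraction of sampling groups held out per status.
#' @param pool_batches pool measurements across GC-column batches? Default
#'   `FALSE`: the column replacement is a dominant confound, so each batch
#'   is analyzed separately.
#' @param seed integer seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(alpha = 0.05,
                       c_grid = 10^seq(-4, 1, by = 0.5),
                       n_grid = c(5L, 10L, 20L, 40L, 80L, 120L, 175L, 250L),
                       smote_k = 5L,
                       probe_realizations = 100000L,
                       delta_grid = c(0.05, 0.10, 0.20),
                       cv_scheme = c("loo", "stratified"),
                       cv_folds = 5L,
                       test_fraction = 0.25,
                       pool_batches = FALSE,
                       seed = 1L) {
  cv_scheme <- match.arg(cv_scheme)
  stopifnot(alpha > 0, alpha <= 1, all(c_grid > 0), all(n_grid >= 1),
            smote_k >= 1, probe_realizations >= 100,
            all(delta_grid > 0), all(delta_grid < 1),
            test_fraction > 0, test_fraction < 1, cv_folds >= 2)
  structure(list(alpha = alpha, c_grid = as.numeric(c_grid),
                 n_grid = as.integer(n_grid), smote_k = as.integer(smote_k),
                 probe_realizations = as.integer(probe_realizations),
                 delta_grid = as.numeric(delta_grid), cv_scheme = cv_scheme,
                 cv_folds = as.integer(cv_folds),
                 test_fraction = test_fraction,
                 pool_batches = isTRUE(pool_batches), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys matching [run_config] arguments override the defaults; unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf)
  unname(tools::md5sum(tf))
}

# Stratified group-aware train/test split: per status, a test_fraction of
# the (subject, status) sampling groups is held out (at least one, and at
# least one group per status stays in training).
split_train_test <- function(dataset, rows, test_fraction, seed) {
  meta <- dataset$meta[rows, , drop = FALSE]
  grp <- sampling_group(meta)
  out <- withr::with_seed(as.integer(seed), {
    test_groups <- character(0)
    for (st in .voc_statuses) {
      g <- unique(grp[meta$status == st])
      if (length(g) < 2) {
        stop("need at least 2 sampling groups with status '", st,
             "' to split train/test")
      }
      n_test <- min(length(g) - 1L, max(1L, round(test_fraction * length(g))))
      test_groups <- c(test_groups, sample(g, n_test))
    }
    test_groups
  })
  list(train = rows[!grp %in% out], test = rows[grp %in% out])
}

run_one_batch <- function(dataset, rows, config, log_fn) {
  sub <- dataset[rows]
  audit <- validate_dataset(sub)
  for (f in audit$flags) log_fn(paste("validate:", f))
  logged <- log_transform(sub)
  split <- split_train_test(logged, seq_len(n_measurements(logged)),
                            config$test_fraction, config$seed)
  log_fn(sprintf("split: %d train rows, %d test rows",
                 length(split$train), length(split$test)))
  ranked <- mannwhitney_rank(logged, split$train)
  sig <- suppressWarnings(select_significant(ranked, config$alpha))
  log_fn(sprintf("ranking: %d descriptors significant at alpha = %g",
                 nrow(sig), config$alpha))
  scaler <- fit_scaler(logged, split$train)
  std <- apply_scaler(logged, scaler)
  pca <- if (nrow(sig) >= 2) {
    pca_project(std, sig$descriptor_id, k = 2L)
  } else {
    log_fn("pca: skipped (< 2 significant descriptors)")
    NULL
  }
  grid <- grid_search(logged, split$train, config$c_grid, config$n_grid,
                      scheme = config$cv_scheme, k = config$cv_folds,
                      smote_k = config$smote_k, seed = config$seed)
  log_fn(sprintf("grid: best CV score %.4f at C = %g, N = %d",
                 grid$best_score, grid$best_C, grid$best_N))
  hold <- evaluate_holdout(logged, split$train, split$test,
                           C = grid$best_C, n_top = grid$best_N,
                           smote_k = config$smote_k, seed = config$seed)
  log_fn(sprintf("holdout: F1w %.4f, sensitivity %.4f, specificity %.4f",
                 hold$metrics[["f1_weighted"]],
                 hold$metrics[["sensitivity"]],
                 hold$metrics[["specificity"]]))
  shap <- linear_shap(hold$fit, hold$X_train_orig)
  probe <- probe_relevance(hold$X_train, hold$y_train, C = grid$best_C,
                           R = config$probe_realizations, seed = config$seed,
                           deltas = config$delta_grid)
  log_fn(sprintf("probe: rank range [%d, %d]; retained %s",
                 probe$min_rank, probe$max_rank,
                 paste(lengths(probe$retained), collapse = "/")))
  reports <- lapply(config$delta_grid, function(d) {
    relevance_report(probe, shap, sub, delta = d)
  })
  names(reports) <- format(config$delta_grid)
  list(rows = rows, train_rows = rows[split$train], test_rows = rows[split$test],
       validation = audit, ranked = ranked, significant = sig, pca = pca,
       grid = grid, holdout = hold, metrics = hold$metrics, shap = shap,
       probe = probe, retained = probe$retained, reports = reports)
}

#' Run the full discrimination pipeline
#'
#' Executes, per GC-column batch (batches are not pooled unless
#' `pool_batches` is set, since the column replacement dominates the
#' variance): validation, log transform, group-aware stratified train/test
#' split, Mann-Whitney ranking and significance screening, PCA artifacts,
#' (C, N) grid search with SMOTE-rebalanced group-aware CV, holdout
#' evaluation, SHAP attribution, probe-variable relevance selection, and
#' per-delta relevance reports. All stochastic stages derive from the
#' config seed, so a rerun with identical inputs reproduces every number.
#'
#' @param measurements a [voc_dataset] or path to a measurement CSV.
#' @param library a [voc_library] or path to a library CSV; ignored (taken
#'   from the dataset) when `measurements` is already a dataset.
#' @param config a [run_config], or path to a YAML config.
#' @param log_path optional path; the timestamped stage log is appended
#'   there as well as being kept in the report.
#' @return a `run_report`: `config`, `config_hash`, `seed`, `batches`
#'   (named list of per-batch stage outputs), `log`.
#' @export
run_pipeline <- function(measurements, library = NULL, config = run_config(),
                         log_path = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.character(measurements)) {
    if (is.character(library)) library <- read_descriptor_library(library)
    if (!inherits(library, "voc_library")) {
      stop("reading a measurement table requires a descriptor library")
    }
    measurements <- read_measurement_table(measurements, library)
  }
  stopifnot(inherits(measurements, "voc_dataset"))
  if (measurements$transform_state != "raw") {
    stop("run_pipeline expects a raw dataset")
  }
  if (max(config$n_grid) > ncol(measurements$areas)) {
    stop("config error: n_grid value ", max(config$n_grid),
         " exceeds library size ", ncol(measurements$areas))
  }
  hash <- config_hash(config)
  log_lines <- character(0)
  log_fn <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
    log_lines <<- c(log_lines, line)
    if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
    invisible(NULL)
  }
  log_fn(sprintf("run: seed %d, config %s", config$seed, hash))
  batches <- unique(measurements$meta$batch)
  runs <- if (length(batches) > 1 && !config$pool_batches) {
    log_fn(sprintf("batches: %s analyzed separately (pool_batches = FALSE)",
                   paste(batches, collapse = ", ")))
    lapply(batches, function(b) {
      log_fn(paste("batch:", b))
      run_one_batch(measurements, which(measurements$meta$batch == b),
                    config, log_fn)
    })
  } else {
    list(run_one_batch(measurements, seq_len(n_measurements(measurements)),
                       config, log_fn))
  }
  names(runs) <- if (length(runs) == length(batches)) batches else "pooled"
  structure(list(config = config, config_hash = hash, seed = config$seed,
                 batches = runs, log = log_lines),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      "; ", length(x$batches), " batch run(s)\n", sep = "")
  for (nm in names(x$batches)) {
    b <- x$batches[[nm]]
    cat(sprintf("  %s: best (C = %g, N = %d), holdout F1w %.3f, retained %s\n",
                nm, b$grid$best_C, b$grid$best_N,
                b$metrics[["f1_weighted"]],
                paste(lengths(b$retained), collapse = "/")))
  }
  invisible(x)
}

#' Retained descriptor sets of a pipeline run
#'
#' @param report a `run_report`.
#' @param batch batch name or index (default: first).
#' @return named list of descriptor-id sets, one per risk delta.
#' @export
retained_sets <- function(report, batch = 1L) {
  stopifnot(inherits(report, "run_report"))
  report$batches[[batch]]$retained
}

#' Compare the retained descriptor sets of two pipeline runs
#'
#' Jaccard index of the retained sets at every risk delta the two runs have
#' in common (deltas present in only one run are dropped with a warning),
#' plus a Jaccard curve over nested top-m sets of the two probe-free
#' reference rankings.
#'
#' @param run1,run2 `run_report` objects with probe results.
#' @param batch1,batch2 batch name or index within each report.
#' @return list with `deltas`, `jaccard` (named per delta), and `curve`
#'   (a [jaccard_curve] data frame).
#' @export
run_two_dataset_comparison <- function(run1, run2, batch1 = 1L, batch2 = 1L) {
  stopifnot(inherits(run1, "run_report"), inherits(run2, "run_report"))
  b1 <- run1$batches[[batch1]]; b2 <- run2$batches[[batch2]]
  if (is.null(b1$probe) || is.null(b2$probe)) {
    stop("both runs must contain probe-relevance retained sets")
  }
  d1 <- b1$probe$deltas; d2 <- b2$probe$deltas
  common <- intersect(d1, d2)
  if (length(common) == 0) stop("no common delta between the two runs")
  if (length(common) < length(d1) || length(common) < length(d2)) {
    warning("delta grids differ; comparison restricted to common deltas: ",
            paste(format(common), collapse = ", "))
  }
  jac <- vapply(common, function(d) {
    jaccard(b1$retained[[which(abs(d1 - d) < 1e-12)]],
            b2$retained[[which(abs(d2 - d) < 1e-12)]])
  }, numeric(1))
  names(jac) <- format(common)
  r1 <- b1$probe$reference$descriptor_id
  r2 <- b2$probe$reference$descriptor_id
  curve <- jaccard_curve(r1, r2, seq_len(min(length(r1), length(r2))))
  list(deltas = common, jaccard = jac, curve = curve)
}
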