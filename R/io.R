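#' Read a measurement table
#'
#' Reads a CSV of vectorized measurements: metadata columns (`subject_id`,
#' `site`, `status`, `batch`, `replicate`) followed by one column per library
#' descriptor. Descriptor columns may appear in any order in the file; they
#' are re-aligned to library order by name. A missing library descriptor or
#' an extra, unknown column is an error, as are negative or non-numeric
#' areas (named by row and column) and unknown metadata tokens.
#'
#' An optional leading comment line `# transform_state: <state>` (written by
#' [write_measurement_table]) restores the transform state; absent, the state
#' is `raw`.
#'
#' @param path CSV file path.
#' @param library a [voc_library] defining the expected descriptor columns.
#' @return a [voc_dataset].
#' @export
read_measurement_table <- function(path, library) {
  stopifnot(inherits(library, "voc_library"))
  first <- readLines(path, n = 1L)
  state <- "raw"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("transform_state:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2 && m[2] %in% .voc_states) state <- m[2]
  }
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  comment.char = "#", check.names = FALSE)
  missing_meta <- setdiff(.voc_meta_cols, names(tab))
  if (length(missing_meta)) {
    stop("measurement table missing metadata column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  desc_cols <- setdiff(names(tab), .voc_meta_cols)
  missing_desc <- setdiff(library$descriptor_id, desc_cols)
  if (length(missing_desc)) {
    stop("measurement table missing descriptor column(s): ",
         paste(missing_desc, collapse = ", "))
  }
  extra <- setdiff(desc_cols, library$descriptor_id)
  if (length(extra)) {
    stop("unknown column(s) not in library: ", paste(extra, collapse = ", "))
  }
  n <- nrow(tab)
  areas <- matrix(0, n, nrow(library),
                  dimnames = list(NULL, library$descriptor_id))
  for (id in library$descriptor_id) {
    raw <- tab[[id]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad)) {
      stop("non-numeric area at row ", bad[1], ", column '", id, "': '",
           raw[bad[1]], "'")
    }
    if (state %in% c("raw", "logged")) {
      neg <- which(val < 0)
      if (length(neg)) {
        stop("negative area at row ", neg[1], ", column '", id, "': ",
             raw[neg[1]])
      }
    }
    areas[, id] <- val
  }
  voc_dataset(areas, tab[, .voc_meta_cols, drop = FALSE], library, state)
}

#' Write a measurement table
#'
#' Writes the dataset as CSV (metadata columns then descriptor columns in
#' library order), preceded by a `# transform_state:` comment so that
#' [read_measurement_table] restores the state. Areas are printed with full
#' double precision so the write/read round trip is exact.
#'
#' @param dataset a [voc_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "voc_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# transform_state: ", dataset$transform_state), con)
  num <- as.data.frame(
    matrix(sprintf("%.17g", dataset$areas), nrow(dataset$areas)),
    stringsAsFactors = FALSE, optional = TRUE
  )
  if (nrow(dataset$areas) == 0) {
    num <- as.data.frame(matrix(character(0), 0, ncol(dataset$areas)))
  }
  names(num) <- colnames(dataset$areas)
  out <- cbind(dataset$meta[, .voc_meta_cols, drop = FALSE], num)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a dataset and report its structure
#'
#' Reporting-only audit used before any analysis stage: per-measurement
#' non-zero descriptor counts, per-status sample counts, replicate counts per
#' (subject, site, status) sampling, subjects present in only one status, and
#' samplings exceeding the configured replicate maximum (the acquisition
#' protocol analyzed at most 4 technical replicates per sampling).
#'
#' @param dataset a [voc_dataset].
#' @param max_replicates maximum technical replicates per sampling (default 4).
#' @return a `voc_validation` list with elements `measurement` (data frame
#'   with non-zero counts), `status_counts`, `replicates` (counts per
#'   sampling with an `over_max` flag), `single_status_subjects`, and
#'   `flags` (character vector of human-readable warnings).
#' @export
validate_dataset <- function(dataset, max_replicates = 4L) {
  stopifnot(inherits(dataset, "voc_dataset"))
  meta <- dataset$meta
  nz <- if (nrow(dataset$areas)) rowSums(dataset$areas > 0) else integer(0)
  measurement <- cbind(meta, nonzero_count = as.integer(nz))
  status_counts <- c(table(factor(meta$status, levels = .voc_statuses)))
  reps <- if (nrow(meta)) {
    agg <- aggregate(list(n_replicates = meta$replicate),
                     by = list(subject_id = meta$subject_id, site = meta$site,
                               status = meta$status),
                     FUN = length)
    agg$over_max <- agg$n_replicates > max_replicates
    agg
  } else {
    data.frame(subject_id = character(0), site = character(0),
               status = character(0), n_replicates = integer(0),
               over_max = logical(0))
  }
  by_subj <- split(meta$status, meta$subject_id)
  single <- names(by_subj)[vapply(by_subj, function(s) length(unique(s)) < 2, logical(1))]
  flags <- character(0)
  if (any(reps$over_max)) {
    over <- reps[reps$over_max, ]
    flags <- c(flags, sprintf(
      "sampling (%s, %s, %s) has %d replicates (max %d)",
      over$subject_id, over$site, over$status, over$n_replicates, max_replicates))
  }
  if (length(single)) {
    flags <- c(flags, sprintf("subject %s present in only one status", single))
  }
  for (st in .voc_statuses) {
    if (nrow(meta) && status_counts[[st]] == 0) {
      flags <- c(flags, sprintf("no measurements with status '%s'", st))
    }
  }
  structure(list(measurement = measurement, status_counts = status_counts,
                 replicates = reps, single_status_subjects = single,
                 flags = flags),
            class = "voc_validation")
}

#' @export
print.voc_validation <- function(x, ...) {
  cat("<voc_validation> ", nrow(x$measurement), " measurements; status: ",
      paste(sprintf("%s=%d", names(x$status_counts), x$status_counts),
            collapse = ", "), "\n", sep = "")
  if (length(x$flags)) cat(paste0("  ! ", x$flags, "\n"), sep = "")
  else cat("  no flags\n")
  invisible(x)
}
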