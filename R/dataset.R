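#' Descriptor library
#'
#' The ordered registry of screened compounds. Every measurement vector has
#' one peak area per library entry, in library order; the order therefore
#' defines the vector index of each descriptor. Display names are informative
#' only (tentative spectral-match identities) and play no role in any
#' computation.
#'
#' @param descriptor_id character vector of unique descriptor identifiers.
#' @param display_name optional character vector of informative compound
#'   names; defaults to the ids.
#' @return A `voc_library` data frame with columns `descriptor_id` and
#'   `display_name`.
#' @export
#' @examples
#' voc_library(c("d1", "d2", "d3"))
voc_library <- function(descriptor_id, display_name = descriptor_id) {
  descriptor_id <- as.character(descriptor_id)
  display_name <- as.character(display_name)
  if (length(descriptor_id) < 1) stop("library must contain at least one descriptor")
  if (anyDuplicated(descriptor_id)) {
    dup <- unique(descriptor_id[duplicated(descriptor_id)])
    stop("duplicate descriptor_id: ", paste(dup, collapse = ", "))
  }
  if (length(display_name) != length(descriptor_id)) {
    stop("display_name must match descriptor_id in length")
  }
  out <- data.frame(descriptor_id = descriptor_id, display_name = display_name,
                    stringsAsFactors = FALSE)
  class(out) <- c("voc_library", "data.frame")
  out
}

#' Read / write a descriptor library table
#'
#' CSV with columns `descriptor_id` and `display_name`.
#'
#' @param path file path.
#' @return `read_descriptor_library` returns a [voc_library];
#'   `write_descriptor_library` returns `path` invisibly.
#' @export
read_descriptor_library <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("descriptor_id", "display_name") %in% names(tab))) {
    stop("library table must have columns descriptor_id, display_name")
  }
  voc_library(tab$descriptor_id, tab$display_name)
}

#' @rdname read_descriptor_library
#' @param library a [voc_library].
#' @export
write_descriptor_library <- function(library, path) {
  stopifnot(inherits(library, "voc_library"))
  write.csv(as.data.frame(library), path, row.names = FALSE)
  invisible(path)
}

#' Measurement dataset
#'
#' Container for a set of vectorized chromatograms: a numeric peak-area matrix
#' (one row per measurement, one column per library descriptor, in library
#' order) plus per-measurement metadata. `transform_state` tracks where the
#' dataset sits in the `raw -> logged -> standardized` chain so that stages
#' run out of order are rejected.
#'
#' @param areas numeric matrix, rows = measurements, columns = descriptors in
#'   library order. Column names, if present, must equal the library ids.
#' @param meta data frame with columns `subject_id`, `site` (`hand`/`breast`),
#'   `status` (`pre`/`post`), `batch` (`column1`/`column2`), `replicate`
#'   (integer >= 1).
#' @param library a [voc_library].
#' @param transform_state one of `"raw"`, `"logged"`, `"standardized"`.
#' @return A `voc_dataset` object.
#' @export
voc_dataset <- function(areas, meta, library, transform_state = "raw") {
  stopifnot(inherits(library, "voc_library"))
  transform_state <- match.arg(transform_state, .voc_states)
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (ncol(areas) != nrow(library)) {
    stop("areas has ", ncol(areas), " columns but library has ",
         nrow(library), " descriptors")
  }
  if (!is.null(colnames(areas)) && !identical(colnames(areas), library$descriptor_id)) {
    stop("areas column names do not match library order")
  }
  colnames(areas) <- library$descriptor_id
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_meta <- setdiff(.voc_meta_cols, names(meta))
  if (length(missing_meta)) {
    stop("meta is missing columns: ", paste(missing_meta, collapse = ", "))
  }
  if (nrow(meta) != nrow(areas)) stop("meta and areas row counts differ")
  meta$subject_id <- as.character(meta$subject_id)
  check_token <- function(x, allowed, what) {
    bad <- setdiff(unique(as.character(x)), allowed)
    if (length(bad)) {
      stop("unknown ", what, " token(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
    }
    as.character(x)
  }
  meta$site <- check_token(meta$site, .voc_sites, "site")
  meta$status <- check_token(meta$status, .voc_statuses, "status")
  meta$batch <- check_token(meta$batch, .voc_batches, "batch")
  rep_num <- suppressWarnings(as.numeric(meta$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num))) {
    stop("replicate must be an integer >= 1")
  }
  meta$replicate <- as.integer(rep_num)
  if (nrow(areas) > 0) {
    if (any(!is.finite(areas))) stop("areas must be finite")
    if (transform_state %in% c("raw", "logged") && any(areas < 0)) {
      stop("negative area in ", transform_state, " dataset")
    }
  }
  rownames(areas) <- NULL
  rownames(meta) <- NULL
  structure(list(areas = areas, meta = meta, library = library,
                 transform_state = transform_state),
            class = "voc_dataset")
}

#' @export
print.voc_dataset <- function(x, ...) {
  cat("<voc_dataset> ", nrow(x$areas), " measurements x ",
      ncol(x$areas), " descriptors [", x$transform_state, "]\n", sep = "")
  if (nrow(x$meta)) {
    cat("  status: ", paste(sprintf("%s=%d", names(table(x$meta$status)),
                                    table(x$meta$status)), collapse = ", "),
        "; batches: ", paste(unique(x$meta$batch), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of measurements in a dataset
#' @param dataset a [voc_dataset].
#' @return integer count.
#' @export
n_measurements <- function(dataset) {
  stopifnot(inherits(dataset, "voc_dataset"))
  nrow(dataset$areas)
}

#' Subset a dataset by measurement rows
#' @param x a [voc_dataset].
#' @param i integer or logical row index.
#' @param ... ignored.
#' @return a [voc_dataset] with the selected measurements.
#' @export
`[.voc_dataset` <- function(x, i, ...) {
  voc_dataset(x$areas[i, , drop = FALSE], x$meta[i, , drop = FALSE],
              x$library, x$transform_state)
}

# Sampling-group key: all technical replicates of one (subject, status)
# sampling share a key and must never straddle a train/validation/test split.
sampling_group <- function(meta) {
  paste(meta$subject_id, meta$status, sep = "::")
}
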