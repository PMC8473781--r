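#' ROI time-series container
#'
#' Bundles one subject's regional BOLD-like time series with its repetition
#' time. Rows are timepoints, columns are regions of interest (ROIs).
#'
#' @param data numeric matrix, T timepoints x R regions.
#' @param subject_id subject identifier.
#' @param tr_seconds repetition time in seconds (default 2).
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, subject_id = "subject", tr_seconds = 2) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("time series must have at least 2 timepoints and 2 regions")
  if (anyNA(data) || any(!is.finite(data)))
    stop("time series contains missing or non-finite values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be a positive number")
  v <- apply(data, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stop(sprintf("zero-variance column(s) (dead ROI): %s",
                 paste(colnames(data)[bad] %||% bad, collapse = ", ")))
  }
  structure(list(subject_id = as.character(subject_id),
                 data = data, tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series '%s': %d timepoints x %d regions (TR = %gs)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$data)

#' Read a subject's ROI time series from delimited text
#'
#' Expects a rectangular numeric table, rows = timepoints, columns = regions,
#' with an optional header row of ROI names. Zero-variance columns (dead ROIs)
#' and non-numeric cells are errors.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param subject_id subject id; defaults to the file name without extension.
#' @param tr_seconds repetition time in seconds.
#' @return a [roi_timeseries()] object.
#' @export
read_timeseries <- function(path, delimiter = "\t", subject_id = NULL,
                            tr_seconds = 2) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- utils::read.delim(path, sep = delimiter, header = has_header,
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) == 0) stop("empty time-series file: ", path)
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(raw))
  if (anyNA(num)) {
    bad <- which(colSums(is.na(num)) > 0)
    stop(sprintf("non-numeric cells in column(s) %s of %s",
                 paste(bad, collapse = ", "), path))
  }
  colnames(num) <- if (has_header) first else NULL
  roi_timeseries(num, subject_id = subject_id %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 tr_seconds = tr_seconds)
}

#' Write a subject's ROI time series to delimited text
#'
#' @param ts a [roi_timeseries()] object.
#' @param path output path.
#' @param delimiter field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, delimiter = "\t") {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$data, path, sep = delimiter, row.names = FALSE,
                     col.names = !is.null(colnames(ts$data)), quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' CSV with headers `subject_id, group, series_path, cipe_total, ielt_minutes,
#' mean_fd`. Group labels must be `patient` or `control`; blank clinical cells
#' are kept as `NA`, never coerced to zero.
#'
#' @param path CSV path.
#' @return a `data.frame` of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  as_cohort_manifest(df)
}

#' Validate a manifest data frame
#'
#' @param df data frame with the manifest columns.
#' @return the validated manifest.
#' @export
as_cohort_manifest <- function(df) {
  required <- c("subject_id", "group", "series_path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest lacks required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("no subjects in manifest")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), c("patient", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  for (col in c("cipe_total", "ielt_minutes", "mean_fd")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest CSV
#'
#' @param manifest a manifest data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects windowing, clustering and classification parameters plus the single
#' seed that governs every stochastic stage (fanned out via [stage_seed()]).
#'
#' @param window see [window_params()].
#' @param cluster see [cluster_params()].
#' @param classify see [classify_params()].
#' @param seed integer master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(window = window_params(), cluster = cluster_params(),
                            classify = classify_params(), seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(window = window, cluster = cluster, classify = classify,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return for `read_config`, a [pipeline_config()]; for `write_config`,
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  pipeline_config(
    window = do.call(window_params, lst$window %||% list()),
    cluster = do.call(cluster_params, lst$cluster %||% list()),
    classify = do.call(classify_params, lst$classify %||% list()),
    seed = lst$seed %||% 1L)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  lst <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}
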