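#' Construct a measurement set
#'
#' A measurement set is the unit of every analysis in this package: an
#' \eqn{N \times d} numeric feature matrix in which each row is one
#' measurement of some item (a subject, sample, or specimen), together with
#' the item label of every row and, optionally, a session index and a class
#' label. Writing \eqn{s_i} for the number of measurements of item \eqn{i},
#' \eqn{N = \sum_i s_i}. Items observed only once carry no within-item pair
#' and are excluded (with a warning) from replicability statistics that need
#' replicates; they are retained in the object and flagged.
#'
#' @param features numeric matrix (or vector, treated as one column) with one
#'   row per measurement; no missing or non-finite values are allowed.
#' @param ids item label per row; coerced to character.
#' @param sessions optional positive integer session index per row.
#' @param classes optional class label per row (e.g. the covariate whose
#'   predictability is of downstream interest).
#' @return An object of class `"measurement_set"`: a list with elements
#'   `features`, `ids`, `sessions`, `classes`, and `singletons` (labels of
#'   items with a single measurement).
#' @examples
#' ms <- measurement_set(matrix(rnorm(8), 4, 2), ids = c("a", "a", "b", "b"))
#' ms
#' @export
measurement_set <- function(features, ids, sessions = NULL, classes = NULL) {
  if (is.vector(features) && is.numeric(features)) {
    features <- matrix(features, ncol = 1L)
  }
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!all(is.finite(features))) {
    stop("'features' must be numeric with no missing or non-finite values")
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(features)) {
    stop("length(ids) must equal nrow(features)")
  }
  if (!is.null(sessions)) {
    sessions <- as.integer(sessions)
    if (length(sessions) != nrow(features) || anyNA(sessions) || any(sessions < 1L)) {
      stop("'sessions' must be positive integers, one per measurement")
    }
  }
  if (!is.null(classes)) {
    classes <- as.character(classes)
    if (length(classes) != nrow(features)) {
      stop("'classes' must have one entry per measurement")
    }
  }
  si <- table(ids)
  singletons <- names(si)[si < 2L]
  structure(
    list(features = features, ids = ids, sessions = sessions,
         classes = classes, singletons = singletons),
    class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  si <- table(x$ids)
  cat(sprintf("Measurement set: %d measurements of %d items in %d dimension(s)\n",
              nrow(x$features), length(si), ncol(x$features)))
  cat(sprintf("  measurements per item: %s\n",
              paste(range(si), collapse = "-")))
  if (length(x$singletons)) {
    cat(sprintf("  %d item(s) with a single measurement (excluded from replicability statistics)\n",
                length(x$singletons)))
  }
  if (!is.null(x$sessions)) cat(sprintf("  sessions: %s\n", paste(sort(unique(x$sessions)), collapse = ", ")))
  if (!is.null(x$classes)) cat(sprintf("  classes: %s\n", paste(sort(unique(x$classes)), collapse = ", ")))
  invisible(x)
}

#' Read a measurement table from disk
#'
#' Long-form tables have one row per measurement with a mandatory `item`
#' column, optional `session` and `class` columns, and all remaining columns
#' numeric features. `long_tsv` is tab-separated, `wide_csv` comma-separated
#' (the layouts are identical apart from the delimiter).
#'
#' @param path file path.
#' @param format `"long_tsv"` or `"wide_csv"`; defaults from the file
#'   extension (`.csv` implies `wide_csv`).
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "wide_csv" else "long_tsv"
  }
  format <- match.arg(format, c("long_tsv", "wide_csv"))
  sep <- if (format == "wide_csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"item" %in% names(df)) {
    stop("measurement table must contain an 'item' column: ", path)
  }
  sessions <- if ("session" %in% names(df)) df$session else NULL
  classes <- if ("class" %in% names(df)) df$class else NULL
  feat_cols <- setdiff(names(df), c("item", "session", "class"))
  if (!length(feat_cols)) stop("measurement table has no feature columns")
  feats <- df[feat_cols]
  bad <- !vapply(feats, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric feature column(s): ", paste(feat_cols[bad], collapse = ", "))
  }
  measurement_set(as.matrix(feats), ids = df$item,
                  sessions = sessions, classes = classes)
}

#' Write a measurement set to disk
#'
#' Inverse of [read_measurements()]; `read(write(ms))` restores values,
#' labels, sessions and classes.
#'
#' @param ms a [measurement_set()].
#' @param path file path.
#' @param format `"long_tsv"` or `"wide_csv"`.
#' @export
write_measurements <- function(ms, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "wide_csv" else "long_tsv"
  }
  format <- match.arg(format, c("long_tsv", "wide_csv"))
  feats <- ms$features
  if (is.null(colnames(feats))) colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  df <- data.frame(item = ms$ids, stringsAsFactors = FALSE)
  if (!is.null(ms$sessions)) df$session <- ms$sessions
  if (!is.null(ms$classes)) df$class <- ms$classes
  df <- cbind(df, as.data.frame(feats))
  utils::write.table(df, path, sep = if (format == "wide_csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes any of the package's result objects (discr fits, test results,
#' ranking tables, ...) to JSON (canonical) or TSV (tabular results only).
#'
#' @param result a result object or a data frame.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(result)) {
      result <- as.data.frame(unclass(result)[!vapply(unclass(result), is.null, logical(1))])
    }
    utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- if (is.data.frame(result)) result else unclass(result)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  invisible(path)
}
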