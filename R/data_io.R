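# Readers and writers: KEEL `.dat` files, generic delimited files, dataset
# summaries, and JSON experiment reports.

#' Construct a labeled dataset
#'
#' The universal input record of the package: a numeric feature matrix plus a
#' binary label vector using the imbalanced-learning convention that
#' `"positive"` denotes the minority (non-target) class and `"negative"` the
#' majority (target) class.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Character vector of `"positive"` / `"negative"`, one per row.
#' @param feature_names Optional character vector of column names.
#' @param name Dataset name used in reports.
#'
#' @return An object of class `labeled_dataset` with fields `features`,
#'   `labels`, `feature_names` and `name`.
#' @export
labeled_dataset <- function(features, labels,
                            feature_names = colnames(features),
                            name = "dataset") {
  features <- as_matrix(features, "features")
  labels <- tolower(trimws(as.character(labels)))
  if (nrow(features) < 1L || ncol(features) < 1L) {
    stop("dataset must have at least one sample and one feature", call. = FALSE)
  }
  if (length(labels) != nrow(features)) {
    stop("length(labels) must equal nrow(features)", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad)) {
    stop(sprintf("unknown label value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, name = name),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset '%s'> %d samples x %d features (%d positive, %d negative)\n",
              x$name, nrow(x$features), ncol(x$features),
              sum(x$labels == "positive"), sum(x$labels == "negative")))
  invisible(x)
}

parse_keel_attribute <- function(line, lineno) {
  body <- trimws(sub("^@attribute", "", line, ignore.case = TRUE))
  if (grepl("\\{", body)) {
    name <- trimws(sub("\\{.*$", "", body))
    vals <- sub("^.*\\{", "", body)
    vals <- sub("\\}.*$", "", vals)
    values <- trimws(strsplit(vals, ",")[[1]])
    list(name = name, type = "nominal", values = values)
  } else {
    parts <- strsplit(body, "[[:space:]]+")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("line %d: cannot parse @attribute declaration", lineno),
           call. = FALSE)
    }
    type <- tolower(sub("\\[.*$", "", parts[2]))
    if (!type %in% c("real", "integer", "numeric")) {
      stop(sprintf("line %d: unsupported attribute type '%s'", lineno, parts[2]),
           call. = FALSE)
    }
    # range bounds like `real [0.0, 9.0]` are parsed but deliberately not
    # enforced: published KEEL files occasionally violate their own ranges
    list(name = parts[1], type = "numeric", values = NULL)
  }
}

#' Read a KEEL `.dat` imbalanced-classification file
#'
#' Parses the KEEL dialect: `@relation`, `@attribute name real [a, b]`,
#' `@attribute name {v1, v2}`, optional `@inputs` / `@outputs`, and an
#' `@data` section of comma-separated rows.  The output attribute (named by
#' `@outputs`, otherwise the last declared attribute) becomes the label and
#' must take the values `positive` / `negative` (matched case-insensitively,
#' whitespace stripped).  All remaining attributes must be numeric; nominal
#' non-label attributes are rejected because the distance-based classifiers
#' downstream require numeric features.
#'
#' @param path Path to a `.dat` file.
#' @return A [labeled_dataset()].
#' @export
read_keel_dat <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  data_at <- which(grepl("^[[:space:]]*@data", lines, ignore.case = TRUE))
  if (!length(data_at)) {
    stop(sprintf("%s: no @data marker found", path), call. = FALSE)
  }
  data_at <- data_at[1]
  header <- lines[seq_len(data_at - 1L)]

  relation <- "keel"
  attrs <- list()
  outputs <- NULL
  for (i in seq_along(header)) {
    ln <- trimws(header[i])
    if (ln == "" || grepl("^%", ln)) next
    if (grepl("^@relation", ln, ignore.case = TRUE)) {
      relation <- trimws(sub("^@relation", "", ln, ignore.case = TRUE))
    } else if (grepl("^@attribute", ln, ignore.case = TRUE)) {
      attrs[[length(attrs) + 1L]] <- parse_keel_attribute(ln, i)
    } else if (grepl("^@outputs", ln, ignore.case = TRUE)) {
      outputs <- trimws(strsplit(sub("^@outputs", "", ln, ignore.case = TRUE), ",")[[1]])
    }
    # @inputs is accepted and ignored: attribute order defines the columns
  }
  if (!length(attrs)) stop(sprintf("%s: no @attribute declarations", path), call. = FALSE)

  attr_names <- vapply(attrs, `[[`, "", "name")
  label_name <- if (!is.null(outputs)) outputs[1] else attr_names[length(attr_names)]
  label_pos <- match(label_name, attr_names)
  if (is.na(label_pos)) {
    stop(sprintf("%s: @outputs attribute '%s' not declared", path, label_name),
         call. = FALSE)
  }
  feat_pos <- setdiff(seq_along(attrs), label_pos)
  nominal_feats <- feat_pos[vapply(attrs[feat_pos], `[[`, "", "type") == "nominal"]
  if (length(nominal_feats)) {
    stop(sprintf("%s: nominal non-label attribute(s) not supported: %s",
                 path, paste(attr_names[nominal_feats], collapse = ", ")),
         call. = FALSE)
  }

  body_idx <- seq(data_at + 1L, length.out = max(0L, length(lines) - data_at))
  body_idx <- body_idx[trimws(lines[body_idx]) != ""]
  n <- length(body_idx)
  if (!n) stop(sprintf("%s: no data rows after @data", path), call. = FALSE)

  X <- matrix(NA_real_, nrow = n, ncol = length(feat_pos))
  labels <- character(n)
  for (r in seq_len(n)) {
    lineno <- body_idx[r]
    cells <- trimws(strsplit(lines[lineno], ",")[[1]])
    if (length(cells) != length(attrs)) {
      stop(sprintf("%s: line %d has %d fields, expected %d",
                   path, lineno, length(cells), length(attrs)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells[feat_pos]))
    if (anyNA(vals)) {
      stop(sprintf("%s: line %d has non-numeric feature value(s)", path, lineno),
           call. = FALSE)
    }
    X[r, ] <- vals
    lab <- tolower(cells[label_pos])
    if (!lab %in% c("positive", "negative")) {
      stop(sprintf("%s: line %d has unknown label '%s'", path, lineno, cells[label_pos]),
           call. = FALSE)
    }
    labels[r] <- lab
  }
  labeled_dataset(X, labels, feature_names = attr_names[feat_pos], name = relation)
}

#' Read a delimited text file with a header row
#'
#' @param path File path.
#' @param label_column Name of the column holding the class label.
#' @param positive_label Value in `label_column` mapped to `"positive"`; every
#'   other value becomes `"negative"`.
#' @param sep Field separator (default comma).
#' @return A [labeled_dataset()].
#' @export
read_delimited <- function(path, label_column, positive_label, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not present in %s", label_column, path),
         call. = FALSE)
  }
  raw <- trimws(as.character(df[[label_column]]))
  labels <- ifelse(raw == positive_label, "positive", "negative")
  if (!any(labels == "positive")) {
    warning(sprintf("positive label '%s' not found in column '%s'; dataset has 0 positives",
                    positive_label, label_column))
  }
  feat <- df[setdiff(names(df), label_column)]
  for (nm in names(feat)) {
    v <- suppressWarnings(as.numeric(as.character(feat[[nm]])))
    if (anyNA(v)) {
      stop(sprintf("%s: column '%s' has non-numeric value(s)", path, nm),
           call. = FALSE)
    }
    feat[[nm]] <- v
  }
  labeled_dataset(as.matrix(feat), labels, feature_names = names(feat),
                  name = basename(path))
}

#' Summarize class balance of a dataset
#'
#' Counts both classes and reports the imbalance ratio, majority count
#' divided by minority count, as an unrounded real (presentation layers may
#' round; the stored value is exact).
#'
#' @param dataset A [labeled_dataset()].
#' @return An object of class `dataset_summary` with fields `n_features`,
#'   `n_samples`, `n_minority`, `n_majority`, `imbalance_ratio`.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n_min <- sum(dataset$labels == "positive")
  n_maj <- sum(dataset$labels == "negative")
  if (n_min == 0L || n_maj == 0L) {
    stop("both classes must be represented: imbalance ratio undefined", call. = FALSE)
  }
  structure(
    list(n_features = ncol(dataset$features),
         n_samples = nrow(dataset$features),
         n_minority = n_min, n_majority = n_maj,
         imbalance_ratio = n_maj / n_min),
    class = "dataset_summary"
  )
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("%d samples, %d features | minority %d, majority %d | imbalance ratio %.2f\n",
              x$n_samples, x$n_features, x$n_minority, x$n_majority,
              x$imbalance_ratio))
  invisible(x)
}

#' Write an experiment report collection to JSON
#'
#' Serializes a list of report records (typically the `aggregate` components
#' of [run_ocnn_experiment()] results) as JSON.  Undefined metrics (`NA`,
#' `NaN`) are written as JSON `null`, never as the string `"NaN"`, so the
#' files remain parseable by any JSON reader.  Metric values are written at
#' full precision; rounding is a presentation concern.
#'
#' @param reports A (possibly empty) list of named lists / records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(reports, path) {
  reports <- lapply(reports, sanitize_record)
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

sanitize_record <- function(x) {
  if (is.list(x)) return(lapply(x, sanitize_record))
  if (is.numeric(x)) x[!is.finite(x) & !is.na(x)] <- NA_real_
  if (is.numeric(x)) x[is.nan(x)] <- NA_real_
  x
}

#' Read a report collection written by [write_report()]
#'
#' @param path Path to a JSON report file.
#' @return The list structure that was written (JSON `null` maps back to `NA`).
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  null_to_na(out)
}

null_to_na <- function(x) {
  if (is.list(x)) {
    x[vapply(x, is.null, TRUE)] <- NA
    lapply(x, null_to_na)
  } else x
}

#' Write a labeled dataset as a KEEL `.dat` file
#'
#' The inverse of [read_keel_dat()] on the dialect this package supports;
#' used by the synthetic generator so the reader is exercised end to end.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keel_dat <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- dataset$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@relation %s", dataset$name), con)
  for (j in seq_len(ncol(X))) {
    writeLines(sprintf("@attribute %s real [%.6g, %.6g]",
                       dataset$feature_names[j], min(X[, j]), max(X[, j])), con)
  }
  writeLines("@attribute class {positive, negative}", con)
  writeLines(sprintf("@inputs %s", paste(dataset$feature_names, collapse = ", ")), con)
  writeLines("@outputs class", con)
  writeLines("@data", con)
  rows <- apply(X, 1, function(r) paste(format(r, trim = TRUE, digits = 17),
                                        collapse = ", "))
  writeLines(paste(rows, dataset$labels, sep = ", "), con)
  invisible(path)
}
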