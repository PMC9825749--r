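#' mbtraj: microbiome maturation trajectories for longitudinal data
#'
#' Tools to derive a reference microbiome trajectory (Microbiome Maturation
#' Index, MMI, versus time) from longitudinal feature-abundance tables,
#' compare trajectories between groups, detect and explain longitudinal
#' anomalies, and simulate interventions that return anomalous samples to
#' the reference trajectory.
#'
#' @section Data model:
#' A feature table is a tibble whose first column is `sample_id` and whose
#' remaining columns are numeric feature abundances (counts, relative
#' abundances, or log-ratios; see [value_kind()]). Sample metadata is a
#' tibble with `sample_id`, `subject_id`, `time`, `group` and optionally
#' `is_reference`. [mb_dataset()] pairs the two.
#'
#' @keywords internal
"_PACKAGE"

#' Feature-table value kind
#'
#' Feature tables carry a `value_kind` attribute declaring the measurement
#' scale: `"counts"` (non-negative, typically integer), `"relative"`
#' (rows sum to 1) or `"logratio"` (signed, scale-free). When the attribute
#' is absent it is inferred: counts if all values are whole numbers,
#' relative if every row sums to 1 within 1e-6, otherwise counts.
#'
#' @param features a feature table (tibble with `sample_id` + numeric columns).
#' @param value string, one of `"counts"`, `"relative"`, `"logratio"`.
#' @return `value_kind()` returns the (possibly inferred) kind;
#'   `set_value_kind()` returns the table with the attribute set.
#' @export
value_kind <- function(features) {
  vk <- attr(features, "value_kind", exact = TRUE)
  if (!is.null(vk)) return(vk)
  m <- feature_matrix(features)
  if (all(abs(m - round(m)) < 1e-9)) return("counts")
  if (all(abs(rowSums(m) - 1) < 1e-6)) return("relative")
  "counts"
}

#' @rdname value_kind
#' @export
set_value_kind <- function(features, value) {
  value <- match.arg(value, c("counts", "relative", "logratio"))
  attr(features, "value_kind") <- value
  features
}

#' Construct and validate a feature table
#'
#' @param x a data frame with a `sample_id` column (or row names) and
#'   numeric feature columns, or a numeric matrix with sample row names.
#' @param value_kind optional explicit kind; inferred when `NULL`.
#' @return a validated tibble with `sample_id` first and the `value_kind`
#'   attribute set.
#' @export
feature_table <- function(x, value_kind = NULL) {
  if (is.matrix(x)) {
    ids <- rownames(x) %||% paste0("S", seq_len(nrow(x)))
    x <- tibble::as_tibble(x, .name_repair = "minimal")
    x <- dplyr::bind_cols(tibble::tibble(sample_id = ids), x)
  }
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    stopf("feature table must have a 'sample_id' column")
  }
  x$sample_id <- as.character(x$sample_id)
  x <- dplyr::relocate(x, "sample_id")
  validate_features(x)
  kind <- value_kind %||% value_kind(x)
  if (kind %in% c("counts", "relative")) {
    m <- feature_matrix(x)
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      stopf("negative abundance at sample '%s', feature '%s'",
            rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]])
    }
  }
  if (kind == "relative") {
    m <- feature_matrix(x)
    bad <- which(abs(rowSums(m) - 1) > 1e-9)
    if (length(bad) > 0) {
      stopf("relative-abundance rows must sum to 1: sample '%s' sums to %.6g",
            x$sample_id[bad[1]], rowSums(m)[bad[1]])
    }
  }
  set_value_kind(x, kind)
}

validate_features <- function(x) {
  if (nrow(x) == 0 || ncol(x) < 2) stopf("feature table is empty")
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0) {
    stopf("duplicate sample ids: %s", paste(unique(dup), collapse = ", "))
  }
  feats <- setdiff(names(x), "sample_id")
  dupf <- feats[duplicated(feats)]
  if (length(dupf) > 0) {
    stopf("duplicate feature ids: %s", paste(unique(dupf), collapse = ", "))
  }
  not_num <- feats[!vapply(x[feats], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stopf("non-numeric feature columns: %s", paste(not_num, collapse = ", "))
  }
  m <- as.matrix(x[feats])
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stopf("non-finite value at sample '%s', feature '%s'",
          x$sample_id[bad[1]], feats[bad[2]])
  }
  invisible(x)
}

#' Extract the numeric abundance matrix from a feature table
#'
#' @param features a feature table.
#' @return numeric matrix, samples x features, with sample ids as row names.
#' @export
feature_matrix <- function(features) {
  feats <- setdiff(names(features), "sample_id")
  m <- as.matrix(features[feats])
  rownames(m) <- features$sample_id
  m
}

#' @rdname feature_matrix
#' @export
feature_ids <- function(features) {
  setdiff(names(features), "sample_id")
}

#' Read a feature-abundance table
#'
#' Reads CSV/TSV (header row required, first column holding ids, '.' decimal
#' separator) or BIOM (HDF5 or JSON, via the biomformat package). The result
#' is always oriented samples-as-rows.
#'
#' @param path file path.
#' @param fmt `"csv"`, `"tsv"` or `"biom"`; default guessed from the
#'   file extension.
#' @param orientation how the file on disk is oriented. BIOM files carry
#'   their own orientation (observations = features) and ignore this.
#' @param value_kind optional override of the inferred kind.
#' @return a feature table (see [feature_table()]).
#' @export
read_feature_table <- function(path,
                               fmt = c("csv", "tsv", "biom"),
                               orientation = c("samples_as_rows",
                                               "features_as_rows"),
                               value_kind = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (missing(fmt)) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("tsv", "txt")) "tsv" else if (ext == "biom") "biom" else "csv"
  }
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (fmt == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("reading BIOM requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # features x samples
    df <- tibble::as_tibble(t(m), rownames = "sample_id")
    return(feature_table(df, value_kind = value_kind))
  }
  delim <- if (fmt == "tsv") "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2) stopf("feature table is empty")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) stopf("non-numeric cells in %s", path)
  if (orientation == "features_as_rows") {
    m <- t(m)
    df <- tibble::as_tibble(m, .name_repair = "minimal")
    names(df) <- ids
    df <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(raw)[-1]), df)
  } else {
    df <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                           tibble::as_tibble(m, .name_repair = "minimal"))
  }
  feature_table(df, value_kind = value_kind)
}

#' Write a feature table to CSV
#'
#' CSV is the canonical on-disk format: samples as rows, `sample_id` first.
#'
#' @param features a feature table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(tibble::as_tibble(features), path, progress = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Requires columns `sample_id`, `subject_id` and `time`; `group` defaults
#' to a single label `"all"` and `is_reference` to unset (resolved later by
#' [define_reference()]).
#'
#' @param path CSV/TSV file path.
#' @return tibble with columns sample_id, subject_id, time, group and,
#'   when present in the file, is_reference.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  md <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param md a data frame to validate/normalize in place of a file.
#' @export
sample_metadata <- function(md) {
  md <- tibble::as_tibble(md)
  need <- c("sample_id", "subject_id", "time")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0) {
    stopf("metadata lacks required column(s): %s", paste(miss, collapse = ", "))
  }
  md$sample_id <- as.character(md$sample_id)
  md$subject_id <- as.character(md$subject_id)
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup) > 0) {
    stopf("duplicated sample_id in metadata: %s",
          paste(unique(dup), collapse = ", "))
  }
  t_num <- suppressWarnings(as.numeric(md$time))
  bad <- which(!is.finite(t_num) | t_num < 0)
  if (length(bad) > 0) {
    stopf("non-numeric or negative time at metadata row %d (sample '%s')",
          bad[1], md$sample_id[bad[1]])
  }
  md$time <- t_num
  if (!"group" %in% names(md)) md$group <- "all"
  md$group <- as.character(md$group)
  if ("is_reference" %in% names(md)) md$is_reference <- as.logical(md$is_reference)
  dplyr::relocate(md, "sample_id", "subject_id", "time", "group")
}

#' Assemble a longitudinal microbiome dataset
#'
#' Pairs a feature table with sample metadata. Samples present in only one
#' of the two inputs are dropped with a warning giving the count (orphan
#' records are common in longitudinal studies); zero overlap is an error.
#'
#' @param features a feature table.
#' @param metadata a metadata tibble (see [sample_metadata()]).
#' @param time_unit string naming the time unit (e.g. "days").
#' @return an object of class `mb_dataset`: a list with `features`,
#'   `metadata` (row order matched to features) and `time_unit`.
#' @export
mb_dataset <- function(features, metadata, time_unit = "days") {
  features <- feature_table(features)
  metadata <- sample_metadata(metadata)
  common <- intersect(features$sample_id, metadata$sample_id)
  if (length(common) == 0) stopf("no overlapping samples between table and metadata")
  dropped <- length(unique(c(features$sample_id, metadata$sample_id))) - length(common)
  if (dropped > 0) {
    warnf("%d sample%s dropped (present in only one of table/metadata)",
          dropped, if (dropped == 1) "" else "s")
  }
  kind <- value_kind(features)
  features <- features[match(common, features$sample_id), , drop = FALSE]
  features <- set_value_kind(features, kind)
  metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  if (length(unique(metadata$time)) < 2) {
    stopf("dataset needs at least 2 distinct time points")
  }
  if (length(unique(metadata$subject_id)) < 2) {
    stopf("dataset needs at least 2 subjects")
  }
  structure(list(features = features, metadata = metadata,
                 time_unit = time_unit),
            class = "mb_dataset")
}

#' @export
print.mb_dataset <- function(x, ...) {
  cat(sprintf(
    "<mb_dataset> %d samples x %d features (%s); %d subjects, time %g-%g %s, groups: %s\n",
    nrow(x$features), length(feature_ids(x$features)),
    value_kind(x$features),
    length(unique(x$metadata$subject_id)),
    min(x$metadata$time), max(x$metadata$time), x$time_unit,
    paste(unique(x$metadata$group), collapse = ", ")))
  invisible(x)
}

# Subset a dataset to the given sample ids (order preserved as given).
dataset_subset <- function(ds, sample_ids) {
  keep <- match(sample_ids, ds$features$sample_id)
  if (anyNA(keep)) stopf("unknown sample id(s): %s",
                         paste(sample_ids[is.na(keep)], collapse = ", "))
  kind <- value_kind(ds$features)
  out <- ds
  out$features <- set_value_kind(ds$features[keep, , drop = FALSE], kind)
  out$metadata <- ds$metadata[keep, , drop = FALSE]
  out
}

# Reference subset helper: samples flagged is_reference, or all when absent.
reference_subset <- function(ds) {
  md <- ds$metadata
  if ("is_reference" %in% names(md) && !all(is.na(md$is_reference))) {
    ids <- md$sample_id[which(md$is_reference)]
    if (length(ids) == 0) stopf("no reference samples flagged in metadata")
    dataset_subset(ds, ids)
  } else {
    ds
  }
}

#' Write / read a dataset as a CSV pair
#'
#' @param ds an `mb_dataset`.
#' @param dir directory receiving `features.csv` and `metadata.csv`.
#' @return `write_dataset()`: the directory, invisibly. `read_dataset()`:
#'   an `mb_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(ds$features, file.path(dir, "features.csv"))
  readr::write_csv(ds$metadata, file.path(dir, "metadata.csv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param time_unit time unit label for the re-read dataset.
#' @export
read_dataset <- function(dir, time_unit = "days") {
  mb_dataset(read_feature_table(file.path(dir, "features.csv")),
             read_sample_metadata(file.path(dir, "metadata.csv")),
             time_unit = time_unit)
}
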