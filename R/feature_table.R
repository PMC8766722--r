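#' ROI feature table for one imaging modality
#'
#' The universal data container of the pipeline: one row per subject, one
#' column per named ROI feature, plus a binary diagnosis label per subject
#' (0 = cognitively normal, CN; 1 = Alzheimer's disease, AD).
#'
#' @param x Numeric matrix of feature values, subjects in rows. Row names are
#'   subject identifiers, column names are feature names; both must be unique.
#' @param label Integer vector of 0/1 diagnosis labels, one per row of `x`.
#'   The character labels `"CN"`/`"AD"` are accepted and mapped to 0/1.
#' @param modality Character scalar naming the modality (e.g. `"smri"`).
#'
#' @return An object of class `feature_table`: a list with elements `x`,
#'   `label` and `modality`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), c("a", "b")))
#' ft <- feature_table(x, rep(0:1, each = 5), "smri")
#' ft
feature_table <- function(x, label, modality = "unnamed") {
  if (!is.matrix(x) || !is.numeric(x)) {
    nf_stop("'x' must be a numeric matrix", class = "neurofuse_input_error")
  }
  if (is.character(label) || is.factor(label)) {
    lab <- as.character(label)
    bad <- setdiff(unique(lab), c("CN", "AD", "0", "1"))
    if (length(bad)) {
      nf_stop("unrecognized label value(s): ", paste(bad, collapse = ", "),
              class = "neurofuse_input_error")
    }
    label <- ifelse(lab %in% c("AD", "1"), 1L, 0L)
  }
  label <- as.integer(label)
  if (length(label) != nrow(x)) {
    nf_stop("label length (", length(label), ") != number of subjects (",
            nrow(x), ")", class = "neurofuse_input_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    nf_stop("feature matrix contains missing or non-finite values",
            class = "neurofuse_input_error")
  }
  if (anyNA(label) || !all(label %in% c(0L, 1L))) {
    nf_stop("labels must be binary 0/1 (CN/AD)", class = "neurofuse_input_error")
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    dup <- if (!is.null(colnames(x))) colnames(x)[duplicated(colnames(x))][1] else NULL
    nf_stop("feature names must be present and unique",
            if (!is.null(dup)) paste0(" (duplicate: ", dup, ")") else "",
            class = "neurofuse_input_error")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("sub", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) {
    nf_stop("duplicate subject id: ", rownames(x)[duplicated(rownames(x))][1],
            class = "neurofuse_input_error")
  }
  structure(
    list(x = x, label = label, modality = as.character(modality)[1]),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> modality '%s': %d subjects (%d CN / %d AD), %d features\n",
    x$modality, nrow(x$x), sum(x$label == 0), sum(x$label == 1), ncol(x$x)
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Subset a feature table by subjects and/or features
#'
#' @param table A [feature_table()].
#' @param subjects Subject identifiers (or indices) to keep; `NULL` keeps all.
#' @param features Feature names to keep; `NULL` keeps all.
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
subset_table <- function(table, subjects = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  idx <- if (is.null(subjects)) seq_len(nrow(table$x)) else {
    if (is.character(subjects)) {
      miss <- setdiff(subjects, rownames(table$x))
      if (length(miss)) {
        nf_stop("unknown subject id(s): ", paste(miss, collapse = ", "),
                class = "neurofuse_input_error")
      }
      match(subjects, rownames(table$x))
    } else subjects
  }
  feat <- if (is.null(features)) colnames(table$x) else {
    miss <- setdiff(features, colnames(table$x))
    if (length(miss)) {
      nf_stop("missing feature(s): ", paste(miss, collapse = ", "),
              class = "neurofuse_input_error")
    }
    features
  }
  feature_table(table$x[idx, feat, drop = FALSE], table$label[idx], table$modality)
}

#' Read a feature table from CSV
#'
#' Expects a header row; first column subject id, second column the diagnosis
#' label (`CN`/`AD` or `0`/`1`), remaining columns numeric features.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param modality Modality name to attach; defaults to the file base name.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, modality = NULL) {
  if (!file.exists(path)) {
    nf_stop("file not found: ", path, class = "neurofuse_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) {
    nf_stop("need at least subject id, label and one feature column",
            class = "neurofuse_io_error")
  }
  featnames <- colnames(df)[-(1:2)]
  if (anyDuplicated(featnames)) {
    nf_stop("duplicate feature header: ", featnames[duplicated(featnames)][1],
            class = "neurofuse_io_error")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    nf_stop("duplicate subject id: ", ids[duplicated(ids)][1],
            class = "neurofuse_io_error")
  }
  labraw <- df[[2]]
  if (is.character(labraw)) {
    message("mapping labels: CN -> 0, AD -> 1")
  }
  vals <- df[, -(1:2), drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      nf_stop("non-numeric cell(s) in feature column '", featnames[j], "'",
              class = "neurofuse_io_error")
    }
  }
  x <- as.matrix(vals)
  dimnames(x) <- list(ids, featnames)
  if (is.null(modality)) modality <- sub("\\.csv$", "", basename(path))
  feature_table(x, labraw, modality)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: columns `subject_id`, `label` (0/1),
#' then the features.
#'
#' @param table A [feature_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(
    subject_id = rownames(table$x),
    label = table$label,
    table$x,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
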