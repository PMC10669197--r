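#' Per-subject record of segment features
#'
#' @param subject_id Unique subject identifier.
#' @param age Age in years (> 0).
#' @param segments Named list of 13-value feature vectors (as from
#'   [segment_features()]), keyed by segment label.
#' @param qc Optional named list of [path_qc()] results per segment.
#' @param quality_ok Logical; `FALSE` marks a failed segmentation-quality
#'   check (exclusion criterion 1).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, age, segments, qc = NULL,
                           quality_ok = TRUE) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    vm_stop("subject_id must be a single string")
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age <= 0)
    vm_stop("age must be a positive number")
  if (anyDuplicated(names(segments)))
    vm_stop("segment labels must be unique")
  structure(list(subject_id = subject_id, age = age, segments = segments,
                 qc = qc, quality_ok = isTRUE(quality_ok)),
            class = "subject_record")
}

#' Apply cohort exclusion criteria
#'
#' Mirrors the study's exclusion logic with numeric surrogates:
#' criterion 1 — the record's segmentation quality flag is `FALSE`;
#' criterion 2 — a required segment is absent or has missing/non-finite
#' features; criterion 3 — the path QC of a required segment is
#' `"suspect"`. Retained records have complete 39-feature vectors.
#'
#' @param records List of [subject_record()] objects.
#' @param required Segment labels every retained subject must provide.
#' @return List with `retained` (records) and `log` (data frame with
#'   `subject_id`, `criterion`, `detail`); the two partition the input.
#' @export
apply_exclusions <- function(records, required = vm_segment_labels()) {
  logs <- list()
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    reason <- NULL
    if (!isTRUE(r$quality_ok)) {
      reason <- list(criterion = 1L, detail = "segmentation quality check failed")
    } else {
      missing_seg <- setdiff(required, names(r$segments))
      bad <- required[vapply(required, function(lb) {
        f <- r$segments[[lb]]
        is.null(f) || length(f) != 13L || !all(is.finite(f))
      }, logical(1))]
      if (length(missing_seg) || length(bad)) {
        reason <- list(criterion = 2L,
                       detail = paste0("missing/incomplete segment(s): ",
                                       paste(union(missing_seg, bad),
                                             collapse = ", ")))
      } else if (!is.null(r$qc)) {
        sus <- required[vapply(required, function(lb) {
          q <- r$qc[[lb]]
          !is.null(q) && identical(q$flag, "suspect")
        }, logical(1))]
        if (length(sus))
          reason <- list(criterion = 3L,
                         detail = paste0("suspect path in: ",
                                         paste(sus, collapse = ", ")))
      }
    }
    if (is.null(reason)) {
      keep[i] <- TRUE
    } else {
      logs[[length(logs) + 1L]] <- data.frame(subject_id = r$subject_id,
                                              criterion = reason$criterion,
                                              detail = reason$detail)
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(subject_id = character(), criterion = integer(),
               detail = character())
  list(retained = records[keep], log = log)
}

#' Assemble the modeling feature table
#'
#' One row per subject, ordered by subject id; columns `subject_id`, `age`,
#' then the 39 features in the documented order (R-ICA block, L-ICA block,
#' BA block; 13 features each in [vm_feature_suffixes()] order).
#'
#' @param records List of complete [subject_record()]s (run
#'   [apply_exclusions()] first).
#' @return A `feature_table` data frame.
#' @export
assemble_table <- function(records) {
  ids <- vapply(records, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    vm_stop("duplicate subject id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- vm_feature_names()
  rows <- lapply(records, function(r) {
    v <- setNames(rep(NA_real_, length(cols)), cols)
    for (lb in names(r$segments)) {
      f <- r$segments[[lb]]
      nm <- paste0(lb, "_", vm_feature_suffixes())
      hit <- intersect(nm, cols)
      v[hit] <- unclass(f)[hit]
    }
    c(age = r$age, v)
  })
  tab <- data.frame(subject_id = ids, check.names = FALSE)
  tab <- cbind(tab, do.call(rbind, rows))
  tab <- tab[order(tab$subject_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("feature_table", "data.frame")
  tab
}

.table_schema <- function() c("subject_id", "age", vm_feature_names())

#' Read / write the cohort feature table as CSV
#'
#' CSV is the canonical on-disk format (UTF-8, '.' decimal); the header must
#' match the documented schema exactly. Write-then-read round-trips values
#' to better than 1e-12 relative.
#'
#' @param table A `feature_table`.
#' @param path CSV file path.
#' @return `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  if (!all(.table_schema() %in% names(table)))
    vm_stop("table does not follow the feature-table schema")
  write.csv(table[, .table_schema(), drop = FALSE], path,
            row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  want <- .table_schema()
  missing_cols <- setdiff(want, names(tab))
  extra <- setdiff(names(tab), want)
  if (length(missing_cols) || length(extra))
    vm_stop("feature-table schema mismatch;",
            if (length(missing_cols)) paste0(" missing: ",
                                             paste(missing_cols, collapse = ", ")),
            if (length(extra)) paste0(" unexpected: ",
                                      paste(extra, collapse = ", ")))
  tab <- tab[, want, drop = FALSE]
  class(tab) <- c("feature_table", "data.frame")
  tab
}
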