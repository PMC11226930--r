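#' Read participant profiles from CSV
#'
#' One row per participant per assessment point; required columns are
#' `participant_id`, `assessment_point`, and one column per schema
#' variable. Row-level problems are collected and reported together: in
#' strict mode (default) any bad row aborts the read with the offending
#' row numbers; otherwise bad rows are dropped with a warning.
#'
#' @param path CSV file path.
#' @param schema A `feature_schema`.
#' @param strict Abort on any invalid row (default) instead of skipping.
#' @return List of `participant_profile`s (empty for an empty file).
#' @export
read_participants <- function(path, schema, strict = TRUE) {
  stopifnot(inherits(schema, "feature_schema"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) return(list())
  v <- schema$variables
  needed <- c("participant_id", "assessment_point", v$name)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(df), needed)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }

  cat_names <- v$name[v$kind == "categorical"]
  num_names <- v$name[v$kind == "numerical"]
  profiles <- vector("list", nrow(df))
  errors <- character(0)
  for (r in seq_len(nrow(df))) {
    res <- tryCatch({
      num <- suppressWarnings(
        stats::setNames(as.numeric(unlist(df[r, num_names])), num_names))
      if (anyNA(num)) stop("unparseable numerical value")
      participant_profile(
        schema, df$participant_id[r],
        stats::setNames(as.character(df[r, cat_names]), cat_names),
        num, df$assessment_point[r]
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0("row ", r, ": ", conditionMessage(res)))
    } else {
      profiles[[r]] <- res
    }
  }
  if (length(errors)) {
    msg <- paste(errors, collapse = "\n  ")
    if (strict) stop("invalid participant row(s):\n  ", msg)
    warning("skipped invalid participant row(s):\n  ", msg)
  }
  Filter(Negate(is.null), profiles)
}

#' Persist and load a knowledge base as JSON lines
#'
#' One valid record per line, in insertion order, so the on-disk file has
#' the same append-only semantics as the in-memory store. Reading
#' re-validates every record; a corrupt line or a record violating the
#' validity invariant (reduction below 5) fails with its line number.
#'
#' @param kb A `knowledge_base`.
#' @param path File path (conventionally `.jsonl`).
#' @return `write_kb()`: `path`, invisibly. `read_kb()`: a
#'   `knowledge_base`.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  lines <- vapply(kb$records, function(r) {
    as.character(jsonlite::toJSON(
      list(
        insertion_index = r$insertion_index,
        program = r$program,
        effective_subdimension = r$effective_subdimension,
        reduction = r$reduction,
        participant_id = r$profile$participant_id,
        assessment_point = r$profile$assessment_point,
        categorical_values = as.list(r$profile$categorical_values),
        numerical_values = as.list(r$profile$numerical_values)
      ),
      auto_unbox = TRUE, digits = NA
    ))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kb
#' @param schema The `feature_schema` the stored profiles conform to.
#' @export
read_kb <- function(path, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  kb <- knowledge_base(schema)
  if (!file.exists(path)) stop("knowledge-base file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  for (ln in seq_along(lines)) {
    rec <- tryCatch({
      x <- jsonlite::fromJSON(lines[ln], simplifyVector = TRUE)
      prof <- participant_profile(schema, x$participant_id,
                                  unlist(x$categorical_values),
                                  unlist(x$numerical_values),
                                  x$assessment_point)
      valid_record(prof, x$program, x$effective_subdimension, x$reduction)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      stop("line ", ln, ": ", conditionMessage(rec))
    }
    kb <- update_knowledge_base(kb, rec)
  }
  kb
}

#' Write a trial result as tidy CSV
#'
#' One row per participant-stage, suitable for [evaluate_trial()] after
#' re-reading.
#'
#' @param trial A `trial_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_result", "data.frame")
  out
}
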