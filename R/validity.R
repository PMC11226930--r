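#' Per-subdimension burnout reductions
#'
#' `pre - post` for each subdimension on the normalized 0-100 scale;
#' positive values are improvements, negative values mean worsening.
#'
#' @param pre,post `burnout_scores` objects or named normalized vectors
#'   with elements `personal`, `work`, `client`.
#' @return Named numeric vector of reductions.
#' @export
#' @examples
#' subdimension_reductions(c(personal = 45, work = 40, client = 39),
#'                         c(personal = 40, work = 37, client = 35))
subdimension_reductions <- function(pre, post) {
  normalized_subscores(pre) - normalized_subscores(post)
}

#' Classify a completed program stage as valid or invalid
#'
#' A stage is valid when exactly one subdimension's normalized score
#' decreased by at least `threshold` points (default 5); that
#' subdimension is the effective one and the record may enter the
#' knowledge base. Two or more such reductions are taken to indicate that
#' burnout decreased for reasons other than the program, and the stage is
#' invalid (`multi_dimension`); no sufficient reduction is invalid
#' (`insufficient_reduction`). The classification does not depend on the
#' order in which subdimensions are supplied.
#'
#' @param reductions Named numeric vector from
#'   [subdimension_reductions()].
#' @param threshold Minimum normalized reduction (default 5 points).
#' @return A `validity_classification`: list with `valid` (logical),
#'   `effective_subdimension` (or `NA`), `status` (one of `"valid"`,
#'   `"multi_dimension"`, `"insufficient_reduction"`), and the
#'   `reductions` examined.
#' @export
#' @examples
#' classify_validity(c(personal = 5, work = 3, client = 4)) # valid(personal)
#' classify_validity(c(personal = 5, work = 5, client = 4)) # multi_dimension
classify_validity <- function(reductions, threshold = 5) {
  red <- normalized_subscores(reductions)
  hits <- names(red)[red >= threshold]
  status <- if (length(hits) == 1) "valid"
            else if (length(hits) >= 2) "multi_dimension"
            else "insufficient_reduction"
  structure(
    list(
      valid = status == "valid",
      effective_subdimension = if (status == "valid") hits else NA_character_,
      status = status,
      reductions = red
    ),
    class = "validity_classification"
  )
}

#' @export
print.validity_classification <- function(x, ...) {
  if (x$valid) {
    cat("valid: effective subdimension =", x$effective_subdimension, "\n")
  } else {
    cat("invalid:", x$status, "\n")
  }
  invisible(x)
}

#' Extract valid records from a participant history
#'
#' Applies the validity classification to every completed program stage
#' and returns one `valid_record` per valid stage. Both stages of one
#' participant may independently be valid. Each entry must pair the
#' outcome with the profile at the assessment preceding the program;
#' entries with a missing profile or outcome raise an error.
#'
#' @param history A list of entries, each a list with elements `profile`
#'   (`participant_profile` at the pre-program assessment) and `outcome`
#'   (`program_outcome`).
#' @param threshold Validity threshold passed to [classify_validity()].
#' @return A list of `valid_record`s (insertion indices unassigned).
#' @export
extract_valid_records <- function(history, threshold = 5) {
  records <- list()
  for (k in seq_along(history)) {
    entry <- history[[k]]
    if (is.null(entry$profile) || is.null(entry$outcome)) {
      stop("history entry ", k, " is missing its profile or outcome")
    }
    stopifnot(inherits(entry$profile, "participant_profile"),
              inherits(entry$outcome, "program_outcome"))
    red <- subdimension_reductions(entry$outcome$pre, entry$outcome$post)
    cls <- classify_validity(red, threshold)
    if (cls$valid) {
      records[[length(records) + 1L]] <- valid_record(
        entry$profile, entry$outcome$program,
        cls$effective_subdimension,
        cls$reductions[[cls$effective_subdimension]]
      )
    }
  }
  records
}
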