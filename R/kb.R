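#' A valid program-outcome record
#'
#' One (profile, program, effective-subdimension) triple admitted to the
#' knowledge base: the participant's profile at the assessment preceding
#' the program, the program taken, the single subdimension whose
#' normalized score dropped by at least the validity threshold, and the
#' size of that drop.
#'
#' @param profile `participant_profile` at the pre-program assessment
#'   (`pretest` for stage 1, `posttest1` for stage 2).
#' @param program One of [burnout_programs()].
#' @param effective_subdimension One of [burnout_subdimensions()].
#' @param reduction Normalized-scale reduction (must be >= 5).
#' @param insertion_index Ordinal position in the knowledge base;
#'   assigned by [update_knowledge_base()], `NA` until then.
#' @return A `valid_record`.
#' @export
valid_record <- function(profile, program, effective_subdimension, reduction,
                         insertion_index = NA_integer_) {
  stopifnot(inherits(profile, "participant_profile"))
  program <- match.arg(program, burnout_programs())
  effective_subdimension <- match.arg(effective_subdimension, burnout_subdimensions())
  reduction <- as.numeric(reduction)
  if (!is.finite(reduction) || reduction < 5) {
    stop("a valid record requires a reduction of at least 5 normalized points; got ",
         reduction)
  }
  structure(
    list(profile = profile, program = program,
         effective_subdimension = effective_subdimension,
         reduction = reduction,
         insertion_index = as.integer(insertion_index)),
    class = "valid_record"
  )
}

#' Create an empty knowledge base
#'
#' The knowledge base is the ordered, append-only collection of valid
#' records the recommender searches. Records are only ever added (with a
#' strictly increasing insertion index); existing records are never
#' modified or reordered, so recommendations are auditable after the fact.
#'
#' @param schema The `feature_schema` all stored profiles conform to.
#' @return A `knowledge_base` with zero records.
#' @export
knowledge_base <- function(schema) {
  stopifnot(inherits(schema, "feature_schema"))
  structure(
    list(
      schema = schema,
      records = list(),
      # numeric feature matrix aligned with records, for vectorized ranking
      features = matrix(numeric(0), nrow = 0, ncol = nrow(schema$variables),
                        dimnames = list(NULL, schema$variables$name))
    ),
    class = "knowledge_base"
  )
}

#' Append valid records to a knowledge base
#'
#' Append-only update: existing records and their order are untouched;
#' each new record receives the next insertion index. A record for a
#' (participant, assessment point) pair already stored is rejected.
#'
#' @param kb A `knowledge_base`.
#' @param new_records A single `valid_record` or a list of them.
#' @return The grown `knowledge_base`.
#' @export
update_knowledge_base <- function(kb, new_records) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (inherits(new_records, "valid_record")) new_records <- list(new_records)
  if (length(new_records) == 0) return(kb)
  if (!all(vapply(new_records, inherits, TRUE, "valid_record"))) {
    stop("all records must be valid_record objects")
  }
  seen <- vapply(kb$records, function(r) {
    paste(r$profile$participant_id, r$profile$assessment_point)
  }, "")
  for (rec in new_records) {
    key <- paste(rec$profile$participant_id, rec$profile$assessment_point)
    if (key %in% seen) {
      stop("duplicate record for participant '", rec$profile$participant_id,
           "' at ", rec$profile$assessment_point)
    }
    seen <- c(seen, key)
    rec$insertion_index <- length(kb$records) + 1L
    kb$records[[rec$insertion_index]] <- rec
    kb$features <- rbind(kb$features, profile_features(rec$profile, kb$schema))
  }
  kb
}

#' Number of records in a knowledge base
#' @param kb A `knowledge_base`.
#' @return Integer count.
#' @export
kb_size <- function(kb) length(kb$records)

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>", length(x$records), "valid record(s)\n")
  if (length(x$records)) {
    tab <- table(vapply(x$records, function(r) r$program, ""))
    cat("  programs:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
    tab <- table(vapply(x$records, function(r) r$effective_subdimension, ""))
    cat("  effective subdimensions:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
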