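#' Recommender configuration
#'
#' Tunable policy pieces of the two-stage recommender. The cold-start
#' preallocation map sends each dominant burnout subdimension to a
#' program when no valid record is available; the fallback order resolves
#' exclusions; the tie priority orders subdimensions when normalized
#' scores tie. All three are explicit configuration because only their
#' existence, not their content, is fixed by the procedure.
#'
#' @param cold_start_map Named character vector subdimension -> program.
#' @param fallback_order Permutation of [burnout_programs()] used when
#'   the mapped program is excluded.
#' @param tie_priority Permutation of [burnout_subdimensions()]; earlier
#'   entries win ties for the dominant subdimension.
#' @param threshold Validity threshold (normalized points).
#' @return A `recommender_config` list.
#' @export
recommender_config <- function(
    cold_start_map = c(personal = "mindfulness", work = "storytelling",
                       client = "act"),
    fallback_order = c("laughter", "mindfulness", "storytelling", "act"),
    tie_priority = c("work", "client", "personal"),
    threshold = 5) {
  stopifnot(setequal(names(cold_start_map), burnout_subdimensions()),
            all(cold_start_map %in% burnout_programs()),
            setequal(fallback_order, burnout_programs()),
            setequal(tie_priority, burnout_subdimensions()))
  structure(
    list(cold_start_map = cold_start_map, fallback_order = fallback_order,
         tie_priority = tie_priority, threshold = threshold),
    class = "recommender_config"
  )
}

#' Dominant burnout subdimension
#'
#' The subdimension with the highest normalized score. Ties are broken by
#' a fixed priority (default work > client > personal).
#'
#' @param scores A `burnout_scores` object or named normalized vector.
#' @param priority Tie-break order over subdimensions.
#' @return One of [burnout_subdimensions()].
#' @export
#' @examples
#' dominant_subdimension(c(personal = 50, work = 70, client = 70)) # "work"
dominant_subdimension <- function(scores, priority = c("work", "client", "personal")) {
  stopifnot(setequal(priority, burnout_subdimensions()))
  s <- normalized_subscores(scores)[priority]
  priority[which.max(s)]
}

#' Cold-start program allocation
#'
#' Resolves a program from the preallocation map when no valid record can
#' be matched; an excluded mapped program falls through to the first
#' non-excluded program in the configured fallback order.
#'
#' @param dominant Dominant subdimension of the new participant.
#' @param excluded Programs that may not be recommended (e.g., the
#'   stage-1 program at stage 2).
#' @param config A [recommender_config()].
#' @return A program id.
#' @export
cold_start_allocation <- function(dominant, excluded = character(0),
                                  config = recommender_config()) {
  dominant <- match.arg(dominant, burnout_subdimensions())
  excluded <- as.character(excluded)
  if (!all(excluded %in% burnout_programs())) stop("unknown excluded program")
  if (setequal(excluded, burnout_programs())) stop("all programs are excluded")
  prog <- config$cold_start_map[[dominant]]
  if (!prog %in% excluded) return(prog)
  remaining <- setdiff(config$fallback_order, excluded)
  remaining[1]
}

new_recommendation <- function(program, stage, dominant, cold_start,
                               matched = NULL, dissimilarity = NA_real_,
                               audit = NULL) {
  structure(
    list(program = program, stage = stage,
         dominant_subdimension = dominant, cold_start = cold_start,
         matched_record = matched, dissimilarity = dissimilarity,
         audit = audit),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation> stage", x$stage, "->", x$program, "\n")
  cat("  dominant subdimension:", x$dominant_subdimension, "\n")
  if (x$cold_start) {
    cat("  cold start (no eligible valid record)\n")
  } else {
    cat(sprintf("  matched record #%d (participant %s), dissimilarity %.3f\n",
                x$matched_record$insertion_index,
                x$matched_record$profile$participant_id, x$dissimilarity))
  }
  invisible(x)
}

# Shared matching core: filter-then-rank with fallback. `excluded` programs
# are a hard constraint; the dominant-subdimension match is soft (dropped
# when it empties the candidate set).
match_record <- function(kb, new, stage, dominant, excluded, config) {
  hard <- function(r) !(r$program %in% excluded)
  strict <- function(r) hard(r) && r$effective_subdimension == dominant
  ranked <- rank_records(kb, new, stage = stage, candidate_filter = strict)
  if (nrow(ranked) == 0) {
    ranked <- rank_records(kb, new, stage = stage, candidate_filter = hard)
  }
  if (nrow(ranked) == 0) return(NULL)
  top <- ranked[1, ]
  list(record = kb$records[[top$insertion_index]],
       dissimilarity = top$dissimilarity)
}

#' Stage-1 program recommendation
#'
#' From the pretest profile: the candidate set is the valid records whose
#' effective subdimension equals the new participant's dominant burnout
#' subdimension; the program of the least-dissimilar candidate is
#' recommended. If no record matches the subdimension, the whole
#' knowledge base is searched; if the knowledge base is empty, the
#' cold-start preallocation map decides.
#'
#' @param kb A `knowledge_base`.
#' @param new `participant_profile` at pretest.
#' @param config A [recommender_config()].
#' @return A `recommendation`.
#' @export
recommend_stage1 <- function(kb, new, config = recommender_config()) {
  dominant <- dominant_subdimension(profile_burnout(new, kb$schema),
                                    config$tie_priority)
  m <- match_record(kb, new, stage = 1, dominant = dominant,
                    excluded = character(0), config = config)
  if (is.null(m)) {
    return(new_recommendation(cold_start_allocation(dominant, character(0), config),
                              stage = 1, dominant = dominant, cold_start = TRUE))
  }
  new_recommendation(m$record$program, stage = 1, dominant = dominant,
                     cold_start = FALSE, matched = m$record,
                     dissimilarity = m$dissimilarity)
}

#' Stage-2 program recommendation
#'
#' Same matching procedure from the posttest-1 profile, restricted to the
#' three programs the participant has not yet taken; the dominant
#' subdimension is recomputed from the posttest-1 burnout scores and the
#' comparison uses the reduced stage-2 variable subset.
#'
#' @param kb A `knowledge_base`.
#' @param new `participant_profile` at posttest 1.
#' @param program1 The participant's stage-1 program (never recommended
#'   again).
#' @param config A [recommender_config()].
#' @return A `recommendation`; its program is guaranteed to differ from
#'   `program1`.
#' @export
recommend_stage2 <- function(kb, new, program1, config = recommender_config()) {
  program1 <- match.arg(program1, burnout_programs())
  dominant <- dominant_subdimension(profile_burnout(new, kb$schema),
                                    config$tie_priority)
  m <- match_record(kb, new, stage = 2, dominant = dominant,
                    excluded = program1, config = config)
  if (is.null(m)) {
    return(new_recommendation(cold_start_allocation(dominant, program1, config),
                              stage = 2, dominant = dominant, cold_start = TRUE))
  }
  new_recommendation(m$record$program, stage = 2, dominant = dominant,
                     cold_start = FALSE, matched = m$record,
                     dissimilarity = m$dissimilarity)
}

#' Audit a recommendation: full ranked candidate table
#'
#' Reproduces the manual verification workflow: every knowledge-base
#' record is listed with its per-element dissimilarity breakdown, total,
#' and eligibility under the matching filter, ordered as the recommender
#' ranks them. The top eligible row's program equals what the
#' corresponding `recommend_stage*()` call returns.
#'
#' @param kb A `knowledge_base` (nonempty).
#' @param new A `participant_profile`.
#' @param stage 1 or 2.
#' @param program1 Stage-1 program, required when `stage = 2`.
#' @param config A [recommender_config()].
#' @return A data frame with one row per record: identification columns,
#'   `eligible` (passes the hard exclusion), `matches_subdimension`,
#'   `dissimilarity`, and one `d_<variable>` column per compared
#'   variable. The `recommendation` is attached as an attribute.
#' @export
audit_recommendation <- function(kb, new, stage = 1, program1 = NULL,
                                 config = recommender_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (stage == 2 && is.null(program1)) stop("stage 2 audit requires program1")
  excluded <- if (stage == 2) program1 else character(0)
  dominant <- dominant_subdimension(profile_burnout(new, kb$schema),
                                    config$tie_priority)
  ranked <- rank_records(kb, new, stage = stage)
  rec <- if (stage == 1) recommend_stage1(kb, new, config)
         else recommend_stage2(kb, new, program1, config)

  vars <- schema_vars(kb$schema, if (stage == 2) 2 else NULL)
  breakdowns <- matrix(NA_real_, nrow = nrow(ranked), ncol = length(vars),
                       dimnames = list(NULL, paste0("d_", vars)))
  for (r in seq_len(nrow(ranked))) {
    rec_prof <- kb$records[[ranked$insertion_index[r]]]$profile
    bd <- profile_dissimilarity(rec_prof, new, kb$schema, vars = vars)
    breakdowns[r, ] <- bd$per_element
  }
  out <- cbind(
    ranked,
    eligible = !(ranked$program %in% excluded),
    matches_subdimension = ranked$effective_subdimension == dominant,
    as.data.frame(breakdowns)
  )
  attr(out, "recommendation") <- rec
  attr(out, "dominant_subdimension") <- dominant
  out
}
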