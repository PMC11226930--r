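#' Replay the sequential adaptive trial on a simulated cohort
#'
#' Processes participants one at a time through the full seven-stage
#' flow: pretest, stage-1 recommendation, simulated program response,
#' posttest 1, validity classification and knowledge-base update, stage-2
#' recommendation among the remaining programs, second response,
#' posttest 2, and a final validity/update step. The knowledge base grows
#' during the run, so later participants are recommended from more valid
#' data — exactly the optimization dynamic of deployment.
#'
#' Policies: `"similarity"` (the nearest-valid-record engine),
#' `"preallocated"` (always the cold-start subdimension map, as in the
#' pilot), `"random"` (uniform over admissible programs), `"fixed"`
#' (always `fixed_program` at stage 1), and `"oracle"` (the subgroup-best
#' program when heterogeneity is on, random otherwise).
#'
#' @param spec A [cohort_spec()].
#' @param policy One of `"similarity"`, `"preallocated"`, `"random"`,
#'   `"fixed"`, `"oracle"`.
#' @param initial_kb Starting `knowledge_base` (default empty).
#' @param fixed_program Program for the `"fixed"` policy.
#' @param config A [recommender_config()].
#' @param seed Seed for the whole run (cohort + responses); default
#'   `spec$seed`. Identical inputs give bit-identical results.
#' @param cohort Optional pre-sampled cohort (list of pretest profiles);
#'   when supplied the cohort is not re-drawn.
#' @return A `trial_result`: data frame with one row per completed
#'   participant-stage (columns include `participant_id`, `order`,
#'   `stage`, `program`, `best_program`, `cold_start`, `dissimilarity`,
#'   per-subdimension and total reductions, `valid`,
#'   `effective_subdimension`, `satisfaction`, `kb_size_at_rec`), with
#'   the final knowledge base in `attr(, "kb")`.
#' @export
run_closed_loop_trial <- function(spec,
                                  policy = c("similarity", "preallocated",
                                             "random", "fixed", "oracle"),
                                  initial_kb = NULL, fixed_program = NULL,
                                  config = recommender_config(),
                                  seed = spec$seed, cohort = NULL) {
  policy <- match.arg(policy)
  if (policy == "fixed" && is.null(fixed_program)) {
    stop("the fixed policy requires fixed_program")
  }
  if (!is.null(seed)) set.seed(seed)
  schema <- spec$schema
  kb <- initial_kb %||% knowledge_base(schema)
  if (is.null(cohort)) cohort <- sample_cohort(spec, seed = NULL)

  choose_program <- function(profile, stage, excluded) {
    admissible <- setdiff(burnout_programs(), excluded)
    dom <- dominant_subdimension(profile_burnout(profile, schema),
                                 config$tie_priority)
    switch(policy,
      similarity = {
        rec <- if (stage == 1) recommend_stage1(kb, profile, config)
               else recommend_stage2(kb, profile, excluded, config)
        list(program = rec$program, cold_start = rec$cold_start,
             dissimilarity = rec$dissimilarity, dominant = dom)
      },
      preallocated = list(program = cold_start_allocation(dom, excluded, config),
                          cold_start = TRUE, dissimilarity = NA_real_,
                          dominant = dom),
      random = list(program = sample(admissible, 1), cold_start = NA,
                    dissimilarity = NA_real_, dominant = dom),
      fixed = {
        prog <- if (fixed_program %in% admissible) fixed_program
                else setdiff(config$fallback_order, excluded)[1]
        list(program = prog, cold_start = NA, dissimilarity = NA_real_,
             dominant = dom)
      },
      oracle = {
        best <- subgroup_best_program(profile, spec)
        prog <- if (!is.na(best) && best %in% admissible) best
                else sample(admissible, 1)
        list(program = prog, cold_start = NA, dissimilarity = NA_real_,
             dominant = dom)
      })
  }

  rows <- vector("list", 2L * length(cohort))
  nrows <- 0L
  for (k in seq_along(cohort)) {
    profile <- cohort[[k]]
    stage_profile <- profile
    program1 <- NULL
    for (stage in 1:2) {
      if (stage == 2 && spec$dropout > 0 && stats::runif(1) < spec$dropout) break
      excluded <- if (stage == 2) program1 else character(0)
      choice <- choose_program(stage_profile, stage, excluded)
      kb_at_rec <- kb_size(kb)
      outcome <- simulate_response(stage_profile, choice$program, spec)
      red <- subdimension_reductions(outcome$pre, outcome$post)
      cls <- classify_validity(red, config$threshold)
      if (cls$valid) {
        kb <- update_knowledge_base(kb, valid_record(
          stage_profile, choice$program, cls$effective_subdimension,
          cls$reductions[[cls$effective_subdimension]]
        ))
      }
      nrows <- nrows + 1L
      rows[[nrows]] <- data.frame(
        participant_id = profile$participant_id,
        order = k,
        stage = stage,
        policy = policy,
        dominant_subdimension = choice$dominant,
        program = choice$program,
        best_program = subgroup_best_program(stage_profile, spec),
        cold_start = choice$cold_start,
        dissimilarity = choice$dissimilarity,
        kb_size_at_rec = kb_at_rec,
        pre_total = outcome$pre$total,
        post_total = outcome$post$total,
        total_reduction = outcome$pre$total - outcome$post$total,
        red_personal = red[["personal"]],
        red_work = red[["work"]],
        red_client = red[["client"]],
        valid = cls$valid,
        effective_subdimension = cls$effective_subdimension,
        satisfaction = outcome$satisfaction,
        stringsAsFactors = FALSE
      )
      if (stage == 1) {
        program1 <- choice$program
        stage_profile <- profile_with_burnout(
          stage_profile, schema, outcome$post$normalized, "posttest1")
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(nrows)])
  rownames(out) <- NULL
  class(out) <- c("trial_result", "data.frame")
  attr(out, "kb") <- kb
  attr(out, "policy") <- policy
  out
}

#' Replay the pilot-then-optimization deployment
#'
#' A pilot cohort receives the preallocated subdimension-mapped programs
#' (seeding the knowledge base), then the main cohort runs under the
#' similarity policy against the growing knowledge base — the end-to-end
#' deployment sequence.
#'
#' @param spec A [cohort_spec()] for the main cohort (its `n` is the main
#'   cohort size).
#' @param n_pilot Pilot size (default 10).
#' @param config A [recommender_config()].
#' @param seed Seed for the full replay.
#' @return A `trial_result` covering pilot and main participants (column
#'   `phase` distinguishes them), final knowledge base in `attr(, "kb")`.
#' @export
replay_trial <- function(spec, n_pilot = 10, config = recommender_config(),
                         seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  pilot_spec <- spec
  pilot_spec$n <- as.integer(n_pilot)
  pilot_cohort <- lapply(sample_cohort(pilot_spec, seed = NULL), function(p) {
    p$participant_id <- sub("^sim_", "pilot_", p$participant_id)
    p
  })
  pilot <- run_closed_loop_trial(pilot_spec, policy = "preallocated",
                                 config = config, seed = NULL,
                                 cohort = pilot_cohort)
  main <- run_closed_loop_trial(spec, policy = "similarity",
                                initial_kb = attr(pilot, "kb"),
                                config = config, seed = NULL)
  pilot$phase <- "pilot"
  main$phase <- "optimization"
  main$order <- main$order + n_pilot
  out <- rbind(as.data.frame(pilot), as.data.frame(main))
  class(out) <- c("trial_result", "data.frame")
  attr(out, "kb") <- attr(main, "kb")
  out
}

#' Subgroup-best match rate of assigned programs
#'
#' Fraction of stage assignments equal to the participant's subgroup-best
#' program, optionally restricted to the last part of the cohort (where
#' the knowledge base is largest). Only defined under heterogeneity.
#'
#' @param trial A `trial_result`.
#' @param stage Stage to evaluate (1, 2, or `NULL` for both).
#' @param last_n Restrict to participants with the `last_n` highest
#'   orders (`NULL` for all).
#' @return Proportion in \[0, 1\] (`NaN` when no rows qualify).
#' @export
match_rate <- function(trial, stage = 1, last_n = NULL) {
  d <- as.data.frame(trial)
  if (!is.null(stage)) d <- d[d$stage == stage, ]
  if (!is.null(last_n)) {
    cutoff <- sort(unique(d$order), decreasing = TRUE)
    cutoff <- cutoff[min(last_n, length(cutoff))]
    d <- d[d$order >= cutoff, ]
  }
  d <- d[!is.na(d$best_program), ]
  mean(d$program == d$best_program)
}
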