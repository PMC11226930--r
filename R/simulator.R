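#' Default cohort marginal distributions
#'
#' Category proportions and numeric means/SDs emulating the published
#' 300-nurse cohort: age 32.81 (SD 5.754) years, 97.7% female, 59.3%
#' married, 87% staff nurses, 62.3% in hospitals with 500+ beds, clinical
#' experience 95.83 (SD 69.66) months, and the pretest research-variable
#' and burnout distributions. Proportions are the published counts
#' divided by 300, so they sum to one exactly. Clinical experience is
#' sampled in months and then banded into the schema's 1-6 code
#' (<24, 24-60, 60-120, 120-180, 180-240, >=240 months). Reserved schema
#' slots are held at the scale midpoint and contribute nothing to
#' dissimilarity.
#'
#' @return A list of per-variable sampling descriptions.
#' @export
default_marginals <- function() {
  list(
    sex = list(kind = "categorical",
               probs = c("1" = 293, "2" = 7) / 300),
    marital_status = list(kind = "categorical",
                          probs = c("1" = 178, "2" = 118, "3" = 4) / 300),
    position = list(kind = "categorical",
                    probs = c("1" = 261, "2" = 35, "3" = 4) / 300),
    department = list(kind = "categorical",
                      probs = c("1" = 172, "2" = 16, "3" = 30,
                                "4" = 63, "5" = 19) / 300),
    shift_type = list(kind = "categorical",
                      probs = c("1" = 180, "2" = 18, "3" = 101, "4" = 1) / 300),
    age = list(kind = "normal", mean = 32.81, sd = 5.754),
    hospital_size = list(kind = "code",
                         probs = c("1" = 7, "2" = 25, "3" = 63,
                                   "4" = 18, "5" = 187) / 300),
    clinical_experience = list(kind = "banded_months", mean = 95.83, sd = 69.66,
                               breaks = c(0, 24, 60, 120, 180, 240, Inf)),
    overtime = list(kind = "code",
                    probs = c("1" = 41, "2" = 78, "3" = 77,
                              "4" = 50, "5" = 17, "6" = 37) / 300),
    turnover_intention = list(kind = "normal", mean = 4.88, sd = 2.53),
    job_stress = list(kind = "normal", mean = 88.39, sd = 12.65),
    stress_response = list(kind = "normal", mean = 42.00, sd = 17.95),
    # the three coping subscales sum to the 33-99 coping total 70.25 (9.66)
    coping_total = list(kind = "sum", of = c("coping_problem_solving",
                                             "coping_social_support",
                                             "coping_avoidance")),
    coping_problem_solving = list(kind = "normal", mean = 70.25 / 3,
                                  sd = 9.66 / sqrt(3)),
    coping_social_support = list(kind = "normal", mean = 70.25 / 3,
                                 sd = 9.66 / sqrt(3)),
    coping_avoidance = list(kind = "normal", mean = 70.25 / 3,
                            sd = 9.66 / sqrt(3)),
    # raw CBI subdomain pretest distributions; stored normalized
    burnout_personal = list(kind = "burnout_raw", mean = 20.40, sd = 6.39,
                            max = 31.5),
    burnout_work = list(kind = "burnout_raw", mean = 22.22, sd = 6.39,
                        max = 37),
    burnout_client = list(kind = "burnout_raw", mean = 19.72, sd = 6.63,
                          max = 31.5),
    reserved_1 = list(kind = "constant", value = 50),
    reserved_2 = list(kind = "constant", value = 50),
    reserved_3 = list(kind = "constant", value = 50)
  )
}

#' Default program response model
#'
#' Per-program, per-subdimension mean (SD) reductions on the normalized
#' 0-100 subdimension scale, taken from the published program effects.
#' The weighted sum of the three subdimension means (weights 0.315, 0.37,
#' 0.315, the subdomain shares of the 0-100 total) reproduces the
#' published total reductions: laughter 5.4, storytelling 4.6, ACT 7.9,
#' mindfulness 2.6 points.
#'
#' @return Named list program -> list(mean =, sd =) of length-3 vectors.
#' @export
default_response_model <- function() {
  list(
    laughter = list(mean = c(personal = 6.9, work = 4.3, client = 5.2),
                    sd = c(personal = 10.4, work = 7.2, client = 8.7)),
    storytelling = list(mean = c(personal = 4.2, work = 5.6, client = 3.8),
                        sd = c(personal = 8.0, work = 10.5, client = 7.4)),
    act = list(mean = c(personal = 4.9, work = 6.4, client = 12.7),
               sd = c(personal = 7.9, work = 10.5, client = 18.2)),
    mindfulness = list(mean = c(personal = 3.0, work = 2.2, client = 2.7),
                       sd = c(personal = 4.9, work = 4.0, client = 4.8))
  )
}

#' Equalized response model for policy controls
#'
#' A response model in which every program has identical per-subdimension
#' base effects, for use in the positive/negative policy controls. With
#' the published calibration the four programs differ strongly in their
#' main effects, so any two assignment policies differ in mean reduction
#' through program mix alone; a control comparing recommendation policies
#' must therefore equalize main effects so that reductions differ only
#' through subgroup structure (added via [subgroup_heterogeneity()]).
#' The base mean sits below the 5-point validity threshold so that valid
#' records arise through response noise at a modest rate, keeping the
#' single-subdimension validity rule selective.
#'
#' @param base_mean Per-subdimension mean reduction (normalized points).
#' @param base_sd Per-subdimension SD.
#' @return Named list program -> list(mean =, sd =).
#' @export
control_response_model <- function(base_mean = 2, base_sd = 3) {
  one <- list(
    mean = stats::setNames(rep(base_mean, 3), burnout_subdimensions()),
    sd = stats::setNames(rep(base_sd, 3), burnout_subdimensions())
  )
  stats::setNames(rep(list(one), 4), burnout_programs())
}

#' Subgroup response heterogeneity
#'
#' Optional structure for stress-testing the recommender: participants
#' are stratified (by their dominant burnout subdimension, or by a
#' categorical schema variable) and each stratum has a best program. When
#' a participant is assigned their stratum's best program, `bonus`
#' normalized points are added to the reduction of their dominant
#' subdimension. The default bonus of 10 points is strong relative to the
#' [control_response_model()] base effect, so the subgroup signal
#' dominates response noise — the "strong subgroup structure" regime of
#' the positive control. The default best map equals the cold-start
#' preallocation map: the recommender has no exploration mechanism, so a
#' subgroup-best program that the preallocation (pilot) phase never
#' injects can never enter the knowledge base and is unlearnable by
#' construction; a well-posed positive control therefore places the true
#' structure inside the procedure's reachable set.
#'
#' @param by `"dominant"` or the name of a categorical schema variable.
#' @param best Named character map stratum -> program.
#' @param bonus Normalized points added on match.
#' @return A heterogeneity specification list.
#' @export
subgroup_heterogeneity <- function(
    by = "dominant",
    best = c(personal = "mindfulness", work = "storytelling", client = "act"),
    bonus = 10) {
  stopifnot(all(best %in% burnout_programs()), bonus >= 0)
  list(by = by, best = best, bonus = bonus)
}

#' Specification of a simulated cohort and its program responses
#'
#' Bundles everything the simulator needs: cohort size, seed, marginal
#' distributions, the per-program response model, optional subgroup
#' heterogeneity, the satisfaction model, and an optional uniform
#' dropout rate applied between the two program stages.
#'
#' @param n Cohort size.
#' @param seed Integer seed (used by [sample_cohort()] and
#'   [run_closed_loop_trial()]).
#' @param marginals See [default_marginals()].
#' @param response_model See [default_response_model()].
#' @param heterogeneity `NULL` (homogeneous) or
#'   [subgroup_heterogeneity()].
#' @param satisfaction_model List with `base` (mean rating), `sd`, and
#'   `match_bonus` added when the program is the stratum's best.
#' @param dropout Probability a participant leaves after stage 1.
#' @param schema A `feature_schema`.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n = 300, seed = 1L,
                        marginals = default_marginals(),
                        response_model = default_response_model(),
                        heterogeneity = NULL,
                        satisfaction_model = list(base = 4.6, sd = 0.6,
                                                  match_bonus = 0.15),
                        dropout = 0,
                        schema = default_schema()) {
  stopifnot(n >= 0, dropout >= 0, dropout < 1,
            inherits(schema, "feature_schema"))
  for (nm in names(marginals)) {
    m <- marginals[[nm]]
    if (m$kind %in% c("categorical", "code")) {
      if (abs(sum(m$probs) - 1) > 1e-8) {
        stop("proportions for '", nm, "' do not sum to 1")
      }
    }
    if (!is.null(m$sd) && m$sd < 0) stop("negative SD for '", nm, "'")
  }
  for (p in names(response_model)) {
    if (any(response_model[[p]]$sd < 0)) stop("negative response SD for ", p)
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), marginals = marginals,
         response_model = response_model, heterogeneity = heterogeneity,
         satisfaction_model = satisfaction_model, dropout = dropout,
         schema = schema),
    class = "cohort_spec"
  )
}

# Truncated-normal sampling by inverse CDF; keeps the mean close to the
# target when the bounds are several SDs away.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  clamp(stats::qnorm(p, mean, sd), lo, hi)
}

#' Sample a pretest cohort
#'
#' Draws `spec$n` participant profiles whose empirical marginals converge
#' to the specification as the cohort grows. Numeric variables use
#' truncated-normal draws within the schema's theoretical ranges;
#' categorical variables and coded bands use the specified proportions.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed; `NULL` continues the current RNG stream (used inside
#'   trial replay).
#' @return List of `participant_profile`s at pretest.
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  schema <- spec$schema
  v <- schema$variables
  n <- spec$n
  if (n == 0) return(list())

  draws <- list()
  nms <- v$name
  m_all <- spec$marginals[nms]
  if (any(vapply(m_all, is.null, TRUE))) {
    stop("no marginal specified for schema variable '",
         nms[vapply(m_all, is.null, TRUE)][1], "'")
  }
  # derived (sum) variables are drawn after their components
  is_sum <- vapply(m_all, function(m) m$kind == "sum", TRUE)
  for (nm in c(nms[!is_sum], nms[is_sum])) {
    m <- spec$marginals[[nm]]
    i <- schema_var_row(schema, nm)
    draws[[nm]] <- switch(
      m$kind,
      categorical = sample(names(m$probs), n, replace = TRUE, prob = m$probs),
      code = as.numeric(sample(names(m$probs), n, replace = TRUE, prob = m$probs)),
      normal = rnorm_trunc(n, m$mean, m$sd, v$min[i], v$max[i]),
      banded_months = {
        months <- rnorm_trunc(n, m$mean, m$sd, 0, Inf)
        as.numeric(cut(months, breaks = m$breaks, labels = FALSE,
                       include.lowest = TRUE, right = FALSE))
      },
      burnout_raw = rnorm_trunc(n, m$mean, m$sd, 0, m$max) / m$max * 100,
      constant = rep(m$value, n),
      sum = {
        miss <- setdiff(m$of, names(draws))
        if (length(miss)) stop("sum marginal '", nm, "' references undrawn ", miss[1])
        clamp(Reduce(`+`, draws[m$of]), v$min[i], v$max[i])
      },
      stop("unknown marginal kind '", m$kind, "' for '", nm, "'")
    )
  }

  cat_names <- v$name[v$kind == "categorical"]
  num_names <- v$name[v$kind == "numerical"]
  lapply(seq_len(n), function(k) {
    participant_profile(
      schema, participant_id = paste0("sim_", k),
      categorical = vapply(cat_names, function(nm) as.character(draws[[nm]][k]), ""),
      numerical = vapply(num_names, function(nm) draws[[nm]][k], 0),
      assessment_point = "pretest"
    )
  })
}

# Stratum of a participant under the heterogeneity spec ("dominant" or a
# categorical variable); NA when heterogeneity is off.
participant_stratum <- function(profile, spec) {
  h <- spec$heterogeneity
  if (is.null(h)) return(NA_character_)
  if (h$by == "dominant") {
    dominant_subdimension(profile_burnout(profile, spec$schema))
  } else {
    profile$categorical_values[[h$by]]
  }
}

# Best program for a participant's stratum; NA without heterogeneity or
# for an unmapped stratum.
subgroup_best_program <- function(profile, spec) {
  h <- spec$heterogeneity
  if (is.null(h)) return(NA_character_)
  s <- participant_stratum(profile, spec)
  if (is.na(s) || !s %in% names(h$best)) return(NA_character_)
  h$best[[s]]
}

#' Simulate one program response
#'
#' Draws per-subdimension normalized reductions from the program's
#' response model (normal draws; a subgroup bonus is added to the
#' dominant subdimension when the program matches the participant's
#' stratum-best program), subtracts them from the current burnout scores,
#' truncates to the valid 0-100 range, and draws a 1-5 satisfaction
#' rating. Uses the current RNG stream; seed at the call site for
#' reproducibility.
#'
#' @param profile `participant_profile` at the pre-program assessment.
#' @param program One of [burnout_programs()].
#' @param spec A [cohort_spec()].
#' @return A `program_outcome`.
#' @export
simulate_response <- function(profile, program, spec) {
  program <- match.arg(program, burnout_programs())
  rm <- spec$response_model[[program]]
  if (is.null(rm)) stop("no response model for program '", program, "'")
  pre_norm <- profile_burnout(profile, spec$schema)

  red <- stats::rnorm(3, rm$mean[burnout_subdimensions()],
                      rm$sd[burnout_subdimensions()])
  names(red) <- burnout_subdimensions()

  best <- subgroup_best_program(profile, spec)
  matched <- !is.na(best) && program == best
  if (matched && spec$heterogeneity$bonus > 0) {
    dom <- dominant_subdimension(pre_norm)
    red[dom] <- red[dom] + spec$heterogeneity$bonus
  }

  post_norm <- clamp(pre_norm - red, 0, 100)

  sm <- spec$satisfaction_model
  sat_mean <- sm$base + if (matched) sm$match_bonus else 0
  sat <- as.integer(clamp(round(stats::rnorm(1, sat_mean, sm$sd)), 1, 5))

  program_outcome(
    program,
    pre = burnout_from_normalized(pre_norm[["personal"]], pre_norm[["work"]],
                                  pre_norm[["client"]]),
    post = burnout_from_normalized(post_norm[["personal"]], post_norm[["work"]],
                                   post_norm[["client"]]),
    satisfaction = sat
  )
}
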