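# Independent oracles and fixture builders. The oracles deliberately
# re-derive quantities from first principles (naive loops, textbook
# formulas) so they share no code path with the implementation.

# Brute-force Gower-style dissimilarity: explicit per-variable loop over
# raw profile values.
oracle_dissimilarity <- function(p, q, schema, vars = NULL) {
  v <- schema$variables
  if (is.null(vars)) vars <- v$name
  total <- 0
  for (nm in vars) {
    i <- which(v$name == nm)
    if (v$kind[i] == "categorical") {
      total <- total +
        (if (p$categorical_values[[nm]] == q$categorical_values[[nm]]) 0 else 1)
    } else if (v$degenerate[i]) {
      total <- total +
        (if (p$numerical_values[[nm]] == q$numerical_values[[nm]]) 0 else 1)
    } else {
      d <- abs(p$numerical_values[[nm]] - q$numerical_values[[nm]]) / v$range[i]
      total <- total + min(d, 1)
    }
  }
  total
}

# Random role-free schema with n_cat categorical and n_num numerical vars.
random_schema <- function(n_cat, n_num) {
  vars <- list()
  for (i in seq_len(n_cat)) {
    vars[[length(vars) + 1L]] <- list(
      name = paste0("c", i), kind = "categorical",
      codes = as.character(seq_len(sample(2:5, 1)))
    )
  }
  for (i in seq_len(n_num)) {
    lo <- runif(1, -10, 10)
    vars[[length(vars) + 1L]] <- list(
      name = paste0("x", i), kind = "numerical",
      min = lo, max = lo + runif(1, 0.5, 50)
    )
  }
  load_schema(list(variables = vars))
}

random_profile <- function(schema, id = "p") {
  v <- schema$variables
  cats <- vapply(v$name[v$kind == "categorical"], function(nm) {
    sample(schema$codes[[nm]], 1)
  }, "")
  idx <- which(v$kind == "numerical")
  nums <- stats::setNames(stats::runif(length(idx), v$min[idx], v$max[idx]),
                          v$name[idx])
  participant_profile(schema, id, cats, nums)
}

# Default-schema profile with fixed demographics and chosen normalized
# burnout scores; other values overridable.
make_profile <- function(schema, id, burnout = c(50, 50, 50),
                         assessment_point = "pretest", overrides = list()) {
  cats <- c(sex = "1", marital_status = "1", position = "1",
            department = "1", shift_type = "1")
  nums <- c(age = 30, hospital_size = 3, clinical_experience = 2,
            overtime = 2, turnover_intention = 5, job_stress = 80,
            stress_response = 40, coping_total = 69,
            coping_problem_solving = 23, coping_social_support = 23,
            coping_avoidance = 23,
            burnout_personal = burnout[1], burnout_work = burnout[2],
            burnout_client = burnout[3],
            reserved_1 = 50, reserved_2 = 50, reserved_3 = 50)
  for (nm in names(overrides)) {
    if (nm %in% names(cats)) cats[nm] <- overrides[[nm]]
    else nums[nm] <- overrides[[nm]]
  }
  participant_profile(schema, id, cats, nums, assessment_point)
}

# Random knowledge base over the default schema.
random_kb <- function(schema, n_records) {
  kb <- knowledge_base(schema)
  if (n_records == 0) return(kb)
  recs <- lapply(seq_len(n_records), function(i) {
    valid_record(
      make_profile(schema, paste0("r", i),
                   burnout = stats::runif(3, 0, 100),
                   overrides = list(
                     age = stats::runif(1, 22, 60),
                     hospital_size = sample(1:5, 1),
                     department = as.character(sample(1:5, 1)),
                     job_stress = stats::runif(1, 23, 115))),
      program = sample(burnout_programs(), 1),
      effective_subdimension = sample(burnout_subdimensions(), 1),
      reduction = stats::runif(1, 5, 20)
    )
  })
  update_knowledge_base(kb, recs)
}

# The four users of the published validity worked example: pretest,
# posttest-1 and posttest-2 normalized burnout triplets per user, with the
# program-stage labels the example prints.
table2_history <- function(schema) {
  scores <- list(
    A = list(pre = c(45, 40, 39), post1 = c(40, 37, 35), post2 = c(36, 35, 33)),
    B = list(pre = c(45, 40, 39), post1 = c(42, 37, 35), post2 = c(40, 37, 33)),
    C = list(pre = c(45, 40, 39), post1 = c(40, 35, 35), post2 = c(40, 33, 33)),
    D = list(pre = c(45, 40, 39), post1 = c(40, 37, 35), post2 = c(36, 31, 33))
  )
  history <- list()
  for (u in names(scores)) {
    s <- scores[[u]]
    history[[length(history) + 1L]] <- list(
      profile = make_profile(schema, u, burnout = s$pre),
      outcome = program_outcome(
        "mindfulness",
        pre = burnout_from_normalized(s$pre[1], s$pre[2], s$pre[3]),
        post = burnout_from_normalized(s$post1[1], s$post1[2], s$post1[3])
      )
    )
    history[[length(history) + 1L]] <- list(
      profile = make_profile(schema, u, burnout = s$post1,
                             assessment_point = "posttest1"),
      outcome = program_outcome(
        "laughter",
        pre = burnout_from_normalized(s$post1[1], s$post1[2], s$post1[3]),
        post = burnout_from_normalized(s$post2[1], s$post2[2], s$post2[3])
      )
    )
  }
  history
}

# Textbook paired t statistic.
oracle_paired_t <- function(pre, post) {
  d <- pre - post
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Spearman rho as Pearson correlation of ranks.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Scheffe-adjusted p value for the pairwise contrast of groups i and j in
# a one-way layout.
oracle_scheffe_p <- function(y, g, i, j) {
  g <- as.factor(g)
  k <- nlevels(g)
  n <- length(y)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (n - k)
  ni <- sum(g == levels(g)[i]); nj <- sum(g == levels(g)[j])
  diff <- mean(y[g == levels(g)[i]]) - mean(y[g == levels(g)[j]])
  fstat <- diff^2 / (mse * (1 / ni + 1 / nj)) / (k - 1)
  stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
}
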