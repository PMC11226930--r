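test_that("cohort sampling reproduces the target marginals", {
  spec <- cohort_spec(n = 300, seed = 101)
  cohort <- sample_cohort(spec)
  expect_length(cohort, 300)
  ages <- vapply(cohort, function(p) p$numerical_values[["age"]], 0)
  # mean age within 3 SE of 32.81 (SD 5.754)
  expect_lt(abs(mean(ages) - 32.81), 3 * 5.754 / sqrt(300))
  expect_true(all(ages >= 22 & ages <= 60))
  # female proportion within 3 SE of 0.977 at n = 3000
  spec_big <- cohort_spec(n = 3000, seed = 102)
  sex <- vapply(sample_cohort(spec_big), function(p) p$categorical_values[["sex"]], "")
  p_f <- mean(sex == "1")
  expect_lt(abs(p_f - 0.977), 3 * sqrt(0.977 * 0.023 / 3000))
  # empty cohort
  expect_length(sample_cohort(cohort_spec(n = 0, seed = 1)), 0)
  # reproducibility
  expect_equal(sample_cohort(spec), cohort)
})

test_that("spec validation catches inconsistent inputs", {
  m <- default_marginals()
  m$sex$probs <- c("1" = 0.5, "2" = 0.4)
  expect_error(cohort_spec(marginals = m), "sum to 1")
  m2 <- default_marginals()
  m2$age$sd <- -1
  expect_error(cohort_spec(marginals = m2), "negative SD")
})

test_that("simulated responses are calibrated to the published program effects", {
  spec <- cohort_spec(n = 1, seed = 5)
  profile <- make_profile(default_schema(), "p", burnout = c(65, 60, 63))
  # zero-noise zero-mean response model leaves scores unchanged
  spec0 <- spec
  spec0$response_model <- lapply(spec$response_model, function(m) {
    list(mean = m$mean * 0, sd = m$sd * 0)
  })
  out0 <- simulate_response(profile, "act", spec0)
  expect_equal(out0$post$normalized, out0$pre$normalized)
  # reductions larger than the remaining score truncate at zero
  spec_big <- spec0
  spec_big$response_model$act$mean <- c(personal = 500, work = 500, client = 500)
  low <- make_profile(default_schema(), "low", burnout = c(3, 2, 1))
  out_t <- simulate_response(low, "act", spec_big)
  expect_equal(unname(out_t$post$normalized), c(0, 0, 0))
  # mean total reduction over many draws approaches the published value
  # (7.9 points for ACT; slack covers truncation bias plus Monte-Carlo error)
  set.seed(99)
  reductions <- replicate(4000, {
    out <- simulate_response(profile, "act", spec)
    out$pre$total - out$post$total
  })
  expect_lt(abs(mean(reductions) - 7.9), 0.4)
  expect_error(simulate_response(profile, "yoga", spec))
})

test_that("closed-loop trials are seed-reproducible and internally consistent", {
  spec <- cohort_spec(n = 25, seed = 17, heterogeneity = subgroup_heterogeneity())
  t1 <- run_closed_loop_trial(spec, policy = "similarity")
  t2 <- run_closed_loop_trial(spec, policy = "similarity")
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # KB size equals the number of stages classified valid
  expect_equal(kb_size(attr(t1, "kb")), sum(t1$valid))
  # stage-2 program never repeats stage 1 for the same participant
  s1 <- t1[t1$stage == 1, ]; s2 <- t1[t1$stage == 2, ]
  expect_true(all(s1$program[match(s2$participant_id, s1$participant_id)] !=
                    s2$program))
})

test_that("fixed and preallocated policies assign as declared", {
  spec <- cohort_spec(n = 12, seed = 23)
  tf <- run_closed_loop_trial(spec, policy = "fixed", fixed_program = "laughter")
  expect_true(all(tf$program[tf$stage == 1] == "laughter"))
  expect_true(all(tf$program[tf$stage == 2] != "laughter"))
  # preallocated (pilot) policy: stage-1 program is the cold-start map of
  # the dominant subdimension
  tp <- run_closed_loop_trial(spec, policy = "preallocated")
  cfg <- recommender_config()
  s1 <- tp[tp$stage == 1, ]
  expect_equal(s1$program, unname(cfg$cold_start_map[s1$dominant_subdimension]))
  expect_true(all(s1$cold_start))
})

test_that("replay runs a preallocated pilot before similarity optimization", {
  spec <- cohort_spec(n = 15, seed = 29)
  tr <- replay_trial(spec, n_pilot = 10)
  pilot <- tr[tr$phase == "pilot", ]
  expect_equal(length(unique(pilot$participant_id)), 10)
  expect_true(all(pilot$cold_start))
  main <- tr[tr$phase == "optimization", ]
  expect_equal(length(unique(main$participant_id)), 15)
  expect_equal(kb_size(attr(tr, "kb")), sum(tr$valid))
  # bit-identical under the same seed
  tr2 <- replay_trial(spec, n_pilot = 10)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("dropout removes second stages at the configured rate", {
  spec <- cohort_spec(n = 200, seed = 31, dropout = 0.5)
  tr <- run_closed_loop_trial(spec, policy = "random")
  n2 <- sum(tr$stage == 2)
  expect_equal(sum(tr$stage == 1), 200)
  expect_lt(abs(n2 / 200 - 0.5), 3 * sqrt(0.25 / 200))
})
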