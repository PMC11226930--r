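test_that("element dissimilarities follow the match and range-scaling rules", {
  # categorical: 0 on match, 1 on mismatch, codes are opaque labels
  expect_equal(categorical_element_dissimilarity(1, 3), 1)
  expect_equal(categorical_element_dissimilarity("c", "c"), 0)
  expect_equal(categorical_element_dissimilarity("ICU", "general ward"), 1)
  expect_error(categorical_element_dissimilarity("1", "9", codes = c("1", "2")),
               "outside allowed set")
  # numerical: |a-b|/R, clipped
  expect_equal(numerical_element_dissimilarity(45, 45, 38), 0)
  expect_equal(numerical_element_dissimilarity(3, 5, 4), 0.5)
  expect_equal(numerical_element_dissimilarity(4, 5, 4), 0.25)
  expect_equal(numerical_element_dissimilarity(0, 100, 10), 1) # clipped
  expect_error(numerical_element_dissimilarity(1, 2, 0), "R must be > 0")
  # degenerate variable behaves categorically
  expect_equal(numerical_element_dissimilarity(3, 3, 0, degenerate = TRUE), 0)
  expect_equal(numerical_element_dissimilarity(3, 4, 0, degenerate = TRUE), 1)
})

test_that("worked-example element contributions are reproduced", {
  # marital-status codes 1 vs 3 -> 1; age 45 vs 45 -> 0.00;
  # hospital-size codes (3,5) and (4,5) on the 1-5 code range -> 0.50, 0.25
  expect_equal(categorical_element_dissimilarity("1", "3"), 1)
  sch <- default_schema()
  v <- sch$variables
  r_hosp <- v$range[v$name == "hospital_size"]
  expect_equal(r_hosp, 4)
  expect_equal(numerical_element_dissimilarity(45, 45, v$range[v$name == "age"]), 0)
  expect_equal(numerical_element_dissimilarity(3, 5, r_hosp), 0.5)
  expect_equal(numerical_element_dissimilarity(4, 5, r_hosp), 0.25)
  # age range 22-60 reproduces the printed age contributions at 2 dp
  r_age <- v$range[v$name == "age"]
  expect_equal(round(numerical_element_dissimilarity(30, 45, r_age), 2), 0.39)
  expect_equal(round(numerical_element_dissimilarity(25, 45, r_age), 2), 0.53)
  # clinical-experience band 1-6 reproduces 0.40 / 0.40 / 0.20... (codes 1,2 vs 3)
  r_exp <- v$range[v$name == "clinical_experience"]
  expect_equal(numerical_element_dissimilarity(1, 3, r_exp), 0.4)
  expect_equal(numerical_element_dissimilarity(2, 3, r_exp), 0.2)
})

test_that("profile dissimilarity matches a brute-force oracle on random schemas", {
  set.seed(42)
  for (rep in 1:25) {
    sch <- random_schema(sample(1:3, 1), sample(1:3, 1))
    p <- random_profile(sch, "p")
    q <- random_profile(sch, "q")
    got <- profile_dissimilarity(p, q, sch)
    expect_equal(got$total, oracle_dissimilarity(p, q, sch))
    expect_equal(got$total, sum(got$per_element))
    # symmetry and bounds
    expect_equal(profile_dissimilarity(q, p, sch)$total, got$total)
    expect_true(all(got$per_element >= 0 & got$per_element <= 1))
    expect_true(got$total >= 0 && got$total <= nrow(sch$variables))
    # identity
    expect_equal(profile_dissimilarity(p, p, sch)$total, 0)
  }
})

test_that("identical profiles have zero dissimilarity and extremes attain the bound", {
  sch <- default_schema()
  p <- make_profile(sch, "a", burnout = c(45, 40, 39))
  expect_equal(profile_dissimilarity(p, p, sch)$total, 0)
  pair <- extreme_profile_pair(sch)
  expect_equal(profile_dissimilarity(pair$low, pair$high, sch)$total, 22)
  # stage-2 subset bound equals its variable count
  expect_equal(profile_dissimilarity(pair$low, pair$high, sch, stage = 2)$total,
               sum(sch$variables$stage2))
})

test_that("out-of-range values are clipped with a warning, not rejected", {
  sch <- load_schema(list(variables = list(
    list(name = "x", kind = "numerical", min = 0, max = 10)
  )))
  p <- participant_profile(sch, "p", character(0), c(x = 0))
  q <- participant_profile(sch, "q", character(0), c(x = 10))
  q$numerical_values[["x"]] <- 50 # corrupt after validation
  expect_warning(d <- profile_dissimilarity(p, q, sch), "clipped")
  expect_equal(d$total, 1)
})

test_that("rank_records orders ascending with insertion-order tie-breaks", {
  sch <- default_schema()
  kb <- knowledge_base(sch)
  # three stored users at graded distances from the probe
  probe <- make_profile(sch, "new", burnout = c(50, 50, 50))
  mk <- function(id, age) {
    valid_record(make_profile(sch, id, burnout = c(50, 50, 50),
                              overrides = list(age = age)),
                 "act", "work", 6)
  }
  kb <- update_knowledge_base(kb, list(mk("far", 60), mk("near", 31), mk("mid", 50)))
  r <- rank_records(kb, probe)
  expect_equal(r$participant_id, c("near", "mid", "far"))
  expect_equal(r$dissimilarity, sort(r$dissimilarity))
  # equal totals -> earliest insertion first (duplicate of "near")
  kb <- update_knowledge_base(kb, mk("near_twin", 31))
  r2 <- rank_records(kb, probe)
  expect_equal(r2$participant_id[1:2], c("near", "near_twin"))
  expect_equal(r2$insertion_index[1:2], sort(r2$insertion_index[1:2]))
  # ranking agrees with a brute-force scan
  oracle <- vapply(kb$records, function(rec) {
    oracle_dissimilarity(rec$profile, probe, sch)
  }, 0)
  expect_equal(r2$dissimilarity, sort(oracle))
  # single candidate
  kb1 <- update_knowledge_base(knowledge_base(sch), mk("only", 40))
  expect_equal(rank_records(kb1, probe)$participant_id, "only")
  # empty candidate set signals cold start rather than erroring
  r0 <- rank_records(knowledge_base(sch), probe)
  expect_equal(nrow(r0), 0)
  expect_true(attr(r0, "cold_start"))
  r_f <- rank_records(kb, probe, candidate_filter = function(rec) FALSE)
  expect_true(attr(r_f, "cold_start"))
})

test_that("vectorized ranking equals the per-profile dissimilarity path", {
  sch <- default_schema()
  set.seed(7)
  kb <- random_kb(sch, 15)
  probe <- make_profile(sch, "probe", burnout = runif(3, 0, 100))
  for (stage in 1:2) {
    r <- rank_records(kb, probe, stage = stage)
    direct <- vapply(r$insertion_index, function(i) {
      profile_dissimilarity(kb$records[[i]]$profile, probe, sch,
                            stage = if (stage == 2) 2 else NULL)$total
    }, 0)
    expect_equal(r$dissimilarity, direct)
  }
})
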