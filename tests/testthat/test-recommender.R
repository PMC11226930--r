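test_that("dominant subdimension uses the fixed tie priority", {
  expect_equal(dominant_subdimension(c(personal = 50, work = 70, client = 60)),
               "work")
  # work/client tied at the maximum -> work
  expect_equal(dominant_subdimension(c(personal = 10, work = 70, client = 70)),
               "work")
  expect_equal(dominant_subdimension(c(personal = 50, work = 50, client = 50)),
               "work")
  # configurable priority
  expect_equal(dominant_subdimension(c(personal = 50, work = 50, client = 50),
                                     priority = c("client", "work", "personal")),
               "client")
})

test_that("cold-start allocation maps subdimensions and honors exclusions", {
  cfg <- recommender_config()
  expect_equal(cold_start_allocation("personal", config = cfg), "mindfulness")
  expect_equal(cold_start_allocation("work", config = cfg), "storytelling")
  expect_equal(cold_start_allocation("client", config = cfg), "act")
  # excluded mapped program -> first non-excluded in fallback order
  expect_equal(cold_start_allocation("personal", excluded = "mindfulness",
                                     config = cfg), "laughter")
  expect_equal(cold_start_allocation("personal",
                                     excluded = c("mindfulness", "laughter"),
                                     config = cfg), "storytelling")
  expect_error(cold_start_allocation("personal",
                                     excluded = burnout_programs()),
               "all programs are excluded")
})

test_that("stage-1 recommendation filters by dominant subdimension then ranks", {
  sch <- default_schema()
  kb <- knowledge_base(sch)
  new <- make_profile(sch, "new", burnout = c(40, 70, 50)) # dominant work

  # empty KB -> cold start through the map
  rec0 <- recommend_stage1(kb, new)
  expect_true(rec0$cold_start)
  expect_equal(rec0$program, "storytelling")

  # single record -> that record's program regardless of subdimension
  kb1 <- update_knowledge_base(kb, valid_record(
    make_profile(sch, "r1", burnout = c(80, 20, 20)), "laughter", "personal", 7))
  rec1 <- recommend_stage1(kb1, new)
  expect_false(rec1$cold_start)
  expect_equal(rec1$program, "laughter")

  # matching record wins over a closer non-matching one
  kb2 <- update_knowledge_base(kb1, valid_record(
    make_profile(sch, "r2", burnout = c(40, 70, 50)), "act", "work", 6))
  rec2 <- recommend_stage1(kb2, new)
  expect_equal(rec2$program, "act")
  expect_equal(rec2$matched_record$profile$participant_id, "r2")
  expect_equal(rec2$dissimilarity, 0)
})

test_that("adding a strictly closer eligible record changes the match to it", {
  sch <- default_schema()
  set.seed(21)
  new <- make_profile(sch, "new", burnout = c(30, 80, 40))
  kb <- update_knowledge_base(knowledge_base(sch), valid_record(
    make_profile(sch, "far", burnout = c(20, 90, 60),
                 overrides = list(age = 55)), "mindfulness", "work", 6))
  before <- recommend_stage1(kb, new)
  expect_equal(before$program, "mindfulness")
  kb <- update_knowledge_base(kb, valid_record(
    make_profile(sch, "close", burnout = c(30, 80, 40)), "laughter", "work", 8))
  after <- recommend_stage1(kb, new)
  expect_equal(after$program, "laughter")
  expect_lt(after$dissimilarity, before$dissimilarity)
})

test_that("stage-2 recommendation never repeats the stage-1 program", {
  sch <- default_schema()
  new <- make_profile(sch, "new", burnout = c(40, 70, 50),
                      assessment_point = "posttest1")
  # nearest matching record took program1: next-nearest different program wins
  kb <- update_knowledge_base(knowledge_base(sch), list(
    valid_record(make_profile(sch, "r1", burnout = c(40, 70, 50)),
                 "act", "work", 6),
    valid_record(make_profile(sch, "r2", burnout = c(45, 65, 50)),
                 "mindfulness", "work", 6)
  ))
  rec <- recommend_stage2(kb, new, program1 = "act")
  expect_equal(rec$program, "mindfulness")
  # eligible set empty -> cold start over the remaining three
  kb_only <- update_knowledge_base(knowledge_base(sch), valid_record(
    make_profile(sch, "r1", burnout = c(40, 70, 50)), "act", "work", 6))
  rec2 <- recommend_stage2(kb_only, new, program1 = "act")
  expect_true(rec2$cold_start)
  expect_false(rec2$program == "act")
  # stage-2 cold start with the mapped program excluded
  rec3 <- recommend_stage2(knowledge_base(sch), new, program1 = "storytelling")
  expect_true(rec3$cold_start)
  expect_equal(rec3$program, "laughter") # fallback order head
})

test_that("knowledge-base updates are append-only and reject duplicates", {
  sch <- default_schema()
  set.seed(33)
  kb <- random_kb(sch, 10)
  before_ids <- vapply(kb$records, function(r) r$profile$participant_id, "")
  rec <- valid_record(make_profile(sch, "extra", burnout = c(60, 50, 40)),
                      "laughter", "personal", 9)
  kb2 <- update_knowledge_base(kb, rec)
  expect_equal(kb_size(kb2), 11)
  expect_equal(vapply(kb2$records[1:10], function(r) r$profile$participant_id, ""),
               before_ids)
  expect_equal(vapply(kb2$records, function(r) r$insertion_index, 0L), 1:11)
  # appending nothing is the identity
  expect_equal(update_knowledge_base(kb, list()), kb)
  # duplicate (participant, assessment point) rejected
  expect_error(update_knowledge_base(kb2, rec), "duplicate record")
  # records failing the validity invariant cannot be constructed
  expect_error(valid_record(make_profile(sch, "x"), "act", "work", 4.9),
               "at least 5")
})

test_that("audit report is consistent with the recommendation and its bounds", {
  sch <- default_schema()
  set.seed(8)
  kb <- random_kb(sch, 5)
  new <- make_profile(sch, "new", burnout = c(30, 80, 40))
  audit <- audit_recommendation(kb, new, stage = 1)
  expect_equal(nrow(audit), 5)
  rec <- attr(audit, "recommendation")
  # top eligible-and-matching row (or top eligible row if none match)
  elig <- audit[audit$eligible, ]
  top <- if (any(elig$matches_subdimension)) {
    elig[elig$matches_subdimension, ][1, ]
  } else {
    elig[1, ]
  }
  expect_equal(rec$program, top$program)
  expect_equal(rec$dissimilarity, top$dissimilarity)
  # per-element columns lie in [0,1] and sum to the total
  dcols <- grep("^d_", names(audit), value = TRUE)
  expect_length(dcols, 22)
  expect_true(all(audit[dcols] >= 0 & audit[dcols] <= 1))
  expect_equal(rowSums(audit[dcols]), audit$dissimilarity)
  expect_true(all(audit$dissimilarity >= 0 & audit$dissimilarity <= 22))
})

test_that("recommendation is deterministic for identical inputs", {
  sch <- default_schema()
  set.seed(13)
  kb <- random_kb(sch, 12)
  new <- make_profile(sch, "new", burnout = c(70, 20, 60))
  r1 <- recommend_stage1(kb, new)
  r2 <- recommend_stage1(kb, new)
  expect_identical(r1, r2)
})
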