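test_that("exactly 36 facet addresses exist and are structurally comparable", {
  keys <- facet_addresses()
  expect_length(keys, 36L)
  expect_false(anyDuplicated(keys) > 0)
  a <- facet_address("structure", 1, "intrinsic", "formal_system")
  b <- as_facet_address("S1.intrinsic.formal_system")
  expect_identical(a, b)
  expect_error(facet_address("structure", 1, "intrinsic", "entities"),
               "not valid")
  expect_error(as_facet_address("S4.intrinsic.x"))
})

test_that("an empty record yields one error and 36 gaps; intrinsic-only records are invalid", {
  iss <- validate(facet_record("m"))
  sev <- issue_severities(iss)
  expect_equal(sum(sev == "error"), 1L)
  expect_equal(sum(sev == "gap"), 36L)
  expect_match(iss[[which(sev == "error")]]$message, "extrinsic")

  r <- facet_record("m", slots = list(
    facet_slot("S2.intrinsic.entities", text = "x"),
    facet_slot("S3.intrinsic.programme", text = "y")))
  iss2 <- validate(r)
  expect_true(any(issue_severities(iss2) == "error"))

  r3 <- set_slot(r, facet_slot("S1.extrinsic.biological_system", text = "frog"))
  iss3 <- validate(r3)
  expect_false(any(issue_severities(iss3) == "error"))
})

test_that("structured payloads are only accepted at their home address", {
  setup <- simulation_setup(0, 10, 0.1)
  ok <- facet_record("m", slots = list(
    facet_slot("F3.intrinsic.setup",
               structured = list(type = "simulation_setup", value = setup)),
    facet_slot("S1.extrinsic.biological_system", text = "x")))
  expect_false(any(issue_severities(validate(ok)) == "error"))

  bad <- facet_record("m", slots = list(
    facet_slot("B3.intrinsic.outcome",
               structured = list(type = "simulation_setup", value = setup)),
    facet_slot("S1.extrinsic.biological_system", text = "x")))
  issb <- validate(bad)
  expect_true(any(grepl("not allowed", vapply(issb, `[[`, character(1),
                                              "message"))))
})

test_that("coverage counts (cell, side) combinations and is monotone in filling", {
  r <- facet_record("m")
  expect_equal(sum(coverage(r)$cells$covered), 0L)
  r <- set_slot(r, facet_slot("S2.intrinsic.entities", text = "x"))
  cov1 <- coverage(r)
  expect_equal(sum(cov1$cells$covered), 1L)
  set.seed(3)
  for (k in sample(facet_addresses(), 10)) {
    covered_before <- cov1$cells$covered
    r <- set_slot(r, facet_slot(k, text = "y"))
    cov1 <- coverage(r)
    expect_true(all(cov1$cells$covered >= covered_before))
  }
})

test_that("gap issues and uncovered aspects agree between validate and coverage", {
  for (seed in 1:5) {
    r <- random_record(seed)
    iss <- validate(r)
    gaps <- sort(issue_addresses(iss)[issue_severities(iss) == "gap"])
    expect_equal(gaps, sort(coverage(r)$gaps))
  }
})

test_that("completeness questions cover exactly the unfilled aspects", {
  q <- completeness_questions(facet_record("m"))
  expect_equal(nrow(q), 36L)
  expect_match(q$question[q$address == "S1.intrinsic.formal_system"],
               "formal system")
  full <- facet_record("m", slots = lapply(facet_addresses(), facet_slot,
                                           text = "filled"))
  expect_equal(nrow(completeness_questions(full)), 0L)
  near <- facet_record("m", slots = lapply(
    setdiff(facet_addresses(),
            c("F1.extrinsic.questions", "F1.extrinsic.assumptions")),
    facet_slot, text = "filled"))
  qn <- completeness_questions(near)
  expect_setequal(qn$address, c("F1.extrinsic.questions",
                                "F1.extrinsic.assumptions"))
  expect_true(any(grepl("questions", qn$question)))
  expect_true(any(grepl("assumptions", qn$question)))
})

test_that("facet records survive serialization for arbitrary slot fills", {
  for (seed in 1:8) {
    r <- random_record(seed)
    f <- withr::local_tempfile(fileext = ".yaml")
    write_facet_record(r, f)
    r2 <- read_facet_record(f)
    expect_equal(r2$model_id, r$model_id)
    expect_setequal(names(r2$slots), names(r$slots))
    for (k in names(r$slots)) {
      expect_identical(r2$slots[[k]]$text, r$slots[[k]]$text)
      expect_equal(lapply(r2$slots[[k]]$annotations, unclass),
                   lapply(r$slots[[k]]$annotations, unclass))
    }
    expect_equal(r2$meta$origin$publication_id, r$meta$origin$publication_id)
    expect_equal(length(r2$meta$relations), length(r$meta$relations))
    # a second write is byte-identical (stable key order)
    f2 <- withr::local_tempfile(fileext = ".yaml")
    write_facet_record(r2, f2)
    expect_identical(readLines(f2), readLines(f))
  }
})

test_that("the relation vocabulary is closed", {
  expect_error(global_meta(relations = list(
    list(other_model_id = "x", relation_type = "inspired_by"))),
    "relation_type")
})
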