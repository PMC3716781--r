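test_that("the two cell-cycle records share the mitotic cell-cycle annotation", {
  rep <- compare_structure(bundle1()$record, bundle2()$record)
  s1 <- rep$cells[["S1.extrinsic"]]
  expect_true("obo.go:GO:0000278" %in% s1$shared)
  # the taxonomy options are specific to the Model 1 record
  expect_true("taxonomy:7625" %in% s1$source_only)
})

test_that("structural comparison is symmetric up to swapping the only-sets", {
  a <- bundle1()$record
  b <- bundle2()$record
  ab <- compare_structure(a, b)
  ba <- compare_structure(b, a)
  for (nm in names(ab$cells)) {
    expect_setequal(ab$cells[[nm]]$shared, ba$cells[[nm]]$shared)
    expect_setequal(ab$cells[[nm]]$source_only, ba$cells[[nm]]$target_only)
    expect_setequal(ab$cells[[nm]]$target_only, ba$cells[[nm]]$source_only)
    expect_length(intersect(ab$cells[[nm]]$shared,
                            ab$cells[[nm]]$source_only), 0L)
  }
})

test_that("self-comparison and empty records behave as set algebra dictates", {
  a <- bundle1()$record
  self <- compare_structure(a, a)
  for (nm in names(self$cells)) {
    expect_length(self$cells[[nm]]$source_only, 0L)
    expect_length(self$cells[[nm]]$target_only, 0L)
  }
  e <- compare_structure(facet_record("x"), facet_record("y"))
  for (nm in names(e$cells)) {
    expect_length(e$cells[[nm]]$shared, 0L)
    expect_length(e$cells[[nm]]$source_only, 0L)
    expect_length(e$cells[[nm]]$target_only, 0L)
  }
})

test_that("behavioural class-set relations follow set algebra", {
  expect_equal(compare_behaviour(character(), character()), "equal")
  expect_equal(compare_behaviour("stable_fixed_point",
                                 c("stable_fixed_point",
                                   "limit_cycle_oscillation")), "subset")
  expect_equal(compare_behaviour(c("a", "b"), "a"), "superset")
  expect_equal(compare_behaviour("a", "b"), "disjoint")
  expect_equal(compare_behaviour(c("a", "b"), c("b", "c")), "overlapping")
  set.seed(21)
  pool <- letters[1:5]
  for (i in 1:50) {
    a <- sample(pool, sample(0:4, 1))
    b <- sample(pool, sample(0:4, 1))
    rel <- compare_behaviour(a, b)
    expect_equal(rel == "equal", setequal(a, b))
    if (rel == "subset") expect_true(all(a %in% b) && !setequal(a, b))
    if (rel == "superset") expect_true(all(b %in% a) && !setequal(a, b))
    if (rel == "disjoint") expect_length(intersect(a, b), 0L)
    if (rel == "overlapping") {
      expect_gt(length(intersect(a, b)), 0L)
      expect_false(all(a %in% b) || all(b %in% a))
    }
  }
})

test_that("both models exhibit the same set of dynamics classes", {
  labels1 <- names(bundle1()$regime_points)
  labels2 <- names(bundle2()$regime_points)
  expect_equal(compare_behaviour(labels1, labels2), "equal")
})

test_that("the identity mapping on a model against itself has zero deviation", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$limit_cycle_oscillation)
  rep <- check_abstraction(inst, inst,
                           variable_mapping(list(u = quote(u), v = quote(v))),
                           simulation_setup(0, 40, 0.1), tolerance = 1e-12)
  expect_equal(rep$verdict, "consistent")
  expect_equal(max(rep$deviation$max), 0)
})

test_that("the six-variable model maps onto its two-variable abstraction within the pinned tolerance", {
  ap <- abstraction_pair()
  src <- instantiate(ap$source_model, ap$source_inst)
  tgt <- instantiate(ap$target_model, ap$target_inst)
  rep <- check_abstraction(src, tgt, ap$mapping, ap$setup, ap$tolerance)
  expect_true(all(is.finite(rep$deviation$max)))
  expect_true(all(rep$deviation$max >= 0))
  expect_equal(rep$verdict, "consistent")
  # deterministic: rerunning reproduces the deviations exactly
  rep2 <- check_abstraction(src, tgt, ap$mapping, ap$setup, ap$tolerance)
  expect_identical(rep$deviation, rep2$deviation)
})

test_that("mappings referencing unknown symbols are rejected", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$stable_fixed_point)
  expect_error(check_abstraction(
    inst, inst, variable_mapping(list(u = quote(ghost + 1))),
    simulation_setup(0, 5, 0.5), 1), "ghost")
  expect_error(check_abstraction(
    inst, inst, variable_mapping(list(nosuch = quote(u))),
    simulation_setup(0, 5, 0.5), 1), "nosuch")
})
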