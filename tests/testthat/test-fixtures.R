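test_that("Model 1 reconstructs with six state equations and the printed metadata", {
  b1 <- bundle1()
  prog <- build_programme(b1$model)
  expect_length(prog$state_symbols, 6L)
  expect_setequal(prog$state_symbols, c("C2", "CP", "pM", "M", "Y", "YP"))
  expect_equal(b1$record$meta$origin$publication_id, "1831270")
  expect_equal(b1$record$meta$origin$authors, "John J. Tyson")
  expect_match(b1$record$meta$access[[1]]$location, "BIOMD0000000005")
  rel <- b1$record$meta$relations[[1]]
  expect_equal(rel$other_model_id, "tyson1991-model2")
  expect_equal(rel$relation_type, "abstraction")
})

test_that("Model 2 reconstructs with two states and its lineage relations", {
  b2 <- bundle2()
  prog <- build_programme(b2$model)
  expect_length(prog$state_symbols, 2L)
  rels <- b2$record$meta$relations
  others <- vapply(rels, `[[`, character(1), "other_model_id")
  types <- vapply(rels, `[[`, character(1), "relation_type")
  expect_true("tyson1991-model1" %in% others)
  expect_equal(types[others == "Brusselator"], "modified_version_of")
  expect_match(b2$record$meta$access[[1]]$location, "BIOMD0000000006")
})

test_that("the Model 1 record validates with exactly the documented gaps", {
  iss <- validate(bundle1()$record)
  sev <- issue_severities(iss)
  expect_equal(sum(sev == "error"), 0L)
  gaps <- issue_addresses(iss)[sev == "gap"]
  expect_setequal(gaps, c("F2.extrinsic.initial_state",
                          "F3.extrinsic.experimental_settings",
                          "F3.extrinsic.result_calculation",
                          "B2.extrinsic.measurements",
                          "B2.extrinsic.key",
                          "B3.extrinsic.results"))
  cov <- coverage(bundle1()$record)
  by_side <- tapply(cov$cells$covered, cov$cells$side, sum)
  expect_lt(by_side[["extrinsic"]], by_side[["intrinsic"]])
})

test_that("the packaged records carry the printed cross-references", {
  rec <- bundle1()$record
  keyset <- function(key) vapply(rec$slots[[key]]$annotations,
                                 function(a) paste0(a$namespace, ":", a$identifier),
                                 character(1))
  expect_true("uniprot:P04551" %in% keyset("S2.extrinsic.objects"))
  expect_true("biomodels.sbo:SBO:0000252" %in% keyset("S2.extrinsic.objects"))
  expect_true("biomodels.sbo:SBO:0000472" %in% keyset("S2.extrinsic.quantities"))
  expect_true(all(c("biomodels.sbo:SBO:0000180", "reactome:REACT_6308") %in%
                    keyset("S3.extrinsic.interactions")))
  expect_true("biomodels.sbo:SBO:0000012" %in% keyset("S3.extrinsic.mechanisms"))
  expect_true("biomodels.sbo:SBO:0000293" %in% keyset("S1.intrinsic.formalism"))
  expect_true(all(c("taxonomy:7625", "taxonomy:33511", "taxonomy:6072",
                    "obo.go:GO:0000278") %in%
                    keyset("S1.extrinsic.biological_system")))
  expect_true("cl:CL:0000007" %in% keyset("F2.extrinsic.boundary_conditions"))
  expect_true("kisao:KISAO_0000280" %in% keyset("F3.intrinsic.setup"))
  expect_true("teddy:TEDDY_0000113" %in% keyset("B1.intrinsic.dynamics"))
  expect_true("teddy:TEDDY_0000074" %in% keyset("B1.intrinsic.diversification"))
})

test_that("regime points classify to their keys for both models", {
  for (b in list(bundle2(), bundle1())) {
    protocol <- default_protocol(b$model)
    for (lb in names(b$regime_points)) {
      res <- classify(instantiate(b$model, b$regime_points[[lb]]), protocol)
      expect_equal(res$class$label, lb, label = paste(b$model$id, lb))
    }
  }
})

test_that("the regime finder is deterministic and fails informatively on impossible targets", {
  b2 <- bundle2()
  i1 <- find_regime_parameters(b2$model, "stable_fixed_point", seed = 77L)
  i2 <- find_regime_parameters(b2$model, "stable_fixed_point", seed = 77L)
  expect_identical(i1$parameter_values, i2$parameter_values)
  # a spec collapsed onto a single stable point cannot yield an oscillation
  p <- i1$parameter_values
  collapsed <- list(bounds = lapply(p, identity), n = 3L,
                    initial_values = i1$initial_values)
  expect_error(
    find_regime_parameters(b2$model, "limit_cycle_oscillation",
                           spec = collapsed, seed = 1L),
    "exhausted.*stable_fixed_point")
})

test_that("exported fixture documents parse back with their content intact", {
  dir <- withr::local_tempdir()
  paths <- export_fixtures(dir)
  expect_true(all(file.exists(paths)))
  m1 <- read_sbml(file.path(dir, "tyson1991-model1.sbml.xml"))$model
  expect_length(build_programme(m1)$state_symbols, 6L)
  rec <- read_facet_record(file.path(dir, "tyson1991-model1.record.yaml"))
  expect_equal(rec$model_id, "tyson1991-model1")
  sed <- read_sedml_lite(file.path(dir, "tyson1991-model1.fig3a.sedml.xml"))
  expect_equal(sed$setup$algorithm$identifier, "KISAO_0000280")
  doc <- read_dyml(file.path(dir, "tyson1991-model2.dyml.yaml"))
  expect_equal(doc$model_ref, "tyson1991-model2")
  expect_gt(length(doc$statements), 0L)
})

test_that("fixture SBML round-trips preserve programme semantics", {
  for (b in list(bundle1(), bundle2())) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(b$model, b$record, f)
    m2 <- read_sbml(f)$model
    p1 <- build_programme(b$model)
    p2 <- build_programme(m2)
    inst <- b$regime_points$stable_fixed_point
    set.seed(31)
    for (i in 1:10) {
      st <- c(setNames(runif(length(p1$state_symbols), 0.05, 1.5),
                       p1$state_symbols),
              unlist(inst$parameter_values))
      e1 <- semfacets:::programme_eval_env(p1, st)
      e2 <- semfacets:::programme_eval_env(p2, st)
      for (s in p1$state_symbols)
        expect_equal(eval(p2$rhs[[s]], e2), eval(p1$rhs[[s]], e1),
                     tolerance = 1e-12)
    }
  }
})
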