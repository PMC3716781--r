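test_that("the packaged six-ODE model round-trips through SBML", {
  b1 <- bundle1()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(b1$model, b1$record, f)
  rr <- read_sbml(f)
  m <- rr$model
  expect_length(m$species, 8L)
  expect_setequal(model_species_ids(m),
                  c("C2", "CP", "pM", "M", "Y", "YP", "AP", "aa"))
  expect_length(m$reactions, 9L)
  # boundary pools keep their marking
  const <- vapply(m$species, `[[`, logical(1), "constant")
  expect_setequal(model_species_ids(m)[const], c("AP", "aa"))
  # C2 carries the UniProt cross-reference, harvested into S2-extrinsic
  anns <- rr$record$slots[["S2.extrinsic.objects"]]$annotations
  keys <- vapply(anns, function(a) paste0(a$namespace, ":", a$identifier),
                 character(1))
  expect_true("uniprot:P04551" %in% keys)
  # derived programme is unchanged by the round trip
  p1 <- build_programme(b1$model)
  p2 <- build_programme(m)
  params <- list(k1 = 0.02, k2 = 0.01, k3 = 200, k4 = 150, k4p = 0.02,
                 k5 = 0.01, k6 = 1, k7 = 0.6, k8 = 1000, k9 = 10)
  set.seed(5)
  for (i in 1:20) {
    st <- c(setNames(runif(6, 0.05, 2), p1$state_symbols),
            AP = 1, aa = 1, unlist(params))
    for (s in p1$state_symbols) {
      e1 <- semfacets:::programme_eval_env(p1, st)
      e2 <- semfacets:::programme_eval_env(p2, st)
      expect_equal(eval(p2$rhs[[s]], e2), eval(p1$rhs[[s]], e1),
                   tolerance = 1e-12)
    }
  }
})

test_that("the derived Model 1 programme equals the printed six equations", {
  prog <- build_programme(bundle1()$model)
  printed <- list(
    C2 = quote(k6 * M - k8 * AP * C2 + k9 * CP),
    CP = quote(-k3 * CP * Y + k8 * AP * C2 - k9 * CP),
    pM = quote(k3 * CP * Y - pM * (k4p + k4 * (M / (C2 + CP + pM + M))^2) +
                 k5 * AP * M),
    M  = quote(pM * (k4p + k4 * (M / (C2 + CP + pM + M))^2) - k5 * AP * M -
                 k6 * M),
    Y  = quote(k1 * aa - k2 * Y - k3 * CP * Y),
    YP = quote(k6 * M - k7 * YP))
  params <- list(k1 = 0.015, k2 = 0.01, k3 = 180, k4 = 120, k4p = 0.018,
                 k5 = 0.02, k6 = 1.2, k7 = 0.6, k8 = 900, k9 = 15,
                 AP = 1, aa = 1)
  defs <- prog$algebraic[prog$algebraic_order]
  for (s in names(printed)) {
    expect_true(expr_equal_numeric(
      prog$rhs[[s]], printed[[s]],
      symbols = prog$state_symbols, n = 100, tol = 1e-9, seed = 17,
      defs = defs, params = params))
  }
})

test_that("the two-variable model matches its printed equations and record", {
  b2 <- bundle2()
  prog <- build_programme(b2$model)
  expect_length(prog$state_symbols, 2L)
  printed_du <- quote(k4 * (v - u) * (k4p / k4 + u^2) - k6 * u)
  printed_dv <- quote(r_syn - k6 * u)
  params <- list(k4 = 200, k4p = 0.02, k6 = 1.3, r_syn = 0.015)
  defs <- prog$algebraic[prog$algebraic_order]
  expect_true(expr_equal_numeric(prog$rhs$u, printed_du, c("u", "v"),
                                 seed = 3, defs = defs, params = params))
  expect_true(expr_equal_numeric(prog$rhs$v, printed_dv, c("u", "v"),
                                 seed = 3, defs = defs, params = params))
  # on the diagonal u = v the activation term vanishes: du/dt = -k6 u
  env <- list2env(c(list(u = 0.4, v = 0.4), params))
  assign("alpha", eval(prog$algebraic$alpha, env), env)
  expect_equal(eval(prog$rhs$u, env), -params$k6 * 0.4)
})

test_that("random models survive the SBML round trip", {
  for (seed in 1:6) {
    m <- random_model(seed)
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, NULL, f)
    m2 <- read_sbml(f)$model
    expect_equal(model_species_ids(m2), model_species_ids(m))
    expect_equal(m2$parameters[order(names(m2$parameters))],
                 m$parameters[order(names(m$parameters))])
    set.seed(seed + 50)
    st <- setNames(runif(length(m$species), 0.05, 2),
                   vapply(m$species, `[[`, character(1), "id"))
    p1 <- build_programme(m); p2 <- build_programme(m2)
    e1 <- semfacets:::programme_eval_env(p1, st)
    e2 <- semfacets:::programme_eval_env(p2, st)
    for (s in p1$state_symbols)
      expect_equal(eval(p2$rhs[[s]], e2), eval(p1$rhs[[s]], e1),
                   tolerance = 1e-12)
  }
})

test_that("unsupported constructs raise explicit errors instead of misparsing", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfEvents><event/></listOfEvents></model></sbml>'), f)
  expect_error(read_sbml(f), "listOfEvents")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfRules><rateRule variable="x"/></listOfRules></model></sbml>'), f)
  expect_error(read_sbml(f), "rateRule")
  # kinetic law with an undeclared symbol is a model error naming the symbol
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies><species id="A" initialAmount="1"/></listOfSpecies>',
    '<listOfReactions><reaction id="r"><listOfReactants>',
    '<speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>kGhost</ci><ci>A</ci></apply></math></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>'), f)
  expect_error(read_sbml(f), "kGhost")
})

test_that("a zero-reaction document yields an all-zero programme", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies><species id="A" initialAmount="1"/>',
    '<species id="B" initialAmount="2"/></listOfSpecies></model></sbml>'), f)
  prog <- build_programme(read_sbml(f)$model)
  expect_equal(eval(prog$rhs$A, list(A = 1, B = 2)), 0)
  expect_equal(eval(prog$rhs$B, list(A = 1, B = 2)), 0)
})

test_that("annotations with an empty namespace are refused at serialization", {
  m <- decay_model()
  m$species[[1L]]$annotations <- list(structure(
    list(namespace = "", identifier = "X", qualifier = NULL),
    class = "sf_annotation"))
  expect_error(write_sbml(m, NULL, withr::local_tempfile(fileext = ".xml")),
               "empty namespace")
})
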