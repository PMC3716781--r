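test_that("a single dissociation reaction yields the textbook rhs", {
  m <- ode_model("mini",
    species = list(species("M", initial_amount = 1),
                   species("C2"), species("YP")),
    parameters = list(k6 = 2),
    reactions = list(reaction("R6", reactants = c(M = 1L),
                              products = c(C2 = 1L, YP = 1L),
                              kinetic_law = quote(k6 * M))))
  prog <- build_programme(m)
  st <- c(M = 0.7, C2 = 0.1, YP = 0.2)
  env <- list2env(c(as.list(st), list(k6 = 2)))
  expect_equal(eval(prog$rhs$M, env), -2 * 0.7)
  expect_equal(eval(prog$rhs$C2, env), 2 * 0.7)
  expect_equal(eval(prog$rhs$YP, env), 2 * 0.7)
})

test_that("an empty network derives an all-zero programme", {
  m <- ode_model("empty", species = list(species("A"), species("B")))
  prog <- build_programme(m)
  expect_equal(eval(prog$rhs$A, list(A = 5, B = 1)), 0)
  expect_equal(eval(prog$rhs$B, list(A = 5, B = 1)), 0)
})

test_that("programme construction matches a brute-force oracle on random networks", {
  for (seed in 1:10) {
    m <- random_model(seed)
    prog <- build_programme(m)
    set.seed(seed + 100)
    for (rep in 1:5) {
      st <- setNames(runif(length(m$species), 0.05, 2),
                     vapply(m$species, `[[`, character(1), "id"))
      want <- oracle_rhs(m, st)
      env <- list2env(c(as.list(st), m$parameters))
      got <- vapply(prog$state_symbols, function(s) eval(prog$rhs[[s]], env),
                    numeric(1))
      expect_equal(got, want[prog$state_symbols], tolerance = 1e-12)
    }
  }
})

test_that("adding a reaction adds exactly its stoichiometry-weighted law", {
  for (seed in 11:15) {
    m <- random_model(seed)
    extra <- reaction("extra", reactants = c(S1 = 1L), products = c(S2 = 2L),
                      kinetic_law = quote(p1 * S1))
    m2 <- ode_model(m$id, species = m$species, parameters = m$parameters,
                    reactions = c(m$reactions, list(extra)))
    p1v <- m$parameters$p1
    set.seed(seed)
    st <- setNames(runif(length(m$species), 0.05, 2),
                   vapply(m$species, `[[`, character(1), "id"))
    base <- oracle_rhs(m, st)
    env <- list2env(c(as.list(st), m$parameters))
    prog2 <- build_programme(m2)
    got <- vapply(prog2$state_symbols, function(s) eval(prog2$rhs[[s]], env),
                  numeric(1))
    flux <- p1v * st[["S1"]]
    want <- base
    want[["S1"]] <- want[["S1"]] - flux
    want[["S2"]] <- want[["S2"]] + 2 * flux
    expect_equal(got, want[prog2$state_symbols], tolerance = 1e-12)
  }
})

test_that("total cdc2 is conserved identically, symbolically and numerically", {
  prog <- build_programme(bundle1()$model)
  expect_identical(conserved_total_symbolic(prog, c("C2", "CP", "pM", "M")), 0)
  params <- c(k1 = 0.02, k2 = 0.01, k3 = 200, k4 = 150, k4p = 0.02,
              k5 = 0.01, k6 = 1, k7 = 0.6, k8 = 1000, k9 = 10)
  set.seed(42)
  for (i in 1:1000) {
    st <- c(setNames(runif(6, 0.01, 2), c("C2", "CP", "pM", "M", "Y", "YP")),
            params)
    expect_lt(abs(conserved_total_residual(prog, c("C2", "CP", "pM", "M"), st)),
              1e-12)
  }
  # a single member is generally not conserved
  st <- c(C2 = 0.3, CP = 0.2, pM = 0.1, M = 0.25, Y = 0.4, YP = 0.1, params)
  expect_gt(abs(conserved_total_residual(prog, "C2", st)), 1e-6)
  expect_error(conserved_total_residual(prog, "nope", st), "unknown")
})

test_that("single-species decay drift equals the closed form", {
  prog <- build_programme(decay_model(k = 0.7))
  expect_equal(conserved_total_residual(prog, "X", c(X = 1.3)), -0.7 * 1.3)
})

test_that("undeclared symbols and cyclic algebraic definitions are rejected", {
  expect_error(
    ode_model("bad", species = list(species("A")),
              reactions = list(reaction("r", reactants = c(A = 1L),
                                        kinetic_law = quote(kmiss * A)))),
    "kmiss")
  expect_error(
    ode_model("cyc", species = list(species("A")),
              algebraic = list(u = quote(w + 1), w = quote(u + 1))),
    "cyclic")
  expect_error(
    reaction("r", reactants = c(A = 1L), kinetic_law = quote(sin(A))),
    "unsupported")
})

test_that("constant species get no rate equation but stay usable in laws", {
  m <- ode_model("bnd",
    species = list(species("X"), species("E", initial_amount = 2,
                                          constant = TRUE)),
    parameters = list(k = 1),
    reactions = list(reaction("r", products = c(X = 1L), modifiers = "E",
                              kinetic_law = quote(k * E))))
  prog <- build_programme(m)
  expect_equal(prog$state_symbols, "X")
  expect_equal(eval(prog$rhs$X, list(k = 1, E = 2, X = 0)), 2)
})
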