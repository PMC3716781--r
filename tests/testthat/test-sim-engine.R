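test_that("linear decay reproduces the closed form on the output grid", {
  inst <- instantiate(decay_model(k = 1, x0 = 1))
  traj <- run_timecourse(inst, simulation_setup(0, 1, 0.5))
  expect_equal(traj$index, c(0, 0.5, 1))
  expect_equal(unname(traj$raw[, "X"]), exp(-c(0, 0.5, 1)), tolerance = 1e-6)
})

test_that("instantiation is rejected unless the system is closed and non-negative", {
  b2 <- bundle2()
  inst <- b2$regime_points$limit_cycle_oscillation
  expect_s3_class(instantiate(b2$model, inst), "sf_sim_instance")
  partial <- instantiation(
    parameter_values = inst$parameter_values[c("k4", "k4p", "r_syn")],
    initial_values = inst$initial_values)
  expect_error(instantiate(b2$model, partial), "k6")
  expect_error(instantiation(initial_values = list(u = -1)), "non-negative")
  expect_error(instantiate(b2$model, instantiation(
    parameter_values = c(inst$parameter_values, list(zz = 1)))), "zz")
})

test_that("setup invariants are enforced", {
  expect_error(simulation_setup(0, 0, 0.1), "t_end")
  expect_error(simulation_setup(0, 10, -1), "positive")
  expect_error(simulation_setup(0, 10, 20), "exceeds")
  expect_error(simulation_setup(0, 10, 0.1,
    perturbations = list(list(time = 50, symbol = "u", delta = 1))),
    "outside")
})

test_that("total cdc2 stays conserved along an integrated trajectory", {
  b1 <- bundle1()
  inst <- instantiate(b1$model, b1$regime_points$limit_cycle_oscillation)
  traj <- run_timecourse(inst, simulation_setup(0, 100, 0.1))
  total <- rowSums(traj$raw[, c("C2", "CP", "pM", "M")])
  expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
})

test_that("halving solver tolerances leaves the endpoint unchanged to 1e-6", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$limit_cycle_oscillation)
  setup <- simulation_setup(0, 50, 0.1)
  t1 <- run_timecourse(inst, setup, rtol = 1e-9, atol = 1e-9)
  t2 <- run_timecourse(inst, setup, rtol = 5e-10, atol = 5e-10)
  end1 <- t1$raw[nrow(t1$raw), ]
  end2 <- t2$raw[nrow(t2$raw), ]
  expect_lt(max(abs(end1 - end2) / pmax(abs(end1), 1e-8)), 1e-6)
})

test_that("a zero-delta perturbation leaves the trajectory bitwise unchanged", {
  inst <- instantiate(decay_model())
  plain <- run_timecourse(inst, simulation_setup(0, 2, 0.1))
  with0 <- run_timecourse(inst, simulation_setup(0, 2, 0.1,
    perturbations = list(list(time = 1, symbol = "X", delta = 0))))
  expect_identical(with0$raw, plain$raw)
  # a real perturbation is an instantaneous increment at its time
  kicked <- run_timecourse(inst, simulation_setup(0, 2, 0.1,
    perturbations = list(list(time = 1, symbol = "X", delta = 0.5))))
  i <- match(1, kicked$index)
  expect_gt(kicked$raw[i + 1L, "X"], plain$raw[i + 1L, "X"] + 0.4)
})

test_that("postprocess is pointwise and leaves raw data untouched", {
  b1 <- bundle1()
  inst <- instantiate(b1$model, b1$regime_points$limit_cycle_oscillation)
  traj <- run_timecourse(inst, simulation_setup(0, 60, 0.2))
  out <- postprocess(traj, b1$model, list(
    M_over_CT = quote(M / CT),
    YT_over_CT = quote(YT / CT),
    M_identity = quote(M)))
  expect_identical(out$raw, traj$raw)
  expect_true(all(out$outcome[, "M_over_CT"] >= 0 &
                  out$outcome[, "M_over_CT"] <= 1))
  expect_true(all(is.finite(out$outcome[, "YT_over_CT"])))
  expect_identical(unname(out$outcome[, "M_identity"]),
                   unname(traj$raw[, "M"]))
  # pointwise: permuting rows permutes outcomes identically
  set.seed(9)
  perm <- sample(nrow(traj$raw))
  traj_p <- traj
  traj_p$raw <- traj$raw[perm, , drop = FALSE]
  traj_p$index <- traj$index[perm]
  out_p <- postprocess(traj_p, b1$model, list(M_over_CT = quote(M / CT)))
  expect_equal(unname(out_p$outcome[, 1]),
               unname(out$outcome[perm, "M_over_CT"]))
  expect_error(postprocess(traj, b1$model, list(bad = quote(Q / CT))), "Q")
})

test_that("SED-ML-lite documents round-trip and reject non-time-course types", {
  for (seed in 1:5) {
    set.seed(seed)
    setup <- simulation_setup(
      t_start = 0, t_end = runif(1, 10, 200), step = runif(1, 0.01, 1),
      algorithm = annotation("kisao", sprintf("KISAO_%07d", sample(999, 1))),
      perturbations = if (seed %% 2) list(list(time = 5, symbol = "u",
                                               delta = runif(1))) else list(),
      postprocess = list(ratio = quote(u / v)))
    ov <- instantiation(parameter_values = list(k4 = runif(1, 1, 100)),
                        initial_values = list(u = runif(1)))
    f <- withr::local_tempfile(fileext = ".xml")
    write_sedml_lite(setup, ov, f)
    back <- read_sedml_lite(f)
    expect_equal(back$setup$t_end, setup$t_end)
    expect_equal(back$setup$step, setup$step)
    expect_equal(back$setup$algorithm$identifier, setup$algorithm$identifier)
    expect_equal(back$setup$perturbations, setup$perturbations)
    expect_equal(lapply(back$setup$postprocess, deparse1),
                 lapply(setup$postprocess, deparse1))
    expect_equal(back$overrides$parameter_values, ov$parameter_values)
    expect_equal(back$overrides$initial_values, ov$initial_values)
  }
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sedmlLite version="1"><steadyState/></sedmlLite>'), f)
  expect_error(read_sedml_lite(f), "steadyState")
  writeLines(c('<?xml version="1.0"?>',
               '<sedmlLite version="1">',
               '<uniformTimeCourse initialTime="0" outputEndTime="10" outputStep="0.1"/>',
               '</sedmlLite>'), f)
  expect_error(read_sedml_lite(f), "algorithm")
})

test_that("the packaged time-course description matches its reconstruction", {
  b1 <- bundle1()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sedml_lite(b1$sedml$setup, b1$sedml$overrides, f)
  back <- read_sedml_lite(f)
  expect_equal(back$setup$t_start, 0)
  expect_equal(back$setup$t_end, 100)
  expect_equal(back$setup$step, 0.001)
  expect_equal(back$setup$algorithm$namespace, "kisao")
  expect_equal(back$setup$algorithm$identifier, "KISAO_0000280")
  expect_setequal(names(back$setup$postprocess), c("M_over_CT", "YT_over_CT"))
})

test_that("trajectory export writes a delimited table with time first", {
  inst <- instantiate(decay_model())
  traj <- run_timecourse(inst, simulation_setup(0, 1, 0.25))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, f)
  tab <- utils::read.delim(f)
  expect_equal(names(tab)[1], "time")
  expect_equal(tab$X, unname(traj$raw[, "X"]), tolerance = 1e-12)
})
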