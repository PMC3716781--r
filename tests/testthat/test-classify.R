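test_that("a relaxation to x = 2 classifies as a stable fixed point", {
  inst <- instantiate(relax_model(a = 2))
  res <- classify(inst, classification_protocol(horizon = 200, step = 0.1))
  expect_equal(res$class$label, "stable_fixed_point")
  expect_equal(format_urn(res$class$teddy), "urn:miriam:teddy:TEDDY_0000113")
  expect_equal(unname(res$characteristics$steady_state_values[["X"]]), 2,
               tolerance = 1e-6)
})

test_that("the packaged oscillatory point classifies as a limit cycle with a consistent period", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$limit_cycle_oscillation)
  protocol <- default_protocol(b2$model)
  res <- classify(inst, protocol)
  expect_equal(res$class$label, "limit_cycle_oscillation")
  expect_gt(res$characteristics$period, 0)
  ext <- res$characteristics$amplitude_extrema
  expect_true(all(vapply(ext, function(e) e[["min"]] <= e[["max"]],
                         logical(1))))
  # independent period oracle: autocorrelation of the post-transient series
  traj <- run_timecourse(inst, simulation_setup(0, protocol$horizon,
                                                protocol$step))
  post <- traj$index >= protocol$horizon / 2
  p_acf <- acf_period(traj$index[post], traj$raw[post, "u"])
  expect_lt(abs(p_acf - res$characteristics$period) /
              res$characteristics$period, 0.02)
})

test_that("the packaged excitable point shows a suprathreshold excursion and return", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$excitable_switch)
  res <- classify(inst, default_protocol(b2$model))
  expect_equal(res$class$label, "excitable_switch")
  expect_gte(res$characteristics$excursion_magnitude, 10)
  expect_false(is.null(res$characteristics$steady_state_values))
})

test_that("classification is deterministic given instance and protocol", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$limit_cycle_oscillation)
  protocol <- default_protocol(b2$model)
  r1 <- classify(inst, protocol)
  r2 <- classify(inst, protocol)
  expect_identical(r1$class$label, r2$class$label)
  expect_identical(r1$characteristics$period, r2$characteristics$period)
})

test_that("protocol invariants are checked", {
  expect_error(classification_protocol(horizon = -1), "positive")
  expect_error(classification_protocol(horizon = 1, step = 0.3),
               "post-transient")
  expect_error(classification_protocol(transient_fraction = 1), "transient")
})

test_that("the Jacobian verdict matches closed forms on canonical systems", {
  inst <- instantiate(relax_model(a = 0))   # dx/dt = -x
  v <- jacobian_class_at_fixed_point(inst, c(X = 0))
  expect_equal(v$verdict, "stable")
  expect_equal(v$real_parts, -1)

  sad <- instantiate(saddle_model())
  vs <- jacobian_class_at_fixed_point(sad, c(X = 0, Y = 0))
  expect_equal(vs$verdict, "unstable")
  expect_setequal(vs$sign_pattern, c(-1, 1))

  expect_error(jacobian_class_at_fixed_point(inst, c(X = 5)),
               "not an equilibrium")
})

test_that("simulation verdict and Jacobian oracle agree at a stable regime point", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$stable_fixed_point)
  res <- classify(inst, default_protocol(b2$model))
  expect_equal(res$class$label, "stable_fixed_point")
  v <- jacobian_class_at_fixed_point(inst,
                                     res$characteristics$steady_state_values)
  expect_equal(v$verdict, "stable")
})

test_that("Newton equilibrium search lands on the analytic equilibrium", {
  b2 <- bundle2()
  inst <- instantiate(b2$model, b2$regime_points$stable_fixed_point)
  p <- inst$parameters
  eq <- newton_equilibrium(inst, c(u = 0.01, v = 0.5))
  expect_equal(unname(eq[["u"]]), p[["r_syn"]] / p[["k6"]], tolerance = 1e-8)
  f <- inst$rhs_fun(0, eq, NULL)[[1]]
  expect_lt(max(abs(f)), 1e-10)
})
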