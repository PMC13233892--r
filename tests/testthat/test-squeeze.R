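## The full-load depletion run is the most expensive fixture in this file;
## it is computed once and shared across the blocks that examine it.
.squeeze_cache <- new.env(parent = emptyenv())
squeeze_full_run <- function() {
  if (is.null(.squeeze_cache$full)) {
    cfg <- squeeze_config(h_e = 1.25e-4, dt = 1e-3, T_final = 0.3)
    .squeeze_cache$full <- run_squeeze_benchmark(
      cfg, newton = newton_config(rtol = 1e-7, maxit = 60))
  }
  .squeeze_cache$full
}

test_that("the smooth rectangular window is a C2 plateau function", {
  expect_equal(smooth_rect(0.5), 1)
  expect_equal(smooth_rect(c(0.2, 0.8)), c(1, 1))
  expect_equal(smooth_rect(c(-0.1, 0, 1, 1.1)), c(0, 0, 0, 0))
  expect_equal(smooth_rect(0.1), 0.5)          # midpoint of the quintic ramp
  expect_equal(smooth_rect(0.9), 0.5)
  ## C2: the quintic ramp has vanishing first and second derivatives at
  ## its knots, so central second differences across each knot tend to 0
  h <- 1e-3
  for (s0 in c(0, 0.2, 0.8, 1)) {
    d2 <- (smooth_rect(s0 - h) - 2 * smooth_rect(s0) + smooth_rect(s0 + h)) / h^2
    expect_lt(abs(d2), 2)        # interior second derivatives are O(1/0.2^2)
  }
})

test_that("zero load leaves the porosity probes constant", {
  cfg <- squeeze_config(p_o = 0, h_e = 2.5e-4, dt = 0.05, T_final = 0.2)
  run <- run_squeeze_benchmark(cfg)
  expect_true(run$converged)
  pr <- probe_porosity(run)
  expect_lt(max(abs(pr$phi_point - 0.5)), 1e-9)
  expect_lt(max(abs(pr$phi_line_avg - 0.5)), 1e-9)
})

test_that("full load drives the monitor porosity to zero (modified formulation)", {
  run <- squeeze_full_run()
  expect_true(run$converged)
  pr <- probe_porosity(run)
  expect_lt(min(pr$phi_point), 0.01)
  expect_lt(min(pr$phi_line_avg), 0.05)
  ## the traction vanishes at t = 0: the first step stays quiescent
  expect_equal(pr$phi_point[1], 0.5, tolerance = 1e-4)
})

test_that("filtration velocity vanishes inside deeply depleted regions", {
  run <- squeeze_full_run()
  diag <- porozero:::filtration_diagnostics(run$U, run$Vs, run$ctx)
  deep <- diag$phi < 1e-3
  expect_gt(sum(deep), 0)
  ## the interior of the dry zone carries essentially no filtration flux;
  ## the cells at the depletion front still exchange fluid with the wet side
  expect_lt(max(diag$vflt[deep]), 5e-3 * max(diag$vflt))
})

test_that("the traditional formulation fails once the porosity collapses", {
  cfg <- squeeze_config(h_e = 1.25e-4, dt = 1e-3, T_final = 0.3,
                        formulation = "traditional")
  run <- run_squeeze_benchmark(cfg, newton = newton_config(rtol = 1e-7,
                                                           maxit = 40))
  expect_false(run$converged)
  ## failure happens after substantial depletion, not at the start
  expect_lt(min(run$probe$min_phi), 0.1)
  expect_gt(run$failure$t, 0.02)
})

test_that("both formulations agree at reduced load while porosity stays saturated", {
  base <- list(p_o = 10, h_e = 2.5e-4, dt = 5e-3, T_final = 0.1)
  runs <- lapply(c("modified", "traditional"), function(f) {
    cfg <- do.call(squeeze_config, c(base, list(formulation = f)))
    run_squeeze_benchmark(cfg, newton = newton_config(rtol = 1e-9))
  })
  expect_true(runs[[1]]$converged && runs[[2]]$converged)
  expect_gt(min(runs[[1]]$probe$min_phi), 0.3)   # well above phi_fc
  lay <- runs[[1]]$ctx$layout
  for (idx in list(seq_len(lay$off_v),
                   (lay$off_v + 1):lay$off_p,
                   (lay$off_p + 1):(lay$off_p + lay$nnode))) {
    d <- sqrt(sum((runs[[1]]$U[idx] - runs[[2]]$U[idx])^2)) /
      max(sqrt(sum(runs[[2]]$U[idx]^2)), 1e-300)
    expect_lt(d, 1e-3)
  }
})

test_that("sealed runs conserve the fluid content", {
  cfg <- squeeze_config(p_o = 10, h_e = 2.5e-4, dt = 5e-3, T_final = 0.1,
                        pressure_bc = "sealed")
  run <- run_squeeze_benchmark(cfg, newton = newton_config(rtol = 1e-9))
  expect_true(run$converged)
  fc <- porozero:::fluid_content(run$U, run$ctx)
  expect_lt(abs(fc["current"] - fc["reference"]) / fc["reference"], 1e-3)
})
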