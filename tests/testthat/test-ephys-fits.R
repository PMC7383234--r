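volt_grid <- seq(-110, 40, by = 10)

test_that("noiseless Boltzmann points are recovered essentially exactly", {
  pts <- data.frame(voltage = volt_grid,
                    response = boltzmann(volt_grid, 1, -20, 9.5))
  f <- fit_boltzmann(pts)
  expect_equal(f$top, 1, tolerance = 1e-6)
  expect_equal(f$v_half, -20, tolerance = 1e-6)
  expect_equal(f$slope, 9.5, tolerance = 1e-6)
  expect_lt(f$rms, 1e-8)
  expect_true(f$v_half_in_range)
  # midpoint property: y(V50) = top/2
  expect_equal(boltzmann(f$v_half, f$top, f$v_half, f$slope), f$top / 2)
})

test_that("fixed-top and decreasing orientations fit correctly", {
  pts <- data.frame(voltage = volt_grid,
                    response = boltzmann(volt_grid, 1, -35, 7,
                                         decreasing = TRUE))
  f <- fit_boltzmann(pts, decreasing = TRUE)
  expect_equal(f$v_half, -35, tolerance = 1e-5)
  expect_equal(f$slope, 7, tolerance = 1e-5)
  f1 <- fit_boltzmann(pts, fix_top = 1, decreasing = TRUE)
  expect_equal(f1$top, 1)
  expect_equal(f1$v_half, -35, tolerance = 1e-5)
})

test_that("single-Boltzmann V50 is accurate under noise", {
  errs <- vapply(1:25, function(r) {
    pts <- with_local_seed(300 + r, data.frame(
      voltage = volt_grid,
      response = boltzmann(volt_grid, 1, -20, 9.5) +
        rnorm(length(volt_grid), 0, 0.02)))
    abs(fit_boltzmann(pts)$v_half - (-20))
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("tail-current extraction recovers the activation curve", {
  g <- gen_sweeps(ephys_spec(noise_sd = 0), "activation", seed = 1)
  pts <- tail_activation_curve(g$series)
  expect_equal(max(pts$response), 1)  # normalization pins the maximum
  f <- fit_boltzmann(pts)
  expect_equal(f$v_half, g$truth$v_half, tolerance = 0.1)
  expect_equal(f$slope, g$truth$slope, tolerance = 0.1)

  # sweeps entirely below the activation range carry ~zero raw amplitude
  sub <- gen_sweeps(ephys_spec(noise_sd = 0,
                               voltages = seq(-110, -70, by = 10)),
                    "activation", seed = 1)
  amps <- tail_activation_curve(sub$series)$amplitude
  expect_lt(max(amps), 1e-2 * ephys_spec()$i_max)
})

test_that("leak subtraction removes an ohmic component", {
  # leak-only series: residuals ~ 0 everywhere
  sp <- ephys_spec(noise_sd = 0, leak_g_ns = 2, i_max = 1e-9)
  g <- gen_sweeps(sp, "activation", seed = 1)
  clean <- leak_subtract(g$series, c(-110, -80))
  for (sw in clean$sweeps) expect_lt(max(abs(sw$value)), 1e-6)

  # leak + channel: the channel component survives subtraction
  sp2 <- ephys_spec(noise_sd = 1, leak_g_ns = 1.5)
  g2 <- gen_sweeps(sp2, "activation", seed = 2)
  f <- fit_boltzmann(tail_activation_curve(leak_subtract(g2$series,
                                                         c(-110, -80))))
  expect_equal(f$v_half, sp2$activation$v_half, tolerance = 1)

  # zero-conductance input passes through unchanged
  sp0 <- ephys_spec(noise_sd = 0, leak_g_ns = 0, i_max = 1e-9)
  g0 <- gen_sweeps(sp0, "activation", seed = 3)
  out <- leak_subtract(g0$series, c(-110, -80))
  expect_equal(out$sweeps[[16]]$value, g0$series$sweeps[[16]]$value,
               tolerance = 1e-8)
  expect_error(leak_subtract(g0$series, c(-200, -150)), "leak window")
})

test_that("noiseless double Boltzmann is recovered with ordered components", {
  truth <- list(top = 1, fraction = 0.4, v_half_1 = -30, slope_1 = 10,
                v_half_2 = -60, slope_2 = 12)
  pts <- data.frame(
    voltage = volt_grid,
    response = double_boltzmann(volt_grid, truth$top, truth$fraction,
                                truth$v_half_1, truth$slope_1,
                                truth$v_half_2, truth$slope_2,
                                decreasing = TRUE))
  f <- fit_double_boltzmann(pts, decreasing = TRUE)
  expect_gt(f$v_half_1, f$v_half_2)  # ordering convention
  expect_equal(f$v_half_1, truth$v_half_1, tolerance = 1e-4)
  expect_equal(f$v_half_2, truth$v_half_2, tolerance = 1e-4)
  expect_equal(f$fraction, truth$fraction, tolerance = 1e-4)
  expect_false(f$degenerate)
})

test_that("double Boltzmann reduces to single at the F boundaries", {
  # evaluator equivalence
  expect_equal(double_boltzmann(volt_grid, 1, 1, -30, 10, -60, 12),
               boltzmann(volt_grid, 1, -30, 10))
  expect_equal(double_boltzmann(volt_grid, 1, 0, -30, 10, -60, 12),
               boltzmann(volt_grid, 1, -60, 12))
  # fitting a pure single component flags the unidentifiable split
  pts <- data.frame(voltage = volt_grid,
                    response = boltzmann(volt_grid, 1, -20, 9.5,
                                         decreasing = TRUE))
  f <- fit_double_boltzmann(pts, decreasing = TRUE)
  expect_true(f$degenerate)
})

test_that("toxin subtraction is exact pointwise arithmetic", {
  g <- gen_sweeps(ephys_spec(noise_sd = 3), "sctx_pair", seed = 9)
  diff <- sctx_subtract(g$pre, g$post)
  # pre - (pre - post) = post elementwise
  for (i in seq_along(diff$sweeps)) {
    expect_equal(g$pre$sweeps[[i]]$value - diff$sweeps[[i]]$value,
                 g$post$sweeps[[i]]$value, tolerance = 1e-12)
  }
  expect_true(diff$metadata$sctx_sensitive)

  # post = pre gives the all-zero difference
  z <- sctx_subtract(g$pre, g$pre)
  expect_true(all(vapply(z$sweeps, function(s) max(abs(s$value)),
                         numeric(1)) == 0))

  bad <- g$post
  bad$sweeps[[1]]$command <- 999
  expect_error(sctx_subtract(g$pre, bad), "mismatch")
})

test_that("the maximal toxin-sensitive fraction sits at the +20 mV step", {
  g <- gen_sweeps(ephys_spec(noise_sd = 0), "sctx_pair", seed = 1)
  r <- max_fractional_reduction(g$pre, g$post)
  expect_equal(r$voltage, 20)
  expect_equal(r$reduction, g$truth$reduction_at_max, tolerance = 1e-9)
  expect_equal(100 * r$reduction, 52.7, tolerance = 1e-2)
})

test_that("recovery-from-inactivation fits the single exponential", {
  g <- gen_sweeps(ephys_spec(noise_sd = 0), "recovery", seed = 1)
  f <- fit_recovery(g$intervals, g$ratios)
  expect_equal(f$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(f$tau, 500, tolerance = 1e-3)
  # fitted curve plateaus at full recovery
  expect_equal(1 - f$amplitude * exp(-1e6 / f$tau), 1)

  errs <- vapply(1:25, function(r) {
    g <- gen_sweeps(ephys_spec(noise_sd = 0.03), "recovery", seed = 400 + r)
    abs(fit_recovery(g$intervals, g$ratios)$tau - 500) / 500
  }, numeric(1))
  expect_lt(median(errs), 0.10)
  expect_error(fit_recovery(c(10, 20, 50), c(0.3, 0.5, 0.7)), "length")
})
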