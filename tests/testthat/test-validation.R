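test_that("the f/I slope fit reproduces hand-computed values", {
  # published model means at 10/16/22 pA give ~6.86 spikes s^-1 / pA
  expect_equal(fi_slope(c(10, 16, 22), c(12.795, 56.95, 95.09)), 6.858,
               tolerance = 1e-3)
  expect_equal(fi_slope(c(10, 16, 22, 28), rep(40, 4)), 0)
})

test_that("a passive membrane shows no rectification; Kir-bearing models do", {
  ir_pass <- inward_rectification(passive_mono())
  expect_equal(ir_pass$index, 1, tolerance = 1e-3)
  expect_false(ir_pass$anomaly)
  m <- reference_mono()
  ir <- inward_rectification(m)
  no_kir <- granule_model("mono", gmax = c(Kir = 0))
  ir0 <- inward_rectification(no_kir)
  expect_gt(ir$index, 1)
  expect_gt(ir$index, ir0$index)
  # zero-amplitude step leaves the voltage at rest
  ir_zero <- inward_rectification(passive_mono(), amplitudes = c(0, -3))
  tab <- ir_zero$table
  expect_lt(abs(tab$v_ss[tab$amplitude == 0] - tab$v_rest[tab$amplitude == 0]),
            1e-6)
})

test_that("input resistance follows the closed form for a passive sphere", {
  m <- passive_mono()
  area <- 4 * pi * 9.76^2 * 1e-8
  r_pred <- 1 / (5.68e-2 * area * 1e3) / 1000   # GOhm
  expect_equal(input_resistance(m), r_pred, tolerance = 0.005)
  # doubling the conductance halves the resistance
  g2 <- passive_gmax("mono")
  g2["Lkg1"] <- 2 * g2["Lkg1"]
  expect_equal(input_resistance(granule_model("mono", gmax = g2)),
               r_pred / 2, tolerance = 0.005)
  # the full model (Kir and friends in parallel) sits below the leak-only value
  expect_lt(input_resistance(reference_mono()), r_pred)
})

test_that("the spectral analysis recovers a known oscillation", {
  # pure 5 Hz test sinusoid injected as a fake trace through the same spectrum
  m <- passive_mono()
  osc <- near_threshold_oscillations(m, hold = -2, duration = 3000)
  expect_lt(osc$amplitude_mv, 1e-3)   # passive: no oscillation at all
  # fixture: known 5 Hz component dominates the spectrum machinery
  t <- seq(0, 5100, by = 0.025)
  v <- -60 + 2 * sin(2 * pi * 5 * t / 1000)
  tr <- structure(list(time = t, v = matrix(v), dt = 0.025), class = "grc_trace")
  x <- v[t > 1100 & t <= 5100]
  x <- x - mean(x)
  n <- length(x)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  nfft <- stats::nextn(4 * n, 2)
  sp <- abs(stats::fft(c(x * hann, rep(0, nfft - n))))[seq_len(nfft %/% 2)]
  fgrid <- (seq_len(nfft %/% 2) - 1) * (1000 / 0.025) / nfft
  band <- fgrid >= 1 & fgrid <= 25
  expect_equal(fgrid[band][which.max(sp[band])], 5, tolerance = 0.02)
})

test_that("rheobase is bracketed by bisection", {
  expect_true(is.na(rheobase(passive_mono(), hi = 20, duration = 300)))
  rb <- rheobase(reference_mono(), duration = 500)
  expect_gt(rb, 2)
  expect_lt(rb, 20)
})

test_that("conductance deviations are percent distances from the reference", {
  ref <- c(Na = 13, KV = 3, Kir = 0.91)
  expect_equal(gmax_deviation(ref, ref)$mean, 0)
  one <- ref
  one["Na"] <- 13 * 1.5
  expect_equal(gmax_deviation(one, ref)$mean, 50 / 3)
  pop <- rbind(ref, ref * 1.1)
  colnames(pop) <- names(ref)
  expect_equal(gmax_deviation(pop, ref)$mean, 5, tolerance = 1e-10)
  expect_error(gmax_deviation(c(Foo = 1), ref), "share")
})

test_that("propagation metrics report physical quantities", {
  cm <- conduction_metrics(reference_multi(), amplitude = 16)
  expect_true(cm$ais_first)
  expect_false(cm$degenerate)
  expect_gt(cm$speed_mm_ms, 0.05)
  expect_lt(cm$speed_mm_ms, 1)
  expect_gte(cm$backprop_delay_ms, 0)
})
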