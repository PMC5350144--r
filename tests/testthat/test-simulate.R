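test_that("passive compartment matches the RC charging closed form", {
  m <- passive_mono()
  tr <- simulate_model(m, step_protocol(10, onset = 50, offset = 550,
                                        total = 600))
  area <- 4 * pi * 9.76^2 * 1e-8               # cm^2
  g <- 5.68e-2 * area * 1e3                    # uS
  tau <- (area * 1e3) / g                      # nF/uS = ms
  t <- tr$time
  pred <- -58 + ifelse(t < 50, 0, 0.01 / g * (1 - exp(-(t - 50) / tau)))
  pred[t > 550] <- NA
  w <- t >= 50 & t <= 550
  amp <- 0.01 / g
  expect_lt(max(abs(tr$v[w, 1] - pred[w])) / amp, 0.005)   # < 0.5% of step
})

test_that("the full model holds its resting state without input", {
  m <- reference_mono()
  tr <- simulate_model(m, step_protocol(0, onset = 10, offset = 20,
                                        total = 1000))
  expect_lt(max(abs(tr$v[, 1] - tr$v[1, 1])), 0.5)
})

test_that("spike timing is stable under step-size refinement", {
  m <- reference_mono()
  p <- step_protocol(16, onset = 100, offset = 1100, total = 1100)
  s1 <- detect_spikes(simulate_model(m, p, dt = 0.025))
  s2 <- detect_spikes(simulate_model(m, p, dt = 0.0125))
  expect_lte(abs(nrow(s1) - nrow(s2)), 1)
  expect_lt(abs(s1$peak_time[1] - s2$peak_time[1]), 0.05)
  f1 <- extract_features(simulate_model(m, p, dt = 0.025))[["mean_frequency"]]
  f2 <- extract_features(simulate_model(m, p, dt = 0.0125))[["mean_frequency"]]
  expect_lt(abs(f1 - f2) / f2, 0.02)
})

test_that("the ZAP waveform has the analytic frequency sweep", {
  p <- zap_protocol(A = 10, f_max = 10, duration = 30000)
  t <- seq(0, 30000, by = 0.025)
  i <- zap_current(p$A, p$B, t)
  expect_equal(i[1], 0)
  expect_true(all(abs(i) <= 10))
  # zero crossings at t_k = sqrt(k*pi/B) (k = 1, 2, ...; skip the t = 0 root)
  zc <- t[which(diff(sign(i)) != 0)]
  zc <- zc[zc > 1]
  k <- round((zc / 1000)^2 * p$B / pi)
  expect_true(all(k >= 1))
  expect_lt(max(abs(zc - sqrt(k * pi / p$B) * 1000)), 0.05)
  expect_error(zap_current(10, p$B, c(-1, 0)), "negative")
})

test_that("subthreshold voltage attenuation in the multi model is below 2%", {
  m <- passive_multi()
  tr <- simulate_model(m, step_protocol(-5, onset = 50, offset = 550,
                                        total = 600), record = "all")
  t <- tr$time
  ss <- t > 450 & t <= 550
  dv <- colMeans(tr$v[ss, ]) - tr$v[1, ]
  att <- 1 - dv[c("dend1", "axon15")] / dv["soma"]
  expect_true(all(abs(att) < 0.02))
})

test_that("injected charge is conserved in the passive multi model", {
  m <- passive_multi()
  tr <- simulate_model(m, step_protocol(-5, onset = 50, offset = 350,
                                        total = 400), record = "all",
                       record_currents = TRUE)
  t <- tr$time
  dt <- t[2] - t[1]
  comps <- m$compartments
  cm_nf <- comps$area_um2 * 1e-8 * 1e3
  w <- t >= 50 & t < 350
  q_inj <- -0.005 * 300                                    # nA*ms = pC
  q_cap <- sum(cm_nf * (tr$v[max(which(w)) + 1, ] - tr$v[min(which(w)), ]))
  base <- colMeans(tr$currents[t < 50, , drop = FALSE])
  q_ion <- sum((colSums(tr$currents[w, , drop = FALSE]) -
                  base * sum(w)) * dt)
  expect_lt(abs((q_cap + q_ion - q_inj) / q_inj), 0.01)
})

test_that("the action potential arises in the AIS and reaches the axon last", {
  cm <- conduction_metrics(reference_multi(), amplitude = 16)
  pk <- cm$peaks
  t_ais <- pk$peak_time[pk$label == "AIS"]
  expect_true(cm$ais_first)
  expect_lte(t_ais, pk$peak_time[pk$label == "soma"])
  expect_lt(pk$peak_time[pk$label == "soma"],
            pk$peak_time[pk$label == "axon15"])
  expect_lt(t_ais, min(pk$peak_time[grepl("^dend", pk$label)]))
})

test_that("simulation inputs are validated", {
  m <- passive_mono()
  expect_error(simulate_model(m, step_protocol(10), record = "dend1"),
               "unknown compartment")
  expect_error(simulate_model(m, step_protocol(10, injection_site = "axon01")),
               "unknown injection site")
})

test_that("the compiled integrator agrees with an adaptive reference solver", {
  m <- reference_mono()
  sys <- mono_rhs_system(m, inj_nA = 0.016, onset = 100)
  settle <- deSolve::lsoda(sys$y0, c(-500, 0),
                           function(t, y, p) sys$rhs(-1000, y, p), NULL,
                           rtol = 1e-7, atol = 1e-9)
  y1 <- settle[nrow(settle), -1]
  out <- deSolve::lsoda(y1, seq(0, 250, by = 0.025), sys$rhs, NULL,
                        rtol = 1e-7, atol = 1e-9)
  sp_ref <- detect_spikes(list(time = out[, "time"], v = matrix(out[, "V"])))
  tr <- simulate_model(m, step_protocol(16, onset = 100, offset = 250,
                                        total = 250), dt = 0.025)
  sp <- detect_spikes(tr)
  expect_equal(out[1, "V"], tr$v[1, 1], tolerance = 1e-4,
               ignore_attr = TRUE)                       # same resting state
  expect_equal(nrow(sp), nrow(sp_ref))
  expect_lt(max(abs(sp$peak_time[1:3] - sp_ref$peak_time[1:3])), 0.1)
  expect_lt(max(abs(sp$peak_v[1:3] - sp_ref$peak_v[1:3])), 0.5)
})
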