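test_that("spike detection finds constructed spikes and nothing else", {
  flat <- synth_trace(numeric(0), total = 500)
  expect_equal(nrow(detect_spikes(flat)), 0)
  peaks <- c(150, 180, 220, 280, 360)
  tr <- synth_trace(peaks)
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 5)
  expect_lt(max(abs(sp$peak_time - peaks)), 0.025)
  expect_equal(nrow(detect_spikes(tr, threshold = 100)), 0)
  bad <- tr
  bad$time <- bad$time^1.01
  expect_error(detect_spikes(bad), "uniform")
})

test_that("interval statistics follow their definitions", {
  # constant ISIs: no adaptation, no variability
  tr <- synth_trace(seq(150, 450, by = 25), total = 600)
  f <- extract_features(tr)
  expect_equal(f[["adaptation_index"]], 0, tolerance = 1e-8)
  expect_equal(f[["ISI_CV"]], 0, tolerance = 1e-8)
  expect_equal(f[["time_to_first_spike"]], 50, tolerance = 0.03)
  # ISIs {8, 12}: sample-sd convention gives CV = 0.283
  tr2 <- synth_trace(c(200, 208, 220), total = 400)
  f2 <- extract_features(tr2)
  expect_equal(f2[["ISI_CV"]], sd(c(8, 12)) / 10, tolerance = 1e-3)
  expect_equal(round(f2[["ISI_CV"]], 3), 0.283)
  # mean frequency: n spikes over onset-to-last-spike, in Hz
  expect_equal(f2[["mean_frequency"]], 3 / (220 - 100) * 1000, tolerance = 1e-3)
})

test_that("interval statistics are invariant under time rescaling", {
  isis <- c(10, 14, 9, 22, 17)
  t1 <- synth_trace(150 + cumsum(isis))
  t2 <- synth_trace(150 + 3 * cumsum(isis))
  f1 <- extract_features(t1)
  f2 <- extract_features(t2)
  expect_equal(f1[["ISI_CV"]], f2[["ISI_CV"]], tolerance = 1e-6)
  expect_equal(f1[["adaptation_index"]], f2[["adaptation_index"]],
               tolerance = 1e-6)
})

test_that("features agree with an independent reference implementation", {
  for (seed in 1:20) {
    tr <- random_synth_trace(seed)
    ours <- extract_features(tr)
    ref <- ref_features(tr$time, tr$v[, 1], onset = 100)
    expect_equal(ours, ref, tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("features that need spikes are flagged missing", {
  f <- extract_features(synth_trace(numeric(0), total = 400))
  expect_false(is.na(f[["resting_voltage"]]))
  expect_true(all(is.na(f[setdiff(feature_names(), "resting_voltage")])))
  f1 <- extract_features(synth_trace(200, total = 400))
  expect_false(is.na(f1[["time_to_first_spike"]]))
  expect_true(is.na(f1[["ISI_CV"]]))
})

test_that("objectives are z-distances with a penalty for missing features", {
  tmpl <- reference_templates("exp")
  feats <- list()
  for (s in c(10, 16, 22)) {
    rr <- tmpl[tmpl$stim_pA == s, ]
    feats[[as.character(s)]] <- setNames(rr$mean, rr$feature)
  }
  z <- objective_scores(feats, tmpl)
  expect_equal(length(z), 30)
  expect_true(all(z == 0))
  # resting -64 against -68.5 +- 12.5 -> 0.36
  feats[["10"]]["resting_voltage"] <- -64
  z2 <- objective_scores(feats, tmpl)
  expect_equal(unname(z2["resting_voltage@10"]), abs(-64 + 68.5) / 12.5)
  expect_equal(round(z2["resting_voltage@10"], 2), c("resting_voltage@10" = 0.36))
  # a non-spiking trace gets the penalty on every spike objective
  feats[["16"]][setdiff(feature_names(), "resting_voltage")] <- NA
  z3 <- objective_scores(feats, tmpl)
  expect_true(all(z3[paste0(setdiff(feature_names(), "resting_voltage"),
                            "@16")] == 250))
  expect_true(all(z3 >= 0))
  bad <- tmpl
  bad$sd[1] <- 0
  expect_error(objective_scores(feats, bad), "positive")
})

test_that("templates round-trip through CSV losslessly", {
  tmpl <- reference_templates("exp")
  path <- tempfile(fileext = ".csv")
  write_templates(tmpl, path)
  back <- read_templates(path)
  expect_equal(back$mean, tmpl$mean)
  expect_equal(back$sd, tmpl$sd)
  expect_equal(back$feature, tmpl$feature)
})
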