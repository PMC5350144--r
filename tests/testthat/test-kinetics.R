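test_that("gate steady state follows the alpha/beta closed forms", {
  # alpha and beta equal at V0 -> m_inf = 1/2 by symmetry
  g <- gate_ab("x", 1,
               alpha = list(form = "exp", A = 2, V0 = -40, K = 10),
               beta  = list(form = "exp", A = 2, V0 = -40, K = -10))
  ss <- gate_steady_state(g, -40)
  expect_equal(ss$minf, 0.5)
  # constant alpha = 1/ms, beta = 3/ms -> m_inf = 1/4, tau = 1/4 ms
  g2 <- gate_ab("x", 1,
                alpha = list(form = "exp", A = 1, V0 = 0, K = 1e12),
                beta  = list(form = "exp", A = 3, V0 = 0, K = 1e12))
  ss2 <- gate_steady_state(g2, -55)
  expect_equal(ss2$minf, 0.25, tolerance = 1e-9)
  expect_equal(ss2$tau, 0.25, tolerance = 1e-9)
  # linoid limit at V = V0 equals A*K
  g3 <- gate_ab("x", 1,
                alpha = list(form = "linoid", A = -0.1, V0 = -40, K = -10),
                beta  = list(form = "exp", A = 0, V0 = 0, K = 1e12))
  a40 <- with(gate_steady_state(g3, -40), minf / tau)
  expect_equal(a40, 1, tolerance = 1e-6)
  expect_error(gate_steady_state(g, NaN), "finite")
})

test_that("shipped kinetics gates are well formed over the physiological range", {
  kin <- kinetics_set()
  v <- seq(-100, 60, by = 0.5)
  for (ch in kin$channels) {
    if (!identical(ch$kind, "hh")) next
    for (g in ch$gates) {
      ss <- gate_steady_state(g, v, ca = 1e-4)
      expect_true(all(ss$minf >= 0 & ss$minf <= 1))
      expect_true(all(ss$tau > 0))
    }
  }
})

test_that("the inward-rectifier gate opens with hyperpolarization", {
  kir <- kinetics_set()$channels$Kir$gates[[1]]
  v <- seq(-100, -40, by = 1)
  minf <- gate_steady_state(kir, v)$minf
  expect_true(all(diff(minf) < 0))
})

test_that("channel current follows the ohmic form with gating product", {
  leak <- channel_spec("Lkg1", gmax = 5.68e-2, erev = -58)
  expect_equal(channel_current(leak, numeric(0), v = -48), 5.68e-4)
  expect_equal(channel_current(leak, numeric(0), v = -58), 0)
  kin <- kinetics_set()
  na <- channel_spec("Na", gates = kin$channels$Na$gates, gmax = 13,
                     erev = 87.39)
  expect_equal(channel_current(na, c(0, 0.7), v = 0), 0)        # closed gate
  expect_equal(channel_current(na, c(0.5, 0.8), v = 87.39), 0)  # at reversal
  # exponents applied: m^3 * h
  expect_equal(channel_current(na, c(0.5, 0.8), v = -20),
               13 * 0.5^3 * 0.8 * (-20 - 87.39) * 1e-3)
  expect_error(channel_current(na, c(1.2, 0.5), v = 0), "0, 1")
  expect_error(channel_current(na, 0.5, v = 0), "per gate")
})

test_that("the Markov generator has zero row sums and conserves occupancy", {
  p <- markov_na_params()
  for (v in c(-80, -40, 0, 30)) {
    q <- markov_q(p, v)
    expect_lt(max(abs(rowSums(q))), 1e-10)
    expect_true(all(q - diag(diag(q)) >= 0))
  }
  occ <- setNames(c(1, rep(0, 12)), markov_state_labels())
  for (i in 1:200) occ <- markov_step(p, occ, v = -30, dt = 0.05)
  expect_lt(abs(sum(occ) - 1), 1e-9)
  expect_true(all(occ >= 0))
})

test_that("iterated Markov stepping reaches the analytic stationary state", {
  p <- markov_na_params()
  for (v in c(-60, -35)) {
    q <- markov_q(p, v)
    A <- rbind(t(unclass(q)), rep(1, 13))
    stat <- qr.solve(A, c(rep(0, 13), 1))
    occ1 <- c(1, rep(0, 12))                       # all closed
    occ2 <- c(rep(0, 5), 1, rep(0, 7))             # all open
    for (i in 1:4000) {
      occ1 <- markov_step(p, occ1, v, dt = 1)
      occ2 <- markov_step(p, occ2, v, dt = 1)
    }
    expect_equal(unname(occ1), unname(stat), tolerance = 1e-6)
    expect_equal(unname(occ2), unname(stat), tolerance = 1e-6)
  }
})

test_that("calcium pool follows the first-order shell model", {
  pool <- calcium_pool()
  # fixed point: no current at rest
  expect_equal(update_calcium(pool, 0, dt = 1)$cai, pool$carest)
  # free decay from 2x rest: after t = 1/beta, within 1% of carest*(1 + 1/e)
  p2 <- calcium_pool(cai = 2e-4)
  steps <- 100
  dt <- (1 / p2$beta) / steps
  for (i in seq_len(steps)) p2 <- update_calcium(p2, 0, dt)
  expect_equal(p2$cai, 1e-4 * (1 + exp(-1)), tolerance = 0.01)
  # constant inward current: plateau at carest + |I|/(2 F d beta) within 0.5%
  p3 <- calcium_pool()
  i_ca <- -0.05  # mA/cm^2, inward
  for (i in 1:5000) p3 <- update_calcium(p3, i_ca, dt = 0.01)
  ss <- p3$carest + 0.05 / (2 * 96485.33212 * p3$depth * 1e-4 * p3$beta)
  expect_equal(p3$cai, ss, tolerance = 0.005)
  # floor clamp warns
  expect_warning(update_calcium(calcium_pool(cai = 1.5e-6), 1, dt = 5), "floor")
})

test_that("calcium reversal is the two-concentration Nernst potential", {
  expect_equal(calcium_reversal(calcium_pool(cai = 2, cao = 2)), 0)
  # standard concentrations at 30 C reproduce the tabulated Ca-HVA reversal
  expect_equal(calcium_reversal(calcium_pool()), 129.33, tolerance = 3e-4)
  # ratio dependence: doubling both concentrations changes nothing
  expect_equal(calcium_reversal(calcium_pool(cai = 2e-4, cao = 4)),
               calcium_reversal(calcium_pool()))
  # monotone decreasing in [Ca]i
  cais <- c(5e-5, 1e-4, 5e-4, 1e-3)
  e <- vapply(cais, function(x) calcium_reversal(calcium_pool(cai = x)),
              numeric(1))
  expect_true(all(diff(e) < 0))
  expect_error(calcium_pool(cai = -1), "cai")
})
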