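test_that("the additive epsilon indicator is the maximal translation", {
  expect_equal(epsilon_indicator(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(epsilon_indicator(c(1, 3), c(2, 2)), 1)
  expect_lte(epsilon_indicator(c(1, 1), c(2, 3)), 0)   # dominance
  expect_error(epsilon_indicator(1:3, 1:2), "length")
})

test_that("IBEA fitness matches a brute-force evaluation of the formula", {
  expect_equal(ibea_fitness(matrix(c(1, 2), 1)), 0)
  obj3 <- rbind(c(1, 3), c(2, 2), c(3, 1))
  expect_equal(ibea_fitness(obj3), bf_ibea_fitness(obj3))
  set.seed(42)
  for (i in 1:5) {
    obj <- matrix(runif(10 * 4), 10, 4)
    expect_equal(ibea_fitness(obj), bf_ibea_fitness(obj))
  }
  # duplicating an individual preserves the relative ranking of the others
  obj <- matrix(runif(12), 6, 2)
  r1 <- rank(ibea_fitness(obj))
  r2 <- rank(ibea_fitness(rbind(obj, obj[3, ])))[1:6]
  expect_equal(order(r1[-3]), order(r2[-3]))
  # degenerate population: identical objectives give uniform fitness
  expect_true(all(ibea_fitness(matrix(1, 4, 3)) == 0))
})

test_that("environmental selection keeps the best-k in one dimension", {
  set.seed(7)
  obj <- matrix(runif(9), ncol = 1)
  keep <- environmental_selection(obj, 4)
  expect_setequal(keep, order(obj[, 1])[1:4])
  expect_equal(environmental_selection(obj, 9), 1:9)
  # ties broken by stable index order
  expect_equal(environmental_selection(matrix(1, 5, 2), 2), c(1, 2))
  expect_equal(bf_environmental_selection(matrix(1, 5, 2), 2), c(1, 2))
})

test_that("environmental selection matches the brute-force removal loop", {
  set.seed(11)
  for (i in 1:6) {
    n <- sample(5:10, 1)
    obj <- matrix(runif(n * 3), n, 3)
    k <- sample(2:(n - 1), 1)
    expect_equal(environmental_selection(obj, k),
                 bf_environmental_selection(obj, k))
  }
})

test_that("variation respects probabilities and bounds", {
  rng <- data.frame(gene = c("a", "b"), lo = c(0, 1), hi = c(1, 3))
  parents <- rbind(c(0.5, 2), c(0.8, 1.5))
  set.seed(1)
  expect_equal(vary(parents, rng, p_mut = 0, p_recomb = 0), parents)
  # zero-width range: gene pinned even under forced mutation
  rng0 <- data.frame(gene = "a", lo = 0.5, hi = 0.5)
  off <- vary(matrix(c(0.5, 0.5), 2, 1), rng0, p_mut = 1, p_recomb = 0)
  expect_true(all(off == 0.5))
  # bounds always respected
  set.seed(2)
  off2 <- vary(matrix(runif(200, 0, 1), ncol = 2), rng, p_mut = 1,
               p_recomb = 1, p_swap = 0.5)
  expect_true(all(off2[, 1] >= 0 & off2[, 1] <= 1))
  expect_true(all(off2[, 2] >= 1 & off2[, 2] <= 3))
  # empirical mutation rate of a single gene matches p_mut (binomial 3 sigma)
  set.seed(3)
  n <- 1e4
  G <- matrix(rep(0.5, n), ncol = 1)
  rng1 <- data.frame(gene = "a", lo = 0, hi = 1)
  off3 <- vary(G, rng1, p_mut = 0.5, p_recomb = 0)
  frac <- mean(off3 != 0.5)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("the optimizer solves a one-gene analytic problem", {
  rng <- structure(data.frame(gene = "g", compartment = "soma",
                              lo = 0, hi = 10),
                   class = c("grc_ranges", "data.frame"))
  cfg <- opt_config(population = 20, generations = 20, cycles = 1, seed = 4)
  toy <- function(g) c(quad = (g - 3)^2)
  model <- structure(list(mode = "mono"), class = "grc_model")
  res <- run_optimization(model, NULL, cfg, ranges = rng, objective_fun = toy)
  best <- res$population[which.min(res$objectives[, 1]), 1]
  expect_lt(abs(best - 3) / 3, 0.01)
  # best objective sum is non-increasing in >= 90% of generations
  steps <- diff(res$history$best)
  expect_gte(mean(steps <= 1e-12), 0.9)
  # determinism: identical seed reproduces the trajectory exactly
  res2 <- run_optimization(model, NULL, cfg, ranges = rng, objective_fun = toy)
  expect_identical(res$population, res2$population)
  expect_identical(res$history, res2$history)
})

test_that("between-cycle range resets stay inside the initial envelope", {
  rng <- structure(data.frame(gene = c("g1", "g2"), compartment = "soma",
                              lo = c(0, -5), hi = c(10, 5)),
                   class = c("grc_ranges", "data.frame"))
  cfg <- opt_config(population = 16, generations = 5, cycles = 3, seed = 9)
  toy <- function(g) c(a = (g[1] - 2)^2, b = (g[2] + 1)^2)
  model <- structure(list(mode = "mono"), class = "grc_model")
  res <- run_optimization(model, NULL, cfg, ranges = rng, objective_fun = toy)
  expect_true(all(res$ranges$lo >= rng$lo - 1e-12))
  expect_true(all(res$ranges$hi <= rng$hi + 1e-12))
  expect_true(all(res$ranges$lo < res$ranges$hi))
})
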