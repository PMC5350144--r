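test_that("mono model geometry is the equivalent sphere", {
  m <- granule_model("mono")
  expect_equal(nrow(m$compartments), 1)
  expect_equal(m$compartments$area_um2, 4 * pi * 9.76^2, tolerance = 1e-10)
  expect_equal(m$v_init, -65)
})

test_that("multi model geometry and channel placement follow the tables", {
  m <- granule_model("multi")
  comps <- m$compartments
  expect_equal(nrow(comps), 7 + 14)   # soma + 4 dendrites + AIS + 15 axon segs
  expect_equal(sum(grepl("^dend", comps$label)), 4)
  d <- comps[comps$label == "dend1", ]
  expect_equal(c(d$diam, d$length), c(0.75, 15))
  s <- comps[comps$label == "soma", ]
  expect_equal(c(s$diam, s$length), c(5.8, 5.6))
  a <- comps[comps$label == "AIS", ]
  expect_equal(c(a$diam, a$length), c(1.5, 2.5))
  expect_equal(sum(comps$length[grepl("^axon", comps$label)]), 70)
  expect_true(all(comps$diam[grepl("^axon", comps$label)] == 0.3))
  # tree is connected and acyclic: every non-root parent precedes its child
  expect_true(all(comps$parent[-1] < seq_len(nrow(comps))[-1]))

  ch <- m$channels
  expect_setequal(ch$compartment[ch$channel == "Na"], c("AIS", "axon"))
  expect_setequal(ch$compartment[ch$channel %in% c("Kir", "Kslow", "KA")],
                  "soma")
  expect_setequal(ch$compartment[ch$channel %in% c("KCa", "Ca-HVA")],
                  "dendrite")
  expect_setequal(ch$compartment[ch$channel == "Lkg"],
                  c("dendrite", "soma", "AIS", "axon"))
})

test_that("a passive (leak-only) model is valid and quiescent", {
  m <- passive_mono()
  tr <- simulate_model(m, step_protocol(0, onset = 10, offset = 20, total = 200))
  expect_lt(max(abs(tr$v[, 1] + 58)), 1e-6)
})

test_that("axial conductance is the series half-cylinder formula", {
  cyl <- list(diam = 1, length = 10)
  g <- axial_conductance(cyl, cyl, ra = 100)
  expect_equal(1 / g, 12.73, tolerance = 1e-3)  # MOhm
  big <- list(diam = 2, length = 30)
  expect_equal(axial_conductance(cyl, big, 100), axial_conductance(big, cyl, 100))
  expect_equal(axial_conductance(cyl, big, 50), 2 * axial_conductance(cyl, big, 100))
  expect_error(axial_conductance(list(diam = 0, length = 10), cyl, 100),
               "diameter")
})

test_that("model configs validate before any compute", {
  expect_error(build_model(list(mode = "mono", nonsense = 1)), "unknown config")
  expect_error(build_model(list(gmax = list(Na = 1))), "mode")
  expect_error(granule_model("mono", gmax = c(NoSuchGene = 1)), "unknown gene")
  expect_error(granule_model("mono", gmax = c(Na = -2)), ">= 0")
  cfg <- list(mode = "mono", gmax = list(Na = 12, Kir = 0.8))
  m <- build_model(cfg)
  expect_equal(m$channels$density[m$channels$gene == "Na"], 12)
  expect_equal(m$channels$density[m$channels$gene == "Kir"], 0.8)
})

test_that("gene vectors set conductances and the calcium decay", {
  m <- granule_model("mono", gmax = c(Calc = 1.2, KCa = 4.4))
  expect_equal(m$calcium$beta, 1.2)
  expect_equal(m$channels$density[m$channels$gene == "KCa"], 4.4)
  # multi mode uses its own dendritic-shell decay default
  expect_equal(granule_model("multi")$calcium$beta, 0.1)
  expect_equal(granule_model("mono")$calcium$beta, 1.5)
})
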