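test_that("single pool follows the closed-form washin curve", {
  mdl <- toy_pool()
  sys <- emuDecompose(mdl, "B[1]")
  fl <- FluxState(net = c("in" = 2, out = 2), pools = c(B = 0.5))
  tt <- c(0, 5, 15, 30, 60)
  sim <- simulateLabeling(sys, fl, tracerProgram(purity = 1), times = tt,
                          ngrid = 500)
  expect_equal(sim$mids[["B[1]"]][2, ], 1 - exp(-2 * tt / 60 / 0.5),
               tolerance = 1e-7)
  ## at t = c/v the labeled fraction is 1 - 1/e
  tau_min <- 0.5 / 2 * 60
  sim2 <- simulateLabeling(sys, fl, tracerProgram(purity = 1),
                           times = tau_min, ngrid = 500)
  expect_equal(sim2$mids[["B[1]"]][2, 1], 1 - exp(-1), tolerance = 1e-7)
})

test_that("long-time MIDs approach the tracer-determined plateau", {
  p <- 0.99
  fl <- toy_rich_flux()
  sys <- emuDecompose(toy_rich(), c("R[1,2,3,4]", "Q[1,2]"))
  sim <- simulateLabeling(sys, fl, tracerProgram(species = "IN", purity = p),
                          times = c(0, 3000), ngrid = 600)
  for (id in names(sim$mids)) {
    sz <- length(leafMFA:::emuParse(id)$subset)
    expect_equal(sim$mids[[id]][1, 2], (1 - p)^sz, tolerance = 1e-4)
  }
  ## t = 0 is exactly unlabeled
  expect_equal(sim$mids[["R[1,2,3,4]"]][, 1], c(1, 0, 0, 0, 0))
})

test_that("EMU cascade matches the brute-force isotopomer oracle", {
  skip_if_not_installed("deSolve")
  tt <- c(0, 1, 3, 10, 30, 60)
  cases <- list(
    list(model = toy_split(), species = "A",
         flux = FluxState(net = c(r1 = 2, r2 = 2, r3 = 2),
                          pools = c(B = 0.3, C = 0.15, D = 0.8)),
         targets = c("D[1,2,3]", "B[1,2]")),
    list(model = toy_rich(), species = "IN", flux = toy_rich_flux(),
         targets = c("R[1,2,3,4]", "Q[1,2]", "P[1,2]")))
  for (cs in cases) {
    sys <- emuDecompose(cs$model, cs$targets)
    sim <- simulateLabeling(sys, cs$flux,
                            tracerProgram(species = cs$species, purity = 0.99),
                            times = tt, ngrid = 2500)
    orc <- oracleSimulate(cs$model, cs$flux, tt, purity = 0.99)
    for (tg in cs$targets) {
      p <- leafMFA:::emuParse(tg)
      for (k in seq_along(tt)) {
        expect_lt(max(abs(sim$mids[[tg]][, k] - orc$mid(p$met, p$subset, k))),
                  1e-6, label = paste(tg, "t =", tt[k], "abs deviation"))
      }
    }
  }
})

test_that("symmetric scrambling halves positional label in succinate-like pools", {
  skip_if_not_installed("deSolve")
  ## In toy_rich, Q is symmetric: positional EMUs Q[1] and Q[2] must carry
  ## identical labeling even though P labels position-asymmetrically is not
  ## the case here (both IN atoms identical), so build an asymmetric feed.
  mdl <- parseNetworkModel(c(
    "@met IN carbons=1 source", "@met U carbons=1",
    "@met Q carbons=2 symmetric=yes", "@met S carbons=2 sink",
    "up: 1 IN (a) -> 1 U (a)",
    "mk: 1 U (a) + 1 IN (b) -> 1 Q (ab)",
    "out: 1 Q (ab) -> 1 S (ab)"))
  fl <- FluxState(net = c(up = 1, mk = 1, out = 1),
                  pools = c(U = 2.0, Q = 0.1))
  sys <- emuDecompose(mdl, c("Q[1]", "Q[2]", "Q[1,2]"))
  sim <- simulateLabeling(sys, fl, tracerProgram(species = "IN", purity = 1),
                          times = c(5, 20), ngrid = 800)
  ## scrambling makes the two positions identical
  expect_equal(sim$mids[["Q[1]"]], sim$mids[["Q[2]"]], tolerance = 1e-9)
  orc <- oracleSimulate(mdl, fl, c(5, 20), purity = 1)
  expect_equal(sim$mids[["Q[1,2]"]][, 2], orc$mid("Q", c(1, 2), 3),
               tolerance = 1e-6)
})

test_that("M0 decreases monotonically under a pure step tracer", {
  spec <- generatorSpec("mini")
  sys <- emuDecompose(spec$model, fragmentTargets(spec$fragments))
  sim <- simulateLabeling(sys, spec$truth, tracerProgram(purity = 0.99),
                          times = c(0, 1, 2, 5, 10, 20, 40, 60), ngrid = 400)
  for (id in names(sim$mids)) {
    m0 <- sim$mids[[id]][1, ]
    expect_true(all(diff(m0) <= 1e-8), label = paste("M0 monotone for", id))
  }
})

test_that("grid refinement changes target MIDs below 1e-6", {
  fl <- toy_rich_flux()
  sys <- emuDecompose(toy_rich(), "R[1,2,3,4]")
  tt <- c(0, 2, 10, 60)
  a <- simulateLabeling(sys, fl, tracerProgram(species = "IN"), times = tt,
                        ngrid = 2000)
  b <- simulateLabeling(sys, fl, tracerProgram(species = "IN"), times = tt,
                        ngrid = 4000)
  expect_lt(max(abs(a$mids[["R[1,2,3,4]"]] - b$mids[["R[1,2,3,4]"]])), 1e-6)
})

test_that("non-steady flux states are rejected", {
  mdl <- toy_pool()
  sys <- emuDecompose(mdl, "B[1]")
  bad <- FluxState(net = c("in" = 2, out = 1), pools = c(B = 0.5))
  expect_error(simulateLabeling(sys, bad, times = 10), "steady state")
})

test_that("exponential washin slows early labeling but not the plateau", {
  mdl <- toy_pool()
  sys <- emuDecompose(mdl, "B[1]")
  fl <- FluxState(net = c("in" = 60, out = 60), pools = c(B = 0.5))
  step <- simulateLabeling(sys, fl, tracerProgram(purity = 1, tau_switch = 0),
                           times = c(0.25, 30), ngrid = 600)
  wash <- simulateLabeling(sys, fl, tracerProgram(purity = 1, tau_switch = 5),
                           times = c(0.25, 30), ngrid = 600)
  expect_lt(wash$mids[["B[1]"]][2, 1], step$mids[["B[1]"]][2, 1])
  expect_equal(wash$mids[["B[1]"]][2, 2], step$mids[["B[1]"]][2, 2],
               tolerance = 1e-4)
})

test_that("meanEnrichment computes fractional labeling", {
  expect_equal(meanEnrichment(c(1, 0, 0)), 0)
  expect_equal(meanEnrichment(c(0, 0, 1)), 1)
  expect_equal(meanEnrichment(c(0.25, 0.5, 0.25)), 0.5)
  expect_error(meanEnrichment(c(0.5, 0.4)), "sum to 1")
})
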