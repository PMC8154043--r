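test_that("residuals are variance-weighted differences plus boundary terms", {
  spec <- generatorSpec("mini")
  d0 <- generateDataset(spec, seed = 1, noise = FALSE)
  cfg <- fitConfig("mini")
  ## noiseless data at the generating truth: SSR exactly zero
  r0 <- fluxResiduals(spec$model, spec$truth, d0, cfg, ngrid = 400)
  expect_lt(r0$ssr, 1e-12)
  expect_equal(r0$n, nrow(midData(d0)) + 3 + length(cfg$pools_fit))
  ## displacing one datum by 2 sd adds an SSR contribution of 4
  d1 <- d0
  i <- which(midData(d1)$fragment == "tri_c" & midData(d1)$time == 5)[1]
  d1@data$value[i] <- d1@data$value[i] + 2 * d1@data$sd[i]
  r1 <- fluxResiduals(spec$model, spec$truth, d1, cfg, ngrid = 400)
  expect_equal(r1$ssr, 4, tolerance = 1e-6)
  ## fragments not in the model are rejected
  d2 <- d0
  d2@fragments <- rbind(d2@fragments,
                        fragmentDef("ghost", "NOPE.c:1-2"))
  expect_error(fluxResiduals(spec$model, spec$truth, d2, cfg),
               "unknown metabolite|absent from the model")
})

test_that("SSR at truth lies inside the empirical noise band", {
  ## the exact SSR-at-truth distribution under the generator's truncated,
  ## renormalized, sd-floored noise has no closed form; simulate it
  spec <- generatorSpec("mini")
  cfg <- fitConfig("mini")
  ssrs <- vapply(1:60, function(s) {
    d <- generateDataset(spec, seed = 1000 + s)
    fluxResiduals(spec$model, spec$truth, d, cfg, ngrid = 300)$ssr
  }, 0)
  d <- generateDataset(spec, seed = 1)
  s1 <- fluxResiduals(spec$model, spec$truth, d, cfg, ngrid = 300)$ssr
  expect_gt(s1, stats::quantile(ssrs, 0.005))
  expect_lt(s1, stats::quantile(ssrs, 0.995))
})

test_that("truth-started fit on noiseless data stays at the truth", {
  spec <- generatorSpec("mini")
  d0 <- generateDataset(spec, seed = 1, noise = FALSE)
  cfg <- fitConfig("mini")
  tr <- spec$truth
  th_truth <- fluxStartTheta(cfg, tr)
  fit <- fitFluxes(spec$model, d0, cfg, n_starts = 1, seed = 1,
                   start = th_truth, explore_iter = 2, polish_iter = 10,
                   n_polish = 1, ngrid = 400)
  expect_lt(fit@ssr, 1e-6)
  rel <- abs(fit@flux@net - tr@net) / pmax(abs(tr@net), 1e-6)
  expect_lt(max(rel), 1e-3)
  ## projected dilutions recover the generator's values
  expect_equal(fit@flux@dilution[names(tr@dilution)], tr@dilution,
               tolerance = 1e-3)
})

test_that("multi-start fit recovers the truth from random starts (noiseless)", {
  spec <- generatorSpec("mini")
  d0 <- generateDataset(spec, seed = 1, noise = FALSE)
  cfg <- fitConfig("mini")
  fit <- fitFluxes(spec$model, d0, cfg, n_starts = 12, seed = 3,
                   explore_iter = 30, polish_iter = 60, n_polish = 2,
                   ngrid = 400)
  tr <- spec$truth
  major <- names(which(abs(tr@net) > 0.1))
  rel <- abs(fit@flux@net[major] - tr@net[major]) / abs(tr@net[major])
  expect_lt(max(rel), 0.02)
  rl <- fit@diagnostics$RL
  expect_equal(rl$RL_total, 1.35, tolerance = 0.03)
})

test_that("flux recovery from noisy replicates is accurate for major fluxes", {
  spec <- generatorSpec("mini")
  cfg <- fitConfig("mini")
  tr <- spec$truth
  major <- names(which(tr@net > 0.3))
  rels <- c()
  for (s in 1:6) {
    d <- generateDataset(spec, seed = 200 + s)
    fit <- fitFluxes(spec$model, d, cfg, n_starts = 4, seed = s,
                     explore_iter = 25, polish_iter = 30, n_polish = 1)
    rels <- c(rels, abs(fit@flux@net[major] - tr@net[major]) / tr@net[major])
  }
  expect_lt(stats::median(rels), 0.10)
})

test_that("forced scenarios hold their equality and never improve the SSR", {
  spec <- generatorSpec("mini")
  cfg <- fitConfig("mini")
  d <- generateDataset(spec, seed = 11)
  fu <- fitFluxes(spec$model, d, cfg, "unconstrained", n_starts = 4, seed = 1)
  fits <- list(fu)
  for (sc in c("forced_co2np", "forced_tca", "forced_fatty_acid")) {
    f <- fitFluxes(spec$model, d, cfg, sc, n_starts = 2, seed = 1,
                   start = fu@par, explore_iter = 15, polish_iter = 25)
    rl <- f@diagnostics$RL
    forced_val <- switch(sc, forced_co2np = rl$RL_total,
                         forced_tca = rl$tca,
                         forced_fatty_acid = rl$fatty_acid)
    expect_equal(forced_val, cfg$RL_measured, tolerance = 1e-8, label = sc)
    expect_gte(f@ssr, fu@ssr - 1e-6)
    fits[[sc]] <- f
  }
  tab <- scenarioCompare(fits)
  expect_equal(tab$scenario[1], "unconstrained")
  expect_true(all(diff(tab$ssr) >= -1e-9))
})

test_that("scenarioCompare validates inputs", {
  spec <- generatorSpec("mini")
  cfg <- fitConfig("mini")
  d <- generateDataset(spec, seed = 11)
  fu <- fitFluxes(spec$model, d, cfg, n_starts = 2, seed = 1,
                  explore_iter = 10, polish_iter = 10)
  expect_error(scenarioCompare(list(fu)), "at least two")
  ## identical fits compare with zero SSR difference
  tab <- scenarioCompare(list(fu, fu))
  expect_equal(tab$dssr, c(0, 0))
  ## different data -> digest mismatch
  f2 <- fu
  f2@diagnostics$digest <- fu@diagnostics$digest + 1
  expect_error(scenarioCompare(list(fu, f2)), "different datasets")
})

test_that("chi-square acceptance interval and verdicts", {
  acc <- chi2Accept(810, 1753)
  expect_equal(acc$lower, qchisq(0.025, 1753), tolerance = 1e-12)
  expect_equal(acc$upper, qchisq(0.975, 1753), tolerance = 1e-12)
  expect_equal(round(acc$lower, 1), 1638.9)
  expect_equal(round(acc$upper, 1), 1870.9)
  expect_false(acc$accepted)   # under-dispersed relative to 1753 dof
  expect_true(chi2Accept(1750, 1753)$accepted)
  expect_false(chi2Accept(0, 10)$accepted)
  expect_false(chi2Accept(100, 10)$accepted)
})

test_that("the objective is smooth: forward and central differences agree", {
  spec <- generatorSpec("mini")
  cfg <- fitConfig("mini")
  d <- generateDataset(spec, seed = 5)
  ctx <- leafMFA:::.fit_context(spec$model, d, cfg, "unconstrained", 200)
  th <- leafMFA:::.start_theta(ctx)
  ctx$nres_hint <- length(leafMFA:::.evaluate(ctx, th)$res)
  ssr <- function(t) leafMFA:::.evaluate(ctx, t)$ssr
  set.seed(8)
  for (k in 1:3) {
    th_k <- th + stats::rnorm(length(th), 0, 0.05)
    h <- 1e-4
    for (j in sample(seq_along(th), 3)) {
      tp <- th_k; tp[j] <- tp[j] + h
      tm <- th_k; tm[j] <- tm[j] - h
      fwd <- (ssr(tp) - ssr(th_k)) / h
      cen <- (ssr(tp) - ssr(tm)) / (2 * h)
      expect_equal(fwd, cen, tolerance = 1e-2)
    }
  }
})
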