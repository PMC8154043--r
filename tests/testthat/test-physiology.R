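test_that("laiskRL is exact on noise-free lines through a common point", {
  ## three constructed lines through (Ci* = 40, A* = -1.4)
  ci <- c(30, 60, 100, 200)
  mk <- function(s, l) data.frame(light = l, Ci = ci,
                                  A = -1.4 + s * (ci - 40), replicate = 1)
  curves <- rbind(mk(0.02, 50), mk(0.05, 120), mk(0.08, 500))
  est <- laiskRL(curves)
  expect_equal(est$RL$value, 1.4, tolerance = 1e-10)
  expect_equal(est$Ci_star, 40, tolerance = 1e-8)
})

test_that("laiskRL is exact for random common-point constructions", {
  set.seed(21)
  for (k in 1:10) {
    rl <- stats::runif(1, 0.5, 3); cistar <- stats::runif(1, 20, 60)
    slopes <- sort(stats::runif(stats::rpois(1, 2) + 3, 0.01, 0.1))
    curves <- do.call(rbind, lapply(seq_along(slopes), function(j)
      data.frame(light = j * 50, Ci = c(30, 80, 150, 300),
                 A = -rl + slopes[j] * (c(30, 80, 150, 300) - cistar),
                 replicate = 1)))
    est <- laiskRL(curves)
    expect_equal(est$RL$value, rl, tolerance = 1e-8)
    expect_equal(est$Ci_star, cistar, tolerance = 1e-6)
  }
})

test_that("laiskRL recovers the truth from the five-light measurement design", {
  curves <- generateGasExchange(truth_RL = 1.4, truth_Ci_star = 40,
                                noise_sd = 0.1, n_reps = 4, seed = 5)
  est <- laiskRL(curves)
  expect_equal(est$RL$value, 1.4, tolerance = 0.15)
  expect_gt(est$RL$sd, 0)
  expect_equal(est$RL$n, 4)
  ## area -> fresh weight conversion lands near the printed pair
  perFW <- areaToFW(est$RL$value, 536)
  expect_equal(perFW, 9.4, tolerance = 0.1 * 9.4)
})

test_that("laiskRL rejects unstable or underdetermined inputs", {
  ci <- c(30, 60, 100)
  two <- rbind(data.frame(light = 50, Ci = ci, A = 1 + 0.02 * ci, replicate = 1),
               data.frame(light = 90, Ci = ci, A = 1 + 0.02 * ci, replicate = 1))
  expect_error(laiskRL(two), "three light levels")
  par3 <- do.call(rbind, lapply(c(50, 90, 120), function(l)
    data.frame(light = l, Ci = ci, A = 1 + 0.02 * ci, replicate = 1)))
  expect_error(laiskRL(par3), "parallel")
})

test_that("meanCI95 reproduces the summary-statistics interval", {
  expect_equal(meanCI95(9.4, 1.3, 4), c(8.1, 10.7))
  expect_equal(meanCI95(5, 0, 3), c(5, 5))
  expect_equal(meanCI95(0, 1, 4, digits = 2), c(-0.98, 0.98))
})

test_that("sucroseRate recovers the active fraction and printed rate", {
  ## plateau at M0 = 0.4 (active fraction 0.6), fast active pool
  syn <- generateSucroseLabeling(active_fraction = 0.6, tau_min = 3)
  est <- sucroseRate(syn$f361, syn$f451, syn$times, suc_conc = 3.6,
                     transit_time = 0.5)
  expect_equal(est$active_fraction, 0.6, tolerance = 1e-4)
  expect_equal(est$rate$value, 4.32, tolerance = 1e-3)
  expect_equal(round(est$rate$value, 1), 4.3)
  ## fully active pool: rate = conc / transit
  syn2 <- generateSucroseLabeling(active_fraction = 1, tau_min = 3)
  est2 <- sucroseRate(syn2$f361, syn2$f451, syn2$times, suc_conc = 3.6,
                      transit_time = 0.5)
  expect_equal(est2$rate$value, 3.6 / 0.5, tolerance = 1e-3)
  ## 70/30 split with noise recovered within 0.02
  syn3 <- generateSucroseLabeling(active_fraction = 0.7, tau_min = 3,
                                  noise_sd = 0.01, seed = 4)
  est3 <- sucroseRate(syn3$f361, syn3$f451, syn3$times)
  expect_equal(est3$active_fraction, 0.7, tolerance = 0.02)
})

test_that("sucroseRate errors when M0 has not plateaued", {
  syn <- generateSucroseLabeling(active_fraction = 0.6, tau_min = 60)
  expect_error(sucroseRate(syn$f361, syn$f451, syn$times), "plateau")
})

test_that("sucroseRate is invariant to swapping fragments with their weights", {
  syn <- generateSucroseLabeling(active_fraction = 0.55, tau_min = 3)
  a <- sucroseRate(syn$f361, syn$f451, syn$times)
  b <- sucroseRate(syn$f451, syn$f361, syn$times, fru_weights = c(0.92, 0.54))
  expect_equal(a$rate$value, b$rate$value, tolerance = 1e-10)
})

test_that("starchRate fits the linear buildup", {
  tt <- 2:8
  est <- starchRate(tt, 5 + 9.5 * tt)
  expect_equal(est$rate$value, 9.5, tolerance = 1e-10)
  expect_equal(est$r_squared, 1)
  expect_equal(starchRate(tt, rep(7, 7))$rate$value, 0)
  set.seed(2)
  noisy <- starchRate(tt, 3 + 5 * tt + stats::rnorm(7, 0, 0.5))
  expect_lt(abs(noisy$rate$value - 5), 2 * noisy$rate$sd + 1e-9)
  expect_error(starchRate(c(2, 3), c(1, 2)), ">= 3 points")
})

test_that("fattyAcidCO2 reproduces the printed leaf-turnover bound", {
  out <- fattyAcidCO2(43, c(0.016, 0.04), 12, 8, 256.4)
  expect_equal(round(out, 3), c(0.005, 0.012))
  expect_equal(fattyAcidCO2(0, 0.04), 0)
  ## linear in content and turnover
  expect_equal(fattyAcidCO2(86, 0.04), 2 * fattyAcidCO2(43, 0.04))
  expect_equal(fattyAcidCO2(43, 0.08), 2 * fattyAcidCO2(43, 0.04))
})

test_that("areaToFW converts with the fixture leaf mass per area", {
  expect_equal(areaToFW(1.4, 536), 9.40, tolerance = 1e-2)
  expect_equal(areaToFW(0, 536), 0)
  expect_equal(areaToFW(18.3, 536), 122.9, tolerance = 0.05)
})
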