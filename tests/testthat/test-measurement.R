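test_that("natural-abundance matrix matches hand-built binomial terms", {
  a <- 0.0107
  M1 <- naturalAbundanceMatrix("", 1)
  expect_equal(M1, matrix(c(1 - a, a, 0, 1), 2, 2), tolerance = 1e-12)
  M2 <- naturalAbundanceMatrix("", 2)
  expect_equal(M2[2, 1], 2 * a * (1 - a), tolerance = 1e-12)
  expect_equal(M2[3, 1], a^2, tolerance = 1e-12)
  ## zero abundances -> identity
  tab0 <- lapply(isotopeTable(), function(x) c(1, numeric(length(x) - 1)))
  expect_equal(naturalAbundanceMatrix("C2Si", 3, tab0), diag(4))
})

test_that("correction matrix inverts a forward-simulated spectrum", {
  M <- naturalAbundanceMatrix("C8H20NOSi", 3)
  x <- c(0.55, 0.2, 0.05, 0.2)
  raw <- drop(M %*% x)
  rec <- correctMID(raw, M)
  expect_equal(as.numeric(rec), x, tolerance = 1e-10)
  ## identity matrix leaves input unchanged
  expect_equal(as.numeric(correctMID(x, diag(4))), x)
  ## unlabeled compound's raw spectrum corrects to [1, 0, ...]
  raw0 <- drop(M %*% c(1, 0, 0, 0))
  expect_equal(as.numeric(correctMID(raw0, M)), c(1, 0, 0, 0),
               tolerance = 1e-10)
  ## inconsistent spectrum triggers the negative-component warning
  bad <- raw0; bad[1] <- bad[1] - 0.1; bad[2] <- bad[2] + 0.1
  expect_warning(correctMID(c(0.2, 0, 0.8, 0), M), "negative")
})

test_that("round-trip correction holds for all fixture formulas", {
  fr <- camelinaFragments()
  set.seed(3)
  for (i in which(nzchar(fr$formula))) {
    pc <- leafMFA:::.parse_components(fr[i, ])
    n <- length(pc$comps[[1]]$positions)
    M <- naturalAbundanceMatrix(fr$formula[i], n)
    x <- stats::runif(n + 1); x <- x / sum(x)
    expect_equal(as.numeric(correctMID(drop(M %*% x), M)), x,
                 tolerance = 1e-10, label = fr$fragment[i])
  }
})

test_that("fragment prediction mixes moieties and dilution correctly", {
  ## fructosyl fully labeled (M6), glucosyl unlabeled -> m/z 361 M6 = 0.54
  sim <- list(times = 0,
              mids = list("SUC.c[1,2,3,4,5,6]" = matrix(c(1, rep(0, 6))),
                          "SUC.c[7,8,9,10,11,12]" = matrix(c(rep(0, 6), 1))))
  fr <- fragmentDef("suc_361", "SUC.c:1-6|SUC.c:7-12", "0.46|0.54")
  pred <- predictFragment(sim, fr[1, ], numeric(0))
  expect_equal(pred[7, 1], 0.54)
  expect_equal(pred[1, 1], 0.46)
  ## full dilution returns the unlabeled vector at all times
  pred1 <- predictFragment(sim, fr[1, ], c(SUC.c = 1))
  expect_equal(pred1[, 1], c(1, rep(0, 6)))
  ## d = 0.4 with active M0 = 0 at plateau -> observed M0 = 0.4
  sim2 <- list(times = 0,
               mids = list("SUC.c[1,2,3,4,5,6]" = matrix(c(0, rep(0, 5), 1)),
                           "SUC.c[7,8,9,10,11,12]" = matrix(c(0, rep(0, 5), 1))))
  pred2 <- predictFragment(sim2, fr[1, ], c(SUC.c = 0.4))
  expect_equal(pred2[1, 1], 0.4)
  expect_equal(sum(pred2[, 1]), 1)
  ## dilution mixing is affine in d
  d1 <- predictFragment(sim2, fr[1, ], c(SUC.c = 0.2))
  d2 <- predictFragment(sim2, fr[1, ], c(SUC.c = 0.6))
  dm <- predictFragment(sim2, fr[1, ], c(SUC.c = 0.4))
  expect_equal((d1 + d2) / 2, dm, tolerance = 1e-12)
})

test_that("missing trajectories raise an error", {
  sim <- list(times = 0, mids = list())
  fr <- fragmentDef("x", "SUC.c:1-6")
  expect_error(predictFragment(sim, fr[1, ], numeric(0)), "missing trajectory")
})

test_that("sucrose deconvolution solves the printed mixing system", {
  ## unlabeled in, unlabeled out
  u <- c(1, rep(0, 6))
  dec <- deconvolveSucrose(u, u)
  expect_equal(dec$fGlu, u)
  expect_equal(dec$fFru, u)
  ## forward-mix random moieties, recover exactly
  set.seed(9)
  fGlu <- stats::runif(7); fGlu <- fGlu / sum(fGlu)
  fFru <- stats::runif(7); fFru <- fFru / sum(fFru)
  f361 <- 0.54 * fFru + 0.46 * fGlu
  f451 <- 0.92 * fFru + 0.08 * fGlu
  dec2 <- deconvolveSucrose(f361, f451)
  expect_equal(dec2$fGlu, fGlu, tolerance = 1e-10)
  expect_equal(dec2$fFru, fFru, tolerance = 1e-10)
  ## the fully-13C6-fructosyl standard: M6 mixture fractions
  m6 <- c(rep(0, 6), 1)
  f361s <- 0.54 * m6 + 0.46 * u
  f451s <- 0.92 * m6 + 0.08 * u
  dec3 <- deconvolveSucrose(f361s, f451s)
  expect_equal(dec3$fFru, m6, tolerance = 1e-10)
  expect_equal(dec3$fGlu, u, tolerance = 1e-10)
  ## re-mixing reproduces the inputs (linear consistency)
  expect_equal(0.54 * dec2$fFru + 0.46 * dec2$fGlu, f361, tolerance = 1e-10)
  ## degenerate coefficients error
  expect_error(deconvolveSucrose(u, u, fru_weights = c(0.5, 0.5)),
               "degenerate")
})
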