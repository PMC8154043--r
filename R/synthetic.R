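## Synthetic-data generation: ground-truth labeling datasets emulating a
## 13CO2 leaf labeling experiment (12 sampling times over 0-60 min, three
## replicates, fragment-specific Gaussian noise truncated at zero and
## renormalized, slow-labeling organic-acid pools behind large vacuolar
## dilution), plus gas-exchange curve and sucrose-labeling generators for
## the physiology estimators.

#' Specification for the synthetic dataset generator
#'
#' Defaults encode the study conditions: the leaf fixture truth (shunt 4.6,
#' TCA-associated release 1.6 offset by PEP carboxylation 1.1, plastidic
#' pyruvate decarboxylation 0, starch 9.5, sucrose export 4.3, v_o/v_c 0.2),
#' the 12-point 0-60 min sampling grid, 3 replicates, 99 atom % tracer and
#' per-fragment sd of 0.01-0.02 mole fraction.
#'
#' @param model "camelina" or "mini".
#' @param times sampling times, minutes.
#' @param replicates biological replicates per time point.
#' @param purity tracer purity (atom fraction 13C).
#' @param sd_floor lower bound applied to reported measurement sd.
#' @param boundary_sd named sds for the measured boundary rates
#'   (A_net, starch, sucrose; umol gFW-1 h-1).
#' @return list of class \code{"generatorSpec"}.
#' @export
generatorSpec <- function(model = c("camelina", "mini"),
                          times = c(0, 0.5, 1, 2, 2.5, 3, 5, 7, 10, 15, 30, 60),
                          replicates = 3, purity = 0.99, sd_floor = 0.005,
                          boundary_sd = NULL) {
  name <- match.arg(model)
  mdl <- if (name == "camelina") camelinaLeafModel() else miniLeafModel()
  truth <- if (name == "camelina") camelinaTruth(mdl) else miniTruth(mdl)
  frags <- if (name == "camelina") camelinaFragments() else miniFragments()
  cfg <- fitConfig(name)
  if (is.null(boundary_sd))
    boundary_sd <- if (name == "camelina")
      c(A_net = 5, starch = 0.1, sucrose = 1.08)
    else c(A_net = 0.2, starch = 0.1, sucrose = 0.1)
  structure(list(name = name, model = mdl, truth = truth, fragments = frags,
                 times = times, replicates = replicates, purity = purity,
                 sd_floor = sd_floor, boundary_sd = boundary_sd,
                 pool_meas_sd = 0.2, config = cfg), class = "generatorSpec")
}

.trunc_noise <- function(x, sd, rng_ok = 50) {
  ## Gaussian noise truncated at zero (redraw), vectorized
  out <- x + stats::rnorm(length(x), 0, sd)
  for (k in seq_len(rng_ok)) {
    bad <- out < 0
    if (!any(bad)) break
    out[bad] <- x[bad] + stats::rnorm(sum(bad), 0, sd[bad])
  }
  out[out < 0] <- 0
  out
}

#' Generate a synthetic MID labeling dataset with known truth
#'
#' Simulates the truth flux state, predicts every fragment (moiety mixing
#' plus inactive-pool dilution), averages \code{replicates} noisy replicates
#' per measurement (truncated Gaussian, renormalized per time point), jitters
#' the boundary rates within their sd, and records the truth for recovery
#' scoring. Fully reproducible from \code{seed}.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @param seed integer seed.
#' @param noise logical; FALSE returns the deterministic prediction
#'   (replicate count 1, no jitter).
#' @param ngrid simulator grid resolution.
#' @return a \code{\link{MIDTimeSeries}} with the truth record in
#'   \code{@meta$truth}.
#' @export
generateDataset <- function(spec, seed = 1, noise = TRUE, ngrid = 400) {
  stopifnot(inherits(spec, "generatorSpec"))
  if (any(spec$truth@pools <= 0)) stop("infeasible truth: non-positive pools")
  set.seed(seed)
  sys <- emuDecompose(spec$model, fragmentTargets(spec$fragments))
  sim <- simulateLabeling(sys, spec$truth, tracerProgram(purity = spec$purity),
                          times = spec$times, ngrid = ngrid)
  rows <- list()
  for (i in seq_len(nrow(spec$fragments))) {
    fr <- spec$fragments[i, ]
    pred <- predictFragment(sim, fr, spec$truth@dilution)
    w <- nrow(pred)
    ## signal-dependent noise (MS counting statistics): full fragment sd at
    ## mid-scale fractions, much smaller near 0 and 1
    sd_rep <- fr$sd * (0.15 + 1.7 * sqrt(pmax(pred * (1 - pred), 0)))
    if (noise) {
      acc <- 0
      for (r in seq_len(spec$replicates)) {
        rep_m <- matrix(.trunc_noise(as.vector(pred), as.vector(sd_rep)),
                        w, ncol(pred))
        rep_m <- sweep(rep_m, 2, colSums(rep_m), "/")
        acc <- acc + rep_m
      }
      meas <- acc / spec$replicates
      sd_eff <- pmax(sd_rep / sqrt(spec$replicates), spec$sd_floor)
    } else {
      meas <- pred
      sd_eff <- pmax(sd_rep, spec$sd_floor)
    }
    rows[[i]] <- data.frame(
      fragment = fr$fragment,
      time = rep(spec$times, each = w),
      iso = rep(0:(w - 1), length(spec$times)),
      value = as.vector(meas),
      sd = as.vector(sd_eff), stringsAsFactors = FALSE)
  }
  truth_rl <- computeRL(spec$model, spec$truth)
  truth_A <- netAssimilation(spec$model, spec$truth)
  bmap <- spec$config$boundary
  bval <- c(A_net = truth_A,
            starch = unname(spec$truth@net[[bmap$starch]]),
            sucrose = unname(spec$truth@net[[bmap$sucrose]]))
  bsd <- spec$boundary_sd[names(bval)]
  if (noise) bval <- bval + stats::rnorm(length(bval), 0, bsd)
  rates <- data.frame(quantity = names(bval), value = unname(bval),
                      sd = unname(bsd), stringsAsFactors = FALSE)
  ## measured pool sizes of the quantified metabolites (lognormal, 20%
  ## measurement error, weighted with a conservative 0.25 log-sd). A
  ## chemical pool measurement sees the TOTAL pool -- active plus inactive
  ## (vacuolar) -- i.e. active/(1 - dilution fraction).
  dil <- spec$truth@dilution
  pmets <- sort(unique(c(spec$config$pools_fit, names(dil))))
  pmets <- pmets[pmets %in% names(spec$truth@pools)]
  pm <- spec$truth@pools[pmets] /
    (1 - ifelse(pmets %in% names(dil), dil[pmets], 0))
  if (noise) pm <- pm * exp(stats::rnorm(length(pm), 0, spec$pool_meas_sd))
  rates <- rbind(rates, data.frame(
    quantity = paste0("pool:", names(pm)), value = unname(pm),
    sd = 0.25, stringsAsFactors = FALSE))
  new("MIDTimeSeries",
      data = do.call(rbind, rows), fragments = spec$fragments, rates = rates,
      meta = list(truth = spec$truth, truth_RL = truth_rl,
                  truth_A_net = truth_A, RL_measured = spec$config$RL_measured,
                  purity = spec$purity, replicates = spec$replicates,
                  seed = seed, model = spec$name))
}

#' Generate synthetic A-Ci gas-exchange curves with a common intersection
#'
#' Linear CO2-response lines at several sub-saturating light levels, all
#' passing through the common point (Ci*, -R_L), with light-dependent slopes
#' and Gaussian noise on the assimilation rate. Emulates the measurement
#' design used for common-intersection (Laisk) estimation of respiration in
#' the light.
#'
#' @param truth_RL true R_L (umol CO2 m-2 s-1, positive).
#' @param truth_Ci_star true intersection Ci (uL L-1).
#' @param light_levels PAR values; slopes increase saturating with light.
#' @param ci_points intercellular CO2 values sampled per curve.
#' @param noise_sd Gaussian sd on A (umol m-2 s-1).
#' @param n_reps biological replicates.
#' @param seed integer seed.
#' @return data.frame with columns light, Ci, A, replicate.
#' @export
generateGasExchange <- function(truth_RL = 1.4, truth_Ci_star = 40,
                                light_levels = c(50, 90, 120, 175, 500),
                                ci_points = c(30, 50, 75, 100, 150, 250, 400),
                                noise_sd = 0.1, n_reps = 4, seed = 1) {
  if (length(light_levels) < 2) stop("need at least two light levels")
  set.seed(seed)
  slopes <- 0.09 * light_levels / (light_levels + 120)
  out <- list()
  for (r in seq_len(n_reps)) {
    sl <- slopes * exp(stats::rnorm(length(slopes), 0, 0.02))
    for (j in seq_along(light_levels)) {
      A <- -truth_RL + sl[j] * (ci_points - truth_Ci_star) +
        stats::rnorm(length(ci_points), 0, noise_sd)
      out[[length(out) + 1]] <- data.frame(
        light = light_levels[j], Ci = ci_points, A = A, replicate = r)
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic two-pool sucrose labeling time course
#'
#' The active moiety pool labels with time constant \code{tau_min} while the
#' inactive fraction stays unlabeled; moiety MIDs move mass from M0 to M6 and
#' are mixed into the m/z 361 and 451 fragment signals with the configured
#' glucosyl/fructosyl weights.
#'
#' @param active_fraction fraction of the sucrose pool that turns over.
#' @param tau_min labeling time constant of the active pool (minutes).
#' @param times sampling times (minutes).
#' @param fru_weights fructosyl fraction in (m/z 361, m/z 451).
#' @param noise_sd Gaussian noise sd (0 = deterministic).
#' @param seed integer seed.
#' @return list with \code{times}, \code{f361}, \code{f451} (7 x T matrices).
#' @export
generateSucroseLabeling <- function(active_fraction = 0.6, tau_min = 6,
                                    times = c(0, 0.5, 1, 2, 2.5, 3, 5, 7, 10,
                                              15, 30, 60),
                                    fru_weights = c(0.54, 0.92),
                                    noise_sd = 0, seed = 1) {
  set.seed(seed)
  lab <- active_fraction * (1 - exp(-times / tau_min))
  moiety <- function(l) rbind(1 - l, matrix(0, 5, length(l)), l)
  fGlu <- moiety(lab); fFru <- moiety(lab)
  mix <- function(wf) wf * fFru + (1 - wf) * fGlu
  f361 <- mix(fru_weights[1]); f451 <- mix(fru_weights[2])
  if (noise_sd > 0) {
    jig <- function(m) {
      m <- matrix(.trunc_noise(as.vector(m), rep(noise_sd, length(m))),
                  nrow(m), ncol(m))
      sweep(m, 2, colSums(m), "/")
    }
    f361 <- jig(f361); f451 <- jig(f451)
  }
  list(times = times, f361 = f361, f451 = f451)
}
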