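## Gas-exchange and rate estimators that constrain the flux analysis:
## common-intersection (Laisk) respiration in the light, sucrose synthesis
## rate from moiety labeling, starch synthesis rate from its linear buildup,
## a fatty-acid-turnover CO2 bound, and leaf-area/fresh-weight conversion.

#' Common-intersection (Laisk) estimate of respiration in the light
#'
#' Fits an ordinary least-squares line A = a + s Ci to each light level's
#' CO2-response points and finds the common intersection by regressing
#' intercepts on slopes (a = A* - Ci* s): the slope of that regression is
#' -Ci* and its intercept is A*, so R_L = -A*. Replicate-level estimates are
#' aggregated to mean and sd.
#'
#' @param curves data.frame with columns \code{light}, \code{Ci}, \code{A}
#'   and optionally \code{replicate}.
#' @param slope_tol minimum spread of the per-light slopes; near-parallel
#'   lines make the intersection unstable.
#' @return list with \code{RL} (list value/sd/n, umol CO2 m-2 s-1),
#'   \code{Ci_star} (uL L-1), and the per-replicate estimates.
#' @export
laiskRL <- function(curves, slope_tol = 1e-3) {
  if (is.null(curves$replicate)) curves$replicate <- 1L
  reps <- unique(curves$replicate)
  est <- lapply(reps, function(r) {
    cv <- curves[curves$replicate == r, ]
    lights <- unique(cv$light)
    if (length(lights) < 3)
      stop("laiskRL: need at least three light levels, got ", length(lights))
    fits <- t(vapply(lights, function(l) {
      sub <- cv[cv$light == l, ]
      if (nrow(sub) < 2) stop("laiskRL: fewer than 2 points at light ", l)
      stats::coef(stats::lm(A ~ Ci, data = sub))
    }, c(a = 0, s = 0)))
    if (diff(range(fits[, 2])) < slope_tol)
      stop("laiskRL: intersection unstable (slopes nearly parallel, spread ",
           signif(diff(range(fits[, 2])), 3), ")")
    cf <- stats::coef(stats::lm(fits[, 1] ~ fits[, 2]))
    c(A_star = unname(cf[1]), Ci_star = unname(-cf[2]))
  })
  A_star <- vapply(est, `[[`, 0, "A_star")
  Ci_star <- vapply(est, `[[`, 0, "Ci_star")
  list(RL = list(value = mean(-A_star),
                 sd = if (length(reps) > 1) stats::sd(-A_star) else 0,
                 n = length(reps), units = "umol CO2 m-2 s-1"),
       Ci_star = mean(Ci_star),
       replicates = data.frame(replicate = reps, RL = -A_star,
                               Ci_star = Ci_star))
}

#' 95% confidence interval of a mean from summary statistics
#'
#' mean +/- 1.96 sd/sqrt(n), rounded to the configured display precision.
#'
#' @param mean,sd,n summary statistics (n >= 2, sd >= 0).
#' @param digits rounding for display (default 1 decimal).
#' @return numeric c(lower, upper).
#' @examples
#' meanCI95(9.4, 1.3, 4)  # (8.1, 10.7)
#' @export
meanCI95 <- function(mean, sd, n, digits = 1) {
  stopifnot(n >= 2, sd >= 0)
  half <- 1.96 * sd / sqrt(n)
  round(c(mean - half, mean + half), digits)
}

#' Sucrose synthesis rate from moiety labeling kinetics
#'
#' Deconvolves the glucosyl and fructosyl moiety MIDs from the m/z 361 and
#' 451 fragments, detects the late-time plateau of the unlabeled (M0)
#' fraction, and computes the synthesis rate as
#' active_fraction x [sucrose] / transit time.
#'
#' @param f361,f451 7 x T MID matrices of the two sucrose fragments.
#' @param times sampling times, minutes.
#' @param suc_conc leaf sucrose concentration, umol gFW-1.
#' @param transit_time time to reach the export pool, hours.
#' @param fru_weights fructosyl mixing fractions (see
#'   \code{\link{deconvolveSucrose}}).
#' @param plateau_from start of the plateau window, minutes.
#' @param slope_tol maximum |dM0/dt| inside the window, fraction per minute.
#' @return list with \code{rate} (value/sd, umol sucrose gFW-1 h-1) and
#'   \code{active_fraction}.
#' @export
sucroseRate <- function(f361, f451, times, suc_conc = 3.6, transit_time = 0.5,
                        fru_weights = c(0.54, 0.92), plateau_from = 30,
                        slope_tol = 0.001) {
  win <- which(times >= plateau_from)
  if (length(win) < 2) stop("sucroseRate: need >= 2 points at t >= ",
                            plateau_from, " min")
  m0 <- vapply(seq_along(times), function(k) {
    dec <- deconvolveSucrose(f361[, k], f451[, k], fru_weights)
    c(dec$fGlu[1], dec$fFru[1])
  }, c(0, 0))
  m0w <- colMeans(m0)[win]
  slope <- stats::coef(stats::lm(m0w ~ times[win]))[2]
  if (abs(slope) > slope_tol)
    stop("sucroseRate: no plateau detected after ", plateau_from,
         " min (M0 slope ", signif(slope, 3), " per min)")
  active <- 1 - mean(m0w)
  sd_act <- stats::sd(c(1 - m0[1, win], 1 - m0[2, win]))
  list(rate = list(value = active * suc_conc / transit_time,
                   sd = sd_act * suc_conc / transit_time,
                   units = "umol sucrose gFW-1 h-1"),
       active_fraction = active)
}

#' Starch synthesis rate from its linear buildup after illumination
#'
#' @param times_h sampling times, hours after illumination.
#' @param starch starch content, umol glucose gFW-1.
#' @param window time window used for the regression (hours).
#' @return list with \code{rate} (value = OLS slope, sd = its standard
#'   error), and \code{r_squared} as a linearity check.
#' @export
starchRate <- function(times_h, starch, window = c(2, 8.5)) {
  sel <- times_h >= window[1] & times_h <= window[2]
  if (sum(sel) < 3) stop("starchRate: need >= 3 points within the window")
  fit <- stats::lm(starch[sel] ~ times_h[sel])
  sm <- summary(fit)
  list(rate = list(value = unname(stats::coef(fit)[2]),
                   sd = unname(sm$coefficients[2, 2]),
                   units = "umol glucose gFW-1 h-1"),
       r_squared = sm$r.squared)
}

#' CO2 release implied by fatty-acid turnover
#'
#' Every palmitate made by the plastidic fatty-acid synthase releases
#' \code{co2_per_molecule} CO2 during pyruvate decarboxylation to
#' acetyl-CoA. Converts a leaf fatty-acid content and a daily turnover
#' fraction (replaced by synthesis during the photoperiod) into a CO2
#' release rate per leaf area.
#'
#' @param content_ug_per_cm2 fatty-acid content, ug cm-2 leaf area.
#' @param turnover_frac_per_day fraction turned over per day (vector gives a
#'   range).
#' @param daylength_h photoperiod, hours.
#' @param co2_per_molecule CO2 released per fatty-acid molecule synthesized.
#' @param molar_mass g mol-1 (palmitate 256.4).
#' @return numeric vector, umol CO2 m-2 s-1 (one entry per turnover value).
#' @examples
#' fattyAcidCO2(43, c(0.016, 0.04))  # about 0.005 - 0.012
#' @export
fattyAcidCO2 <- function(content_ug_per_cm2 = 43,
                         turnover_frac_per_day = c(0.016, 0.04),
                         daylength_h = 12, co2_per_molecule = 8,
                         molar_mass = 256.4) {
  stopifnot(content_ug_per_cm2 >= 0, daylength_h > 0, molar_mass > 0)
  ug_per_cm2_s <- content_ug_per_cm2 * turnover_frac_per_day /
    (daylength_h * 3600)
  umol_per_m2_s <- ug_per_cm2_s * 1e4 / molar_mass
  umol_per_m2_s * co2_per_molecule
}

#' Convert a leaf-area rate to a fresh-weight rate
#'
#' @param rate_per_area umol m-2 s-1.
#' @param fw_per_area_g_m2 leaf fresh weight per area, g m-2.
#' @return umol gFW-1 h-1.
#' @examples
#' areaToFW(1.4, 536)  # about 9.4
#' @export
areaToFW <- function(rate_per_area, fw_per_area_g_m2 = 536) {
  stopifnot(fw_per_area_g_m2 > 0)
  rate_per_area * 3600 / fw_per_area_g_m2
}
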