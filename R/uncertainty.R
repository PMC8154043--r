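## Confidence intervals for fluxes and derived quantities by (a) parameter
## continuation -- step the quantity away from its optimum, re-optimize all
## other parameters, and find where the profile SSR crosses
## SSR_min + qchisq(0.95, 1) -- and (b) Monte-Carlo resampling of the data
## within the measurement sd followed by warm-started refits.

#' Profile-likelihood confidence interval for a scalar quantity (engine)
#'
#' Generic continuation engine: the quantity is driven to a sequence of
#' targets through a stiff penalty residual while all parameters are
#' re-optimized; the CI bound is where the penalty-free SSR crosses
#' \code{ssr0 + qchisq(level, 1)} (3.84 at 95%), located by linear
#' interpolation between the bracketing steps, with step halving near the
#' crossing. A profile still flat at \code{max_steps} yields an open
#' (infinite) bound, flagged in the result.
#'
#' @param resfun function(par) -> residual vector (penalty-free objective).
#' @param par optimizer-scale parameter vector at the optimum.
#' @param qfun function(par) -> scalar quantity.
#' @param level confidence level.
#' @param step initial step size (default 10% of |q0| or 0.05).
#' @param max_steps maximum continuation steps per direction.
#' @param refit_iter LM iterations per step.
#' @param sd_pen penalty sd tying the quantity to its target.
#' @return list with \code{estimate}, \code{lower}, \code{upper},
#'   \code{open_lower}, \code{open_upper}, \code{ssr0}.
#' @export
profileCI <- function(resfun, par, qfun, level = 0.95, step = NULL,
                      max_steps = 25, refit_iter = 15, sd_pen = NULL) {
  q0 <- qfun(par)
  ssr0 <- sum(resfun(par)^2)
  thr <- stats::qchisq(level, 1)
  if (is.null(step)) step <- max(0.1 * abs(q0), 0.05)
  if (is.null(sd_pen)) sd_pen <- max(abs(q0), 1) * 1e-3
  one_dir <- function(sgn) {
    ## step targets outward, but track the ACHIEVED quantity: a target the
    ## parameterization cannot reach (e.g. negative R_L) leaves q stuck at
    ## the feasibility boundary, which closes the interval there
    par_k <- par; q_prev <- q0; d_prev <- 0; st <- step
    for (k in seq_len(max_steps)) {
      q_t <- q_prev + sgn * st
      aug <- function(th) c(resfun(th), (qfun(th) - q_t) / sd_pen)
      opt <- try(suppressWarnings(minpack.lm::nls.lm(
        par = par_k, fn = aug,
        control = minpack.lm::nls.lm.control(
          maxiter = refit_iter, ftol = 1e-10, epsfcn = 1e-6,
          diag = rep(1, length(par_k))))),
        silent = TRUE)
      if (inherits(opt, "try-error")) return(list(bound = sgn * Inf, open = TRUE))
      par_k <- opt$par
      q_ach <- qfun(par_k)
      d_k <- sum(resfun(par_k)^2) - ssr0
      if (d_k > thr) {
        if (d_k - d_prev < 1e-12 || abs(q_ach - q_prev) < 1e-12)
          return(list(bound = q_ach, open = FALSE))
        ## interpolate on the sqrt(dSSR) scale: exact for locally quadratic
        ## profiles, conservative-robust otherwise
        frac <- (sqrt(thr) - sqrt(max(d_prev, 0))) /
          (sqrt(d_k) - sqrt(max(d_prev, 0)))
        return(list(bound = q_prev + (q_ach - q_prev) * frac, open = FALSE))
      }
      if (sgn * (q_ach - q_prev) < 0.05 * st)
        ## quantity pinned at a domain boundary with acceptable SSR
        return(list(bound = q_ach, open = FALSE))
      ## grow steps over flat stretches, shrink when rising fast
      if (d_k - d_prev < 0.2 * thr) st <- st * 1.7
      else if (d_k - d_prev > 0.6 * thr) st <- st * 0.6
      q_prev <- q_ach; d_prev <- d_k
    }
    list(bound = sgn * Inf, open = TRUE)
  }
  up <- one_dir(1); lo <- one_dir(-1)
  list(estimate = q0, lower = lo$bound, upper = up$bound,
       open_lower = lo$open, open_upper = up$open, ssr0 = ssr0)
}

.quantity_fun <- function(ctx, quantity) {
  if (quantity %in% c("RL_total", "shunt", "tca", "fatty_acid")) {
    cv <- ctx$compcoef[[quantity]]
    function(th) { st <- .theta_to_state(ctx, th); sum(cv * st$p) }
  } else if (grepl("^flux:", quantity)) {
    rid <- sub("^flux:", "", quantity)
    function(th) .theta_to_state(ctx, th)$flux@net[[rid]]
  } else stop("unknown quantity: ", quantity)
}

#' Parameter-continuation confidence interval for a fitted quantity
#'
#' @param model,data,config as in \code{\link{fitFluxes}}.
#' @param fit the converged \code{FitResult} to profile around.
#' @param quantity \code{"RL_total"}, \code{"shunt"}, \code{"tca"},
#'   \code{"fatty_acid"}, or \code{"flux:<reaction id>"}.
#' @param level confidence level (0.95).
#' @param ngrid simulator grid used during profiling.
#' @param ... passed to \code{\link{profileCI}}.
#' @return data.frame with quantity, estimate, lower, upper, method, level,
#'   open-interval flags.
#' @export
continuationCI <- function(model, data, config, fit, quantity = "RL_total",
                           level = 0.95, ngrid = 100, ...) {
  ctx <- .fit_context(model, data, config, fit@scenario, ngrid)
  ctx$nres_hint <- NULL
  resfun <- function(th) .evaluate(ctx, th)$res
  ctx$nres_hint <- length(resfun(fit@par))
  pr <- profileCI(resfun, fit@par, .quantity_fun(ctx, quantity),
                  level = level, ...)
  data.frame(quantity = quantity, estimate = pr$estimate, lower = pr$lower,
             upper = pr$upper, method = "continuation", level = level,
             open_lower = pr$open_lower, open_upper = pr$open_upper,
             stringsAsFactors = FALSE)
}

#' Perturb a dataset within its measurement uncertainty
#'
#' Every MID entry is resampled from a zero-truncated normal around the
#' measured value with its sd and renormalized per fragment/time point;
#' boundary rates are resampled from their normal distributions. Uses the
#' current RNG state.
#'
#' @param data a \code{MIDTimeSeries}.
#' @return a perturbed copy.
#' @export
perturbDataset <- function(data) {
  d <- data@data
  d$value <- .trunc_noise(d$value, d$sd)
  tot <- stats::ave(d$value, paste(d$fragment, d$time), FUN = sum)
  d$value <- d$value / tot
  r <- data@rates
  if (nrow(r)) {
    ## pool-size rows are lognormal (their sd column is a log-scale sd)
    ispool <- startsWith(r$quantity, "pool:")
    r$value[!ispool] <- r$value[!ispool] +
      stats::rnorm(sum(!ispool), 0, r$sd[!ispool])
    r$value[ispool] <- r$value[ispool] *
      exp(stats::rnorm(sum(ispool), 0, r$sd[ispool]))
  }
  new("MIDTimeSeries", data = d, fragments = data@fragments, rates = r,
      meta = data@meta)
}

#' Monte-Carlo confidence intervals by data perturbation and refitting
#'
#' Draws perturbed datasets (\code{\link{perturbDataset}}), refits each by
#' Levenberg-Marquardt warm-started from the unperturbed optimum, and
#' reports percentile intervals of the requested quantities. Reproducible
#' given \code{seed}; draws use seed-indexed substreams.
#'
#' @param model,data,config as in \code{\link{fitFluxes}}.
#' @param fit baseline \code{FitResult}.
#' @param quantities character vector (see \code{\link{continuationCI}}).
#' @param n_draws number of Monte-Carlo draws (3000 in a full analysis;
#'   desk-scale runs use 100-200).
#' @param seed integer seed.
#' @param refit_iter LM iterations per refit.
#' @param level confidence level.
#' @param ngrid simulator grid during refits.
#' @param max_fail_frac error if more than this fraction of draws fails to
#'   refit.
#' @return data.frame, one row per quantity, plus the draw matrix as
#'   attribute \code{"draws"}.
#' @export
monteCarloCI <- function(model, data, config, fit,
                         quantities = "RL_total", n_draws = 200, seed = 1,
                         refit_iter = 8, level = 0.95, ngrid = 100,
                         max_fail_frac = 0.1) {
  ctx <- .fit_context(model, data, config, fit@scenario, ngrid)
  ctx$nres_hint <- NULL
  ctx$nres_hint <- length(.evaluate(ctx, fit@par)$res)
  qfuns <- lapply(quantities, .quantity_fun, ctx = ctx)
  set.seed(seed)
  subseeds <- sample.int(1e6, n_draws)
  draws <- matrix(NA_real_, n_draws, length(quantities),
                  dimnames = list(NULL, quantities))
  fails <- 0
  for (i in seq_len(n_draws)) {
    set.seed(subseeds[i])
    dat_i <- perturbDataset(data)
    ctx_i <- ctx
    ctx_i$data <- dat_i
    for (fid in names(ctx_i$meas)) {
      sub <- dat_i@data[dat_i@data$fragment == fid, ]
      m <- ctx_i$meas[[fid]]
      vm <- m$value
      vm[cbind(sub$iso + 1, match(sub$time, ctx_i$times))] <- sub$value
      ctx_i$meas[[fid]]$value <- vm
    }
    opt <- try(suppressWarnings(minpack.lm::nls.lm(
      par = fit@par, fn = function(th) .evaluate(ctx_i, th)$res,
      control = minpack.lm::nls.lm.control(maxiter = refit_iter,
                                           ftol = 1e-10, epsfcn = 1e-6,
                                           diag = rep(1, length(fit@par))))),
      silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(sum(opt$par))) {
      fails <- fails + 1
      next
    }
    for (j in seq_along(qfuns)) draws[i, j] <- qfuns[[j]](opt$par)
  }
  if (fails > max_fail_frac * n_draws)
    stop("monteCarloCI: ", fails, "/", n_draws, " draws failed to refit")
  a <- (1 - level) / 2
  out <- do.call(rbind, lapply(seq_along(quantities), function(j) {
    v <- draws[, j]
    v <- v[is.finite(v)]
    data.frame(quantity = quantities[j],
               estimate = stats::median(v),
               lower = unname(stats::quantile(v, a)),
               upper = unname(stats::quantile(v, 1 - a)),
               method = "monte_carlo", level = level, n_draws = length(v),
               stringsAsFactors = FALSE)
  }))
  attr(out, "draws") <- draws
  out
}
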