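## Variance-weighted nonlinear least-squares flux fitting (INST-MFA).
##
## Parameterization: the steady-state flux space is coordinatized by a set of
## pinned reactions (one per free-flux dimension); every other net flux is
## the linear steady-state completion v = Mp %*% p. The rubisco oxygenation
## flux is driven by the ratio r = v_o/v_c (logit-bounded inside the
## configured interval), exchange fluxes and pool sizes are fitted on log
## scale, and inactive-pool dilution fractions -- which enter the predicted
## fragments affinely -- are profiled out by linear least squares at every
## objective evaluation (variable projection). Forced-R_L scenarios eliminate
## one pinned flux by solving the linear component equation exactly, so the
## forcing holds as a hard equality throughout the optimization.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))
## smooth positive transform for pinned fluxes: p = softplus(theta)
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplus_inv <- function(p) {
  p <- pmax(p, 1e-8)
  ifelse(p > 30, p, log(expm1(p)))
}

.data_digest <- function(data) {
  x <- data@data$value
  signif(sum(x * seq_along(x)) + sum(data@rates$value), 12)
}

.fit_context <- function(model, data, config, scenario = "unconstrained",
                         ngrid = 150) {
  scenario <- match.arg(scenario, c("unconstrained", "forced_co2np",
                                    "forced_tca", "forced_fatty_acid",
                                    "forced_shunt"))
  frags <- data@fragments
  known_mets <- model@metabolites$id
  for (i in seq_len(nrow(frags))) {
    pc <- .parse_components(frags[i, ])
    for (cp in pc$comps) if (!cp$met %in% known_mets)
      stop("fragment ", frags$fragment[i], " references metabolite ",
           cp$met, " absent from the model")
  }
  system <- emuDecompose(model, fragmentTargets(frags))
  comp <- emuCompile(system)
  B <- freeFluxBasis(model)
  pins <- config$pins
  Bp <- B[pins, , drop = FALSE]
  if (nrow(Bp) != ncol(Bp)) stop("fitConfig pins (", nrow(Bp),
                                 ") must match free-flux dimension (", ncol(Bp), ")")
  Mp <- B %*% solve(Bp)             # reactions x pins
  rownames(Mp) <- rownames(B); colnames(Mp) <- pins
  ## R_L component coefficients (linear in net fluxes, hence in pins)
  roles <- vapply(model@reactions, `[[`, "", "co2")
  grp <- vapply(model@reactions, `[[`, "", "co2Group")
  svec <- function(sel) {
    s <- setNames(numeric(length(roles)), names(roles)); s[sel] <- 1; s
  }
  Srl <- list(shunt = svec(roles == "release" & grp == "shunt"),
              tca = svec(roles == "release" & grp == "tca") -
                svec(roles == "fix"),
              fatty_acid = svec(roles == "release" & grp == "fa"))
  compcoef <- lapply(Srl, function(s) drop(s %*% Mp))
  compcoef$RL_total <- compcoef$shunt + compcoef$tca + compcoef$fatty_acid
  elim <- NULL; elim_coef <- NULL
  if (scenario != "unconstrained") {
    elim <- unname(config$scenario_elim[[scenario]])
    qname <- switch(scenario, forced_co2np = "RL_total",
                    forced_tca = "tca", forced_fatty_acid = "fatty_acid",
                    forced_shunt = "shunt")
    elim_coef <- compcoef[[qname]]
    if (abs(elim_coef[[elim]]) < 1e-12)
      stop("scenario ", scenario, ": eliminated pin has zero coefficient")
  }
  rev <- vapply(model@reactions, `[[`, TRUE, "reversible")
  times <- sort(unique(data@data$time))
  meas <- list()
  for (i in seq_len(nrow(frags))) {
    fid <- frags$fragment[i]
    sub <- data@data[data@data$fragment == fid, ]
    w <- max(sub$iso) + 1
    vm <- matrix(NA_real_, w, length(times))
    sm <- matrix(NA_real_, w, length(times))
    vm[cbind(sub$iso + 1, match(sub$time, times))] <- sub$value
    sm[cbind(sub$iso + 1, match(sub$time, times))] <- sub$sd
    pc <- .parse_components(frags[i, ])
    meas[[fid]] <- list(row = frags[i, ], value = vm, sd = sm, pc = pc,
                        w = w)
  }
  dil_flag <- model@metabolites$dilution
  names(dil_flag) <- model@metabolites$id
  dil_mets <- sort(unique(unlist(lapply(meas, function(m)
    Filter(function(mm) isTRUE(dil_flag[[mm]]),
           vapply(m$pc$comps, `[[`, "", "met"))))))
  purity <- if (!is.null(data@meta$purity)) data@meta$purity else 0.99
  free_pins <- setdiff(pins, c(if (!is.null(config$ratio)) config$ratio$reaction,
                               elim))
  theta_names <- c(if (!is.null(config$ratio)) "r",
                   free_pins,
                   paste0("ex_", config$exch_fit),
                   paste0("pl_", config$pools_fit))
  list(model = model, data = data, config = config, scenario = scenario,
       comp = comp, Mp = Mp, compcoef = compcoef, elim = elim,
       elim_coef = elim_coef, rev = rev, times = times, meas = meas,
       dil_mets = dil_mets, tracer = tracerProgram(purity = purity),
       ngrid = ngrid, free_pins = free_pins, theta_names = theta_names,
       RL_target = config$RL_measured, digest = .data_digest(data))
}

.ratio_from_theta <- function(cfg, th) {
  b <- cfg$ratio$bounds
  if (is.null(b)) 0.5 * .sigmoid(th) else b[1] + diff(b) * .sigmoid(th)
}

.theta_to_state <- function(ctx, theta) {
  cfg <- ctx$config
  names(theta) <- ctx$theta_names
  ## clamp against optimizer trial steps running off to overflow
  theta <- pmin(pmax(theta, -60), 60)
  p <- setNames(numeric(length(cfg$pins)), cfg$pins)
  p[ctx$free_pins] <- .softplus(theta[ctx$free_pins])
  if (!is.null(ctx$elim)) {
    cv <- ctx$elim_coef
    p[ctx$elim] <- 0
    p[ctx$elim] <- (ctx$RL_target - sum(cv * p)) / cv[[ctx$elim]]
  }
  r <- NA_real_
  if (!is.null(cfg$ratio)) {
    r <- .ratio_from_theta(cfg, theta[["r"]])
    rp <- cfg$ratio$reaction
    p[rp] <- 0
    alpha <- sum(ctx$Mp[cfg$ratio$vc, ] * p)
    beta <- ctx$Mp[cfg$ratio$vc, rp]
    p[rp] <- r * alpha / (1 - r * beta)
  }
  v <- drop(ctx$Mp %*% p)
  exch <- cfg$exch_defaults
  if (length(cfg$exch_fit))
    exch[cfg$exch_fit] <- exp(theta[paste0("ex_", cfg$exch_fit)])
  pools <- cfg$pools_default
  if (length(cfg$pools_fit))
    pools[cfg$pools_fit] <- exp(theta[paste0("pl_", cfg$pools_fit)])
  ## fixed-length smooth penalty block against negative irreversible fluxes
  ## (smooth hinge ~ 100*|v| for v < 0, ~0 for v > 0.1; nls.lm needs both a
  ## constant residual length and differentiability)
  ## free pins are positive by construction (softplus); penalize only the
  ## dependent (completed) irreversible fluxes and the eliminated pin
  vi <- v[!ctx$rev & !(names(v) %in% ctx$free_pins)]
  pen <- -log1p(exp(pmin(-100 * vi, 30)))
  pen[vi < -0.3] <- 100 * vi[vi < -0.3]  # continuous linear continuation
  list(flux = FluxState(net = v, exch = exch, pools = pools),
       p = p, r = r, pen = pen)
}

#' Optimizer-scale parameter vector corresponding to a flux state
#'
#' Builds the \code{fitFluxes} parameter vector (softplus-scale pinned
#' fluxes, logit-scale oxygenation ratio, log-scale exchanges and pools)
#' whose decoded state equals the given \code{FluxState}. Useful for
#' truth-started fits and warm starts.
#'
#' @param config a \code{\link{fitConfig}}.
#' @param flux a \code{FluxState} covering the configured pins, exchange
#'   fluxes and pools.
#' @return named numeric parameter vector.
#' @export
fluxStartTheta <- function(config, flux) {
  th <- numeric(0)
  free <- config$pins
  if (!is.null(config$ratio)) {
    r0 <- flux@net[[config$ratio$reaction]] / flux@net[[config$ratio$vc]]
    b <- config$ratio$bounds
    z <- if (is.null(b)) r0 / 0.5 else (r0 - b[1]) / diff(b)
    th <- c(r = max(min(.logit(min(max(z, 1e-8), 1 - 1e-8)), 12), -12))
    free <- setdiff(free, config$ratio$reaction)
  }
  th <- c(th, .softplus_inv(setNames(flux@net[free], free)))
  th <- c(th, setNames(log(flux@exch[config$exch_fit]),
                       paste0("ex_", config$exch_fit)))
  th <- c(th, setNames(log(flux@pools[config$pools_fit]),
                       paste0("pl_", config$pools_fit)))
  th
}

## one objective evaluation: simulate, project dilutions, residuals.
.evaluate <- function(ctx, theta, detail = FALSE) {
  st <- try(.theta_to_state(ctx, theta), silent = TRUE)
  nres <- ctx$nres_hint
  if (inherits(st, "try-error"))
    return(list(res = rep(1e4, if (is.null(nres)) 1000 else nres), ssr = Inf))
  sim <- try(simulateLabeling(ctx$comp, st$flux, ctx$tracer,
                              times = ctx$times, ngrid = ctx$ngrid),
             silent = TRUE)
  if (inherits(sim, "try-error"))
    return(list(res = rep(1e4, if (is.null(nres)) 1000 else nres), ssr = Inf))
  nd <- length(ctx$dil_mets)
  ylist <- list(); Dlist <- list(); frag_rows <- integer(0)
  for (fid in names(ctx$meas)) {
    m <- ctx$meas[[fid]]
    base <- NULL
    coefs <- matrix(0, length(m$value), nd)
    u <- c(1, numeric(m$w - 1))
    for (k in seq_along(m$pc$comps)) {
      cp <- m$pc$comps[[k]]
      tr <- sim$mids[[emuId(cp$met, cp$positions)]]
      wk <- m$pc$weights[k]
      base <- if (is.null(base)) wk * tr else base + wk * tr
      j <- match(cp$met, ctx$dil_mets)
      if (!is.na(j)) coefs[, j] <- coefs[, j] + as.vector(wk * (u - tr))
    }
    y <- (m$value - base) / m$sd
    D <- coefs / as.vector(m$sd)
    ok <- !is.na(as.vector(y))
    ylist[[fid]] <- as.vector(y)[ok]
    Dlist[[fid]] <- D[ok, , drop = FALSE]
    frag_rows <- c(frag_rows, rep(match(fid, names(ctx$meas)), sum(ok)))
  }
  y <- unlist(ylist, use.names = FALSE)
  D <- do.call(rbind, Dlist)
  ## box-constrained ridge least squares: the relative ridge picks the
  ## minimum-norm split when components are collinear (e.g. co-measured
  ## GAP/DHAP pools), and an active-set pass enforces d in [0, 0.995]
  box_lls <- function(Dm, ym) {
    A <- crossprod(Dm)
    lam <- 1e-9 * mean(diag(A)) + 1e-12
    b <- drop(crossprod(Dm, ym))
    d <- drop(solve(A + diag(lam, nd), b))
    lo <- 0; hi <- 0.995
    fixed <- rep(NA_real_, nd)
    for (pass in 1:4) {
      viol <- which(is.na(fixed) & (d < lo | d > hi))
      if (!length(viol)) break
      fixed[viol] <- pmin(pmax(d[viol], lo), hi)
      free <- which(is.na(fixed))
      d[!is.na(fixed)] <- fixed[!is.na(fixed)]
      if (!length(free)) break
      bf <- b[free] - A[free, !is.na(fixed), drop = FALSE] %*%
        fixed[!is.na(fixed)]
      d[free] <- drop(solve(A[free, free, drop = FALSE] +
                              diag(lam, length(free)), bf))
    }
    pmin(pmax(d, lo), hi)
  }
  rates <- ctx$data@rates
  if (nd > 0) {
    d <- box_lls(D, y)
    ## second pass: include the measured-total-pool rows, which depend on d
    ## through total = active/(1-d), linearized at the first-pass solution
    pq <- if (nrow(rates)) rates$quantity else character(0)
    prows <- which(startsWith(pq, "pool:") &
                     sub("^pool:", "", pq) %in% ctx$dil_mets)
    if (length(prows)) {
      for (it in 1:4) {
        Dx <- matrix(0, length(prows), nd)
        yx <- numeric(length(prows))
        for (k in seq_along(prows)) {
          i <- prows[k]
          met <- sub("^pool:", "", rates$quantity[i])
          j <- match(met, ctx$dil_mets)
          d1 <- min(d[j], 0.99)
          sdp <- rates$sd[i]
          a <- log(rates$value[i] * (1 - d1) / st$flux@pools[[met]]) / sdp
          bcoef <- 1 / ((1 - d1) * sdp)
          Dx[k, j] <- bcoef
          yx[k] <- a + bcoef * d1
        }
        d_new <- box_lls(rbind(D, Dx), c(y, yx))
        delta <- max(abs(d_new - d))
        d <- d_new
        if (delta < 1e-9) break
      }
    }
  } else d <- numeric(0)
  names(d) <- ctx$dil_mets
  mid_res <- y - if (nd > 0) drop(D %*% d) else 0
  ## boundary-rate residuals
  rates <- ctx$data@rates
  bres <- numeric(0)
  if (nrow(rates)) {
    bmap <- ctx$config$boundary
    for (i in seq_len(nrow(rates))) {
      q <- rates$quantity[i]
      if (startsWith(q, "pool:")) {
        ## measured TOTAL pool size (active/(1-d)), lognormal: the sd
        ## column holds the log-scale sd
        met <- sub("^pool:", "", q)
        dm <- if (met %in% names(d)) d[[met]] else 0
        tot <- st$flux@pools[[met]] / (1 - dm)
        bres <- c(bres, (log(rates$value[i]) - log(tot)) / rates$sd[i])
      } else {
        target <- bmap[[q]]
        val <- if (identical(target, "A_net"))
          netAssimilation(ctx$model, st$flux) else st$flux@net[[target]]
        bres <- c(bres, (rates$value[i] - val) / rates$sd[i])
      }
    }
  }
  res <- c(mid_res, bres, st$pen)
  res[!is.finite(res)] <- 1e4
  out <- list(res = res, ssr = sum(mid_res^2) + sum(bres^2))
  if (detail) {
    names(d) <- ctx$dil_mets
    st$flux@dilution <- d
    sres <- vapply(seq_along(ctx$meas), function(i)
      sum(mid_res[frag_rows == i]^2), 0)
    out$flux <- st$flux
    out$p <- st$p
    out$r <- st$r
    out$sres <- data.frame(fragment = names(ctx$meas), sres = sres,
                           stringsAsFactors = FALSE)
    out$nres <- length(mid_res) + length(bres)
    out$npar <- length(ctx$theta_names) + length(d)
  }
  out
}

.start_theta <- function(ctx) {
  cfg <- ctx$config
  st <- cfg$start
  rates <- ctx$data@rates
  for (pn in names(cfg$start_boundary)) {
    q <- cfg$start_boundary[[pn]]
    i <- match(q, rates$quantity)
    if (!is.na(i)) st[pn] <- max(rates$value[i], 0.1)
  }
  theta <- numeric(0)
  if (!is.null(cfg$ratio)) theta <- c(r = 0)
  theta <- c(theta, .softplus_inv(st[ctx$free_pins]))
  theta <- c(theta, setNames(log(cfg$exch_defaults[cfg$exch_fit]),
                             paste0("ex_", cfg$exch_fit)))
  theta <- c(theta, setNames(log(cfg$pools_default[cfg$pools_fit]),
                             paste0("pl_", cfg$pools_fit)))
  theta[ctx$theta_names]
}

.jitter_theta <- function(ctx, theta0) {
  th <- theta0
  if (!is.null(ctx$config$ratio)) th[["r"]] <- stats::runif(1, -2, 2)
  th[ctx$free_pins] <- .softplus_inv(
    .softplus(th[ctx$free_pins]) *
      exp(stats::runif(length(ctx$free_pins), -1.2, 1.2)))
  ex <- paste0("ex_", ctx$config$exch_fit)
  th[ex] <- th[ex] + stats::runif(length(ex), -1.6, 1.6)
  pl <- paste0("pl_", ctx$config$pools_fit)
  th[pl] <- th[pl] + stats::runif(length(pl), -1.1, 1.1)
  th
}

#' Weighted residuals and SSR of a flux state against a dataset
#'
#' Evaluates the INST-MFA objective at a given flux state: each MID residual
#' is (measured - predicted)/sd, boundary-rate residuals are appended with
#' their own sd. The state's own dilution fractions are used (no profiling).
#'
#' @param model a \code{NetworkModel}.
#' @param flux a \code{FluxState} (steady state).
#' @param data a \code{MIDTimeSeries}.
#' @param config a \code{\link{fitConfig}} (for the boundary-rate mapping).
#' @param ngrid simulator grid resolution.
#' @return list with \code{residuals}, \code{ssr}, \code{sres} (per-fragment
#'   squared residuals), \code{n} (residual count).
#' @export
fluxResiduals <- function(model, flux, data, config, ngrid = 300) {
  system <- emuDecompose(model, fragmentTargets(data@fragments))
  comp <- emuCompile(system)
  purity <- if (!is.null(data@meta$purity)) data@meta$purity else 0.99
  times <- sort(unique(data@data$time))
  sim <- simulateLabeling(comp, flux, tracerProgram(purity = purity),
                          times = times, ngrid = ngrid)
  res <- numeric(0); sres <- numeric(0)
  for (i in seq_len(nrow(data@fragments))) {
    fr <- data@fragments[i, ]
    pred <- predictFragment(sim, fr, flux@dilution)
    sub <- data@data[data@data$fragment == fr$fragment, ]
    pv <- pred[cbind(sub$iso + 1, match(sub$time, times))]
    ri <- (sub$value - pv) / sub$sd
    res <- c(res, ri)
    sres <- c(sres, sum(ri^2))
  }
  bres <- numeric(0)
  if (nrow(data@rates)) {
    bmap <- config$boundary
    for (i in seq_len(nrow(data@rates))) {
      q <- data@rates$quantity[i]
      if (startsWith(q, "pool:")) {
        met <- sub("^pool:", "", q)
        dm <- if (met %in% names(flux@dilution)) flux@dilution[[met]] else 0
        tot <- flux@pools[[met]] / (1 - dm)
        bres <- c(bres, (log(data@rates$value[i]) - log(tot)) /
                    data@rates$sd[i])
      } else {
        target <- bmap[[q]]
        val <- if (identical(target, "A_net")) netAssimilation(model, flux)
        else flux@net[[target]]
        bres <- c(bres, (data@rates$value[i] - val) / data@rates$sd[i])
      }
    }
  }
  list(residuals = c(res, bres), ssr = sum(res^2) + sum(bres^2),
       sres = data.frame(fragment = data@fragments$fragment, sres = sres),
       n = length(res) + length(bres))
}

#' Fit fluxes, pools and dilution fractions to MID time courses
#'
#' Multi-start Levenberg-Marquardt minimization of the variance-weighted SSR
#' over free net fluxes (steady-state pins), the rubisco oxygenation ratio,
#' log exchange fluxes and log pool sizes, with dilution fractions profiled
#' out linearly at each evaluation. Starts are drawn log-uniformly around the
#' configuration's start point (deterministic given \code{seed}); every start
#' is explored briefly and the best \code{n_polish} are polished.
#'
#' @param model a \code{NetworkModel}.
#' @param data a \code{MIDTimeSeries} (measured or synthetic).
#' @param config a \code{\link{fitConfig}}.
#' @param scenario one of \code{"unconstrained"}, \code{"forced_co2np"},
#'   \code{"forced_tca"}, \code{"forced_fatty_acid"}, \code{"forced_shunt"}.
#'   Forced scenarios hold the respective R_L component (or the total) equal
#'   to \code{config$RL_measured} as a hard equality.
#' @param n_starts number of multi-starts.
#' @param seed integer seed (start jitter reproducibility).
#' @param explore_iter,polish_iter LM iteration budget per phase.
#' @param n_polish how many top starts to polish.
#' @param ngrid simulator grid resolution during fitting.
#' @param start optional named starting parameter vector (optimizer scale),
#'   e.g. \code{bestFit@par} for a warm start.
#' @return a \code{\linkS4class{FitResult}}.
#' @export
fitFluxes <- function(model, data, config, scenario = "unconstrained",
                      n_starts = 20, seed = 1, explore_iter = 25,
                      polish_iter = 60, n_polish = 2, ngrid = 100,
                      start = NULL) {
  ctx <- .fit_context(model, data, config, scenario, ngrid)
  set.seed(seed)
  theta0 <- .start_theta(ctx)
  e0 <- .evaluate(ctx, theta0)
  ctx$nres_hint <- length(e0$res)
  starts <- list(theta0)
  if (!is.null(start)) {
    stopifnot(all(ctx$theta_names %in% names(start)))
    starts <- c(list(start[ctx$theta_names]), starts)
  }
  while (length(starts) < n_starts)
    starts[[length(starts) + 1]] <- .jitter_theta(ctx, theta0)
  objfun <- function(th) .evaluate(ctx, th)$res
  ctrl <- function(it) minpack.lm::nls.lm.control(
    maxiter = it, ftol = 1e-10, ptol = 1e-8, epsfcn = 1e-6)
  ## stage A: explore each start over the flux coordinates only (pools and
  ## exchanges held at their start values) -- cheap and finds the basin;
  ## stage B polishes the best starts over the full parameter vector.
  flux_par <- intersect(c("r", ctx$free_pins), ctx$theta_names)
  explored <- lapply(starts, function(th) {
    objsub <- function(s) { th2 <- th; th2[flux_par] <- s; objfun(th2) }
    fitl <- try(suppressWarnings(
      minpack.lm::nls.lm(par = th[flux_par], fn = objsub,
                         control = ctrl(explore_iter))), silent = TRUE)
    if (inherits(fitl, "try-error")) return(list(ssr = Inf, par = th))
    th[flux_par] <- fitl$par
    s <- .evaluate(ctx, th)$ssr
    list(ssr = if (is.null(s) || !is.finite(s)) Inf else s, par = th)
  })
  ssrs <- vapply(explored, `[[`, 0, "ssr")
  if (all(!is.finite(ssrs))) stop("fitFluxes: no start converged")
  ## polish the chains from the provided warm start and/or the default start
  ## first (they are the best-informed), then the remaining top explorers
  anchor <- seq_len(if (is.null(start)) 1 else 2)
  pol <- unique(c(anchor[is.finite(ssrs[anchor])], order(ssrs)))
  pol <- pol[seq_len(min(max(n_polish, length(anchor)), length(pol)))]
  best <- NULL; best_ssr <- Inf; info <- NA_integer_; niter <- 0
  for (k in pol) {
    th_k <- explored[[k]]$par
    ## quick flux-coordinate refinement, then the full-vector polish
    objsub <- function(s) { th2 <- th_k; th2[flux_par] <- s; objfun(th2) }
    pre <- try(suppressWarnings(
      minpack.lm::nls.lm(par = th_k[flux_par], fn = objsub,
                         control = ctrl(12))), silent = TRUE)
    if (!inherits(pre, "try-error")) th_k[flux_par] <- pre$par
    fitl <- try(suppressWarnings(
      minpack.lm::nls.lm(par = th_k, fn = objfun,
                         control = ctrl(polish_iter))), silent = TRUE)
    if (inherits(fitl, "try-error")) next
    s <- .evaluate(ctx, fitl$par)$ssr
    if (is.finite(s) && s < best_ssr) {
      best_ssr <- s; best <- fitl$par; info <- fitl$info; niter <- fitl$niter
    }
  }
  if (is.null(best)) stop("fitFluxes: polishing failed for every start")
  fin <- .evaluate(ctx, best, detail = TRUE)
  dof <- fin$nres - fin$npar
  rl <- computeRL(model, fin$flux)
  vovc <- if (!is.null(config$ratio))
    fin$flux@net[[config$ratio$reaction]] / fin$flux@net[[config$ratio$vc]]
  else NA_real_
  new("FitResult", flux = fin$flux, par = best, ssr = fin$ssr,
      sres = fin$sres, dof = dof,
      chi2 = chi2Accept(fin$ssr, dof),
      scenario = scenario,
      diagnostics = list(n_starts = length(starts), seed = seed,
                         explore_ssr = ssrs, lm_info = info,
                         lm_iter = niter, digest = ctx$digest,
                         vo_vc = vovc, RL = rl,
                         A_net = netAssimilation(model, fin$flux)))
}

#' Two-sided chi-square acceptance test for an SSR
#'
#' A statistically consistent fit has SSR within
#' \code{[qchisq(alpha/2, dof), qchisq(1 - alpha/2, dof)]}; values below the
#' interval indicate over-fitting/over-estimated sd, values above indicate
#' model-data mismatch.
#'
#' @param ssr sum of squared variance-weighted residuals.
#' @param dof degrees of freedom (measurements minus fitted parameters).
#' @param alpha test level (default 0.05 for a 95% interval).
#' @return list with \code{lower}, \code{upper}, \code{accepted}.
#' @examples
#' chi2Accept(810, 1753)  # interval [1638.9, 1870.9]: under-dispersed
#' @export
chi2Accept <- function(ssr, dof, alpha = 0.05) {
  stopifnot(dof >= 1)
  lo <- stats::qchisq(alpha / 2, dof)
  hi <- stats::qchisq(1 - alpha / 2, dof)
  list(lower = lo, upper = hi, accepted = (ssr >= lo && ssr <= hi))
}

#' Compare forced-scenario fits by goodness of fit
#'
#' @param results list of \code{FitResult}s fitted to the identical dataset.
#' @return data.frame (scenario, ssr, dssr vs best, vo, vc, vo_vc), sorted by
#'   SSR.
#' @export
scenarioCompare <- function(results) {
  if (length(results) < 2) stop("need at least two fits to compare")
  digs <- vapply(results, function(r) r@diagnostics$digest, 0)
  if (length(unique(digs)) != 1)
    stop("scenarioCompare: fits were made on different datasets")
  tab <- do.call(rbind, lapply(results, function(r) {
    rl <- r@diagnostics$RL
    data.frame(scenario = r@scenario, ssr = r@ssr,
               vo_vc = r@diagnostics$vo_vc,
               RL_total = rl$RL_total, shunt = rl$shunt, tca = rl$tca,
               fatty_acid = rl$fatty_acid, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$ssr), ]
  tab$dssr <- tab$ssr - tab$ssr[1]
  rownames(tab) <- NULL
  tab
}
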