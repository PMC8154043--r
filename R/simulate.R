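## EMU labeling kinetics.
##
## Within one EMU size block the balance equations are linear with constant
## coefficients once the fluxes are fixed:
##   c_i dx_i/dt = sum_j v_ij x_j - out_i x_i + b_i(t)
## where b_i(t) collects tracer inputs and convolutions of smaller-block
## solutions. Each block is propagated exactly through the eigendecomposition
## of its coefficient matrix, with the forcing b(t) taken piecewise linear on
## a log-dense internal grid. This is unconditionally stable (exact for the
## linear part), which matters here: plastidic pool turnover times of well
## under a second coexist with a one-hour labeling horizon.

#' Define the tracer switch program
#'
#' At t = 0 the atmosphere is switched from unlabeled CO2 to 13CO2 of the
#' given purity. Data are assumed natural-abundance corrected, so the
#' pre-switch MID is [1, 0] and the post-switch MID is [1 - purity, purity].
#'
#' @param species id of the source metabolite carrying the tracer.
#' @param purity tracer atom fraction (0.99 for 99 atom % 13C).
#' @param tau_switch optional atmosphere-exchange time constant in seconds
#'   (0 = instantaneous step; about 5 s in a fast-switching cuvette).
#' @return a list of class \code{"tracerProgram"}.
#' @export
tracerProgram <- function(species = "CO2in", purity = 0.99, tau_switch = 0) {
  stopifnot(purity > 0, purity <= 1, tau_switch >= 0)
  structure(list(species = species, purity = purity,
                 tau_switch = tau_switch), class = "tracerProgram")
}

## MID of a source-metabolite EMU of size k at the grid times (hours).
## Atoms of a source pool are independent, so the k-atom MID is the k-fold
## convolution of the single-atom distribution.
.input_mid <- function(tracer, met, size, t_hours) {
  lab <- if (met == tracer$species) {
    if (tracer$tau_switch > 0) {
      tau <- tracer$tau_switch / 3600
      ifelse(t_hours > 0, 1 - exp(-t_hours / tau), 0) * tracer$purity
    } else ifelse(t_hours > 0, tracer$purity, 0)
  } else rep(0, length(t_hours))
  out <- matrix(0, size + 1, length(t_hours))
  for (g in seq_along(t_hours)) {
    mid <- 1
    for (k in seq_len(size)) {
      m1 <- c(1 - lab[g], lab[g])
      nm <- numeric(length(mid) + 1)
      nm[seq_along(mid)] <- mid * m1[1]
      nm[seq_along(mid) + 1] <- nm[seq_along(mid) + 1] + mid * m1[2]
      mid <- nm
    }
    out[, g] <- mid
  }
  out
}

#' Precompile an EMU system for repeated simulation
#'
#' Resolves block structure, index maps and term tables once so that
#' \code{\link{simulateLabeling}} only does numeric work per flux state.
#' Called automatically when an \code{EMUSystem} is passed to the simulator;
#' call it yourself when simulating many flux states (fitting, Monte Carlo).
#'
#' @param system an \code{EMUSystem}.
#' @return an opaque list of class \code{"compiledEMU"}.
#' @export
emuCompile <- function(system) {
  model <- system@model
  mets <- model@metabolites
  emus <- system@emus
  sizes <- sort(unique(emus$size))
  is_input <- function(id) mets$source[match(sub("\\[.*", "", id), mets$id)]
  sizeOf <- setNames(emus$size, emus$id)
  ## partition each size class into connected components of the same-size
  ## coupling graph: independent components are much cheaper to decompose
  ## (eigen cost is cubic) and can be propagated separately.
  parent <- setNames(seq_len(nrow(emus)), emus$id)
  findp <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (tm in system@terms) {
    if (length(tm$src) == 1 && !is_input(tm$src) &&
        sizeOf[[tm$src]] == sizeOf[[tm$emu]]) {
      a <- findp(match(tm$emu, emus$id)); b <- findp(match(tm$src, emus$id))
      if (a != b) parent[[b]] <- a
    }
  }
  comp_id <- vapply(seq_len(nrow(emus)), findp, 0L)
  blocks <- list(); blockOf <- integer(0); idxOf <- integer(0)
  for (s in sizes) {
    sel <- which(emus$size == s)
    for (cid in unique(comp_id[sel])) {
      members <- emus$id[sel][comp_id[sel] == cid]
      bi <- length(blocks) + 1
      blocks[[bi]] <- list(size = s, ids = members, n = length(members),
                           internal = list(), inputs = list())
      blockOf[members] <- bi
      idxOf[members] <- seq_along(members)
    }
  }
  for (tm in system@terms) {
    bi <- blockOf[[tm$emu]]
    row <- idxOf[[tm$emu]]
    single_unknown <- length(tm$src) == 1 && !is_input(tm$src)
    if (single_unknown && blockOf[[tm$src]] == bi) {
      blocks[[bi]]$internal[[length(blocks[[bi]]$internal) + 1]] <-
        list(i = row, j = idxOf[[tm$src]], reaction = tm$reaction,
             dir = tm$dir, w = tm$weight)
    } else {
      srcs <- lapply(tm$src, function(s) {
        p <- emuParse(s)
        if (is_input(s)) list(input = TRUE, met = p$met,
                              size = length(p$subset))
        else list(input = FALSE, block = blockOf[[s]], idx = idxOf[[s]],
                  size = length(p$subset))
      })
      blocks[[bi]]$inputs[[length(blocks[[bi]]$inputs) + 1]] <-
        list(i = row, reaction = tm$reaction, dir = tm$dir, w = tm$weight,
             srcs = srcs)
    }
  }
  ## consumption stoichiometry per metabolite: (reaction, dir, coef) triples
  consumed <- list()
  for (r in model@reactions) {
    dirs <- if (r$reversible) c("fwd", "bwd") else "fwd"
    for (d in dirs) {
      side <- if (d == "fwd") r$reactants else r$products
      for (k in seq_len(nrow(side))) {
        m <- side$met[k]
        consumed[[m]] <- c(consumed[[m]],
                           list(list(reaction = r$id, dir = d,
                                     coef = side$coef[k])))
      }
    }
  }
  structure(list(model = model, emus = emus, blocks = blocks,
                 consumed = consumed, targets = system@targets),
            class = "compiledEMU")
}

.flux_of <- function(dirtab, reaction, dir) {
  if (dir == "fwd") dirtab$fwd[[reaction]] else dirtab$bwd[[reaction]]
}

## fold-convolve a list of (width x G) MID matrices, vectorized over the grid
.conv_grid <- function(mats) {
  out <- mats[[1]]
  for (m in mats[-1]) {
    na <- nrow(out); nb <- nrow(m)
    res <- matrix(0, na + nb - 1, ncol(out))
    for (i in seq_len(na)) for (j in seq_len(nb))
      res[i + j - 1, ] <- res[i + j - 1, ] + out[i, ] * m[j, ]
    out <- res
  }
  out
}

#' Simulate MID labeling trajectories for all target EMUs
#'
#' Integrates the EMU cascade for a steady-state flux/pool assignment under a
#' tracer switch at t = 0 and returns the MIDs of every unknown EMU at the
#' requested times.
#'
#' @param system an \code{EMUSystem} or a precompiled object from
#'   \code{\link{emuCompile}}.
#' @param flux a \code{FluxState}; must satisfy steady state (checked to
#'   1e-6 relative) with positive pools for all simulated metabolites.
#' @param tracer a \code{\link{tracerProgram}}.
#' @param times output times in minutes.
#' @param ngrid number of internal (log-dense) grid points; the forcing of
#'   each block is treated as piecewise linear on this grid, so larger values
#'   tighten the only discretization error. 300 is ample for fitting; use
#'   2000 for reference-quality trajectories.
#' @return list of class \code{"simulatedMIDs"}: \code{times} (minutes) and
#'   \code{mids}, a named list of (size+1) x length(times) matrices whose
#'   columns sum to 1.
#' @export
simulateLabeling <- function(system, flux, tracer = tracerProgram(),
                             times = c(0, 0.5, 1, 2, 2.5, 3, 5, 7, 10, 15, 30, 60),
                             ngrid = 300) {
  comp <- if (inherits(system, "compiledEMU")) system else emuCompile(system)
  model <- comp$model
  ssr_rel <- steadyStateResidual(model, flux)
  if (ssr_rel > 1e-6)
    stop("simulateLabeling: flux state violates steady state (relative ",
         signif(ssr_rel, 3), ")")
  t_out <- sort(unique(times)) / 60  # hours
  Tmax <- max(t_out)
  if (Tmax <= 0) stop("simulateLabeling: need a positive time horizon")
  dirtab <- directionalFluxes(model, flux)
  dirtab <- list(fwd = setNames(dirtab$fwd, dirtab$id),
                 bwd = setNames(dirtab$bwd, dirtab$id))
  cons <- vapply(names(comp$consumed), function(m)
    sum(vapply(comp$consumed[[m]], function(e)
      e$coef * .flux_of(dirtab, e$reaction, e$dir), 0)), 0)
  ## start the log-dense grid just below the fastest pool turnover time, so
  ## grid points concentrate where the piecewise-linear forcing needs them
  simmets <- unique(sub("\\[.*", "", comp$emus$id))
  tau <- flux@pools[simmets] / pmax(cons[simmets], 1e-300)
  tfast <- min(c(tau[is.finite(tau) & tau > 0], Tmax))
  t0g <- max(min(tfast / 30, Tmax * 1e-4), Tmax * 1e-10)
  ## one extra point right after zero keeps the tracer-step ramp negligible
  grid <- sort(unique(c(0, t0g * 1e-6, t_out,
                        exp(seq(log(t0g), log(Tmax),
                                length.out = ngrid)))))
  G <- length(grid)
  mets <- model@metabolites
  poolOf <- function(m) {
    p <- flux@pools[[m]]
    if (is.null(p) || is.na(p)) stop("simulateLabeling: missing pool size for ", m)
    p
  }
  ## solutions stored flattened as n x (w*G); column block g spans
  ## ((g-1)*w+1):(g*w), i.e. isotopologue index fastest
  sols <- vector("list", length(comp$blocks))
  inputCache <- new.env(parent = emptyenv())
  srcMid <- function(s) {
    if (s$input) {
      key <- paste0(s$met, ":", s$size)
      if (is.null(inputCache[[key]]))
        inputCache[[key]] <- .input_mid(tracer, s$met, s$size, grid)
      inputCache[[key]]
    } else {
      w <- s$size + 1
      matrix(sols[[s$block]][s$idx, ], w, G)
    }
  }
  hs <- diff(grid)
  for (bi in seq_along(comp$blocks)) {
    blk <- comp$blocks[[bi]]
    n <- blk$n; w <- blk$size + 1
    metOf <- sub("\\[.*", "", blk$ids)
    cvec <- vapply(metOf, poolOf, 0)
    A <- matrix(0, n, n)
    for (tm in blk$internal) {
      v <- .flux_of(dirtab, tm$reaction, tm$dir)
      A[tm$i, tm$j] <- A[tm$i, tm$j] + tm$w * v / cvec[tm$i]
    }
    diag(A) <- diag(A) - vapply(seq_len(n), function(i) {
      cm <- if (metOf[i] %in% names(cons)) cons[[metOf[i]]] else 0
      cm / cvec[i]
    }, 0)
    ## forcing, flattened n x (w*G)
    B <- matrix(0, n, w * G)
    for (tm in blk$inputs) {
      v <- .flux_of(dirtab, tm$reaction, tm$dir)
      if (v == 0 || tm$w == 0) next
      mats <- lapply(tm$srcs, srcMid)
      cv <- .conv_grid(mats)
      B[tm$i, ] <- B[tm$i, ] + (tm$w * v / cvec[tm$i]) * as.vector(cv)
    }
    eg <- tryCatch(eigen(A), error = function(e) NULL)
    Vinv <- if (!is.null(eg)) tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (is.null(eg) || is.null(Vinv) || !all(is.finite(Mod(Vinv)))) {
      A <- A + diag(1e-9 * max(abs(A), 1), n)
      eg <- eigen(A)
      Vinv <- solve(eg$vectors)
    }
    lam <- eg$values
    V <- eg$vectors
    ## project all forcing columns at once
    U <- Vinv %*% B
    ## step propagators for every interval, n x (G-1)
    ZH <- outer(lam, hs)
    E <- exp(ZH)
    H <- matrix(hs, n, G - 1, byrow = TRUE)
    LAM <- matrix(lam, n, G - 1)
    PHI1 <- (E - 1) / LAM
    PHI2H <- (E - 1 - ZH) / (LAM^2 * H)
    small <- which(Mod(ZH) < 1e-5)
    if (length(small)) {
      zs <- ZH[small]
      PHI1[small] <- H[small] * (1 + zs / 2 + zs^2 / 6)
      PHI2H[small] <- H[small] * (0.5 + zs / 6 + zs^2 / 24)
    }
    X <- matrix(0, n, w * G)
    x0 <- matrix(0, n, w); x0[, 1] <- 1
    X[, 1:w] <- x0
    Z <- Vinv %*% x0
    Uk <- U[, 1:w, drop = FALSE]
    for (g in seq_len(G - 1)) {
      cols <- (g * w + 1):((g + 1) * w)
      Uk1 <- U[, cols, drop = FALSE]
      Z <- E[, g] * Z + PHI1[, g] * Uk + PHI2H[, g] * (Uk1 - Uk)
      X[, cols] <- Re(V %*% Z)
      Uk <- Uk1
    }
    sols[[bi]] <- X
  }
  keep <- match(round(t_out, 12), round(grid, 12))
  if (anyNA(keep)) stop("internal grid did not retain requested times")
  mids <- list()
  for (bi in seq_along(comp$blocks)) {
    blk <- comp$blocks[[bi]]
    w <- blk$size + 1
    colsel <- as.vector(outer(1:w, (keep - 1) * w, `+`))
    for (i in seq_len(blk$n)) {
      m <- matrix(sols[[bi]][i, colsel], w, length(keep))
      ## clip tiny negative undershoot from interpolated forcing
      m[m < 0 & m > -1e-9] <- 0
      mids[[blk$ids[i]]] <- sweep(m, 2, colSums(m), "/")
    }
  }
  structure(list(times = t_out * 60, mids = mids),
            class = "simulatedMIDs")
}

#' Mean fractional 13C enrichment of a MID
#'
#' @param mid numeric MID vector over 0..n labeled carbons (sums to 1).
#' @return sum(k * mid_k) / n, a fraction in [0, 1].
#' @examples
#' meanEnrichment(c(0.25, 0.5, 0.25))  # 0.5
#' @export
meanEnrichment <- function(mid) {
  n <- length(mid) - 1
  if (n < 1) stop("meanEnrichment: MID must cover at least one carbon")
  if (abs(sum(mid) - 1) > 1e-6) stop("meanEnrichment: MID must sum to 1")
  sum(seq(0, n) * mid) / n
}
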