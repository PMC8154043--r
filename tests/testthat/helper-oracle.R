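# Brute-force positional isotopomer oracle.
#
# Integrates the full 2^n positional-isotopomer ODE system of a (small)
# network with deSolve and marginalizes to EMU MIDs. Entirely independent of
# the package's EMU cascade and exponential integrator: state representation,
# balance equations and integration method all differ. Only the parsed model
# (atom maps, directional fluxes) is shared, since that is the problem input.
#
# Feasible for networks whose metabolites have <= ~6 carbons.

# marginal distribution of an isotopomer vector over a subset of positions
iso_marginal <- function(x, positions, n) {
  k <- length(positions)
  out <- numeric(2^k)
  for (idx in seq_along(x)) {
    bits <- as.integer(intToBits(idx - 1))[1:n]
    sub <- bits[positions]
    j <- sum(sub * 2^(seq_len(k) - 1))
    out[j + 1] <- out[j + 1] + x[idx]
  }
  out
}

iso_mid <- function(x, positions, n) {
  marg <- iso_marginal(x, positions, n)
  k <- length(positions)
  mid <- numeric(k + 1)
  for (idx in seq_along(marg)) {
    nb <- sum(as.integer(intToBits(idx - 1))[1:k])
    mid[nb + 1] <- mid[nb + 1] + marg[idx]
  }
  mid
}

oracleSimulate <- function(model, flux, times_min, purity = 0.99,
                           rtol = 1e-10, atol = 1e-12) {
  skip_if_not_installed("deSolve")
  mets <- leafMFA::metabolites(model)
  bal <- mets$id[!mets$source & !mets$sink]
  nC <- stats::setNames(mets$carbons, mets$id)
  offs <- list(); pos <- 0
  for (m in bal) { offs[[m]] <- pos; pos <- pos + 2^nC[[m]] }
  ntot <- pos
  dirs <- leafMFA::directionalFluxes(model, flux)
  vfwd <- stats::setNames(dirs$fwd, dirs$id)
  vbwd <- stats::setNames(dirs$bwd, dirs$id)
  # consumption rate per balanced metabolite
  cons <- stats::setNames(numeric(length(bal)), bal)
  for (r in leafMFA::reactions(model)) {
    for (d in if (r$reversible) c("fwd", "bwd") else "fwd") {
      v <- if (d == "fwd") vfwd[[r$id]] else vbwd[[r$id]]
      side <- if (d == "fwd") r$reactants else r$products
      for (k in seq_len(nrow(side)))
        if (side$met[k] %in% bal)
          cons[[side$met[k]]] <- cons[[side$met[k]]] + v * side$coef[k]
    }
  }
  # production instances, reusing the model's atom-map bookkeeping
  insts <- list()
  for (m in bal)
    for (inst in leafMFA:::.production_instances(model, m)) {
      inst$target <- m
      insts[[length(insts) + 1]] <- inst
    }
  src_is_input <- function(id) mets$source[match(id, mets$id)]
  pools <- flux@pools
  rhs <- function(t, y, parms) {
    dy <- numeric(ntot)
    co2lab <- if (t > 0) purity else 0
    getdist <- function(id) {
      if (src_is_input(id)) {
        n <- nC[[id]]
        d <- 1
        for (k in seq_len(n)) d <- as.vector(outer(c(1 - co2lab, co2lab), d))
        d  # bit order irrelevant: atoms iid
      } else y[offs[[id]] + seq_len(2^nC[[id]])]
    }
    for (m in bal) {
      i0 <- offs[[m]]; nm <- 2^nC[[m]]
      dy[i0 + seq_len(nm)] <- dy[i0 + seq_len(nm)] -
        cons[[m]] * y[i0 + seq_len(nm)]
    }
    for (inst in insts) {
      v <- if (inst$dir == "fwd") vfwd[[inst$reaction]] else vbwd[[inst$reaction]]
      rate <- v * inst$w * inst$coef
      if (rate == 0) next
      m <- inst$target; n <- nC[[m]]
      # joint distribution over the product's carbons
      dist <- 1; placed <- integer(0)
      for (j in seq_along(inst$srcMet)) {
        sm <- inst$srcMet[j]
        letters_j <- inst$srcMap[[j]]
        hit <- which(letters_j %in% inst$map)
        if (!length(hit)) next
        marg <- if (src_is_input(sm)) {
          d <- 1
          for (k in seq_along(hit)) d <- as.vector(outer(c(1 - co2lab, co2lab), d))
          # outer() above builds bit order with first atom slowest; recompute
          # properly below via iso_marginal for uniformity
          d
        } else iso_marginal(getdist(sm), hit, nC[[sm]])
        # product positions receiving these source positions
        ppos <- match(letters_j[hit], inst$map)
        newdist <- as.vector(outer(dist, marg))
        dist <- newdist
        placed <- c(placed, ppos)
      }
      # map combined bit index -> product isotopomer index
      prodvec <- numeric(2^n)
      kbits <- length(placed)
      for (idx in seq_len(2^kbits)) {
        bits <- as.integer(intToBits(idx - 1))[seq_len(max(kbits, 1))]
        pidx <- sum(bits[seq_len(kbits)] * 2^(placed - 1))
        prodvec[pidx + 1] <- prodvec[pidx + 1] + dist[idx]
      }
      i0 <- offs[[m]]
      dy[i0 + seq_len(2^n)] <- dy[i0 + seq_len(2^n)] + rate * prodvec
    }
    for (m in bal) {
      i0 <- offs[[m]]; nm <- 2^nC[[m]]
      dy[i0 + seq_len(nm)] <- dy[i0 + seq_len(nm)] / pools[[m]]
    }
    list(dy)
  }
  y0 <- numeric(ntot)
  for (m in bal) y0[offs[[m]] + 1] <- 1
  tt <- sort(unique(c(0, times_min))) / 60
  sol <- deSolve::ode(y0, tt, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  list(times = tt * 60, sol = sol, offs = offs, nC = nC,
       mid = function(met, positions, timeidx) {
         y <- sol[timeidx, -1]
         iso_mid(y[offs[[met]] + seq_len(2^nC[[met]])], positions, nC[[met]])
       })
}
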