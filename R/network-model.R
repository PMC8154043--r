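## Atom-transition network parsing, stoichiometry and R_L accounting.
##
## Model flat-file dialect (one declaration or reaction per line, '#' comments):
##   @met Met.c carbons=3 [dilution=yes] [symmetric=yes] [source] [sink]
##   id: 1 A.c (abc) + 1 CO2in (d) -> 1 B.p (dcba) | reversible=yes | co2=fix
## Carbon positions are 1-based left-to-right; letters a-z are assigned per
## reactant. co2 is one of none | release:shunt | release:tca | release:fa |
## fix | pr. Atom maps may be omitted only on zero-carbon species and on
## products that are sinks (lumped export/efflux reactions); such reactions
## consume label but produce none.

.parse_met_line <- function(line, lineno) {
  toks <- strsplit(trimws(sub("^@met\\s+", "", line)), "\\s+")[[1]]
  if (!length(toks)) stop("model error (line ", lineno, "): empty @met line")
  id <- toks[1]
  out <- list(id = id, carbons = NA_integer_, source = FALSE, sink = FALSE,
              dilution = FALSE, symmetric = FALSE)
  for (tk in toks[-1]) {
    if (grepl("^carbons=", tk)) out$carbons <- as.integer(sub("^carbons=", "", tk))
    else if (tk == "source") out$source <- TRUE
    else if (tk == "sink") out$sink <- TRUE
    else if (grepl("^dilution=", tk)) out$dilution <- sub(".*=", "", tk) == "yes"
    else if (grepl("^symmetric=", tk)) out$symmetric <- sub(".*=", "", tk) == "yes"
    else stop("model error (line ", lineno, "): unknown @met token '", tk, "'")
  }
  if (is.na(out$carbons)) stop("model error (line ", lineno, "): @met ", id,
                               " lacks carbons=")
  out
}

.parse_side <- function(txt, rid) {
  parts <- strsplit(txt, "\\+")[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("model error: reaction ", rid, " has an empty side")
  met <- character(0); coef <- numeric(0); map <- character(0)
  for (p in parts) {
    m <- regmatches(p, regexec(
      "^([0-9.eE+-]+\\s+)?([A-Za-z0-9_.]+)\\s*(\\(([a-z]*)\\))?$", p))[[1]]
    if (!length(m)) stop("model error: cannot parse species '", p,
                         "' in reaction ", rid)
    cf <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    if (is.na(cf) || cf <= 0) stop("model error: non-positive coefficient in ",
                                   rid, " ('", p, "')")
    met <- c(met, m[3]); coef <- c(coef, cf)
    map <- c(map, if (nzchar(m[4])) m[5] else NA_character_)
  }
  data.frame(met = met, coef = coef, map = map, stringsAsFactors = FALSE)
}

.parse_rxn_line <- function(line, lineno) {
  halves <- strsplit(line, "\\|")[[1]]
  body <- trimws(halves[1])
  rev <- FALSE; co2 <- "none"; grp <- ""
  for (opt in trimws(halves[-1])) {
    if (grepl("^reversible=", opt)) rev <- sub(".*=", "", opt) == "yes"
    else if (grepl("^co2=", opt)) {
      val <- sub("^co2=", "", opt)
      if (grepl(":", val)) {
        grp <- sub(".*:", "", val); co2 <- sub(":.*", "", val)
      } else co2 <- val
      if (!co2 %in% c("none", "release", "fix", "pr"))
        stop("model error (line ", lineno, "): unknown co2 role '", val, "'")
      if (nzchar(grp) && !grp %in% c("shunt", "tca", "fa"))
        stop("model error (line ", lineno, "): unknown co2 group '", grp, "'")
    } else stop("model error (line ", lineno, "): unknown option '", opt, "'")
  }
  cp <- regmatches(body, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", body))[[1]]
  if (!length(cp)) stop("model error (line ", lineno, "): missing reaction id")
  rid <- cp[2]
  sides <- strsplit(cp[3], "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("model error (line ", lineno, "): reaction ",
                               rid, " needs exactly one '->'")
  list(id = rid, reactants = .parse_side(sides[1], rid),
       products = .parse_side(sides[2], rid),
       reversible = rev, co2 = co2, co2Group = grp)
}

.validate_reaction <- function(rxn, mets) {
  rid <- rxn$id
  lookup <- function(id) {
    i <- match(id, mets$id)
    if (is.na(i)) stop("model error: reaction ", rid,
                       " references undeclared metabolite '", id, "'")
    i
  }
  for (side in c("reactants", "products")) {
    tb <- rxn[[side]]
    for (k in seq_len(nrow(tb))) {
      i <- lookup(tb$met[k])
      nc <- mets$carbons[i]
      mp <- tb$map[k]
      if (!is.na(mp) && nchar(mp) != nc)
        stop("atom-map error: reaction ", rid, ", species ", tb$met[k],
             " has ", nchar(mp), " mapped positions but ", nc, " carbons")
      if (is.na(mp) && nc > 0 && side == "reactants" &&
          !all(mets$sink[match(rxn$products$met, mets$id)]))
        stop("atom-map error: reaction ", rid, ": unmapped reactant ",
             tb$met[k], " outside a pure-sink reaction")
      if (is.na(mp) && nc > 0 && side == "products" &&
          !mets$sink[i])
        stop("atom-map error: reaction ", rid, ": unmapped non-sink product ",
             tb$met[k])
    }
  }
  fully_mapped <- !anyNA(rxn$reactants$map) &&
    all(!is.na(rxn$products$map) |
          mets$carbons[match(rxn$products$met, mets$id)] == 0 |
          mets$sink[match(rxn$products$met, mets$id)])
  if (fully_mapped && nrow(rxn$reactants)) {
    rl <- unlist(strsplit(rxn$reactants$map[!is.na(rxn$reactants$map)], ""))
    pl <- unlist(strsplit(rxn$products$map[!is.na(rxn$products$map)], ""))
    if (anyDuplicated(rl))
      stop("atom-map error: reaction ", rid, ": reactant letters reused")
    if (anyDuplicated(pl))
      stop("atom-map error: reaction ", rid, ": product letters reused")
    if (length(setdiff(pl, rl)))
      stop("atom-balance error: reaction ", rid, ": product positions ",
           paste(setdiff(pl, rl), collapse = ","),
           " do not originate from any reactant")
    missing <- setdiff(rl, pl)
    has_unmapped_sink <- any(is.na(rxn$products$map) &
                               mets$sink[match(rxn$products$met, mets$id)])
    if (length(missing) && !has_unmapped_sink)
      stop("atom-balance error: reaction ", rid, ": reactant positions ",
           paste(missing, collapse = ","), " are not mapped to any product")
  }
  invisible(TRUE)
}

#' Parse an atom-transition network model
#'
#' Reads the flat-file model dialect (see the package vignette) describing a
#' compartmentalized metabolic network with carbon atom transitions,
#' reversibility flags and CO2-release/fixation tags, validates the atom
#' bookkeeping of every reaction, and returns a \code{\linkS4class{NetworkModel}}.
#'
#' @param text path to a model file, or a character vector of model lines
#'   (a single string with embedded newlines also works).
#' @return a validated \code{NetworkModel}.
#' @examples
#' mdl <- parseNetworkModel(c(
#'   "@met A carbons=3 source", "@met B carbons=3", "@met C carbons=2",
#'   "@met CO2out carbons=1 sink",
#'   "r1: 1 A (abc) -> 1 B (abc)",
#'   "r2: 1 B (abc) -> 1 C (ab) + 1 CO2out (c) | co2=release:shunt"))
#' mdl
#' @export
parseNetworkModel <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  text <- unlist(strsplit(text, "\n", fixed = TRUE))
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]
  met_lines <- grepl("^@met", text)
  mets_l <- lapply(which(met_lines), function(i) .parse_met_line(text[i], i))
  mets <- do.call(rbind, lapply(mets_l, as.data.frame))
  if (is.null(mets) || !nrow(mets)) stop("model error: no metabolites declared")
  if (anyDuplicated(mets$id))
    stop("model error: duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  rxns <- lapply(which(!met_lines), function(i) .parse_rxn_line(text[i], i))
  ids <- vapply(rxns, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("model error: duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(rxns) <- ids
  for (rxn in rxns) .validate_reaction(rxn, mets)
  new("NetworkModel", metabolites = mets, reactions = rxns)
}

#' Serialize a network model to its flat-file dialect
#'
#' \code{parseNetworkModel(serializeNetworkModel(m))} reproduces \code{m}
#' exactly (bit-exact round trip).
#'
#' @param model a \code{NetworkModel}.
#' @return character vector of model lines.
#' @export
serializeNetworkModel <- function(model) {
  m <- model@metabolites
  met_lines <- vapply(seq_len(nrow(m)), function(i) {
    paste0("@met ", m$id[i], " carbons=", m$carbons[i],
           if (m$dilution[i]) " dilution=yes" else "",
           if (m$symmetric[i]) " symmetric=yes" else "",
           if (m$source[i]) " source" else "",
           if (m$sink[i]) " sink" else "")
  }, "")
  side_txt <- function(tb) paste(vapply(seq_len(nrow(tb)), function(k) {
    paste0(format(tb$coef[k], digits = 15), " ", tb$met[k],
           if (!is.na(tb$map[k])) paste0(" (", tb$map[k], ")") else "")
  }, ""), collapse = " + ")
  rxn_lines <- vapply(model@reactions, function(r) {
    paste0(r$id, ": ", side_txt(r$reactants), " -> ", side_txt(r$products),
           " | reversible=", if (r$reversible) "yes" else "no",
           " | co2=", r$co2,
           if (nzchar(r$co2Group)) paste0(":", r$co2Group) else "")
  }, "")
  c(met_lines, rxn_lines)
}

#' Stoichiometric matrix over balanced metabolites
#'
#' @param model a \code{NetworkModel}.
#' @return numeric matrix, rows = balanced (non-source, non-sink) metabolites,
#'   columns = reactions, entries = signed stoichiometric coefficients.
#' @export
stoichiometricMatrix <- function(model) {
  if (!length(model@reactions)) stop("model error: empty reaction list")
  m <- model@metabolites
  bal <- m$id[!m$source & !m$sink]
  N <- matrix(0, length(bal), length(model@reactions),
              dimnames = list(bal, names(model@reactions)))
  for (r in model@reactions) {
    for (k in seq_len(nrow(r$reactants))) {
      i <- match(r$reactants$met[k], bal)
      if (!is.na(i)) N[i, r$id] <- N[i, r$id] - r$reactants$coef[k]
    }
    for (k in seq_len(nrow(r$products))) {
      i <- match(r$products$met[k], bal)
      if (!is.na(i)) N[i, r$id] <- N[i, r$id] + r$products$coef[k]
    }
  }
  N
}

#' Basis of the steady-state (free) flux space
#'
#' Columns form an orthonormal basis of the null space of the balanced
#' stoichiometric matrix; any steady-state net-flux vector is \code{B \%*\% y}.
#'
#' @param model a \code{NetworkModel}.
#' @param tol singular-value tolerance relative to the largest.
#' @return matrix (reactions x d); \code{d} is the number of free fluxes.
#' @export
freeFluxBasis <- function(model, tol = 1e-10) {
  N <- stoichiometricMatrix(model)
  sv <- svd(N, nu = 0, nv = ncol(N))
  r <- sum(sv$d > tol * max(sv$d, .Machine$double.eps))
  if (r >= ncol(N))
    stop("model error: zero-dimensional null space (over-constrained model)")
  B <- sv$v[, (r + 1):ncol(N), drop = FALSE]
  rownames(B) <- colnames(N)
  B
}

#' Solve for a steady-state net-flux vector with pinned coordinates
#'
#' Finds \code{v} with \code{N v = 0} and \code{v[names(pins)] = pins}. If the
#' pins do not determine the null space completely the minimum-norm completion
#' is returned; inconsistent pins raise an error.
#'
#' @param model a \code{NetworkModel}.
#' @param pins named numeric vector of pinned net fluxes.
#' @param tol feasibility tolerance.
#' @return named numeric vector of net fluxes over all reactions.
#' @export
steadyStateFlux <- function(model, pins, tol = 1e-6) {
  B <- freeFluxBasis(model)
  idx <- match(names(pins), rownames(B))
  if (anyNA(idx)) stop("unknown reaction in pins: ",
                       paste(names(pins)[is.na(idx)], collapse = ", "))
  Bp <- B[idx, , drop = FALSE]
  sv <- svd(Bp)
  pos <- sv$d > 1e-10 * max(sv$d)
  y <- sv$v[, pos, drop = FALSE] %*% ((crossprod(sv$u[, pos, drop = FALSE],
                                                 pins)) / sv$d[pos])
  v <- drop(B %*% y)
  if (max(abs(v[idx] - pins)) > tol * max(1, max(abs(pins))))
    stop("steadyStateFlux: pinned fluxes are inconsistent with steady state")
  names(v) <- rownames(B)
  v
}

#' Net and exchange fluxes resolved into directional fluxes
#'
#' @param model a \code{NetworkModel}.
#' @param flux a \code{FluxState}.
#' @return data.frame with reaction id, forward and backward flux.
#' @export
directionalFluxes <- function(model, flux) {
  ids <- names(model@reactions)
  net <- flux@net[ids]
  ex <- setNames(numeric(length(ids)), ids)
  rev <- vapply(model@reactions, `[[`, TRUE, "reversible")
  ex[names(flux@exch)] <- flux@exch
  ex[!rev] <- 0
  data.frame(id = ids, fwd = pmax(net, 0) + ex, bwd = pmax(-net, 0) + ex,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition non-photorespiratory CO2 release (R_L)
#'
#' R_L is the net sum of CO2-releasing fluxes other than photorespiratory
#' glycine decarboxylation, minus non-rubisco carboxylation (PEP carboxylase).
#' Components follow the reaction tags: \code{release:shunt} (6-phosphogluconate
#' decarboxylation of the G6P/OPP shunt), \code{release:tca} (TCA-associated
#' decarboxylations, offset by \code{fix} reactions), and \code{release:fa}
#' (plastidic pyruvate decarboxylation feeding fatty-acid synthesis).
#' Components sum to the total by construction.
#'
#' @param model a \code{NetworkModel} with tagged reactions.
#' @param flux a \code{FluxState} (only net fluxes are used).
#' @return list with \code{RL_total}, \code{shunt}, \code{tca},
#'   \code{fatty_acid} (mumol CO2 gFW^-1 h^-1).
#' @export
computeRL <- function(model, flux) {
  roles <- vapply(model@reactions, `[[`, "", "co2")
  grp <- vapply(model@reactions, `[[`, "", "co2Group")
  rel <- names(roles)[roles == "release"]
  untagged <- rel[!nzchar(grp[rel])]
  if (length(untagged))
    stop("computeRL: untagged decarboxylations (no co2 group): ",
         paste(untagged, collapse = ", "))
  v <- flux@net[names(roles)]
  shunt <- sum(v[rel[grp[rel] == "shunt"]])
  fa <- sum(v[rel[grp[rel] == "fa"]])
  tca <- sum(v[rel[grp[rel] == "tca"]]) - sum(v[roles == "fix"])
  list(RL_total = shunt + tca + fa, shunt = shunt, tca = tca, fatty_acid = fa)
}

#' Net CO2 assimilation implied by a flux state
#'
#' Uptake through reactions consuming the 1-carbon source metabolite
#' (rubisco carboxylation, PEP carboxylation) minus all CO2 release
#' (photorespiratory and non-photorespiratory).
#'
#' @param model a \code{NetworkModel}.
#' @param flux a \code{FluxState}.
#' @return net assimilation, mumol CO2 gFW^-1 h^-1.
#' @export
netAssimilation <- function(model, flux) {
  m <- model@metabolites
  co2src <- m$id[m$source & m$carbons == 1]
  up <- 0; relv <- 0
  for (r in model@reactions) {
    take <- r$reactants$met %in% co2src
    if (any(take)) up <- up + flux@net[r$id] * sum(r$reactants$coef[take])
    if (r$co2 %in% c("release", "pr")) relv <- relv + flux@net[r$id]
  }
  unname(up - relv)
}

#' Maximum steady-state mass-balance violation of a flux state
#'
#' @param model a \code{NetworkModel}.
#' @param flux a \code{FluxState}.
#' @return max |N v| over balanced metabolites, relative to max |v|.
#' @export
steadyStateResidual <- function(model, flux) {
  N <- stoichiometricMatrix(model)
  max(abs(N %*% flux@net[colnames(N)])) / max(abs(flux@net), .Machine$double.eps)
}
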