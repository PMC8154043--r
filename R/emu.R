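## Elementary metabolite unit (EMU) decomposition.
##
## An EMU is a subset of a metabolite's carbon atoms; its mass isotopologue
## distribution (MID) can be balanced independently of the rest of the
## molecule. Backward traversal of the atom maps from the measured fragments
## yields the minimal set of EMUs needed to simulate them, organised in
## blocks of increasing size: production terms whose source atoms split over
## several species couple a block only to strictly smaller blocks (through
## MID convolutions), so the blocks form an acyclic cascade.

emuId <- function(met, subset) paste0(met, "[", paste(subset, collapse = ","), "]")

emuParse <- function(id) {
  m <- regmatches(id, regexec("^(.*)\\[([0-9,]+)\\]$", id))[[1]]
  if (!length(m)) stop("malformed EMU id: ", id)
  list(met = m[2], subset = as.integer(strsplit(m[3], ",")[[1]]))
}

## production instances of a metabolite: for every reaction direction that
## produces `met`, the produced occurrence's letter map plus the letter maps
## of the source side. Symmetric metabolites get two half-weight instances
## (identity and mirrored), which implements 50/50 rotational scrambling.
.production_instances <- function(model, met) {
  mets <- model@metabolites
  out <- list()
  for (r in model@reactions) {
    sides <- list(fwd = list(prod = r$products, src = r$reactants),
                  bwd = list(prod = r$reactants, src = r$products))
    dirs <- if (r$reversible) c("fwd", "bwd") else "fwd"
    for (d in dirs) {
      prod <- sides[[d]]$prod; src <- sides[[d]]$src
      if (anyNA(src$map)) next  # pure-sink reactions produce no label
      hit <- which(prod$met == met & !is.na(prod$map))
      for (k in hit) {
        base <- list(reaction = r$id, dir = d, coef = prod$coef[k],
                     map = strsplit(prod$map[k], "")[[1]],
                     srcMet = src$met, srcMap = strsplit(src$map, ""))
        if (mets$symmetric[match(met, mets$id)]) {
          m1 <- base; m1$w <- 0.5
          m2 <- base; m2$w <- 0.5; m2$map <- rev(base$map)
          out <- c(out, list(m1, m2))
        } else {
          base$w <- 1
          out <- c(out, list(base))
        }
      }
    }
  }
  out
}

## for one production instance and a carbon subset S of the produced species,
## locate the source EMU(s): the preimage positions of S grouped by source
## occurrence. Returns character vector of EMU ids (possibly length > 1 for
## convolution terms).
.instance_sources <- function(inst, subset) {
  letters_needed <- inst$map[subset]
  srcs <- character(0)
  for (j in seq_along(inst$srcMet)) {
    pos <- which(inst$srcMap[[j]] %in% letters_needed)
    if (length(pos)) srcs <- c(srcs, emuId(inst$srcMet[j], sort(pos)))
  }
  tot <- sum(vapply(srcs, function(s) length(emuParse(s)$subset), 0L))
  if (tot != length(subset))
    stop("internal atom-map inconsistency producing ",
         emuId("?", subset), " via ", inst$reaction)
  srcs
}

#' Decompose a network into the EMU system required for target fragments
#'
#' Performs backward traversal of the atom-transition maps from the target
#' (measured) EMUs, collecting the minimal set of unknown EMUs and their
#' flux-weighted production terms, ordered by EMU size then lexicographically.
#'
#' @param model a \code{NetworkModel}.
#' @param targets character vector of EMU ids (\code{"Met.c[1,2,3]"}), or a
#'   data.frame with columns \code{met} and \code{positions}
#'   (comma-separated string).
#' @return an \code{\linkS4class{EMUSystem}}.
#' @examples
#' mdl <- parseNetworkModel(c(
#'   "@met A carbons=3 source", "@met B carbons=3", "@met C carbons=3",
#'   "r1: 1 A (abc) -> 1 B (abc)", "r2: 1 B (abc) -> 1 C (abc)"))
#' emuDecompose(mdl, "C[1,2,3]")
#' @export
emuDecompose <- function(model, targets) {
  if (is.data.frame(targets))
    targets <- vapply(seq_len(nrow(targets)), function(i)
      emuId(targets$met[i],
            as.integer(strsplit(targets$positions[i], ",")[[1]])), "")
  targets <- unique(targets)
  mets <- model@metabolites
  for (tg in targets) {
    p <- emuParse(tg)
    i <- match(p$met, mets$id)
    if (is.na(i)) stop("target references unknown metabolite: ", p$met)
    if (any(p$subset < 1) || any(p$subset > mets$carbons[i]))
      stop("target positions outside 1..n_carbons: ", tg)
    if (mets$source[i])
      stop("target on a source metabolite with no defined input MID: ", tg)
  }
  is_input <- function(id) mets$source[match(emuParse(id)$met, mets$id)]
  prodCache <- new.env(parent = emptyenv())
  getProd <- function(met) {
    if (is.null(prodCache[[met]]))
      prodCache[[met]] <- .production_instances(model, met)
    prodCache[[met]]
  }
  known <- character(0)
  queue <- targets
  terms <- list()
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    if (id %in% known) next
    known <- c(known, id)
    p <- emuParse(id)
    for (inst in getProd(p$met)) {
      srcs <- .instance_sources(inst, p$subset)
      terms[[length(terms) + 1]] <- list(
        emu = id, reaction = inst$reaction, dir = inst$dir,
        weight = inst$w * inst$coef, src = srcs)
      for (s in srcs) if (!is_input(s) && !(s %in% known)) queue <- c(queue, s)
    }
  }
  sizes <- vapply(known, function(id) length(emuParse(id)$subset), 0L)
  ord <- order(sizes, known)
  emus <- data.frame(id = known[ord],
                     met = vapply(known[ord], function(i) emuParse(i)$met, ""),
                     subset = vapply(known[ord], function(i)
                       paste(emuParse(i)$subset, collapse = ","), ""),
                     size = sizes[ord], row.names = NULL,
                     stringsAsFactors = FALSE)
  new("EMUSystem", emus = emus, terms = terms, targets = targets,
      model = model)
}

#' Convolve two mass isotopologue distributions
#'
#' The MID of a composite EMU is the discrete convolution of its parts.
#'
#' @param a,b numeric MID vectors (each summing to 1 within 1e-8,
#'   non-negative).
#' @return numeric vector of length \code{length(a) + length(b) - 1}.
#' @examples
#' convolveMID(c(0.5, 0.5), c(0.5, 0.5))  # 0.25 0.5 0.25
#' @export
convolveMID <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("convolveMID: negative entries")
  if (abs(sum(a) - 1) > 1e-8 || abs(sum(b) - 1) > 1e-8)
    stop("convolveMID: inputs must each sum to 1")
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}

#' Dump the EMU dependency graph as an edge list
#'
#' Debug helper: one row per (production term, source EMU) pair.
#'
#' @param system an \code{EMUSystem}.
#' @return data.frame with columns \code{emu}, \code{reaction}, \code{dir},
#'   \code{weight}, \code{source}.
#' @export
emuEdgeList <- function(system) {
  do.call(rbind, lapply(system@terms, function(tm)
    data.frame(emu = tm$emu, reaction = tm$reaction, dir = tm$dir,
               weight = tm$weight, source = tm$src,
               stringsAsFactors = FALSE)))
}
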