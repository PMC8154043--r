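#' @import methods
#' @importFrom stats setNames
NULL

#' NetworkModel: a compartmentalized atom-transition network
#'
#' Holds the metabolite table, the reaction list (with carbon atom
#' transitions), and bookkeeping used by the EMU machinery. Compartments are
#' encoded as suffixes on metabolite ids: \code{".p"} plastid, \code{".c"}
#' cytosol, \code{".m"} mitochondrion. Construct with
#' \code{\link{parseNetworkModel}}; do not fill slots by hand.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{carbons},
#'   \code{source}, \code{sink}, \code{dilution}, \code{symmetric}.
#' @slot reactions list; each element has \code{id}, \code{reactants},
#'   \code{products} (data.frames with \code{met}, \code{coef}, \code{map}),
#'   \code{reversible}, \code{co2} (one of \code{"none"}, \code{"release"},
#'   \code{"fix"}, \code{"pr"}) and \code{co2Group} (\code{"shunt"},
#'   \code{"tca"}, \code{"fa"} or \code{""}).
#'
#' @export
setClass("NetworkModel",
  representation(metabolites = "data.frame", reactions = "list"))

#' FluxState: a steady-state flux/pool/dilution assignment
#'
#' Net fluxes are signed (mumol gFW^-1 h^-1; negative net flux through a
#' reversible reaction means the backward direction dominates), exchange
#' fluxes are the non-negative bidirectional component of reversible
#' reactions, pool sizes are concentrations (mumol gFW^-1) of balanced
#' metabolites, and dilution fractions give, per metabolite carrying an
#' inactive (typically vacuolar) pool, the fraction of measured signal coming
#' from that unlabeled pool.
#'
#' @slot net named numeric, one entry per reaction.
#' @slot exch named numeric, one entry per reversible reaction, all >= 0.
#' @slot pools named numeric, one entry per balanced metabolite, all > 0.
#' @slot dilution named numeric in [0,1] for metabolites with dilution pools.
#'
#' @export
setClass("FluxState",
  representation(net = "numeric", exch = "numeric",
                 pools = "numeric", dilution = "numeric"))

#' EMUSystem: size-ordered elementary metabolite unit balance blocks
#'
#' Result of \code{\link{emuDecompose}}. EMUs are identified as
#' \code{"met[i,j,...]"} with 1-based carbon positions. The \code{terms} list
#' records, for every unknown EMU, the flux-weighted production terms; terms
#' whose sources all live in strictly smaller size blocks (or are tracer
#' inputs) become convolution inputs of a block.
#'
#' @slot emus data.frame with columns \code{id}, \code{met}, \code{subset},
#'   \code{size}; ordered by size then lexicographically (deterministic).
#' @slot terms list of production terms (\code{emu}, \code{reaction},
#'   \code{dir}, \code{weight}, \code{src} character vector of EMU ids).
#' @slot targets character, ids of the EMUs backing measured fragments.
#' @slot model the \code{NetworkModel} the system was derived from.
#'
#' @export
setClass("EMUSystem",
  representation(emus = "data.frame", terms = "list",
                 targets = "character", model = "NetworkModel"))

#' MIDTimeSeries: measured or simulated isotopologue fraction time courses
#'
#' A long-format container for mass isotopologue distributions of fragment
#' ions over a labeling time course, together with the fragment definitions,
#' measured boundary rates and generator metadata (when synthetic).
#'
#' @slot data data.frame with columns \code{fragment}, \code{time} (min),
#'   \code{iso} (0-based isotopologue index), \code{value}, \code{sd}.
#' @slot fragments data.frame of fragment definitions (see
#'   \code{\link{fragmentTable}}).
#' @slot rates data.frame of boundary-rate measurements
#'   (\code{quantity}, \code{value}, \code{sd}).
#' @slot meta list (tracer purity, replicate count, truth record for
#'   synthetic data, ...).
#'
#' @export
setClass("MIDTimeSeries",
  representation(data = "data.frame", fragments = "data.frame",
                 rates = "data.frame", meta = "list"))

#' FitResult: outcome of an INST-MFA least-squares fit
#'
#' @slot flux best-fit \code{FluxState}.
#' @slot par named numeric, optimizer-scale parameters at the optimum.
#' @slot ssr variance-weighted sum of squared residuals.
#' @slot sres data.frame of per-fragment squared residuals.
#' @slot dof residual degrees of freedom (number of residuals minus number of
#'   fitted parameters).
#' @slot chi2 list with the two-sided chi-square acceptance interval and
#'   verdict (see \code{\link{chi2Accept}}).
#' @slot scenario scenario label (\code{"unconstrained"},
#'   \code{"forced_co2np"}, \code{"forced_tca"}, \code{"forced_fatty_acid"},
#'   \code{"forced_shunt"}).
#' @slot diagnostics list (number of starts, convergence info, data digest).
#'
#' @export
setClass("FitResult",
  representation(flux = "FluxState", par = "numeric", ssr = "numeric",
                 sres = "data.frame", dof = "numeric", chi2 = "list",
                 scenario = "character", diagnostics = "list"))

setValidity("NetworkModel", function(object) {
  m <- object@metabolites
  if (anyDuplicated(m$id)) return("duplicate metabolite ids")
  if (any(m$carbons < 0)) return("negative carbon counts")
  if (any(m$source & m$sink)) return("metabolite flagged both source and sink")
  ids <- vapply(object@reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) return("duplicate reaction ids")
  TRUE
})

setValidity("FluxState", function(object) {
  if (any(object@exch < 0)) return("negative exchange flux")
  if (length(object@pools) && any(object@pools <= 0)) return("non-positive pool size")
  d <- object@dilution
  if (length(d) && (any(d < 0) || any(d > 1))) return("dilution fraction outside [0,1]")
  TRUE
})

setMethod("show", "NetworkModel", function(object) {
  m <- object@metabolites
  cat("NetworkModel:", sum(!m$source & !m$sink), "balanced metabolites (",
      sum(m$source), "source,", sum(m$sink), "sink ),",
      length(object@reactions), "reactions\n")
  rel <- vapply(object@reactions, `[[`, "", "co2")
  cat("  CO2 roles: release", sum(rel == "release"), "| fix", sum(rel == "fix"),
      "| photorespiratory", sum(rel == "pr"), "\n")
})

setMethod("show", "FluxState", function(object) {
  cat("FluxState:", length(object@net), "net fluxes,", length(object@exch),
      "exchange fluxes,", length(object@pools), "pools,",
      length(object@dilution), "dilution fractions\n")
  cat("  |net| range:", signif(range(abs(object@net)), 4), "umol gFW-1 h-1\n")
})

setMethod("show", "EMUSystem", function(object) {
  sz <- table(object@emus$size)
  cat("EMUSystem:", nrow(object@emus), "unknown EMUs in",
      length(sz), "size blocks (", paste(names(sz), sz, sep = ":", collapse = " "),
      "),", length(object@targets), "targets\n")
})

setMethod("show", "MIDTimeSeries", function(object) {
  cat("MIDTimeSeries:", length(unique(object@data$fragment)), "fragments,",
      length(unique(object@data$time)), "time points,",
      nrow(object@data), "MID entries\n")
  if (nrow(object@rates))
    cat("  boundary rates:", paste(object@rates$quantity, collapse = ", "), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult [", object@scenario, "]  SSR =", signif(object@ssr, 6),
      " dof =", object@dof, "\n")
  if (length(object@chi2))
    cat("  chi-square 95% acceptance [", signif(object@chi2$lower, 6), ",",
        signif(object@chi2$upper, 6), "]:",
        if (isTRUE(object@chi2$accepted)) "accepted" else "rejected", "\n")
})

# ---- accessors ----

#' Accessors for model and result objects
#'
#' @param object a \code{NetworkModel}, \code{FluxState}, \code{EMUSystem},
#'   \code{MIDTimeSeries} or \code{FitResult}.
#' @return \code{metabolites}/\code{reactions} return the model tables;
#'   \code{netFluxes}, \code{exchangeFluxes}, \code{poolSizes},
#'   \code{dilutionFractions} the named numeric slots of a \code{FluxState};
#'   \code{midData}, \code{fragmentTable}, \code{boundaryRates} the tables of
#'   a \code{MIDTimeSeries}; \code{bestFlux} and \code{fitSSR} the fitted
#'   state and SSR of a \code{FitResult}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
metabolites <- function(object) object@metabolites

#' @rdname accessors
#' @export
reactions <- function(object) object@reactions

#' @rdname accessors
#' @export
netFluxes <- function(object) object@net

#' @rdname accessors
#' @export
exchangeFluxes <- function(object) object@exch

#' @rdname accessors
#' @export
poolSizes <- function(object) object@pools

#' @rdname accessors
#' @export
dilutionFractions <- function(object) object@dilution

#' @rdname accessors
#' @export
midData <- function(object) object@data

#' @rdname accessors
#' @export
fragmentTable <- function(object) object@fragments

#' @rdname accessors
#' @export
boundaryRates <- function(object) object@rates

#' @rdname accessors
#' @export
bestFlux <- function(object) object@flux

#' @rdname accessors
#' @export
fitSSR <- function(object) object@ssr

#' Construct a FluxState
#'
#' @param net named numeric vector of net fluxes (one per reaction).
#' @param exch named numeric vector of exchange fluxes (reversible reactions).
#' @param pools named numeric vector of pool sizes.
#' @param dilution named numeric vector of dilution fractions in [0,1].
#' @return a validated \code{FluxState}.
#' @export
FluxState <- function(net, exch = numeric(0), pools = numeric(0),
                      dilution = numeric(0)) {
  new("FluxState", net = net, exch = exch, pools = pools, dilution = dilution)
}
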