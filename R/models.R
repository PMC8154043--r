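## Built-in network models, ground-truth flux states and fit configurations.
##
## `camelinaLeafModel()` is the full leaf fixture: C3 cycle, photorespiration,
## starch/sucrose synthesis, glycolysis, PEP carboxylation, noncyclic
## TCA-associated reactions, G6P/OPP shunt and plastidic fatty-acid precursor
## synthesis, with inactive (vacuolar) dilution pools on measured
## metabolites. `miniLeafModel()` is a small leaf-like network for
## scaled-down statistical experiments.

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "leafMFA")
  if (!nzchar(p)) p <- file.path("inst", "extdata", f)  # pre-install fallback
  if (!file.exists(p)) stop("cannot locate bundled file ", f)
  p
}

#' Built-in leaf network models
#'
#' @return a validated \code{NetworkModel}.
#' @export
camelinaLeafModel <- function() parseNetworkModel(.extdata("camelina_model.txt"))

#' @rdname camelinaLeafModel
#' @export
miniLeafModel <- function() parseNetworkModel(.extdata("mini_model.txt"))

#' Read a fragment definition table (tab-separated)
#'
#' @param path TSV with columns fragment, components, weights, formula, sd.
#' @return data.frame.
#' @export
readFragmentTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' @rdname camelinaLeafModel
#' @export
camelinaFragments <- function() readFragmentTable(.extdata("camelina_fragments.tsv"))

#' @rdname camelinaLeafModel
#' @export
miniFragments <- function() readFragmentTable(.extdata("mini_fragments.tsv"))

.camelina_pools <- function() c(
  RuBP.p = 0.30, PGA.p = 0.60, GAP.p = 0.04, DHAP.p = 0.10, FBP.p = 0.12,
  F6P.p = 0.30, G6P.p = 0.50, E4P.p = 0.02, SBP.p = 0.10, S7P.p = 0.15,
  R5P.p = 0.03, X5P.p = 0.03, Ru5P.p = 0.03, PG2.p = 0.03, GLY.p = 1.2,
  SER.p = 0.8, GLYC.p = 0.08, ADPG.p = 0.01, PEP.p = 0.05, PYR.p = 0.05,
  ACA.p = 0.02, DHAP.c = 0.10, GAP.c = 0.04, FBP.c = 0.10, F6P.c = 0.20,
  G6P.c = 1.00, UDPG.c = 0.12, SUC.c = 2.16, PGA.c = 0.30, PEP.c = 0.15,
  PYR.c = 0.10, OAA.c = 0.05, MAL.c = 1.5, ALA.c = 0.10, ASP.c = 1.0,
  GLU.c = 2.5, ACA.c = 0.02, OAA.m = 0.05, MAL.m = 0.50, FUM.m = 0.30,
  SUCC.m = 0.40, CIT.m = 1.2, AKG.m = 0.30)

.camelina_dilution <- function() c(
  RuBP.p = 0.075, PGA.p = 0.08, PGA.c = 0.10, GAP.p = 0.07, DHAP.p = 0.07,
  DHAP.c = 0.09, FBP.p = 0.11, FBP.c = 0.13, F6P.p = 0.12, F6P.c = 0.14,
  G6P.p = 0.11, G6P.c = 0.14, E4P.p = 0.08, SBP.p = 0.075, S7P.p = 0.055,
  R5P.p = 0.065, X5P.p = 0.07, Ru5P.p = 0.07, PG2.p = 0.07, GLY.p = 0.28,
  SER.p = 0.31, GLYC.p = 0.15, ADPG.p = 0.065, UDPG.c = 0.21, SUC.c = 0.40,
  PEP.c = 0.09, MAL.c = 0.92, ALA.c = 0.22, ASP.c = 0.45,
  GLU.c = 0.90, MAL.m = 0.92, FUM.m = 0.93, SUCC.m = 0.93, CIT.m = 0.86,
  AKG.m = 0.95)

.camelina_exchange <- function() c(
  pgk = 50, tpi_p = 100, fba_p = 20, tkt1 = 10, sba = 10, tkt2 = 10,
  rpi = 20, rpe = 20, pgi_p = 20, tpt = 40, tpi_c = 10, fba_c = 5,
  pgi_c = 10, gapdh_c = 5, eno = 5, ala_ta = 6, asp_ta = 2, mdh_c = 0.3,
  oaat = 1, sdh = 0.15, fum = 0.3, mdh_m = 0.3)

#' Ground-truth flux state of the camelina leaf fixture
#'
#' Net fluxes are the steady-state completion of the pinned decarboxylation,
#' carbohydrate-output and anaplerotic fluxes (shunt 4.6, cytosolic pyruvate
#' dehydrogenase 0.8 with the coupled isocitrate-dehydrogenase release, PEP
#' carboxylation 1.1, starch 9.5, sucrose export 4.3, plastidic pyruvate
#' decarboxylation 0, rubisco oxygenation at v_o/v_c = 0.2); carboxylation
#' (about 132 umol gFW-1 h-1) follows from carbon conservation. Flux units
#' umol gFW-1 h-1, pools umol gFW-1.
#'
#' @param model the fixture model (pass to avoid re-parsing).
#' @return a \code{FluxState} satisfying steady state to machine precision.
#' @export
camelinaTruth <- function(model = camelinaLeafModel()) {
  pins0 <- c(shunt = 4.6, starch = 9.5, export = 4.3, pepc = 1.1,
             pdh_c = 0.8, akgdh = 0, pdh_p = 0)
  ## rbc_o enters the pins; v_c is linear in (pins, rbc_o), so solve
  ## rbc_o = ratio * v_c(pins, rbc_o) for rbc_o.
  ratio <- 0.2
  v0 <- steadyStateFlux(model, c(pins0, rbc_o = 0))
  v1 <- steadyStateFlux(model, c(pins0, rbc_o = 1))
  alpha <- v0[["rbc_c"]]; beta <- v1[["rbc_c"]] - alpha
  rbc_o <- ratio * alpha / (1 - ratio * beta)
  v <- steadyStateFlux(model, c(pins0, rbc_o = rbc_o))
  FluxState(net = v, exch = .camelina_exchange(),
            pools = .camelina_pools(), dilution = .camelina_dilution())
}

#' Ground-truth flux state of the mini leaf model
#'
#' @param model the mini model.
#' @return a \code{FluxState}.
#' @export
miniTruth <- function(model = miniLeafModel()) {
  v <- steadyStateFlux(model, c(carb = 12, shuntm = 1, pdhm = 0.3,
                                fam = 0.05, expx = 2.5))
  FluxState(net = v, exch = c(tpt = 5),
            pools = c(ACC.p = 0.3, TRI.p = 0.4, C1.p = 0.05, TRI.c = 0.5,
                      PYR.c = 0.2, ACE.c = 0.05, CIT2.c = 1.5),
            dilution = c(ACC.p = 0.1, TRI.p = 0.08, TRI.c = 0.15,
                         PYR.c = 0.2, CIT2.c = 0.9))
}

#' Fit configuration for a model
#'
#' Bundles the parameterization the optimizer uses: which net fluxes are the
#' free coordinates (pins), the rubisco-oxygenation ratio handling, which
#' exchange fluxes and pools are fitted (the rest stay at model defaults),
#' the scenario-forcing elimination rules, and the measured R_L used by
#' forced scenarios.
#'
#' @param model "camelina" or "mini".
#' @param vovc_bounds numeric c(lower, upper) for the rubisco oxygenation to
#'   carboxylation ratio, or NULL to leave the ratio free in (0, 0.5)
#'   (camelina only).
#' @return list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(model = c("camelina", "mini"),
                      vovc_bounds = c(0.2, 0.25)) {
  model <- match.arg(model)
  if (model == "camelina") {
    structure(list(
      name = "camelina",
      pins = c("rbc_o", "shunt", "starch", "export", "pepc", "pdh_c",
               "akgdh", "pdh_p"),
      ratio = list(reaction = "rbc_o", vc = "rbc_c", bounds = vovc_bounds),
      exch_fit = c("ala_ta", "asp_ta", "mdh_c", "pgi_p", "pgi_c", "tpt",
                   "tkt1", "tkt2", "rpi", "rpe"),
      exch_defaults = .camelina_exchange(),
      pools_fit = c("RuBP.p", "PGA.p", "FBP.p", "F6P.p", "G6P.p", "G6P.c",
                    "S7P.p", "SBP.p", "R5P.p", "E4P.p", "PG2.p", "GLY.p",
                    "SER.p", "ADPG.p", "UDPG.c", "SUC.c", "PEP.c", "PYR.c",
                    "ALA.c", "ASP.c", "GLU.c", "CIT.m", "MAL.c", "AKG.m"),
      pools_default = .camelina_pools(),
      scenario_elim = c(forced_co2np = "shunt", forced_shunt = "shunt",
                        forced_tca = "akgdh", forced_fatty_acid = "pdh_p"),
      boundary = list(A_net = "A_net", starch = "starch", sucrose = "sps"),
      ## generic start values; starch/export are replaced by the measured
      ## boundary rates of the dataset being fitted
      start = c(shunt = 2, starch = 9, export = 4, pepc = 1, pdh_c = 0.5,
                akgdh = 0.2, pdh_p = 0.2),
      start_boundary = c(starch = "starch", export = "sucrose"),
      RL_measured = 9.3), class = "fitConfig")
  } else {
    structure(list(
      name = "mini",
      pins = c("carb", "shuntm", "pdhm", "fam", "expx"),
      ratio = NULL,
      exch_fit = "tpt",
      exch_defaults = c(tpt = 5),
      pools_fit = c("ACC.p", "TRI.p", "TRI.c", "PYR.c", "CIT2.c"),
      pools_default = miniTruth(miniLeafModel())@pools,
      scenario_elim = c(forced_co2np = "shuntm", forced_shunt = "shuntm",
                        forced_tca = "pdhm", forced_fatty_acid = "fam"),
      boundary = list(A_net = "A_net", starch = "c1sink", sucrose = "expx"),
      start = c(carb = 10, shuntm = 0.5, pdhm = 0.2, fam = 0.2, expx = 2),
      start_boundary = c(expx = "sucrose"),
      RL_measured = 2.0), class = "fitConfig")
  }
}
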