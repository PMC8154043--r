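## Plain-text readers/writers and the end-to-end orchestration:
## simulate/generate -> fit scenarios -> scenario table -> confidence
## intervals -> report bundle. All outputs are delimited text that round-trip
## through this module's own readers.

#' Write / read a MID dataset as delimited text
#'
#' Three tab-separated files under \code{dir}: \code{mids.tsv} (fragment,
#' time, iso, value, sd), \code{fragments.tsv} (definitions) and
#' \code{rates.tsv} (boundary rates). \code{readMIDDataset} reassembles the
#' \code{MIDTimeSeries}; numeric round-trip is exact to the printed
#' precision (15 significant digits).
#'
#' @param data a \code{MIDTimeSeries}.
#' @param dir output directory (created if missing).
#' @return \code{writeMIDDataset}: the directory, invisibly;
#'   \code{readMIDDataset}: a \code{MIDTimeSeries}.
#' @export
writeMIDDataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) utils::write.table(
    format(df, digits = 15, scientific = FALSE, trim = TRUE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(data@data, "mids.tsv")
  utils::write.table(data@fragments, file.path(dir, "fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  wr(data@rates, "rates.tsv")
  meta <- data@meta
  keep <- c("purity", "replicates", "seed", "model", "RL_measured")
  ml <- vapply(intersect(keep, names(meta)), function(k)
    paste0(k, "=", format(meta[[k]], digits = 15)), "")
  writeLines(ml, file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname writeMIDDataset
#' @export
readMIDDataset <- function(dir) {
  d <- utils::read.delim(file.path(dir, "mids.tsv"), stringsAsFactors = FALSE)
  fr <- utils::read.delim(file.path(dir, "fragments.tsv"),
                          stringsAsFactors = FALSE, na.strings = "NA")
  rt <- utils::read.delim(file.path(dir, "rates.tsv"), stringsAsFactors = FALSE)
  meta <- list()
  mf <- file.path(dir, "meta.txt")
  if (file.exists(mf)) {
    for (ln in readLines(mf)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      val <- utils::type.convert(kv[2], as.is = TRUE)
      meta[[kv[1]]] <- val
    }
  }
  new("MIDTimeSeries", data = d, fragments = fr, rates = rt, meta = meta)
}

#' Write a FluxState as a delimited table
#'
#' @param flux a \code{FluxState}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFluxTable <- function(flux, path) {
  rows <- rbind(
    data.frame(kind = "net", id = names(flux@net), value = unname(flux@net)),
    if (length(flux@exch))
      data.frame(kind = "exchange", id = names(flux@exch),
                 value = unname(flux@exch)),
    if (length(flux@pools))
      data.frame(kind = "pool", id = names(flux@pools),
                 value = unname(flux@pools)),
    if (length(flux@dilution))
      data.frame(kind = "dilution", id = names(flux@dilution),
                 value = unname(flux@dilution)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full INST-MFA pipeline and write a report bundle
#'
#' Fits the requested scenarios to a dataset, compares them by SSR, profiles
#' the R_L confidence interval, and writes delimited report tables: one flux
#' table per scenario, the scenario comparison (SSR, v_o/v_c, R_L
#' decomposition), per-fragment squared residuals, the R_L partition of the
#' best fit, CI tables, and a key=value summary with seeds and versions.
#'
#' @param data a \code{MIDTimeSeries} (e.g. from \code{\link{generateDataset}}
#'   or \code{\link{readMIDDataset}}).
#' @param model a \code{NetworkModel}.
#' @param config a \code{\link{fitConfig}}.
#' @param scenarios character vector of scenario labels to fit.
#' @param outdir report directory.
#' @param seed integer seed.
#' @param n_starts multi-starts for the first scenario; later scenarios are
#'   warm-started from the first fit.
#' @param ci one of "continuation", "none".
#' @param ... passed to \code{\link{fitFluxes}}.
#' @return list with fits, scenario table and CI table, invisibly.
#' @export
runPipeline <- function(data, model, config,
                        scenarios = c("unconstrained", "forced_co2np"),
                        outdir = "leafMFA_report", seed = 1, n_starts = 10,
                        ci = c("continuation", "none"), ...) {
  ci <- match.arg(ci)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  fits <- list()
  first <- TRUE
  for (sc in scenarios) {
    fits[[sc]] <- stage(paste0("fit:", sc), fitFluxes(
      model, data, config, scenario = sc, seed = seed,
      n_starts = if (first) n_starts else max(2, n_starts %/% 3),
      start = if (!first) fits[[1]]@par else NULL, ...))
    writeFluxTable(fits[[sc]]@flux,
                   file.path(outdir, paste0("fluxes_", sc, ".tsv")))
    first <- FALSE
  }
  cmp <- if (length(fits) >= 2) stage("scenario_compare",
                                      scenarioCompare(fits)) else NULL
  if (!is.null(cmp))
    utils::write.table(cmp, file.path(outdir, "scenario_compare.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sres <- stage("sres", {
    tb <- fits[[1]]@sres
    names(tb)[2] <- paste0("sres_", scenarios[1])
    for (sc in scenarios[-1]) tb[[paste0("sres_", sc)]] <- fits[[sc]]@sres$sres
    tb
  })
  utils::write.table(sres, file.path(outdir, "sres.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  best <- fits[[which.min(vapply(fits, fitSSR, 0))]]
  rl <- computeRL(model, best@flux)
  utils::write.table(
    data.frame(component = names(rl), value = unlist(rl)),
    file.path(outdir, "rl_decomposition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  citab <- NULL
  if (ci == "continuation")
    citab <- stage("ci", continuationCI(model, data, config, fits[[1]],
                                        "RL_total"))
  if (!is.null(citab))
    utils::write.table(citab, file.path(outdir, "ci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  summary_lines <- c(
    paste0("leafMFA_version=", as.character(utils::packageVersion("leafMFA"))),
    paste0("R_version=", R.version.string),
    paste0("seed=", seed),
    paste0("scenarios=", paste(scenarios, collapse = ",")),
    paste0("best_scenario=", best@scenario),
    vapply(names(fits), function(sc)
      paste0("ssr_", sc, "=", format(fits[[sc]]@ssr, digits = 10)), ""),
    paste0("dof=", fits[[1]]@dof),
    paste0("RL_total=", format(rl$RL_total, digits = 10)),
    paste0("RL_shunt=", format(rl$shunt, digits = 10)),
    paste0("RL_tca=", format(rl$tca, digits = 10)),
    paste0("RL_fatty_acid=", format(rl$fatty_acid, digits = 10)))
  writeLines(summary_lines, file.path(outdir, "summary.txt"))
  invisible(list(fits = fits, comparison = cmp, ci = citab, sres = sres,
                 rl = rl))
}
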