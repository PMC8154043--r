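## Mapping between instrument-space and model-space MIDs: natural-abundance
## correction matrices, fragment composition (moiety mixing), inactive-pool
## dilution, and the sucrose glucosyl/fructosyl deconvolution.

#' Default isotope abundance table
#'
#' Mass-shift distributions (shift 0, +1, +2, ...) per element, IUPAC values;
#' 13C natural abundance 0.0107. Pass a modified copy to
#' \code{\link{naturalAbundanceMatrix}} to change the correction basis.
#'
#' @return named list of numeric vectors.
#' @export
isotopeTable <- function() {
  list(C  = c(0.9893, 0.0107),
       H  = c(0.999885, 0.000115),
       N  = c(0.99636, 0.00364),
       O  = c(0.99757, 0.00038, 0.00205),
       S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
       Si = c(0.92223, 0.04685, 0.03092))
}

.conv_vec <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}

.parse_formula <- function(formula) {
  if (is.numeric(formula)) return(formula)
  if (!nzchar(formula)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- numeric(0)
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- gsub("[A-Za-z]", "", tk)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) +
      (if (nzchar(n)) as.numeric(n) else 1)
  }
  counts
}

#' Natural-abundance correction matrix for a fragment
#'
#' Builds the square matrix \code{M} with \code{raw = M \%*\% corrected}:
#' column \code{j} gives the mass-shift distribution of a molecule whose
#' \code{j} tracer-labeled skeleton carbons are fixed while the remaining
#' \code{n - j} skeleton carbons and all derivatization/heteroatom positions
#' carry natural isotope abundance. The window is truncated to M0..Mn.
#'
#' @param formula extra (non-skeleton) atom counts: a chemical formula string
#'   such as \code{"C8H20NOSi"} or a named numeric vector; \code{""} for none.
#' @param n_skeleton number of skeleton (tracer) carbons.
#' @param abundances isotope table (see \code{\link{isotopeTable}}).
#' @return (n+1) x (n+1) matrix.
#' @export
naturalAbundanceMatrix <- function(formula, n_skeleton,
                                   abundances = isotopeTable()) {
  counts <- .parse_formula(formula)
  extra <- 1
  for (el in names(counts)) {
    if (!el %in% names(abundances)) stop("no abundance entry for element ", el)
    for (k in seq_len(counts[[el]])) extra <- .conv_vec(extra, abundances[[el]])
  }
  n <- n_skeleton
  aC <- if (length(abundances$C) > 1) abundances$C[2] / sum(abundances$C[1:2]) else 0
  M <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    skel <- stats::dbinom(0:(n - j), n - j, aC)
    dj <- .conv_vec(skel, extra)
    for (i in j:n) {
      k <- i - j + 1
      if (k <= length(dj)) M[i + 1, j + 1] <- dj[k]
    }
  }
  if (abs(det(M)) < 1e-12) stop("natural-abundance matrix is singular")
  M
}

#' Correct a raw MID for natural abundance
#'
#' Solves \code{M x = raw}, clips small negative components to zero and
#' renormalizes. Components more negative than -0.01 indicate an
#' inconsistent spectrum; these are flagged (attribute \code{"flagged"}) and
#' a warning is logged.
#'
#' @param raw numeric raw MID vector.
#' @param matrix correction matrix from \code{\link{naturalAbundanceMatrix}}.
#' @return corrected MID vector summing to 1.
#' @export
correctMID <- function(raw, matrix) {
  if (length(raw) != nrow(matrix)) stop("correctMID: length mismatch")
  x <- solve(matrix, raw)
  flagged <- any(x < -0.01)
  if (flagged)
    warning("correctMID: large negative components after correction (",
            signif(min(x), 3), ")")
  x[x < 0] <- 0
  x <- x / sum(x)
  attr(x, "flagged") <- flagged
  x
}

## ---- fragment definitions ----

#' Build a fragment definition table
#'
#' Fragments are the measured ions; each is backed by one or more EMU
#' components (moieties or compartment variants of the same carbon skeleton)
#' mixed with fixed weights. \code{components} uses
#' \code{"Met.c:1-3"} syntax, multiple components separated by \code{"|"};
#' weights likewise (\code{"0.54|0.46"}), omitted = equal weight 1.
#'
#' @param fragment character ids.
#' @param components component spec strings.
#' @param weights weight spec strings (must sum to 1 when given).
#' @param formula extra-atom formulas for natural-abundance handling.
#' @param sd default measurement sd (mole fraction).
#' @return data.frame usable as the \code{fragments} slot of a
#'   \code{MIDTimeSeries}.
#' @export
fragmentDef <- function(fragment, components, weights = NA_character_,
                        formula = "", sd = 0.01) {
  data.frame(fragment = fragment, components = components,
             weights = weights, formula = formula, sd = sd,
             stringsAsFactors = FALSE)
}

.parse_positions <- function(txt) {
  if (grepl("-", txt)) {
    ab <- as.integer(strsplit(txt, "-")[[1]])
    seq(ab[1], ab[2])
  } else as.integer(strsplit(txt, ",")[[1]])
}

.parse_components <- function(row) {
  comps <- strsplit(row$components, "|", fixed = TRUE)[[1]]
  parsed <- lapply(comps, function(cp) {
    kv <- strsplit(cp, ":", fixed = TRUE)[[1]]
    list(met = kv[1], positions = .parse_positions(kv[2]))
  })
  w <- if (is.na(row$weights)) rep(1 / length(parsed), length(parsed))
  else as.numeric(strsplit(row$weights, "|", fixed = TRUE)[[1]])
  if (length(w) != length(parsed) || any(w < 0) || abs(sum(w) - 1) > 1e-6)
    stop("fragment ", row$fragment, ": bad mixture weights")
  list(comps = parsed, weights = w)
}

#' EMU targets required by a fragment table
#'
#' @param fragments a fragment definition data.frame.
#' @return character vector of EMU ids to pass to \code{\link{emuDecompose}}.
#' @export
fragmentTargets <- function(fragments) {
  unique(unlist(lapply(seq_len(nrow(fragments)), function(i) {
    pc <- .parse_components(fragments[i, ])
    vapply(pc$comps, function(cp) emuId(cp$met, cp$positions), "")
  })))
}

#' Predict the measured MID of a fragment from simulated EMU trajectories
#'
#' Each component EMU trajectory is first mixed with the unlabeled vector
#' according to its metabolite's dilution fraction (the metabolically
#' inactive, typically vacuolar, pool), then components are combined with the
#' fragment's fixed mixture weights.
#'
#' @param sim result of \code{\link{simulateLabeling}}.
#' @param frag one row of a fragment definition table.
#' @param dilution named numeric vector of dilution fractions per metabolite
#'   (missing metabolites get 0).
#' @return (size+1) x length(times) matrix of predicted fractions.
#' @export
predictFragment <- function(sim, frag, dilution = numeric(0)) {
  pc <- .parse_components(frag)
  out <- NULL
  for (k in seq_along(pc$comps)) {
    cp <- pc$comps[[k]]
    id <- emuId(cp$met, cp$positions)
    m <- sim$mids[[id]]
    if (is.null(m)) stop("predictFragment: missing trajectory for ", id)
    d <- if (cp$met %in% names(dilution)) dilution[[cp$met]] else 0
    u <- c(1, numeric(nrow(m) - 1))
    md <- (1 - d) * m + d * u
    out <- if (is.null(out)) pc$weights[k] * md else out + pc$weights[k] * md
  }
  out
}

#' Deconvolve sucrose moiety MIDs from the m/z 361 and 451 fragments
#'
#' The two GC-MS sucrose fragments are fixed mixtures of the glucosyl and
#' fructosyl moieties: \code{f361 = a1*fFru + (1-a1)*fGlu},
#' \code{f451 = a2*fFru + (1-a2)*fGlu} with default a1 = 0.54, a2 = 0.92
#' (measured standard; a cited alternative is 0.60/0.95). Solves the 2x2
#' system per isotopologue, clips to [0,1] and renormalizes.
#'
#' @param f361,f451 numeric MID vectors (length 7 for sucrose moieties).
#' @param fru_weights fructosyl fractions c(in m/z 361, in m/z 451).
#' @return list with \code{fGlu} and \code{fFru}.
#' @export
deconvolveSucrose <- function(f361, f451, fru_weights = c(0.54, 0.92)) {
  if (length(f361) != length(f451)) stop("deconvolveSucrose: length mismatch")
  A <- rbind(c(fru_weights[1], 1 - fru_weights[1]),
             c(fru_weights[2], 1 - fru_weights[2]))
  if (abs(det(A)) < 1e-6)
    stop("deconvolveSucrose: degenerate mixing coefficients")
  sol <- solve(A, rbind(f361, f451))
  clipnorm <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x / sum(x) }
  list(fGlu = clipnorm(sol[2, ]), fFru = clipnorm(sol[1, ]))
}
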