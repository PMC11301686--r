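## Proteoform inference from deconvoluted intact-mass lists:
## glycoform ladders, small named mass shifts, and disulfide-bridge
## counting between nonreduced and reduced runs. Inputs are already
## deconvoluted (z = 1) mass lists; no raw-spectrum processing here.

#' Deconvoluted intact-mass list
#'
#' One entry per deconvoluted mass: the neutral mass, its intensity,
#' whether it is monoisotopic or average, and the sample condition
#' (reduced or nonreduced).
#'
#' @slot mass numeric, positive neutral masses (Da).
#' @slot intensity numeric, arbitrary units.
#' @slot mode character, `"mono"` or `"avg"` per entry.
#' @slot condition character, `"reduced"` or `"nonreduced"` per entry.
#' @slot label character annotation per entry.
#' @seealso [detectLadders()], [relateMasses()], [pairConditions()]
#' @export
setClass("DeconMassList",
  representation(mass = "numeric", intensity = "numeric",
                 mode = "character", condition = "character",
                 label = "character"))

setValidity("DeconMassList", function(object) {
  msgs <- character()
  n <- length(object@mass)
  if (any(object@mass <= 0)) msgs <- c(msgs, "masses must be positive")
  if (length(object@intensity) != n || length(object@mode) != n ||
      length(object@condition) != n || length(object@label) != n)
    msgs <- c(msgs, "all slots must have one entry per mass")
  if (!all(object@mode %in% c("mono", "avg")))
    msgs <- c(msgs, "mode must be 'mono' or 'avg'")
  if (!all(object@condition %in% c("reduced", "nonreduced")))
    msgs <- c(msgs, "condition must be 'reduced' or 'nonreduced'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DeconMassList
#'
#' @param mass Numeric vector of neutral masses (Da).
#' @param intensity Numeric vector (recycled), default 1.
#' @param mode `"mono"` or `"avg"` (recycled).
#' @param condition `"reduced"` or `"nonreduced"` (recycled).
#' @param label Character annotations (recycled), default `""`.
#' @return A [DeconMassList-class].
#' @examples
#' DeconMassList(c(13871.96, 13887.95), mode = "avg")
#' @export
DeconMassList <- function(mass, intensity = 1, mode = "avg",
                          condition = "nonreduced", label = "") {
  n <- length(mass)
  methods::new("DeconMassList", mass = as.numeric(mass),
               intensity = rep_len(as.numeric(intensity), n),
               mode = rep_len(mode, n),
               condition = rep_len(condition, n),
               label = rep_len(label, n))
}

setMethod("show", "DeconMassList", function(object) {
  cat("DeconMassList with ", length(object@mass), " entries (",
      paste(unique(object@mode), collapse = "/"), "; ",
      paste(unique(object@condition), collapse = "/"), ")\n", sep = "")
  print(utils::head(as.data.frame(object)))
})

#' @describeIn DeconMassList-class number of entries
#' @param x A `DeconMassList`.
#' @export
setMethod("length", "DeconMassList", function(x) length(x@mass))

#' Coerce a DeconMassList to data.frame
#' @param x A [DeconMassList-class].
#' @param ... Unused.
#' @return `data.frame` with columns `mass`, `intensity`, `mode`,
#'   `condition`, `label`.
#' @export
as.data.frame.DeconMassList <- function(x, ...) {
  data.frame(mass = x@mass, intensity = x@intensity, mode = x@mode,
             condition = x@condition, label = x@label,
             stringsAsFactors = FALSE)
}

.massVec <- function(ml) if (methods::is(ml, "DeconMassList")) ml@mass else as.numeric(ml)
.intensityVec <- function(ml, n)
  if (methods::is(ml, "DeconMassList")) ml@intensity else rep(1, n)

.stepTable <- function(steps, mode) {
  if (is.data.frame(steps)) {
    col <- if (mode == "mono") "mono" else "avg"
    stats::setNames(steps[[col]], steps$name)
  } else if (is.numeric(steps) && !is.null(names(steps))) {
    steps
  } else stop("steps must be a glycanSteps()-style data.frame or a named numeric vector")
}

#' Glycoform ladder hit
#'
#' A maximal chain of intact masses whose consecutive gaps each equal a
#' registered glycan (or other) step within tolerance.
#'
#' @slot baseMass numeric, lightest member mass.
#' @slot steps character, step name per gap (length = members - 1).
#' @slot members integer indices into the input mass list, increasing
#'   in mass.
#' @slot residuals numeric Da, observed gap minus step mass, per gap.
#' @slot intensity numeric, summed intensity of the members.
#' @export
setClass("LadderHit",
  representation(baseMass = "numeric", steps = "character",
                 members = "integer", residuals = "numeric",
                 intensity = "numeric"))

setMethod("show", "LadderHit", function(object) {
  cat("LadderHit: base ", formatMass(object@baseMass, 2), " Da + ",
      paste(object@steps, collapse = " + "),
      "  (", length(object@members), " members, max |residual| ",
      formatMass(max(abs(object@residuals)), 3), " Da)\n", sep = "")
})

#' Detect glycoform ladders in an intact-mass list
#'
#' Finds maximal chains of masses whose adjacent gaps each match one
#' registered step within tolerance. Extension is greedy with
#' best-residual tie-breaking (each mass links to the candidate with
#' the smallest residual); chains that cannot be extended to lighter or
#' heavier members are reported when they contain at least two members,
#' sorted by summed intensity. Intensity plays no role while building
#' chains, only in ranking.
#'
#' @param ml [DeconMassList-class] or numeric mass vector.
#' @param steps Step registry: [glycanSteps()]-style data.frame or
#'   named numeric vector of deltas (Da).
#' @param tol Positive tolerance (Da). Default 0.05 for monoisotopic,
#'   0.5 for average data.
#' @param mode `"mono"` or `"avg"`; used to pick step masses and the
#'   default tolerance when `ml` is a plain numeric vector.
#' @return List of [LadderHit-class] objects (possibly empty).
#' @examples
#' detectLadders(c(10000, 10203.079, 10406.159), tol = 0.05,
#'               mode = "mono")
#' @export
detectLadders <- function(ml, steps = glycanSteps(), tol = NULL,
                          mode = c("mono", "avg")) {
  if (methods::is(ml, "DeconMassList")) mode <- ml@mode[1]
  else mode <- match.arg(mode)
  if (is.null(tol))
    tol <- unname(defaultTolerances()[
      if (mode == "mono") "da_mono" else "da_avg"])
  if (tol <= 0) stop("tolerance must be positive")
  masses <- .massVec(ml)
  intens <- .intensityVec(ml, length(masses))
  if (length(masses) < 2L) return(list())
  stp <- .stepTable(steps, mode)
  ord <- order(masses)
  m <- masses[ord]
  n <- length(m)
  succ <- rep(NA_integer_, n)
  succStep <- rep(NA_character_, n)
  succRes <- rep(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    gaps <- m[(i + 1L):n] - m[i]
    best <- NULL
    for (j in seq_along(gaps)) {
      res <- gaps[j] - stp
      k <- which.min(abs(res))
      if (abs(res[k]) <= tol &&
          (is.null(best) || abs(res[k]) < abs(best$res))) {
        best <- list(j = i + j, step = names(stp)[k], res = res[k])
      }
    }
    if (!is.null(best)) {
      succ[i] <- best$j; succStep[i] <- best$step; succRes[i] <- best$res
    }
  }
  isSucc <- rep(FALSE, n)
  isSucc[stats::na.omit(succ)] <- TRUE
  hits <- list()
  for (s in which(!isSucc & !is.na(succ))) {
    chain <- s; stepsOut <- character(); resOut <- numeric()
    cur <- s
    while (!is.na(succ[cur])) {
      stepsOut <- c(stepsOut, succStep[cur])
      resOut <- c(resOut, succRes[cur])
      cur <- succ[cur]
      chain <- c(chain, cur)
    }
    if (length(chain) >= 2L) {
      idx <- ord[chain]
      hits[[length(hits) + 1L]] <- methods::new("LadderHit",
        baseMass = masses[idx[1]], steps = stepsOut,
        members = as.integer(idx), residuals = resOut,
        intensity = sum(intens[idx]))
    }
  }
  if (length(hits) > 1L)
    hits <- hits[order(vapply(hits, function(h) h@intensity,
                              numeric(1)), decreasing = TRUE)]
  hits
}

#' Disulfide-bridge estimate
#'
#' @slot nBridges integer, estimated bridge count (>= 0).
#' @slot deltaMass numeric, reduced minus nonreduced mass (Da).
#' @slot residual numeric, delta minus `nBridges` times the per-bridge
#'   step (Da).
#' @slot accepted logical, `TRUE` when the residual is within
#'   tolerance.
#' @slot mode character, `"mono"` or `"avg"`.
#' @export
setClass("DisulfideEstimate",
  representation(nBridges = "integer", deltaMass = "numeric",
                 residual = "numeric", accepted = "logical",
                 mode = "character"))

setMethod("show", "DisulfideEstimate", function(object) {
  cat("DisulfideEstimate: ", object@nBridges, " bridge(s), delta ",
      formatMass(object@deltaMass), " Da, residual ",
      formatMass(object@residual), " Da",
      if (!object@accepted) " [NOT accepted]", "\n", sep = "")
})

#' Count disulfide bridges from a reduced/nonreduced mass pair
#'
#' Each disulfide bridge reduced to two free thiols adds two hydrogens
#' (2.01565 Da monoisotopic). The bridge count is the nearest integer
#' multiple of that step in the reduced-minus-nonreduced mass shift.
#'
#' @param m_nonreduced Intact mass under nonreducing conditions (Da).
#' @param m_reduced Intact mass of the same proteoform after reduction
#'   (Da), same mode.
#' @param tol Acceptance tolerance on the residual (Da); default 0.05
#'   mono / 0.5 avg.
#' @param mode `"mono"` or `"avg"`.
#' @return A [DisulfideEstimate-class].
#' @examples
#' countDisulfides(6414.61, 6424.68, tol = 0.1)   # five bridges
#' @export
countDisulfides <- function(m_nonreduced, m_reduced, tol = NULL,
                            mode = c("mono", "avg")) {
  mode <- match.arg(mode)
  stopifnot(m_nonreduced > 0, m_reduced > 0)
  if (is.null(tol))
    tol <- unname(defaultTolerances()[
      if (mode == "mono") "da_mono" else "da_avg"])
  k <- massConstants()
  step <- if (mode == "mono") k[["ss_step_mono"]] else k[["ss_step_avg"]]
  delta <- m_reduced - m_nonreduced
  if (delta < -tol)
    stop("reduced mass below nonreduced mass beyond tolerance: ",
         "inconsistent condition pair")
  n <- max(0L, as.integer(round(delta / step)))
  residual <- delta - n * step
  methods::new("DisulfideEstimate", nBridges = n, deltaMass = delta,
               residual = residual, accepted = abs(residual) <= tol,
               mode = mode)
}

#' Relate masses by registered small shifts
#'
#' All ordered pairs (lighter to heavier) in a mass list whose
#' difference matches a registered delta -- oxidation (O), CO, water,
#' glycan steps, or custom deltas -- within tolerance, each labelled by
#' the best-fitting delta.
#'
#' @param ml [DeconMassList-class] or numeric mass vector.
#' @param deltas Named numeric vector of deltas (Da); default
#'   [shiftDeltas()] for the data mode.
#' @param tol Positive tolerance (Da); default 0.05 mono / 0.5 avg.
#' @param mode `"mono"` or `"avg"` (when `ml` is a plain vector).
#' @return `data.frame` with columns `from`, `to` (indices, lighter to
#'   heavier), `fromMass`, `toMass`, `delta` (name), `deltaMass`,
#'   `residual`.
#' @examples
#' relateMasses(c(13871.96, 13887.95), tol = 0.5, mode = "avg")
#' @export
relateMasses <- function(ml, deltas = NULL, tol = NULL,
                         mode = c("mono", "avg")) {
  if (methods::is(ml, "DeconMassList")) mode <- ml@mode[1]
  else mode <- match.arg(mode)
  if (is.null(deltas)) deltas <- shiftDeltas(mode)
  if (is.null(tol))
    tol <- unname(defaultTolerances()[
      if (mode == "mono") "da_mono" else "da_avg"])
  if (tol <= 0) stop("tolerance must be positive")
  masses <- .massVec(ml)
  out <- data.frame(from = integer(0), to = integer(0),
                    fromMass = numeric(0), toMass = numeric(0),
                    delta = character(0), deltaMass = numeric(0),
                    residual = numeric(0), stringsAsFactors = FALSE)
  n <- length(masses)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- i; b <- j
    if (masses[a] > masses[b]) { a <- j; b <- i }
    gap <- masses[b] - masses[a]
    res <- gap - deltas
    k <- which.min(abs(res))
    if (abs(res[k]) <= tol)
      out[nrow(out) + 1L, ] <- list(a, b, masses[a], masses[b],
                                    names(deltas)[k], deltas[[k]],
                                    res[[k]])
  }
  out
}

#' Pair nonreduced and reduced mass lists by disulfide shifts
#'
#' Cross-condition candidate pairing: every (nonreduced, reduced) pair
#' whose mass difference is `n` times the per-bridge step for some
#' `0 <= n <= max_bridges` within tolerance, with its
#' [DisulfideEstimate-class]. One-to-many pairings are allowed and
#' flagged.
#'
#' @param nonred Nonreduced masses ([DeconMassList-class] or numeric).
#' @param red Reduced masses.
#' @param max_bridges Maximum bridge count considered (>= 0).
#' @param tol Positive tolerance (Da); default 0.05 mono / 0.5 avg.
#' @param mode `"mono"` or `"avg"` (when inputs are plain vectors).
#' @return `data.frame` with columns `nonredIdx`, `redIdx`,
#'   `nonredMass`, `redMass`, `nBridges`, `residual`, `ambiguous`
#'   (TRUE when either member also occurs in another pairing).
#' @examples
#' pairConditions(13553.88, 13567.99, max_bridges = 10, tol = 0.1,
#'                mode = "mono")
#' @export
pairConditions <- function(nonred, red, max_bridges = 10L, tol = NULL,
                           mode = c("mono", "avg")) {
  if (methods::is(nonred, "DeconMassList")) mode <- nonred@mode[1]
  else mode <- match.arg(mode)
  if (max_bridges < 0) stop("max_bridges must be >= 0")
  if (is.null(tol))
    tol <- unname(defaultTolerances()[
      if (mode == "mono") "da_mono" else "da_avg"])
  k <- massConstants()
  step <- if (mode == "mono") k[["ss_step_mono"]] else k[["ss_step_avg"]]
  mn <- .massVec(nonred); mr <- .massVec(red)
  out <- data.frame(nonredIdx = integer(0), redIdx = integer(0),
                    nonredMass = numeric(0), redMass = numeric(0),
                    nBridges = integer(0), residual = numeric(0))
  for (i in seq_along(mn)) for (j in seq_along(mr)) {
    delta <- mr[j] - mn[i]
    if (delta < -tol) next
    n <- max(0L, as.integer(round(delta / step)))
    if (n > max_bridges) next
    residual <- delta - n * step
    if (abs(residual) <= tol)
      out[nrow(out) + 1L, ] <- list(i, j, mn[i], mr[j], n, residual)
  }
  out$ambiguous <- duplicated(out$nonredIdx) |
    duplicated(out$nonredIdx, fromLast = TRUE) |
    duplicated(out$redIdx) | duplicated(out$redIdx, fromLast = TRUE)
  out
}
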