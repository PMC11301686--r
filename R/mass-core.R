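## Peptide representation and exact mass arithmetic.
##
## Display dialect: sequences are written as in venom peptidomics
## tables -- "pE" for an N-terminal pyroglutamate residue and
## modification markers "_ox_", "_diox_", "_CAM_" immediately after the
## modified residue, e.g. "pEKW_ox_". The parser is whitespace-tolerant
## and also accepts the variants "pGlu" and "(ox)".

#' Peptide with positional modifications
#'
#' An S4 container for a venom peptide: ordered residue codes (single
#' letters plus the compound code `pE` for pyroglutamate) and a
#' per-position list of modification names from
#' [modificationRegistry()]. Construct with [parsePeptide()].
#'
#' @slot residues character vector of residue codes.
#' @slot mods list, one character vector of modification names per
#'   position (possibly empty).
#' @seealso [parsePeptide()], [neutralMass()], [fragmentLadder()]
#' @export
setClass("Peptide",
  representation(residues = "character", mods = "list"))

setValidity("Peptide", function(object) {
  msgs <- character()
  tab <- residueMasses()
  bad <- setdiff(object@residues, tab$code)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown residue code(s): ",
                           paste(unique(bad), collapse = ", ")))
  if (length(object@mods) != length(object@residues))
    msgs <- c(msgs, "mods list must have one entry per residue")
  reg <- modificationRegistry()
  n <- length(object@residues)
  for (i in seq_len(n)) {
    for (m in object@mods[[i]]) {
      j <- match(m, reg$name)
      if (is.na(j)) {
        msgs <- c(msgs, paste0("unknown modification: ", m))
        next
      }
      tgt <- strsplit(reg$targets[j], ",", fixed = TRUE)[[1]]
      ok <- object@residues[i] %in% tgt ||
        ("Nterm" %in% tgt && i == 1L) || ("Cterm" %in% tgt && i == n)
    if (!ok)
        msgs <- c(msgs, paste0("modification '", m,
                               "' not allowed on residue '",
                               object@residues[i], "' at position ", i))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Parse a peptide display string
#'
#' Parses the table dialect of venom peptidomics: leading `pE`
#' (pyroglutamate), uppercase single-letter residues, and modification
#' markers `_ox_`, `_diox_`, `_CAM_` directly after the residue they
#' sit on. Whitespace is ignored; the lenient aliases `pGlu` (for `pE`)
#' and `(ox)` / `(diox)` / `(CAM)` are accepted and normalised.
#'
#' @param x Character scalar, e.g. `"pEKW_ox_"`.
#' @return A [Peptide-class] object. Parsing then rendering with
#'   [renderPeptide()] reproduces the canonical display string.
#' @examples
#' p <- parsePeptide("pEKW_ox_")
#' renderPeptide(p)
#' @export
parsePeptide <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("[[:space:]]", "", x)
  s <- gsub("pGlu", "pE", s, fixed = TRUE)
  s <- gsub("\\(([A-Za-z]+)\\)", "_\\1_", s)
  chars <- strsplit(s, "")[[1]]
  residues <- character()
  mods <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "p" && i < length(chars) && chars[i + 1L] == "E") {
      residues <- c(residues, "pE"); mods <- c(mods, list(character()))
      i <- i + 2L
    } else if (ch == "_") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "_") j <- j + 1L
      if (j > length(chars))
        stop("unterminated modification marker in '", x, "'")
      m <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!length(residues))
        stop("modification marker '_", m, "_' with no preceding residue")
      mods[[length(mods)]] <- c(mods[[length(mods)]], m)
      i <- j + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      residues <- c(residues, ch); mods <- c(mods, list(character()))
      i <- i + 1L
    } else {
      stop("cannot parse token '", ch, "' at position ", i, " of '", x, "'")
    }
  }
  if (!length(residues)) stop("empty peptide string")
  methods::new("Peptide", residues = residues, mods = mods)
}

#' Render a peptide back to its display string
#'
#' @param p A [Peptide-class].
#' @return Character scalar in the canonical dialect
#'   (`pE` prefix, `_ox_`-style markers).
#' @examples
#' renderPeptide(parsePeptide("pE KW (ox)"))
#' @export
renderPeptide <- function(p) {
  stopifnot(methods::is(p, "Peptide"))
  paste0(vapply(seq_along(p@residues), function(i) {
    paste0(p@residues[i],
           paste0(vapply(p@mods[[i]], function(m) paste0("_", m, "_"),
                         character(1)), collapse = ""))
  }, character(1)), collapse = "")
}

setMethod("show", "Peptide", function(object) {
  iso <- which(object@residues %in% c("I", "L"))
  cat("Peptide: ", renderPeptide(object), "\n", sep = "")
  cat("  length: ", length(object@residues),
      "  [M+H]+ mono: ",
      formatMass(mz(neutralMass(object), 1L)), "\n", sep = "")
  if (length(iso))
    cat("  isobaric I/L position(s): ", paste(iso, collapse = ", "),
        " (MS cannot distinguish Leu/Ile)\n", sep = "")
})

#' Peptide length in residues
#' @param x A [Peptide-class].
#' @return Integer residue count (`pE` counts as one residue).
#' @export
setMethod("length", "Peptide", function(x) length(x@residues))

#' Flag isobaric Leu/Ile positions
#'
#' Leucine and isoleucine share an elemental composition; mass
#' spectrometry cannot tell them apart, so positions carrying either
#' are flagged as isobaric in reports.
#'
#' @param p A [Peptide-class].
#' @return Integer vector of 1-based positions holding I or L.
#' @examples
#' isobaricPositions(parsePeptide("pEKWLDPEIPP"))
#' @export
isobaricPositions <- function(p) {
  stopifnot(methods::is(p, "Peptide"))
  which(p@residues %in% c("I", "L"))
}

.asPeptide <- function(p) {
  if (methods::is(p, "Peptide")) p else parsePeptide(p)
}

.residueMassVector <- function(p, mode) {
  tab <- residueMasses()
  col <- if (mode == "mono") "mono" else "avg"
  base <- tab[[col]][match(p@residues, tab$code)]
  reg <- modificationRegistry()
  mod <- vapply(p@mods, function(ms) {
    if (!length(ms)) return(0)
    sum(reg[[col]][match(ms, reg$name)])
  }, numeric(1))
  base + mod
}

#' Neutral peptide mass
#'
#' Sum of residue masses, modification deltas and one water
#' (18.010565 Da mono / 18.0153 Da average) completing the backbone.
#'
#' @param p A [Peptide-class] or a display string (parsed on the fly).
#' @param mode `"mono"` (monoisotopic, default) or `"avg"` (average).
#' @return Neutral mass M in Da.
#' @examples
#' neutralMass("pEKW")           # 443.217
#' neutralMass("G")              # single glycine: residue + water
#' @export
neutralMass <- function(p, mode = c("mono", "avg")) {
  mode <- match.arg(mode)
  p <- .asPeptide(p)
  k <- massConstants()
  w <- if (mode == "mono") k[["water_mono"]] else k[["water_avg"]]
  sum(.residueMassVector(p, mode)) + w
}

#' m/z of a protonated ion
#'
#' @param neutral_mass Neutral mass M (Da).
#' @param z Positive integer charge.
#' @return `(M + z * 1.00728) / z`.
#' @examples
#' mz(neutralMass("pEKW"), 1)    # 444.224
#' mz(1131.571, 2)               # 566.793
#' @export
mz <- function(neutral_mass, z = 1L) {
  if (any(z < 1) || any(z != as.integer(z)))
    stop("charge z must be a positive integer")
  (neutral_mass + z * massConstants()[["proton"]]) / z
}

#' m/z of a multimer ion
#'
#' Noncovalent peptide multimers (e.g. the abundant 2M+H dimer ion of
#' the tripeptide svMP inhibitors) at charge z:
#' `(n * M + z * 1.00728) / z`.
#'
#' @param p [Peptide-class] or display string.
#' @param n Multimer count (>= 1).
#' @param z Charge (>= 1).
#' @param mode `"mono"` or `"avg"`.
#' @return m/z of the nM + zH ion.
#' @examples
#' multimerIonMz("pEKW", n = 2, z = 1)   # 887.441
#' @export
multimerIonMz <- function(p, n = 1L, z = 1L, mode = c("mono", "avg")) {
  if (n < 1 || n != as.integer(n)) stop("multimer count n must be >= 1")
  mz(n * neutralMass(p, match.arg(mode)), z)
}

#' b/y fragment ion ladder
#'
#' Singly-charged-convention fragment series for collision-induced
#' dissociation: `b_i` = sum of the first i residue masses (+ charge
#' protons), `y_i` = sum of the last i residue masses + water
#' (+ charge protons). Positional modifications travel with their
#' residue. A peptide of n residues yields n - 1 ions per series.
#'
#' @param p [Peptide-class] or display string.
#' @param series `"b"` or `"y"`.
#' @param z Charge (>= 1); ladders are reported as m/z.
#' @param mode `"mono"` or `"avg"`.
#' @return Named numeric vector of m/z, names `b1..` or `y1..`.
#' @examples
#' fragmentLadder("pEKW", "b")   # b1 = pE immonium-series 112.039
#' fragmentLadder("pEKW", "y")
#' @export
fragmentLadder <- function(p, series = c("b", "y"), z = 1L,
                           mode = c("mono", "avg")) {
  series <- match.arg(series)
  mode <- match.arg(mode)
  if (z < 1 || z != as.integer(z)) stop("charge z must be >= 1")
  p <- .asPeptide(p)
  n <- length(p@residues)
  if (n == 0L) stop("empty peptide")
  if (n == 1L)
    return(stats::setNames(numeric(0), character(0)))
  k <- massConstants()
  w <- if (mode == "mono") k[["water_mono"]] else k[["water_avg"]]
  rm <- .residueMassVector(p, mode)
  idx <- seq_len(n - 1L)
  if (series == "b") {
    neutral <- cumsum(rm)[idx]
  } else {
    neutral <- cumsum(rev(rm))[idx] + w
  }
  vals <- (neutral + z * k[["proton"]]) / z
  stats::setNames(vals, paste0(series, idx))
}

#' Match observed against theoretical m/z values
#'
#' Greedy nearest-first matching: candidate pairs within tolerance are
#' accepted in order of increasing absolute error, each observed and
#' each theoretical peak used at most once.
#'
#' @param observed Numeric vector of observed m/z.
#' @param theoretical Numeric vector of theoretical m/z.
#' @param tol Positive tolerance.
#' @param unit `"ppm"` (default, relative to the theoretical value) or
#'   `"Da"`.
#' @return List with `matches` (data.frame: `observed`, `theoretical`,
#'   `error_da`, `error_ppm`), `unmatched_observed` and
#'   `unmatched_theoretical` (numeric vectors).
#' @examples
#' matchObserved(c(444.2240), c(444.2241), tol = 10)
#' @export
matchObserved <- function(observed, theoretical, tol = 10,
                          unit = c("ppm", "Da")) {
  unit <- match.arg(unit)
  if (tol <= 0) stop("tolerance must be positive")
  empty <- data.frame(observed = numeric(0), theoretical = numeric(0),
                      error_da = numeric(0), error_ppm = numeric(0))
  if (!length(observed) || !length(theoretical))
    return(list(matches = empty, unmatched_observed = observed,
                unmatched_theoretical = theoretical))
  cand <- expand.grid(oi = seq_along(observed), ti = seq_along(theoretical))
  cand$err <- observed[cand$oi] - theoretical[cand$ti]
  lim <- if (unit == "ppm") tol * 1e-6 * theoretical[cand$ti] else tol
  cand <- cand[abs(cand$err) <= lim, , drop = FALSE]
  cand <- cand[order(abs(cand$err)), , drop = FALSE]
  usedO <- logical(length(observed)); usedT <- logical(length(theoretical))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    oi <- cand$oi[r]; ti <- cand$ti[r]
    if (!usedO[oi] && !usedT[ti]) {
      keep[r] <- TRUE; usedO[oi] <- TRUE; usedT[ti] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  matches <- data.frame(
    observed = observed[cand$oi],
    theoretical = theoretical[cand$ti],
    error_da = cand$err,
    error_ppm = cand$err / theoretical[cand$ti] * 1e6)
  matches <- matches[order(matches$theoretical), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_observed = observed[!usedO],
       unmatched_theoretical = theoretical[!usedT])
}

#' Format a mass for display
#'
#' Display rounding is 3 decimals, matching peptidomics table style;
#' all comparisons inside the package are on full precision.
#'
#' @param x Numeric.
#' @param digits Decimals (default 3).
#' @return Character vector.
#' @export
formatMass <- function(x, digits = 3L) {
  formatC(x, format = "f", digits = digits)
}
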