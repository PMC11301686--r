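## Seeded generators for every input kind the analysis modules
## consume, each returning its ground truth alongside, so the whole
## pipeline is testable without instrument data. Noise models are
## deliberately simple: Gaussian mass error, white absorbance noise,
## uniform decoy m/z.

#' Simulate a chromatogram of Gaussian peaks
#'
#' Sum of Gaussian peaks on a uniform time grid, with optional white
#' absorbance noise. The analytic area of each peak
#' (`height * width * sqrt(2 pi)`) is returned as ground truth.
#'
#' @param peaks `data.frame` with columns `center` (min), `width`
#'   (Gaussian sigma, min, > 0), `height` (mAU).
#' @param timeRange Numeric length-2, time window (min).
#' @param dt Sampling interval (min).
#' @param noiseSd White-noise standard deviation (mAU).
#' @param seed Integer seed fixing all randomness.
#' @return List: `chromatogram` ([Chromatogram-class]), `trueAreas`
#'   (numeric, per peak), `trueFractions` (normalised areas).
#' @examples
#' sim <- simChromatogram(data.frame(center = c(3, 7),
#'                                   width = 0.2, height = c(60, 40)))
#' sim$trueFractions
#' @export
simChromatogram <- function(peaks,
                            timeRange = c(0, max(peaks$center) +
                                            6 * max(peaks$width)),
                            dt = 0.005, noiseSd = 0, seed = 1L) {
  stopifnot(is.data.frame(peaks), nrow(peaks) >= 1L,
            all(c("center", "width", "height") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  set.seed(seed)
  tt <- seq(timeRange[1], timeRange[2], by = dt)
  a <- numeric(length(tt))
  for (i in seq_len(nrow(peaks)))
    a <- a + peaks$height[i] *
      exp(-(tt - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  if (noiseSd > 0) a <- a + stats::rnorm(length(tt), 0, noiseSd)
  areas <- peaks$height * peaks$width * sqrt(2 * pi)
  list(chromatogram = Chromatogram(tt, a),
       trueAreas = areas,
       trueFractions = areas / sum(areas))
}

#' Simulate a deconvoluted mass list with planted structure
#'
#' Plants glycan ladders (members at exact registered steps from a
#' base mass) and reduced/nonreduced disulfide pairs, then perturbs
#' every mass with Gaussian error of standard deviation `sigma`.
#'
#' @param ladders `data.frame` with columns `base` (Da) and `steps`
#'   (comma-separated step names, e.g. `"HexNAc,HexNAc"`), or `NULL`.
#' @param bridgePairs `data.frame` with columns `mass` (nonreduced,
#'   Da) and `n` (bridge count), or `NULL`.
#' @param extra Numeric vector of unrelated masses.
#' @param sigma Gaussian mass-error SD (Da).
#' @param mode `"mono"` or `"avg"`.
#' @param seed Integer seed.
#' @return List: `masses` ([DeconMassList-class], nonreduced entries),
#'   `reduced` ([DeconMassList-class] or `NULL`), `truth` (list with
#'   the planted `ladders` member masses and `bridgePairs`).
#' @examples
#' sim <- simMassList(ladders = data.frame(
#'   base = 10000, steps = "HexNAc,HexNAc,Hex"), sigma = 0.01)
#' detectLadders(sim$masses, tol = 0.05)
#' @export
simMassList <- function(ladders = NULL, bridgePairs = NULL,
                        extra = numeric(), sigma = 0,
                        mode = c("mono", "avg"), seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  gl <- glycanSteps()
  stepMass <- stats::setNames(
    if (mode == "mono") gl$mono else gl$avg, gl$name)
  k <- massConstants()
  ssStep <- if (mode == "mono") k[["ss_step_mono"]] else k[["ss_step_avg"]]
  nonred <- numeric(); truthLadders <- list()
  if (!is.null(ladders)) {
    stopifnot(all(ladders$base > 0))
    for (i in seq_len(nrow(ladders))) {
      nms <- trimws(strsplit(ladders$steps[i], ",")[[1]])
      if (any(!nms %in% names(stepMass)))
        stop("unregistered ladder step(s): ",
             paste(setdiff(nms, names(stepMass)), collapse = ", "))
      members <- ladders$base[i] + cumsum(c(0, stepMass[nms]))
      truthLadders[[i]] <- list(members = members, steps = nms)
      nonred <- c(nonred, members)
    }
  }
  red <- numeric()
  if (!is.null(bridgePairs)) {
    nonred <- c(nonred, bridgePairs$mass)
    red <- bridgePairs$mass + bridgePairs$n * ssStep
  }
  nonred <- c(nonred, extra)
  jitter <- function(x) if (sigma > 0 && length(x))
    x + stats::rnorm(length(x), 0, sigma) else x
  obsNon <- jitter(nonred)
  obsRed <- jitter(red)
  list(
    masses = if (length(obsNon))
      DeconMassList(obsNon, mode = mode, condition = "nonreduced")
      else NULL,
    reduced = if (length(obsRed))
      DeconMassList(obsRed, mode = mode, condition = "reduced")
      else NULL,
    truth = list(ladders = truthLadders, bridgePairs = bridgePairs))
}

#' Simulate a peptide MS/MS spectrum
#'
#' Full singly charged b/y fragment ladder of the peptide plus
#' uniform-random decoy peaks; the annotated true peaks are returned
#' as ground truth.
#'
#' @param p [Peptide-class] or display string.
#' @param decoys Number of uniform-random decoy peaks.
#' @param seed Integer seed.
#' @param mzRange Range for decoy m/z; default spans the true ladder.
#' @return List: `spectrum` (`data.frame` with columns `mz`,
#'   `intensity`), `truth` (`data.frame`: `ion`, `mz`).
#' @examples
#' simMsms("pEKW", decoys = 0)$spectrum
#' @export
simMsms <- function(p, decoys = 0L, seed = 1L, mzRange = NULL) {
  p <- .asPeptide(p)
  set.seed(seed)
  b <- fragmentLadder(p, "b")
  y <- fragmentLadder(p, "y")
  truth <- data.frame(ion = c(names(b), names(y)), mz = c(b, y),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  if (is.null(mzRange))
    mzRange <- c(max(50, min(truth$mz) - 50), max(truth$mz) + 50)
  decoyMz <- if (decoys > 0)
    stats::runif(decoys, mzRange[1], mzRange[2]) else numeric()
  spec <- data.frame(
    mz = c(truth$mz, decoyMz),
    intensity = c(stats::runif(nrow(truth), 0.5, 1),
                  stats::runif(length(decoyMz), 0.01, 0.3)))
  spec <- spec[order(spec$mz), , drop = FALSE]
  rownames(spec) <- NULL
  list(spectrum = spec, truth = truth)
}

#' Simulate a complete synthetic venom data set
#'
#' Draws a random venom layout -- fraction areas, one peptide
#' fraction, gel bands with densitometric shares, and top3 family
#' assignments -- renders it as a chromatogram plus band and
#' assignment tables, and returns the analytically derived true
#' composition. The default scale (7 fractions, up to 12 bands, 8
#' families) mirrors one typical viper venom proteome.
#'
#' @param seed Integer seed fixing the layout and all noise.
#' @param nFractions Number of HPLC fractions.
#' @param families Toxin families to draw from (defaults to the eight
#'   commonest).
#' @param noiseSd Chromatogram white-noise SD (mAU).
#' @return List: `chromatogram`, `boundaries` (`data.frame` `id`,
#'   `start`, `end`), `bands`, `assignments`,
#'   `peptide_fraction_ids`, `trueComposition`
#'   ([VenomComposition-class]).
#' @examples
#' sv <- simVenom(seed = 7)
#' compositionTable(sv$trueComposition)
#' @export
simVenom <- function(seed = 1L, nFractions = 7L,
                     families = c("svMP_PIII", "svSP", "PLA2", "CTL",
                                  "DI", "LAAO", "CRISP", "VEGF"),
                     noiseSd = 0) {
  set.seed(seed)
  stopifnot(nFractions >= 2L)
  w <- stats::rgamma(nFractions, shape = 2, rate = 1)
  frac <- w / sum(w)
  centers <- seq(10, 10 + 12 * (nFractions - 1), by = 12)
  width <- 0.6
  heights <- frac / (width * sqrt(2 * pi))   # unit total area
  bounds <- data.frame(id = paste0("F", seq_len(nFractions)),
                       start = centers - 6, end = centers + 6)
  pepId <- "F1"                      # early-eluting peptide fraction
  bands <- NULL; assignments <- NULL
  acc <- stats::setNames(numeric(length(toxinFamilies())),
                         toxinFamilies())
  acc["peptides"] <- frac[1]
  bandCounter <- 0L
  for (i in 2L:nFractions) {
    nb <- sample(1:2, 1)
    sh <- stats::rgamma(nb, 2, 1); sh <- sh / sum(sh)
    for (k in seq_len(nb)) {
      bandCounter <- bandCounter + 1L
      bid <- paste0("B", bandCounter)
      bands <- rbind(bands, data.frame(
        fraction = paste0("F", i), band = bid, share = sh[k],
        stringsAsFactors = FALSE))
      nf <- sample(1:2, 1)
      fams <- sample(families, nf)
      ints <- stats::runif(nf, 1e8, 5e9)
      assignments <- rbind(assignments, data.frame(
        band = bid, family = fams, top3 = ints,
        stringsAsFactors = FALSE))
      contrib <- frac[i] * sh[k] * ints / sum(ints)
      for (q in seq_len(nf))
        acc[fams[q]] <- acc[fams[q]] + contrib[q]
    }
  }
  # render last so the layout draws above are not disturbed by the
  # generator's own seeding
  sim <- simChromatogram(
    data.frame(center = centers, width = width, height = heights),
    timeRange = c(0, max(centers) + 6), dt = 0.01,
    noiseSd = noiseSd, seed = seed)
  list(chromatogram = sim$chromatogram, boundaries = bounds,
       bands = bands, assignments = assignments,
       peptide_fraction_ids = pepId,
       trueComposition = VenomComposition(100 * acc))
}
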