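## Three-evidence "snake venomics" relative quantification:
## RP-HPLC peak integrals (214 nm) -> densitometric band split ->
## top3 ion-intensity split -> toxin-family composition.
## Each stage is a partition of the previous one, so abundance is
## conserved from chromatogram to final composition.

#' Chromatogram trace
#'
#' @slot time numeric, strictly increasing retention times (min).
#' @slot absorbance numeric, absorbance at 214 nm (mAU), same length.
#' @export
setClass("Chromatogram",
  representation(time = "numeric", absorbance = "numeric"))

setValidity("Chromatogram", function(object) {
  msgs <- character()
  if (length(object@time) != length(object@absorbance))
    msgs <- c(msgs, "time and absorbance must have equal length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Chromatogram
#' @param time Retention times (min), strictly increasing.
#' @param absorbance Absorbance at 214 nm (mAU).
#' @return A [Chromatogram-class].
#' @export
Chromatogram <- function(time, absorbance) {
  methods::new("Chromatogram", time = as.numeric(time),
               absorbance = as.numeric(absorbance))
}

setMethod("show", "Chromatogram", function(object) {
  cat("Chromatogram: ", length(object@time), " points, ",
      formatMass(min(object@time), 2), "-",
      formatMass(max(object@time), 2), " min, max ",
      formatMass(max(object@absorbance), 1), " mAU\n", sep = "")
})

#' Integrate chromatogram fractions
#'
#' Trapezoidal integration of baseline-corrected absorbance over
#' user-supplied (valley-to-valley) fraction bounds, then
#' normalisation so the relative areas over all fractions sum to 1.
#'
#' @param chrom A [Chromatogram-class].
#' @param boundaries `data.frame` with columns `start`, `end`
#'   (minutes, `[start, end)`, non-overlapping, inside the time range)
#'   and optionally `id`.
#' @param baseline `"linear"` (default; straight line between the
#'   absorbances at the fraction bounds), `"none"`, or `"minimum"`
#'   (constant at the in-fraction minimum).
#' @return `data.frame`: `id`, `start`, `end`, `area` (mAU min),
#'   `fraction` (relative area, sums to 1).
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' a <- dnorm(t, 3, 0.3) + dnorm(t, 7, 0.3)
#' integrateFractions(Chromatogram(t, a),
#'                    data.frame(start = c(1, 5), end = c(5, 9)),
#'                    baseline = "none")
#' @export
integrateFractions <- function(chrom, boundaries,
                               baseline = c("linear", "none",
                                            "minimum")) {
  baseline <- match.arg(baseline)
  stopifnot(methods::is(chrom, "Chromatogram"),
            is.data.frame(boundaries),
            all(c("start", "end") %in% names(boundaries)))
  b <- boundaries[order(boundaries$start), , drop = FALSE]
  if (any(b$end <= b$start))
    stop("fraction bounds must satisfy start < end")
  if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)] - 1e-9))
    stop("fraction bounds must not overlap")
  tr <- range(chrom@time)
  if (any(b$start < tr[1] - 1e-9) || any(b$end > tr[2] + 1e-9))
    stop("fraction bounds outside the chromatogram time range")
  ids <- if ("id" %in% names(b)) as.character(b$id)
         else paste0("F", seq_len(nrow(b)))
  areas <- vapply(seq_len(nrow(b)), function(i) {
    inside <- chrom@time > b$start[i] & chrom@time < b$end[i]
    tt <- c(b$start[i], chrom@time[inside], b$end[i])
    aa <- stats::approx(chrom@time, chrom@absorbance, xout = tt)$y
    base <- switch(baseline,
      none = rep(0, length(tt)),
      linear = stats::approx(x = c(b$start[i], b$end[i]),
                             y = aa[c(1, length(aa))], xout = tt)$y,
      minimum = rep(min(aa), length(tt)))
    pracma::trapz(tt, aa - base)
  }, numeric(1))
  total <- sum(areas)
  if (total <= 0) stop("total integrated area is not positive")
  data.frame(id = ids, start = b$start, end = b$end, area = areas,
             fraction = areas / total, stringsAsFactors = FALSE)
}

#' Split a fraction's venom share across gel bands
#'
#' Densitometric partition: each band's venom fraction is the
#' chromatographic fraction area times the band's densitometric share.
#'
#' @param fraction Scalar venom fraction (0-1) of the HPLC fraction.
#' @param shares Numeric densitometric shares, must sum to 1 within
#'   1e-6.
#' @return Numeric vector of per-band venom fractions (sums to
#'   `fraction`).
#' @examples
#' bandSplit(0.5, c(0.7, 0.2, 0.1))
#' @export
bandSplit <- function(fraction, shares) {
  stopifnot(length(fraction) == 1L, fraction >= 0)
  if (abs(sum(shares) - 1) > 1e-6)
    stop("densitometric shares must sum to 1 (got ", sum(shares), ")")
  if (any(shares < 0)) stop("densitometric shares must be >= 0")
  fraction * shares
}

#' Split a band's venom share across protein families by top3 intensity
#'
#' Label-free partition: each family in a band receives the band's
#' venom fraction weighted by its top3 ion intensity relative to the
#' band total. Single-family bands pass through unchanged.
#'
#' @param band_fraction Scalar venom fraction (0-1) of the band.
#' @param assignment `data.frame` with columns `family` (from
#'   [toxinFamilies()]) and `top3` (>= 0 intensities).
#' @return Named numeric vector of per-family venom fractions.
#'   All-zero intensities raise a condition of class
#'   `venompep_degenerate_band`.
#' @examples
#' top3Split(0.30, data.frame(family = c("svSP", "PLA2"),
#'                            top3 = c(2e9, 1e9)))
#' @export
top3Split <- function(band_fraction, assignment) {
  stopifnot(is.data.frame(assignment),
            all(c("family", "top3") %in% names(assignment)),
            nrow(assignment) >= 1L)
  bad <- setdiff(assignment$family, toxinFamilies())
  if (length(bad))
    stop("unknown toxin famil(ies): ", paste(bad, collapse = ", "))
  if (any(assignment$top3 < 0)) stop("top3 intensities must be >= 0")
  total <- sum(assignment$top3)
  if (total == 0)
    stop(structure(class = c("venompep_degenerate_band", "error",
                             "condition"),
                   list(message = "all top3 intensities are zero",
                        call = sys.call())))
  stats::setNames(band_fraction * assignment$top3 / total,
                  assignment$family)
}

#' Toxin-family venom composition
#'
#' Percent of whole venom per toxin family, including the `peptides`
#' and `unknown` buckets; percentages are non-negative and sum to 100.
#'
#' @slot percent named numeric vector over [toxinFamilies()].
#' @export
setClass("VenomComposition", representation(percent = "numeric"))

setValidity("VenomComposition", function(object) {
  msgs <- character()
  if (is.null(names(object@percent)) ||
      !all(names(object@percent) %in% toxinFamilies()))
    msgs <- c(msgs, "percent must be named by toxinFamilies() entries")
  if (any(object@percent < -1e-9))
    msgs <- c(msgs, "percentages must be >= 0")
  if (abs(sum(object@percent) - 100) > 0.01)
    msgs <- c(msgs, paste0("percentages must sum to 100 (got ",
                           sum(object@percent), ")"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a VenomComposition from named percentages
#'
#' @param percent Named numeric vector (percent of whole venom) over
#'   [toxinFamilies()] names; missing families are filled with 0.
#' @return A [VenomComposition-class].
#' @examples
#' VenomComposition(c(svSP = 46, PLA2 = 18, peptides = 16,
#'                    unknown = 20))
#' @export
VenomComposition <- function(percent) {
  full <- stats::setNames(numeric(length(toxinFamilies())),
                          toxinFamilies())
  full[names(percent)] <- percent
  methods::new("VenomComposition", percent = full)
}

setMethod("show", "VenomComposition", function(object) {
  tab <- compositionTable(object)
  tab <- tab[tab$percent > 0, , drop = FALSE]
  cat("VenomComposition (% of whole venom):\n")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-10s %5.1f\n", tab$family[i], tab$percent[i]))
})

#' Composition as a table
#'
#' Families sorted by abundance, then the `peptides` and `unknown`
#' buckets last (the conventional display order). Percent display
#' rounds to one decimal; the stored values keep full precision.
#'
#' @param vc A [VenomComposition-class].
#' @return `data.frame` with columns `family`, `percent`.
#' @export
compositionTable <- function(vc) {
  stopifnot(methods::is(vc, "VenomComposition"))
  p <- vc@percent
  tox <- setdiff(names(p), c("peptides", "unknown"))
  tox <- tox[order(p[tox], decreasing = TRUE)]
  data.frame(family = c(tox, "peptides", "unknown"),
             percent = unname(p[c(tox, "peptides", "unknown")]),
             stringsAsFactors = FALSE)
}

#' Total svMP umbrella abundance
#'
#' svMP are conventionally reported both by subclass and as an
#' umbrella including the disintegrin-like/cysteine-rich (DC) proteins
#' derived from P-III precursors.
#'
#' @param vc A [VenomComposition-class].
#' @return Scalar percent: svMP_PI + svMP_PIII + DC.
#' @export
svMPUmbrella <- function(vc) {
  stopifnot(methods::is(vc, "VenomComposition"))
  unname(sum(vc@percent[c("svMP_PI", "svMP_PIII", "DC")]))
}

#' Compose a venom from fractions, bands and family assignments
#'
#' The full three-evidence partition: every HPLC fraction is either
#' flagged as a peptide fraction (summed into `peptides`), carries gel
#' bands whose densitometric shares split it and whose top3
#' assignments split each band across families, or is unassigned
#' (summed into `unknown`). Bands whose intensities are all zero are
#' routed to `unknown` with a warning.
#'
#' @param fractions Output of [integrateFractions()] (columns `id`,
#'   `fraction`), or a named numeric vector of relative areas summing
#'   to 1.
#' @param bands `data.frame` with columns `fraction` (fraction id),
#'   `band` (band id) and `share` (densitometric share; shares within
#'   a fraction must sum to 1 within 1e-6). May be `NULL`.
#' @param assignments `data.frame` with columns `band`, `family`,
#'   `top3`. May be `NULL`.
#' @param peptide_fraction_ids Character ids of fractions that are
#'   peptide material (no gel band; quantified directly).
#' @return A [VenomComposition-class].
#' @examples
#' composeVenom(c(F1 = 0.6, F2 = 0.4), bands = NULL,
#'              assignments = NULL, peptide_fraction_ids = "F2")
#' @export
composeVenom <- function(fractions, bands = NULL, assignments = NULL,
                         peptide_fraction_ids = character()) {
  if (is.data.frame(fractions)) {
    fr <- stats::setNames(fractions$fraction, fractions$id)
  } else fr <- fractions
  if (abs(sum(fr) - 1) > 1e-6)
    stop("fraction areas must sum to 1")
  acc <- stats::setNames(numeric(length(toxinFamilies())),
                         toxinFamilies())
  withBands <- if (is.null(bands)) character() else
    unique(as.character(bands$fraction))
  dup <- intersect(withBands, peptide_fraction_ids)
  if (length(dup))
    stop("fraction(s) both flagged peptide and carrying bands: ",
         paste(dup, collapse = ", "))
  for (id in names(fr)) {
    f <- fr[[id]]
    if (id %in% peptide_fraction_ids) {
      acc["peptides"] <- acc["peptides"] + f
    } else if (id %in% withBands) {
      bb <- bands[as.character(bands$fraction) == id, , drop = FALSE]
      bf <- bandSplit(f, bb$share)
      for (k in seq_len(nrow(bb))) {
        bid <- as.character(bb$band[k])
        asg <- if (is.null(assignments)) NULL else
          assignments[as.character(assignments$band) == bid, ,
                      drop = FALSE]
        if (is.null(asg) || nrow(asg) == 0L) {
          acc["unknown"] <- acc["unknown"] + bf[k]
          next
        }
        split <- tryCatch(top3Split(bf[k], asg),
          venompep_degenerate_band = function(e) {
            warning("band '", bid,
                    "' has zero total top3 intensity; routed to unknown",
                    call. = FALSE)
            c(unknown = bf[k])
          })
        for (famNm in names(split))
          acc[famNm] <- acc[famNm] + split[[famNm]]
      }
    } else {
      acc["unknown"] <- acc["unknown"] + f
    }
  }
  VenomComposition(100 * acc)
}

#' Plot a venom composition
#'
#' Pie (families clockwise by abundance, then peptides in gray and
#' unknown in black) or horizontal bar chart.
#'
#' @param vc A [VenomComposition-class].
#' @param type `"pie"` or `"bar"`.
#' @param main Plot title.
#' @return Invisibly, the displayed table.
#' @export
plotComposition <- function(vc, type = c("pie", "bar"), main = "") {
  type <- match.arg(type)
  tab <- compositionTable(vc)
  tab <- tab[tab$percent > 0, , drop = FALSE]
  cols <- grDevices::hcl.colors(max(1, nrow(tab)), "Spectral")
  cols[tab$family == "peptides"] <- "gray"
  cols[tab$family == "unknown"] <- "black"
  lab <- sprintf("%s (%.1f%%)", tab$family, tab$percent)
  if (type == "pie") {
    graphics::pie(tab$percent, labels = lab, col = cols,
                  clockwise = TRUE, main = main)
  } else {
    graphics::barplot(rev(tab$percent), names.arg = rev(tab$family),
                      horiz = TRUE, col = rev(cols), las = 1,
                      xlab = "% of whole venom", main = main)
  }
  invisible(tab)
}
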