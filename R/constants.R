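## Physical constants and registries shared across the package.
## Monoisotopic values follow standard element masses; the proton mass
## is fixed at 1.00728 Da, consistent with the printed ion arithmetic
## of the peptide tables this package reproduces.

#' Physical constants used in all mass equations
#'
#' @description Named numeric vector of the constants behind every mass
#'   computation: the proton mass added per charge, the mass of water
#'   completing a peptide backbone, and the per-bridge mass step used in
#'   disulfide counting (two hydrogens gained on reduction).
#'
#' @return Named numeric vector with elements `proton`, `water_mono`,
#'   `water_avg`, `ss_step_mono`, `ss_step_avg` (all Da).
#' @examples
#' massConstants()["proton"]
#' @export
massConstants <- function() {
  c(proton      = 1.00728,
    water_mono  = 18.010565,
    water_avg   = 18.0153,
    ss_step_mono = 2.015650,   # 2 x 1.007825
    ss_step_avg  = 2.015880)
}

## Residue table: 20 standard residues plus pyroglutamate "pE".
## pE (C5H5NO2) is modeled as a first-position residue, not a delta:
## the cyclized mass is identical whether formed from Gln (-NH3) or
## Glu (-H2O), matching the agnostic "pE" notation of venom peptidomics.
.RESIDUES <- data.frame(
  code    = c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E",
              "M","H","F","R","Y","W","pE"),
  formula = c("C2H3NO","C3H5NO","C3H5NO2","C5H7NO","C5H9NO","C4H7NO2",
              "C3H5NOS","C6H11NO","C6H11NO","C4H6N2O2","C4H5NO3",
              "C5H8N2O2","C6H12N2O","C5H7NO3","C5H9NOS","C6H7N3O",
              "C9H9NO","C6H12N4O","C9H9NO2","C11H10N2O","C5H5NO2"),
  mono = c(57.02146, 71.03711, 87.03203, 97.05276, 99.06841, 101.04768,
           103.00918, 113.08406, 113.08406, 114.04293, 115.02694,
           128.05858, 128.09496, 129.04259, 131.04048, 137.05891,
           147.06841, 156.10111, 163.06333, 186.07931, 111.03203),
  avg  = c(57.0514, 71.0780, 87.0774, 97.1154, 99.1313, 101.1040,
           103.1428, 113.1579, 113.1579, 114.1028, 115.0876, 128.1294,
           128.1725, 129.1142, 131.1960, 137.1395, 147.1742, 156.1859,
           163.1736, 186.2103, 111.0989),
  stringsAsFactors = FALSE
)

#' Residue mass table
#'
#' The 20 standard amino acid residues plus the pyroglutamate residue
#' `pE` (C5H5NO2, mono 111.03203 Da), which caps the N-terminus of most
#' viper venom BPP and svMP-inhibitor peptides. Leu and Ile are kept as
#' distinct codes with identical (isobaric) mass.
#'
#' @return `data.frame` with columns `code`, `formula`, `mono`, `avg`.
#' @examples
#' residueMasses()[residueMasses()$code == "pE", ]
#' @export
residueMasses <- function() .RESIDUES

## Modification registry. Deltas in Da; `targets` lists residue codes
## (or "Nterm"/"Cterm") the modification may sit on.
.MODS <- data.frame(
  name = c("ox", "diox", "CAM", "hydration"),
  mono = c(15.994915, 31.989830, 57.021464, 18.010565),
  avg  = c(15.9994,   31.9988,   57.0513,   18.0153),
  targets = c("W,M,H,C", "W", "C", "Cterm"),
  stringsAsFactors = FALSE
)

#' Modification registry
#'
#' Registered post-translational modification deltas: oxidation (`ox`,
#' +15.9949, Trp/Met among others), dioxidation (`diox`, +31.9898),
#' carbamidomethylation (`CAM`, +57.02146, protected Cys from tryptic
#' digests) and hydration (+18.0106).
#'
#' @return `data.frame` with columns `name`, `mono`, `avg`, `targets`.
#' @examples
#' modificationRegistry()
#' @export
modificationRegistry <- function() .MODS

#' Glycan step registry
#'
#' Monosaccharide residue masses observed as consecutive steps in
#' intact-mass glycoform ladders of venom glycoproteins (notably the
#' heavily N-glycosylated serine proteases): HexNAc (N-acetylhexosamine),
#' Hex (hexose) and NeuAc (N-acetylneuraminic acid).
#'
#' @return `data.frame` with columns `name`, `mono`, `avg`, `symbol`.
#' @examples
#' glycanSteps()
#' @export
glycanSteps <- function() {
  data.frame(
    name   = c("HexNAc", "Hex", "NeuAc"),
    mono   = c(203.079373, 162.052824, 291.095417),
    avg    = c(203.1928, 162.1408, 291.2550),
    symbol = c("filled square", "circle", "filled rhombus"),
    stringsAsFactors = FALSE
  )
}

#' Small-shift delta registry
#'
#' Named neutral mass deltas used when relating proteoform masses:
#' single oxygen (O), carbon monoxide (CO), water (H2O), plus the
#' glycan steps. Exact masses are stored; observed shifts printed at
#' two decimals match through the tolerance, with the discrepancy
#' surfaced in the residual.
#'
#' @return Named numeric vector (mono Da) by default, or with
#'   `mode = "avg"` the average-mass analogues.
#' @param mode `"mono"` or `"avg"`.
#' @examples
#' shiftDeltas()
#' @export
shiftDeltas <- function(mode = c("mono", "avg")) {
  mode <- match.arg(mode)
  gl <- glycanSteps()
  if (mode == "mono") {
    c(O = 15.994915, CO = 27.994915, H2O = 18.010565,
      stats::setNames(gl$mono, gl$name))
  } else {
    c(O = 15.9994, CO = 28.0101, H2O = 18.0153,
      stats::setNames(gl$avg, gl$name))
  }
}

#' Controlled toxin-family vocabulary
#'
#' The family labels a viper venom composition is partitioned into:
#' metalloproteinase subclasses (svMP_PI, svMP_PIII) and their
#' disintegrin-like/cysteine-rich derivatives (DC), phospholipases A2
#' (PLA2), serine proteases (svSP), C-type lectins (CTL), disintegrins
#' (DI), L-amino acid oxidases (LAAO), CRISP, VEGF, Kunitz inhibitors
#' (KUN), NGF, phosphodiesterases (PDE), 5'-nucleotidases (5N),
#' natriuretic peptides (NP), plus the `peptides` and `unknown` buckets.
#'
#' @return Character vector of valid family names.
#' @examples
#' toxinFamilies()
#' @export
toxinFamilies <- function() {
  c("svMP_PI", "svMP_PIII", "DC", "PLA2", "svSP", "CTL", "DI", "LAAO",
    "CRISP", "VEGF", "KUN", "NGF", "PDE", "5N", "NP",
    "peptides", "unknown")
}

#' Default matching tolerances
#'
#' @return Named numeric vector: `ppm_mono` (ppm, peptide-level
#'   monoisotopic data), `da_mono` (Da, monoisotopic intact masses),
#'   `da_avg` (Da, deconvoluted average masses).
#' @examples
#' defaultTolerances()
#' @export
defaultTolerances <- function() {
  c(ppm_mono = 10, da_mono = 0.05, da_avg = 0.5)
}
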