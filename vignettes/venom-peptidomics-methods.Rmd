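---
title: "Methods: venom peptide masses, the BPP grammar, proteoform inference and venomics quantification"
author: "venompep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: venom peptide masses, the BPP grammar, proteoform inference and venomics quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venompep)
```

## Scope

Viper venoms are dominated by a handful of toxin protein families
(metalloproteinases, phospholipases A2, serine proteases, C-type
lectins, disintegrins, and several minor families) plus an abundant
peptide fraction of pyroglutamate-initiated bradykinin-potentiating
peptides (BPP), tripeptidic svMP inhibitors and natriuretic peptides.
`venompep` implements the desk-scale computational layer of a
clade-wide venomics study of such venoms: exact mass bookkeeping for
the peptides and their ions, a formal grammar for the BPP family,
proteoform inference from deconvoluted intact-mass lists, and the
three-evidence relative quantification that turns chromatograms, gel
densitometry and MS intensities into a venom composition. It does
*not* do database search, raw-spectrum deconvolution, or gel image
processing — those belong to dedicated search engines and imaging
tools; this package starts from their tabular outputs.

## Mass model

All masses are computed from a residue table of the 20 standard amino
acids plus pyroglutamate (`pE`, C5H5NO2, monoisotopic 111.03203 Da).
`pE` is modelled as a first-position *residue*, not a modification
delta: the cyclized mass is the same whether it formed from Gln (loss
of NH3) or Glu (loss of H2O), so the residue model stays agnostic
about the precursor, exactly as the `pE` notation itself is. Constants
are fixed at proton 1.00728 Da and water 18.010565 Da (mono) /
18.0153 Da (average); a neutral peptide is the residue sum plus
modification deltas plus one water, and ions follow
$m/z = (nM + z \cdot 1.00728)/z$ for an $n$-mer at charge $z$.

```{r}
mz(neutralMass("pEKW"), 1)          # [M+H]+ of the svMP-i core
multimerIonMz("pEKW", n = 2)        # its abundant 2M+H dimer ion
```

Fragment ladders use the singly-charged b/y convention:
$b_i = \sum_{1..i} r + z \cdot 1.00728$,
$y_i = \sum_{n-i+1..n} r + \mathrm{H_2O} + z \cdot 1.00728$, which
gives the complementarity $b_i + y_{n-i} = M + 2 \cdot 1.00728$ used
as a standing test invariant. Modifications (`_ox_` +15.9949,
`_diox_` +31.9898, `_CAM_` +57.02146, hydration +18.0106) travel with
their position, so only fragments containing the modified residue
shift. Leu/Ile are distinct codes with identical mass; reports flag
their positions as isobaric rather than guessing.

Display strings round to three decimals (table convention); all
comparisons run at full precision. Default match tolerances are
10 ppm for peptide-level monoisotopic data and 0.5 Da for
deconvoluted average intact masses, both overridable per call.

## The BPP consensus grammar

Full-length BPP of Palearctic vipers follow the modular pattern

```
pE X W (P Z){1,2} P (EI | KV) P P L E
```

with X mainly K/N/R, Z in {G, S, V}, and C-terminal truncation down
to the tripeptide core `pEXW`. `parseBpp()` matches a sequence as a
prefix of an enumerated full-length template; `enumerateBpp()` is the
inverse, and the two are tested against each other (every enumerated
member must parse back with consistent truncation).

Design choices where the pattern itself is silent:

* **Anchors.** Position 1 (`pE`) and position 3 (`W`) must match
  exactly in every mode. This keeps `pEKY`, `pERRPPEIPP` and the
  poly-Gly peptide outside the grammar, consistent with their listing
  apart from the three family sections.
* **Position 2 is open.** Any residue is accepted at X; residues
  outside K/N/R are classified `family = "other"` and flagged rare,
  so exclusives like `pEMWPGPKVPP` still parse without diluting the
  three-family classification.
* **Lenient deviations.** Strict mode tolerates no mismatch. Lenient
  mode tolerates one *contiguous block of at most two* mismatched
  non-anchor positions, every mismatch recorded in the parse. A
  single-substitution allowance would reject `pEKWLDPEIPP`, whose two
  adjacent deviations (L4, D5) clearly belong to one local edit; the
  block rule admits exactly that kind of variant while still
  rejecting scattered double substitutions.
* **Truncation is reported against the shortest consistent
  template.** A heavily truncated peptide such as `pEKW` is a prefix
  of both repeat-1 and repeat-2 templates; reporting against the
  shortest keeps `truncation + length = template length` well defined
  and minimal.

Substitution naming against natriuretic-peptide references
(`nameSubstitutions()`) uses 1-based reference numbering for its
canonical labels (`K3E` against lebetin 1β `DNKPPKKGPPNG`). Because a
second numbering convention that starts at the second residue also
circulates for these fragments, the alternative label (`K2E`) is
emitted alongside, explicitly tagged; terminal extensions and
truncations are reported separately and never counted as
substitutions.

## Intact-mass proteoform inference

Inputs are already-deconvoluted neutral mass lists (z = 1), average
or monoisotopic, from nonreduced or reduced runs.

* **Glycoform ladders.** `detectLadders()` links masses whose
  pairwise gap equals one registered step (HexNAc 203.0794, Hex
  162.0528, NeuAc 291.0954 Da mono; average analogues alongside)
  within tolerance. Each mass links to its best-residual single-step
  successor; maximal chains of ≥ 2 members are reported, ranked by
  summed intensity. Intensity plays no role during chain building —
  the data give no principled intensity rule — only in ranking.
  Assignment prefers one step over composites (fewest steps first),
  so a 406.16 Da gap with no intermediate member is *not* called
  2×HexNAc.
* **Small shifts.** `relateMasses()` labels lighter-to-heavier pairs
  with the best-fitting registered delta (O 15.9949, CO 27.9949, H2O
  18.0106, glycan steps, or custom). The registry stores exact
  masses; a shift printed as Δ27.97 still matches CO at average-mode
  tolerance, with the discrepancy visible in the residual rather than
  hidden.
* **Disulfide counting.** Reducing one bridge adds two hydrogens
  (2.01565 Da mono, 2.01588 average). `countDisulfides()` rounds the
  reduced-minus-nonreduced shift to the nearest multiple and accepts
  when the residual is within tolerance; `pairConditions()` applies
  the same rule across whole condition lists, keeping and flagging
  one-to-many candidates instead of silently picking one.

```{r}
countDisulfides(6414.61, 6424.68, tol = 0.1)  # CRISP fragment pair
```

Default tolerances are 0.05 Da (mono) and 0.5 Da (average, matching
two-decimal deconvoluted mass reporting).

## Three-evidence quantification

`integrateFractions()` → `bandSplit()` → `top3Split()` →
`composeVenom()` implement the standard three-step "snake venomics"
partition: relative HPLC peak area (214 nm) × densitometric band
share × top3 ion-intensity share. Each stage is a partition of the
previous, so abundance is conserved end to end; compositions are
invariant under absorbance scaling and fraction reordering, and both
properties are tested. Fractions flagged as peptide material bypass
the gel and sum into `peptides`; unassigned material sums into
`unknown`; a band whose intensities are all zero is routed to
`unknown` with a warning rather than dropped. DC proteins are kept as
their own family and also available inside the svMP umbrella via
`svMPUmbrella()`, mirroring the field's dual reporting.

Numerical choices: trapezoidal integration with user-supplied
valley-to-valley bounds; baseline either `none`, a straight line
between the boundary absorbances (default), or a constant in-fraction
minimum. Exact peak-boundary and baseline conventions differ between
laboratories; these defaults are declared, not inferred, and every
alternative is selectable. Percentages are summed before any display
rounding (one decimal for display; full precision stored).

## Synthetic data and what passing tests mean

`simChromatogram()`, `simMassList()`, `simMsms()` and `simVenom()`
generate every input kind with the ground truth returned alongside,
under a single integer seed (same seed, byte-identical output). Noise
models are deliberately minimal — Gaussian mass error, white
absorbance noise, uniform decoy m/z — chosen for controllability, not
instrument realism. They do not emulate isotope envelopes,
deconvolution artifacts, chemical baselines, detector saturation or
co-elution, so recovery results on synthetic data bound what the
algorithms can do under their own assumptions; they are not evidence
about any particular instrument's output.

Default scales, chosen once to mirror one typical venom proteome at
desk scale: 7 fractions, up to two gel bands per fraction and two
families per band from an eight-family draw; planted ladders of 3–5
members in the 8–40 kDa range. Detection recall is evaluated at mass
noise σ = tol/3 over 200 seeded replicates, with recall counted at
the *member* level (a planted ladder member is recalled when it
appears in a reported ladder): with σ = tol/3 the gap between two
independently perturbed members exceeds the tolerance in a few
percent of cases, so demanding every gap of every ladder survive
would measure the noise model, not the detector — member-level recall
is the quantity the chain detector can and should hold above 0.95.
Bridge-count recall is the fraction of replicates whose planted count
is returned exactly. The composition round trip (synthetic venom →
chromatogram + tables → pipeline → composition) is required to agree
with the planted truth within 0.5 percentage points per family; with
well-separated Gaussian peaks and a 0.01 min grid the integration
error is orders of magnitude below that, so the bound mainly guards
the partition arithmetic.

## Command line

The same operations are scriptable through `venompepCLI()` /
`inst/scripts/venompep` (`pepmass`, `fragment`, `motif`,
`motif-enumerate`, `np-compare`, `ladders`, `disulfides`, `quantify`,
`simulate`, `validate-table`). Results go to standard output or
declared files, diagnostics to standard error, exit status 0/1/2, so
the commands compose in shell pipelines.

## Known limitations

* Only b/y fragment series; no a/c/x/z ions and no neutral losses
  beyond the registered modification set.
* Ladder and disulfide inference report counts and chains only — no
  glycosite localisation, no disulfide connectivity.
* The BPP grammar classifies sequences; it makes no claim about
  physiological activity, and precursor-gene reconstruction is out of
  scope.
* Peptide tables, mass lists and chromatograms are consumed as
  text tables; raw mzML/MGF ingestion is not part of this layer.
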