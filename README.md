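# venompep

Desk-scale computational tools for viper venom peptidomics and
venomics quantification.

Viper venoms combine a dozen toxin protein families with an abundant
peptide fraction of pyroglutamate-initiated bradykinin-potentiating
peptides (BPP), tripeptidic snake-venom-metalloproteinase inhibitors
(svMP-i: pEKW, pENW, pERW) and natriuretic peptides. `venompep` is for
venomics/peptidomics practitioners who have instrument-level outputs —
annotated peptide tables, deconvoluted intact-mass lists, HPLC traces,
gel densitometry, top3 intensities — and need the exact arithmetic and
bookkeeping that turns them into results:

* **Mass layer** — monoisotopic/average masses of modified peptides
  with an N-terminal pyroglutamate residue (`pE`, C5H5NO2,
  111.03203 Da), their charge states, noncovalent multimer ions
  (`(nM + z·1.00728)/z`) and b/y fragment ladders, plus tolerance-aware
  observed-vs-theoretical matching.
* **BPP grammar** — the modular consensus
  `pE X W (P Z){1,2} P (EI|KV) P P L E` (X mainly K/N/R, Z ∈ {G,S,V},
  C-terminal truncation down to the pEXW core) as a parser +
  enumerator pair, with K/N/R family classification and substitution
  naming against natriuretic-peptide references.
* **Intact-mass profiler** — glycoform ladder detection (HexNAc
  203.08, Hex 162.05, NeuAc 291.10 Da steps), named small-shift
  relations (O, CO, H2O), and disulfide-bridge counting from
  reduced/nonreduced pairs (2.01565 Da per bridge).
* **Snake-venomics quantification** — the three-evidence partition
  (HPLC peak integral × densitometric band share × top3 intensity
  share) into a toxin-family composition summing to 100 %.
* **Synthetic data** — seeded generators for every input kind with
  ground truth returned alongside, so the full pipeline is testable
  without instrument files.

## Worked example

```r
library(venompep)

parsePeptide("pEKW_ox_")
#> Peptide: pEKW_ox_
#>   length: 3  [M+H]+ mono: 460.219
```

The oxidised svMP-i core weighs 460.219 as [M+H]+ — the unmodified
peptide (444.224) plus one oxygen. Its parse against the BPP grammar,
and that of a longer family member:

```r
parseBpp("pEKWPVPGPEIPP")
#> BppParse: matched, family K
#>   template: pEKWPVPGPEIPPLE  truncation: 2 residue(s)
#>   repeat: 2  Z: V,G  branch: EI
```

a Lys-family BPP with two (P,Z) repeats, the EI branch, and two
residues (LE) truncated from the full-length template.

Counting disulfide bridges of a CRISP fragment from its nonreduced
(6414.61 Da) and reduced (6424.68 Da) monoisotopic masses:

```r
countDisulfides(6414.61, 6424.68, tol = 0.1)
#> DisulfideEstimate: 5 bridge(s), delta 10.070 Da, residual -0.008 Da
```

The 10.07 Da shift is five times the two-hydrogen step — five bridges
through all ten cysteines, with 8 mDa left over.

A glycoform ladder in an average-mass serine-protease cluster:

```r
detectLadders(c(30327.40, 30530.48, 30733.56, 30895.61),
              tol = 0.5, mode = "avg")
#> LadderHit: base 30327.40 Da + HexNAc + HexNAc + Hex
#>   (4 members, max |residual| 0.113 Da)
```

And the full quantification round trip on a synthetic venom:

```r
sv <- simVenom(seed = 7)
fr <- integrateFractions(sv$chromatogram, sv$boundaries,
                         baseline = "none")
composeVenom(fr, sv$bands, sv$assignments, sv$peptide_fraction_ids)
#> VenomComposition (% of whole venom):
#>   PLA2        22.5
#>   LAAO        16.4
#>   VEGF        11.4
#>   CTL          8.1
#>   DI           7.9
#>   CRISP        2.2
#>   svSP         1.4
#>   peptides    30.0
```

which recovers the generator's planted composition to machine
precision here, and within 0.5 percentage points per family under the
test suite's noisy conditions.

A small transcribed peptidomics table ships under
`inst/extdata/viper_peptidomics_table.tsv`; `readPeptideTable()`
recomputes every stored [M+H]+ from its sequence and flags rows that
disagree by more than 0.005 Da.

The same operations are available from the shell via
`inst/scripts/venompep` (`pepmass`, `fragment`, `motif`, `ladders`,
`disulfides`, `quantify`, `simulate`, ...).

## Documentation

The methods vignette
(`vignettes/venom-peptidomics-methods.Rmd`) documents the mass model
and its constants, the grammar's anchor and leniency rules, the
ladder/disulfide inference choices, the quantification partition and
its invariants, and what the synthetic-data noise models do and do
not emulate.
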