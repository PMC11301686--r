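test_that("display-string parsing round-trips and rejects bad tokens", {
  for (s in c("pEKW", "pEKW_ox_", "pERW_diox_PGPKVPP",
              "IGSVSGLGC_CAM_NK", "pEKWPM_ox_PGPEIPP")) {
    expect_identical(renderPeptide(parsePeptide(s)), s)
  }
  # whitespace tolerance and lenient aliases normalise to the dialect
  expect_identical(renderPeptide(parsePeptide("pE KW (ox)")), "pEKW_ox_")
  expect_identical(renderPeptide(parsePeptide("pGluKW")), "pEKW")
  expect_error(parsePeptide("pEKZ"), "unknown residue")
  expect_error(parsePeptide("pEK1W"), "cannot parse token '1'")
  expect_error(parsePeptide(""), "empty")
  # modification target checking
  expect_error(parsePeptide("pEG_CAM_W"), "not allowed")
})

test_that("neutral masses match frozen and oracle values", {
  expect_equal(neutralMass("pEKW"), 443.217, tolerance = 1e-3)
  expect_equal(mz(neutralMass("pEKW"), 1), 444.224, tolerance = 5e-4)
  expect_equal(neutralMass("G"), 75.032, tolerance = 1e-3)
  # oracle: independent elemental-composition adder
  expect_equal(neutralMass("pENWPGPK"),
               oracle_peptide_mass(c("pE", "N", "W", "P", "G", "P",
                                     "K")),
               tolerance = 1e-4)
  expect_equal(neutralMass("pENWPGPK"), 808.387, tolerance = 1e-3)
  # modified peptide: CAM adds the full carbamidomethyl delta
  expect_equal(neutralMass("IGSVSGLGC_CAM_NK"),
               oracle_peptide_mass(
                 c("I","G","S","V","S","G","L","G","C","N","K"),
                 mod_delta = oracle_formula_mass("C2H3N1O1")),
               tolerance = 1e-4)
  # avg mass exceeds mono for every residue
  tab <- residueMasses()
  expect_true(all(tab$avg > tab$mono))
  expect_true(all(tab$mono > 0))
})

test_that("neutral mass is additive under concatenation", {
  set.seed(42)
  water <- massConstants()[["water_mono"]]
  for (i in 1:25) {
    a <- random_peptides(1, with_pE = FALSE)
    b <- random_peptides(1, with_pE = FALSE)
    expect_equal(neutralMass(paste0(a, b)),
                 neutralMass(a) + neutralMass(b) - water,
                 tolerance = 1e-9)
  }
})

test_that("mz arithmetic: proton identity, monotonicity, domain", {
  expect_equal(mz(1000, 1) - 1000, 1.00728, tolerance = 1e-12)
  expect_equal(mz(1131.571, 2), 566.793, tolerance = 5e-4)
  expect_equal(mz(1326.697, 2), (1326.697 + 2 * 1.00728) / 2)
  M <- 2500.123
  zz <- vapply(1:6, function(z) mz(M, z), numeric(1))
  expect_true(all(diff(zz) < 0))
  expect_error(mz(1000, 0), "positive integer")
})

test_that("multimer ions reproduce dimer values and the n=1 identity", {
  expect_equal(multimerIonMz("pEKW", n = 2, z = 1), 887.441,
               tolerance = 5e-4)
  expect_equal(multimerIonMz("pENW", n = 2, z = 1), 859.337,
               tolerance = 5e-4)
  expect_equal(multimerIonMz("pENWPSPKVPP", n = 1, z = 1),
               mz(neutralMass("pENWPSPKVPP"), 1))
  expect_error(multimerIonMz("pEKW", n = 0), "n must be")
})

test_that("b/y ladders match manual sums and are complementary", {
  b <- fragmentLadder("pEKW", "b")
  y <- fragmentLadder("pEKW", "y")
  expect_equal(unname(b), c(112.039, 240.134), tolerance = 1e-3)
  expect_equal(unname(y), c(205.097, 333.192), tolerance = 1e-3)
  expect_named(b, c("b1", "b2"))
  # single residue: no cleavable bond
  expect_length(fragmentLadder("G", "b"), 0)
  expect_error(fragmentLadder("", "b"))
  # complementarity b_i + y_(n-i) = M + 2 * proton, with mods carried
  set.seed(7)
  for (s in c("pEKWPVPGPEIPP", "pERW_ox_PGPKVPP",
              random_peptides(5))) {
    p <- parsePeptide(s)
    n <- length(p)
    if (n < 2) next
    b <- fragmentLadder(p, "b"); y <- fragmentLadder(p, "y")
    M <- neutralMass(p)
    for (i in seq_len(n - 1))
      expect_equal(b[[i]] + y[[n - i]], M + 2 * 1.00728,
                   tolerance = 1e-9)
  }
})

test_that("modifications shift only the fragments that contain them", {
  b0 <- fragmentLadder("pEKWPSPK", "b")
  b1 <- fragmentLadder("pEKW_ox_PSPK", "b")
  d <- b1 - b0
  expect_equal(unname(d[1:2]), c(0, 0))
  expect_equal(unname(d[3:6]), rep(15.994915, 4), tolerance = 1e-6)
})

test_that("observed/theoretical matching is greedy and one-to-one", {
  r <- matchObserved(444.2240, 444.2241, tol = 10)
  expect_equal(nrow(r$matches), 1)
  r <- matchObserved(444.30, 444.2241, tol = 10)
  expect_equal(nrow(r$matches), 0)
  expect_equal(r$unmatched_observed, 444.30)
  # self-consistency: a ladder against itself matches fully at 0 ppm
  lad <- c(fragmentLadder("pEKW", "b"), fragmentLadder("pEKW", "y"))
  r <- matchObserved(unname(lad), unname(lad), tol = 10)
  expect_equal(nrow(r$matches), length(lad))
  expect_true(all(abs(r$matches$error_ppm) < 1e-9))
  # each theoretical peak used at most once
  r <- matchObserved(c(500.000, 500.001), 500.0005, tol = 10,
                     unit = "Da")
  expect_equal(nrow(r$matches), 1)
  expect_length(r$unmatched_observed, 1)
  expect_error(matchObserved(1, 1, tol = 0), "positive")
  # empty inputs give an empty report, not an error
  r <- matchObserved(numeric(), numeric(), tol = 10)
  expect_equal(nrow(r$matches), 0)
})

test_that("stored table ion masses are regenerated from sequences", {
  tab <- readPeptideTable(system.file("extdata",
                                      "viper_peptidomics_table.tsv",
                                      package = "venompep"))
  expect_gt(nrow(tab), 30)
  expect_true(all(tab$massOk))
  # doubly charged column, where present, within 0.005 Da
  has2 <- !is.na(tab$z2_mz)
  z2 <- vapply(tab$sequence[has2],
               function(s) mz(neutralMass(s), 2), numeric(1))
  expect_true(all(abs(z2 - tab$z2_mz[has2]) <= 0.005))
})

test_that("a fragment spectrum is de novo sequenced up to I/L", {
  # exhaustive residue search on consecutive b-ion gaps (the stated
  # small-scale annotation route), on peptides of <= 8 residues
  tab <- residueMasses()
  denovo <- function(p) {
    b <- fragmentLadder(p, "b")
    M <- neutralMass(p)
    last <- M - massConstants()[["water_mono"]] +
      1.00728 - b[length(b)]
    deltas <- c(b[1] - 1.00728, diff(b), last)
    unname(vapply(deltas, function(d) {
      hit <- tab$code[abs(tab$mono - d) < 1e-3]
      paste(sort(hit), collapse = "/")
    }, character(1)))
  }
  rec <- denovo(parsePeptide("pENWPGPK"))
  expect_identical(rec, c("pE", "N", "W", "P", "G", "P", "K"))
  rec <- denovo(parsePeptide("pEKWLDPE"))
  expect_identical(rec, c("pE", "K", "W", "I/L", "D", "P", "E"))
})
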