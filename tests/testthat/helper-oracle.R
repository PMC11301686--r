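# Independent elemental-composition mass oracle.
# Keeps its own residue formula table and element masses so that
# expected values never flow through the package's own mass path.

.ORACLE_ELEMENTS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                      O = 15.9949146221, S = 31.97207069)

.ORACLE_FORMULAS <- c(
  G = "C2H3N1O1",  A = "C3H5N1O1",  S = "C3H5N1O2",  P = "C5H7N1O1",
  V = "C5H9N1O1",  T = "C4H7N1O2",  C = "C3H5N1O1S1", L = "C6H11N1O1",
  I = "C6H11N1O1", N = "C4H6N2O2",  D = "C4H5N1O3",  Q = "C5H8N2O2",
  K = "C6H12N2O1", E = "C5H7N1O3",  M = "C5H9N1O1S1", H = "C6H7N3O1",
  F = "C9H9N1O1",  R = "C6H12N4O1", Y = "C9H9N1O2",  W = "C11H10N2O1",
  pE = "C5H5N1O2")

oracle_formula_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)",
                                       formula))[[1]]
  total <- 0
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- gsub("[^0-9]", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + .ORACLE_ELEMENTS[[el]] * n
  }
  total
}

# Neutral monoisotopic peptide mass from residue codes (tokens, not a
# display string), plus water H2O.
oracle_peptide_mass <- function(codes, mod_delta = 0) {
  sum(vapply(codes, function(cd)
    oracle_formula_mass(.ORACLE_FORMULAS[[cd]]), numeric(1))) +
    oracle_formula_mass("H2O") + mod_delta
}

# Random peptide display strings for property-style tests.
random_peptides <- function(n, min_len = 2, max_len = 12,
                            with_pE = TRUE) {
  aas <- setdiff(names(.ORACLE_FORMULAS), "pE")
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    body <- paste(sample(aas, len, replace = TRUE), collapse = "")
    if (with_pE && stats::runif(1) < 0.5)
      paste0("pE", substr(body, 2, len)) else body
  }, character(1))
}
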