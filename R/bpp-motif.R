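## Modular consensus grammar of viper bradykinin-potentiating peptides.
##
## Full-length members follow pE X W (P Z){1,2} P (EI|KV) P P L E with
## X mainly K/N/R, Z in {G,S,V}, and extensive C-terminal truncation
## down to the tripeptide core pEXW (the svMP inhibitors pEKW, pENW,
## pERW). Position 1 (pE) and position 3 (W) are anchors.

.bppTemplates <- function(X, Z, repeats, branches) {
  out <- list()
  for (x in X) for (r in repeats) for (b in branches) {
    zcombos <- if (r == 1L) lapply(Z, function(z) z)
               else unlist(lapply(Z, function(z1) lapply(Z, function(z2)
                 c(z1, z2))), recursive = FALSE)
    for (zc in zcombos) {
      mid <- unlist(lapply(zc, function(z) c("P", z)))
      toks <- c("pE", x, "W", mid, "P", strsplit(b, "")[[1]],
                "P", "P", "L", "E")
      out[[length(out) + 1L]] <- list(tokens = toks, X = x,
                                      repeats = r, Z = zc, branch = b)
    }
  }
  out
}

.tokensToString <- function(toks) paste(toks, collapse = "")

#' Result of matching a peptide against the BPP grammar
#'
#' @slot matched logical: does the sequence parse as a (possibly
#'   truncated) grammar member?
#' @slot family `"K"`, `"N"`, `"R"`, or `"other"` (second-position
#'   residue outside the common alphabet, flagged rare); `NA` when
#'   unmatched.
#' @slot rare logical: TRUE when the second-position residue is outside
#'   the default K/N/R alphabet.
#' @slot repeatCount integer 1 or 2 from the best-matching template
#'   (`NA` when unmatched).
#' @slot zObserved character: Z residues actually present in the query.
#' @slot branch `"EI"`, `"KV"` or `"absent"` (truncated before the
#'   branch block).
#' @slot truncation integer residues missing from the full-length
#'   C-terminus of the best (shortest consistent) template.
#' @slot deviations data.frame of tolerated mismatches (`position`,
#'   `expected`, `observed`).
#' @slot modsStripped logical: modifications were removed before
#'   grammar matching.
#' @slot template character: display string of the best template.
#' @export
setClass("BppParse",
  representation(matched = "logical", family = "character",
                 rare = "logical", repeatCount = "integer",
                 zObserved = "character", branch = "character",
                 truncation = "integer", deviations = "data.frame",
                 modsStripped = "logical", template = "character"))

setMethod("show", "BppParse", function(object) {
  if (!object@matched) {
    cat("BppParse: no match\n")
    return(invisible(NULL))
  }
  cat("BppParse: matched, family ", object@family,
      if (object@rare) " (rare X)" else "", "\n", sep = "")
  cat("  template: ", object@template,
      "  truncation: ", object@truncation, " residue(s)\n", sep = "")
  cat("  repeat: ", object@repeatCount,
      "  Z: ", paste(object@zObserved, collapse = ","),
      "  branch: ", object@branch, "\n", sep = "")
  if (nrow(object@deviations))
    cat("  deviations: ",
        paste0(object@deviations$expected, object@deviations$position,
               object@deviations$observed, collapse = ", "), "\n",
        sep = "")
})

.noBppMatch <- function(stripped) {
  methods::new("BppParse", matched = FALSE, family = NA_character_,
               rare = FALSE, repeatCount = NA_integer_,
               zObserved = character(0), branch = "absent",
               truncation = NA_integer_,
               deviations = data.frame(position = integer(0),
                                       expected = character(0),
                                       observed = character(0)),
               modsStripped = stripped, template = NA_character_)
}

#' Parse a peptide against the BPP consensus grammar
#'
#' Longest-prefix match of the (modification-stripped) sequence against
#' all full-length grammar templates. The anchors -- pyroglutamate at
#' position 1 and Trp at position 3 -- must match exactly. Position 2
#' (X) accepts any residue; residues outside the default K/N/R alphabet
#' are classified `family = "other"` and flagged rare. In strict mode
#' no other mismatch is tolerated; in lenient mode one contiguous block
#' of at most two mismatched non-anchor positions is tolerated and
#' every mismatched position is recorded in `deviations`.
#'
#' @param seq Display string or [Peptide-class]. Modifications are
#'   stripped before matching (recorded in `modsStripped`).
#' @param strict Logical; default `FALSE` (lenient).
#' @param X,Z Character vectors: the common second-position alphabet
#'   and the repeat-position alphabet.
#' @param branches Character vector of branch blocks.
#' @return A [BppParse-class] object; `matched = FALSE` when the
#'   sequence is not a grammar member (never an error).
#' @examples
#' parseBpp("pEKW")              # svMP-inhibitor core, family K
#' parseBpp("pERWPGPKVPPLE")     # full-length, no truncation
#' parseBpp("AAAA")              # no pE anchor: unmatched
#' @export
parseBpp <- function(seq, strict = FALSE,
                     X = c("K", "N", "R"), Z = c("G", "S", "V"),
                     branches = c("EI", "KV")) {
  p <- .asPeptide(seq)
  stripped <- any(lengths(p@mods) > 0)
  toks <- p@residues
  n <- length(toks)
  if (n < 3L || toks[1] != "pE" || toks[3] != "W")
    return(.noBppMatch(stripped))
  tpls <- .bppTemplates(X = toks[2], Z = Z, repeats = c(1L, 2L),
                        branches = branches)
  best <- NULL
  for (tp in tpls) {
    m <- length(tp$tokens)
    if (n > m) next
    cmp <- toks != tp$tokens[seq_len(n)]
    cmp[2] <- FALSE                       # X position free by construction
    mis <- which(cmp)
    if (any(mis %in% c(1L, 3L))) next     # anchors must hold
    if (strict && length(mis)) next
    if (!strict && length(mis)) {
      # one contiguous block (at most 2 positions) of non-anchor
      # mismatches tolerated
      if (length(mis) > 2L || (max(mis) - min(mis) + 1L) != length(mis))
        next
    }
    cand <- list(tp = tp, mis = mis, tlen = m)
    if (is.null(best) ||
        length(mis) < length(best$mis) ||
        (length(mis) == length(best$mis) && m < best$tlen))
      best <- cand
  }
  if (is.null(best)) return(.noBppMatch(stripped))
  tp <- best$tp
  fam <- if (toks[2] %in% c("K", "N", "R")) toks[2] else "other"
  zpos <- if (tp$repeats == 1L) 5L else c(5L, 7L)
  branchStart <- if (tp$repeats == 1L) 7L else 9L
  methods::new("BppParse",
    matched = TRUE, family = fam, rare = !(toks[2] %in% X),
    repeatCount = tp$repeats,
    zObserved = toks[zpos[zpos <= n]],
    branch = if (n >= branchStart) tp$branch else "absent",
    truncation = best$tlen - n,
    deviations = data.frame(position = best$mis,
                            expected = tp$tokens[best$mis],
                            observed = toks[best$mis],
                            stringsAsFactors = FALSE),
    modsStripped = stripped,
    template = .tokensToString(tp$tokens))
}

#' Enumerate BPP grammar members
#'
#' All full-length sequences of the grammar
#' `pE X W (P Z){1,2} P (EI|KV) P P L E` over the given alphabets, plus
#' every C-terminal truncation of at least `minLen` residues,
#' deduplicated and sorted.
#'
#' @param X Second-position alphabet (default K/N/R).
#' @param Z Repeat-position alphabet (default G/S/V).
#' @param repeats Integer subset of `c(1, 2)`.
#' @param branches Branch blocks.
#' @param minLen Minimum length (residues, `pE` counts as one) of
#'   reported truncations; must be >= 3 (the pEXW core).
#' @param fullOnly If `TRUE`, only full-length members.
#' @return Character vector of display strings, lexicographically
#'   sorted.
#' @examples
#' enumerateBpp(X = "K", Z = "G", repeats = 1, branches = "KV",
#'              fullOnly = TRUE)
#' @export
enumerateBpp <- function(X = c("K", "N", "R"), Z = c("G", "S", "V"),
                         repeats = c(1L, 2L), branches = c("EI", "KV"),
                         minLen = 3L, fullOnly = FALSE) {
  if (!length(X) || !length(Z) || !length(branches))
    stop("alphabets must be non-empty")
  if (minLen < 3L)
    stop("minLen must be >= 3 (the pEXW core)")
  tpls <- .bppTemplates(X, Z, as.integer(repeats), branches)
  seqs <- character()
  for (tp in tpls) {
    m <- length(tp$tokens)
    lens <- if (fullOnly) m else seq(from = max(minLen, 3L), to = m)
    seqs <- c(seqs, vapply(lens, function(l)
      .tokensToString(tp$tokens[seq_len(l)]), character(1)))
  }
  sort(unique(seqs))
}

#' Natriuretic-peptide reference sequences
#'
#' Short references used for substitution naming, e.g. lebetin 1beta.
#'
#' @return `data.frame` with columns `name`, `sequence`.
#' @examples
#' npReferences()
#' @export
npReferences <- function() {
  data.frame(name = "lebetin_1beta", sequence = "DNKPPKKGPPNG",
             stringsAsFactors = FALSE)
}

#' Name substitutions against a reference peptide
#'
#' Ungapped position-wise comparison of a query sequence against a
#' reference after applying an integer offset (query position
#' `p - offset` aligns to reference position `p`). Substitutions are
#' labelled `<refRes><refPos><queryRes>` with 1-based reference
#' numbering; an alternative label numbered from the second reference
#' residue is emitted alongside (`labelAlt`), since both conventions
#' circulate for short venom NP fragments and neither is asserted as
#' canonical. Terminal extensions and truncations are reported
#' separately, never as substitutions.
#'
#' @param query Query sequence (plain uppercase string).
#' @param ref Reference sequence, or a row name from [npReferences()].
#' @param offset Integer: negative values mean the query extends the
#'   reference N-terminus (e.g. `-1` for one extra leading residue).
#' @return List: `substitutions` (data.frame `refPos`, `refRes`,
#'   `queryRes`, `label`, `labelAlt`), `nTermExtension`,
#'   `cTermExtension`, `nTermTruncation`, `cTermTruncation` (character
#'   strings, possibly empty).
#' @examples
#' nameSubstitutions("DNEPPKKVPPN", "lebetin_1beta")
#' nameSubstitutions("EDNEPPKKLPPS", "lebetin_1beta", offset = -1)
#' @export
nameSubstitutions <- function(query, ref, offset = 0L) {
  refs <- npReferences()
  if (ref %in% refs$name) ref <- refs$sequence[match(ref, refs$name)]
  stopifnot(nchar(query) > 0, nchar(ref) > 0)
  q <- strsplit(toupper(query), "")[[1]]
  r <- strsplit(toupper(ref), "")[[1]]
  refPos <- seq_along(r)
  qIdx <- refPos - offset
  inside <- qIdx >= 1L & qIdx <= length(q)
  if (!any(inside)) stop("offset produces zero overlap with reference")
  covered <- refPos[inside]
  diffs <- covered[r[covered] != q[covered - offset]]
  subs <- data.frame(
    refPos = diffs, refRes = r[diffs], queryRes = q[diffs - offset],
    label = paste0(r[diffs], diffs, q[diffs - offset]),
    labelAlt = paste0(r[diffs], diffs - 1L, q[diffs - offset]),
    stringsAsFactors = FALSE)
  qPos <- seq_along(q)
  rIdx <- qPos + offset
  list(
    substitutions = subs,
    nTermExtension = paste(q[rIdx < 1L], collapse = ""),
    cTermExtension = paste(q[rIdx > length(r)], collapse = ""),
    nTermTruncation = paste(r[refPos < min(covered)], collapse = ""),
    cTermTruncation = paste(r[refPos > max(covered)], collapse = ""))
}
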