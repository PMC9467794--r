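#' The standard genetic code with synonymous-family structure
#'
#' Builds the standard (nuclear) genetic code as used throughout the package:
#' the codon-to-amino-acid map, the synonymous codon family of every amino
#' acid, and each amino acid's degeneracy class (1, 2, 3, 4 or 6 synonyms).
#' Serine, leucine and arginine are treated as single six-fold families;
#' isoleucine is the only three-fold family; methionine and tryptophan are
#' single-codon amino acids. The three stop codons form the `TER` family.
#'
#' Codons are stored internally in the DNA alphabet. The canonical reporting
#' order sorts sense codons by second base, then first, then third (base rank
#' U < C < A < G) — the column-wise order of the classical codon table, which
#' keeps output diffable — with the stop codons last.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character, 64 DNA codons to three-letter amino-acid
#'   symbols, `"TER"` for stops), `family_of` (list: amino acid to its codon
#'   vector in canonical order), `degeneracy` (named integer per amino acid),
#'   `codon_order` (all 64 codons, canonical order), `sense_codons` (61),
#'   `syn_codons` (the 59 codons of amino acids with two or more synonyms),
#'   and `fourfold_codons` (the 32 codons of fully fourfold-degenerate boxes,
#'   including the fourfold halves of Leu, Ser and Arg).
#' @examples
#' gc <- standard_genetic_code()
#' gc$degeneracy[c("Met", "Ile", "Leu")]
#' @export
standard_genetic_code <- function() {
  aa3 <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val", `*` = "TER"
  )
  code1 <- Biostrings::GENETIC_CODE
  codon_to_aa <- stats::setNames(unname(aa3[code1]), names(code1))

  rank <- c(T = 1, C = 2, A = 3, G = 4)  # U < C < A < G on the DNA alphabet
  codons <- names(codon_to_aa)
  p1 <- rank[substr(codons, 1, 1)]
  p2 <- rank[substr(codons, 2, 2)]
  p3 <- rank[substr(codons, 3, 3)]
  is_stop <- codon_to_aa == "TER"
  ord <- order(is_stop, p2, p1, p3)
  codon_order <- codons[ord]
  codon_to_aa <- codon_to_aa[codon_order]

  family_of <- split(names(codon_to_aa), codon_to_aa)
  # preserve within-family canonical order, and order families by first codon
  family_of <- lapply(family_of, function(x) x[order(match(x, codon_order))])
  fam_first <- vapply(family_of, function(x) match(x[1], codon_order), 0L)
  family_of <- family_of[order(fam_first)]
  degeneracy <- vapply(family_of, length, 0L)

  sense <- codon_order[codon_to_aa[codon_order] != "TER"]
  multi_aa <- names(degeneracy)[degeneracy >= 2L & names(degeneracy) != "TER"]
  syn <- sense[codon_to_aa[sense] %in% multi_aa]

  # fourfold-degenerate boxes: Ala/Gly/Pro/Thr/Val plus the NNU/NNC/NNA/NNG
  # halves of the sixfold families (CTN for Leu, TCN for Ser, CGN for Arg)
  ff_prefix <- c("GC", "GG", "CC", "AC", "GT", "CT", "TC", "CG")
  fourfold <- codon_order[substr(codon_order, 1, 2) %in% ff_prefix]

  structure(
    list(
      codon_to_aa = codon_to_aa,
      family_of = family_of,
      degeneracy = degeneracy,
      codon_order = codon_order,
      sense_codons = sense,
      syn_codons = syn,
      fourfold_codons = fourfold
    ),
    class = "genetic_code"
  )
}

#' Flavour classes of amino acids
#'
#' Amino-acid groupings used to annotate RSCU tables: delicious amino acids
#' (DAA), Strecker amino acids (SAA) and branched-chain amino acids (BCAA).
#' These classes matter in meat-quality work because DAA/SAA content shapes
#' flavour and BCAAs dominate muscle protein.
#'
#' @return Named list of character vectors of three-letter amino-acid symbols.
#' @export
flavour_classes <- function() {
  list(
    DAA  = c("Glu", "Gly", "Ser", "Asp", "Arg", "Ile"),
    SAA  = c("Phe", "Cys", "Ile", "Leu"),
    BCAA = c("Leu", "Ile", "Val")
  )
}

#' Convert codons between DNA and RNA spelling
#'
#' @param codons Character vector of codons.
#' @return Character vector with `T` replaced by `U` (`codon_to_rna`) or `U`
#'   by `T` (`codon_to_dna`).
#' @export
codon_to_rna <- function(codons) chartr("Tt", "Uu", codons)

#' @rdname codon_to_rna
#' @export
codon_to_dna <- function(codons) chartr("Uu", "Tt", codons)

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$sense_codons), "sense codons,",
      sum(x$codon_to_aa == "TER"), "stops;",
      length(x$syn_codons), "synonymous codons in",
      sum(x$degeneracy >= 2 & names(x$degeneracy) != "TER"),
      "multi-codon families\n")
  invisible(x)
}
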