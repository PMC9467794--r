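#' Restrict a codon count table to synonymously variable codons
#'
#' Keeps the 59 sense codons of amino acids with at least two synonyms: the
#' universe behind every "s"-subscripted statistic (GC3s, T3s, ...). ATG
#' (Met), TGG (Trp) and the three stop codons are removed.
#'
#' @param counts A `codon_count_table`.
#' @param code Genetic code.
#' @return A `codon_count_table` whose `counts` vector covers only the 59
#'   synonymous codons; `n_codons` is their total.
#' @export
synonymous_codon_set <- function(counts, code = standard_genetic_code()) {
  stopifnot(inherits(counts, "codon_count_table"))
  kept <- counts$counts[code$syn_codons]
  structure(
    list(gene_id = counts$gene_id, counts = kept,
         n_codons = sum(kept), n_skipped = counts$n_skipped),
    class = "codon_count_table"
  )
}

#' Positional nucleotide composition of a coding sequence
#'
#' Computes the base-composition statistics used in codon-usage surveys:
#' whole-sequence A/T and G/C fractions, GC content at each codon position of
#' synonymously variable codons (GC1s, GC2s, GC3s, AT3s, GC12), and the
#' per-base third-position fractions T3s, C3s, A3s, G3s.
#'
#' A/T and G/C are taken over all nucleotides of counted codons, including
#' Met, Trp and stops. The "s" statistics are taken over the 59 synonymous
#' codons only. `gc12` is the arithmetic mean of `gc1s` and `gc2s`.
#'
#' Two conventions are offered for the per-base third-position fractions.
#' Under `"simple"`, the fraction of synonymous third positions carrying the
#' base (the four values sum to 1). Under `"per_base_denominator"` (default,
#' CodonW-compatible), the denominator for base B counts only codons whose
#' synonymous family has at least one member ending in B, so the four values
#' may sum to more than 1.
#'
#' @param counts A `codon_count_table`.
#' @param code Genetic code.
#' @param x3s_convention `"per_base_denominator"` (default) or `"simple"`.
#' @param s_universe Universe for `gc1s`/`gc2s`: `"synonymous"` (default,
#'   same 59-codon universe as `gc3s`) or `"all"` (every counted codon).
#' @return An object of class `composition_profile`: a list with `gene_id`,
#'   `at_frac`, `gc_frac`, `t3s`, `c3s`, `a3s`, `g3s`, `gc3s`, `at3s`,
#'   `gc1s`, `gc2s`, `gc12` and `n_syn_codons`.
#' @examples
#' cc <- codon_counts(cds_record("g1", "ATGGCCGCGTAA"))
#' composition_profile(cc)$gc3s   # only GCC/GCG are synonymous: 1
#' @export
composition_profile <- function(counts, code = standard_genetic_code(),
                                x3s_convention = c("per_base_denominator",
                                                   "simple"),
                                s_universe = c("synonymous", "all")) {
  x3s_convention <- match.arg(x3s_convention)
  s_universe <- match.arg(s_universe)
  stopifnot(inherits(counts, "codon_count_table"))
  if (counts$n_codons <= 0L) stop("empty codon count table")

  all_codons <- names(counts$counts)
  cnt <- counts$counts

  base_at_pos <- function(codons, pos) substr(codons, pos, pos)
  # whole-sequence composition over all counted codons
  gc_total <- 0
  for (p in 1:3) {
    gc_total <- gc_total +
      sum(cnt[base_at_pos(all_codons, p) %in% c("G", "C")])
  }
  gc_frac <- gc_total / (3 * sum(cnt))
  at_frac <- 1 - gc_frac

  syn <- code$syn_codons
  syn_cnt <- cnt[syn]
  n_syn <- sum(syn_cnt)
  if (n_syn == 0L) {
    stop("no synonymous codons observed for '", counts$gene_id,
         "'; composition profile undefined")
  }

  third <- base_at_pos(syn, 3)
  gc3s <- sum(syn_cnt[third %in% c("G", "C")]) / n_syn

  pos_gc <- function(p, universe, universe_cnt) {
    sum(universe_cnt[base_at_pos(universe, p) %in% c("G", "C")]) /
      sum(universe_cnt)
  }
  if (s_universe == "synonymous") {
    gc1s <- pos_gc(1, syn, syn_cnt)
    gc2s <- pos_gc(2, syn, syn_cnt)
  } else {
    gc1s <- pos_gc(1, all_codons, cnt)
    gc2s <- pos_gc(2, all_codons, cnt)
  }

  # per-base third-position fractions
  x3s <- stats::setNames(numeric(4), c("T", "C", "A", "G"))
  if (x3s_convention == "simple") {
    for (b in names(x3s)) x3s[b] <- sum(syn_cnt[third == b]) / n_syn
  } else {
    aa_of <- code$codon_to_aa[syn]
    for (b in names(x3s)) {
      fams_with_b <- unique(aa_of[third == b])
      denom <- sum(syn_cnt[aa_of %in% fams_with_b])
      x3s[b] <- if (denom > 0) sum(syn_cnt[third == b]) / denom else NA_real_
    }
  }

  structure(
    list(gene_id = counts$gene_id,
         at_frac = at_frac, gc_frac = gc_frac,
         t3s = unname(x3s["T"]), c3s = unname(x3s["C"]),
         a3s = unname(x3s["A"]), g3s = unname(x3s["G"]),
         gc3s = gc3s, at3s = 1 - gc3s,
         gc1s = gc1s, gc2s = gc2s, gc12 = (gc1s + gc2s) / 2,
         n_syn_codons = n_syn,
         x3s_convention = x3s_convention),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s: GC = %.3f, GC3s = %.3f, GC12 = %.4f\n",
              x$gene_id, x$gc_frac, x$gc3s, x$gc12))
  invisible(x)
}

#' @export
as.data.frame.composition_profile <- function(x, ...) {
  data.frame(gene_id = x$gene_id, at = x$at_frac, gc = x$gc_frac,
             t3s = x$t3s, c3s = x$c3s, a3s = x$a3s, g3s = x$g3s,
             gc3s = x$gc3s, at3s = x$at3s,
             gc1s = x$gc1s, gc2s = x$gc2s, gc12 = x$gc12,
             n_syn_codons = x$n_syn_codons, stringsAsFactors = FALSE)
}

#' Composition table for a set of count tables
#'
#' @param count_tables List of `codon_count_table` objects.
#' @param ... Passed to [composition_profile()].
#' @return A data.frame, one row per gene, in input order.
#' @export
composition_table <- function(count_tables, ...) {
  do.call(rbind, lapply(count_tables,
                        function(ct) as.data.frame(composition_profile(ct, ...))))
}
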