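#' Effective number of codons (ENC)
#'
#' Wright's ENC measures how far codon usage departs from uniform synonymous
#' usage: 20 when exactly one codon is used per amino acid, 61 when all
#' synonyms are used equally. For each multi-codon family with total count
#' n >= 2 the codon homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1) with
#' p_i the within-family codon frequencies. F is averaged within each
#' degeneracy class (families with n < 2 or F <= 0 are skipped) and
#'
#'   ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6
#'
#' (9 twofold, 1 threefold, 5 fourfold and 3 sixfold families in the
#' standard code). A missing threefold average (Ile unobserved) is imputed
#' as (F2 + F4)/2; if any other class average is unavailable the statistic
#' is undefined (`NA` with a warning). Values above 61 are capped at 61.
#'
#' @param counts A `codon_count_table`.
#' @param code Genetic code.
#' @return ENC in [20, 61], or `NA` if undefined.
#' @examples
#' # one codon per family -> minimum bias statistic
#' seqs <- strrep("TTTATTGTTTCTCCTACTGCTTATCATCAAAATAAAGATGAATGTCGTGGT", 2)
#' enc(codon_counts(cds_record("g", seqs), frame_policy = "strict"))
#' @export
enc <- function(counts, code = standard_genetic_code()) {
  stopifnot(inherits(counts, "codon_count_table"))
  multi_aa <- names(code$degeneracy)[code$degeneracy >= 2L &
                                       names(code$degeneracy) != "TER"]
  if (sum(counts$counts[code$syn_codons]) == 0L) {
    stop("all synonymous families empty for '", counts$gene_id,
         "'; ENC undefined")
  }
  f_by_class <- list(`2` = numeric(), `3` = numeric(),
                     `4` = numeric(), `6` = numeric())
  for (aa in multi_aa) {
    x <- counts$counts[code$family_of[[aa]]]
    n <- sum(x)
    if (n < 2L) next
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next
    k <- as.character(code$degeneracy[[aa]])
    f_by_class[[k]] <- c(f_by_class[[k]], f)
  }
  fbar <- vapply(f_by_class, function(v) if (length(v)) mean(v) else NA_real_,
                 0)
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  if (anyNA(fbar)) {
    warning("ENC undefined for '", counts$gene_id,
            "': no usable family in degeneracy class ",
            paste(names(fbar)[is.na(fbar)], collapse = ", "))
    return(NA_real_)
  }
  val <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  unname(min(val, 61))
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of relative-adaptiveness weights over all counted codons of
#' multi-codon families (Met, Trp and stops excluded):
#' CAI = exp( sum(X_j * log(max(w_j, floor))) / sum(X_j) ). The floor guards
#' log(0) for codons absent from the reference set.
#'
#' @param counts A `codon_count_table`.
#' @param weights A [reference_weights()] object or named numeric vector
#'   covering all 59 synonymous codons (DNA or RNA names).
#' @param floor Lower bound applied to weights before the log (default 0.01).
#' @param code Genetic code.
#' @return CAI in (0, 1].
#' @export
cai <- function(counts, weights, floor = 0.01,
                code = standard_genetic_code()) {
  stopifnot(inherits(counts, "codon_count_table"))
  w <- stats::setNames(as.numeric(weights), codon_to_dna(names(weights)))
  missing <- setdiff(code$syn_codons, names(w))
  if (length(missing)) {
    stop("reference weights missing for codon(s): ",
         paste(codon_to_rna(missing), collapse = " "))
  }
  x <- counts$counts[code$syn_codons]
  n <- sum(x)
  if (n == 0L) stop("no synonymous codons counted; CAI undefined")
  wf <- pmax(w[code$syn_codons], floor)
  if (any(w[code$syn_codons][x > 0] < floor)) {
    message("CAI floor ", floor, " applied to ",
            sum(w[code$syn_codons][x > 0] < floor), " used codon(s)")
  }
  exp(sum(x * log(wf)) / n)
}

#' Frequency of optimal codons (FOP)
#'
#' Fraction of a gene's synonymous codons (codons of multi-codon families)
#' that belong to the optimal codon set.
#'
#' @param counts A `codon_count_table`.
#' @param optimal An [derive_optimal_codons()] set or character vector of
#'   codons (DNA or RNA).
#' @param code Genetic code.
#' @return FOP in [0, 1].
#' @export
fop <- function(counts, optimal, code = standard_genetic_code()) {
  stopifnot(inherits(counts, "codon_count_table"))
  opt <- codon_to_dna(as.character(optimal))
  x <- counts$counts[code$syn_codons]
  n <- sum(x)
  if (n == 0L) stop("no synonymous codons counted; FOP undefined")
  sum(x[names(x) %in% opt]) / n
}

#' Codon bias index (CBI)
#'
#' Excess usage of optimal codons over the uniform-usage expectation:
#' CBI = (N_opt - N_ran) / (N_tot - N_ran), where N_tot is the synonymous
#' codon count, N_opt the optimal-codon count, and N_ran the expected
#' optimal count under uniform within-family usage
#' (sum over families of family count * optimal codons in family / degeneracy).
#' CBI is 1 when only optimal codons are used, 0 at uniform usage, and
#' negative when optimal codons are avoided.
#'
#' @inheritParams fop
#' @return CBI (at most 1; can be negative).
#' @export
cbi <- function(counts, optimal, code = standard_genetic_code()) {
  stopifnot(inherits(counts, "codon_count_table"))
  opt <- codon_to_dna(as.character(optimal))
  multi_aa <- names(code$degeneracy)[code$degeneracy >= 2L &
                                       names(code$degeneracy) != "TER"]
  n_tot <- 0; n_opt <- 0; n_ran <- 0
  for (aa in multi_aa) {
    cods <- code$family_of[[aa]]
    x <- counts$counts[cods]
    n <- sum(x)
    if (n == 0L) next
    k_opt <- sum(cods %in% opt)
    n_tot <- n_tot + n
    n_opt <- n_opt + sum(x[cods %in% opt])
    n_ran <- n_ran + n * k_opt / length(cods)
  }
  if (n_tot == 0L) stop("no synonymous codons counted; CBI undefined")
  if (abs(n_tot - n_ran) < .Machine$double.eps * n_tot) {
    stop("degenerate CBI denominator (every synonymous codon optimal)")
  }
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Codon-usage index table for a gene set
#'
#' Convenience wrapper computing, per gene, ENC, CAI, CBI, FOP and the
#' GC1s/GC2s/GC12 composition columns. When no optimal set or reference
#' weights are given, both are derived from the analysed set itself (optimal
#' codons by highest mean RSCU; weights as RSCU/RSCUmax of the pooled table),
#' which makes the indices self-referential — appropriate for comparative
#' surveys, not for absolute expressivity claims.
#'
#' @param count_tables List of `codon_count_table` objects.
#' @param optimal Optional optimal codon set.
#' @param weights Optional reference weights.
#' @param cai_floor CAI weight floor.
#' @param code Genetic code.
#' @return Data.frame with columns `gene_id`, `enc`, `cai`, `cbi`, `fop`,
#'   `gc1s`, `gc2s`, `gc12`.
#' @export
cub_index_table <- function(count_tables, optimal = NULL, weights = NULL,
                            cai_floor = 0.01,
                            code = standard_genetic_code()) {
  rscus <- lapply(count_tables, rscu, code = code)
  if (is.null(optimal)) optimal <- derive_optimal_codons(rscus, code = code)
  if (is.null(weights)) weights <- reference_weights(mean_rscu(rscus), code)
  rows <- lapply(count_tables, function(ct) {
    prof <- composition_profile(ct, code = code)
    data.frame(gene_id = ct$gene_id,
               enc = enc(ct, code),
               cai = cai(ct, weights, floor = cai_floor, code = code),
               cbi = cbi(ct, optimal, code),
               fop = fop(ct, optimal, code),
               gc1s = prof$gc1s, gc2s = prof$gc2s, gc12 = prof$gc12,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
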