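#' Relative synonymous codon usage (RSCU)
#'
#' For codon j of an amino acid with n synonyms and family counts X,
#' RSCU_j = X_j * n / sum(X). RSCU is 1 under uniform synonymous usage,
#' above 1 for preferred codons, and above 2 for strongly preferred ones.
#' Families with zero total count are reported as `NA` (undefined), which is
#' distinct from an RSCU of 0.
#'
#' @param counts A `codon_count_table`.
#' @param code Genetic code.
#' @param include_stops Include the three-codon `TER` family (as in pooled
#'   codon-usage tables)? Default `FALSE`.
#' @return A data.frame of class `rscu_table`, one row per codon in canonical
#'   order, with columns `amino_acid`, `codon` (RNA alphabet), `count`,
#'   `rscu`, `preference` (`""`, `"preferred"` for RSCU > 1, `"strong"` for
#'   RSCU > 2) and `flavour` (comma-separated subset of DAA/SAA/BCAA).
#'   The gene id is carried in attribute `gene_id`.
#' @examples
#' cc <- codon_counts(cds_record("g1", "TTTTTTTTTTTC"), frame_policy = "strict")
#' subset(rscu(cc), amino_acid == "Phe")   # RSCU 1.5 / 0.5
#' @export
rscu <- function(counts, code = standard_genetic_code(),
                 include_stops = FALSE) {
  stopifnot(inherits(counts, "codon_count_table"))
  fams <- code$family_of
  fams <- fams[names(fams) != "TER" | include_stops]
  fams <- fams[vapply(fams, length, 0L) >= 1L]

  rows <- lapply(names(fams), function(aa) {
    cods <- fams[[aa]]
    x <- counts$counts[cods]
    tot <- sum(x)
    val <- if (tot > 0) unname(x) * length(cods) / tot else rep(NA_real_,
                                                                length(cods))
    data.frame(amino_acid = aa, codon = codon_to_rna(cods),
               count = unname(x), rscu = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # keep canonical codon order across families
  out <- out[order(match(codon_to_dna(out$codon), code$codon_order)), ]
  rownames(out) <- NULL
  out$preference <- ifelse(is.na(out$rscu), "",
                           ifelse(out$rscu > 2, "strong",
                                  ifelse(out$rscu > 1, "preferred", "")))
  fl <- flavour_classes()
  out$flavour <- vapply(out$amino_acid, function(aa) {
    paste(names(fl)[vapply(fl, function(s) aa %in% s, TRUE)], collapse = ",")
  }, "", USE.NAMES = FALSE)
  structure(out, class = c("rscu_table", "data.frame"),
            gene_id = counts$gene_id)
}

#' Average RSCU tables across species
#'
#' Combines per-species RSCU tables into one pooled table: the `count` column
#' is the sum of counts across species, and `rscu` is the arithmetic mean of
#' the per-species RSCU over the species in which the family was observed.
#' This averaging convention preserves the family-sum identity exactly (each
#' observed family's mean RSCU values sum to its degeneracy). Preference
#' flags are recomputed on the means.
#'
#' @param tables Non-empty list of `rscu_table` objects over a common code.
#' @param set_id Identifier for the pooled table.
#' @return An `rscu_table` (attribute `gene_id` set to `set_id`).
#' @export
mean_rscu <- function(tables, set_id = "mean") {
  if (!length(tables)) stop("mean_rscu() needs at least one RSCU table")
  stopifnot(all(vapply(tables, inherits, TRUE, "rscu_table")))
  ref <- tables[[1]]
  codons <- ref$codon
  for (t in tables[-1]) {
    if (!identical(t$codon, codons)) {
      stop("RSCU tables have differing codon sets; ",
           "use a common genetic code and include_stops setting")
    }
  }
  counts <- Reduce(`+`, lapply(tables, function(t) t$count))
  rscu_mat <- vapply(tables, function(t) t$rscu, numeric(length(codons)))
  rscu_mean <- rowMeans(rscu_mat, na.rm = TRUE)
  rscu_mean[rowSums(!is.na(rscu_mat)) == 0L] <- NA_real_
  out <- ref
  out$count <- counts
  out$rscu <- rscu_mean
  out$preference <- ifelse(is.na(out$rscu), "",
                           ifelse(out$rscu > 2, "strong",
                                  ifelse(out$rscu > 1, "preferred", "")))
  attr(out, "gene_id") <- set_id
  out
}

#' Data-driven optimal codon set
#'
#' Selects, for every multi-codon family, the codon with the highest mean
#' RSCU across the supplied tables; ties break deterministically toward the
#' canonical codon order. This is the default optimal set used by [fop()]
#' and [cbi()] when no organism-specific set is supplied.
#'
#' @param tables Non-empty list of `rscu_table` objects.
#' @param code Genetic code.
#' @return An object of class `optimal_codon_set`: character vector of DNA
#'   codons (one per multi-codon family), with a `provenance` attribute.
#' @export
derive_optimal_codons <- function(tables, code = standard_genetic_code()) {
  pooled <- mean_rscu(tables)
  pooled_dna <- codon_to_dna(pooled$codon)
  multi_aa <- names(code$degeneracy)[code$degeneracy >= 2L &
                                       names(code$degeneracy) != "TER"]
  picks <- vapply(multi_aa, function(aa) {
    cods <- code$family_of[[aa]]
    vals <- pooled$rscu[match(cods, pooled_dna)]
    if (all(is.na(vals))) return(cods[1])   # unobserved family: canonical first
    vals[is.na(vals)] <- -Inf
    cods[which.max(vals)]                   # which.max takes first on ties
  }, "")
  structure(unname(picks), class = "optimal_codon_set",
            provenance = "derived from mean RSCU")
}

#' Relative-adaptiveness weights from a reference RSCU table
#'
#' Builds CAI weights w = RSCU / max family RSCU from a reference gene set's
#' RSCU table (Sharp and Li's relative adaptiveness). Codons of unobserved
#' families get weight 1 (uninformative); zero-count codons get weight 0 and
#' rely on the CAI floor.
#'
#' @param table An `rscu_table` (typically from [mean_rscu()] over a
#'   reference gene set).
#' @param code Genetic code.
#' @return An object of class `reference_weights`: named numeric vector over
#'   the 59 synonymous codons (DNA names), each family's maximum equal to 1.
#' @export
reference_weights <- function(table, code = standard_genetic_code()) {
  stopifnot(inherits(table, "rscu_table"))
  dna <- codon_to_dna(table$codon)
  w <- stats::setNames(rep(NA_real_, length(code$syn_codons)),
                       code$syn_codons)
  multi_aa <- names(code$degeneracy)[code$degeneracy >= 2L &
                                       names(code$degeneracy) != "TER"]
  for (aa in multi_aa) {
    cods <- code$family_of[[aa]]
    vals <- table$rscu[match(cods, dna)]
    if (all(is.na(vals))) {
      w[cods] <- 1
    } else {
      vals[is.na(vals)] <- 0
      w[cods] <- vals / max(vals)
    }
  }
  structure(w, class = "reference_weights",
            provenance = paste0("RSCU/RSCUmax from '",
                                attr(table, "gene_id"), "'"))
}

#' Read or write two-column codon/value files
#'
#' Plain-text exchange format for reference weights and optimal codon sets:
#' tab-separated, two columns (`codon`, `value`), codons in DNA or RNA
#' spelling. For an optimal set the value column is ignored on read and
#' written as 1.
#'
#' @param path File path.
#' @return `read_codon_values()` returns a named numeric vector (DNA codon
#'   names); `write_codon_values()` returns `path` invisibly.
#' @export
read_codon_values <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), codon_to_dna(toupper(df[[1]])))
}

#' @rdname read_codon_values
#' @param values Named numeric vector (codon names), an `optimal_codon_set`,
#'   or a `reference_weights` object.
#' @export
write_codon_values <- function(values, path) {
  if (inherits(values, "optimal_codon_set")) {
    values <- stats::setNames(rep(1, length(values)), unclass(values))
  }
  df <- data.frame(codon = codon_to_rna(names(values)),
                   value = as.numeric(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an RSCU table as TSV
#'
#' Columns `amino_acid`, `codon`, `count`, `rscu`, `preference`, `flavour`,
#' floats at six decimals.
#'
#' @param table An `rscu_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rscu_tsv <- function(table, path) {
  out <- as.data.frame(table)
  out$rscu <- ifelse(is.na(out$rscu), "NA", sprintf("%.6f", out$rscu))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
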