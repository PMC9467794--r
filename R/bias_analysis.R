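#' Expected ENC under mutation-drift equilibrium
#'
#' The reference curve of the ENC-GC3s plot: the ENC a gene is expected to
#' show when codon usage is shaped only by the G+C content s of synonymous
#' third positions, with no selection:
#'
#'   ENC_expected(s) = 2 + s + 29 / (s^2 + (1 - s)^2)
#'
#' Genes falling clearly below the curve use fewer codons than their GC3s
#' predicts, the classical signature of selection on codon usage.
#'
#' @param gc3s Numeric vector of GC3s fractions in [0, 1].
#' @return Expected ENC (same length as input).
#' @examples
#' expected_enc(c(0, 0.5, 1))   # 31, 60.5, 32
#' @export
expected_enc <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Parity rule 2 (PR2) coordinates
#'
#' Third-position base skew of a gene: x = G3/(G3+C3) and y = A3/(A3+T3),
#' tallied by default over the fourfold-degenerate codon boxes only
#' (Sueoka's construction: Ala, Gly, Pro, Thr, Val plus the fourfold halves
#' of Leu, Ser and Arg), where third-position changes are strictly
#' synonymous. At (0.5, 0.5) the two strands are used without bias.
#'
#' @param counts A `codon_count_table`.
#' @param code Genetic code.
#' @param mode `"fourfold"` (default) or `"all3"` (all synonymous codons).
#' @return A list of class `pr2_point` with `gene_id`, `x`, `y` (either may
#'   be `NA` when its denominator is zero, with a warning) and `mode`.
#' @export
pr2_point <- function(counts, code = standard_genetic_code(),
                      mode = c("fourfold", "all3")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "codon_count_table"))
  universe <- if (mode == "fourfold") code$fourfold_codons else code$syn_codons
  x <- counts$counts[universe]
  third <- substr(universe, 3, 3)
  tall <- vapply(c("A", "C", "G", "T"),
                 function(b) sum(x[third == b]), 0)
  ratio <- function(num, den, axis) {
    if (num + den == 0) {
      warning("PR2 ", axis, "-axis undefined for '", counts$gene_id,
              "' (zero denominator)")
      return(NA_real_)
    }
    unname(num / (num + den))
  }
  structure(
    list(gene_id = counts$gene_id,
         x = ratio(tall["G"], tall["C"], "x"),
         y = ratio(tall["A"], tall["T"], "y"),
         mode = mode),
    class = "pr2_point"
  )
}

#' @export
print.pr2_point <- function(x, ...) {
  cat(sprintf("<pr2_point> %s: G3/(G3+C3) = %.4f, A3/(A3+T3) = %.4f [%s]\n",
              x$gene_id, x$x, x$y, x$mode))
  invisible(x)
}

#' Pearson correlation with regression line
#'
#' Product-moment correlation with the exact two-sided t-test p-value
#' (t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom) and the ordinary
#' least-squares slope and intercept of y on x.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-constant.
#' @return A list of class `correlation_result`: `r`, `p_two_sided`, `n`,
#'   `slope`, `intercept`.
#' @export
pearson_cor <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("Pearson correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  slope <- stats::cov(x, y) / stats::var(x)
  structure(
    list(r = r, p_two_sided = p, n = n,
         slope = slope, intercept = mean(y) - slope * mean(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (p = %.4g, n = %d); y = %.4g x + %.4g\n",
              x$r, x$p_two_sided, x$n, x$slope, x$intercept))
  invisible(x)
}

#' Neutrality analysis (GC12 against GC3s)
#'
#' Regresses GC12 (mean GC content of first and second codon positions) on
#' GC3s. A strong correlation indicates that all three positions respond to
#' the same mutational pressure; a weak one implicates selection on the
#' first two positions.
#'
#' @param gc12_values,gc3s_values Numeric vectors of equal length (n >= 3).
#' @return A `correlation_result` (slope/intercept of GC12 on GC3s).
#' @export
neutrality_analysis <- function(gc12_values, gc3s_values) {
  stopifnot(length(gc12_values) == length(gc3s_values))
  pearson_cor(gc3s_values, gc12_values)
}

#' ENC-plot points with below/above-curve classification
#'
#' Annotates each (GC3s, ENC) pair with the expected ENC from
#' [expected_enc()] and classifies the gene as `"below"`, `"above"` or
#' `"on"` the curve (tolerance 1e-9). The sampled reference curve
#' (step 0.01) is attached as attribute `curve` for plotting.
#'
#' @param profiles Data.frame with columns `gene_id`, `gc3s`, `enc`.
#' @return Data.frame with added `expected` and `position` columns;
#'   attribute `curve` holds a data.frame (`gc3s`, `enc`).
#' @export
enc_plot <- function(profiles) {
  stopifnot(all(c("gene_id", "gc3s", "enc") %in% names(profiles)))
  out <- profiles[, c("gene_id", "gc3s", "enc")]
  out$expected <- expected_enc(out$gc3s)
  d <- out$enc - out$expected
  out$position <- ifelse(abs(d) <= 1e-9, "on",
                         ifelse(d < 0, "below", "above"))
  s <- seq(0, 1, by = 0.01)
  attr(out, "curve") <- data.frame(gc3s = s, enc = expected_enc(s))
  out
}

#' Per-codon correlation of RSCU with GC3s across species
#'
#' For every sense codon, the Pearson correlation of its RSCU across species
#' against the species' GC3s values (the data behind correlation heat maps).
#' Codons undefined in some species are correlated over the defined subset;
#' codons with fewer than 3 defined pairs or zero variance get `NA` with a
#' reason, not an error.
#'
#' @param rscu_tables List of `rscu_table` objects, one per species, in the
#'   same order as `gc3s_values`.
#' @param gc3s_values Numeric vector, one GC3s per species (n >= 3).
#' @param code Genetic code.
#' @return Data.frame in canonical codon order: `amino_acid`, `codon`, `n`,
#'   `r`, `p`, `reason` (empty when defined).
#' @export
codon_gc3s_correlations <- function(rscu_tables, gc3s_values,
                                    code = standard_genetic_code()) {
  if (length(rscu_tables) != length(gc3s_values)) {
    stop("need one RSCU table per GC3s value")
  }
  if (length(gc3s_values) < 3L) stop("need at least 3 species")
  ref <- rscu_tables[[1]]
  mat <- vapply(rscu_tables, function(t) t$rscu, numeric(nrow(ref)))
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    v <- mat[i, ]
    ok <- !is.na(v)
    n_ok <- sum(ok)
    res <- data.frame(amino_acid = ref$amino_acid[i], codon = ref$codon[i],
                      n = n_ok, r = NA_real_, p = NA_real_, reason = "",
                      stringsAsFactors = FALSE)
    if (n_ok < 3L) {
      res$reason <- "fewer than 3 defined pairs"
    } else if (stats::sd(v[ok]) == 0 || stats::sd(gc3s_values[ok]) == 0) {
      res$reason <- "zero variance"
    } else {
      pc <- pearson_cor(gc3s_values[ok], v[ok])
      res$r <- pc$r; res$p <- pc$p_two_sided
    }
    res
  })
  do.call(rbind, rows)
}
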