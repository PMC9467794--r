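# Shared fixtures and independent oracles. Everything here is deliberately
# naive and separate from the package's code paths.

CODE <- standard_genetic_code()

# random codon count table over all 64 codons
random_count_table <- function(seed, lambda = 5, gene_id = "rand") {
  withr::with_seed(seed, {
    counts <- stats::setNames(stats::rpois(64, lambda), CODE$codon_order)
  })
  structure(list(gene_id = gene_id, counts = counts,
                 n_codons = sum(counts), n_skipped = 0L),
            class = "codon_count_table")
}

# a count table from an explicit named vector (zeros elsewhere)
count_table_from <- function(..., gene_id = "manual") {
  v <- c(...)
  counts <- stats::setNames(integer(64), CODE$codon_order)
  counts[codon_to_dna(names(v))] <- as.integer(v)
  structure(list(gene_id = gene_id, counts = counts,
                 n_codons = sum(counts), n_skipped = 0L),
            class = "codon_count_table")
}

# random in-frame nucleotide sequence (multiple of 3), possibly with N
random_sequence <- function(n_nt, seed, n_prob = 0) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T", "N"), n_nt, replace = TRUE,
                 prob = c(rep((1 - n_prob) / 4, 4), n_prob)),
          collapse = "")
  })
}

# oracle: character-by-character triplet tally
oracle_triplet_tally <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  counts <- stats::setNames(integer(64), CODE$codon_order)
  skipped <- 0L
  for (i in seq(1, length(ch) - 2, by = 3)) {
    cod <- paste(ch[i:(i + 2)], collapse = "")
    if (grepl("N", cod)) skipped <- skipped + 1L else {
      counts[cod] <- counts[cod] + 1L
    }
  }
  list(counts = counts, skipped = skipped)
}

# one-codon-per-family usage: first codon of every multi-codon family
single_codon_table <- function(per_family = 10L) {
  multi <- names(CODE$degeneracy)[CODE$degeneracy >= 2 &
                                    names(CODE$degeneracy) != "TER"]
  v <- stats::setNames(rep(per_family, length(multi)),
                       vapply(CODE$family_of[multi], `[`, "", 1L))
  count_table_from(v, gene_id = "one_per_family")
}

# a data-independent, G/C-avoiding optimal set: the first A/T-ending codon
# of every multi-codon family (canonical order)
at_optimal_set <- function() {
  multi <- names(CODE$degeneracy)[CODE$degeneracy >= 2 &
                                    names(CODE$degeneracy) != "TER"]
  vapply(CODE$family_of[multi], function(cods) {
    at <- cods[substr(cods, 3, 3) %in% c("A", "T")]
    if (length(at)) at[1] else cods[1]
  }, "")
}

# oracle: Pearson r via the covariance formula, p via the t distribution
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (sum(x * y) - n * mean(x) * mean(y)) /
    ((n - 1) * sd(x) * sd(y))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# oracle: naive O(n^3) complete-linkage agglomeration; returns merge heights
oracle_complete_linkage_heights <- function(mat) {
  D <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# random unrooted tree with strictly positive branch lengths -> additive matrix
random_additive_matrix <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 2))
  })
  list(tree = tr, d = cophenetic(tr))
}
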