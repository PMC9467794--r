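#' Specification for synthetic coding sequences
#'
#' Describes a set of synthetic CDS with controlled codon-usage structure.
#' Codon choice within each synonymous family follows a two-force model:
#' a mutational factor that places total weight `gc3_pressure` on the
#' G/C-ending synonyms and `1 - gc3_pressure` on the A/T-ending ones (split
#' uniformly within each class; families whose synonyms all end in one class
#' use uniform weights), multiplied by `exp(selection_strength)` for codons
#' in the optimal set. With no selection, the expected GC3s of the output
#' equals `gc3_pressure` and the expected ENC tracks [expected_enc()].
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_codons Number of amino-acid codons per gene (start and stop are
#'   added on top).
#' @param gc3_pressure Mutational GC3 pressure theta in [0, 1].
#' @param selection_strength Selection coefficient s >= 0 applied to optimal
#'   codons on the log scale.
#' @param optimal_set Optional codon set (character or `optimal_codon_set`)
#'   receiving selection.
#' @param aa_freqs Optional named probability vector over the 20 amino acids
#'   (three-letter symbols); default uniform.
#' @param seed Integer seed; mandatory, so outputs are reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, n_codons, gc3_pressure,
                           selection_strength = 0, optimal_set = NULL,
                           aa_freqs = NULL, seed) {
  if (missing(seed)) stop("synthetic_spec() requires an explicit seed")
  stopifnot(n_genes >= 1L, n_codons >= 1L,
            gc3_pressure >= 0, gc3_pressure <= 1,
            selection_strength >= 0)
  code <- standard_genetic_code()
  aas <- setdiff(names(code$family_of), "TER")
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  } else {
    if (!setequal(names(aa_freqs), aas)) {
      stop("aa_freqs must be named with the 20 three-letter amino acids")
    }
    aa_freqs <- aa_freqs[aas]
    if (abs(sum(aa_freqs) - 1) > 1e-9 || any(aa_freqs < 0)) {
      stop("aa_freqs must be a probability vector (sum 1, non-negative)")
    }
  }
  if (!is.null(optimal_set)) {
    optimal_set <- codon_to_dna(as.character(optimal_set))
    bad <- setdiff(optimal_set, code$syn_codons)
    if (length(bad)) {
      stop("optimal_set contains non-synonymous codons: ",
           paste(codon_to_rna(bad), collapse = " "))
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), n_codons = as.integer(n_codons),
         gc3_pressure = gc3_pressure,
         selection_strength = selection_strength,
         optimal_set = optimal_set, aa_freqs = aa_freqs,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Per-family codon sampling probabilities under the mutation+selection model.
codon_sampling_probs <- function(spec, code = standard_genetic_code()) {
  theta <- spec$gc3_pressure
  s <- spec$selection_strength
  opt <- spec$optimal_set
  lapply(code$family_of[setdiff(names(code$family_of), "TER")],
         function(cods) {
           third <- substr(cods, 3, 3)
           is_gc <- third %in% c("G", "C")
           w <- numeric(length(cods))
           if (any(is_gc) && any(!is_gc)) {
             w[is_gc] <- theta / sum(is_gc)
             w[!is_gc] <- (1 - theta) / sum(!is_gc)
           } else {
             w[] <- 1 / length(cods)
           }
           if (!is.null(opt) && s > 0) {
             w <- w * exp(s * (cods %in% opt))
           }
           if (sum(w) == 0) w[] <- 1 / length(cods)   # theta 0/1 edge cases
           stats::setNames(w / sum(w), cods)
         })
}

#' Generate synthetic coding sequences
#'
#' Draws each gene codon by codon: the amino acid from `aa_freqs`, then the
#' codon within its family from the mutation-selection weights of the spec
#' (see [synthetic_spec()]). An `ATG` start is prepended and a `TAA` stop
#' appended, so each record has `3 * (n_codons + 2)` nucleotides. Output is
#' fully deterministic given the spec (the caller's RNG state is preserved).
#'
#' @param spec A [synthetic_spec()].
#' @param code Genetic code.
#' @return List of [cds_record()] objects (`ids synth_g1 ... synth_gN`).
#' @examples
#' recs <- generate_cds(synthetic_spec(1, 100, gc3_pressure = 1, seed = 7))
#' recs[[1]]$length_nt
#' @export
generate_cds <- function(spec, code = standard_genetic_code()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  probs <- codon_sampling_probs(spec, code)
  aas <- names(spec$aa_freqs)
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_genes), function(g) {
      aa_draw <- sample(aas, spec$n_codons, replace = TRUE,
                        prob = spec$aa_freqs)
      codons <- character(spec$n_codons)
      for (aa in unique(aa_draw)) {
        idx <- which(aa_draw == aa)
        fam <- probs[[aa]]
        codons[idx] <- sample(names(fam), length(idx), replace = TRUE,
                              prob = fam)
      }
      cds_record(
        id = paste0("synth_g", g),
        sequence = paste0("ATG", paste(codons, collapse = ""), "TAA"),
        description = sprintf(
          "synth_g%d theta=%g s=%g n_codons=%d seed=%d",
          g, spec$gc3_pressure, spec$selection_strength, spec$n_codons,
          spec$seed)
      )
    })
  })
}

#' Specification for inter-species divergence
#'
#' @param n_species Number of descendant species (>= 2).
#' @param sub_prob Per-branch, per-site substitution probability in [0, 1).
#'   When a topology with branch lengths is supplied, the per-edge
#'   probability is `min(sub_prob * edge_length, 0.75)`, so `sub_prob` acts
#'   as a rate per unit branch length.
#' @param topology Optional `phylo` tree with `n_species` tips; `NULL`
#'   (default) means a star: each species diverges independently from the
#'   ancestor.
#' @param seed Integer seed; mandatory.
#' @return An object of class `divergence_spec`.
#' @export
divergence_spec <- function(n_species, sub_prob, topology = NULL, seed) {
  if (missing(seed)) stop("divergence_spec() requires an explicit seed")
  stopifnot(n_species >= 2L, sub_prob >= 0, sub_prob < 1)
  if (!is.null(topology)) {
    stopifnot(inherits(topology, "phylo"))
    if (length(topology$tip.label) != n_species) {
      stop("topology has ", length(topology$tip.label), " tips, expected ",
           n_species)
    }
  }
  structure(list(n_species = as.integer(n_species), sub_prob = sub_prob,
                 topology = topology, seed = as.integer(seed)),
            class = "divergence_spec")
}

# Substitute each site independently with probability p; substitutions are
# uniform over the three alternative bases. Frame-preserving (no indels).
mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p & ch %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- mapply(function(b, k) others[[b]][k], ch[hit], pick)
  }
  paste(ch, collapse = "")
}

#' Generate a diverged multi-species CDS set
#'
#' Draws one ancestral CDS from `spec` and evolves it into `div$n_species`
#' equal-length descendant sequences by per-site substitutions along the
#' given topology (or a star when none is given). Reading frame is preserved
#' (substitutions only, no indels).
#'
#' @param spec A [synthetic_spec()] (its first gene is the ancestor).
#' @param div A [divergence_spec()].
#' @param code Genetic code.
#' @return List of [cds_record()]s named by tip label (`species1 ...` for a
#'   star topology), all of equal length.
#' @export
generate_species_set <- function(spec, div,
                                 code = standard_genetic_code()) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(div, "divergence_spec"))
  anc <- generate_cds(spec, code)[[1]]$sequence
  withr::with_seed(div$seed, {
    if (is.null(div$topology)) {
      labs <- paste0("species", seq_len(div$n_species))
      seqs <- vapply(labs, function(l) mutate_sequence(anc, div$sub_prob), "")
    } else {
      tr <- div$topology
      n_tip <- length(tr$tip.label)
      has_len <- !is.null(tr$edge.length)
      node_seq <- vector("list", n_tip + tr$Nnode)
      root <- n_tip + 1L
      node_seq[[root]] <- anc
      ord <- ape::reorder.phylo(tr, "cladewise")
      for (e in seq_len(nrow(ord$edge))) {
        parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
        p_edge <- if (has_len) {
          min(div$sub_prob * ord$edge.length[e], 0.75)
        } else div$sub_prob
        node_seq[[child]] <- mutate_sequence(node_seq[[parent]], p_edge)
      }
      labs <- tr$tip.label
      seqs <- vapply(seq_len(n_tip), function(i) node_seq[[i]], "")
    }
    mapply(function(l, s) cds_record(l, s, description = l),
           labs, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  })
}

#' Canonical synthetic test fixture
#'
#' Materializes the package's standard end-to-end input: two gene sets of
#' seven species each, emulating a comparative survey of one gene with
#' moderate GC3 pressure and one with high GC3 pressure plus codon
#' selection. Both sets are equal-length within a set (NJ-ready).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_codons Codons per gene (default 600, a typical CDS scale).
#' @return Named character vector of the two FASTA paths
#'   (`geneA`, `geneB`), invisibly.
#' @export
write_fixture_set <- function(dir, seed, n_codons = 600L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  code <- standard_genetic_code()
  specA <- synthetic_spec(1, n_codons, gc3_pressure = 0.55, seed = seed)
  specB <- synthetic_spec(1, n_codons, gc3_pressure = 0.7,
                          selection_strength = 1,
                          optimal_set = vapply(
                            code$family_of[names(code$degeneracy)[
                              code$degeneracy >= 2 &
                                names(code$degeneracy) != "TER"]],
                            `[`, "", 1L),
                          seed = seed + 1L)
  divA <- divergence_spec(7, 0.04, seed = seed + 2L)
  divB <- divergence_spec(7, 0.06, seed = seed + 3L)
  paths <- c(geneA = file.path(dir, "geneA.fasta"),
             geneB = file.path(dir, "geneB.fasta"))
  write_cds_fasta(generate_species_set(specA, divA), paths[["geneA"]])
  write_cds_fasta(generate_species_set(specB, divB), paths[["geneB"]])
  invisible(paths)
}
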