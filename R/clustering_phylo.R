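#' Pairwise p-distances between aligned sequences
#'
#' Proportion of differing sites between every pair of equal-length (i.e.
#' pre-aligned) sequences, with pairwise deletion of positions where either
#' sequence carries `N` or a gap (`-`). Alignment itself is out of scope:
#' supply aligned FASTA or equal-length CDS.
#'
#' @param records List of [cds_record()] objects or a named character vector
#'   of sequences, all the same length, at least 2.
#' @return Symmetric numeric matrix with zero diagonal and sequence ids as
#'   dimnames.
#' @export
p_distance <- function(records) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    seqs <- toupper(chartr("Uu", "Tt", records))
  } else {
    ids <- vapply(records, `[[`, "", "id")
    seqs <- vapply(records, `[[`, "", "sequence")
  }
  if (length(seqs) < 2L) stop("p_distance needs at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths: ",
         paste(unique(lens), collapse = ", "), ")")
  }
  chm <- do.call(rbind, strsplit(seqs, ""))
  valid <- chm == "A" | chm == "C" | chm == "G" | chm == "T"
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) {
        warning("no comparable sites between '", ids[i], "' and '", ids[j],
                "'")
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- mean(chm[i, ok] != chm[j, ok])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' Q(i,j) = (r-2) d(i,j) - R_i - R_j. Ties in Q break deterministically
#' toward the smallest (i, j) pair in current node order. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch, so the pairwise distance of the joined pair is preserved. The
#' result is the usual unrooted tree with a basal trifurcation.
#'
#' @param d Symmetric numeric matrix with labels as dimnames (or a `dist`
#'   object), at least 3 taxa.
#' @return An [ape][ape::read.tree] `phylo` object.
#' @examples
#' d <- matrix(c(0, 3, 8, 9, 3, 0, 9, 10, 8, 9, 0, 9, 9, 10, 9, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)$tip.label
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (anyNA(d)) stop("distance matrix contains NA")

  frag <- rownames(d)
  D <- unname(d)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    dij <- D[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], bi, frag[j], bj)
    dk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
  }
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  b <- c((dab + dac - dbc) / 2, (dab + dbc - dac) / 2,
         (dac + dbc - dab) / 2)
  b <- pmax(b, 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], b[1], frag[2], b[2], frag[3], b[3])
  ape::read.tree(text = nwk)
}

#' Hierarchical clustering of a species-by-codon RSCU matrix
#'
#' Agglomerative clustering of species by their RSCU profiles, the analysis
#' behind RSCU heat-map dendrograms. Undefined RSCU cells are imputed as 0
#' with a message (an unobserved family is treated as total avoidance).
#'
#' @param mat Numeric matrix, species in rows (rownames required), codons in
#'   columns; at least 2 rows.
#' @param distance Distance metric; only `"euclidean"`.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return A [stats::hclust] object (fields `merge`, `height`, `order`,
#'   `labels`).
#' @export
hierarchical_cluster <- function(mat, distance = "euclidean",
                                 linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance, "euclidean")
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("clustering needs at least 2 rows")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  if (anyNA(mat)) {
    message("imputing ", sum(is.na(mat)), " undefined RSCU cell(s) as 0")
    mat[is.na(mat)] <- 0
  }
  stats::hclust(stats::dist(mat, method = distance), method = linkage)
}

#' Dendrogram merge table
#'
#' Serializes an `hclust` result as a TSV-ready data.frame: one row per
#' merge with the two joined items (negative = leaf index, positive = prior
#' merge) and the merge height, plus the leaf order as an attribute.
#'
#' @param h An `hclust` object.
#' @return Data.frame `step`, `left`, `right`, `height`; attribute
#'   `leaf_order` gives labels in plotting order.
#' @export
merge_table <- function(h) {
  stopifnot(inherits(h, "hclust"))
  out <- data.frame(step = seq_along(h$height),
                    left = h$merge[, 1], right = h$merge[, 2],
                    height = h$height)
  attr(out, "leaf_order") <- h$labels[h$order]
  out
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (the symmetric-difference metric). Both trees must have
#' identical leaf label sets.
#'
#' @param t1,t2 `phylo` objects (or `hclust`, converted via [ape::as.phylo]).
#' @return Non-negative integer.
#' @export
compare_trees <- function(t1, t2) {
  as_phy <- function(t) if (inherits(t, "hclust")) ape::as.phylo(t) else t
  t1 <- as_phy(t1); t2 <- as_phy(t2)
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf label sets")
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Non-trivial splits of an unrooted tree, canonicalized so that each split
# is represented by the side NOT containing the alphabetically first tip.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  n <- length(tips)
  out <- character(0)
  for (k in seq_along(parts)) {
    clade <- tips[parts[[k]]]
    if (length(clade) >= n - 1L) next   # root/full set: trivial
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Read and write square PHYLIP distance matrices
#'
#' Standard square PHYLIP format: a first line with the number of taxa, then
#' one row per taxon (label followed by all distances, whitespace-separated).
#'
#' @param path File path.
#' @return `read_phylip_dist()` returns a labelled symmetric matrix;
#'   `write_phylip_dist()` returns `path` invisibly.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1L) {
    stop("malformed PHYLIP distance file: ", path)
  }
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labs[i] <- tok[1]
    d[i, ] <- as.numeric(tok[-1][seq_len(n)])
  }
  dimnames(d) <- list(labs, labs)
  d
}

#' @rdname read_phylip_dist
#' @param d Labelled symmetric matrix.
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labs <- rownames(d)
  lines <- c(format(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(formatC(labs[i], width = -10),
                       sprintf("%.6f", d[i, ])), collapse = " ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
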