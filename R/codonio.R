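#' Construct a CDS record
#'
#' A light container for one coding sequence. RNA input is normalized to the
#' DNA alphabet (U to T) and lower case is upper-cased; only the characters
#' `A`, `C`, `G`, `T`, `N` may remain.
#'
#' @param id Sequence identifier (first whitespace-delimited header token).
#' @param sequence Nucleotide string.
#' @param description Full header line text (may equal `id`).
#' @return An object of class `cds_record` with fields `id`, `description`,
#'   `sequence` and `length_nt`.
#' @export
cds_record <- function(id, sequence, description = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  seq <- toupper(chartr("Uu", "Tt", sequence))
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("record '", id, "' contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  }
  structure(
    list(id = id, description = description, sequence = seq,
         length_nt = nchar(seq)),
    class = "cds_record"
  )
}

#' @export
print.cds_record <- function(x, ...) {
  cat("<cds_record>", x$id, paste0("(", x$length_nt, " nt)"), "\n")
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file of coding sequences. Headers may be wrapped or
#' unwrapped; the record id is the first whitespace-delimited token of the
#' header. RNA sequences are normalized to DNA spelling.
#'
#' @param path Path to a FASTA file.
#' @return A list of [cds_record()] objects, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 demo", "ATGTGGTAA"), fa)
#' read_cds_fasta(fa)[[1]]$length_nt
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a valid FASTA file (", path, "): ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  heads <- names(set)
  ids <- sub("\\s.*$", "", heads)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) at record ",
         which(!nzchar(ids))[1], " of ", path)
  }
  seqs <- as.character(set)
  mapply(function(i, d, s) cds_record(i, s, description = d),
         ids, heads, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write CDS records as multi-FASTA
#'
#' @param records List of [cds_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$description), con)
    starts <- seq(1L, r$length_nt, by = width)
    writeLines(substring(r$sequence, starts,
                         pmin(starts + width - 1L, r$length_nt)), con)
  }
  invisible(path)
}

#' Tabulate codon usage of one CDS
#'
#' Splits a coding sequence into consecutive, non-overlapping triplets from
#' position 1 and counts each of the 64 codons. Triplets containing `N` are
#' skipped (counted in `n_skipped`). Internal stop codons are counted but
#' raise a warning, so that stop rows can still flow into pooled RSCU tables.
#'
#' @param record A [cds_record()], or a single nucleotide string.
#' @param code A [standard_genetic_code()] object.
#' @param frame_policy `"strict"` (default) errors when the length is not a
#'   multiple of 3; `"trim"` drops 1-2 trailing nucleotides with a warning.
#' @return An object of class `codon_count_table`: list with `gene_id`,
#'   `counts` (named integer vector over all 64 codons, canonical order,
#'   DNA alphabet), `n_codons` and `n_skipped`.
#' @examples
#' cc <- codon_counts(cds_record("g1", "ATGTGGTAA"))
#' cc$counts[c("ATG", "TGG", "TAA")]
#' @export
codon_counts <- function(record, code = standard_genetic_code(),
                         frame_policy = c("strict", "trim")) {
  frame_policy <- match.arg(frame_policy)
  if (is.character(record)) record <- cds_record("unnamed", record)
  stopifnot(inherits(record, "cds_record"))
  seq <- record$sequence
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    if (frame_policy == "strict") {
      stop("length of record '", record$id, "' (", n,
           " nt) is not a multiple of 3; use frame_policy = \"trim\" to drop ",
           "trailing bases")
    }
    warning("trimming ", n %% 3L, " trailing nt from record '", record$id, "'")
    seq <- substr(seq, 1L, n - n %% 3L)
    n <- nchar(seq)
  }
  starts <- seq.int(1L, n, by = 3L)
  triplets <- substring(seq, starts, starts + 2L)
  has_n <- grepl("N", triplets, fixed = TRUE)
  counted <- triplets[!has_n]
  counts <- stats::setNames(integer(64L), code$codon_order)
  if (length(counted)) {
    tab <- table(factor(counted, levels = code$codon_order))
    counts[] <- as.integer(tab)
  }
  aa <- code$codon_to_aa[counted]
  internal_stop <- which(aa == "TER")
  internal_stop <- internal_stop[internal_stop < length(triplets)]
  if (length(internal_stop)) {
    warning("record '", record$id, "' has ", length(internal_stop),
            " internal stop codon(s)")
  }
  structure(
    list(gene_id = record$id, counts = counts,
         n_codons = length(counted), n_skipped = sum(has_n)),
    class = "codon_count_table"
  )
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat("<codon_count_table>", x$gene_id, "-", x$n_codons, "codons",
      if (x$n_skipped) paste0("(", x$n_skipped, " skipped)"), "\n")
  invisible(x)
}

#' Write codon count tables as TSV
#'
#' One row per gene and codon, columns `gene_id`, `amino_acid`, `codon`
#' (RNA alphabet) and `count`, in canonical codon order.
#'
#' @param tables List of `codon_count_table` objects (or a single one).
#' @param path Output path.
#' @param code Genetic code.
#' @return `path`, invisibly.
#' @export
write_codon_counts_tsv <- function(tables, path,
                                   code = standard_genetic_code()) {
  if (inherits(tables, "codon_count_table")) tables <- list(tables)
  rows <- lapply(tables, function(ct) {
    data.frame(gene_id = ct$gene_id,
               amino_acid = unname(code$codon_to_aa[code$codon_order]),
               codon = codon_to_rna(code$codon_order),
               count = unname(ct$counts[code$codon_order]),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
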