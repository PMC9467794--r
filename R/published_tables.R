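#' Published MMP-2/MMP-9 codon-usage survey tables
#'
#' Summary statistics from a published seven-mammal survey of the matrix
#' metalloproteinase genes MMP-2 and MMP-9 (Bos grunniens, B. taurus,
#' Macaca mulatta, Mus musculus, Oryctolagus cuniculus, Sus scrofa and
#' Canis lupus familiaris), shipped as plain-text reference data: per-species
#' nucleotide composition (whole-gene A/T and G/C, per-base third-position
#' fractions, GC3s/AT3s), codon-usage indices (ENC, CAI, CBI, FOP,
#' GC1s/GC2s/GC12) and the pooled cross-species RSCU tables.
#'
#' These are the package's desk-scale reference inputs: the correlation,
#' ENC-plot and RSCU-identity checks in the test suite recompute the
#' survey's derived results from these printed values.
#'
#' @param gene `"MMP2"` or `"MMP9"`.
#' @return List with data.frames `composition` (per species), `indices`
#'   (per species) and `rscu` (pooled across species, RNA codons).
#' @examples
#' tabs <- published_mmp_tables("MMP2")
#' cor(tabs$composition$gc3s, tabs$indices$enc)
#' @export
published_mmp_tables <- function(gene = c("MMP2", "MMP9")) {
  gene <- match.arg(gene)
  stem <- tolower(gene)
  rd <- function(part) {
    utils::read.table(
      system.file("extdata", paste0(stem, "_", part, ".tsv"),
                  package = "cubtools", mustWork = TRUE),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  list(composition = rd("composition"), indices = rd("indices"),
       rscu = rd("rscu"))
}
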