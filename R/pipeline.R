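#' Build a run configuration
#'
#' Collects the inputs and convention settings that drive
#' [run_full_analysis()]. Every convention value is validated against its
#' enumerated set at construction time.
#'
#' @param inputs Named character vector/list: gene-set name to CDS FASTA
#'   path. Paths must exist.
#' @param out_dir Output directory (created if needed).
#' @param x3s_convention `"per_base_denominator"` or `"simple"`.
#' @param pr2_mode `"fourfold"` or `"all3"`.
#' @param linkage `"complete"` or `"average"`.
#' @param cai_floor CAI weight floor (default 0.01).
#' @param frame_policy `"strict"` or `"trim"`.
#' @param optimal_file,weights_file Optional two-column codon/value files
#'   (see [read_codon_values()]); when absent both sets are derived from the
#'   analysed data.
#' @return An object of class `run_config`.
#' @export
run_config <- function(inputs, out_dir,
                       x3s_convention = c("per_base_denominator", "simple"),
                       pr2_mode = c("fourfold", "all3"),
                       linkage = c("complete", "average"),
                       cai_floor = 0.01,
                       frame_policy = c("strict", "trim"),
                       optimal_file = NULL, weights_file = NULL) {
  inputs <- unlist(inputs)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    stop("inputs must be a named vector: gene-set name -> FASTA path")
  }
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("input FASTA not found: ", paste(missing, collapse = ", "))
  }
  for (f in c(optimal_file, weights_file)) {
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
  }
  structure(
    list(inputs = inputs, out_dir = out_dir,
         x3s_convention = match.arg(x3s_convention),
         pr2_mode = match.arg(pr2_mode),
         linkage = match.arg(linkage),
         cai_floor = cai_floor,
         frame_policy = match.arg(frame_policy),
         optimal_file = optimal_file, weights_file = weights_file),
    class = "run_config"
  )
}

#' Read a run configuration from a key-value file
#'
#' Flat Debian-control-style (`key: value`) configuration. Recognized keys:
#' `input.<name>` (one per gene set), `out_dir`, `x3s_convention`,
#' `pr2_mode`, `linkage`, `cai_floor`, `frame_policy`, `optimal_file`,
#' `weights_file`. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  # option keys are case-insensitive; input.<name> keeps the set name's case
  opt <- !grepl("^[Ii]nput\\.", names(kv))
  names(kv)[opt] <- tolower(names(kv)[opt])
  names(kv) <- sub("^[Ii]nput\\.", "input.", names(kv))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  in_keys <- grep("^input\\.", names(kv), value = TRUE)
  if (!length(in_keys)) stop("config defines no input.<name> entries")
  inputs <- stats::setNames(resolve(unlist(kv[in_keys])),
                            sub("^input\\.", "", in_keys))
  get <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  run_config(
    inputs = inputs,
    out_dir = resolve(get("out_dir", file.path(base, "cub_out"))),
    x3s_convention = get("x3s_convention", "per_base_denominator"),
    pr2_mode = get("pr2_mode", "fourfold"),
    linkage = get("linkage", "complete"),
    cai_floor = as.numeric(get("cai_floor", 0.01)),
    frame_policy = get("frame_policy", "strict"),
    optimal_file = if (!is.null(kv$optimal_file)) resolve(kv$optimal_file),
    weights_file = if (!is.null(kv$weights_file)) resolve(kv$weights_file)
  )
}

# TSV writer with floats fixed at 6 decimals (comparisons are always done on
# full-precision objects, only the files are rounded).
write_tsv6 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (cl in names(df)[num]) {
    df[[cl]] <- ifelse(is.na(df[[cl]]), "NA", sprintf("%.6f", df[[cl]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full codon-usage-bias workflow
#'
#' Executes, per gene set: codon counting, composition profiles, per-species
#' and pooled RSCU tables, the ENC/CAI/CBI/FOP index table, PR2 points, the
#' neutrality regression, ENC-plot classification, the per-codon RSCU-GC3s
#' correlation matrix, RSCU hierarchical clustering, and (when sequences are
#' equal length) a neighbor-joining tree on p-distances. All tables are
#' written as TSV into `config$out_dir/<set>/`, trees as Newick, plus a
#' machine-readable `summary.json` that records every convention used.
#' Correlation stages need at least 3 sequences; with fewer they are marked
#' `skipped` in the summary rather than aborting the bundle.
#'
#' @param config A [run_config()] or path to a config file.
#' @return Invisibly, a named list per gene set with the computed objects,
#'   output file paths (`files`) and skipped-stage notes (`skipped`).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  code <- standard_genetic_code()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ext_optimal <- if (!is.null(config$optimal_file)) {
    names(read_codon_values(config$optimal_file))
  }
  ext_weights <- if (!is.null(config$weights_file)) {
    read_codon_values(config$weights_file)
  }

  bundle <- list()
  for (set in names(config$inputs)) {
    set_dir <- file.path(config$out_dir, set)
    dir.create(set_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    skipped <- character(0)
    res <- list()
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed for gene set '", set, "': ",
             conditionMessage(e), call. = FALSE)
      })
    }

    records <- stage("read", read_cds_fasta(config$inputs[[set]]))
    counts <- stage("count", lapply(records, codon_counts, code = code,
                                    frame_policy = config$frame_policy))
    n_seq <- length(records)

    res$composition <- stage("composition", composition_table(
      counts, code = code, x3s_convention = config$x3s_convention))
    files["composition"] <- write_tsv6(
      res$composition, file.path(set_dir, "composition.tsv"))

    rscus <- stage("rscu", lapply(counts, rscu, code = code,
                                  include_stops = TRUE))
    per_gene <- do.call(rbind, lapply(rscus, function(t) {
      cbind(gene_id = attr(t, "gene_id"), as.data.frame(t))
    }))
    files["rscu_per_gene"] <- write_tsv6(
      per_gene, file.path(set_dir, "rscu_per_gene.tsv"))
    res$rscu_mean <- stage("rscu", mean_rscu(rscus, set_id = set))
    files["rscu_mean"] <- write_tsv6(
      as.data.frame(res$rscu_mean), file.path(set_dir, "rscu_mean.tsv"))

    res$indices <- stage("indices", cub_index_table(
      counts, optimal = ext_optimal, weights = ext_weights,
      cai_floor = config$cai_floor, code = code))
    files["indices"] <- write_tsv6(
      res$indices, file.path(set_dir, "indices.tsv"))

    res$pr2 <- stage("pr2", do.call(rbind, lapply(counts, function(ct) {
      p <- pr2_point(ct, code = code, mode = config$pr2_mode)
      data.frame(gene_id = p$gene_id, x = p$x, y = p$y, mode = p$mode,
                 stringsAsFactors = FALSE)
    })))
    files["pr2"] <- write_tsv6(res$pr2, file.path(set_dir, "pr2_points.tsv"))

    if (n_seq >= 3) {
      res$neutrality <- stage("neutrality", neutrality_analysis(
        res$indices$gc12, res$composition$gc3s))
      files["neutrality"] <- write_tsv6(
        with(res$neutrality,
             data.frame(r = r, p_two_sided = p_two_sided, n = n,
                        slope = slope, intercept = intercept)),
        file.path(set_dir, "neutrality.tsv"))
    } else skipped <- c(skipped, "neutrality: n<3")

    ep_in <- data.frame(gene_id = res$composition$gene_id,
                        gc3s = res$composition$gc3s,
                        enc = res$indices$enc)
    res$enc_plot <- stage("encplot", enc_plot(ep_in))
    files["encplot_points"] <- write_tsv6(
      res$enc_plot, file.path(set_dir, "encplot_points.tsv"))
    files["encplot_curve"] <- write_tsv6(
      attr(res$enc_plot, "curve"), file.path(set_dir, "encplot_curve.tsv"))

    if (n_seq >= 3) {
      res$codon_cor <- stage("codon_correlation", codon_gc3s_correlations(
        rscus, res$composition$gc3s, code = code))
      files["codon_correlation"] <- write_tsv6(
        res$codon_cor, file.path(set_dir, "codon_gc3s_correlation.tsv"))
    } else skipped <- c(skipped, "codon_correlation: n<3")

    if (n_seq >= 2) {
      sense <- rscus[[1]]$amino_acid != "TER"
      m <- t(vapply(rscus, function(t) t$rscu[sense],
                    numeric(sum(sense))))
      rownames(m) <- vapply(counts, `[[`, "", "gene_id")
      colnames(m) <- rscus[[1]]$codon[sense]
      res$cluster <- stage("cluster", hierarchical_cluster(
        m, linkage = config$linkage))
      mt <- merge_table(res$cluster)
      files["dendrogram"] <- write_tsv6(
        mt, file.path(set_dir, "rscu_dendrogram.tsv"))
      files["dendrogram_newick"] <- file.path(set_dir, "rscu_dendrogram.nwk")
      ape::write.tree(ape::as.phylo(res$cluster),
                      files[["dendrogram_newick"]])
    } else skipped <- c(skipped, "cluster: n<2")

    lens <- vapply(records, `[[`, 0L, "length_nt")
    if (n_seq >= 3 && length(unique(lens)) == 1L) {
      res$nj <- stage("njtree", neighbor_joining(p_distance(records)))
      files["nj_newick"] <- file.path(set_dir, "nj_tree.nwk")
      ape::write.tree(res$nj, files[["nj_newick"]])
    } else {
      skipped <- c(skipped, "njtree: needs >=3 equal-length sequences")
    }

    summary <- list(
      gene_set = set, n_sequences = n_seq,
      conventions = list(x3s_convention = config$x3s_convention,
                         pr2_mode = config$pr2_mode,
                         linkage = config$linkage,
                         cai_floor = config$cai_floor,
                         frame_policy = config$frame_policy,
                         optimal_source = if (is.null(ext_optimal))
                           "derived" else "file",
                         weights_source = if (is.null(ext_weights))
                           "derived" else "file"),
      neutrality = if (!is.null(res$neutrality)) {
        res$neutrality[c("r", "p_two_sided", "n", "slope", "intercept")]
      },
      enc_gc3s_pearson = if (n_seq >= 3) {
        pc <- pearson_cor(res$composition$gc3s, res$indices$enc)
        pc[c("r", "p_two_sided", "n")]
      },
      n_below_curve = sum(res$enc_plot$position == "below"),
      skipped = as.list(skipped)
    )
    files["summary"] <- file.path(set_dir, "summary.json")
    jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")

    res$files <- files
    res$skipped <- skipped
    bundle[[set]] <- res
  }
  invisible(bundle)
}
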