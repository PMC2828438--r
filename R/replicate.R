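#' Run the whole rare-codon study workflow on a corpus
#'
#' One call wiring every stage together for a genome's CDS set: pair
#' counting, P1/P2 testing and rare/normal classification, hypergeometric
#' codon ranking, per-gene indices (F_rare, CAI, CBI, Fop) with their
#' pairwise rank correlations, the whole-set vs subset codon-usage-pattern
#' correlation, and the Mann-Whitney comparison of F_rare between a gene
#' subset (e.g. essential genes) and the rest.
#'
#' @param cds CDS tibble from [read_cds_fasta()] (invalid records are
#'   dropped with a message).
#' @param subset_ids Optional character vector of gene ids forming the
#'   comparison subset (e.g. essential genes).
#' @param alpha,alpha_codon,p2_model Passed to [test_codon_pairs()] and
#'   [codon_contribution()].
#' @param cai_weights,optimal_codons Passed to [gene_indices()].
#' @param motifs Motif table for [annotate_pairs()]; `NULL` skips
#'   annotation.
#' @param code Genetic-code tibble.
#' @return A list of class `rarecodon_study` with elements `pair_tests`,
#'   `contributions`, `rare_codons`, `gene_indices`, `index_correlations`,
#'   `annotation`, and (when `subset_ids` is given) `usage_correlation`
#'   (a `spearman_cor` of the subset's within-family usage pattern against
#'   the whole set's) and `subset_test` (a `mann_whitney` on F_rare).
#' @export
run_study <- function(cds, subset_ids = NULL, alpha = 0.01,
                      alpha_codon = 0.01 / 64, p2_model = "uniform",
                      cai_weights = ecoli_cai_weights(),
                      optimal_codons = ecoli_optimal_codons(),
                      motifs = default_motifs(),
                      code = genetic_code()) {
  cds <- valid_cds(cds)
  if (nrow(cds) == 0L) stop("no valid CDS in input", call. = FALSE)

  counts <- count_codon_pairs(cds, code = code)
  tests <- test_codon_pairs(counts, alpha = alpha, p2_model = p2_model,
    code = code)
  contrib <- codon_contribution(tests, alpha_codon = alpha_codon, code = code)
  rare <- identify_rare_codons(contrib)
  idx <- gene_indices(cds, rare,
    cai_weights = cai_weights,
    optimal_codons = optimal_codons, code = code
  )
  cors <- index_correlations(idx)
  ann <- if (is.null(motifs)) NULL else annotate_pairs(tests, motifs = motifs)

  usage_cor <- NULL
  subset_test <- NULL
  if (!is.null(subset_ids)) {
    sub <- cds[cds$gene_id %in% subset_ids, ]
    if (nrow(sub) == 0L) {
      warning("no subset ids matched the corpus; skipping subset analyses")
    } else {
      whole <- usage_pattern(cds, code)
      part <- usage_pattern(sub, code)
      usage_cor <- spearman_cor(whole$rel_usage, part$rel_usage)
      subset_test <- compare_groups(idx, subset_ids, value = "f_rare",
        labels = c("subset", "rest"))
    }
  }
  structure(
    list(
      pair_tests = tests,
      contributions = contrib,
      rare_codons = rare,
      gene_indices = idx,
      index_correlations = cors,
      annotation = ann,
      usage_correlation = usage_cor,
      subset_test = subset_test
    ),
    class = "rarecodon_study"
  )
}

#' @export
print.rarecodon_study <- function(x, ...) {
  g <- glance(x$pair_tests)
  cat("Rare-codon study\n")
  cat(sprintf("  genes: %d; pairs rare/normal/excluded: %d/%d/%d (P0 = %.4g)\n",
    g$n_genes, g$n_rare, g$n_normal, g$n_excluded, g$p0))
  cat("  rare codons: ", paste(x$rare_codons, collapse = " "), "\n")
  fc <- dplyr::filter(x$index_correlations,
    .data$var1 == "f_rare", .data$var2 == "cai")
  if (nrow(fc) == 1L) {
    cat(sprintf("  Spearman(F_rare, CAI) = %.3f\n", fc$rho))
  }
  invisible(x)
}

#' Write the study's tables to a directory
#'
#' Emits `pairs.tsv` (4096 rows), `codons.tsv` (64 rows), `genes.tsv` (one
#' row per gene), `compare.tsv` (index correlations), `annotations.tsv`
#' and `run.json` (provenance: counts, cutoff, parameters).
#'
#' @param study A `rarecodon_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @param config Optional named list echoed into `run.json`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(study$pair_tests, file.path(dir, "pairs.tsv"))
  readr::write_tsv(study$contributions, file.path(dir, "codons.tsv"))
  readr::write_tsv(study$gene_indices, file.path(dir, "genes.tsv"))
  readr::write_tsv(study$index_correlations, file.path(dir, "compare.tsv"))
  if (!is.null(study$annotation)) {
    readr::write_tsv(study$annotation$pairs, file.path(dir, "annotations.tsv"))
  }
  g <- glance(study$pair_tests)
  run <- c(
    as.list(g),
    list(rare_codons = study$rare_codons, config = config)
  )
  jsonlite::write_json(run, file.path(dir, "run.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
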