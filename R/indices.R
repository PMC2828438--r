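codon_count_matrix <- function(seq) {
  Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(seq), step = 3L)
}

#' F_rare: the per-gene frequency of rare codons
#'
#' The fraction of a gene's codons (terminal stop included when present)
#' that belong to the rare-codon set: F_rare = sum_i n_i(g) / N over rare
#' codons i, with N the total codon count of gene g. Unlike CAI/CBI/Fop it
#' needs no expression reference set. The weighted variant multiplies each
#' rare codon's count by syn(i)/6, down-weighting small synonymous families.
#'
#' @param seq Character vector of in-frame nucleotide sequences.
#' @param rare_codons Non-empty character vector of rare codons.
#' @param code Genetic-code tibble.
#' @param weighted If `TRUE`, weight each count by syn(i)/6.
#' @return Numeric vector of values in \[0, 1\]; exactly 0 when no rare
#'   codon occurs.
#' @examples
#' f_rare("ATGGGAGGAAAATAA", rare_codons = c("GGA", "AGG")) # 2/5
#' @export
f_rare <- function(seq, rare_codons, code = genetic_code(), weighted = FALSE) {
  if (length(rare_codons) == 0L) {
    stop("rare codon set is empty", call. = FALSE)
  }
  if (any(!nzchar(seq))) stop("empty gene sequence", call. = FALSE)
  m <- codon_count_matrix(seq)
  n <- rowSums(m)
  w <- rep(1, length(rare_codons))
  if (weighted) w <- codon_degeneracy(rare_codons, code) / 6
  as.vector(m[, rare_codons, drop = FALSE] %*% w) / n
}

cai_included <- function(code) {
  code$aa != "*" & !code$codon %in% c("ATG", "TGG")
}

weights_vector <- function(weights, code) {
  if (is.data.frame(weights)) {
    w <- stats::setNames(weights$weight, weights$codon)
  } else {
    w <- weights
  }
  w <- w[code$codon]
  names(w) <- code$codon
  w
}

#' Codon Adaptation Index (CAI)
#'
#' Geometric mean of the relative adaptiveness w of a gene's codons,
#' excluding ATG, TGG and stop codons from the product (the conventional
#' treatment, since those offer no synonymous choice).
#'
#' @param seq Character vector of in-frame nucleotide sequences.
#' @param weights Named numeric vector or a tibble with columns `codon`,
#'   `weight` giving relative adaptiveness in (0, 1]; defaults to the
#'   packaged E. coli reference table ([ecoli_cai_weights()]).
#' @param code Genetic-code tibble.
#' @return Numeric vector of CAI values in (0, 1].
#' @export
cai <- function(seq, weights = ecoli_cai_weights(), code = genetic_code()) {
  m <- codon_count_matrix(seq)
  inc <- cai_included(code)
  w <- weights_vector(weights, code)
  used <- colSums(m[, inc, drop = FALSE]) > 0
  if (any(is.na(w[inc][used]) | w[inc][used] <= 0)) {
    stop("missing or non-positive CAI weight for a codon present in input",
      call. = FALSE
    )
  }
  logw <- ifelse(is.na(w) | w <= 0, 0, log(w))
  logw[!inc] <- 0
  n_inc <- rowSums(m[, inc, drop = FALSE])
  if (any(n_inc == 0)) {
    stop("gene with no CAI-countable codons", call. = FALSE)
  }
  exp(as.vector(m %*% logw) / n_inc)
}

degenerate_cols <- function(code) {
  code$aa != "*" & code$syn >= 2L
}

#' Frequency of optimal codons (Fop)
#'
#' N_opt / N_syn, where N_syn counts the gene's codons in degenerate
#' (multi-codon, non-stop) families and N_opt those that are optimal.
#'
#' @param seq Character vector of in-frame nucleotide sequences.
#' @param optimal_codons Character vector of optimal codons; defaults to
#'   the packaged E. coli set ([ecoli_optimal_codons()]).
#' @param code Genetic-code tibble.
#' @return Numeric vector of values in \[0, 1\].
#' @export
fop <- function(seq, optimal_codons = ecoli_optimal_codons(),
                code = genetic_code()) {
  m <- codon_count_matrix(seq)
  deg <- degenerate_cols(code)
  n_syn <- rowSums(m[, deg, drop = FALSE])
  if (any(n_syn == 0)) {
    stop("gene with no degenerate-family codons", call. = FALSE)
  }
  opt <- deg & code$codon %in% optimal_codons
  rowSums(m[, opt, drop = FALSE]) / n_syn
}

#' Codon Bias Index (CBI)
#'
#' (N_opt - N_rand) / (N_tot - N_rand), where N_tot counts codons in
#' degenerate families, N_opt those that are optimal, and N_rand the
#' expected optimal count under uniform synonymous usage
#' (sum over families of n_f * optimal_f / size_f). 1 means exclusive use
#' of optimal codons, 0 random usage, negative values avoidance.
#'
#' @inheritParams fop
#' @return Numeric vector in \[-inf, 1\], typically \[-1, 1\].
#' @export
cbi <- function(seq, optimal_codons = ecoli_optimal_codons(),
                code = genetic_code()) {
  m <- codon_count_matrix(seq)
  deg <- degenerate_cols(code)
  n_tot <- rowSums(m[, deg, drop = FALSE])
  if (any(n_tot == 0)) {
    stop("gene with no degenerate-family codons", call. = FALSE)
  }
  opt <- deg & code$codon %in% optimal_codons
  n_opt <- rowSums(m[, opt, drop = FALSE])
  # per-codon expected-optimal fraction: share of its family that is optimal
  opt_frac <- vapply(seq_len(nrow(code)), function(i) {
    fam <- code$codon[code$aa == code$aa[i]]
    sum(fam %in% optimal_codons) / length(fam)
  }, numeric(1))
  opt_frac[!deg] <- 0
  n_rand <- as.vector(m %*% opt_frac)
  denom <- n_tot - n_rand
  ifelse(abs(denom) < .Machine$double.eps, NA_real_, (n_opt - n_rand) / denom)
}

#' Per-gene codon-bias index table
#'
#' Computes F_rare (plain and syn-weighted), CAI, CBI and Fop for every
#' valid CDS in a gene set.
#'
#' @param cds CDS tibble (valid rows only; see [valid_cds()]).
#' @param rare_codons Character vector of rare codons, e.g. from
#'   [identify_rare_codons()].
#' @param cai_weights CAI relative-adaptiveness table (see [cai()]).
#' @param optimal_codons Optimal-codon set (see [fop()]).
#' @param code Genetic-code tibble.
#' @return A tibble with one row per gene: `gene_id`, `n_codons`,
#'   `rare_count`, `f_rare`, `f_rare_w`, `cai`, `cbi`, `fop`.
#' @export
gene_indices <- function(cds, rare_codons,
                         cai_weights = ecoli_cai_weights(),
                         optimal_codons = ecoli_optimal_codons(),
                         code = genetic_code()) {
  if (!all(cds$is_valid_cds)) {
    stop("input contains invalid CDS; filter with valid_cds() first",
      call. = FALSE
    )
  }
  m <- codon_count_matrix(cds$seq)
  tibble::tibble(
    gene_id = cds$gene_id,
    n_codons = as.integer(rowSums(m)),
    rare_count = as.integer(rowSums(m[, rare_codons, drop = FALSE])),
    f_rare = f_rare(cds$seq, rare_codons, code),
    f_rare_w = f_rare(cds$seq, rare_codons, code, weighted = TRUE),
    cai = cai(cds$seq, cai_weights, code),
    cbi = cbi(cds$seq, optimal_codons, code),
    fop = fop(cds$seq, optimal_codons, code)
  )
}

#' Pooled within-family codon usage pattern
#'
#' Relative usage of each codon within its synonymous family over a pooled
#' gene set (the 64-value pattern used for corpus-to-corpus rank
#' correlations). Families never observed in the corpus get a uniform
#' placeholder value 1/syn and are flagged.
#'
#' @param cds CDS tibble (valid rows only).
#' @param code Genetic-code tibble.
#' @return A 64-row tibble: `codon`, `aa`, `count`, `family_total`,
#'   `rel_usage`, `family_observed`.
#' @export
usage_pattern <- function(cds, code = genetic_code()) {
  if (nrow(cds) == 0L) stop("empty coding-sequence set", call. = FALSE)
  counts <- colSums(codon_count_matrix(cds$seq))
  tibble::tibble(codon = names(counts), count = as.integer(counts)) |>
    dplyr::left_join(code, by = "codon") |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      family_total = sum(.data$count),
      family_observed = .data$family_total > 0L,
      rel_usage = dplyr::if_else(
        .data$family_observed,
        .data$count / .data$family_total,
        1 / .data$syn
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "codon", "aa", "count", "family_total", "rel_usage", "family_observed"
    )
}

#' Packaged E. coli CAI reference weights
#'
#' The classical E. coli relative-adaptiveness table (Sharp & Li 1987),
#' the same reference CodonW uses by default. Replace with your own TSV
#' (`codon`, `weight`) via `read_cai_weights()` for other organisms.
#'
#' @return A tibble with columns `codon`, `weight`.
#' @export
ecoli_cai_weights <- function() {
  read_cai_weights(system.file("extdata", "ecoli_cai_weights.tsv",
    package = "rarecodon", mustWork = TRUE
  ))
}

#' Read a CAI weight table from TSV
#'
#' @param path TSV with columns `codon`, `weight`; `#` comments allowed.
#' @return A tibble with columns `codon`, `weight`.
#' @export
read_cai_weights <- function(path) {
  readr::read_tsv(path,
    comment = "#",
    col_types = readr::cols(codon = "c", weight = "d")
  ) |>
    dplyr::mutate(codon = gsub("U", "T", toupper(.data$codon), fixed = TRUE))
}

#' Packaged E. coli optimal-codon set
#'
#' The optimal codons of E. coli as used by CodonW for Fop/CBI (the
#' Ikemura set). Replace with a plain-text list (one codon per line) for
#' other organisms.
#'
#' @return Character vector of codons.
#' @export
ecoli_optimal_codons <- function() {
  read_gene_list(system.file("extdata", "ecoli_optimal_codons.txt",
    package = "rarecodon", mustWork = TRUE
  ))
}
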