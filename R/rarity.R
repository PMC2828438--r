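#' Encoding-rule null probability of a codon pair
#'
#' Under random synonymous codon usage, a dipeptide is encoded by each
#' compatible codon pair with probability 1 / (syn(c1) * syn(c2)), where
#' `syn` is the degeneracy of each codon's family.
#'
#' @param hexamer Character vector of six-nucleotide strings.
#' @param code Genetic-code tibble from [genetic_code()].
#' @return Numeric vector of null probabilities.
#' @examples
#' pair_null_prob(c("CTGATG", "ATGTGG", "GGAGGA")) # 1/6, 1, 1/16
#' @export
pair_null_prob <- function(hexamer, code = genetic_code()) {
  syn <- syn_lookup(code)
  s1 <- syn[substr(hexamer, 1L, 3L)]
  s2 <- syn[substr(hexamer, 4L, 6L)]
  if (anyNA(s1) || anyNA(s2)) {
    stop("invalid hexamer(s)", call. = FALSE)
  }
  unname(1 / (s1 * s2))
}

#' Lower-tail binomial probability
#'
#' P(X <= k) for X ~ Binomial(n, p): the probability of seeing at most the
#' observed count under the null. Computed with the regularized
#' incomplete-beta routine behind [stats::pbinom], stable for n up to 1e7
#' and small p.
#'
#' @param k Observed count(s), 0 <= k <= n.
#' @param n Number of trials.
#' @param p Success probability.
#' @return Numeric vector of tail probabilities.
#' @export
binom_lower_tail <- function(k, n, p) {
  if (any(k < 0) || any(n < 0) || any(k > n)) {
    stop("need 0 <= k <= n", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  stats::pbinom(k, n, p)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= x) when `draws` balls are drawn without replacement from a
#' population of `total` balls of which `successes` are marked.
#'
#' @param x Observed number of marked balls among the draws.
#' @param successes Number of marked balls in the population.
#' @param total Population size.
#' @param draws Number of draws.
#' @return Numeric vector of upper-tail probabilities.
#' @export
hyper_upper_tail <- function(x, successes, total, draws) {
  if (any(successes > total) || any(draws > total) || any(x < 0)) {
    stop("inconsistent hypergeometric parameters", call. = FALSE)
  }
  stats::phyper(x - 1, successes, total - successes, draws, lower.tail = FALSE)
}

#' Significance cutoff for rare codon pairs
#'
#' The Bonferroni-style cutoff P0 = alpha / n_pairs / n_genes dividing the
#' base level over both the 4096 tests and the number of genes searched.
#' With defaults and 4289 genes, P0 = 0.01/4096/4289 = 5.69225e-10.
#'
#' @param n_genes Number of genes in the corpus.
#' @param alpha Base significance level.
#' @param n_pairs Number of codon pairs tested (64 x 64).
#' @return The cutoff probability P0.
#' @export
rarity_cutoff <- function(n_genes, alpha = 0.01, n_pairs = 4096L) {
  if (n_genes <= 0 || alpha <= 0 || n_pairs <= 0) {
    stop("cutoff parameters must be positive", call. = FALSE)
  }
  alpha / n_pairs / n_genes
}

#' Test every codon pair for under-representation
#'
#' For each of the 4096 hexamers computes two lower-tail binomial
#' probabilities and classifies the pair:
#' \describe{
#'   \item{P1 (in frame)}{k = in-frame pair count, n = count of the
#'     corresponding dipeptide, p = 1/(syn * syn) ([pair_null_prob()]):
#'     is this codon pair used less often than random synonymous encoding
#'     of its dipeptide would give?}
#'   \item{P2 (any frame)}{k = sliding-window hexamer count, n = total
#'     windows, p = (1/4)^6 (or the product of observed mononucleotide
#'     frequencies with `p2_model = "composition"`): is the string itself
#'     depleted at the nucleotide level?}
#' }
#' A pair is \strong{rare} when both P1 < P0 and P2 < P0, with
#' P0 = alpha/4096/n_genes ([rarity_cutoff()]); otherwise \strong{normal}.
#' Pairs whose dipeptide never occurs, or whose two codons are both drawn
#' from the non-degenerate \{ATG, TGG\}, are \strong{excluded} from testing
#' (they carry no synonymous choice), mirroring the reduction from 4096 to
#' the tested-string count reported per run.
#'
#' @param counts A `pair_counts` tibble from [count_codon_pairs()].
#' @param n_genes Number of genes behind the counts; defaults to the
#'   attribute recorded by [count_codon_pairs()].
#' @param alpha Base significance level for the cutoff.
#' @param p2_model `"uniform"` for p = (1/4)^6, `"composition"` for the
#'   observed mononucleotide composition of the corpus.
#' @param code Genetic-code tibble.
#' @return A tibble of class `pair_test` with columns `hexamer`, `codon1`,
#'   `codon2`, `aa_pair`, `k_inframe`, `n_aapair`, `p1_null`, `p1`,
#'   `k_anyframe`, `n_windows`, `p2_null`, `p2`, `status`
#'   (`rare`/`normal`/`excluded`), `exclusion_reason`; attributes `alpha`,
#'   `p0`, `n_genes`, and the `pair_counts` attributes carried over.
#' @export
test_codon_pairs <- function(counts, n_genes = NULL, alpha = 0.01,
                             p2_model = c("uniform", "composition"),
                             code = genetic_code()) {
  p2_model <- match.arg(p2_model)
  n_windows <- attr(counts, "total_windows")
  if (is.null(n_windows)) {
    stop("counts must come from count_codon_pairs()", call. = FALSE)
  }
  if (n_windows <= 0L) {
    stop("empty corpus: no length-6 windows to test", call. = FALSE)
  }
  if (is.null(n_genes)) n_genes <- attr(counts, "n_genes")
  p0 <- rarity_cutoff(n_genes, alpha = alpha)

  if (p2_model == "uniform") {
    p2_null <- rep((1 / 4)^6, nrow(counts))
  } else {
    bf <- attr(counts, "base_freq")
    chars <- strsplit(counts$hexamer, "", fixed = TRUE)
    p2_null <- vapply(chars, function(x) prod(bf[x]), numeric(1))
  }

  nondeg <- counts$codon1 %in% c("ATG", "TGG") &
    counts$codon2 %in% c("ATG", "TGG")
  no_bg <- counts$n_aapair == 0L
  excluded <- nondeg | no_bg
  reason <- dplyr::case_when(
    nondeg ~ "nondegenerate-only (ATG/TGG)",
    no_bg ~ "amino-acid pair absent from corpus",
    .default = NA_character_
  )

  p1 <- rep(NA_real_, nrow(counts))
  p1_null <- pair_null_prob(counts$hexamer, code)
  ok <- !excluded
  p1[ok] <- binom_lower_tail(counts$k_inframe[ok], counts$n_aapair[ok],
    p1_null[ok])
  p2 <- binom_lower_tail(counts$k_anyframe, n_windows, p2_null)

  status <- dplyr::case_when(
    excluded ~ "excluded",
    p1 < p0 & p2 < p0 ~ "rare",
    .default = "normal"
  )

  out <- tibble::tibble(
    hexamer = counts$hexamer,
    codon1 = counts$codon1,
    codon2 = counts$codon2,
    aa_pair = counts$aa_pair,
    k_inframe = counts$k_inframe,
    n_aapair = counts$n_aapair,
    p1_null = p1_null,
    p1 = p1,
    k_anyframe = counts$k_anyframe,
    n_windows = n_windows,
    p2_null = p2_null,
    p2 = p2,
    status = status,
    exclusion_reason = reason
  )
  structure(
    out,
    class = c("pair_test", class(tibble::tibble())),
    alpha = alpha,
    p0 = p0,
    n_genes = n_genes,
    p2_model = p2_model,
    total_inframe_pairs = attr(counts, "total_inframe_pairs"),
    total_windows = n_windows,
    pair_step = attr(counts, "pair_step")
  )
}

#' @export
glance.pair_test <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_rare = sum(x$status == "rare"),
    n_normal = sum(x$status == "normal"),
    n_excluded = sum(x$status == "excluded"),
    n_tested = sum(x$status != "excluded"),
    alpha = attr(x, "alpha"),
    p0 = attr(x, "p0"),
    n_genes = attr(x, "n_genes"),
    p2_model = attr(x, "p2_model"),
    total_windows = attr(x, "total_windows")
  )
}

hexamer_triplets <- function(hexamer) {
  # the 4 triplets of a hexamer at offsets 0..3 (frame unknown)
  c(
    substr(hexamer, 1L, 3L), substr(hexamer, 2L, 4L),
    substr(hexamer, 3L, 5L), substr(hexamer, 4L, 6L)
  )
}

#' Rank codons by their contribution to the rare-pair group
#'
#' Each distinct hexamer contributes its 4 triplets (offsets 0-3, since the
#' reading frame of a rare string is ill-defined); for each of the 64 codons
#' the test asks whether it is enriched among the triplets of the rare
#' group. With x occurrences among the N = 4 * N1 rare-group triplets, K
#' among the normal-group triplets, and M = 4 * (N1 + N2) triplets in all,
#' the upper-tail hypergeometric probability P(X >= x) (drawing N from M
#' with x + K marked) measures over-representation; codons are ranked
#' ascending by it, ties broken by descending x then codon order.
#'
#' @param pairs Either a `pair_test` tibble from [test_codon_pairs()], or
#'   `NULL` if `rare` and `normal` are given directly.
#' @param rare,normal Character vectors of hexamers (used when `pairs` is
#'   `NULL`); each distinct hexamer is counted once.
#' @param alpha_codon Significance level for calling a codon rare; the
#'   default Bonferroni-corrects the base 0.01 over 64 codons. The full
#'   ranked table is always returned so other cutoffs can be applied.
#' @param code Genetic-code tibble.
#' @return A 64-row tibble of class `codon_contribution`, sorted by rank:
#'   `codon`, `aa`, `x`, `k_normal`, `n_draws` (N), `m_total` (M), `p_hyp`,
#'   `rank`, `is_rare_codon`.
#' @export
codon_contribution <- function(pairs = NULL, rare = NULL, normal = NULL,
                               alpha_codon = 0.01 / 64,
                               code = genetic_code()) {
  if (!is.null(pairs)) {
    rare <- pairs$hexamer[pairs$status == "rare"]
    normal <- pairs$hexamer[pairs$status == "normal"]
  }
  rare <- unique(rare)
  normal <- unique(normal)
  if (length(intersect(rare, normal)) > 0L) {
    stop("rare and normal sets must be disjoint", call. = FALSE)
  }
  if (length(rare) == 0L) {
    stop("empty rare set: no codon-contribution test possible", call. = FALSE)
  }
  codons <- code$codon
  x <- table(factor(hexamer_triplets(rare), levels = codons))
  k <- table(factor(hexamer_triplets(normal), levels = codons))
  n1 <- length(rare)
  n2 <- length(normal)
  n_draws <- 4L * n1
  m_total <- 4L * (n1 + n2)

  out <- tibble::tibble(
    codon = codons,
    aa = code$aa,
    x = as.integer(x),
    k_normal = as.integer(k),
    n_draws = n_draws,
    m_total = m_total,
    p_hyp = hyper_upper_tail(as.integer(x), as.integer(x) + as.integer(k),
      m_total, n_draws)
  ) |>
    dplyr::arrange(.data$p_hyp, dplyr::desc(.data$x), .data$codon) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      is_rare_codon = .data$p_hyp < alpha_codon
    )
  structure(
    out,
    class = c("codon_contribution", class(tibble::tibble())),
    alpha_codon = alpha_codon,
    n_rare_pairs = n1,
    n_normal_pairs = n2
  )
}

#' Extract the ranked rare-codon list
#'
#' @param contrib A `codon_contribution` tibble.
#' @param alpha_codon Cutoff on the hypergeometric upper-tail probability;
#'   defaults to the one stored at test time.
#' @return Character vector of rare codons, most significant first.
#' @export
identify_rare_codons <- function(contrib, alpha_codon = NULL) {
  if (is.null(alpha_codon)) alpha_codon <- attr(contrib, "alpha_codon")
  contrib$codon[contrib$p_hyp < alpha_codon]
}
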