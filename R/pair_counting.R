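#' Count codon pairs (hexamers) in a coding-sequence set
#'
#' Counts every one of the 4096 six-nucleotide strings two ways over a set
#' of valid CDS:
#' \itemize{
#'   \item \strong{in frame}: as adjacent codon pairs at codon boundaries.
#'     With the default `pair_step = 1` the pairs overlap, stepping one
#'     codon at a time, so a gene of C codons contributes C - 1 pairs;
#'     `pair_step = 2` counts disjoint pairs instead (sensitivity option).
#'   \item \strong{any frame}: every length-6 window at every nucleotide
#'     offset, so a gene of N nt contributes N - 5 windows.
#' }
#' Genes are never concatenated: no pair or window spans a gene boundary.
#' The amino-acid-pair background `n_aapair` for a hexamer is the total
#' in-frame count of all hexamers translating to the same dipeptide
#' (equivalently, the dipeptide count over the translated proteins at the
#' same step).
#'
#' @param cds CDS tibble; all rows must have `is_valid_cds == TRUE`
#'   (filter with [valid_cds()] first).
#' @param code Genetic-code tibble from [genetic_code()].
#' @param pair_step In-frame step in codons: 1 (overlapping pairs, default)
#'   or 2 (non-overlapping).
#'
#' @return A 4096-row tibble of class `pair_counts` with columns `hexamer`,
#'   `codon1`, `codon2`, `aa_pair`, `k_inframe`, `n_aapair`, `k_anyframe`,
#'   and attributes `n_genes`, `total_inframe_pairs`, `total_windows`
#'   (= sum of N_i - 5), `base_freq` (observed mononucleotide frequencies)
#'   and `pair_step`.
#' @examples
#' cds <- as_cds_tibble("g1", "ATGAAACTGTAA")
#' counts <- count_codon_pairs(cds)
#' dplyr::filter(counts, k_inframe > 0)
#' @export
count_codon_pairs <- function(cds, code = genetic_code(), pair_step = 1L) {
  if (nrow(cds) == 0L) {
    stop("empty coding-sequence set", call. = FALSE)
  }
  if (!all(cds$is_valid_cds)) {
    stop("input contains invalid CDS; filter with valid_cds() first",
      call. = FALSE
    )
  }
  if (!pair_step %in% c(1L, 2L)) {
    stop("pair_step must be 1 or 2 codons", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(cds$seq)

  inframe <- Biostrings::oligonucleotideFrequency(
    set, width = 6L, step = 3L * pair_step, simplify.as = "collapsed"
  )
  anyframe <- Biostrings::oligonucleotideFrequency(
    set, width = 6L, step = 1L, simplify.as = "collapsed"
  )
  base_counts <- colSums(Biostrings::letterFrequency(set, c("A", "C", "G", "T")))

  hexamer <- names(anyframe)
  codon1 <- substr(hexamer, 1L, 3L)
  codon2 <- substr(hexamer, 4L, 6L)
  aa <- code_lookup(code)
  aa_pair <- paste0(aa[codon1], aa[codon2])

  counts <- tibble::tibble(
    hexamer = hexamer,
    codon1 = codon1,
    codon2 = codon2,
    aa_pair = aa_pair,
    k_inframe = as.integer(inframe[hexamer]),
    k_anyframe = as.integer(anyframe[hexamer])
  )
  counts <- counts |>
    dplyr::group_by(.data$aa_pair) |>
    dplyr::mutate(n_aapair = sum(.data$k_inframe)) |>
    dplyr::ungroup() |>
    dplyr::select(
      "hexamer", "codon1", "codon2", "aa_pair",
      "k_inframe", "n_aapair", "k_anyframe"
    )

  structure(
    counts,
    class = c("pair_counts", class(counts)),
    n_genes = nrow(cds),
    total_inframe_pairs = sum(counts$k_inframe),
    total_windows = sum(pmax(cds$length_nt - 5L, 0L)),
    base_freq = base_counts / sum(base_counts),
    pair_step = pair_step
  )
}

#' @export
glance.pair_counts <- function(x, ...) {
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    total_inframe_pairs = attr(x, "total_inframe_pairs"),
    total_windows = attr(x, "total_windows"),
    pair_step = attr(x, "pair_step"),
    n_hexamers_observed_inframe = sum(x$k_inframe > 0L),
    n_hexamers_observed_anyframe = sum(x$k_anyframe > 0L)
  )
}
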