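# E. coli-like amino-acid composition (approximate proteome frequencies),
# renormalized at use. Only the 20 standard residues; stops are never
# sampled -- a single terminal stop is appended.
ECOLI_AA_FREQS <- c(
  A = 0.095, R = 0.055, N = 0.040, D = 0.052, C = 0.012,
  E = 0.058, Q = 0.044, G = 0.074, H = 0.022, I = 0.060,
  L = 0.105, K = 0.044, M = 0.028, F = 0.039, P = 0.044,
  S = 0.058, T = 0.054, W = 0.015, Y = 0.029, V = 0.070
)

#' Specify a synthetic coding-sequence corpus
#'
#' Defines the generative model for [simulate_cds()]: genes are random
#' amino-acid sequences (given residue frequencies) back-translated with
#' controllable within-family codon usage, with optional pair-context
#' suppression of chosen codons. Suppression multiplies a codon's selection
#' weight by `factor` at every position that follows another codon (i.e.
#' everywhere after the initiator ATG), the simplest mechanism that makes
#' the codon's pair contexts rare without touching amino-acid content.
#'
#' @param n_genes Number of genes.
#' @param length_codons Length range (min, max) of the sampled amino-acid
#'   sequence, in codons, drawn uniformly; the initiator ATG and terminal
#'   stop are added on top.
#' @param aa_freqs Named numeric vector of residue frequencies (20 standard
#'   amino acids); defaults to an E. coli-like composition.
#' @param usage Named numeric vector of within-family selection weights
#'   over (a subset of) the 61 sense codons; default uniform within each
#'   family. Weights are renormalized per family. A family none of whose
#'   members is named stays uniform; once any member is named, unnamed
#'   members of that family get zero weight, and a family summing to zero
#'   is an error.
#' @param suppression Named numeric vector of factors in (0, 1], e.g.
#'   `c(GGA = 0.05)` for 20-fold suppression.
#' @param stop_codon Terminal stop appended to every gene.
#' @param seed Integer seed; each gene draws from its own stream derived
#'   from (seed, gene index), so any subset of genes is reproducible.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes, length_codons = c(100L, 400L),
                     aa_freqs = NULL, usage = NULL, suppression = NULL,
                     stop_codon = "TAA", seed = 1L) {
  code <- genetic_code()
  if (is.null(aa_freqs)) aa_freqs <- ECOLI_AA_FREQS
  if (any(aa_freqs < 0) || sum(aa_freqs) <= 0) {
    stop("amino-acid frequencies must be non-negative and sum > 0",
      call. = FALSE)
  }
  if (!all(names(aa_freqs) %in% setdiff(unique(code$aa), "*"))) {
    stop("aa_freqs names must be standard amino-acid symbols", call. = FALSE)
  }
  sense <- code$codon[code$aa != "*"]
  if (is.null(usage)) {
    usage <- stats::setNames(rep(1, length(sense)), sense)
  }
  if (!all(names(usage) %in% sense)) {
    stop("usage names must be sense codons", call. = FALSE)
  }
  if (!is.null(suppression)) {
    if (any(suppression <= 0 | suppression > 1)) {
      stop("suppression factors must lie in (0, 1]", call. = FALSE)
    }
    if (!all(names(suppression) %in% sense)) {
      stop("suppression names must be sense codons", call. = FALSE)
    }
  }
  if (!stop_codon %in% stop_codons(code)) {
    stop("stop_codon must be one of TAA, TAG, TGA", call. = FALSE)
  }
  if (length(length_codons) != 2L || any(length_codons < 1L) ||
    length_codons[1] > length_codons[2]) {
    stop("length_codons must be c(min, max) with 1 <= min <= max",
      call. = FALSE)
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      length_codons = as.integer(length_codons),
      aa_freqs = aa_freqs / sum(aa_freqs),
      usage = usage,
      suppression = suppression,
      stop_codon = stop_codon,
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

gene_seed <- function(seed, i) {
  # documented per-gene stream: (seed * 7919 + i) mod 2^31 - 1
  as.integer((as.double(seed) * 7919 + i) %% 2147483647)
}

#' Generate a synthetic coding-sequence set
#'
#' Draws genes under a [sim_spec()]: per gene, a uniform length, a random
#' amino-acid sequence from the residue frequencies, and one codon per
#' residue from the (suppression-adjusted, renormalized) family weights;
#' the gene is framed by an initiator ATG and the terminal stop. Every
#' generated record is a valid CDS with no internal stops.
#'
#' @param spec A `sim_spec` object.
#' @return A CDS tibble in the format of [read_cds_fasta()].
#' @export
simulate_cds <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_genes == 0L) {
    return(as_cds_tibble(character(), character()))
  }
  code <- genetic_code()
  fams <- split(code$codon[code$aa != "*"], code$aa[code$aa != "*"])
  aas <- names(spec$aa_freqs)

  # per-family codon weights after suppression, renormalized
  fam_w <- lapply(fams, function(cods) {
    w <- spec$usage[cods]
    # families with no stated usage are uniform; within a stated family,
    # unstated members get zero weight
    if (all(is.na(w))) w[] <- 1
    w[is.na(w)] <- 0
    if (!is.null(spec$suppression)) {
      hit <- cods %in% names(spec$suppression)
      w[hit] <- w[hit] * spec$suppression[cods[hit]]
    }
    if (sum(w) <= 0) {
      stop("zero-probability codon family: ", paste(cods, collapse = ","),
        call. = FALSE)
    }
    w / sum(w)
  })

  seqs <- character(spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    set.seed(gene_seed(spec$seed, i))
    len <- sample.int(
      spec$length_codons[2] - spec$length_codons[1] + 1L, 1L
    ) + spec$length_codons[1] - 1L
    aa_seq <- sample(aas, len, replace = TRUE, prob = spec$aa_freqs)
    codons <- character(len)
    for (a in unique(aa_seq)) {
      at <- aa_seq == a
      cods <- fams[[a]]
      if (length(cods) == 1L) {
        codons[at] <- cods
      } else {
        codons[at] <- sample(cods, sum(at), replace = TRUE, prob = fam_w[[a]])
      }
    }
    seqs[i] <- paste0("ATG", paste(codons, collapse = ""), spec$stop_codon)
  }
  as_cds_tibble(sprintf("synth_%05d", seq_len(spec$n_genes)), seqs)
}

#' Run the full rare-codon pipeline on a synthetic corpus
#'
#' Generates a corpus under `spec`, runs pair counting, the P1/P2 tests and
#' classification, and the hypergeometric codon-contribution ranking, and
#' reports where the suppressed codons land — the end-to-end validation
#' that pair-context suppression is recoverable as codon rarity.
#'
#' @param spec A `sim_spec` object (with or without suppression).
#' @param alpha Base level for the pair cutoff P0.
#' @param alpha_codon Cutoff for calling a codon rare.
#' @param p2_model See [test_codon_pairs()].
#' @return A list of class `recovery_report`: `glance` (one-row tibble with
#'   rare/normal/excluded counts and P0), `contributions` (64-row ranked
#'   table), `rare_codons` (character vector), `suppressed` (tibble of the
#'   suppressed codons with their ranks and p_hyp; empty when none),
#'   `seed`.
#' @export
recovery_experiment <- function(spec, alpha = 0.01, alpha_codon = 0.01 / 64,
                                p2_model = "uniform") {
  cds <- simulate_cds(spec)
  counts <- count_codon_pairs(valid_cds(cds))
  tests <- test_codon_pairs(counts, alpha = alpha, p2_model = p2_model)
  g <- glance(tests)
  if (g$n_rare == 0L) {
    contrib <- NULL
    rare_codons <- character()
    suppressed <- tibble::tibble(
      codon = names(spec$suppression) %||% character(),
      rank = NA_integer_, p_hyp = NA_real_, is_rare_codon = FALSE
    )
  } else {
    contrib <- codon_contribution(tests, alpha_codon = alpha_codon)
    rare_codons <- identify_rare_codons(contrib)
    suppressed <- contrib |>
      dplyr::filter(.data$codon %in% names(spec$suppression)) |>
      dplyr::select("codon", "rank", "p_hyp", "is_rare_codon")
  }
  structure(
    list(
      glance = g,
      contributions = contrib,
      rare_codons = rare_codons,
      suppressed = suppressed,
      seed = spec$seed
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Suppressed-codon recovery report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  rare pairs: %d, normal: %d, excluded: %d\n",
    x$glance$n_rare, x$glance$n_normal, x$glance$n_excluded))
  if (nrow(x$suppressed) > 0L) print(as.data.frame(x$suppressed),
    row.names = FALSE)
  cat("  rare codons: ", paste(x$rare_codons, collapse = " "), "\n")
  invisible(x)
}
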