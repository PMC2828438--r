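# Independent brute-force oracles, deliberately naive and separate from the
# package's computation paths.

# lower-tail binomial by enumerating all 2^n outcomes
oracle_binom_lower <- function(k, n, p) {
  if (n == 0) return(1)
  total <- 0
  for (outcome in 0:(2^n - 1)) {
    succ <- sum(bitwAnd(outcome, 2^(0:(n - 1))) > 0)
    if (succ <= k) total <- total + p^succ * (1 - p)^(n - succ)
  }
  total
}

# upper-tail hypergeometric by enumerating all draws of size `draws`
oracle_hyper_upper <- function(x, successes, total, draws) {
  balls <- c(rep(1, successes), rep(0, total - successes))
  draws_mat <- utils::combn(total, draws)
  hits <- apply(draws_mat, 2, function(idx) sum(balls[idx]) >= x)
  mean(hits)
}

# mid-ranks by pairwise counting
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Mann-Whitney U by direct pair comparison (smaller-U convention)
oracle_mw_u <- function(a, b) {
  u1 <- sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  min(u1, length(a) * length(b) - u1)
}

# naive hexamer scans by explicit substring loops
oracle_count_anyframe <- function(seqs, hexamer) {
  total <- 0
  for (s in seqs) {
    if (nchar(s) < 6) next
    for (i in 1:(nchar(s) - 5)) {
      if (substr(s, i, i + 5) == hexamer) total <- total + 1
    }
  }
  total
}

oracle_count_inframe <- function(seqs, hexamer) {
  total <- 0
  for (s in seqs) {
    n_codons <- nchar(s) / 3
    if (n_codons < 2) next
    for (ci in 1:(n_codons - 1)) {
      i <- (ci - 1) * 3 + 1
      if (substr(s, i, i + 5) == hexamer) total <- total + 1
    }
  }
  total
}

# dipeptide counts computed directly on translated proteins
oracle_aapair_counts <- function(seqs) {
  prots <- translate_cds(seqs)
  pairs <- unlist(lapply(prots, function(p) {
    if (nchar(p) < 2) return(character())
    substring(p, 1:(nchar(p) - 1), 2:nchar(p))
  }))
  table(pairs)
}

random_cds <- function(n_codons, rng_seed) {
  set.seed(rng_seed)
  sense <- genetic_code()$codon[genetic_code()$aa != "*"]
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
    "TAA")
}

write_tmp_fasta <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.fasta")
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  }))
  writeLines(lines, path)
  path
}
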