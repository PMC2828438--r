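test_that("f_rare is the plain rare-codon fraction", {
  rare13 <- c("GGA", "CTC", "TAG", "CTA", "ACA", "GAC", "AGG", "AGA",
    "CCC", "GGG", "GAG", "ACT", "ATA")
  expect_equal(f_rare("ATGGGAGGAAAATAA", rare13), 2 / 5)
  expect_equal(f_rare(strrep("AAA", 10), rare13), 0)
  expect_equal(f_rare(strrep("GGA", 7), rare13), 1)
  # syn-weighted variant scales each count by syn(i)/6
  expect_equal(f_rare("ATGGGAGGAAAATAA", rare13, weighted = TRUE),
    2 * (4 / 6) / 5)
  expect_error(f_rare("ATGTAA", character()), "empty")
})

test_that("CAI is the geometric mean over non-singleton codons", {
  w <- stats::setNames(rep(1, 64), genetic_code()$codon)
  expect_equal(cai("ATGAAAAAGTGGTAA", w), 1)
  w["AAG"] <- 0.25
  # gene AAA AAG: ATG/TGG/stop excluded from the product
  expect_equal(cai("ATGAAAAAGTGGTAA", w), sqrt(0.25))
  w[] <- 0.3
  expect_equal(cai("ATGAAACTGGATTAA", w), 0.3)
  expect_error(cai("ATGTGGTAA", w), "no CAI-countable")
})

test_that("Fop and CBI follow the optimal-codon definitions", {
  opt <- c("GGT", "GGC")
  expect_equal(fop("GGTGGTGGTGGC", opt), 1)
  expect_equal(fop("GGAGGAGGAGGG", opt), 0)
  expect_equal(cbi("GGTGGTGGTGGC", opt), 1)
  # 3 of 4 Gly codons optimal, half the family is optimal: (3-2)/(4-2)
  expect_equal(cbi("GGTGGTGGTGGA", opt), 0.5)
  expect_equal(fop("GGTGGTGGTGGA", opt), 0.75)
  # random usage gives CBI near 0 in expectation; exact at the balance point
  expect_equal(cbi("GGTGGTGGAGGA", opt), 0)
  expect_error(fop("ATGTGGTAA", opt), "no degenerate")
})

test_that("gene_indices assembles all per-gene columns consistently", {
  spec <- sim_spec(30, c(50, 120), seed = 6)
  cds <- simulate_cds(spec)
  idx <- gene_indices(cds, rare_codons = c("GGA", "AGG"))
  expect_equal(nrow(idx), 30L)
  expect_equal(idx$n_codons, cds$n_codons)
  expect_equal(idx$f_rare, idx$rare_count / idx$n_codons)
  expect_true(all(idx$f_rare >= 0 & idx$f_rare <= 1))
  expect_true(all(idx$cai > 0 & idx$cai <= 1))
  expect_true(all(idx$fop >= 0 & idx$fop <= 1))
  expect_true(all(idx$cbi <= 1))
})

test_that("F_rare and Fop are negatively associated when the sets
           partition each degenerate family", {
  code <- genetic_code()
  deg <- code[code$aa != "*" & code$syn >= 2, ]
  opt <- ecoli_optimal_codons()
  rare <- setdiff(deg$codon, opt) # complement within degenerate families
  spec <- sim_spec(60, c(80, 150), seed = 12)
  cds <- simulate_cds(spec)
  idx <- gene_indices(cds, rare_codons = rare)
  expect_lte(stats::cor(idx$f_rare, idx$fop), 0)
})

test_that("usage pattern normalizes within families and flags empties", {
  up <- usage_pattern(as_cds_tibble("g", "ATGATG"))
  expect_equal(up$rel_usage[up$codon == "ATG"], 1)
  gly <- up[up$aa == "G", ]
  expect_false(any(gly$family_observed))
  expect_equal(gly$rel_usage, rep(0.25, 4))
  # family shares sum to 1
  sums <- tapply(up$rel_usage, up$aa, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  # pooled counts invariant to gene order
  spec <- sim_spec(8, c(20, 50), seed = 21)
  cds <- simulate_cds(spec)
  expect_equal(
    usage_pattern(cds)$count,
    usage_pattern(cds[rev(seq_len(nrow(cds))), ])$count
  )
})

test_that("empirical codon usage of a generated corpus matches its spec", {
  # uniform within-family usage: each family member's share ~ 1/syn
  spec <- sim_spec(150, c(200, 300), seed = 31)
  cds <- simulate_cds(spec)
  up <- usage_pattern(as_cds_tibble(cds$gene_id,
    substr(cds$seq, 4, cds$length_nt - 3))) # drop fixed ATG/stop framing
  code <- genetic_code()
  syn <- stats::setNames(code$syn, code$codon)
  deg <- up[up$aa %in% names(sim_spec(1)$aa_freqs) & up$family_total > 0 &
    syn[up$codon] >= 2, ]
  p <- 1 / syn[deg$codon]
  se <- sqrt(p * (1 - p) / deg$family_total)
  expect_true(all(abs(deg$rel_usage - p) < 3 * se))
})
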