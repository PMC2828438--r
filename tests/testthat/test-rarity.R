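test_that("encoding-rule null probability multiplies degeneracies", {
  expect_equal(pair_null_prob("CTGATG"), 1 / 6)
  expect_equal(pair_null_prob("ATGTGG"), 1)
  expect_equal(pair_null_prob("GGAGGA"), 1 / 16)
  expect_error(pair_null_prob("XXXXXX"), "invalid hexamer")
})

test_that("binomial lower tail matches exhaustive outcome enumeration", {
  for (n in c(1, 3, 7, 12)) {
    for (p in c(0.03, 0.25, 0.5, 1 / 12)) {
      for (k in unique(c(0L, 1L, n %/% 2, n))) {
        expect_equal(binom_lower_tail(k, n, p), oracle_binom_lower(k, n, p),
          tolerance = 1e-12
        )
      }
    }
  }
  expect_equal(binom_lower_tail(5, 5, 0.3), 1)
  expect_equal(binom_lower_tail(1, 3, 0.5), 0.5) # (1 + 3) / 8 outcomes
  expect_equal(binom_lower_tail(0, 2, 0.25), 0.5625) # 0.75^2
  expect_error(binom_lower_tail(4, 3, 0.5), "k <= n")
})

test_that("binomial tail is monotone in k and n", {
  n <- 50
  p <- 0.2
  tails <- binom_lower_tail(0:n, n, p)
  expect_true(all(diff(tails) >= 0))
  # for fixed k below the mean, a larger corpus makes the tail smaller
  ns <- seq(40, 400, by = 40)
  expect_true(all(diff(binom_lower_tail(4, ns, p)) <= 0))
})

test_that("hypergeometric upper tail matches draw enumeration", {
  for (total in c(6, 9, 12)) {
    for (successes in c(2, total %/% 2)) {
      for (draws in c(2, total %/% 2)) {
        for (x in 0:min(successes, draws)) {
          expect_equal(
            hyper_upper_tail(x, successes, total, draws),
            oracle_hyper_upper(x, successes, total, draws),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("P1 uses the dipeptide background and flags exclusions", {
  # corpus where LK occurs but never as CTGAAA: 20 CTTAAA pairs in a row
  seqs <- paste0("ATG", strrep("CTTAAA", 20), "TAA")
  counts <- count_codon_pairs(as_cds_tibble("g", seqs))
  tests <- test_codon_pairs(counts, n_genes = 1)
  lk <- tests[tests$hexamer == "CTGAAA", ]
  expect_equal(lk$n_aapair, 20L)
  expect_equal(lk$k_inframe, 0L)
  expect_equal(lk$p1, (1 - 1 / 12)^20, tolerance = 1e-12)

  expect_equal(
    tests$status[tests$hexamer %in% c("ATGATG", "ATGTGG", "TGGATG", "TGGTGG")],
    rep("excluded", 4)
  )
  expect_match(tests$exclusion_reason[tests$hexamer == "ATGATG"],
    "nondegenerate")
  # a dipeptide absent from the corpus excludes all its hexamers
  ww <- tests[tests$aa_pair == "CC", ]
  expect_true(all(ww$status == "excluded"))
})

test_that("P2 follows the uniform-composition null over all windows", {
  spec <- sim_spec(5, c(20, 40), seed = 2)
  cds <- simulate_cds(spec)
  counts <- count_codon_pairs(cds)
  tests <- test_codon_pairs(counts)
  n_win <- attr(counts, "total_windows")
  absent <- tests[tests$k_anyframe == 0L, ][1, ]
  expect_equal(absent$p2, (1 - 0.25^6)^n_win, tolerance = 1e-12)
  expect_equal(tests$p2,
    stats::pbinom(tests$k_anyframe, n_win, 0.25^6))
  # k = n corner: full mass
  expect_equal(binom_lower_tail(n_win, n_win, 0.25^6), 1)
})

test_that("empty corpora cannot be tested", {
  cds <- as_cds_tibble("g", "ATGTAA")
  counts <- count_codon_pairs(cds)
  attr(counts, "total_windows") <- 0L
  expect_error(test_codon_pairs(counts), "empty corpus")
})

test_that("the cutoff and classification implement the conjunction rule", {
  expect_equal(rarity_cutoff(4289), 0.01 / 4096 / 4289)
  p0 <- rarity_cutoff(4289)
  # classification needs BOTH tails below P0
  spec <- sim_spec(100, c(100, 200), suppression = c(GGA = 0.02), seed = 4)
  tests <- test_codon_pairs(count_codon_pairs(simulate_cds(spec)))
  g <- glance(tests)
  expect_equal(g$n_rare + g$n_normal + g$n_excluded, 4096L)
  rare <- tests[tests$status == "rare", ]
  if (nrow(rare) > 0) {
    expect_true(all(rare$p1 < attr(tests, "p0") & rare$p2 < attr(tests, "p0")))
  }
  normal <- tests[tests$status == "normal", ]
  expect_true(all(normal$p1 >= attr(tests, "p0") |
    normal$p2 >= attr(tests, "p0")))
})

test_that("codon contribution counts the 4 triplets of each distinct pair", {
  contrib <- codon_contribution(rare = "AAATTT", normal = "AAAAAA")
  aaa <- contrib[contrib$codon == "AAA", ]
  expect_equal(aaa$x, 1L)
  expect_equal(aaa$k_normal, 4L)
  expect_equal(aaa$n_draws, 4L)
  expect_equal(aaa$m_total, 8L)
  expect_equal(aaa$p_hyp, 1) # only 3 non-AAA triplets exist in 8
  ttt <- contrib[contrib$codon == "TTT", ]
  expect_equal(ttt$x, 1L)
  expect_equal(ttt$k_normal, 0L)
  # conservation
  expect_equal(sum(contrib$x), 4L)
  expect_equal(sum(contrib$x + contrib$k_normal), 8L)
  expect_equal(sort(contrib$rank), 1:64)
  expect_error(codon_contribution(rare = character(), normal = "AAAAAA"),
    "empty rare set")
  expect_error(codon_contribution(rare = "AAAAAA", normal = "AAAAAA"),
    "disjoint")
})

test_that("rare-codon identification applies the codon-level cutoff", {
  contrib <- tibble::tibble(
    codon = genetic_code()$codon,
    p_hyp = rep(1, 64)
  )
  attr(contrib, "alpha_codon") <- 0.01 / 64
  expect_equal(identify_rare_codons(contrib), character())
  contrib$p_hyp[contrib$codon == "GGA"] <- 1e-20
  expect_equal(identify_rare_codons(contrib), "GGA")
})
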