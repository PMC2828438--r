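all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  sort(apply(grid, 1, paste0, collapse = ""))
}

naive_stop_scan <- function(h) {
  hits <- 0
  for (off in 0:3) {
    if (substr(h, off + 1, off + 3) %in% c("TAA", "TAG", "TGA")) {
      hits <- hits + 1
    }
  }
  hits
}

test_that("stop-codon scanning finds every offset", {
  expect_equal(find_stop_codons("ATGTAA"),
    tibble::tibble(hexamer = "ATGTAA", stop_codon = "TAA", offset = 3L))
  expect_equal(find_stop_codons("AATAAG")$offset, 2L)
  expect_equal(nrow(find_stop_codons("CTGCTG")), 0L)
  # TAATAA: offsets 0 and 3, plus ATA? no - only stops count
  expect_equal(find_stop_codons("TAATAA")$offset, c(0L, 3L))
})

test_that("stop scan agrees with naive enumeration over all 4096 hexamers", {
  hx <- all_hexamers()
  hits <- find_stop_codons(hx)
  got <- table(factor(hits$hexamer, levels = hx))
  expect_equal(as.integer(got), vapply(hx, naive_stop_scan, numeric(1)),
    ignore_attr = TRUE)
  # subset property: an in-frame second-codon stop is always detected
  second_stop <- hx[substr(hx, 4, 6) %in% c("TAA", "TAG", "TGA")]
  expect_true(all(second_stop %in% hits$hexamer))
})

test_that("IUPAC motifs match with ambiguity codes and both strands", {
  motifs <- tibble::tibble(
    name = c("EcoRI", "Dam", "Dcm"),
    recognition = c("GAATTC", "GATC", "CCWGG"),
    source = NA_character_
  )
  hits <- scan_motifs("GAATTC", motifs)
  expect_true(any(hits$name == "EcoRI" & hits$offset == 0))
  expect_equal(scan_motifs("AGATCT", motifs[2, ])$offset, 1L)
  dcm <- scan_motifs("CCTGGA", motifs[3, ])
  expect_true(any(dcm$name == "Dcm" & dcm$offset == 0 & dcm$strand == "+"))
  # CCWGG is its own IUPAC reverse complement, so CCAGG is found on "+"
  expect_true(any(scan_motifs("TCCAGG", motifs[3, ])$strand == "+"))
  # a non-palindromic site is found via its reverse complement
  bsai <- tibble::tibble(name = "BsaI", recognition = "GGTCTC",
    source = NA_character_)
  minus <- scan_motifs("GAGACC", bsai)
  expect_true(any(minus$strand == "-"))
  expect_equal(nrow(scan_motifs("GGTCTC", bsai)), 1L)
  # motifs longer than a hexamer can never match
  long <- tibble::tibble(name = "EcoKI", recognition = "AACNNNNNNGTGC",
    source = NA_character_)
  expect_equal(nrow(scan_motifs(all_hexamers()[1:50], long)), 0L)
  bad_cols <- file.path(withr::local_tempdir(), "bad.tsv")
  writeLines(c("enzyme\tsite", "EcoRI\tGAATTC"), bad_cols)
  expect_error(read_motifs(bad_cols), "name")
})

test_that("malformed motifs are rejected at load time", {
  path <- file.path(withr::local_tempdir(), "motifs.tsv")
  writeLines(c("name\trecognition", "Bad\tGAXTTC"), path)
  expect_error(read_motifs(path), "malformed IUPAC")
  writeLines(c("name\trecognition", "Short\tGAT"), path)
  expect_error(read_motifs(path), "malformed IUPAC")
  ok_path <- file.path(withr::local_tempdir(), "ok.tsv")
  writeLines(c("name\trecognition", "EcoRI\tgaattc"), ok_path)
  expect_equal(read_motifs(ok_path)$recognition, "GAATTC")
})

test_that("group annotation summarises stop and site content", {
  ann <- annotate_pairs(rare = c("ATGTAA", "CTGCTG"), normal = "GAATTC",
    motifs = default_motifs())
  expect_equal(sum(ann$pairs$is_stop_containing[ann$pairs$group == "rare"]),
    1L)
  expect_true(ann$pairs$is_site_containing[ann$pairs$hexamer == "GAATTC"])
  expect_equal(nrow(ann$summary), 2L)
  # empty motif list: no site hits anywhere
  none <- annotate_pairs(rare = c("ATGTAA", "GAATTC"), normal = character(),
    motifs = tibble::tibble(name = character(), recognition = character(),
      source = character()))
  expect_equal(sum(none$pairs$n_site_hits), 0L)
  # iteration order does not change the summary
  ann2 <- annotate_pairs(rare = c("CTGCTG", "ATGTAA"), normal = "GAATTC",
    motifs = default_motifs())
  expect_equal(
    dplyr::arrange(ann$summary, group),
    dplyr::arrange(ann2$summary, group)
  )
})

test_that("packaged motif list loads and is IUPAC-clean", {
  motifs <- default_motifs()
  expect_true(all(c("EcoRI", "Dam", "Dcm") %in% motifs$name))
  expect_true(all(grepl("^[ACGTRYSWKMBDHVN]{4,}$", motifs$recognition)))
})
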