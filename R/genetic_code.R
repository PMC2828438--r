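#' The genetic code as a tidy table
#'
#' Returns the codon table used by every statistic in the package as a
#' 64-row tibble: one row per codon (lexicographic A < C < G < T order),
#' its amino-acid symbol (`*` for stop) and the degeneracy `syn` of its
#' synonymous family, i.e. how many codons encode the same amino acid.
#' Under the standard code `syn` takes values in \{1, 2, 3, 4, 6\}; the
#' three stop codons are treated as a 3-member family.
#'
#' @param codon_to_aa Optional named character vector of length 64 mapping
#'   codons to single-letter amino-acid symbols, for non-standard codes.
#'   Defaults to the standard (bacterial) table from
#'   [Biostrings::GENETIC_CODE].
#'
#' @return A tibble with columns `codon`, `aa`, `syn`.
#' @examples
#' code <- genetic_code()
#' dplyr::filter(code, codon %in% c("ATG", "CTG", "TAA"))
#' @export
genetic_code <- function(codon_to_aa = NULL) {
  if (is.null(codon_to_aa)) {
    codon_to_aa <- as.character(Biostrings::GENETIC_CODE)
    names(codon_to_aa) <- names(Biostrings::GENETIC_CODE)
    names(codon_to_aa) <- gsub("U", "T", names(codon_to_aa), fixed = TRUE)
  }
  codons <- sort(names(codon_to_aa))
  if (length(codons) != 64L || !all(grepl("^[ACGT]{3}$", codons))) {
    stop("a genetic code must map exactly the 64 ACGT codons", call. = FALSE)
  }
  aa <- unname(codon_to_aa[codons])
  fam <- table(aa)
  tibble::tibble(
    codon = codons,
    aa = aa,
    syn = as.integer(fam[aa])
  )
}

#' Load an alternative genetic code from a TSV file
#'
#' The file must have two columns, `codon` and `aa`, covering all 64 codons.
#' `U` in codons is mapped to `T`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble as returned by [genetic_code()].
#' @export
read_genetic_code <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("codon", "aa") %in% names(tab))) {
    stop("genetic-code table needs 'codon' and 'aa' columns", call. = FALSE)
  }
  map <- toupper(tab$aa)
  names(map) <- gsub("U", "T", toupper(tab$codon), fixed = TRUE)
  genetic_code(map)
}

code_lookup <- function(code) {
  stats::setNames(code$aa, code$codon)
}

syn_lookup <- function(code) {
  stats::setNames(code$syn, code$codon)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

#' Translate in-frame coding sequences
#'
#' @param seq Character vector of nucleotide sequences, each with length
#'   divisible by 3. Stop codons translate to `*`.
#' @param code Genetic-code tibble from [genetic_code()].
#' @return Character vector of amino-acid sequences, one symbol per codon.
#' @examples
#' translate_cds(c("ATGTGG", "ATGAAATAA"))
#' @export
translate_cds <- function(seq, code = genetic_code()) {
  seq <- toupper(gsub("U", "T", seq, fixed = TRUE))
  bad <- nchar(seq) %% 3L != 0L
  if (any(bad)) {
    stop(
      "sequence length not divisible by 3 for: ",
      paste(utils::head(which(bad), 5L), collapse = ", "),
      call. = FALSE
    )
  }
  aa <- code_lookup(code)
  vapply(seq, function(s) {
    cods <- split_codons(s)
    out <- aa[cods]
    if (anyNA(out)) {
      stop("sequence contains non-ACGT codon(s): ",
        paste(unique(cods[is.na(out)]), collapse = ", "),
        call. = FALSE
      )
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Degeneracy of a codon's synonymous family
#'
#' @param codon Character vector of codons.
#' @inheritParams translate_cds
#' @return Integer vector; e.g. 1 for ATG, 6 for CTG, 3 for stops under the
#'   standard code.
#' @examples
#' codon_degeneracy(c("ATG", "CTG", "GGA"))
#' @export
codon_degeneracy <- function(codon, code = genetic_code()) {
  codon <- toupper(gsub("U", "T", codon, fixed = TRUE))
  out <- syn_lookup(code)[codon]
  if (anyNA(out)) {
    stop("unknown codon(s): ", paste(unique(codon[is.na(out)]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(out)
}

stop_codons <- function(code = genetic_code()) {
  code$codon[code$aa == "*"]
}
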