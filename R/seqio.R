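#' Read coding sequences from a multi-FASTA file
#'
#' Reads a (possibly gzipped) multi-FASTA of coding sequences and validates
#' each record as a CDS. Records are never silently altered or dropped:
#' sequences containing symbols outside \{A, C, G, T\} (after uppercasing and
#' mapping U to T) or whose length is not a multiple of 3, or shorter than
#' 6 nt, are retained with `is_valid_cds = FALSE` and a reason. Downstream
#' counting functions require pre-filtering to valid records (see
#' [valid_cds()]).
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @param code Genetic-code tibble from [genetic_code()].
#' @param strip_terminal_stop If `TRUE`, a terminal stop codon is removed
#'   from each valid CDS before any downstream counting. The default keeps
#'   it: bacterial gene downloads normally include the stop, and stop-codon
#'   context is part of the pair statistics.
#' @param keep_inframe_prefix If `TRUE`, sequences whose length is not a
#'   multiple of 3 are truncated to their longest in-frame prefix and kept
#'   (flagged in `invalid_reason` as recovered) instead of being marked
#'   invalid.
#'
#' @return A tibble with one row per FASTA record, in file order: `gene_id`
#'   (first whitespace-delimited token of the header), `seq`, `length_nt`,
#'   `n_codons`, `is_valid_cds`, `has_terminal_stop`, `internal_stop_count`,
#'   `invalid_reason`.
#' @export
read_cds_fasta <- function(path, code = genetic_code(),
                           strip_terminal_stop = FALSE,
                           keep_inframe_prefix = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  as_cds_tibble(ids, as.character(set),
    code = code,
    strip_terminal_stop = strip_terminal_stop,
    keep_inframe_prefix = keep_inframe_prefix
  )
}

#' Assemble and validate a CDS tibble from id and sequence vectors
#'
#' Workhorse behind [read_cds_fasta()] and the simulator; useful for
#' building small in-memory gene sets.
#'
#' @param gene_id Character vector of identifiers.
#' @param seq Character vector of nucleotide sequences.
#' @inheritParams read_cds_fasta
#' @return The validated CDS tibble described in [read_cds_fasta()].
#' @export
as_cds_tibble <- function(gene_id, seq, code = genetic_code(),
                          strip_terminal_stop = FALSE,
                          keep_inframe_prefix = FALSE) {
  seq <- unname(toupper(gsub("U", "T", seq, fixed = TRUE)))
  gene_id <- unname(as.character(gene_id))
  reason <- character(length(seq))

  clean <- grepl("^[ACGT]*$", seq)
  reason[!clean] <- "non-ACGT symbols"

  len <- nchar(seq)
  offframe <- clean & len %% 3L != 0L
  if (keep_inframe_prefix && any(offframe)) {
    seq[offframe] <- substr(seq[offframe], 1L, (len[offframe] %/% 3L) * 3L)
    len <- nchar(seq)
    reason[offframe] <- "truncated to in-frame prefix"
    offframe <- rep(FALSE, length(seq))
  }
  reason[offframe] <- "length not a multiple of 3"
  short <- clean & !offframe & len < 6L
  reason[short] <- "shorter than 6 nt"

  valid <- clean & !offframe & !short
  stops <- stop_codons(code)

  has_stop <- rep(FALSE, length(seq))
  internal <- integer(length(seq))
  aa <- code_lookup(code)
  for (i in which(valid)) {
    cods <- split_codons(seq[i])
    is_stop <- aa[cods] == "*"
    has_stop[i] <- is_stop[length(is_stop)]
    internal[i] <- sum(is_stop[-length(is_stop)])
    if (strip_terminal_stop && has_stop[i]) {
      seq[i] <- substr(seq[i], 1L, nchar(seq[i]) - 3L)
      has_stop[i] <- FALSE
    }
  }
  len <- nchar(seq)
  if (strip_terminal_stop) {
    short2 <- valid & len < 6L
    valid[short2] <- FALSE
    reason[short2] <- "shorter than 6 nt after stop removal"
  }

  n_invalid <- sum(!valid)
  if (n_invalid > 0L) {
    message(n_invalid, " of ", length(seq),
      " sequences failed CDS validation and are flagged invalid")
  }

  tibble::tibble(
    gene_id = gene_id,
    seq = seq,
    length_nt = len,
    n_codons = ifelse(valid, len %/% 3L, NA_integer_),
    is_valid_cds = valid,
    has_terminal_stop = has_stop,
    internal_stop_count = ifelse(valid, internal, NA_integer_),
    invalid_reason = ifelse(reason == "", NA_character_, reason)
  )
}

#' Keep only valid coding sequences
#'
#' @param cds A CDS tibble from [read_cds_fasta()] or [simulate_cds()].
#' @return The rows with `is_valid_cds == TRUE`.
#' @export
valid_cds <- function(cds) {
  dplyr::filter(cds, .data$is_valid_cds)
}

#' Read a gene-subset list
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("gene list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a CDS tibble to a multi-FASTA file
#'
#' @param cds A CDS tibble.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cds))) {
    writeLines(paste0(">", cds$gene_id[i]), con)
    s <- cds$seq[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
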