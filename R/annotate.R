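IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
  N = "[ACGT]"
)

iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  cls <- IUPAC_CLASS[chars]
  if (anyNA(cls)) {
    stop("malformed IUPAC motif: ", motif, call. = FALSE)
  }
  paste0(cls, collapse = "")
}

#' Find stop codons at any offset of a hexamer
#'
#' Scans the four triplets of each hexamer (offsets 0-3; the reading frame
#' of an arbitrary six-nucleotide string is unknown) for the nonsense
#' codons TAA, TAG, TGA on the sense strand.
#'
#' @param hexamer Character vector of six-nucleotide strings.
#' @return A tibble with one row per hit: `hexamer`, `stop_codon`, `offset`
#'   (0-based start of the triplet within the hexamer).
#' @examples
#' find_stop_codons(c("ATGTAA", "AATAAG", "CTGCTG"))
#' @export
find_stop_codons <- function(hexamer) {
  stops <- c("TAA", "TAG", "TGA")
  purrr::map_dfr(hexamer, function(h) {
    tri <- substring(h, 1:4, 3:6)
    hit <- tri %in% stops
    tibble::tibble(
      hexamer = h[rep(1, sum(hit))],
      stop_codon = tri[hit],
      offset = which(hit) - 1L
    )
  })
}

#' Read a restriction-site motif table
#'
#' @param path TSV with columns `name`, `recognition` (IUPAC nucleotide
#'   string, length >= 4) and optionally `source`; `#` comments allowed.
#'   Motifs are validated at load time.
#' @return A tibble of motifs.
#' @export
read_motifs <- function(path) {
  tab <- readr::read_tsv(path, comment = "#",
    col_types = readr::cols(.default = "c"))
  if (!all(c("name", "recognition") %in% names(tab))) {
    stop("motif table needs 'name' and 'recognition' columns", call. = FALSE)
  }
  tab$recognition <- toupper(tab$recognition)
  bad <- nchar(tab$recognition) < 4L |
    !grepl("^[ACGTRYSWKMBDHVN]+$", tab$recognition)
  if (any(bad)) {
    stop("malformed IUPAC motif(s): ",
      paste(tab$name[bad], collapse = ", "), call. = FALSE)
  }
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  tibble::as_tibble(tab[c("name", "recognition", "source")])
}

#' Packaged restriction-enzyme and methylase motif list
#'
#' A static list of recognition motifs of common E. coli-relevant
#' restriction enzymes and methylation systems (EcoRI, EcoRV, Dam, Dcm,
#' ...). It is deliberately small and replaceable: supply your own table
#' with [read_motifs()] to extend or localize it.
#'
#' @return A tibble of motifs (`name`, `recognition`, `source`).
#' @export
default_motifs <- function() {
  read_motifs(system.file("extdata", "restriction_motifs.tsv",
    package = "rarecodon", mustWork = TRUE
  ))
}

#' Scan hexamers for restriction-site motifs
#'
#' Matches IUPAC motifs against each hexamer on both strands (recognition
#' sites are double-stranded, so a motif and its reverse complement are
#' both searched on the given sequence); motifs longer than 6 nt cannot
#' match and are skipped. Offsets are 0-based on the given strand. A motif
#' that is its own IUPAC reverse complement (e.g. CCWGG, GATC) is scanned
#' once and its hits reported as `+` only.
#'
#' @param hexamer Character vector of six-nucleotide strings.
#' @param motifs Motif tibble from [read_motifs()] / [default_motifs()].
#' @param both_strands Scan the reverse complement of each motif too.
#' @return A tibble with one row per hit: `hexamer`, `name`, `offset`,
#'   `strand` (`+`/`-`).
#' @export
scan_motifs <- function(hexamer, motifs = default_motifs(),
                        both_strands = TRUE) {
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    rec <- motifs$recognition[i]
    len <- nchar(rec)
    if (len > 6L) next
    pats <- list(`+` = iupac_regex(rec))
    if (both_strands) {
      # reverse-complement in IUPAC space (ambiguity codes complement too)
      rc <- iupac_revcomp(rec)
      if (rc != rec) pats[["-"]] <- iupac_regex(rc)
    }
    for (strand in names(pats)) {
      for (off in 0:(6L - len)) {
        sub <- substr(hexamer, off + 1L, off + len)
        hit <- grepl(paste0("^", pats[[strand]], "$"), sub)
        if (any(hit)) {
          hits[[length(hits) + 1L]] <- tibble::tibble(
            hexamer = hexamer[hit],
            name = motifs$name[i],
            offset = off,
            strand = strand
          )
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(
      hexamer = character(), name = character(),
      offset = integer(), strand = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(hits), .data$hexamer, .data$name, .data$offset)
}

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

iupac_revcomp <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  paste0(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Annotate classified codon pairs for stability-related features
#'
#' For each hexamer in the rare and normal groups, records any-frame stop
#' codons (sense strand) and restriction-site motif hits (both strands),
#' and summarises the per-group counts — the features implicated in gene
#' (mRNA/DNA) instability.
#'
#' @param pairs A `pair_test` tibble from [test_codon_pairs()], or `NULL`
#'   if `rare`/`normal` are given.
#' @param rare,normal Character vectors of hexamers (used when `pairs` is
#'   `NULL`).
#' @param motifs Motif tibble; see [default_motifs()].
#' @return A list of class `pair_annotation`: `pairs` (per-hexamer tibble
#'   with `group`, `n_stop_hits`, `stop_codons`, `n_site_hits`, `sites`,
#'   `is_stop_containing`, `is_site_containing`), `summary` (per-group
#'   counts), `stop_hits` and `site_hits` (hit-level tibbles).
#' @export
annotate_pairs <- function(pairs = NULL, rare = NULL, normal = NULL,
                           motifs = default_motifs()) {
  if (!is.null(pairs)) {
    rare <- pairs$hexamer[pairs$status == "rare"]
    normal <- pairs$hexamer[pairs$status == "normal"]
  }
  tab <- dplyr::bind_rows(
    tibble::tibble(hexamer = unique(rare), group = "rare"),
    tibble::tibble(hexamer = unique(normal), group = "normal")
  )
  if (nrow(tab) == 0L) stop("no hexamers to annotate", call. = FALSE)
  stop_hits <- find_stop_codons(tab$hexamer)
  site_hits <- scan_motifs(tab$hexamer, motifs)

  stop_sum <- stop_hits |>
    dplyr::group_by(.data$hexamer) |>
    dplyr::summarise(
      n_stop_hits = dplyr::n(),
      stop_codons = paste(unique(.data$stop_codon), collapse = ","),
      .groups = "drop"
    )
  site_sum <- site_hits |>
    dplyr::group_by(.data$hexamer) |>
    dplyr::summarise(
      n_site_hits = dplyr::n(),
      sites = paste(unique(.data$name), collapse = ","),
      .groups = "drop"
    )
  ann <- tab |>
    dplyr::left_join(stop_sum, by = "hexamer") |>
    dplyr::left_join(site_sum, by = "hexamer") |>
    dplyr::mutate(
      n_stop_hits = dplyr::coalesce(.data$n_stop_hits, 0L),
      n_site_hits = dplyr::coalesce(.data$n_site_hits, 0L),
      is_stop_containing = .data$n_stop_hits > 0L,
      is_site_containing = .data$n_site_hits > 0L
    )
  summary <- ann |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_stop_containing = sum(.data$is_stop_containing),
      n_site_containing = sum(.data$is_site_containing),
      .groups = "drop"
    )
  structure(
    list(pairs = ann, summary = summary,
      stop_hits = stop_hits, site_hits = site_hits),
    class = "pair_annotation"
  )
}

#' @export
print.pair_annotation <- function(x, ...) {
  cat("Codon-pair annotation\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
glance.pair_annotation <- function(x, ...) {
  tidyr::pivot_wider(x$summary,
    names_from = "group",
    values_from = c("n_pairs", "n_stop_containing", "n_site_containing")
  )
}

#' @export
tidy.pair_annotation <- function(x, ...) x$pairs
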