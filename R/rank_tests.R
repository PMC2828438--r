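#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks), with a
#' two-sided p value from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return An object of class `spearman_cor` with elements `rho`,
#'   `statistic`, `p_value`, `n`; has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # rho = 0.8
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    statistic <- sign(rho) * Inf
    p <- 0
  } else {
    statistic <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(statistic), df = n - 2)
  }
  structure(
    list(rho = rho, statistic = statistic, p_value = p, n = n),
    class = "spearman_cor"
  )
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat("Spearman rank correlation\n")
  cat(sprintf("  rho = %.4f  (n = %d, two-sided p = %.3g)\n",
    x$rho, x$n, x$p_value))
  invisible(x)
}

#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble::tibble(
    estimate = x$rho, statistic = x$statistic,
    p.value = x$p_value, n = x$n, method = "spearman"
  )
}

#' @export
glance.spearman_cor <- function(x, ...) tidy(x)

#' Mann-Whitney U test (rank-sum test) for two groups
#'
#' Ranks the pooled values (mid-ranks for ties) and reports the statistics
#' in the layout of classical statistics packages: U is the smaller of the
#' two U statistics, W the rank sum of the group attaining it, and Z the
#' tie-corrected normal approximation (U - n1*n2/2) / sigma with a
#' two-sided p value.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `mann_whitney` with per-group rank sums and
#'   mean ranks, `u`, `w`, `z`, `p_value`; has tidy() and glance() methods.
#' @export
mann_whitney <- function(a, b, labels = c("a", "b")) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  r1 <- sum(r[seq_len(n1)])
  r2 <- sum(r) - r1
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  if (u1 <= u2) {
    u <- u1
    w <- r1
  } else {
    u <- u2
    w <- r2
  }
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (u - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(
    list(
      groups = tibble::tibble(
        group = labels, n = c(n1, n2),
        rank_sum = c(r1, r2), mean_rank = c(r1 / n1, r2 / n2)
      ),
      u = u, w = w, z = z, p_value = p
    ),
    class = "mann_whitney"
  )
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat("Mann-Whitney U test\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  cat(sprintf("  U = %.2f  W = %.2f  Z = %.3f  two-sided p = %.3g\n",
    x$u, x$w, x$z, x$p_value))
  invisible(x)
}

#' @export
tidy.mann_whitney <- function(x, ...) x$groups

#' @export
glance.mann_whitney <- function(x, ...) {
  tibble::tibble(
    u = x$u, w = x$w, statistic = x$z, p.value = x$p_value,
    n1 = x$groups$n[1], n2 = x$groups$n[2]
  )
}

#' Pairwise Spearman correlations between index columns
#'
#' All pairwise rank correlations among chosen columns of a per-gene index
#' table (the classical index-comparison matrix).
#'
#' @param idx Tibble from [gene_indices()].
#' @param cols Character vector of column names to correlate.
#' @return A long tibble: `var1`, `var2`, `rho`, `p_value`, `n`, covering
#'   every ordered pair (diagonal rho = 1).
#' @export
index_correlations <- function(idx,
                               cols = c("f_rare", "cai", "cbi", "fop")) {
  missing <- setdiff(cols, names(idx))
  if (length(missing) > 0L) {
    stop("columns not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tidyr::expand_grid(var1 = cols, var2 = cols) |>
    dplyr::mutate(purrr::map2_dfr(.data$var1, .data$var2, function(v1, v2) {
      if (v1 == v2) {
        return(tibble::tibble(rho = 1, p_value = NA_real_,
          n = sum(stats::complete.cases(idx[[v1]]))))
      }
      s <- spearman_cor(idx[[v1]], idx[[v2]])
      tibble::tibble(rho = s$rho, p_value = s$p_value, n = s$n)
    }))
}

#' Compare an index between two gene groups
#'
#' Joins a group assignment onto a per-gene index table and runs the
#' Mann-Whitney test on the chosen column (e.g. F_rare of essential vs
#' non-essential genes).
#'
#' @param idx Tibble from [gene_indices()].
#' @param groups Either a tibble with columns `gene_id`, `group` (exactly
#'   two distinct groups), or a character vector of gene ids forming the
#'   first group (the rest of `idx` forms the second).
#' @param value Name of the index column to compare.
#' @param labels Group labels used when `groups` is an id vector.
#' @return A `mann_whitney` object.
#' @export
compare_groups <- function(idx, groups, value = "f_rare",
                           labels = c("subset", "rest")) {
  if (!value %in% names(idx)) {
    stop("column not found: ", value, call. = FALSE)
  }
  if (is.data.frame(groups)) {
    merged <- dplyr::inner_join(idx, groups, by = "gene_id")
    lev <- sort(unique(merged$group))
    if (length(lev) != 2L) {
      stop("need exactly two groups, got ", length(lev), call. = FALSE)
    }
    mann_whitney(
      merged[[value]][merged$group == lev[1]],
      merged[[value]][merged$group == lev[2]],
      labels = as.character(lev)
    )
  } else {
    sel <- idx$gene_id %in% groups
    if (!any(sel)) stop("no genes matched the subset ids", call. = FALSE)
    mann_whitney(idx[[value]][sel], idx[[value]][!sel], labels = labels)
  }
}
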