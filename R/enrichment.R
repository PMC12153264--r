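#' Cross-tabulate anchor vs candidate presence
#'
#' Builds the 2x2 contingency table over genomes for two family columns:
#' `a` = anchor+ family+, `b` = anchor+ family-, `c` = anchor- family+,
#' `d` = anchor- family-.  The four cells always sum to the genome count.
#'
#' @param pa A `presence_matrix`.
#' @param anchor,candidate Family accessions (must differ).
#' @return Named integer vector `c(a=, b=, c=, d=)`.
#' @export
contingency_for_family <- function(pa, anchor, candidate) {
  if (normalize_family_id(anchor) == normalize_family_id(candidate)) {
    stop("anchor and candidate must be different families")
  }
  x <- pa_column(pa, anchor)
  y <- pa_column(pa, candidate)
  c(a = sum(x == 1L & y == 1L), b = sum(x == 1L & y == 0L),
    c = sum(x == 0L & y == 1L), d = sum(x == 0L & y == 0L))
}

as_table_counts <- function(table) {
  if (is.matrix(table)) table <- as.vector(t(table))
  if (length(table) != 4L || any(is.na(table)) || any(table < 0) ||
      any(table != round(table))) {
    stop("a 2x2 table of non-negative integer counts (a, b, c, d) is required")
  }
  as.numeric(table)
}

# log C(n, k) via log-factorials; the whole test runs in log space so that
# tables with counts in the thousands keep full precision.
log_choose <- function(n, k) {
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
}

#' Exact hypergeometric test on a 2x2 table
#'
#' Conditional on both margins, cell `a` follows a hypergeometric
#' distribution.  The one-tailed p-values sum that distribution's tail; the
#' two-sided p-value follows the conventional definition: the sum of the
#' probabilities of all attainable tables whose probability does not exceed
#' that of the observed table (within a relative tolerance of 1e-7, the usual
#' guard against ties broken by floating-point noise).  All probabilities are
#' computed in log space from log-factorials, so the test is stable for
#' genome collections of arbitrary size.
#'
#' When a margin is zero in both rows or both columns only one table is
#' attainable and the p-value is 1 by convention (a message is emitted when
#' `options(profscreen.verbose = TRUE)`).
#'
#' The sample odds ratio `ad/bc` is reported as-is (possibly 0, `Inf`, or
#' `NaN` for a doubly degenerate table); `odds_ratio_corrected` is the
#' Haldane-Anscombe version with 0.5 added to every cell, always finite and
#' the one to use when any cell is empty.
#'
#' @param table 2x2 counts: vector `c(a, b, c, d)` (row-wise) or a 2x2 matrix.
#' @param alternative `"two_sided"` (default), `"greater"` (enrichment of
#'   `a`), or `"less"`.
#' @return List with `p_value`, `odds_ratio`, `odds_ratio_corrected`.
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tb <- as_table_counts(table)
  a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
  m1 <- a + b          # anchor-positive genomes
  m2 <- cc + d         # anchor-negative genomes
  k <- a + cc          # family-positive genomes
  n <- m1 + m2
  if (n == 0) {
    stop("at least one margin must be positive")
  }

  lo <- max(0, k - m2)
  hi <- min(k, m1)
  if (lo == hi) {
    if (isTRUE(getOption("profscreen.verbose", FALSE))) {
      message("degenerate margins: single attainable table, p = 1")
    }
    p <- 1
  } else {
    xs <- lo:hi
    logp <- log_choose(m1, xs) + log_choose(m2, k - xs) - log_choose(n, k)
    logp_obs <- logp[xs == a]
    p <- switch(alternative,
      two_sided = sum(exp(logp[logp <= logp_obs + log1p(1e-7)])),
      greater = sum(exp(logp[xs >= a])),
      less = sum(exp(logp[xs <= a]))
    )
    # extreme tables can underflow the probability sum to 0; clamp to the
    # smallest positive double so p stays in (0, 1]
    p <- min(1, max(p, .Machine$double.xmin))
  }

  list(
    p_value = p,
    odds_ratio = (a * d) / (b * cc),
    odds_ratio_corrected = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: on the sorted p-values,
#' `q(i) = min over j >= i of min(1, p(j) * m / j)`, mapped back to the input
#' order.  Input p-values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Screen all families for over-/under-representation
#'
#' For every non-anchor family the anchor-positive and anchor-negative genome
#' sets are crossed with the family's presence column, the exact two-sided
#' test of [fisher_exact()] is applied, and q-values are computed over the
#' whole screen with [bh_adjust()].  A family is called `over` when its odds
#' ratio exceeds 1 and `q <= alpha`, `under` when the odds ratio is below 1
#' and `q <= alpha`, else `none`; for doubly degenerate tables the direction
#' falls back to the Haldane-Anscombe corrected odds ratio.  Results are
#' ranked by q-value, then by the magnitude of the corrected log odds ratio.
#'
#' @param pa A `presence_matrix` with at least two families.
#' @param anchor Anchor family accession; its column must contain both
#'   positive and negative genomes.
#' @param alpha FDR level for the direction call (default 0.05).
#' @return Tibble: `family_id`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `odds_ratio_corrected`, `p_value`, `q_value`, `direction`.
#' @export
screen_all_families <- function(pa, anchor, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (ncol(pa$m) < 2L) {
    stop("the matrix must contain at least two families")
  }
  x <- pa_column(pa, anchor)
  if (all(x == 1L) || all(x == 0L)) {
    stop("anchor column is constant; the positive/negative comparison is undefined")
  }
  candidates <- setdiff(colnames(pa$m), normalize_family_id(anchor))
  rows <- lapply(candidates, function(fid) {
    tb <- contingency_for_family(pa, anchor, fid)
    ft <- fisher_exact(tb, "two_sided")
    or_dir <- if (is.nan(ft$odds_ratio)) ft$odds_ratio_corrected else ft$odds_ratio
    tibble::tibble(
      family_id = fid, a = unname(tb["a"]), b = unname(tb["b"]),
      c = unname(tb["c"]), d = unname(tb["d"]),
      odds_ratio = ft$odds_ratio,
      odds_ratio_corrected = ft$odds_ratio_corrected,
      p_value = ft$p_value, or_dir = or_dir
    )
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- bh_adjust(res$p_value)
  res$direction <- ifelse(res$q_value > alpha, "none",
                          ifelse(res$or_dir > 1, "over",
                                 ifelse(res$or_dir < 1, "under", "none")))
  res$or_dir <- NULL
  res[order(res$q_value, -abs(log(res$odds_ratio_corrected))), ]
}

#' Conditional co-occurrence summary for an anchor/partner pair
#'
#' Counts anchor-positive, partner-positive and dual-positive genomes and the
#' two conditional percentages P(partner | anchor) and P(anchor | partner),
#' globally and per domain of life.  Exact percentages are stored; one-decimal
#' and integer-rounded renderings are provided because published prose
#' typically rounds coarsely.  Percentages with an empty denominator are `NA`.
#'
#' @param pa A `presence_matrix` with genome metadata.
#' @param anchor,partner Family accessions.
#' @return List with `global` (one-row tibble) and `by_stratum` (one row per
#'   domain of life).
#' @export
cooccurrence_summary <- function(pa, anchor, partner) {
  x <- pa_column(pa, anchor)
  y <- pa_column(pa, partner)
  strata <- pa$metadata$domain_of_life

  summarize_stratum <- function(keep, label) {
    xs <- x[keep]; ys <- y[keep]
    n_anchor <- sum(xs == 1L)
    n_partner <- sum(ys == 1L)
    n_both <- sum(xs == 1L & ys == 1L)
    pga <- if (n_anchor > 0) 100 * n_both / n_anchor else NA_real_
    pgp <- if (n_partner > 0) 100 * n_both / n_partner else NA_real_
    tibble::tibble(
      stratum = label,
      n_genomes = sum(keep),
      n_anchor_pos = n_anchor, n_partner_pos = n_partner, n_both = n_both,
      pct_partner_given_anchor = pga,
      pct_partner_given_anchor_1dp = round(pga, 1),
      pct_partner_given_anchor_int = round(pga),
      pct_anchor_given_partner = pgp,
      pct_anchor_given_partner_1dp = round(pgp, 1),
      pct_anchor_given_partner_int = round(pgp)
    )
  }

  by_stratum <- dplyr::bind_rows(lapply(
    sort(unique(strata)),
    function(s) summarize_stratum(strata == s, s)
  ))
  list(
    global = summarize_stratum(rep(TRUE, length(x)), "all"),
    by_stratum = by_stratum
  )
}

#' Write enrichment screen results as TSV
#'
#' @param results Tibble from [screen_all_families()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
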