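# Shared numeric helpers. Conventions fixed package-wide:
#  * coordinates are 0-based half-open,
#  * percentiles use linear interpolation (quantile type 7),
#  * coefficients of variation use the population standard deviation.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

spacing_cv <- function(spacings) {
  if (length(spacings) < 2) return(0)
  m <- mean(spacings)
  if (m == 0) return(0)
  pop_sd(spacings) / m
}

pctl <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

# bp overlap between [s1, e1) and [s2, e2); vectorised
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

midpoint <- function(start, end) floor((start + end) / 2)

# 0-based half-open tibble -> GRanges (1-based closed)
gr_from_tbl <- function(tbl, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand %||% "*"
  )
}

#' One-sided Wilcoxon rank-sum p-value (alternative: x stochastically less)
#'
#' Computes `P(W <= W_obs)` for the rank sum of `x` in the pooled sample.
#' The p-value is exact by full enumeration of all `choose(m + n, m)` group
#' assignments whenever that count is at most `exact_limit` (ties are handled
#' exactly via midranks); exact via the null Mann-Whitney distribution when
#' the data are tie-free; and otherwise a normal approximation with
#' continuity and tie correction.
#'
#' @param x,y Numeric vectors (the alternative is that `x` tends to be
#'   smaller than `y`).
#' @param exact_limit Maximum number of arrangements enumerated exactly.
#' @return A single p-value in (0, 1].
#' @export
rank_sum_p_less <- function(x, y, exact_limit = 2e5) {
  m <- length(x)
  n <- length(y)
  if (m == 0 || n == 0) abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  has_ties <- anyDuplicated(pooled) > 0

  if (choose(m + n, min(m, n)) <= exact_limit) {
    idx <- utils::combn(m + n, m)
    w_all <- colSums(matrix(r[idx], nrow = m))
    return(mean(w_all <= w_obs + 1e-9))
  }
  if (!has_ties) {
    u_obs <- w_obs - m * (m + 1) / 2
    return(stats::pwilcox(u_obs, m, n))
  }
  # normal approximation, tie-corrected variance, continuity correction
  u_obs <- w_obs - m * (m + 1) / 2
  nn <- m + n
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
  sigma2 <- (m * n / 12) * ((nn + 1) - tie_term)
  z <- (u_obs - m * n / 2 + 0.5) / sqrt(sigma2)
  stats::pnorm(z)
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of observing at least `q` marked draws when `k` draws are
#' taken without replacement from `m` marked and `n` unmarked items.
#'
#' @param q Observed marked draws (foreground hits).
#' @param m Total marked items (hits in foreground + background).
#' @param n Total unmarked items.
#' @param k Number of draws (foreground size).
#' @return Upper-tail p-value `P(X >= q)`.
#' @export
hyper_enrichment_p <- function(q, m, n, k) {
  stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
}

stop_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
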