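#' Exact Fisher p-value for a 2x2 table
#'
#' Computes the exact hypergeometric p-value for the table
#' `[[a, b], [c, d]]` with all margins fixed. Point probabilities are
#' evaluated in log space (via `lchoose`), so cohort-scale tables
#' (N around 2000) do not overflow.
#'
#' Sidedness conventions:
#' * `"greater"` — probability of `a` or more successes in the first row
#'   (enrichment in the first group); the convention of collapsing burden
#'   tools such as TRAPD.
#' * `"less"` — probability of `a` or fewer.
#' * `"two.sided"` — minimum-likelihood rule: the sum of point probabilities
#'   of all tables with the given margins whose point probability does not
#'   exceed that of the observed table, with a relative tie tolerance of
#'   `1e-7` so floating-point-equal probabilities are counted as ties.
#'
#' Degenerate margins (an empty row or column) leave a single admissible
#' table, so the p-value is 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `a` = carriers among cases, `b` = non-carriers among cases,
#'   `c` = carriers among controls, `d` = non-carriers among controls.
#'   Vectorised over tables.
#' @param alternative `"greater"`, `"two.sided"`, or `"less"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' # 8/247 case carriers vs 12/1622 control carriers
#' fisher_exact_p(8, 239, 12, 1610, alternative = "two.sided")  # 0.0025
#' @export
fisher_exact_p <- function(a, b, c, d,
                           alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0) ||
      any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    fisher_exact_one(a[i], b[i], c[i], d[i], alternative)
  }, numeric(1))
}

fisher_exact_one <- function(a, b, c, d, alternative) {
  r1 <- a + b   # first-row margin (e.g. number of cases)
  c1 <- a + c   # first-column margin (e.g. total carriers)
  N <- a + b + c + d
  lo <- max(0, c1 - (N - r1))
  hi <- min(r1, c1)
  if (hi <= lo) return(1)  # single admissible table
  x <- lo:hi
  # log point probabilities of every table with these margins
  lp <- lchoose(r1, x) + lchoose(N - r1, c1 - x) - lchoose(N, c1)
  lp_obs <- lp[x == a]
  p <- switch(alternative,
    greater = sum(exp(lp[x >= a])),
    less = sum(exp(lp[x <= a])),
    two.sided = sum(exp(lp[lp <= lp_obs + log(1 + 1e-7)]))
  )
  min(p, 1)
}

#' Gene inclusion rule
#'
#' A gene enters the burden analysis only when both cohorts show at least
#' `min_variants` distinct qualifying variant sites in it; genes below the
#' threshold in either cohort are excluded, as their association could be
#' driven by a single variant.
#'
#' @param case_sites,control_sites Integer vectors: distinct qualifying
#'   sites per gene in each cohort.
#' @param min_variants Threshold (default 3).
#' @return Logical vector.
#' @examples
#' gene_inclusion(c(3, 2, 0), c(3, 50, 0))  # TRUE FALSE FALSE
#' @export
gene_inclusion <- function(case_sites, control_sites, min_variants = 3L) {
  stopifnot(all(case_sites >= 0), all(control_sites >= 0))
  case_sites >= min_variants & control_sites >= min_variants
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' with the input order restored. The family size `m` may exceed the number
#' of p-values supplied (tests whose p-values are not being adjusted still
#' count toward the family).
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param m Family size; defaults to `length(p)` and must not be smaller.
#' @return Numeric vector of adjusted values, same order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("family size m must be at least length(p)", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH", n = m)
}
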