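# Builders and independent brute-force oracles shared across test files.

# tiny cohort from a sites x samples dosage matrix
make_cohort <- function(dosage, genes = "G1", label = "case",
                        consequence = "missense_variant", pop_af = 0.001,
                        qual = 99, depth = 50) {
  dosage <- as.matrix(dosage)
  n_var <- nrow(dosage)
  n_s <- ncol(dosage)
  variants <- tibble::tibble(
    chrom = "1", pos = seq_len(n_var) * 10L, ref = "A", alt = "T",
    gene = rep_len(genes, n_var),
    consequence = rep_len(consequence, n_var),
    pop_af = rep_len(pop_af, n_var),
    qual = rep_len(qual, n_var),
    variant_id = paste0("v", seq_len(n_var))
  )
  depth_m <- matrix(rep_len(depth, n_var * n_s), n_var, n_s)
  burden_cohort(variants, dosage, depth_m, paste0("s", seq_len(n_s)), label)
}

# brute-force carrier category for one individual's dosage vector
brute_classify <- function(dos) {
  dos <- dos[!is.na(dos)]
  if (any(dos == 2)) "hom"
  else if (sum(dos == 1) >= 2) "ch"
  else if (sum(dos == 1) == 1) "het"
  else "none"
}

# brute-force Fisher p by enumerating every table with the fixed margins,
# using stats::dhyper as the independent point-probability source
brute_fisher <- function(a, b, c, d,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- probs[x == a]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[x >= a]),
    less = sum(probs[x <= a])
  )
  min(p, 1)
}

# brute-force per-individual scan for gene-set carriers
brute_set_carriers <- function(cohort, genes, model) {
  v <- cohort$variants
  carriers <- vapply(seq_along(cohort$samples), function(j) {
    any(vapply(genes, function(g) {
      rows <- which(v$gene == g)
      if (length(rows) == 0) return(FALSE)
      cat_g <- brute_classify(cohort$dosage[rows, j])
      if (model == "dominant") cat_g != "none"
      else cat_g %in% c("ch", "hom")
    }, logical(1)))
  }, logical(1))
  sum(carriers)
}

# printed per-gene carrier table used as end-to-end regression input:
# the five dominant-model rows whose carrier composition is unambiguous
table1_rows <- function() {
  tibble::tibble(
    gene = c("PNPT1", "FBXL4", "MRPS2", "NDUFB8", "SLC25A19"),
    case_het = c(8L, 21L, 16L, 4L, 4L),
    case_hom = c(0L, 3L, 0L, 0L, 0L),
    ctrl_het = c(12L, 83L, 51L, 6L, 6L),
    p_dom_printed = c(0.0025, 0.0048, 0.0111, 0.0327, 0.0327)
  )
}
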