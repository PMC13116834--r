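#' Analysis configuration
#'
#' Bundles every tunable threshold of the burden pipeline in one list, with
#' the values used by the study design as defaults: rare means population
#' allele frequency strictly below 5%, a genotype qualifies only with site
#' quality strictly over 20 and depth strictly over 10, and a gene is tested
#' only when both cohorts carry at least three distinct qualifying sites.
#'
#' @param max_pop_af Population allele-frequency cutoff; a variant is rare
#'   when its AF is strictly below this value. Missing AF counts as rare
#'   (absence from the reference database is taken as evidence of rarity).
#' @param min_site_quality Site QUAL threshold; strict (`qual > threshold`).
#' @param min_depth Per-genotype depth threshold; strict (`depth > threshold`).
#' @param min_variants Minimum number of distinct qualifying variant sites a
#'   gene must show in *each* cohort to be tested.
#' @param lof_terms Sequence Ontology consequence terms counted as
#'   loss-of-function.
#' @param missense_terms Consequence terms counted as missense.
#' @param alternative Sidedness of the exact carrier test. `"greater"` (the
#'   default) tests for enrichment in cases, the convention of collapsing
#'   burden tools such as TRAPD; `"two.sided"` uses the minimum-likelihood
#'   two-sided rule; `"less"` tests for depletion.
#' @param gene_key,csq_key,af_key INFO keys holding the gene symbol,
#'   consequence term and population allele frequency in input VCFs.
#' @param alpha Nominal significance threshold used in reports.
#'
#' @return A list of class `burden_config`.
#' @examples
#' cfg <- burden_config()
#' cfg$max_pop_af
#' @export
burden_config <- function(max_pop_af = 0.05,
                          min_site_quality = 20,
                          min_depth = 10,
                          min_variants = 3L,
                          lof_terms = c("frameshift_variant", "stop_gained",
                                        "splice_donor_variant",
                                        "splice_acceptor_variant"),
                          missense_terms = "missense_variant",
                          alternative = c("greater", "two.sided", "less"),
                          gene_key = "GENE",
                          csq_key = "CSQ",
                          af_key = "AF",
                          alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(
    is.numeric(max_pop_af), length(max_pop_af) == 1L,
    max_pop_af > 0, max_pop_af <= 1,
    is.numeric(min_site_quality), min_site_quality >= 0,
    is.numeric(min_depth), min_depth >= 0,
    is.numeric(min_variants), min_variants >= 0,
    is.character(lof_terms), is.character(missense_terms),
    is.numeric(alpha), alpha > 0, alpha < 1
  )
  structure(
    list(
      max_pop_af = max_pop_af,
      min_site_quality = min_site_quality,
      min_depth = min_depth,
      min_variants = as.integer(min_variants),
      lof_terms = lof_terms,
      missense_terms = missense_terms,
      alternative = alternative,
      gene_key = gene_key,
      csq_key = csq_key,
      af_key = af_key,
      alpha = alpha
    ),
    class = "burden_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Flat keys matching the arguments of [burden_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `burden_config` list.
#' @export
read_burden_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(burden_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  do.call(burden_config, vals[intersect(names(vals), known)])
}

#' @export
print.burden_config <- function(x, ...) {
  cat("<burden_config>\n")
  cat("  rare if pop AF <", x$max_pop_af,
      "(missing AF counts as rare)\n")
  cat("  genotype QC: quality >", x$min_site_quality,
      "and depth >", x$min_depth, "\n")
  cat("  gene inclusion: >=", x$min_variants,
      "qualifying sites in each cohort\n")
  cat("  exact test alternative:", x$alternative, "\n")
  cat("  LoF terms:", paste(x$lof_terms, collapse = ", "), "\n")
  invisible(x)
}
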