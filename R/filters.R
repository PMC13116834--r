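#' Classify consequence terms into missense / LoF / other
#'
#' Sequence Ontology terms are mapped to the two variant classes the burden
#' analysis tests: missense, and loss-of-function (frameshift, stop-gain and
#' canonical splice donor/acceptor by default). Everything else — including
#' unknown terms — is `"other"` and never qualifies. Unknown terms trigger
#' one warning per term per call.
#'
#' @param consequence Character vector of consequence terms.
#' @param cfg A [burden_config()] carrying `lof_terms` and `missense_terms`.
#' @return Factor-free character vector in `{"missense", "lof", "other"}`.
#' @examples
#' classify_consequence(c("missense_variant", "stop_gained", "synonymous_variant"))
#' @export
classify_consequence <- function(consequence, cfg = burden_config()) {
  out <- rep("other", length(consequence))
  out[consequence %in% cfg$missense_terms] <- "missense"
  out[consequence %in% cfg$lof_terms] <- "lof"
  known <- c(cfg$missense_terms, cfg$lof_terms,
             "synonymous_variant", "intron_variant", "intergenic_variant",
             "5_prime_UTR_variant", "3_prime_UTR_variant",
             "splice_region_variant", "upstream_gene_variant",
             "downstream_gene_variant", "stop_lost", "start_lost",
             "inframe_deletion", "inframe_insertion", "other")
  unknown <- setdiff(unique(consequence[out == "other"]), known)
  if (length(unknown) > 0) {
    warning("unrecognised consequence terms classed as 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

#' Is a variant rare?
#'
#' A variant is rare when its population allele frequency is strictly below
#' the cutoff (default 5%). A missing frequency counts as rare: absence from
#' the reference population database is evidence of rarity.
#'
#' @param pop_af Numeric vector of population allele frequencies; NA allowed.
#' @param cfg A [burden_config()].
#' @return Logical vector.
#' @examples
#' is_rare(c(0.049, 0.05, NA))
#' @export
is_rare <- function(pop_af, cfg = burden_config()) {
  is.na(pop_af) | pop_af < cfg$max_pop_af
}

#' Per-genotype QC
#'
#' A genotype call passes QC when the site quality is strictly over the
#' quality threshold, its read depth is strictly over the depth threshold,
#' and the genotype is called. QC is per-genotype: the same site may qualify
#' in one sample and fail in another (depth varies by sample); a failing
#' genotype is treated as dosage 0 downstream rather than dropping the site.
#'
#' @param site_quality Numeric vector (recycled) of site QUAL values.
#' @param depth Numeric vector of per-genotype read depths.
#' @param dosage Integer vector of allele dosages; NA means uncalled.
#' @param cfg A [burden_config()].
#' @return Logical vector.
#' @examples
#' passes_qc(site_quality = 21, depth = 11, dosage = 1)  # TRUE
#' passes_qc(site_quality = 20, depth = 50, dosage = 1)  # FALSE: "over 20" is strict
#' @export
passes_qc <- function(site_quality, depth, dosage, cfg = burden_config()) {
  !is.na(dosage) &
    !is.na(site_quality) & site_quality > cfg$min_site_quality &
    !is.na(depth) & depth > cfg$min_depth
}

#' Qualifying variants of one class, as tibble + cleaned dosage matrix
#'
#' Applies the full qualifying-variant filter chain to a cohort: keeps sites
#' that are rare and of the requested consequence class, zeroes out genotype
#' calls failing per-genotype QC, and returns the reduced cohort view used by
#' collapsing. The filter chain is idempotent and monotone in its thresholds.
#'
#' @param cohort A [burden_cohort()].
#' @param variant_class `"missense"`, `"lof"`, or `"any"` (both classes).
#' @param cfg A [burden_config()].
#' @return A list with `variants` (tibble of qualifying sites, with a
#'   `consequence_class` column) and `dosage` (integer matrix, QC-failing
#'   genotypes set to 0, no NA left).
#' @export
qualifying_variants <- function(cohort,
                                variant_class = c("missense", "lof", "any"),
                                cfg = burden_config()) {
  stopifnot(inherits(cohort, "burden_cohort"))
  variant_class <- match.arg(variant_class)
  v <- cohort$variants
  cls <- classify_consequence(v$consequence, cfg)
  keep <- is_rare(v$pop_af, cfg) &
    if (variant_class == "any") cls != "other" else cls == variant_class
  v <- dplyr::mutate(v[keep, , drop = FALSE],
                     consequence_class = cls[keep])
  d <- cohort$dosage[keep, , drop = FALSE]
  dp <- cohort$depth[keep, , drop = FALSE]
  qual <- matrix(v$qual, nrow(d), ncol(d))  # site quality recycled per sample
  ok <- passes_qc(qual, dp, d, cfg)
  d[!ok] <- 0L
  list(variants = v, dosage = d)
}

#' Filter-stage counts for the run manifest
#'
#' @param cohort A [burden_cohort()].
#' @param cfg A [burden_config()].
#' @return One-row tibble: records read, rare, and qualifying sites by class.
#' @export
filter_stage_counts <- function(cohort, cfg = burden_config()) {
  v <- cohort$variants
  cls <- classify_consequence(v$consequence, cfg)
  rare <- is_rare(v$pop_af, cfg)
  tibble::tibble(
    cohort = cohort$label,
    n_records = nrow(v),
    n_rare = sum(rare),
    n_qualifying_missense = sum(rare & cls == "missense"),
    n_qualifying_lof = sum(rare & cls == "lof")
  )
}
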