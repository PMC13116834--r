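# gene x sample matrices of qualifying-genotype summaries; shared by the
# per-gene collapse and the gene-set collapse
gene_sample_summaries <- function(cohort, variant_class, cfg) {
  q <- qualifying_variants(cohort, variant_class, cfg)
  d <- q$dosage
  gene <- q$variants$gene
  if (nrow(d) == 0) {
    empty <- matrix(0L, 0, length(cohort$samples),
                    dimnames = list(NULL, cohort$samples))
    return(list(hom = empty > 0, het_count = empty, ac = empty,
                n_sites = integer(0)))
  }
  hom <- rowsum((d == 2L) + 0L, gene) > 0
  het_count <- rowsum((d == 1L) + 0L, gene)
  ac <- rowsum(d + 0L, gene)
  site_observed <- rowSums(d > 0L) > 0
  n_sites <- vapply(split(site_observed, gene), sum, numeric(1))
  list(hom = hom, het_count = het_count, ac = ac,
       n_sites = as.integer(n_sites[rownames(hom)]))
}

#' Collapse qualifying genotypes into per-gene carrier counts
#'
#' Assigns each individual to exactly one carrier category per gene, with
#' precedence HOM > CH > HET: any homozygous qualifying site makes the
#' individual a HOM carrier; otherwise two or more distinct heterozygous
#' qualifying sites make a putative compound heterozygote (CH; phase-naive,
#' as unphased exome data cannot establish trans configuration); otherwise a
#' single heterozygous site makes a HET carrier. `total_ac` is the sum of
#' qualifying allele dosages over all individuals. `n_sites` counts distinct
#' qualifying sites with at least one carrier in this cohort, the quantity
#' the gene-inclusion rule checks.
#'
#' @param cohort A [burden_cohort()].
#' @param variant_class `"missense"`, `"lof"`, or `"any"`.
#' @param cfg A [burden_config()].
#' @return Tibble with one row per gene observed in the cohort: `gene`,
#'   `n_het`, `n_ch`, `n_hom`, `total_ac`, `n_sites`, `n_samples`.
#' @examples
#' # an individual with one heterozygous qualifying site is a HET carrier;
#' # with two distinct heterozygous sites, a CH carrier
#' @export
collapse_carriers <- function(cohort,
                              variant_class = c("missense", "lof", "any"),
                              cfg = burden_config()) {
  variant_class <- match.arg(variant_class)
  s <- gene_sample_summaries(cohort, variant_class, cfg)
  ch <- !s$hom & s$het_count >= 2L
  het <- !s$hom & s$het_count == 1L
  tibble::tibble(
    gene = rownames(s$hom) %||% character(0),
    n_het = as.integer(rowSums(het)),
    n_ch = as.integer(rowSums(ch)),
    n_hom = as.integer(rowSums(s$hom)),
    total_ac = as.integer(rowSums(s$ac)),
    n_sites = s$n_sites,
    n_samples = n_samples(cohort)
  )
}

#' Collapse a single gene
#'
#' @inheritParams collapse_carriers
#' @param gene Gene symbol; must have qualifying variants in the cohort.
#' @return One-row tibble as in [collapse_carriers()].
#' @export
collapse_gene <- function(cohort, gene,
                          variant_class = c("missense", "lof", "any"),
                          cfg = burden_config()) {
  counts <- collapse_carriers(cohort, variant_class, cfg)
  row <- counts[counts$gene == gene, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("gene not present among qualifying variants: ", gene, call. = FALSE)
  }
  row
}

#' Dominant-model carriers
#'
#' An individual is a dominant-model carrier when they harbor at least one
#' qualifying allele in the gene: HET + CH + HOM.
#'
#' @param counts Tibble from [collapse_carriers()] (or any tibble with
#'   `n_het`, `n_ch`, `n_hom` columns).
#' @return Integer vector, one entry per row of `counts`.
#' @export
dominant_carriers <- function(counts) {
  as.integer(counts$n_het + counts$n_ch + counts$n_hom)
}

#' Recessive-model carriers
#'
#' An individual is a recessive-model carrier when they carry a putative
#' biallelic genotype: homozygous for a qualifying variant, or heterozygous
#' at two or more distinct qualifying sites (unphased compound heterozygote).
#'
#' @inheritParams dominant_carriers
#' @return Integer vector.
#' @export
recessive_carriers <- function(counts) {
  as.integer(counts$n_ch + counts$n_hom)
}

#' Per-individual carrier status across genes
#'
#' @param cohort A [burden_cohort()].
#' @param variant_class `"missense"`, `"lof"`, or `"any"`.
#' @param model `"dominant"` or `"recessive"`.
#' @param cfg A [burden_config()].
#' @return Logical gene x sample matrix: is each individual a carrier in
#'   each gene under the chosen inheritance model?
#' @export
carrier_matrix <- function(cohort,
                           variant_class = c("missense", "lof", "any"),
                           model = c("dominant", "recessive"),
                           cfg = burden_config()) {
  variant_class <- match.arg(variant_class)
  model <- match.arg(model)
  s <- gene_sample_summaries(cohort, variant_class, cfg)
  if (model == "dominant") {
    s$hom | s$het_count >= 1L
  } else {
    s$hom | s$het_count >= 2L
  }
}
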