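#' Gene-level case-control burden test
#'
#' Runs the full gene-level collapsing burden analysis for one variant
#' class: collapse qualifying genotypes per gene in each cohort, apply the
#' gene-inclusion rule (at least `min_variants` distinct qualifying sites in
#' each cohort), test every included gene with the exact carrier test under
#' both inheritance models, and adjust p-values with Benjamini-Hochberg
#' separately per model, with the family size equal to the number of genes
#' tested for this variant class. Excluded genes are kept in the output
#' flagged `tested = FALSE` with `NA` p-values — never silently dropped.
#'
#' The dominant 2x2 table contrasts HET+CH+HOM carriers against
#' non-carriers across cohorts; the recessive table contrasts CH+HOM
#' (putative biallelic) carriers against the rest.
#'
#' @param cases,controls [burden_cohort()] objects sharing the same
#'   filtering configuration.
#' @param variant_class `"missense"` or `"lof"` (or `"any"`).
#' @param cfg A [burden_config()]; `cfg$alternative` fixes the sidedness of
#'   the exact test.
#' @return A tibble of class `gene_burden`, sorted by dominant-model
#'   p-value, with per-cohort carrier counts (`case_het`, `case_ch`,
#'   `case_hom`, `case_ac`, `case_sites`, `case_n`, and `ctrl_*`
#'   equivalents), `p_dom`, `p_rec`, `q_dom`, `q_rec`, and `tested`.
#' @examples
#' cfg <- simulation_config(n_cases = 60, n_controls = 120, n_genes = 4,
#'                          seed = 7)
#' sim <- simulate_cohorts(cfg)
#' run_gene_burden(sim$cases, sim$controls, "missense")
#' @export
run_gene_burden <- function(cases, controls,
                            variant_class = c("missense", "lof", "any"),
                            cfg = burden_config()) {
  stopifnot(inherits(cases, "burden_cohort"),
            inherits(controls, "burden_cohort"))
  variant_class <- match.arg(variant_class)

  case_counts <- collapse_carriers(cases, variant_class, cfg)
  ctrl_counts <- collapse_carriers(controls, variant_class, cfg)

  res <- dplyr::full_join(
    dplyr::rename_with(case_counts, ~ paste0("case_", sub("^n_", "", .x)),
                       -"gene"),
    dplyr::rename_with(ctrl_counts, ~ paste0("ctrl_", sub("^n_", "", .x)),
                       -"gene"),
    by = "gene"
  )
  res <- dplyr::mutate(
    res,
    dplyr::across(dplyr::starts_with(c("case_", "ctrl_")),
                  ~ tidyr::replace_na(.x, 0L)),
    case_n = n_samples(cases),
    ctrl_n = n_samples(controls),
    # rename to the report schema
    case_ac = .data$case_total_ac, ctrl_ac = .data$ctrl_total_ac,
    tested = gene_inclusion(.data$case_sites, .data$ctrl_sites,
                            cfg$min_variants)
  )
  res <- dplyr::select(res, -"case_total_ac", -"ctrl_total_ac",
                       -"case_samples", -"ctrl_samples")

  if (!any(res$tested)) {
    warning("no genes pass the inclusion rule (>= ", cfg$min_variants,
            " qualifying sites in each cohort) for class '", variant_class,
            "'", call. = FALSE)
  }

  case_dom <- res$case_het + res$case_ch + res$case_hom
  ctrl_dom <- res$ctrl_het + res$ctrl_ch + res$ctrl_hom
  case_rec <- res$case_ch + res$case_hom
  ctrl_rec <- res$ctrl_ch + res$ctrl_hom
  t_idx <- which(res$tested)

  res$p_dom <- res$p_rec <- NA_real_
  res$p_dom[t_idx] <- fisher_exact_p(
    case_dom[t_idx], res$case_n[t_idx] - case_dom[t_idx],
    ctrl_dom[t_idx], res$ctrl_n[t_idx] - ctrl_dom[t_idx],
    alternative = cfg$alternative
  )
  res$p_rec[t_idx] <- fisher_exact_p(
    case_rec[t_idx], res$case_n[t_idx] - case_rec[t_idx],
    ctrl_rec[t_idx], res$ctrl_n[t_idx] - ctrl_rec[t_idx],
    alternative = cfg$alternative
  )
  res$q_dom <- res$q_rec <- NA_real_
  res$q_dom[t_idx] <- bh_adjust(res$p_dom[t_idx])
  res$q_rec[t_idx] <- bh_adjust(res$p_rec[t_idx])

  res <- dplyr::arrange(res, dplyr::desc(.data$tested), .data$p_dom,
                        .data$gene)
  res <- dplyr::relocate(
    res, "gene",
    "case_het", "case_ch", "case_hom", "case_ac", "case_sites", "case_n",
    "ctrl_het", "ctrl_ch", "ctrl_hom", "ctrl_ac", "ctrl_sites", "ctrl_n",
    "p_dom", "p_rec", "q_dom", "q_rec", "tested"
  )
  structure(res,
            class = c("gene_burden", class(res)),
            variant_class = variant_class,
            alternative = cfg$alternative,
            n_tested = length(t_idx),
            alpha = cfg$alpha)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a gene burden result
#'
#' One row per tested gene and inheritance model, with the carrier counts
#' entering the 2x2 table and raw/adjusted p-values.
#'
#' @param x A `gene_burden` tibble from [run_gene_burden()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `model`, `case_carriers`,
#'   `case_n`, `ctrl_carriers`, `ctrl_n`, `estimate` (carrier odds ratio,
#'   unconditional), `p.value`, `q.value`.
#' @export
tidy.gene_burden <- function(x, ...) {
  tested <- dplyr::filter(tibble::as_tibble(x), .data$tested)
  long <- dplyr::bind_rows(
    dominant = dplyr::transmute(
      tested, gene = .data$gene,
      case_carriers = .data$case_het + .data$case_ch + .data$case_hom,
      case_n = .data$case_n,
      ctrl_carriers = .data$ctrl_het + .data$ctrl_ch + .data$ctrl_hom,
      ctrl_n = .data$ctrl_n,
      p.value = .data$p_dom, q.value = .data$q_dom),
    recessive = dplyr::transmute(
      tested, gene = .data$gene,
      case_carriers = .data$case_ch + .data$case_hom,
      case_n = .data$case_n,
      ctrl_carriers = .data$ctrl_ch + .data$ctrl_hom,
      ctrl_n = .data$ctrl_n,
      p.value = .data$p_rec, q.value = .data$q_rec),
    .id = "model"
  )
  dplyr::relocate(
    dplyr::mutate(
      long,
      estimate = (.data$case_carriers / pmax(.data$case_n - .data$case_carriers, 0.5)) /
        pmax(.data$ctrl_carriers / pmax(.data$ctrl_n - .data$ctrl_carriers, 0.5),
             .Machine$double.eps)
    ),
    "gene", "model", "case_carriers", "case_n", "ctrl_carriers", "ctrl_n",
    "estimate", "p.value", "q.value"
  )
}

#' Summarise a gene burden result in one row
#'
#' @param x A `gene_burden` tibble.
#' @param ... Unused.
#' @return A one-row tibble: genes observed and tested, nominally
#'   significant counts per model, and FDR-significant counts per model.
#' @export
glance.gene_burden <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble::tibble(
    variant_class = attr(x, "variant_class"),
    n_genes = nrow(x),
    n_tested = sum(x$tested),
    n_nominal_dom = sum(x$p_dom < alpha, na.rm = TRUE),
    n_nominal_rec = sum(x$p_rec < alpha, na.rm = TRUE),
    n_fdr_dom = sum(x$q_dom < alpha, na.rm = TRUE),
    n_fdr_rec = sum(x$q_rec < alpha, na.rm = TRUE)
  )
}

#' Plot a gene burden result
#'
#' Dot plot of -log10 p-values per tested gene and inheritance model, with
#' the nominal significance threshold drawn as a dashed line.
#'
#' @param object A `gene_burden` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_burden <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  long <- tidy(object)
  long <- dplyr::mutate(
    long, gene = stats::reorder(.data$gene, -.data$p.value))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = -log10(.data$p.value), y = .data$gene,
                               colour = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = expression(-log[10](p)), y = NULL, colour = "model",
      title = paste0("Rare-variant burden (",
                     attr(object, "variant_class"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
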