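#' Run the full burden pipeline
#'
#' Orchestrates every stage for one pair of cohort VCFs: ingest, qualifying
#' variant filtering, per-gene collapsing and burden testing for each
#' requested variant class, optional panel-level gene-set testing, and
#' deterministic TSV reports plus a JSON run manifest recording the
#' configuration, input digests and filter-stage counts. Re-running with
#' identical inputs and configuration reproduces byte-identical TSVs.
#'
#' Report p-values are rounded to 4 decimals in the `p_dom`/`p_rec` display
#' columns; full-precision values are retained in `p_dom_full`/`p_rec_full`.
#'
#' @param case_vcf,control_vcf Paths to the cohort VCFs, or already-loaded
#'   [burden_cohort()] objects.
#' @param panels Optional panel source for gene-set tests: a directory, file
#'   paths, or a named list of gene symbol vectors. `NULL` skips gene-set
#'   testing (a warning notes gene-level results only).
#' @param cfg A [burden_config()].
#' @param out_dir Output directory; created if needed.
#' @param variant_classes Variant classes to analyse.
#' @return Invisibly, a list with `gene` (named list of `gene_burden`
#'   tibbles per class), `geneset` (tibble or NULL), `manifest` (list), and
#'   the paths written.
#' @export
run_pipeline <- function(case_vcf, control_vcf, panels = NULL,
                         cfg = burden_config(),
                         out_dir = ".",
                         variant_classes = c("missense", "lof")) {
  t0 <- Sys.time()
  load_cohort <- function(x, label) {
    if (inherits(x, "burden_cohort")) x else read_cohort(x, label, cfg)
  }
  cases <- load_cohort(case_vcf, "case")
  controls <- load_cohort(control_vcf, "control")

  panel_list <- NULL
  if (!is.null(panels)) {
    panel_list <- if (is.list(panels)) panels else read_gene_panels(panels)
    if (length(panel_list) == 0) {
      warning("no panels found; emitting gene-level results only",
              call. = FALSE)
      panel_list <- NULL
    }
  }

  gene_results <- purrr::map(
    rlang::set_names(variant_classes),
    function(cl) {
      withCallingHandlers(
        run_gene_burden(cases, controls, cl, cfg),
        warning = function(w) {
          message("note [", cl, "]: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
    }
  )

  geneset_results <- NULL
  if (!is.null(panel_list)) {
    geneset_results <- run_geneset_burden(cases, controls, panel_list,
                                          variant_class = "missense",
                                          model = "dominant", cfg = cfg)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (cl in variant_classes) {
    res <- gene_results[[cl]]
    out <- dplyr::mutate(
      tibble::as_tibble(res),
      p_dom_full = .data$p_dom, p_rec_full = .data$p_rec,
      p_dom = round(.data$p_dom, 4), p_rec = round(.data$p_rec, 4),
      q_dom = round(.data$q_dom, 4), q_rec = round(.data$q_rec, 4)
    )
    p <- file.path(out_dir, paste0("gene_burden_", cl, ".tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("gene_", cl)]] <- p
  }
  if (!is.null(geneset_results)) {
    p <- file.path(out_dir, "geneset_burden.tsv")
    utils::write.table(tibble::as_tibble(geneset_results), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$geneset <- p
  }

  digest_or_na <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unname(tools::md5sum(x))
    } else {
      NA_character_
    }
  }
  manifest <- list(
    tool = "rvburden",
    version = as.character(utils::packageVersion("rvburden")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    inputs = list(
      case_vcf = if (is.character(case_vcf)) case_vcf else "in-memory cohort",
      control_vcf = if (is.character(control_vcf)) control_vcf
                    else "in-memory cohort",
      case_md5 = digest_or_na(case_vcf),
      control_md5 = digest_or_na(control_vcf)
    ),
    filter_counts = dplyr::bind_rows(filter_stage_counts(cases, cfg),
                                     filter_stage_counts(controls, cfg)),
    genes_tested = purrr::map_int(gene_results, ~ sum(.x$tested)),
    n_panels = length(panel_list %||% list())
  )
  mp <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  paths$manifest <- mp

  invisible(list(gene = gene_results, geneset = geneset_results,
                 manifest = manifest, paths = paths))
}
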