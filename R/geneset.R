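#' Read gene panels
#'
#' Panels are plain-text files with one gene symbol per line; blank lines
#' and `#` comments are ignored. Duplicate symbols within a panel are
#' dropped with a warning. The panel name is the file name without
#' extension.
#'
#' @param paths Character vector of panel file paths, or a single directory
#'   (every `*.txt`/`*.list` file in it is read).
#' @return A named list of character vectors (one per panel).
#' @export
read_gene_panels <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(txt|list)$", full.names = TRUE)
  }
  if (length(paths) == 0) return(list())
  panels <- lapply(paths, function(p) {
    lines <- trimws(readLines(p, warn = FALSE))
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (anyDuplicated(lines)) {
      warning("duplicate gene symbols in panel ", basename(p),
              "; keeping unique set", call. = FALSE)
      lines <- unique(lines)
    }
    lines
  })
  names(panels) <- sub("\\.[^.]*$", "", basename(paths))
  panels
}

#' Count carriers across a gene set
#'
#' Collapses carrier status at the individual level across every member
#' gene of a panel: under the dominant model an individual counts once if
#' they carry at least one qualifying allele in *any* member gene; under
#' the recessive model, if they are a recessive-model carrier (homozygous
#' or putative compound heterozygote) in at least one member gene. Genes
#' absent from the cohort contribute nothing.
#'
#' @param cohort A [burden_cohort()].
#' @param genes Non-empty character vector of member gene symbols.
#' @param model `"dominant"` or `"recessive"`.
#' @param variant_class `"missense"`, `"lof"`, or `"any"`.
#' @param cfg A [burden_config()].
#' @return Integer: number of carrier individuals (each counted once).
#' @export
set_carriers <- function(cohort, genes,
                         model = c("dominant", "recessive"),
                         variant_class = c("missense", "lof", "any"),
                         cfg = burden_config()) {
  model <- match.arg(model)
  variant_class <- match.arg(variant_class)
  if (length(genes) == 0) {
    stop("gene set must contain at least one gene symbol", call. = FALSE)
  }
  cm <- carrier_matrix(cohort, variant_class, model, cfg)
  member <- rownames(cm) %in% genes
  if (!any(member)) return(0L)
  as.integer(sum(colSums(cm[member, , drop = FALSE]) > 0))
}

#' Panel-level burden tests
#'
#' For each supplied panel, and for the union of all panel genes, collapses
#' carrier status across the set in each cohort and applies the exact
#' carrier test. The paper-style default tests the dominant model with no
#' multiple-testing correction across panels (results are nominal);
#' `adjust = TRUE` adds BH-adjusted values across the panel family.
#'
#' @param cases,controls [burden_cohort()] objects.
#' @param panels Named list of character vectors (from
#'   [read_gene_panels()]), or a single character vector (treated as one
#'   panel named `"set"`).
#' @param variant_class `"missense"`, `"lof"`, or `"any"`.
#' @param model `"dominant"` or `"recessive"`.
#' @param cfg A [burden_config()].
#' @param union_set Add a row for the union of all panel genes
#'   (default TRUE when more than one panel).
#' @param adjust Add BH-adjusted p-values across panels (default FALSE).
#' @return A tibble of class `geneset_burden`: one row per panel with panel
#'   size, carrier counts in each cohort, cohort sizes and `p.value`.
#' @export
run_geneset_burden <- function(cases, controls, panels,
                               variant_class = c("missense", "lof", "any"),
                               model = c("dominant", "recessive"),
                               cfg = burden_config(),
                               union_set = length(panels) > 1,
                               adjust = FALSE) {
  variant_class <- match.arg(variant_class)
  model <- match.arg(model)
  if (is.character(panels)) panels <- list(set = panels)
  if (length(panels) == 0) {
    stop("no panels supplied", call. = FALSE)
  }
  if (any(lengths(panels) == 0)) {
    stop("gene set must contain at least one gene symbol", call. = FALSE)
  }
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    stop("panels must be named", call. = FALSE)
  }
  if (union_set) {
    panels <- c(panels, list(all_panel_genes = unique(unlist(panels))))
  }

  case_cm <- carrier_matrix(cases, variant_class, model, cfg)
  ctrl_cm <- carrier_matrix(controls, variant_class, model, cfg)
  count_set <- function(cm, genes) {
    member <- rownames(cm) %in% genes
    if (!any(member)) 0L
    else as.integer(sum(colSums(cm[member, , drop = FALSE]) > 0))
  }

  res <- purrr::imap_dfr(panels, function(genes, name) {
    a <- count_set(case_cm, genes)
    b <- count_set(ctrl_cm, genes)
    tibble::tibble(
      set = name,
      n_genes = length(unique(genes)),
      case_carriers = a, case_n = n_samples(cases),
      ctrl_carriers = b, ctrl_n = n_samples(controls)
    )
  })
  res$p.value <- fisher_exact_p(
    res$case_carriers, res$case_n - res$case_carriers,
    res$ctrl_carriers, res$ctrl_n - res$ctrl_carriers,
    alternative = cfg$alternative
  )
  if (adjust) res$q.value <- bh_adjust(res$p.value)
  structure(res,
            class = c("geneset_burden", class(res)),
            variant_class = variant_class, model = model,
            alternative = cfg$alternative)
}

#' Plot panel-level burden results
#'
#' Carrier-frequency dot plot per panel: case and control carrier fractions
#' side by side, annotated with the exact-test p-value.
#'
#' @param object A `geneset_burden` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geneset_burden <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  case = .data$case_carriers / .data$case_n,
                  control = .data$ctrl_carriers / .data$ctrl_n),
    cols = c("case", "control"),
    names_to = "cohort", values_to = "carrier_freq"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$carrier_freq, y = .data$set,
                               colour = .data$cohort)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "carrier frequency", y = NULL,
                  title = "Gene-set carrier burden") +
    ggplot2::theme_minimal()
}
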