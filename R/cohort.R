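#' Construct a cohort genotype container
#'
#' A `burden_cohort` holds one cohort's annotated variant sites together with
#' its samples-by-sites genotype dosages and depths. Variants are a tibble
#' (one row per biallelic site); dosages and depths are integer matrices with
#' one row per variant and one column per sample, `NA` marking uncalled
#' genotypes. This is the object every pipeline stage consumes; it is built
#' by [read_cohort()] from a VCF or directly by [simulate_cohorts()].
#'
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `pop_af` (NA allowed), `qual`.
#' @param dosage Integer matrix, variants x samples, entries in
#'   `{0, 1, 2, NA}`.
#' @param depth Integer matrix of per-genotype read depths, same shape.
#' @param samples Character vector of sample identifiers (column order).
#' @param label Cohort label, `"case"` or `"control"`.
#'
#' @return An object of class `burden_cohort`.
#' @export
burden_cohort <- function(variants, dosage, depth, samples,
                          label = c("case", "control")) {
  label <- match.arg(label)
  variants <- tibble::as_tibble(variants)
  needed <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
              "consequence", "pop_af", "qual")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants tibble lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dosage <- as.matrix(dosage)
  depth <- as.matrix(depth)
  stopifnot(
    nrow(dosage) == nrow(variants),
    ncol(dosage) == length(samples),
    all(dim(depth) == dim(dosage)),
    all(dosage %in% c(0L, 1L, 2L, NA)),
    all(variants$pos >= 1, na.rm = TRUE),
    anyDuplicated(variants$variant_id) == 0
  )
  storage.mode(dosage) <- "integer"
  storage.mode(depth) <- "integer"
  rownames(dosage) <- rownames(depth) <- variants$variant_id
  colnames(dosage) <- colnames(depth) <- samples
  structure(
    list(label = label, samples = as.character(samples),
         variants = variants, dosage = dosage, depth = depth),
    class = "burden_cohort"
  )
}

#' @export
print.burden_cohort <- function(x, ...) {
  cat("<burden_cohort> ", x$label, ": ", length(x$samples), " samples, ",
      nrow(x$variants), " variant sites, ",
      dplyr::n_distinct(x$variants$gene), " genes\n", sep = "")
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A `burden_cohort`.
#' @return Integer cohort size.
#' @export
n_samples <- function(cohort) {
  stopifnot(inherits(cohort, "burden_cohort"))
  length(cohort$samples)
}

# dosage of one alt allele from diploid GT strings; handles phased and
# multi-allelic calls, "." anywhere in the call means uncalled
gt_to_dosage <- function(gt, allele_index = 1L) {
  gt <- sub(":.*$", "", gt)
  common <- c(
    "0/0" = 0L, "0|0" = 0L,
    "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
    "1/1" = 2L, "1|1" = 2L,
    "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_
  )
  out <- rep(NA_integer_, length(gt))
  if (allele_index == 1L) {
    hit <- gt %in% names(common)
    out[hit] <- common[gt[hit]]
  } else {
    hit <- rep(FALSE, length(gt))
  }
  todo <- which(!hit & !is.na(gt))
  if (length(todo) > 0) {
    tgt <- as.character(allele_index)
    parts <- strsplit(gt[todo], "[/|]")
    out[todo] <- vapply(parts, function(a) {
      if (length(a) == 0 || any(a == ".")) NA_integer_ else sum(a == tgt)
    }, integer(1))
  }
  out
}

# pull one key out of a semicolon-delimited INFO string; NA when absent
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

# i-th element of a comma-separated per-allele annotation; a scalar value
# applies to every allele
allele_slot <- function(x, i) {
  parts <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
  vapply(seq_along(x), function(j) {
    p <- parts[[j]]
    if (length(p) == 0) NA_character_
    else if (length(p) == 1) p[1]
    else if (i[j] <= length(p)) p[i[j]]
    else NA_character_
  }, character(1))
}

#' Read an annotated cohort VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped) whose records carry a gene
#' symbol, a consequence term and a population allele frequency in INFO
#' fields (key names configurable via [burden_config()]), and per-sample
#' `GT` with `DP`. Multi-allelic records are split into one biallelic site
#' per alternate allele, with comma-separated per-allele annotations sliced
#' accordingly; sample order is preserved as in the header.
#'
#' @param path Path to the VCF file.
#' @param label Cohort label, `"case"` or `"control"`.
#' @param cfg A [burden_config()]; supplies the annotation key names.
#'
#' @return A [burden_cohort()].
#' @export
read_cohort <- function(path, label = c("case", "control"),
                        cfg = burden_config()) {
  label <- match.arg(label)
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    stop("no variant records in ", path, call. = FALSE)
  }
  samples <- colnames(vcf@gt)[-1]
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  )
  if (is.null(dp_raw)) dp_raw <- matrix(NA_real_, nrow(fix), length(samples))

  for (key in c(cfg$gene_key, cfg$csq_key)) {
    vals <- info_field(fix$INFO, key)
    if (anyNA(vals)) {
      first_bad <- which(is.na(vals))[1]
      stop("INFO key '", key, "' missing, first offending record: ",
           fix$CHROM[first_bad], ":", fix$POS[first_bad], call. = FALSE)
    }
  }

  # one output row per (record, alt allele)
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_len(nrow(fix)), n_alt)
  aidx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  info <- fix$INFO[rec]
  af_chr <- allele_slot(info_field(info, cfg$af_key), aidx)
  variants <- tibble::tibble(
    chrom = fix$CHROM[rec],
    pos = as.integer(fix$POS[rec]),
    ref = fix$REF[rec],
    alt = unlist(alt_list, use.names = FALSE),
    gene = allele_slot(info_field(info, cfg$gene_key), aidx),
    consequence = allele_slot(info_field(info, cfg$csq_key), aidx),
    pop_af = suppressWarnings(as.numeric(af_chr)),
    qual = suppressWarnings(as.numeric(fix$QUAL[rec]))
  )
  variants$variant_id <- paste0(variants$chrom, ":", variants$pos, "_",
                                variants$ref, ">", variants$alt)

  dosage <- matrix(NA_integer_, nrow(variants), length(samples))
  for (k in sort(unique(aidx))) {
    rows_k <- which(aidx == k)
    gt_k <- gt_raw[rec[rows_k], , drop = FALSE]
    dosage[rows_k, ] <- gt_to_dosage(as.vector(gt_k), allele_index = k)
  }
  depth <- matrix(as.integer(round(dp_raw[rec, , drop = FALSE])),
                  nrow(variants), length(samples))

  burden_cohort(variants, dosage, depth, samples, label)
}

#' Write a cohort to a VCF file
#'
#' Emits a VCF 4.2 file with a self-describing header declaring the INFO
#' keys that [read_cohort()] consumes, `GT:DP` genotypes, and one biallelic
#' record per variant site. Output is gzip-compressed (vcfR convention);
#' name the file `*.vcf.gz`.
#'
#' @param cohort A [burden_cohort()].
#' @param path Output path (should end in `.vcf.gz`).
#' @param cfg A [burden_config()]; supplies annotation key names.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, cfg = burden_config()) {
  stopifnot(inherits(cohort, "burden_cohort"))
  v <- cohort$variants
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=", cfg$gene_key,
           ",Number=A,Type=String,Description=\"Gene symbol\">"),
    paste0("##INFO=<ID=", cfg$csq_key,
           ",Number=A,Type=String,Description=\"Consequence term\">"),
    paste0("##INFO=<ID=", cfg$af_key,
           ",Number=A,Type=Float,Description=\"Population allele frequency\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
  )
  af_part <- ifelse(is.na(v$pop_af), "",
                    paste0(";", cfg$af_key, "=", format(v$pop_af, trim = TRUE,
                                                        scientific = FALSE)))
  info <- paste0(cfg$gene_key, "=", v$gene, ";",
                 cfg$csq_key, "=", v$consequence, af_part)
  fix <- cbind(
    CHROM = v$chrom, POS = as.character(v$pos), ID = v$variant_id,
    REF = v$ref, ALT = v$alt,
    QUAL = ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE)),
    FILTER = "PASS", INFO = info
  )
  gt_code <- c("0/0", "0/1", "1/1")
  d <- cohort$dosage
  gt_chr <- matrix(ifelse(is.na(d), "./.", gt_code[d + 1L]),
                   nrow(d), ncol(d))
  dp_chr <- matrix(ifelse(is.na(cohort$depth), ".",
                          as.character(cohort$depth)),
                   nrow(d), ncol(d))
  gt <- cbind(FORMAT = rep("GT:DP", nrow(d)),
              matrix(paste(gt_chr, dp_chr, sep = ":"), nrow(d), ncol(d),
                     dimnames = list(NULL, cohort$samples)))
  out <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}
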