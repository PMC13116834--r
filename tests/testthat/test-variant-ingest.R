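# VCF ingestion, QC, rarity and consequence classification.

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">"
  )
  writeLines(c(header, lines), path)
  path
}

test_that("a three-record single-sample VCF transcribes dosages directly", {
  p <- write_test_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tT\t99\tPASS\tGENE=G1;CSQ=missense_variant;AF=0.001\tGT:DP\t0/1:30",
    "1\t200\t.\tG\tC\t80\tPASS\tGENE=G1;CSQ=missense_variant;AF=0.002\tGT:DP\t1/1:25",
    "1\t300\t.\tT\tA\t70\tPASS\tGENE=G2;CSQ=stop_gained;AF=0.003\tGT:DP\t0/0:40"
  ))
  cohort <- read_cohort(p, "case")
  expect_equal(nrow(cohort$variants), 3)
  expect_equal(unname(cohort$dosage[, 1]), c(1L, 2L, 0L))
  expect_equal(unname(cohort$depth[, 1]), c(30L, 25L, 40L))
  expect_equal(cohort$variants$gene, c("G1", "G1", "G2"))
  expect_equal(cohort$variants$pop_af, c(0.001, 0.002, 0.003))
  expect_equal(cohort$variants$qual, c(99, 80, 70))
  expect_equal(cohort$samples, "S1")
})

test_that("multi-allelic records split into per-allele biallelic sites", {
  p <- write_test_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste0("1\t500\t.\tA\tT,G\t99\tPASS\t",
           "GENE=G1,G1;CSQ=missense_variant,stop_gained;AF=0.001,0.02\t",
           "GT:DP\t1/2:30\t2/2:20")
  ))
  cohort <- read_cohort(p, "case")
  expect_equal(nrow(cohort$variants), 2)
  expect_equal(cohort$variants$pos, c(500L, 500L))
  expect_equal(cohort$variants$alt, c("T", "G"))
  expect_equal(cohort$variants$consequence,
               c("missense_variant", "stop_gained"))
  expect_equal(cohort$variants$pop_af, c(0.001, 0.02))
  # S1 is 1/2: one copy of each allele; S2 is 2/2
  expect_equal(unname(cohort$dosage), matrix(c(1L, 1L, 0L, 2L), 2))
})

test_that("missing genotypes read as NA and missing files/keys are fatal", {
  p <- write_test_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tT\t99\tPASS\tGENE=G1;CSQ=missense_variant\tGT:DP\t./.:."
  ))
  cohort <- read_cohort(p, "case")
  expect_true(is.na(cohort$dosage[1, 1]))
  expect_true(is.na(cohort$variants$pop_af[1]))  # absent AF key -> NA

  expect_error(read_cohort(tempfile(), "case"), "not found")
  p2 <- write_test_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tT\t99\tPASS\tCSQ=missense_variant;AF=0.1\tGT:DP\t0/1:30"
  ))
  expect_error(read_cohort(p2, "case"), "GENE.*1:100")
})

test_that("per-genotype QC uses strict thresholds and uncalled fails", {
  expect_true(passes_qc(site_quality = 21, depth = 11, dosage = 1))
  expect_false(passes_qc(site_quality = 20, depth = 50, dosage = 1))
  expect_false(passes_qc(site_quality = 50, depth = 10, dosage = 1))
  expect_false(passes_qc(site_quality = 50, depth = 50,
                         dosage = NA_integer_))
  # vectorised over genotypes of one site
  expect_equal(passes_qc(99, c(11, 10, 9), c(1L, 1L, 1L)),
               c(TRUE, FALSE, FALSE))
})

test_that("rarity is a strict cutoff and missing AF counts as rare", {
  expect_equal(is_rare(c(0.049, 0.05, NA, 0, 0.2)),
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
  cfg <- burden_config(max_pop_af = 0.01)
  expect_false(is_rare(0.0499, cfg))
})

test_that("consequence terms map to missense / lof / other", {
  expect_equal(
    classify_consequence(c("missense_variant", "stop_gained",
                           "frameshift_variant", "splice_donor_variant",
                           "splice_acceptor_variant", "synonymous_variant")),
    c("missense", "lof", "lof", "lof", "lof", "other")
  )
  expect_warning(out <- classify_consequence("weird_term"), "weird_term")
  expect_equal(out, "other")
})

test_that("filtering is idempotent and monotone in thresholds", {
  withr::with_seed(11, {
    dos <- matrix(sample(0:2, 60, replace = TRUE, prob = c(.7, .2, .1)), 12)
    cohort <- make_cohort(
      dos, genes = rep(c("G1", "G2", "G3"), each = 4),
      consequence = sample(c("missense_variant", "stop_gained",
                             "synonymous_variant"), 12, replace = TRUE),
      pop_af = runif(12, 0, 0.1),
      depth = matrix(sample(5:40, 60, replace = TRUE), 12)
    )
  })
  cfg <- burden_config()
  q1 <- qualifying_variants(cohort, "any", cfg)
  # idempotent: re-filtering the filtered view changes nothing
  sub <- make_cohort(q1$dosage, genes = q1$variants$gene,
                     consequence = q1$variants$consequence,
                     pop_af = q1$variants$pop_af)
  q2 <- qualifying_variants(sub, "any", cfg)
  expect_equal(unname(q2$dosage), unname(q1$dosage))

  # monotone: loosening thresholds never removes a qualifying genotype
  loose <- burden_config(max_pop_af = 0.5, min_depth = 0)
  q3 <- qualifying_variants(cohort, "any", loose)
  strict_ids <- q1$variants$variant_id
  expect_true(all(strict_ids %in% q3$variants$variant_id))
  keep <- match(strict_ids, q3$variants$variant_id)
  expect_true(all(q3$dosage[keep, ] >= q1$dosage))
})

test_that("an all-passing rare synthetic cohort qualifies every genotype", {
  sim <- simulate_cohorts(simulation_config(
    n_cases = 30, n_controls = 30, n_genes = 4, af_min = 0.01,
    af_max = 0.049, seed = 5, class_mix = c(missense = 1, lof = 0, other = 0)
  ))
  q <- qualifying_variants(sim$cases, "missense")
  expect_equal(unname(q$dosage), unname(sim$cases$dosage))
})

test_that("simulated cohorts round-trip through VCF files", {
  sim <- simulate_cohorts(simulation_config(
    n_cases = 15, n_controls = 25, n_genes = 3, seed = 9,
    qc_failure_rate = 0.2
  ))
  f <- tempfile(fileext = ".vcf.gz")
  write_cohort_vcf(sim$cases, f)
  back <- read_cohort(f, "case")
  expect_equal(unname(back$dosage), unname(sim$cases$dosage))
  expect_equal(unname(back$depth), unname(sim$cases$depth))
  expect_equal(back$samples, sim$cases$samples)
  expect_equal(back$variants$gene, sim$cases$variants$gene)
  expect_equal(back$variants$pop_af, sim$cases$variants$pop_af,
               tolerance = 1e-6)
})
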