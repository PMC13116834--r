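# Synthetic cohort generator: determinism, Hardy-Weinberg structure,
# enrichment and QC-failure behaviour, and prescribed-count fixtures.

test_that("the same seed and config reproduce identical cohorts and files", {
  cfg <- simulation_config(n_cases = 20, n_controls = 30, n_genes = 3,
                           seed = 101, qc_failure_rate = 0.1)
  s1 <- simulate_cohorts(cfg)
  s2 <- simulate_cohorts(cfg)
  expect_identical(s1$cases$dosage, s2$cases$dosage)
  expect_identical(s1$controls$depth, s2$controls$depth)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".vcf.gz"); f2 <- tempfile(fileext = ".vcf.gz")
  write_cohort_vcf(s1$cases, f1)
  write_cohort_vcf(s2$cases, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("per-gene substreams: adding genes leaves existing genes alone", {
  c3 <- simulate_cohorts(simulation_config(n_cases = 15, n_controls = 15,
                                           n_genes = 3, seed = 7))
  c5 <- simulate_cohorts(simulation_config(n_cases = 15, n_controls = 15,
                                           n_genes = 5, seed = 7))
  keep <- c5$cases$variants$gene %in% c("G001", "G002", "G003")
  expect_identical(c5$cases$dosage[keep, ], c3$cases$dosage)
  expect_equal(c5$truth$site_afs[1:3], c3$truth$site_afs)
})

test_that("a site with zero allele frequency yields no carriers", {
  sim <- simulate_cohorts(simulation_config(
    n_cases = 50, n_controls = 50, n_genes = 2, af_min = 0, af_max = 0,
    seed = 3
  ))
  expect_true(all(sim$cases$dosage == 0L))
  expect_true(all(sim$controls$dosage == 0L))
})

test_that("null simulation: case and control AFs differ only by noise", {
  sim <- simulate_cohorts(simulation_config(
    n_cases = 500, n_controls = 500, n_genes = 40, sites_per_gene = 5,
    af_min = 0.01, af_max = 0.04, seed = 77
  ))
  af_case <- rowMeans(sim$cases$dosage) / 2
  af_ctrl <- rowMeans(sim$controls$dosage) / 2
  pool <- (af_case + af_ctrl) / 2
  se <- sqrt(pool * (1 - pool) * (1 / 1000 + 1 / 1000))
  z <- (af_case - af_ctrl) / pmax(se, 1e-9)
  expect_gte(mean(abs(z) <= 4), 0.99)
})

test_that("dominant carriers match the Hardy-Weinberg closed form", {
  # E[dominant carriers] = n * (1 - prod((1 - AF_s)^2)) under independence
  n_seeds <- 100
  obs <- exp <- numeric(0)
  for (seed in seq_len(n_seeds)) {
    sim <- simulate_cohorts(simulation_config(
      n_cases = 200, n_controls = 50, n_genes = 2, sites_per_gene = 4,
      af_min = 0.01, af_max = 0.04, seed = 3000 + seed,
      class_mix = c(missense = 1, lof = 0, other = 0)
    ))
    counts <- dplyr::arrange(collapse_carriers(sim$cases, "missense"), gene)
    truth <- dplyr::arrange(sim$truth, gene)
    obs <- c(obs, dominant_carriers(counts))
    exp <- c(exp, truth$expected_dom_carriers_case)
  }
  mcse <- sd(obs - exp) / sqrt(length(obs))
  expect_lte(abs(mean(obs - exp)), 3 * mcse + 1e-9)
})

test_that("enrichment multiplies the case allele frequency", {
  cfg <- simulation_config(n_cases = 2000, n_controls = 100, n_genes = 2,
                           af_min = 0.005, af_max = 0.01,
                           enrichment = 5, enriched_genes = "G001",
                           seed = 55)
  sim <- simulate_cohorts(cfg)
  expect_equal(sim$truth$enrichment, c(5, 1))
  g1 <- sim$cases$variants$gene == "G001"
  af_hat <- rowMeans(sim$cases$dosage[g1, ]) / 2
  af_true <- 5 * sim$truth$site_afs[[1]]
  expect_equal(mean(af_hat / af_true), 1, tolerance = 0.15)
})

test_that("QC failures mask about the prescribed fraction of alleles", {
  base_cfg <- function(rate) simulation_config(
    n_cases = 400, n_controls = 50, n_genes = 10, sites_per_gene = 5,
    af_min = 0.02, af_max = 0.04, seed = 99, qc_failure_rate = rate,
    class_mix = c(missense = 1, lof = 0, other = 0)
  )
  s0 <- simulate_cohorts(base_cfg(0))
  s3 <- simulate_cohorts(base_cfg(0.3))
  # same seed -> identical genotype draws, only depths differ
  expect_identical(s0$cases$dosage, s3$cases$dosage)
  ac0 <- sum(qualifying_variants(s0$cases, "missense")$dosage)
  ac3 <- sum(qualifying_variants(s3$cases, "missense")$dosage)
  drop <- 1 - ac3 / ac0
  mcse <- sqrt(0.3 * 0.7 / ac0)
  expect_lte(abs(drop - 0.3), 3 * mcse)
})

test_that("invalid configurations fail before generating anything", {
  expect_error(simulation_config(af_max = 0.06), "af_max")
  expect_error(simulation_config(enrichment = -1), "enrichment")
  expect_error(simulation_config(enriched_genes = "NOT_A_GENE"),
               "enriched_genes")
  expect_error(simulation_config(class_mix = c(missense = 1, lof = 1,
                                               other = 0)), "class_mix")
})

test_that("prescribed-count fixtures collapse to exactly what was asked", {
  rows <- table1_rows()
  fx <- make_table1_fixture(rows)
  case_counts <- dplyr::arrange(collapse_carriers(fx$cases, "missense"),
                                match(gene, rows$gene))
  expect_equal(case_counts$n_het, rows$case_het)
  expect_equal(case_counts$n_hom, rows$case_hom)
  expect_equal(case_counts$n_ch, rep(0L, 5))
  ctrl_counts <- dplyr::arrange(collapse_carriers(fx$controls, "missense"),
                                match(gene, rows$gene))
  expect_equal(ctrl_counts$n_het, rows$ctrl_het)
  # FBXL4: dominant carriers 24 cases vs 83 controls
  expect_equal(dominant_carriers(case_counts[case_counts$gene == "FBXL4", ]),
               24L)
  expect_equal(dominant_carriers(ctrl_counts[ctrl_counts$gene == "FBXL4", ]),
               83L)
  # compound-het requests collapse exactly too (DLAT-style row)
  fx2 <- make_table1_fixture(
    tibble::tibble(gene = "DLAT", case_het = 8, case_ch = 7,
                   ctrl_het = 115),
    n_cases = 247, n_controls = 1622)
  cc <- collapse_carriers(fx2$cases, "missense")
  expect_equal(cc$n_het, 8L)
  expect_equal(cc$n_ch, 7L)
  expect_equal(recessive_carriers(cc), 7L)

  # an all-zero request gives cohorts with no qualifying alleles
  fx0 <- make_table1_fixture(tibble::tibble(gene = "EMPTY"),
                             n_cases = 5, n_controls = 5)
  cc0 <- collapse_carriers(fx0$cases, "missense")
  expect_equal(dominant_carriers(cc0), 0L)
  expect_equal(cc0$total_ac, 0L)
  expect_equal(cc0$n_sites, 0L)

  # infeasible counts are refused
  expect_error(
    make_table1_fixture(tibble::tibble(gene = "X", case_het = 10),
                        n_cases = 5, n_controls = 5),
    "exceed cohort size"
  )
})
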