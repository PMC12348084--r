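test_that("Balding-Nichols draws have the closed-form mean and variance", {
  spec <- cohort_spec(n_samples = 10, n_autosomal_variants = 10000,
                      n_x_variants = 0, n_populations = 2, fst = 0.1,
                      ancestral_maf_range = c(0.3, 0.3), seed = 11)
  fr <- draw_allele_frequencies(spec)
  f1 <- fr$frequency[fr$population == "EUR"]
  expect_length(f1, 10000)
  # mean p within 3 standard errors; variance fst*p*(1-p) within 10%
  se <- sd(f1) / sqrt(length(f1))
  expect_lt(abs(mean(f1) - 0.3), 3 * se + 1e-12)
  expect_lt(abs(var(f1) - 0.1 * 0.3 * 0.7) / (0.1 * 0.3 * 0.7), 0.1)
})

test_that("population frequencies converge to the ancestral value as fst -> 0", {
  spec <- cohort_spec(n_samples = 10, n_autosomal_variants = 5000,
                      n_x_variants = 0, n_populations = 2, fst = 1e-6,
                      ancestral_maf_range = c(0.2, 0.4), seed = 3)
  fr <- draw_allele_frequencies(spec)
  wide <- tidyr::pivot_wider(fr, names_from = "population", values_from = "frequency")
  expect_lt(max(abs(wide$EUR - wide$AFR)), 0.01)
})

test_that("degenerate structure (fst = 0 with several populations) errors", {
  expect_error(cohort_spec(n_populations = 2, fst = 0), "degenerate")
})

test_that("relationship planting honours copy semantics and hemizygosity", {
  spec <- cohort_spec(
    n_samples = 40, n_autosomal_variants = 2000, n_x_variants = 150,
    n_populations = 1, fst = 0, genotype_error_rate = 0,
    planted_relationships = data.frame(sample_a = 1, sample_b = 2,
                                       degree = "duplicate"),
    seed = 7
  )
  co <- simulate_cohort(spec)
  # duplicate pair identical over every variant before error injection
  expect_identical(co$dataset$calls[1, ], co$dataset$calls[2, ])
  # males carry no heterozygous X calls
  x_cols <- co$dataset$variants$chrom == "X"
  males <- co$true_sex == "male"
  expect_true(all(co$dataset$calls[males, x_cols] %in% c(0L, 2L)))
  # females do show X heterozygotes
  expect_gt(sum(co$dataset$calls[!males, x_cols] == 1L), 0)
})

test_that("gene-dropped siblings recover pedigree kinship through the GRM", {
  spec <- cohort_spec(
    n_samples = 60, n_autosomal_variants = 50000, n_x_variants = 0,
    n_populations = 1, fst = 0, genotype_error_rate = 0,
    autozygosity = 0,
    planted_relationships = data.frame(sample_a = 1, sample_b = 2,
                                       degree = "first"),
    seed = 19
  )
  co <- simulate_cohort(spec)
  grm <- compute_grm(co$dataset)
  expect_lt(abs(grm["S0001", "S0002"] / 2 - 0.25), 0.03)
})

test_that("planted relationship pairs must be disjoint", {
  expect_error(cohort_spec(
    n_samples = 10,
    planted_relationships = data.frame(sample_a = c(1, 2), sample_b = c(2, 3),
                                       degree = c("first", "first"))
  ), "disjoint")
})

test_that("missingness overlay realises its per-genotype probability", {
  spec <- cohort_spec(n_samples = 50, n_autosomal_variants = 2000,
                      n_x_variants = 0, n_populations = 1, fst = 0,
                      specimen_proportions = c(serum = 1),
                      specimen_missing_rates = c(serum = 0.02),
                      autozygosity = 0, seed = 5)
  co <- apply_missingness(simulate_cohort(spec))
  # 100,000 genotypes at rate 0.02: binomial concentration
  expect_lt(abs(mean(is.na(co$dataset$calls)) - 0.02), 0.002)

  # zero rates leave the dataset untouched
  spec0 <- cohort_spec(n_samples = 20, n_autosomal_variants = 500,
                       n_x_variants = 0, n_populations = 1, fst = 0,
                       specimen_missing_rates = c(blood = 0, serum = 0),
                       autozygosity = 0, seed = 6)
  co0 <- simulate_cohort(spec0)
  before <- co0$dataset$calls
  expect_identical(apply_missingness(co0)$dataset$calls, before)
})

test_that("genotype error overlay matches its boundary and closed-form behaviour", {
  spec <- cohort_spec(n_samples = 30, n_autosomal_variants = 30000,
                      n_x_variants = 0, n_populations = 1, fst = 0,
                      autozygosity = 0,
                      planted_relationships = data.frame(sample_a = 1, sample_b = 2,
                                                         degree = "duplicate"),
                      seed = 23)
  co <- simulate_cohort(spec)

  # rate 0: identity
  expect_identical(apply_genotype_errors(co, error_rate = 0)$dataset$calls,
                   co$true_calls)

  # rate 1: every genotype differs from its truth
  co1 <- apply_genotype_errors(co, error_rate = 1, seed = 1)
  expect_true(all(co1$dataset$calls != co$true_calls))

  # rate 0.01 on a duplicate pair: discordance among comparable variants
  # matches the 3x3 outcome enumeration
  coe <- apply_genotype_errors(co, error_rate = 0.01, seed = 2)
  res <- duplicate_concordance(coe$dataset, c("S0001", "S0002"))
  p_vec <- colMeans(co$true_calls, na.rm = TRUE) / 2
  expected <- dup_discordance_expected(0.01, p_vec)
  tol <- 4 * sqrt(expected * (1 - expected) / res$n_comparable)
  expect_lt(abs((1 - res$concordance) - expected), tol)
})

test_that("trait simulation is exact without noise and calibrated under the null", {
  spec <- cohort_spec(n_samples = 150, n_autosomal_variants = 300,
                      n_x_variants = 0, n_populations = 1, fst = 0,
                      autozygosity = 0,
                      trait_specs = data.frame(variant_id = "var000001",
                                               effect_size = 0.7,
                                               residual_sd = 0),
                      seed = 31)
  co <- simulate_cohort(spec)
  tr <- simulate_traits(co)
  expect_equal(tr$trait_var000001, 0.7 * co$true_calls[, 1], tolerance = 1e-12)
  expect_error(simulate_traits(co, data.frame(variant_id = "nope",
                                              effect_size = 1, residual_sd = 1)),
               "unknown variant")

  # null traits: the p < 0.05 part of the replication rule fires at ~5%
  set.seed(99)
  g <- co$true_calls[, 2]
  hits <- vapply(seq_len(1000), function(i) {
    y <- rnorm(150)
    replicate_snp(y, g, expected_sign = 1)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("the same spec yields a byte-identical cohort", {
  spec <- cohort_spec(n_samples = 40, n_autosomal_variants = 800,
                      n_x_variants = 50, seed = 77,
                      batch_effects = c(B002 = 0.03))
  a <- apply_missingness(apply_genotype_errors(simulate_cohort(spec)))
  b <- apply_missingness(apply_genotype_errors(simulate_cohort(spec)))
  expect_identical(a$dataset$calls, b$dataset$calls)
  expect_identical(a$dataset$samples, b$dataset$samples)
  expect_identical(a$true_roh, b$true_roh)
  expect_identical(a$true_kinship, b$true_kinship)
})
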