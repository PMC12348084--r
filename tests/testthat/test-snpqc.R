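test_that("the exact HWE test matches brute-force enumeration", {
  # single feasible table
  expect_equal(hwe_exact_test(0, 0, 25), 1)
  # tiny case, full enumeration over het in {0, 2}
  expect_equal(hwe_exact_test(1, 0, 1), hwe_brute(1, 0, 1), tolerance = 1e-12)
  # all tables up to n = 30
  for (n in c(2, 5, 11, 20, 30)) {
    for (a in 0:n) for (h in 0:(n - a)) {
      b <- n - a - h
      expect_equal(hwe_exact_test(a, h, b), hwe_brute(a, h, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("the HWE test is symmetric, bounded and rejects bad input", {
  set.seed(1)
  a <- sample(0:30, 50, TRUE); h <- sample(0:30, 50, TRUE); b <- sample(0:30, 50, TRUE)
  p1 <- hwe_exact_test(a, h, b)
  p2 <- hwe_exact_test(b, h, a)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 <= 1))
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  # the mid-p variant is strictly smaller than the standard p
  expect_lt(hwe_exact_test(5, 10, 15, midp = TRUE), hwe_exact_test(5, 10, 15))
})

test_that("the exact test is conservative under the null", {
  set.seed(2)
  n <- 500
  p <- runif(10000, 0.05, 0.5)
  g <- t(matrix(rbinom(10000 * n, 2, p), nrow = 10000))
  cnt <- cbind(colSums(g == 2), colSums(g == 1), colSums(g == 0))
  pv <- hwe_exact_test(cnt[, 1], cnt[, 2], cnt[, 3])
  expect_lte(sum(pv <= 1e-6), 1)
})

test_that("variant statistics compute call rate, MAF and HWE as specified", {
  g25 <- c(rep(2L, 25), rep(1L, 50), rep(0L, 25))
  calls <- cbind(g25, c(rep(NA_integer_, 100)), rbinom(100, 2, 0.2))
  storage.mode(calls) <- "integer"
  vs <- variant_stats(tiny_dataset(calls))
  expect_equal(vs$maf[1], 0.5)
  expect_equal(vs$call_rate[2], 0)
  expect_true(is.na(vs$maf[2]))
  # all-missing variants fail every threshold
  expect_false("v2" %in% filter_variants(vs, 0, 0, 0))
})

test_that("X variants use female-only HWE and hemizygous male allele counts", {
  sex <- c("female", "female", "female", "female", "male", "male")
  # females: 2,1,1,0 -> 4 A1 alleles of 8; males hemizygous: 2, 0 -> 1 of 2
  calls <- matrix(c(2L, 1L, 1L, 0L, 2L, 0L), ncol = 1)
  ds <- tiny_dataset(calls, chrom = "X", sex = sex)
  vs <- variant_stats(ds)
  expect_equal(vs$maf[1], 0.5) # (4 + 1) / (8 + 2)
  expect_equal(vs$hwe_p[1], hwe_brute(1, 2, 1), tolerance = 1e-12)
})

test_that("a strong heterozygote excess fails the 1e-6 HWE filter at n = 500", {
  set.seed(3)
  g <- sample(0:2, 500, TRUE, prob = c(0.05, 0.9, 0.05))
  vs <- variant_stats(tiny_dataset(matrix(as.integer(g), ncol = 1)))
  expect_lt(vs$hwe_p[1], 1e-6)
})

test_that("variant filters are strict at their boundaries", {
  stats <- tibble::tibble(
    variant_id = c("at_maf", "above", "at_cr", "at_hwe"),
    call_rate = c(1, 1, 0.95, 1),
    maf = c(0.01, 0.3, 0.3, 0.3),
    hwe_p = c(0.5, 0.5, 0.5, 1e-6)
  )
  expect_identical(filter_variants(stats), "above")
})

test_that("planted failing variants are removed and clean ones kept", {
  spec <- cohort_spec(n_samples = 300, n_autosomal_variants = 3000,
                      n_x_variants = 0, n_populations = 1, fst = 0,
                      autozygosity = 0,
                      variant_defects = list(n_low_maf = 30, n_low_call = 30,
                                             n_hwe_het_excess = 30),
                      seed = 44)
  co <- apply_missingness(simulate_cohort(spec))
  vs <- variant_stats(co$dataset)
  kept <- filter_variants(vs)
  removed <- setdiff(vs$variant_id, kept)
  expect_true(all(co$variant_defects$variant_id %in% removed))
  extras <- setdiff(removed, co$variant_defects$variant_id)
  # beyond the planted set, only exact-test type-I losses are allowed
  expect_lte(length(extras), 2)
})

test_that("duplicate concordance applies the double-het exclusion", {
  ga <- c(0L, 1L, 1L, 2L, 2L, 0L, 1L, 0L, 2L, 1L)
  gb <- c(0L, 1L, 1L, 2L, 2L, 0L, 2L, 0L, 2L, 1L)
  # variants 2, 3, 10 double-het? ga/gb both 1 at positions 2, 3, 10
  ds <- tiny_dataset(rbind(ga, gb))
  res <- duplicate_concordance(ds, c("s01", "s02"))
  expect_equal(res$n_double_het_excluded, 3L)
  expect_equal(res$n_comparable, 7L)
  expect_equal(res$concordance, 6 / 7)
  expect_identical(res$discordant_variant_ids[[1]], "v7")

  # hand-countable case from the rule: 10 variants, 2 double-het, 1 discordant
  ga2 <- c(1L, 1L, 0L, 0L, 2L, 2L, 1L, 0L, 2L, 0L)
  gb2 <- c(1L, 1L, 0L, 0L, 2L, 2L, 2L, 0L, 2L, 0L)
  res2 <- duplicate_concordance(tiny_dataset(rbind(ga2, gb2)), c("s01", "s02"))
  expect_equal(res2$n_double_het_excluded, 2L)
  expect_equal(res2$concordance, 7 / 8)

  # identity and symmetry
  res_id <- duplicate_concordance(ds, c("s01", "s01"))
  expect_equal(res_id$concordance, 1)
  res_ba <- duplicate_concordance(ds, c("s02", "s01"))
  expect_equal(res_ba$concordance, res$concordance)

  # raw mode keeps double-hets in the denominator
  raw <- duplicate_concordance(ds, c("s01", "s02"), include_double_het = TRUE)
  expect_equal(raw$n_comparable, 10L)
})

test_that("discordance under planted error matches the 3x3 enumeration", {
  spec <- cohort_spec(n_samples = 40, n_autosomal_variants = 30000,
                      n_x_variants = 0, n_populations = 1, fst = 0,
                      autozygosity = 0,
                      planted_relationships = data.frame(sample_a = 1, sample_b = 2,
                                                         degree = "duplicate"),
                      seed = 55)
  co <- simulate_cohort(spec)
  coe <- apply_genotype_errors(co, error_rate = 0.01, seed = 3)
  res <- duplicate_concordance(coe$dataset, c("S0001", "S0002"))
  p_vec <- colMeans(co$true_calls) / 2
  expected <- dup_discordance_expected(0.01, p_vec)
  tol <- 4 * sqrt(expected / res$n_comparable)
  expect_lt(abs((1 - res$concordance) - expected), tol)
})

test_that("pooled discordant lists count per-variant pair hits", {
  mk <- function(ids) tibble::tibble(sample_a = "a", sample_b = "b",
                                     n_comparable = 10L, n_concordant = 8L,
                                     concordance = 0.8, n_double_het_excluded = 0L,
                                     discordant_variant_ids = list(ids))
  one <- pool_discordant(mk(c("v1", "v2")))
  expect_equal(one$n_pairs_discordant, c(1L, 1L))

  seven <- pool_discordant(dplyr::bind_rows(lapply(1:7, function(i) mk("v9"))))
  expect_equal(seven$n_pairs_discordant, 7L)

  disjoint <- pool_discordant(dplyr::bind_rows(mk(c("v1", "v2")), mk(c("v3"))))
  expect_equal(nrow(disjoint), 3)
})

test_that("zero comparable variants is an error", {
  ds <- tiny_dataset(rbind(c(1L, NA), c(1L, 2L)))
  expect_error(duplicate_concordance(ds, c("s01", "s02")), "comparable")
})
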