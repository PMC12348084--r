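test_that("imputation-quality stratification counts hand-checkable fractions", {
  info <- tibble::tibble(
    alt_allele_frequency = rep(0.3, 10),
    r2 = rep(c(0.2, 0.4, 0.6, 0.85, 0.95), each = 2)
  )
  s <- summarize_imputation(info)
  common <- dplyr::filter(s, maf_bin == "common")
  expect_equal(common$fraction[match(c(0.3, 0.5, 0.8, 0.9), common$r2_threshold)],
               c(0.8, 0.6, 0.4, 0.2))
  expect_true(all(common$n_variants == 10))

  # perfect imputation: every fraction 1
  s1 <- summarize_imputation(tibble::tibble(alt_allele_frequency = runif(20, 0, 1),
                                            r2 = 1))
  expect_true(all(s1$fraction[s1$n_variants > 0] == 1))
})

test_that("fractions are monotone non-increasing in the threshold", {
  set.seed(1)
  info <- tibble::tibble(alt_allele_frequency = runif(2000, 0, 1),
                         r2 = rbeta(2000, 2, 1))
  s <- summarize_imputation(info)
  for (b in unique(s$maf_bin)) {
    fr <- s$fraction[s$maf_bin == b][order(s$r2_threshold[s$maf_bin == b])]
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("simulated per-bin beta R2 reproduces its tail probabilities", {
  set.seed(2)
  n <- 20000
  maf <- runif(n, 0.05, 0.5)
  r2 <- rbeta(n, 8, 2) # common-variant quality profile
  s <- summarize_imputation(tibble::tibble(alt_allele_frequency = maf, r2 = r2))
  common <- dplyr::filter(s, maf_bin == "common")
  for (i in seq_len(nrow(common))) {
    expect_lt(abs(common$fraction[i] - pbeta(common$r2_threshold[i], 8, 2,
                                             lower.tail = FALSE)), 0.02)
  }
})

test_that("hard calls snap near-integer dosages and drop uncertain ones", {
  expect_identical(hard_call(c(0.05, 1.0, 0.5, 1.93, NA)),
                   c(0L, 1L, NA, 2L, NA))
  expect_error(hard_call(c(0.5, 2.4)), "\\[0, 2\\]")
})

test_that("the APOE haplotype table is a bijection over the 9 genotype combinations", {
  grid <- expand.grid(c1 = 0:2, c2 = 0:2)
  calls <- call_apoe(grid$c1, grid$c2)
  expect_equal(length(unique(calls$diplotype)), 9)
  # anchors of the table
  one <- function(c1, c2) call_apoe(c1, c2)
  expect_equal(one(2, 2)$diplotype, "e4/e4")   # rs429358 C/C + rs7412 C/C
  expect_true(one(2, 2)$e4_carrier)
  expect_equal(one(0, 2)$diplotype, "e3/e3")   # T/T + C/C
  expect_false(one(0, 2)$e4_carrier)
  expect_equal(one(0, 0)$diplotype, "e2/e2")   # T/T + T/T
  expect_equal(one(1, 2)$diplotype, "e3/e4")
  # the double heterozygote resolves to e2/e4 and is flagged
  dh <- one(1, 1)
  expect_equal(dh$diplotype, "e2/e4")
  expect_true(dh$ambiguous)
  expect_true(dh$e4_carrier)
  # e1-containing calls are classed together
  expect_equal(one(2, 1)$diplotype_class, "e1-containing")
  # carriers are exactly the diplotypes containing e4
  expect_identical(calls$e4_carrier, grepl("e4", calls$diplotype))
  # missing input propagates
  expect_true(is.na(call_apoe(NA, 1)$diplotype))
})

# note: genotype arguments to call_apoe count C alleles; rs7412 column below
# is given as counts of C, so rs7412 "C/C" (the e3 background) is 2.
apoe_truth <- function(n, seed = 1) {
  set.seed(seed)
  hap_freq <- c(e2 = 0.08, e3 = 0.77, e4 = 0.15)
  h <- matrix(sample(names(hap_freq), 2 * n, TRUE, prob = hap_freq), ncol = 2)
  c1 <- rowSums(h == "e4")                 # C at rs429358 only on e4
  c2 <- 2 - rowSums(h == "e2")             # C at rs7412 except on e2
  list(c1 = c1, c2 = c2,
       truth = call_apoe(c1, c2, sample_ids = paste0("s", seq_len(n))))
}

test_that("dosage noise degrades APOE concordance monotonically", {
  tr <- apoe_truth(2000)
  conc <- vapply(c(0.05, 0.15, 0.3), function(sdev) {
    set.seed(round(1000 * sdev))
    d1 <- pmin(pmax(tr$c1 + rnorm(2000, 0, sdev), 0), 2)
    d2 <- pmin(pmax(tr$c2 + rnorm(2000, 0, sdev), 0), 2)
    called <- call_apoe(hard_call(d1, 0.49), hard_call(d2, 0.49),
                        sample_ids = tr$truth$sample_id)
    apoe_concordance(called, tr$truth)$concordance
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
})

test_that("end-to-end dosage calling keeps concordance high at noise sd 0.1", {
  tr <- apoe_truth(1000, seed = 5)
  set.seed(6)
  d1 <- pmin(pmax(tr$c1 + rnorm(1000, 0, 0.1), 0), 2)
  d2 <- pmin(pmax(tr$c2 + rnorm(1000, 0, 0.1), 0), 2)
  called <- call_apoe(hard_call(d1), hard_call(d2),
                      sample_ids = tr$truth$sample_id)
  res <- apoe_concordance(called, tr$truth)
  expect_gte(res$concordance, 0.95)
})

test_that("concordance bookkeeping matches hand counts", {
  gold <- call_apoe(c(rep(0, 49), 2), c(rep(2, 49), 2),
                    sample_ids = paste0("s", 1:50))
  called <- gold
  called$diplotype[50] <- "e3/e3" # one E4 carrier called non-carrier
  res <- apoe_concordance(called, gold)
  expect_equal(res$concordance, 0.98)
  expect_equal(res$misclassification$carriers_called_noncarrier, 1)
  expect_equal(res$misclassification$noncarriers_called_carrier, 0)
  # identical inputs: perfect concordance, empty misclassification
  res0 <- apoe_concordance(gold, gold)
  expect_equal(res0$concordance, 1)
  expect_equal(nrow(res0$mismatches), 0)
  expect_error(apoe_concordance(gold[0, ], gold), "overlap")
})

test_that("trait truncation removes extreme values in one pass", {
  set.seed(7)
  y <- rnorm(100)
  g <- rbinom(100, 2, 0.3)
  y[1] <- 10 * sd(y) # a 10-SD outlier
  res <- replicate_snp(y, g, expected_sign = 1)
  expect_equal(res$n_truncated, 1L)
  expect_equal(res$n, 99L)
})

test_that("replication requires both significance and the expected direction", {
  set.seed(8)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  y <- 0.5 * g + rnorm(n)
  hit <- replicate_snp(y, g, expected_sign = 1)
  expect_true(hit$replicated)
  miss <- replicate_snp(y, g, expected_sign = -1)
  expect_false(miss$replicated)

  # power at the designed effect size over 200 replicates
  wins <- vapply(seq_len(200), function(i) {
    replicate_snp(0.5 * g + rnorm(n), g, expected_sign = 1)$replicated
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("a null trait replicates at ~alpha/2 for a fixed expected sign", {
  set.seed(9)
  n <- 150
  g <- rbinom(n, 2, 0.3)
  rate <- mean(vapply(seq_len(400), function(i) {
    replicate_snp(rnorm(n), g, expected_sign = 1)$replicated
  }, logical(1)))
  expect_lt(abs(rate - 0.025), 0.02)
})

test_that("covariates enter the model and collinearity is reported", {
  set.seed(10)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  covs <- tibble::tibble(pc1 = rnorm(n), specimen = sample(c("blood", "serum"), n, TRUE))
  y <- 0.6 * g + 0.8 * covs$pc1 + rnorm(n)
  res <- replicate_snp(y, g, covariates = covs, expected_sign = 1)
  expect_true(res$replicated)
  bad <- dplyr::mutate(covs, pc2 = pc1)
  expect_error(replicate_snp(y, g, covariates = bad, expected_sign = 1),
               "collinear")
  expect_error(replicate_snp(y[1:20], g[1:20], expected_sign = 1), "30")
})
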