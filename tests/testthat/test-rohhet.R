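# A single-sample chromosome with a homozygous tract and heterozygous-rich
# flanks, for direct segment checks.
tract_dataset <- function(n_tract = 150, n_flank = 60, spacing = 20000,
                          gap_at = NULL, gap_bp = NULL, seed = 1) {
  set.seed(seed)
  m <- n_flank + n_tract + n_flank
  g <- integer(m)
  flank_idx <- c(seq_len(n_flank), n_flank + n_tract + seq_len(n_flank))
  g[flank_idx] <- rbinom(2 * n_flank, 2, 0.5) # het-rich flanks
  tract_idx <- n_flank + seq_len(n_tract)
  g[tract_idx] <- 2L # fully homozygous tract
  pos <- 1e6 + spacing * (seq_len(m) - 1)
  if (!is.null(gap_at)) pos[gap_at:m] <- pos[gap_at:m] + gap_bp
  ds <- tiny_dataset(matrix(g, nrow = 1), chrom = "1", pos = as.integer(pos))
  list(ds = ds, tract_pos = pos[tract_idx])
}

test_that("a planted homozygous tract is recovered as exactly one segment", {
  td <- tract_dataset()
  segs <- detect_roh(td$ds)
  expect_equal(nrow(segs), 1)
  covered <- td$tract_pos >= segs$start_bp & td$tract_pos <= segs$end_bp
  expect_gte(mean(covered), 0.95)
  expect_true(verify_roh_segment(td$ds, segs[1, ]))
})

test_that("tracts below the SNP-count threshold are not reported", {
  td <- tract_dataset(n_tract = 80)
  expect_equal(nrow(detect_roh(td$ds)), 0)
})

test_that("a large gap splits the candidate and both halves fail min_kb", {
  # 120-SNP tract at 10 kb spacing: each half spans ~600 kb < 1000 kb
  td <- tract_dataset(n_tract = 120, n_flank = 60, spacing = 10000,
                      gap_at = 120, gap_bp = 1.5e6)
  segs <- detect_roh(td$ds, min_snps = 50)
  expect_equal(nrow(segs), 0)
  # without the gap the same tract is one (density-passing) segment
  td2 <- tract_dataset(n_tract = 120, n_flank = 60, spacing = 10000)
  expect_equal(nrow(detect_roh(td2$ds, min_snps = 50)), 1)
})

test_that("heterozygous flanking variants do not change the reported segments", {
  # flanks at least one window wide keep the tract interior, so extending
  # them further cannot change any window that covers tract SNPs
  td <- tract_dataset(n_flank = 60, seed = 3)
  base <- detect_roh(td$ds)
  set.seed(9)
  extra <- rbinom(120, 2, 0.5)
  g2 <- c(extra[1:60], td$ds$calls[1, ], extra[61:120])
  pos2 <- c(seq(4e5, by = 10000, length.out = 60),
            td$ds$variants$bp_position,
            max(td$ds$variants$bp_position) + seq(20000, by = 20000, length.out = 60))
  ds2 <- tiny_dataset(matrix(as.integer(g2), nrow = 1), chrom = "1",
                      pos = as.integer(pos2))
  ext <- detect_roh(ds2)
  expect_equal(nrow(ext), nrow(base))
  expect_equal(ext$start_bp, base$start_bp)
  expect_equal(ext$end_bp, base$end_bp)
})

test_that("unsorted positions are rejected", {
  ds <- tiny_dataset(matrix(0L, 1, 3), pos = c(300L, 100L, 200L))
  expect_error(detect_roh(ds), "sorted")
})

test_that("every generator-planted segment is found and verifies by direct rule check", {
  spec <- cohort_spec(n_samples = 30, n_autosomal_variants = 20000,
                      n_x_variants = 0, n_populations = 1, fst = 0,
                      autozygosity = 0.03, seed = 66)
  co <- simulate_cohort(spec)
  segs <- detect_roh(co$dataset)
  for (i in seq_len(nrow(segs))) {
    expect_true(verify_roh_segment(co$dataset, segs[i, ]))
  }
  # every planted segment that meets the reporting thresholds is covered
  # (>= 90% of its span) by a detected segment of the same sample
  eligible <- dplyr::filter(co$true_roh, n_snps >= 100,
                            (end_bp - start_bp + 1) >= 1e6)
  expect_gte(nrow(eligible), 20)
  for (i in seq_len(nrow(eligible))) {
    e <- eligible[i, ]
    hit <- dplyr::filter(segs, sample_id == e$sample_id, chrom == e$chrom,
                         start_bp <= e$end_bp, end_bp >= e$start_bp)
    expect_equal(nrow(hit), 1)
    overlap <- min(hit$end_bp, e$end_bp) - max(hit$start_bp, e$start_bp) + 1
    expect_gte(overlap / (e$end_bp - e$start_bp + 1), 0.9)
  }
})

test_that("inbreeding F hits its closed-form anchors", {
  set.seed(11)
  n <- 60; m <- 10000
  p <- runif(m, 0.1, 0.5)
  calls <- t(matrix(rbinom(m * n, 2, p), nrow = m))
  calls[1, ] <- ifelse(p >= 0.5, 2L, 0L) # fully homozygous sample
  storage.mode(calls) <- "integer"
  het <- heterozygosity_f(tiny_dataset(calls))
  expect_equal(het$f_inbreeding[1], 1)
  expect_lt(max(abs(het$f_inbreeding[-1])), 0.05)
  expect_lt(abs(mean(het$f_inbreeding[-1])), 0.02)
})

test_that("planted autozygosity fraction is recovered as inbreeding F", {
  spec <- cohort_spec(n_samples = 40, n_autosomal_variants = 10000,
                      n_x_variants = 0, n_populations = 1, fst = 0,
                      autozygosity = c(0.1, rep(0.01, 39)), seed = 13)
  co <- simulate_cohort(spec)
  het <- heterozygosity_f(co$dataset)
  expect_lt(abs(het$f_inbreeding[1] - 0.1), 0.03)
})

test_that("the LOESS percentile rule flags ~1% by construction", {
  set.seed(21)
  n <- 500
  f <- runif(n, 0, 0.1)
  total <- 5000 * f + 200 * f^2 + rnorm(n, 0, 10)
  d <- tibble::tibble(sample_id = paste0("s", 1:n), total_kb = total,
                      f_inbreeding = f)
  fl <- loess_outliers(d)
  expect_lte(abs(sum(fl$outlier) - ceiling(0.01 * n)), 1)
  # percentile 0 flags nothing
  expect_equal(sum(loess_outliers(d, percentile = 0)$outlier), 0)
})

test_that("samples with ROH far below their F-matched expectation are flagged", {
  set.seed(22)
  n <- 499
  f <- runif(n, 0.01, 0.1)
  total <- 40000 * f + rnorm(n, 0, 150)
  low <- 1:5
  total[low] <- total[low] * 0.2 # 80% reduction
  d <- tibble::tibble(sample_id = paste0("s", 1:n), total_kb = total,
                      f_inbreeding = f)
  fl <- loess_outliers(d)
  expect_true(all(fl$outlier[low]))
})

test_that("grouped fits run per ancestry and degenerate F errors", {
  set.seed(23)
  d <- tibble::tibble(sample_id = paste0("s", 1:60),
                      total_kb = c(rnorm(30, 1000, 50), rnorm(30, 4000, 50)),
                      f_inbreeding = c(runif(30, 0, 0.05), runif(30, 0.1, 0.2)),
                      ancestry = rep(c("EUR", "AFR"), each = 30))
  fl <- loess_outliers(d, group = "ancestry")
  expect_equal(nrow(fl), 60)
  bad <- tibble::tibble(sample_id = paste0("s", 1:30), total_kb = rnorm(30),
                        f_inbreeding = rep(0.02, 30))
  expect_error(loess_outliers(bad), "degenerate")
  expect_error(loess_outliers(d[1:10, ]), "at least 20")
})
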