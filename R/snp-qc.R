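# Variant-level statistics and filters, plus duplicate-pair concordance with
# the double-heterozygote exclusion.

# Conditional probabilities of each feasible heterozygote count given the
# rare-allele count, via the stable mid-out recurrence. Returns list(h, prob).
hwe_het_distribution <- function(n, n_rare) {
  if (n_rare == 0) return(list(h = 0L, prob = 1))
  hs <- seq(n_rare %% 2L, n_rare, by = 2L)
  probs <- numeric(length(hs))
  # start near the mode of the conditional distribution
  h0 <- round(n_rare * (2 * n - n_rare) / (2 * n))
  if (h0 %% 2L != n_rare %% 2L) h0 <- h0 + 1L
  h0 <- min(max(h0, hs[1]), hs[length(hs)])
  i0 <- match(h0, hs)
  probs[i0] <- 1
  # downward: P(h-2) = P(h) * h (h-1) / (4 (hom_r + 1)(hom_c + 1))
  h <- h0
  for (i in rev(seq_len(i0 - 1))) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    h <- h - 2L
  }
  # upward: P(h+2) = P(h) * 4 hom_r hom_c / ((h+2)(h+1))
  h <- h0
  for (i in seq(i0 + 1, length.out = length(hs) - i0)) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i] <- probs[i - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  list(h = hs, prob = probs)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Exact conditional test: with the rare-allele count fixed, all feasible
#' heterozygote counts of matching parity are enumerated and the p-value is
#' the sum of probabilities of tables no more probable than the observed one
#' (two-sided exact; no mid-p correction unless `midp = TRUE`). Monomorphic
#' variants have a single feasible table and p = 1. The test is symmetric in
#' the two homozygote counts. Vectorised over equal-length count vectors.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (non-negative).
#' @param midp Use the mid-p variant (half weight on the observed table).
#' @return Numeric p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2, midp = FALSE) {
  check_that(all(n_hom1 >= 0) && all(n_het >= 0) && all(n_hom2 >= 0),
             "genotype counts must be non-negative.")
  k <- max(length(n_hom1), length(n_het), length(n_hom2))
  n_hom1 <- rep_len(as.numeric(n_hom1), k)
  n_het <- rep_len(as.numeric(n_het), k)
  n_hom2 <- rep_len(as.numeric(n_hom2), k)
  one <- function(a, h, b) {
    n <- a + h + b
    check_that(n >= 1, "need at least one genotype.")
    n_a <- 2 * a + h
    n_rare <- min(n_a, 2 * n - n_a)
    dist <- hwe_het_distribution(n, n_rare)
    p_obs <- dist$prob[match(h, dist$h)]
    if (is.na(p_obs)) abort("observed heterozygote count infeasible for the allele count.")
    p <- sum(dist$prob[dist$prob <= p_obs * (1 + 1e-9)])
    if (midp) p <- p - 0.5 * p_obs
    min(p, 1)
  }
  vapply(seq_len(k), function(i) one(n_hom1[i], n_het[i], n_hom2[i]), numeric(1))
}

#' Per-variant call rate, MAF and Hardy-Weinberg p-value
#'
#' Call rate and minor allele frequency are computed over the given sample
#' subset from non-missing calls. For X-chromosome variants the HWE test uses
#' females only, while reported males contribute one allele each to the MAF
#' (hemizygous 0/2 coding). Monomorphic variants get `hwe_p = 1`; all-missing
#' variants get call rate 0 and `maf = NA` (which fails any threshold).
#'
#' @param dataset A [geno_dataset()].
#' @param sample_ids Optional sample subset.
#' @return Tibble `variant_id`, `chrom`, `call_rate`, `maf`, `hwe_p`.
#' @export
variant_stats <- function(dataset, sample_ids = NULL) {
  ds <- if (is.null(sample_ids)) dataset else subset_geno(dataset, samples = sample_ids)
  check_that(nrow(ds$samples) > 0, "empty sample subset.")
  g <- ds$calls
  call_rate <- colMeans(!is.na(g))
  fr <- allele_freqs(ds)
  maf <- pmin(fr$freq_A1, 1 - fr$freq_A1)
  is_x <- ds$variants$chrom == "X"
  sex <- ds$samples[["self_reported_sex"]] %||% rep("unknown", nrow(ds$samples))
  hwe_counts <- function(gsub) {
    cbind(
      hom1 = colSums(gsub == 2L, na.rm = TRUE),
      het = colSums(gsub == 1L, na.rm = TRUE),
      hom2 = colSums(gsub == 0L, na.rm = TRUE)
    )
  }
  hwe_p <- rep(NA_real_, ncol(g))
  auto_cols <- which(!is_x)
  if (length(auto_cols)) {
    cnt <- hwe_counts(g[, auto_cols, drop = FALSE])
    nz <- rowSums(cnt) > 0
    hwe_p[auto_cols[nz]] <- hwe_exact_test(cnt[nz, 1], cnt[nz, 2], cnt[nz, 3])
    hwe_p[auto_cols[!nz]] <- 1
  }
  x_cols <- which(is_x)
  if (length(x_cols)) {
    fem <- sex == "female"
    if (any(fem)) {
      cnt <- hwe_counts(g[fem, x_cols, drop = FALSE])
      nz <- rowSums(cnt) > 0
      hwe_p[x_cols[nz]] <- hwe_exact_test(cnt[nz, 1], cnt[nz, 2], cnt[nz, 3])
      hwe_p[x_cols[!nz]] <- 1
    } else {
      hwe_p[x_cols] <- 1
    }
  }
  tibble(
    variant_id = ds$variants$variant_id,
    chrom = ds$variants$chrom,
    call_rate = unname(call_rate),
    maf = unname(maf),
    hwe_p = hwe_p
  )
}

#' Threshold filter on variant statistics
#'
#' Retains variants with `call_rate > call_rate_min` AND `maf > maf_min` AND
#' `hwe_p > hwe_p_min`; all inequalities strict, so a variant exactly at a
#' bound is removed. `NA` statistics fail.
#'
#' @param stats Tibble from [variant_stats()].
#' @param call_rate_min,maf_min,hwe_p_min Thresholds.
#' @return Character vector of retained variant ids.
#' @export
filter_variants <- function(stats, call_rate_min = 0.95, maf_min = 0.01,
                            hwe_p_min = 1e-6) {
  keep <- !is.na(stats$call_rate) & stats$call_rate > call_rate_min &
    !is.na(stats$maf) & stats$maf > maf_min &
    !is.na(stats$hwe_p) & stats$hwe_p > hwe_p_min
  stats$variant_id[keep]
}

#' Genotype concordance for a duplicate sample pair
#'
#' A variant is comparable when it is non-missing in both samples and not
#' double-heterozygous (both samples heterozygous genotypes carry no
#' information about mismatches). Concordance is the fraction of comparable
#' variants with equal codes. Callers should restrict to pairs where both
#' samples have call rates above 95%.
#'
#' @param dataset A [geno_dataset()].
#' @param pair Length-2 character vector (or data frame row) of sample ids.
#' @param variant_ids Variant subset; default all autosomal variants.
#' @param include_double_het Sensitivity mode: keep double-heterozygous
#'   variants in the denominator.
#' @return One-row tibble: pair ids, `n_comparable`, `n_concordant`,
#'   `concordance`, `n_double_het_excluded`, `discordant_variant_ids`
#'   (list-column).
#' @export
duplicate_concordance <- function(dataset, pair, variant_ids = NULL,
                                  include_double_het = FALSE) {
  if (is.data.frame(pair)) pair <- c(pair$sample_a[1], pair$sample_b[1])
  ds <- if (is.null(variant_ids)) dataset else subset_geno(dataset, variants = variant_ids)
  ds <- subset_geno(ds, variants = is_autosome(ds$variants$chrom))
  ia <- match(pair[1], ds$samples$sample_id)
  ib <- match(pair[2], ds$samples$sample_id)
  check_that(!anyNA(c(ia, ib)), "unknown sample id in `pair`.")
  ga <- ds$calls[ia, ]; gb <- ds$calls[ib, ]
  both <- !is.na(ga) & !is.na(gb)
  dhet <- both & ga == 1L & gb == 1L
  comparable <- if (include_double_het) both else both & !dhet
  check_that(sum(comparable) > 0, "zero comparable variants for this pair.")
  agree <- comparable & ga == gb
  disc <- comparable & ga != gb
  tibble(
    sample_a = pair[1], sample_b = pair[2],
    n_comparable = sum(comparable),
    n_concordant = sum(agree),
    concordance = sum(agree) / sum(comparable),
    n_double_het_excluded = if (include_double_het) 0L else sum(dhet),
    discordant_variant_ids = list(ds$variants$variant_id[disc])
  )
}

#' Pool discordant variants across duplicate pairs
#'
#' @param results A tibble of [duplicate_concordance()] rows (or list of
#'   them).
#' @return Tibble `variant_id`, `n_pairs_discordant`, sorted descending.
#' @export
pool_discordant <- function(results) {
  if (!is.data.frame(results)) results <- bind_rows(results)
  check_that(nrow(results) >= 1, "need at least one concordance result.")
  tibble(variant_id = unlist(results$discordant_variant_ids)) %>%
    count(.data$variant_id, name = "n_pairs_discordant") %>%
    arrange(desc(.data$n_pairs_discordant), .data$variant_id)
}
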