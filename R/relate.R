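# Genome-wide relatedness: GRM with pairwise-complete variants, kinship-bin
# relationship classification, and PLINK-style method-of-moments IBD.

#' Genetic relationship matrix
#'
#' Entry (j, k) is
#' `(1 / M_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over autosomal variants non-missing in both samples (`M_jk` is that
#' count); allele frequencies are estimated from the dataset. Missing
#' genotypes are handled pairwise-complete, not mean-imputed, so the
#' estimator degrades gracefully under specimen-driven missingness. For an
#' outbred duplicate pair the off-diagonal is ~1; the kinship coefficient is
#' the off-diagonal divided by two.
#'
#' @param dataset A [geno_dataset()].
#' @param variant_ids Optional variant subset (non-autosomal variants are
#'   dropped).
#' @param sample_ids Optional sample subset.
#' @return Symmetric numeric matrix with sample ids as dimnames; entries with
#'   no shared non-missing variants are `NA`.
#' @export
compute_grm <- function(dataset, variant_ids = NULL, sample_ids = NULL) {
  ds <- subset_geno(dataset, samples = sample_ids, variants = variant_ids)
  ds <- subset_geno(ds, variants = is_autosome(ds$variants$chrom))
  check_that(ncol(ds$calls) > 0, "no autosomal variants to work with.")
  st <- standardize_calls(ds$calls)
  check_that(ncol(st$z) > 0, "all variants monomorphic or empty.")
  num <- tcrossprod(st$z)
  obs <- !is.na(ds$calls[, st$keep, drop = FALSE])
  storage.mode(obs) <- "double"
  m_jk <- tcrossprod(obs)
  grm <- num / m_jk
  grm[m_jk == 0] <- NA_real_
  dimnames(grm) <- list(ds$samples$sample_id, ds$samples$sample_id)
  grm
}

#' Classify sample pairs into relationship bins
#'
#' Kinship is taken as the off-diagonal GRM value divided by two (the
#' relationship matrix is on twice the kinship scale for outbred pairs) and
#' binned at the decision bounds 0.354 (duplicate/MZ twin), 0.177
#' (1st degree), 0.0884 (2nd degree) and 0.0442 (3rd degree); intervals are
#' closed on the left and open on the right, so a kinship of exactly 0.177
#' classifies as first degree.
#'
#' @param grm Matrix from [compute_grm()].
#' @param min_kinship Drop pairs below this kinship from the output; `NULL`
#'   keeps all pairs.
#' @return Tibble `sample_a`, `sample_b`, `kinship`, `relationship` (factor:
#'   duplicate_or_MZ, first_degree, second_degree, third_degree, unrelated).
#' @export
classify_relationships <- function(grm, min_kinship = NULL) {
  ids <- rownames(grm)
  ut <- which(upper.tri(grm), arr.ind = TRUE)
  kin <- grm[ut] / 2
  bins <- cut(kin,
              breaks = c(-Inf, 0.0442, 0.0884, 0.177, 0.354, Inf),
              labels = c("unrelated", "third_degree", "second_degree",
                         "first_degree", "duplicate_or_MZ"),
              right = FALSE)
  out <- tibble(
    sample_a = ids[ut[, 1]],
    sample_b = ids[ut[, 2]],
    kinship = kin,
    relationship = bins
  )
  if (!is.null(min_kinship)) out <- filter(out, .data$kinship >= min_kinship)
  arrange(out, desc(.data$kinship))
}

# Per-variant expected IBS-state probabilities given IBD state, with the
# finite-sample correction: powers of p are replaced by their unbiased
# falling-factorial estimators from the 2N sampled alleles.
ibd_expectations <- function(calls) {
  n_i <- colSums(!is.na(calls))
  x <- 2 * n_i                       # alleles sampled
  X <- colSums(calls, na.rm = TRUE)  # A1 allele count
  Y <- x - X
  ok <- x >= 4 & X >= 2 & Y >= 2     # polymorphic with enough alleles
  ff <- function(a, k) {
    out <- a
    for (j in seq_len(k - 1)) out <- out * (a - j)
    out
  }
  D4 <- ff(x, 4); D3 <- ff(x, 3)
  p00 <- 2 * ff(X, 2) * ff(Y, 2) / D4
  p10 <- 4 * ff(X, 3) * Y / D4 + 4 * X * ff(Y, 3) / D4
  p20 <- (ff(X, 4) + ff(Y, 4) + 4 * ff(X, 2) * ff(Y, 2)) / D4
  p11 <- 2 * ff(X, 2) * Y / D3 + 2 * X * ff(Y, 2) / D3
  p21 <- 1 - p11
  list(ok = ok, p00 = p00, p10 = p10, p20 = p20, p11 = p11, p21 = p21)
}

#' Method-of-moments IBD estimation (Z0, Z1, Z2, PI_HAT)
#'
#' For each pair, observed identity-by-state counts (IBS 0/1/2 over variants
#' non-missing in both samples) are combined with their allele-frequency-
#' dependent expectations under each IBD state - including the small-sample
#' correction in which powers of the allele frequency are replaced by
#' unbiased falling-factorial estimators - and solved for the IBD state
#' proportions:
#' `Z0 = N0/E(N0|IBD0)`, `Z1 = (N1 - Z0 E(N1|IBD0)) / E(N1|IBD1)`,
#' `Z2 = (N2 - Z0 E(N2|IBD0) - Z1 E(N2|IBD1)) / M`. Estimates are clipped to
#' `[0, 1]` and renormalised to sum to one; `PI_HAT = Z2 + Z1/2` is the
#' proportion of the genome shared identical-by-descent. Pairs with
#' `PI_HAT > 0.98` are conventionally treated as genetically identical.
#'
#' @param dataset A [geno_dataset()].
#' @param pairs Data frame `sample_a`, `sample_b` (sample ids).
#' @param variant_ids Optional autosomal variant subset.
#' @return Tibble per pair: IBS counts, `Z0`, `Z1`, `Z2`, `PI_HAT`,
#'   `n_variants`.
#' @export
estimate_ibd <- function(dataset, pairs, variant_ids = NULL) {
  pairs <- as_tibble(pairs)
  ds <- if (is.null(variant_ids)) dataset else subset_geno(dataset, variants = variant_ids)
  ds <- subset_geno(ds, variants = is_autosome(ds$variants$chrom))
  ex <- ibd_expectations(ds$calls)
  check_that(any(ex$ok), "no polymorphic autosomal variants for IBD estimation.")
  g <- ds$calls[, ex$ok, drop = FALSE]
  p00 <- ex$p00[ex$ok]; p10 <- ex$p10[ex$ok]; p20 <- ex$p20[ex$ok]
  p11 <- ex$p11[ex$ok]; p21 <- ex$p21[ex$ok]
  one_pair <- function(a, b) {
    ga <- g[a, ]; gb <- g[b, ]
    use <- !is.na(ga) & !is.na(gb)
    d <- abs(ga[use] - gb[use])
    n2 <- sum(d == 0); n1 <- sum(d == 1); n0 <- sum(d == 2)
    m <- sum(use)
    e00 <- sum(p00[use]); e10 <- sum(p10[use]); e20 <- sum(p20[use])
    e11 <- sum(p11[use]); e21 <- sum(p21[use])
    z0 <- n0 / e00
    z1 <- (n1 - z0 * e10) / e11
    z2 <- (n2 - z0 * e20 - z1 * e21) / m
    z <- clamp(c(z0, z1, z2), 0, 1)
    z <- z / sum(z)
    tibble(IBS0 = n0, IBS1 = n1, IBS2 = n2, n_variants = m,
           Z0 = z[1], Z1 = z[2], Z2 = z[3], PI_HAT = z[3] + z[2] / 2)
  }
  ia <- match(pairs$sample_a, ds$samples$sample_id)
  ib <- match(pairs$sample_b, ds$samples$sample_id)
  check_that(!anyNA(c(ia, ib)), "unknown sample id in `pairs`.")
  purrr::map2(ia, ib, one_pair) %>%
    bind_rows() %>%
    mutate(sample_a = pairs$sample_a, sample_b = pairs$sample_b, .before = 1)
}
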