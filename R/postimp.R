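# Post-imputation quality stratification, APOE epsilon-diplotype calling from
# imputed dosages, and the candidate-SNP replication rule.

#' Stratified imputation-quality summary
#'
#' Variants are binned by MAF - rare `[0, 1%)`, low-frequency `[1%, 5%)`,
#' common `[5%, 50%]` - and, per bin, the fraction with imputation R-squared
#' at or above each threshold is reported. MAF is `min(freq, 1 - freq)` of
#' the ALT allele frequency. Rows with missing R2 are excluded from the
#' fractions and counted.
#'
#' @param info_table Tibble as from [read_imputed()]`$info` (needs
#'   `alt_allele_frequency` and `r2`).
#' @param r2_thresholds Thresholds to tabulate.
#' @return Tibble of class `imputation_summary`: `maf_bin`, `n_variants`,
#'   `r2_threshold`, `fraction`; attribute `"n_missing_r2"`.
#' @export
summarize_imputation <- function(info_table, r2_thresholds = c(0.3, 0.5, 0.8, 0.9)) {
  info_table <- as_tibble(info_table)
  check_that(nrow(info_table) > 0, "empty info table.")
  maf <- pmin(info_table$alt_allele_frequency, 1 - info_table$alt_allele_frequency)
  r2 <- info_table$r2
  n_missing <- sum(is.na(r2))
  keep <- !is.na(r2) & !is.na(maf)
  maf <- maf[keep]; r2 <- r2[keep]
  bin <- cut(maf, breaks = c(-Inf, 0.01, 0.05, Inf),
             labels = c("rare", "low_frequency", "common"), right = FALSE)
  out <- purrr::map(r2_thresholds, function(thr) {
    tibble(maf_bin = levels(bin),
           n_variants = as.integer(table(bin)),
           r2_threshold = thr,
           fraction = as.numeric(tapply(r2 >= thr, bin, mean, default = NaN)))
  }) %>% bind_rows() %>% arrange(.data$maf_bin, .data$r2_threshold)
  attr(out, "n_missing_r2") <- n_missing
  class(out) <- c("imputation_summary", class(out))
  out
}

#' Hard-call genotypes from imputed dosages
#'
#' A dosage is converted to the nearest integer genotype when within
#' `threshold` of it, otherwise set missing. `NA` dosages stay missing.
#'
#' @param dosage Numeric vector in `[0, 2]`.
#' @param threshold Maximum distance to the nearest integer.
#' @return Integer vector with `NA` for uncertain dosages.
#' @export
hard_call <- function(dosage, threshold = 0.1) {
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= 2)
  if (!all(ok)) abort("dosages must lie in [0, 2].")
  g <- round(dosage)
  g[abs(dosage - g) > threshold] <- NA
  as.integer(g)
}

# epsilon haplotypes on the (rs429358, rs7412) allele pair:
# (T,T) = e2, (T,C) = e3, (C,C) = e4, (C,T) = e1.
# Genotypes are counts of the C allele at each site. The double heterozygote
# is e2/e4 or e1/e3; it is resolved to e2/e4 (e1 is vanishingly rare) and
# flagged ambiguous.
.apoe_table <- local({
  key <- function(c1, c2) paste(c1, c2, sep = "|")
  tab <- c("2|2" = "e4/e4", "2|1" = "e1/e4", "2|0" = "e1/e1",
           "1|2" = "e3/e4", "1|1" = "e2/e4", "1|0" = "e1/e2",
           "0|2" = "e3/e3", "0|1" = "e2/e3", "0|0" = "e2/e2")
  tab
})

#' Call APOE epsilon diplotypes from the two coding SNPs
#'
#' rs429358 and rs7412 genotypes (counts of the C allele, e.g. produced by
#' [hard_call()] on imputed dosages of a C ALT allele) are combined through
#' the epsilon haplotype table: e2 = rs429358-T/rs7412-T, e3 = T/C,
#' e4 = C/C, e1 = C/T. The rs429358-C/T + rs7412-C/T double heterozygote is
#' resolved as e2/e4 - overwhelmingly the likely phase - and flagged
#' `ambiguous`. Any e1-containing diplotype is classed `e1-containing`.
#'
#' @param rs429358_c_count,rs7412_c_count Integer vectors (0, 1, 2 or `NA`).
#' @param sample_ids Optional ids.
#' @return Tibble `sample_id`, `rs429358`, `rs7412`, `diplotype` (e.g.
#'   `"e3/e4"`), `diplotype_class`, `ambiguous`, `e4_carrier`.
#' @export
call_apoe <- function(rs429358_c_count, rs7412_c_count, sample_ids = NULL) {
  c1 <- as.integer(rs429358_c_count)
  c2 <- as.integer(rs7412_c_count)
  check_that(length(c1) == length(c2), "the two genotype vectors differ in length.")
  check_that(all(is.na(c1) | c1 %in% 0:2) && all(is.na(c2) | c2 %in% 0:2),
             "genotypes must be C-allele counts 0, 1, 2 or NA.")
  dip <- unname(.apoe_table[paste(c1, c2, sep = "|")])
  dip[is.na(c1) | is.na(c2)] <- NA_character_
  ambiguous <- !is.na(c1) & !is.na(c2) & c1 == 1L & c2 == 1L
  cls <- dplyr::case_when(
    is.na(dip) ~ NA_character_,
    grepl("e1", dip) ~ "e1-containing",
    TRUE ~ dip
  )
  tibble(
    sample_id = sample_ids %||% paste0("sample_", seq_along(c1)),
    rs429358 = c1, rs7412 = c2,
    diplotype = dip, diplotype_class = cls,
    ambiguous = ambiguous,
    e4_carrier = ifelse(is.na(dip), NA, grepl("e4", dip))
  )
}

#' Concordance of called against gold-standard APOE diplotypes
#'
#' @param called,gold Tibbles with `sample_id` and `diplotype` (and
#'   optionally `e4_carrier`; recomputed from the diplotype when absent).
#' @return List: `concordance` (fraction of overlapping samples with
#'   identical diplotypes, both non-missing), `n_overlap`,
#'   `misclassification` (e4-carrier cross-tabulation counts), `mismatches`
#'   (per-sample table of the disagreements).
#' @export
apoe_concordance <- function(called, gold) {
  j <- dplyr::inner_join(
    select(as_tibble(called), "sample_id", called = "diplotype"),
    select(as_tibble(gold), "sample_id", gold = "diplotype"),
    by = "sample_id"
  )
  check_that(nrow(j) > 0, "no overlapping samples between called and gold sets.")
  j <- filter(j, !is.na(.data$called) & !is.na(.data$gold))
  check_that(nrow(j) > 0, "no overlapping samples with non-missing diplotypes.")
  j$called_e4 <- grepl("e4", j$called)
  j$gold_e4 <- grepl("e4", j$gold)
  mis <- tibble(
    carriers_called_noncarrier = sum(j$gold_e4 & !j$called_e4),
    noncarriers_called_carrier = sum(!j$gold_e4 & j$called_e4)
  )
  list(
    concordance = mean(j$called == j$gold),
    n_overlap = nrow(j),
    misclassification = mis,
    mismatches = filter(j, .data$called != .data$gold)
  )
}

#' Candidate-SNP replication by linear regression
#'
#' Trait values outside `mean +/- truncate_sd * SD` are removed in a single
#' pass; the trait is then regressed on the dosage plus any covariates by
#' ordinary least squares. Replication requires a two-sided dosage p-value
#' below `alpha` AND a coefficient sign matching the previously reported
#' direction.
#'
#' @param trait_values Numeric trait vector.
#' @param dosages Numeric allele dosages, aligned with the trait.
#' @param covariates Optional data frame of covariates (e.g. top PCs,
#'   specimen, site).
#' @param expected_sign `+1` or `-1`: previously reported direction.
#' @param truncate_sd Truncation width in SDs (single pass, non-iterative).
#' @param alpha Significance level of the rule.
#' @return One-row tibble: `n`, `n_truncated`, `beta`, `beta_sign`,
#'   `p_value`, `expected_sign`, `replicated`.
#' @export
replicate_snp <- function(trait_values, dosages, covariates = NULL,
                          expected_sign, truncate_sd = 4, alpha = 0.05) {
  check_that(expected_sign %in% c(-1, 1), "`expected_sign` must be -1 or +1.")
  df <- tibble(trait = as.numeric(trait_values), dosage = as.numeric(dosages))
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    check_that(nrow(covariates) == nrow(df), "covariates misaligned with trait.")
    df <- bind_cols(df, covariates)
  }
  df <- df[stats::complete.cases(df$trait, df$dosage), , drop = FALSE]
  mu <- mean(df$trait); sdev <- sd(df$trait)
  inside <- abs(df$trait - mu) <= truncate_sd * sdev
  n_trunc <- sum(!inside)
  df <- df[inside, , drop = FALSE]
  check_that(nrow(df) >= 30, "fewer than 30 samples after exclusions.")
  fit <- lm(trait ~ ., data = df)
  cf <- summary(fit)$coefficients
  if (anyNA(fit$coefficients)) {
    bad <- names(fit$coefficients)[is.na(fit$coefficients)]
    abort(sprintf("collinear covariate(s): %s", paste(bad, collapse = ", ")))
  }
  beta <- cf["dosage", "Estimate"]
  p <- cf["dosage", "Pr(>|t|)"]
  tibble(
    n = nrow(df), n_truncated = n_trunc,
    beta = beta, beta_sign = sign(beta),
    p_value = p, expected_sign = expected_sign,
    replicated = (p < alpha) && (sign(beta) == expected_sign)
  )
}
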