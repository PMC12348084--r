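# Per-sample QC: call rates, genetic sex from X homozygosity, specimen/site
# missingness comparisons, and the IQR batch-outlier rule.

#' Per-sample call rates
#'
#' Fraction of non-missing calls per sample over the given variants.
#'
#' @param dataset A [geno_dataset()].
#' @param variant_ids Optional variant subset.
#' @return Tibble `sample_id`, `n_variants`, `call_rate`.
#' @export
sample_call_rates <- function(dataset, variant_ids = NULL) {
  ds <- if (is.null(variant_ids)) dataset else subset_geno(dataset, variants = variant_ids)
  check_that(nrow(ds$variants) > 0, "empty dataset.")
  tibble(
    sample_id = ds$samples$sample_id,
    n_variants = ncol(ds$calls),
    call_rate = unname(rowMeans(!is.na(ds$calls)))
  )
}

#' Infer genetic sex from X-chromosome homozygosity
#'
#' Computes the X inbreeding coefficient
#' `F = (O_hom - E_hom) / (N - E_hom)` per sample, where
#' `E_hom = sum_i (1 - 2 p_i (1 - p_i) N_i / (N_i - 1))` runs over the
#' sample's non-missing, polymorphic, non-pseudoautosomal X variants, with the
#' sample-size-corrected expected heterozygosity and allele frequencies
#' estimated from the dataset. Hemizygous males (coded 0/2) have no X
#' heterozygotes, so `F` is near 1; females under Hardy-Weinberg proportions
#' sit near 0.
#'
#' @param dataset A [geno_dataset()].
#' @param f_female_max,f_male_min Decision thresholds: `F <= f_female_max` is
#'   called female, `F >= f_male_min` male, anything between undetermined.
#' @return Tibble `sample_id`, `n_x_used`, `x_inbreeding_F`, `inferred_sex`,
#'   `self_reported_sex`, `sex_mismatch` (NA when self-report is unknown).
#' @export
infer_sex <- function(dataset, f_female_max = 0.2, f_male_min = 0.8) {
  xi <- which(dataset$variants$chrom == "X")
  check_that(length(xi) > 0, "no X-chromosome variants in dataset.")
  g <- dataset$calls[, xi, drop = FALSE]
  p <- colMeans(g, na.rm = TRUE) / 2
  n_i <- colSums(!is.na(g))
  usable <- is.finite(p) & p > 0 & p < 1 & n_i > 1
  if (!any(usable)) abort("no polymorphic X variants usable for sex inference.")
  g <- g[, usable, drop = FALSE]
  p <- p[usable]
  n_i <- n_i[usable]
  h_i <- 2 * p * (1 - p) * n_i / (n_i - 1) # expected het per variant
  obs <- !is.na(g)
  exp_het <- obs %*% h_i
  obs_het <- (!is.na(g) & g == 1L) %*% rep(1, ncol(g))
  f <- as.numeric((exp_het - obs_het) / exp_het)
  f[exp_het == 0] <- NA_real_
  inferred <- dplyr::case_when(
    is.na(f) ~ "undetermined",
    f >= f_male_min ~ "male",
    f <= f_female_max ~ "female",
    TRUE ~ "undetermined"
  )
  self <- dataset$samples[["self_reported_sex"]] %||% rep("unknown", nrow(dataset$samples))
  mism <- ifelse(self %in% c("male", "female") & inferred != "undetermined",
                 inferred != self, NA)
  tibble(
    sample_id = dataset$samples$sample_id,
    n_x_used = unname(as.integer(rowSums(obs))),
    x_inbreeding_F = f,
    inferred_sex = inferred,
    self_reported_sex = self,
    sex_mismatch = mism
  )
}

#' Compare per-sample missing rates between two groups
#'
#' Two-sided Wilcoxon rank-sum test of per-sample missing rates between the
#' two levels of a grouping variable (specimen type or study site). When
#' `stratify_by` is given the comparison is repeated within each stratum,
#' which is how site effects can be assessed while holding specimen type
#' fixed.
#'
#' @param dataset A [geno_dataset()].
#' @param grouping Column of `dataset$samples` with exactly two levels.
#' @param stratify_by Optional second column; the test is run per stratum.
#' @param variant_ids Optional variant subset for the rates.
#' @return Tibble with one row per (stratum x) comparison: group labels and
#'   medians, `statistic`, `p_value`, group sizes.
#' @export
compare_missingness <- function(dataset, grouping = c("specimen", "site"),
                                stratify_by = NULL, variant_ids = NULL) {
  grouping <- grouping[1]
  check_that(grouping %in% names(dataset$samples),
             sprintf("no `%s` column in the sample table.", grouping))
  rates <- sample_call_rates(dataset, variant_ids)
  df <- tibble(
    sample_id = rates$sample_id,
    missing_rate = 1 - rates$call_rate,
    group = dataset$samples[[grouping]]
  )
  if (!is.null(stratify_by)) {
    df$stratum <- dataset$samples[[stratify_by]]
  } else {
    df$stratum <- "all"
  }
  one <- function(d, stratum) {
    lv <- sort(unique(d$group))
    check_that(length(lv) == 2, sprintf("`%s` must have exactly two groups.", grouping))
    x <- d$missing_rate[d$group == lv[1]]
    y <- d$missing_rate[d$group == lv[2]]
    check_that(length(x) >= 2 && length(y) >= 2, "each group needs at least 2 samples.")
    if (sd(c(x, y)) == 0) {
      # fully tied rates carry no evidence against exchangeability
      stat <- length(x) * length(y) / 2
      pv <- 1
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      stat <- unname(wt$statistic)
      pv <- wt$p.value
    }
    tibble(stratum = stratum, grouping = grouping,
           group_1 = lv[1], group_2 = lv[2],
           n_1 = length(x), n_2 = length(y),
           median_1 = median(x), median_2 = median(y),
           statistic = stat, p_value = pv)
  }
  df %>%
    dplyr::group_split(.data$stratum) %>%
    purrr::map(~ one(.x, .x$stratum[1])) %>%
    bind_rows()
}

#' Flag array batches with outlying mean missing rates
#'
#' Batch means of the per-sample missing rate are computed; a batch is flagged
#' when its mean exceeds `Q3 + 1.5 * (Q3 - Q1)`, quartiles taken over the
#' batch means by the linear-interpolation convention ([stats::quantile()]
#' type 7). The rule is invariant to batch order and to shifting all means by
#' a constant.
#'
#' @param call_rates Numeric per-sample call rates (as from
#'   [sample_call_rates()]), or the tibble that function returns.
#' @param batch_ids Batch label per sample.
#' @return Tibble `batch_id`, `n_samples`, `mean_missing`, `outlier`, with the
#'   threshold as attribute `"threshold"`.
#' @export
flag_batch_outliers <- function(call_rates, batch_ids) {
  if (is.data.frame(call_rates)) call_rates <- call_rates$call_rate
  check_that(length(call_rates) == length(batch_ids),
             "`call_rates` and `batch_ids` lengths differ.")
  out <- tibble(missing = 1 - call_rates, batch_id = as.character(batch_ids)) %>%
    group_by(.data$batch_id) %>%
    summarise(n_samples = dplyr::n(), mean_missing = mean(.data$missing),
              .groups = "drop")
  check_that(nrow(out) >= 4, "need at least 4 batches for the IQR rule.")
  q <- quantile(out$mean_missing, c(0.25, 0.75), type = 7, names = FALSE)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  out$outlier <- out$mean_missing > thr
  attr(out, "threshold") <- thr
  out
}

#' Full per-sample QC report
#'
#' Convenience wrapper bundling [sample_call_rates()], [infer_sex()],
#' [compare_missingness()] for specimen and site, and
#' [flag_batch_outliers()].
#'
#' @param dataset A [geno_dataset()] with specimen/site/batch metadata.
#' @param variant_ids Variant subset used for the call-rate diagnostics.
#' @param f_female_max,f_male_min Sex-call thresholds, see [infer_sex()].
#' @return List of class `sample_qc_report` with elements `per_sample`,
#'   `missingness_tests`, `batches`.
#' @export
sample_qc_report <- function(dataset, variant_ids = NULL,
                             f_female_max = 0.2, f_male_min = 0.8) {
  rates <- sample_call_rates(dataset, variant_ids)
  sex <- infer_sex(dataset, f_female_max, f_male_min)
  per_sample <- left_join(rates, select(sex, -"n_x_used"), by = "sample_id")
  tests <- list()
  for (gv in c("specimen", "site")) {
    if (gv %in% names(dataset$samples) &&
        length(unique(dataset$samples[[gv]])) == 2) {
      tests[[gv]] <- compare_missingness(dataset, gv, variant_ids = variant_ids)
    }
  }
  batches <- NULL
  if ("batch_id" %in% names(dataset$samples) &&
      length(unique(dataset$samples$batch_id)) >= 4) {
    batches <- flag_batch_outliers(rates, dataset$samples$batch_id)
  }
  structure(list(per_sample = per_sample,
                 missingness_tests = bind_rows(tests),
                 batches = batches),
            class = "sample_qc_report")
}

#' @export
print.sample_qc_report <- function(x, ...) {
  cat(sprintf("<sample_qc_report> %d samples; %d sex mismatch(es); %d outlier batch(es)\n",
              nrow(x$per_sample),
              sum(x$per_sample$sex_mismatch, na.rm = TRUE),
              if (is.null(x$batches)) 0L else sum(x$batches$outlier)))
  invisible(x)
}
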