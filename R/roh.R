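# Runs-of-homozygosity detection by scanning window, per-sample inbreeding F,
# and the LOESS-residual low-ROH outlier rule.

# running sums of width w over x (length L-w+1), via cumsum
run_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Detect runs of homozygosity by scanning window
#'
#' For every SNP, the fraction of overlapping `window_snps`-SNP windows that
#' are "homozygous" (at most `window_het_max` heterozygous and
#' `window_missing_max` missing calls) is computed; consecutive SNPs with a
#' fraction of at least `window_hit_threshold` form candidate segments.
#' Candidates are split where the gap between adjacent SNPs exceeds
#' `max_gap_kb`; a candidate is reported when it has at least `min_snps`
#' SNPs, spans at least `min_kb` (length `end_bp - start_bp + 1`), and its
#' density does not exceed `max_density_kb_per_snp` kb per SNP. Chromosomes
#' shorter than one window are scanned as a single truncated window.
#'
#' @param dataset A [geno_dataset()] with position-sorted autosomal variants.
#' @param sample_ids Optional sample subset.
#' @param window_snps Scanning-window size in SNPs.
#' @param min_snps,min_kb Minimum SNP count and length of a reported segment.
#' @param max_density_kb_per_snp Maximum kb per SNP within a segment.
#' @param max_gap_kb Maximum gap between adjacent SNPs within a segment.
#' @param window_het_max,window_missing_max Per-window allowances.
#' @param window_hit_threshold Minimum fraction of homozygous windows for a
#'   SNP to be part of a candidate segment.
#' @return Tibble `sample_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_kb`.
#' @export
detect_roh <- function(dataset, sample_ids = NULL,
                       window_snps = 50, min_snps = 100, min_kb = 1000,
                       max_density_kb_per_snp = 50, max_gap_kb = 1000,
                       window_het_max = 1, window_missing_max = 5,
                       window_hit_threshold = 0.05) {
  ds <- if (is.null(sample_ids)) dataset else subset_geno(dataset, samples = sample_ids)
  ds <- subset_geno(ds, variants = is_autosome(ds$variants$chrom))
  v <- ds$variants
  chroms <- unique(v$chrom)
  for (ch in chroms) {
    check_that(!is.unsorted(v$bp_position[v$chrom == ch]),
               sprintf("variants on chromosome %s are not position-sorted.", ch))
  }
  out <- list()
  for (ch in chroms) {
    idx <- which(v$chrom == ch)
    L <- length(idx)
    w <- min(window_snps, L)
    pos <- v$bp_position[idx]
    gap_break <- c(FALSE, diff(pos) > max_gap_kb * 1000)
    for (s in seq_len(nrow(ds$samples))) {
      g <- ds$calls[s, idx]
      het <- as.numeric(!is.na(g) & g == 1L)
      mis <- as.numeric(is.na(g))
      win_ok <- as.numeric(run_sum(het, w) <= window_het_max &
                             run_sum(mis, w) <= window_missing_max)
      # fraction of covering windows that are homozygous, per SNP
      n_win <- length(win_ok)
      cover_ok <- run_sum(c(rep(0, w - 1), win_ok, rep(0, w - 1)), w)
      n_cover <- pmin(seq_len(L), n_win, w, L - seq_len(L) + 1)
      frac <- cover_ok / n_cover
      hit <- frac >= window_hit_threshold
      # candidate runs of consecutive hit SNPs, split at large gaps
      run_id <- cumsum(!hit | gap_break)
      cand <- which(hit)
      if (!length(cand)) next
      for (rid in unique(run_id[cand])) {
        seg <- cand[run_id[cand] == rid]
        n_snps <- length(seg)
        if (n_snps < min_snps) next
        len_bp <- pos[seg[n_snps]] - pos[seg[1]] + 1
        len_kb <- len_bp / 1000
        if (len_kb < min_kb) next
        if (len_kb / n_snps > max_density_kb_per_snp) next
        out[[length(out) + 1]] <- tibble(
          sample_id = ds$samples$sample_id[s], chrom = ch,
          start_bp = pos[seg[1]], end_bp = pos[seg[n_snps]],
          n_snps = n_snps, length_kb = len_kb
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(sample_id = character(), chrom = character(),
                  start_bp = integer(), end_bp = integer(),
                  n_snps = integer(), length_kb = numeric()))
  }
  bind_rows(out)
}

#' Per-sample inbreeding coefficient from excess homozygosity
#'
#' `F = (O_hom - E_hom) / (N - E_hom)` with
#' `E_hom = sum_i (1 - 2 p_i (1 - p_i) N_i / (N_i - 1))` over the sample's
#' non-missing polymorphic autosomal variants; `N_i` is the number of
#' non-missing samples at variant i and frequencies are estimated from the
#' dataset.
#'
#' @param dataset A [geno_dataset()].
#' @param sample_ids Optional subset of samples to report (frequencies are
#'   estimated from this subset, matching a per-ancestry-group run).
#' @param variant_ids Optional variant subset.
#' @return Tibble `sample_id`, `n_used`, `o_hom`, `e_hom`, `f_inbreeding`
#'   (`NA`, flagged, when `N - E_hom = 0`).
#' @export
heterozygosity_f <- function(dataset, sample_ids = NULL, variant_ids = NULL) {
  ds <- subset_geno(dataset, samples = sample_ids, variants = variant_ids)
  ds <- subset_geno(ds, variants = is_autosome(ds$variants$chrom))
  g <- ds$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  n_i <- colSums(!is.na(g))
  usable <- is.finite(p) & p > 0 & p < 1 & n_i > 1
  check_that(any(usable), "no polymorphic autosomal variants.")
  g <- g[, usable, drop = FALSE]
  h_i <- 2 * p[usable] * (1 - p[usable]) * n_i[usable] / (n_i[usable] - 1)
  obs <- !is.na(g)
  n_used <- rowSums(obs)
  e_het <- as.numeric(obs %*% h_i)
  o_het <- as.numeric((obs & g == 1L) %*% rep(1, ncol(g)))
  o_hom <- n_used - o_het
  e_hom <- n_used - e_het
  f <- ifelse(e_het > 0, (e_het - o_het) / e_het, NA_real_)
  tibble(
    sample_id = ds$samples$sample_id,
    n_used = unname(as.integer(n_used)),
    o_hom = unname(as.integer(o_hom)),
    e_hom = unname(e_hom),
    f_inbreeding = unname(f)
  )
}

#' Per-sample ROH profile
#'
#' Combines [detect_roh()] segment totals with [heterozygosity_f()].
#'
#' @inheritParams detect_roh
#' @param ... Passed to [detect_roh()].
#' @return Tibble of class `roh_profile`: `sample_id`, `n_segments`,
#'   `total_kb`, `f_inbreeding`; segments kept in attribute `"segments"`.
#' @export
roh_profile <- function(dataset, sample_ids = NULL, ...) {
  segs <- detect_roh(dataset, sample_ids = sample_ids, ...)
  het <- heterozygosity_f(dataset, sample_ids = sample_ids)
  totals <- segs %>%
    group_by(.data$sample_id) %>%
    summarise(n_segments = dplyr::n(), total_kb = sum(.data$length_kb),
              .groups = "drop")
  out <- left_join(het, totals, by = "sample_id") %>%
    mutate(n_segments = dplyr::coalesce(.data$n_segments, 0L),
           total_kb = dplyr::coalesce(.data$total_kb, 0)) %>%
    select("sample_id", "n_segments", "total_kb", "f_inbreeding")
  attr(out, "segments") <- segs
  class(out) <- c("roh_profile", class(out))
  out
}

#' Flag low-ROH outliers from a LOESS fit of total ROH on F
#'
#' Local quadratic regression (tricube weights, no robustness iterations) of
#' total ROH length in kb on the inbreeding coefficient, fit separately per
#' group; samples whose residual falls below the `percentile`-th percentile
#' of the group's residual distribution are flagged. These are samples with
#' unusually short ROH given their heterozygosity - a poor-quality-sample
#' signature, as naturally inbred samples show both elevated F and long ROH.
#'
#' @param data Data frame with `sample_id`, `total_kb`, `f_inbreeding` (as
#'   from [roh_profile()]).
#' @param span LOESS smoothing span.
#' @param percentile Flagging percentile of the residual distribution (1 =
#'   1st percentile; 0 flags nothing).
#' @param group Optional column name to fit within (e.g. ancestry).
#' @return Tibble: input columns plus `fitted`, `residual`, `outlier`.
#' @export
loess_outliers <- function(data, span = 0.5, percentile = 1, group = NULL) {
  data <- as_tibble(data)
  check_that(all(c("sample_id", "total_kb", "f_inbreeding") %in% names(data)),
             "`data` needs sample_id, total_kb, f_inbreeding.")
  one <- function(d) {
    check_that(nrow(d) >= 20, "need at least 20 samples per group for the LOESS fit.")
    check_that(sd(d$f_inbreeding, na.rm = TRUE) > 0,
               "degenerate F distribution (zero variance).")
    fit <- loess(total_kb ~ f_inbreeding, data = d, span = span, degree = 2,
                 family = "gaussian", surface = "direct")
    d$fitted <- predict(fit, d)
    d$residual <- d$total_kb - d$fitted
    cut <- quantile(d$residual, percentile / 100, type = 7, names = FALSE,
                    na.rm = TRUE)
    d$outlier <- !is.na(d$residual) & d$residual < cut
    d
  }
  if (is.null(group)) {
    out <- one(data)
  } else {
    check_that(group %in% names(data), sprintf("no `%s` column.", group))
    out <- data %>%
      dplyr::group_split(.data[[group]]) %>%
      purrr::map(one) %>%
      bind_rows()
  }
  out
}
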