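# LD pruning, PCA, and ancestry assignment by the six-SD rule.

#' Greedy sliding-window LD pruning
#'
#' Windows of `window_snps` variants are advanced by `step_snps` along each
#' chromosome (variants must be position-sorted). Within a window, while any
#' retained pair has squared Pearson correlation of genotype codes above
#' `r2_max`, one member of the worst pair is removed - preferring the variant
#' with the higher missing rate, then the lower minor allele frequency, then
#' the later position. After the scan no retained pair within any window
#' exceeds `r2_max`.
#'
#' @param dataset A [geno_dataset()].
#' @param window_snps,step_snps,r2_max Window size, step and r-squared bound.
#' @param variant_ids Optional starting subset (autosomes only are used).
#' @return Character vector of retained variant ids, in position order.
#' @export
ld_prune <- function(dataset, window_snps = 50, step_snps = 5, r2_max = 0.1,
                     variant_ids = NULL) {
  ds <- if (is.null(variant_ids)) dataset else subset_geno(dataset, variants = variant_ids)
  ds <- subset_geno(ds, variants = is_autosome(ds$variants$chrom))
  v <- ds$variants
  keep_all <- character()
  miss <- colMeans(is.na(ds$calls))
  p <- colMeans(ds$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    pos <- v$bp_position[idx]
    check_that(!is.unsorted(pos), sprintf("variants on chromosome %s are not position-sorted.", ch))
    L <- length(idx)
    kept <- rep(TRUE, L)
    starts <- unique(c(seq(1L, max(1L, L - 1L), by = step_snps)))
    for (s in starts) {
      w <- s:min(s + window_snps - 1L, L)
      act <- w[kept[w]]
      if (length(act) < 2) next
      cm <- suppressWarnings(
        cor(ds$calls[, idx[act], drop = FALSE], use = "pairwise.complete.obs"))
      r2 <- cm^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      repeat {
        mx <- max(r2)
        if (mx <= r2_max) break
        hit <- which(r2 == mx, arr.ind = TRUE)[1, ]
        cand <- act[c(hit[1], hit[2])]
        gi <- idx[cand]
        drop_local <- if (miss[gi[1]] != miss[gi[2]]) {
          which.max(miss[gi])
        } else if (!isTRUE(all.equal(maf[gi[1]], maf[gi[2]]))) {
          which.min(maf[gi])
        } else {
          2L # later position
        }
        kept[cand[drop_local]] <- FALSE
        ri <- c(hit[1], hit[2])[drop_local]
        r2[ri, ] <- 0
        r2[, ri] <- 0
      }
    }
    keep_all <- c(keep_all, v$variant_id[idx[kept]])
  }
  keep_all
}

#' Principal component analysis of the genotype matrix
#'
#' Genotypes are mean-centred per variant and scaled by
#' `1/sqrt(2 p (1 - p))`; missing entries become zero after centring (mean
#' imputation); components come from the sample covariance of the
#' standardised matrix and variance-explained fractions are
#' eigenvalue / trace. The sign of each component is fixed by forcing its
#' first non-zero variant loading positive, so repeated runs are
#' reproducible.
#'
#' @param dataset A [geno_dataset()]; callers should pass unrelated samples.
#' @param variant_ids Pruned autosomal variant subset (recommended); `NULL`
#'   uses all autosomal variants.
#' @param n_components Number of components to keep.
#' @return Object of class `qc_pca`: `scores` (tibble `sample_id`,
#'   `PC1`..`PCk`), `var_explained`, `loadings`, `variant_ids`.
#' @export
run_pca <- function(dataset, variant_ids = NULL, n_components = 10) {
  ds <- if (is.null(variant_ids)) dataset else subset_geno(dataset, variants = variant_ids)
  ds <- subset_geno(ds, variants = is_autosome(ds$variants$chrom))
  n <- nrow(ds$samples)
  st <- standardize_calls(ds$calls)
  m_used <- ncol(st$z)
  check_that(n_components <= min(n, m_used),
             "`n_components` exceeds min(n_samples, n_variants).")
  cov <- tcrossprod(st$z)
  eg <- eigen(cov, symmetric = TRUE)
  k <- n_components
  vals <- pmax(eg$values, 0)
  u <- eg$vectors[, seq_len(k), drop = FALSE]
  loadings <- crossprod(st$z, u) # m_used x k
  for (j in seq_len(k)) {
    nz <- which(abs(loadings[, j]) > 1e-8)
    if (length(nz) && loadings[nz[1], j] < 0) {
      u[, j] <- -u[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  scores <- sweep(u, 2, sqrt(vals[seq_len(k)]), "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  used_ids <- ds$variants$variant_id[st$keep]
  structure(list(
    scores = bind_cols(tibble(sample_id = ds$samples$sample_id), as_tibble(scores)),
    var_explained = vals[seq_len(k)] / sum(vals),
    eigenvalues = vals[seq_len(k)],
    loadings = bind_cols(tibble(variant_id = used_ids), as_tibble(loadings, .name_repair = ~ paste0("PC", seq_len(k)))),
    variant_ids = used_ids,
    n_samples = n
  ), class = "qc_pca")
}

#' @export
print.qc_pca <- function(x, ...) {
  ve <- paste0(sprintf("%.1f%%", 100 * head(x$var_explained, 3)), collapse = ", ")
  cat(sprintf("<qc_pca> %d samples, %d variants, %d components (PC1-3 explain %s)\n",
              x$n_samples, length(x$variant_ids),
              length(x$var_explained), ve))
  invisible(x)
}

#' @method tidy qc_pca
#' @export
tidy.qc_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample_id",
                      names_to = "component", values_to = "score")
}

#' @method glance qc_pca
#' @export
glance.qc_pca <- function(x, ...) {
  tibble(n_samples = x$n_samples, n_variants = length(x$variant_ids),
         n_components = length(x$var_explained),
         pve_pc1 = x$var_explained[1], pve_pc2 = x$var_explained[2],
         pve_pc3 = x$var_explained[3])
}

#' Assign genetic ancestry by the six-SD rule
#'
#' For each eligible self-reported group (at least `min_group` members), the
#' mean and SD of the chosen principal component are computed within the
#' group; members within `mean +/- sd_mult * SD` are assigned the group's
#' ancestry label, members outside are flagged as outliers and left
#' unassigned. Samples of non-eligible groups are left unassigned entirely -
#' their ancestry cannot be confidently inferred from a handful of members.
#'
#' @param pca A `qc_pca` object or a scores tibble with `sample_id` and the
#'   component column.
#' @param self_reported_groups Group label per sample, aligned with the score
#'   table.
#' @param component Score column used (default `"PC1"`).
#' @param sd_mult Width of the envelope in group SDs.
#' @param eligible_groups Groups to process; default all with `>= min_group`
#'   members.
#' @param min_group Minimum members for mean/SD estimation.
#' @return Tibble `sample_id`, `self_reported_group`, `score`,
#'   `assigned_ancestry` (`NA` = unassigned), `outlier`.
#' @export
assign_ancestry <- function(pca, self_reported_groups, component = "PC1",
                            sd_mult = 6, eligible_groups = NULL, min_group = 3) {
  scores <- if (inherits(pca, "qc_pca")) pca$scores else as_tibble(pca)
  check_that(component %in% names(scores), sprintf("no `%s` column in scores.", component))
  check_that(nrow(scores) == length(self_reported_groups),
             "`self_reported_groups` must align with the score table.")
  df <- tibble(
    sample_id = scores$sample_id,
    self_reported_group = as.character(self_reported_groups),
    score = scores[[component]]
  )
  sizes <- table(df$self_reported_group)
  if (is.null(eligible_groups)) {
    eligible_groups <- names(sizes)[sizes >= min_group]
  } else {
    small <- eligible_groups[!(eligible_groups %in% names(sizes)) |
                               sizes[eligible_groups] < min_group]
    if (length(small)) {
      warn(sprintf("group(s) too small for ancestry assignment, left unassigned: %s",
                   paste(small, collapse = ", ")))
      eligible_groups <- setdiff(eligible_groups, small)
    }
  }
  df$assigned_ancestry <- NA_character_
  df$outlier <- FALSE
  for (gp in eligible_groups) {
    i <- which(df$self_reported_group == gp)
    mu <- mean(df$score[i])
    sdev <- sd(df$score[i])
    inside <- abs(df$score[i] - mu) <= sd_mult * sdev
    df$assigned_ancestry[i[inside]] <- gp
    df$outlier[i[!inside]] <- TRUE
  }
  df
}
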