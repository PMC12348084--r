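#' Genotype dataset container
#'
#' Bundles a hard-call genotype matrix with its sample and variant metadata.
#' Calls count copies of allele A1 and are coded `0`, `1`, `2` or `NA`
#' (missing). Samples are rows, variants are columns; row and column names
#' carry the identifiers so the matrix and the metadata tables can never drift
#' out of register.
#'
#' @param calls Integer matrix, samples x variants, values in `{0, 1, 2, NA}`.
#' @param samples Data frame with at least `sample_id`; recognised optional
#'   columns are `self_reported_sex` (`"male"`, `"female"`, `"unknown"`),
#'   `self_reported_group`, `specimen` (`"blood"`, `"serum"`), `site`,
#'   `batch_id`.
#' @param variants Data frame with `variant_id`, `chrom` (`"1"`..`"22"`,
#'   `"X"`; `"23"` is accepted and normalised to `"X"`), `bp_position`
#'   (1-based), `allele_A1`, `allele_A2`.
#'
#' @return An object of class `geno_dataset`: a list with tibbles `samples`
#'   and `variants` and the integer matrix `calls`.
#' @export
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2)
#' ds <- geno_dataset(
#'   calls,
#'   samples = data.frame(sample_id = c("s1", "s2")),
#'   variants = data.frame(
#'     variant_id = c("v1", "v2", "v3"), chrom = "1",
#'     bp_position = c(100L, 200L, 300L), allele_A1 = "A", allele_A2 = "G"
#'   )
#' )
#' ds
geno_dataset <- function(calls, samples, variants) {
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  check_that(is.matrix(calls), "`calls` must be a matrix.")
  storage.mode(calls) <- "integer"
  check_that(all(calls %in% c(0L, 1L, 2L) | is.na(calls)),
             "`calls` values must be 0, 1, 2 or NA.")
  check_that("sample_id" %in% names(samples), "`samples` needs a `sample_id` column.")
  check_that(!anyDuplicated(samples$sample_id), "duplicate `sample_id` in `samples`.")
  need <- c("variant_id", "chrom", "bp_position", "allele_A1", "allele_A2")
  check_that(all(need %in% names(variants)),
             paste("`variants` needs columns:", paste(need, collapse = ", ")))
  check_that(!anyDuplicated(variants$variant_id), "duplicate `variant_id` in `variants`.")
  check_that(nrow(samples) == nrow(calls) && nrow(variants) == ncol(calls),
             "`calls` dimensions do not match `samples`/`variants`.")
  samples$sample_id <- unname(as.character(samples$sample_id))
  variants$variant_id <- unname(as.character(variants$variant_id))
  variants$bp_position <- unname(as.integer(variants$bp_position))
  variants$chrom <- unname(norm_chrom(variants$chrom))
  check_that(all(variants$chrom %in% c(as.character(1:22), "X")),
             "`chrom` must be 1..22 or X.")
  check_that(all(variants$bp_position >= 0), "positions must be non-negative.")
  dimnames(calls) <- list(samples$sample_id, variants$variant_id)
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  n_auto <- sum(is_autosome(x$variants$chrom))
  cat(sprintf(
    "<geno_dataset> %d samples x %d variants (%d autosomal, %d X); %.2f%% missing\n",
    nrow(x$samples), nrow(x$variants), n_auto, nrow(x$variants) - n_auto,
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.geno_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param dataset A [geno_dataset()].
#' @param samples,variants Identifiers (character) or positions/logical
#'   vectors selecting rows of the respective metadata table; `NULL` keeps all.
#'   Order is preserved as given.
#' @return A `geno_dataset`.
#' @export
subset_geno <- function(dataset, samples = NULL, variants = NULL) {
  si <- resolve_idx(samples, dataset$samples$sample_id, "samples")
  vi <- resolve_idx(variants, dataset$variants$variant_id, "variants")
  geno_dataset(dataset$calls[si, vi, drop = FALSE],
               dataset$samples[si, , drop = FALSE],
               dataset$variants[vi, , drop = FALSE])
}

resolve_idx <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.character(sel)) {
    idx <- match(sel, ids)
    check_that(!anyNA(idx), sprintf("unknown %s identifier(s).", what))
    return(idx)
  }
  if (is.logical(sel)) {
    check_that(length(sel) == length(ids), sprintf("logical %s selector has wrong length.", what))
    return(which(sel))
  }
  as.integer(sel)
}

#' Allele-A1 frequencies per variant
#'
#' Estimated from non-missing calls. For X-chromosome variants, samples
#' reported male contribute one allele (hemizygous coding 0/2 counts as 0 or 1
#' copies) and females two; autosomes treat everyone as diploid.
#'
#' @inheritParams subset_geno
#' @param sample_ids Optional subset of samples used for estimation.
#' @return Tibble `variant_id`, `chrom`, `n_obs`, `freq_A1`.
#' @export
allele_freqs <- function(dataset, sample_ids = NULL) {
  ds <- if (is.null(sample_ids)) dataset else subset_geno(dataset, samples = sample_ids)
  g <- ds$calls
  is_x <- !is_autosome(ds$variants$chrom)
  male <- (ds$samples[["self_reported_sex"]] %||% "unknown") == "male"
  cnt <- colSums(g, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(g))
  if (any(is_x) && any(male)) {
    gm <- g[male, , drop = FALSE]
    cnt_m <- colSums(gm, na.rm = TRUE)
    tot_m <- colSums(!is.na(gm))
    # males: one allele each; code/2 copies of A1
    cnt[is_x] <- (cnt[is_x] - cnt_m[is_x]) + cnt_m[is_x] / 2
    tot[is_x] <- (tot[is_x] - 2 * tot_m[is_x]) + tot_m[is_x]
  }
  tibble(
    variant_id = ds$variants$variant_id,
    chrom = ds$variants$chrom,
    n_obs = unname(colSums(!is.na(g))),
    freq_A1 = unname(ifelse(tot > 0, cnt / tot, NA_real_))
  )
}

# Standardised genotype matrix for GRM/PCA: (x - 2p)/sqrt(2p(1-p)) with
# missing set to 0 after centring. Returns list(z, p, keep) where keep drops
# monomorphic / all-missing variants.
standardize_calls <- function(calls) {
  p <- colMeans(calls, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  g <- calls[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(g, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  list(z = z, p = p, keep = keep)
}
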