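# End-to-end QC pipeline: pre-filter, sample QC (sex, relatedness,
# specimen/site/batch diagnostics), ancestry inference, duplicate
# concordance, ROH outliers, final per-ancestry variant filters and
# second-pass PCA, with a telescoping run report.

#' Pipeline configuration
#'
#' Defaults are the conventional decision thresholds of array QC: a 90%
#' sample call-rate pre-filter and 1% MAF pre-filter; a sample-QC SNP subset
#' at call rate > 95%, MAF > 0.05, HWE p > 1e-6; LD pruning 50/5/0.1; the
#' six-SD ancestry envelope; final variant filters call rate > 95%,
#' MAF > 0.01, HWE p > 1e-6; a second-pass PCA subset at call rate > 98%
#' and MAF > 0.05; duplicate criterion PI_HAT > 0.98; the standard ROH
#' scanning-window parameters; LOESS span 0.5 with a 1st-percentile outlier
#' cut.
#'
#' @param ... Overrides for any default listed above.
#' @param seed Seed for the (simulation-free) pipeline; kept in the report
#'   fingerprint.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(..., seed = 1L) {
  cfg <- list(
    prefilter_sample_call_rate = 0.90,
    prefilter_maf = 0.01,
    sampleqc_call_rate = 0.95,
    sampleqc_maf = 0.05,
    sampleqc_hwe_p = 1e-6,
    sex_f_female_max = 0.2,
    sex_f_male_min = 0.8,
    prune_window = 50, prune_step = 5, prune_r2 = 0.1,
    ancestry_component = "PC1", ancestry_sd_mult = 6,
    relatedness_kinship_min = 0.0884, # 2nd degree and closer are resolved
    duplicate_pi_hat = 0.98,
    final_call_rate = 0.95, final_maf = 0.01, final_hwe_p = 1e-6,
    secondpass_call_rate = 0.98, secondpass_maf = 0.05,
    n_pcs = 10,
    roh_window_snps = 50, roh_min_snps = 100, roh_min_kb = 1000,
    roh_max_density = 50, roh_max_gap_kb = 1000,
    loess_span = 0.5, loess_percentile = 1,
    min_ancestry_group = 20,
    grm_max_variants = 50000,
    seed = as.integer(seed)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  check_that(length(unknown) == 0,
             paste("unknown config option(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "qc_config")
}

stage_row <- function(stage, n_in, n_out, v_in, v_out, ancestry = NA_character_,
                      note = "") {
  tibble(stage = stage, ancestry = ancestry,
         n_samples_in = n_in, n_samples_out = n_out,
         n_variants_in = v_in, n_variants_out = v_out, note = note)
}

#' Run the full QC pipeline
#'
#' Stages, in order: pre-filter (sample call rate, variant MAF); sample QC
#' (genetic sex check with exclusion of mismatches, GRM relatedness with
#' resolution of 2nd-degree-or-closer pairs by keeping the member with the
#' higher call rate, specimen/site missingness tests, batch-outlier
#' flagging); preliminary PCA and six-SD ancestry assignment (outliers and
#' non-eligible groups excluded); duplicate-pair concordance (reported, not
#' filtered); ROH/heterozygosity LOESS outlier exclusion per ancestry; final
#' variant filters per ancestry; second-pass PCA per ancestry emitting the
#' top PCs as analysis covariates alongside specimen, site and the
#' batch-outlier flag.
#'
#' @param dataset A [geno_dataset()] with sample metadata attached.
#' @param config A [qc_config()].
#' @return Object of class `qc_run`: `stages` (telescoping count table),
#'   `datasets` (cleaned per-ancestry `geno_dataset`s), `covariates`,
#'   `details` (per-stage result tables), `config`.
#' @export
run_pipeline <- function(dataset, config = qc_config()) {
  set.seed(config$seed)
  details <- list()
  stages <- list()
  fail <- function(stage, e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          partial_report = list(stages = bind_rows(stages), details = details))
  }

  ## stage 1: pre-filter ------------------------------------------------
  n0 <- nrow(dataset$samples); v0 <- nrow(dataset$variants)
  tryCatch({
    cr <- sample_call_rates(dataset)
    keep_s <- cr$sample_id[cr$call_rate >= config$prefilter_sample_call_rate]
    ds <- subset_geno(dataset, samples = keep_s)
    fr <- allele_freqs(ds)
    maf <- pmin(fr$freq_A1, 1 - fr$freq_A1)
    keep_v <- fr$variant_id[!is.na(maf) & maf >= config$prefilter_maf]
    ds <- subset_geno(ds, variants = keep_v)
    details$prefilter <- list(
      excluded_samples = setdiff(dataset$samples$sample_id, keep_s))
    stages[[1]] <- stage_row("prefilter", n0, nrow(ds$samples), v0, nrow(ds$variants))
    ds
  }, error = function(e) fail("prefilter", e)) -> ds

  ## stage 2: sample QC -------------------------------------------------
  tryCatch({
    n_in <- nrow(ds$samples); v_in <- nrow(ds$variants)
    vs <- variant_stats(ds)
    subset_ids <- filter_variants(vs, config$sampleqc_call_rate,
                                  config$sampleqc_maf, config$sampleqc_hwe_p)
    rep_sqc <- sample_qc_report(ds, variant_ids = subset_ids,
                                f_female_max = config$sex_f_female_max,
                                f_male_min = config$sex_f_male_min)
    mism <- rep_sqc$per_sample$sample_id[isTRUE_vec(rep_sqc$per_sample$sex_mismatch)]
    ds2 <- subset_geno(ds, samples = setdiff(ds$samples$sample_id, mism))

    grm_ids <- intersect(subset_ids,
                         ds2$variants$variant_id[is_autosome(ds2$variants$chrom)])
    if (length(grm_ids) > config$grm_max_variants) {
      grm_ids <- sort(sample(grm_ids, config$grm_max_variants))
    }
    grm <- compute_grm(ds2, variant_ids = grm_ids)
    related <- classify_relationships(grm, min_kinship = config$relatedness_kinship_min)
    # resolve duplicates/siblings/2nd degree: drop lower-call-rate member
    cr2 <- sample_call_rates(ds2)
    drop <- character()
    for (i in seq_len(nrow(related))) {
      a <- related$sample_a[i]; b <- related$sample_b[i]
      if (a %in% drop || b %in% drop) next
      ra <- cr2$call_rate[match(a, cr2$sample_id)]
      rb <- cr2$call_rate[match(b, cr2$sample_id)]
      drop <- c(drop, if (ra >= rb) b else a)
    }
    details$sample_qc <- list(report = rep_sqc, sex_mismatches = mism,
                              relatedness = related, related_dropped = drop,
                              subset_variants = subset_ids)
    ds3 <- subset_geno(ds2, samples = setdiff(ds2$samples$sample_id, drop))
    stages[[2]] <- stage_row("sample_qc", n_in, nrow(ds3$samples), v_in, v_in,
                             note = sprintf("%d sex mismatch, %d related dropped",
                                            length(mism), length(drop)))
    ds3
  }, error = function(e) fail("sample_qc", e)) -> ds

  ## stage 3: ancestry --------------------------------------------------
  tryCatch({
    n_in <- nrow(ds$samples); v_in <- nrow(ds$variants)
    vs <- variant_stats(ds)
    pool <- filter_variants(vs, config$sampleqc_call_rate, config$sampleqc_maf,
                            config$sampleqc_hwe_p)
    pool <- pool[is_autosome(ds$variants$chrom[match(pool, ds$variants$variant_id)])]
    pruned <- ld_prune(ds, config$prune_window, config$prune_step,
                       config$prune_r2, variant_ids = pool)
    pca <- run_pca(ds, variant_ids = pruned,
                   n_components = min(config$n_pcs, nrow(ds$samples) - 1))
    anc <- assign_ancestry(pca, ds$samples$self_reported_group,
                           component = config$ancestry_component,
                           sd_mult = config$ancestry_sd_mult)
    keep <- anc$sample_id[!is.na(anc$assigned_ancestry)]
    details$ancestry <- list(pca = pca, assignment = anc, pruned_variants = pruned)
    ds4 <- subset_geno(ds, samples = keep)
    stages[[3]] <- stage_row("ancestry", n_in, nrow(ds4$samples), v_in, v_in,
                             note = sprintf("%d outlier(s), %d unassigned",
                                            sum(anc$outlier),
                                            sum(is.na(anc$assigned_ancestry) & !anc$outlier)))
    attr(ds4, "ancestry") <- anc
    ds4
  }, error = function(e) fail("ancestry", e)) -> ds

  anc <- attr(ds, "ancestry")
  anc_of <- setNames(anc$assigned_ancestry, anc$sample_id)

  ## stage 4: duplicate concordance (diagnostic only) --------------------
  tryCatch({
    related <- details$sample_qc$relatedness
    dups <- filter(related, .data$relationship == "duplicate_or_MZ")
    conc <- NULL
    if (nrow(dups) > 0) {
      full_cr <- sample_call_rates(dataset)
      ok <- function(id) {
        r <- full_cr$call_rate[match(id, full_cr$sample_id)]
        !is.na(r) && r > 0.95
      }
      rows <- purrr::pmap(dups, function(sample_a, sample_b, ...) {
        if (ok(sample_a) && ok(sample_b)) {
          duplicate_concordance(dataset, c(sample_a, sample_b))
        } else NULL
      })
      rows <- purrr::compact(rows)
      if (length(rows)) {
        conc <- bind_rows(rows)
        details$concordance <- list(pairs = conc, pooled = pool_discordant(conc))
      }
    }
    n <- nrow(ds$samples); v <- nrow(ds$variants)
    stages[[4]] <- stage_row("concordance", n, n, v, v,
                             note = sprintf("%d duplicate pair(s) compared",
                                            if (is.null(conc)) 0L else nrow(conc)))
  }, error = function(e) fail("concordance", e))

  ## stage 5: ROH / heterozygosity outliers ------------------------------
  tryCatch({
    n_in <- nrow(ds$samples); v_in <- nrow(ds$variants)
    out_ids <- character()
    roh_tabs <- list()
    for (gp in unique(stats::na.omit(anc_of[ds$samples$sample_id]))) {
      ids <- ds$samples$sample_id[anc_of[ds$samples$sample_id] == gp]
      if (length(ids) < config$min_ancestry_group) next
      prof <- roh_profile(ds, sample_ids = ids,
                          window_snps = config$roh_window_snps,
                          min_snps = config$roh_min_snps,
                          min_kb = config$roh_min_kb,
                          max_density_kb_per_snp = config$roh_max_density,
                          max_gap_kb = config$roh_max_gap_kb)
      fl <- loess_outliers(prof, span = config$loess_span,
                           percentile = config$loess_percentile)
      fl$ancestry <- gp
      roh_tabs[[gp]] <- fl
      out_ids <- c(out_ids, fl$sample_id[fl$outlier])
    }
    details$roh <- list(profiles = bind_rows(roh_tabs), outliers = out_ids)
    ds5 <- subset_geno(ds, samples = setdiff(ds$samples$sample_id, out_ids))
    stages[[5]] <- stage_row("roh_outliers", n_in, nrow(ds5$samples), v_in, v_in,
                             note = sprintf("%d low-ROH outlier(s)", length(out_ids)))
    ds5
  }, error = function(e) fail("roh_outliers", e)) -> ds

  ## stages 6-7: per-ancestry variant filters + second-pass PCA ----------
  datasets <- list()
  covariates <- list()
  tryCatch({
    batches <- details$sample_qc$report$batches
    outlier_batches <- if (is.null(batches)) character() else
      batches$batch_id[batches$outlier]
    for (gp in unique(stats::na.omit(anc_of[ds$samples$sample_id]))) {
      ids <- ds$samples$sample_id[anc_of[ds$samples$sample_id] == gp]
      sub <- subset_geno(ds, samples = ids)
      n_in <- nrow(sub$samples); v_in <- nrow(sub$variants)
      vs <- variant_stats(sub)
      final_ids <- filter_variants(vs, config$final_call_rate,
                                   config$final_maf, config$final_hwe_p)
      subf <- subset_geno(sub, variants = final_ids)
      stages[[length(stages) + 1]] <- stage_row("final_variant_filter",
                                                n_in, n_in, v_in, nrow(subf$variants),
                                                ancestry = gp)
      # second-pass PCA on a tighter pruned subset
      vs2 <- variant_stats(subf)
      pool2 <- filter_variants(vs2, config$secondpass_call_rate,
                               config$secondpass_maf, config$final_hwe_p)
      pool2 <- pool2[is_autosome(subf$variants$chrom[match(pool2, subf$variants$variant_id)])]
      pruned2 <- ld_prune(subf, config$prune_window, config$prune_step,
                          config$prune_r2, variant_ids = pool2)
      k <- min(config$n_pcs, length(ids) - 1, length(pruned2))
      pca2 <- run_pca(subf, variant_ids = pruned2, n_components = k)
      cov <- pca2$scores
      meta <- subf$samples
      cov$specimen <- meta$specimen[match(cov$sample_id, meta$sample_id)]
      cov$site <- meta$site[match(cov$sample_id, meta$sample_id)]
      cov$batch_outlier <- meta$batch_id[match(cov$sample_id, meta$sample_id)] %in%
        outlier_batches
      cov$ancestry <- gp
      datasets[[gp]] <- subf
      covariates[[gp]] <- cov
      stages[[length(stages) + 1]] <- stage_row("second_pass_pca",
                                                n_in, n_in,
                                                nrow(subf$variants), nrow(subf$variants),
                                                ancestry = gp,
                                                note = sprintf("%d PCs from %d pruned variants",
                                                               k, length(pruned2)))
    }
  }, error = function(e) fail("final_filters", e))

  structure(list(
    stages = bind_rows(stages),
    datasets = datasets,
    covariates = bind_rows(covariates),
    details = details,
    config = config
  ), class = "qc_run")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.qc_run <- function(x, ...) {
  cat("<qc_run>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' @method tidy qc_run
#' @export
tidy.qc_run <- function(x, ...) x$stages

#' @method glance qc_run
#' @export
glance.qc_run <- function(x, ...) {
  per_anc <- purrr::imap(x$datasets, function(d, gp) {
    tibble(ancestry = gp, n_samples = nrow(d$samples),
           n_variants = nrow(d$variants))
  })
  bind_rows(per_anc)
}

#' Write cleaned per-ancestry datasets and covariates to disk
#'
#' @param run A `qc_run`.
#' @param dir Output directory (created if needed). Each ancestry group gets
#'   a PLINK fileset `<dir>/<ancestry>.{bed,bim,fam}`; covariates go to
#'   `<dir>/covariates.tsv`.
#' @return Invisibly, the paths written.
#' @export
export_qc <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  for (gp in names(run$datasets)) {
    paths[[gp]] <- write_plink(run$datasets[[gp]], file.path(dir, gp))
  }
  cov_path <- file.path(dir, "covariates.tsv")
  write.table(run$covariates, cov_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, covariates = cov_path))
}
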