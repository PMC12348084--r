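# Synthetic cohort generator. Variants are in linkage equilibrium (drawn
# independently); population structure follows the Balding-Nichols model;
# relatives are produced by gene dropping; autozygosity by forcing contiguous
# homozygous tracts. Ground truth is carried in sidecar tables so every
# downstream QC stage can be tested for parameter recovery.

make_variant_table <- function(spec) {
  m <- spec$n_autosomal_variants
  per_chrom <- diff(floor(seq(0, m, length.out = 23)))
  chrom <- rep(as.character(1:22), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) 1e6 + spec$variant_spacing_bp * (seq_len(k) - 1)),
                use.names = FALSE)
  auto <- tibble(
    variant_id = sprintf("var%06d", seq_len(m)),
    chrom = chrom, bp_position = as.integer(pos),
    allele_A1 = "A", allele_A2 = "B"
  )
  if (spec$n_x_variants > 0) {
    xv <- tibble(
      variant_id = sprintf("xvar%05d", seq_len(spec$n_x_variants)),
      chrom = "X",
      bp_position = as.integer(1e6 + spec$variant_spacing_bp * (seq_len(spec$n_x_variants) - 1)),
      allele_A1 = "A", allele_A2 = "B"
    )
    auto <- bind_rows(auto, xv)
  }
  auto
}

# Defect variant selection + allele frequency draw. Must be the first RNG
# consumer after set.seed(spec$seed) so that draw_allele_frequencies() and
# simulate_cohort() agree.
draw_freq_matrix <- function(spec, variants) {
  m <- nrow(variants)
  auto_idx <- which(is_autosome(variants$chrom))
  vd <- spec$variant_defects
  n_def <- vd$n_low_maf + vd$n_low_call + vd$n_hwe_het_excess
  defects <- tibble(variant_id = character(), defect = character())
  def_idx <- integer()
  if (n_def > 0) {
    check_that(n_def <= length(auto_idx), "more planted defects than autosomal variants.")
    def_idx <- sample(auto_idx, n_def)
    defects <- tibble(
      variant_id = variants$variant_id[def_idx],
      defect = rep(c("low_maf", "low_call", "hwe_het_excess"),
                   times = c(vd$n_low_maf, vd$n_low_call, vd$n_hwe_het_excess))
    )
  }
  p_anc <- runif(m, spec$ancestral_maf_range[1], spec$ancestral_maf_range[2])
  low_maf_idx <- def_idx[seq_len(vd$n_low_maf)]
  if (vd$n_low_maf > 0) p_anc[low_maf_idx] <- runif(vd$n_low_maf, 0.0005, 0.002)
  # heterozygote-excess defects use mid-range frequencies so the planted
  # violation is unambiguous rather than frequency-dependent
  het_idx <- def_idx[seq(vd$n_low_maf + vd$n_low_call + 1,
                         length.out = vd$n_hwe_het_excess)]
  if (vd$n_hwe_het_excess > 0) p_anc[het_idx] <- runif(vd$n_hwe_het_excess, 0.25, 0.45)
  K <- spec$n_populations
  if (K == 1) {
    freq <- matrix(p_anc, ncol = 1)
  } else {
    a <- p_anc * (1 - spec$fst) / spec$fst
    b <- (1 - p_anc) * (1 - spec$fst) / spec$fst
    freq <- vapply(seq_len(K), function(k) rbeta(m, a, b), numeric(m))
    # defect variants are kept undifferentiated so their failure mode is the
    # planted one, not a drift artefact
    freq[def_idx, ] <- p_anc[def_idx]
  }
  freq <- clamp(freq, 1e-6, 1 - 1e-6)
  colnames(freq) <- population_labels(spec)
  list(freq = freq, defects = defects)
}

#' Draw per-variant, per-population allele frequencies
#'
#' Ancestral frequency `p` is uniform on `ancestral_maf_range`; each
#' population's frequency is Beta-distributed with mean `p` and variance
#' `fst * p * (1 - p)` (Balding-Nichols shape parameters
#' `a = p(1-fst)/fst`, `b = (1-p)(1-fst)/fst`). With a single population the
#' ancestral frequency is returned unchanged.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble `variant_id`, `chrom`, `population`, `frequency` (long form,
#'   one row per variant x population), frequencies in `(0, 1)`.
#' @export
draw_allele_frequencies <- function(spec) {
  set.seed(spec$seed)
  variants <- make_variant_table(spec)
  fr <- draw_freq_matrix(spec, variants)
  as_tibble(fr$freq) %>%
    mutate(variant_id = variants$variant_id, chrom = variants$chrom) %>%
    tidyr::pivot_longer(-c("variant_id", "chrom"),
                        names_to = "population", values_to = "frequency")
}

transmit <- function(g) rbinom(length(g), 1L, g / 2)

founder_row <- function(freq_pop) rbinom(length(freq_pop), 2L, freq_pop)

#' Simulate a synthetic cohort with ground-truth sidecars
#'
#' Founders draw genotypes `Binomial(2, freq)` per variant given their
#' population; planted relatives are produced by gene dropping (duplicates
#' copy genotypes, full siblings share two simulated parents, 2nd/3rd-degree
#' pairs by chained parent-offspring transmission); X variants are hemizygous
#' in males (coded 0/2); autozygosity tracts force contiguous homozygous
#' stretches whose summed length matches the sample's target fraction.
#' Pedigree gene dropping applies to autosomes; X genotypes of non-duplicate
#' relatives are drawn independently.
#'
#' The returned cohort is clean: call [apply_genotype_errors()] and
#' [apply_missingness()] to overlay the error and missingness processes. The
#' pristine call matrix is kept in `true_calls`.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `dataset` (a [geno_dataset()]),
#'   `true_calls`, `true_sex`, `true_ancestry`, `true_kinship` (pedigree
#'   kinship per planted pair: duplicate 0.5, first 0.25, second 0.125,
#'   third 0.0625), `true_roh` (planted segments), `dispersed`,
#'   `variant_defects`, `allele_freqs` and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed)
  variants <- make_variant_table(spec)
  fr <- draw_freq_matrix(spec, variants)
  freq <- fr$freq
  n <- spec$n_samples
  m <- nrow(variants)
  auto_idx <- which(is_autosome(variants$chrom))
  x_idx <- which(variants$chrom == "X")
  pops <- population_labels(spec)

  ## sample frame -------------------------------------------------------
  pop <- sample(pops, n, replace = TRUE, prob = spec$population_proportions)
  true_sex <- ifelse(runif(n) < spec$sex_ratio, "female", "male")
  specimen <- sample(names(spec$specimen_proportions), n, replace = TRUE,
                     prob = spec$specimen_proportions)
  site <- sample(names(spec$site_proportions), n, replace = TRUE,
                 prob = spec$site_proportions)
  size_choices <- seq(spec$batch_size_range[1], spec$batch_size_range[2])
  batch_sizes <- integer()
  while (sum(batch_sizes) < n) {
    batch_sizes <- c(batch_sizes, size_choices[sample.int(length(size_choices), 1)])
  }
  batch_id <- rep(sprintf("B%03d", seq_along(batch_sizes)), batch_sizes)[seq_len(n)]
  sample_id <- sprintf("S%04d", seq_len(n))

  ## relationships force shared population/sex before genotype draw ------
  rel <- spec$planted_relationships
  if (!is.null(rel)) {
    for (i in seq_len(nrow(rel))) {
      pop[rel$sample_b[i]] <- pop[rel$sample_a[i]]
      if (rel$degree[i] == "duplicate") {
        true_sex[rel$sample_b[i]] <- true_sex[rel$sample_a[i]]
      }
    }
  }

  ## founder genotypes --------------------------------------------------
  calls <- matrix(0L, n, m)
  for (k in seq_along(pops)) {
    rows <- which(pop == pops[k])
    if (length(rows) == 0) next
    calls[rows, ] <- t(matrix(rbinom(m * length(rows), 2L, freq[, k]), nrow = m))
  }
  # X hemizygosity in males: one allele, coded 0/2
  if (length(x_idx) > 0) {
    for (k in seq_along(pops)) {
      rows <- which(pop == pops[k] & true_sex == "male")
      if (length(rows) == 0) next
      calls[rows, x_idx] <- t(matrix(
        2L * rbinom(length(x_idx) * length(rows), 1L, freq[x_idx, k]),
        nrow = length(x_idx)))
    }
  }
  # planted Hardy-Weinberg violations: heterozygote excess
  het_ids <- fr$defects$variant_id[fr$defects$defect == "hwe_het_excess"]
  for (vid in het_ids) {
    j <- match(vid, variants$variant_id)
    p <- freq[j, 1]
    p_het <- min(0.9, 2 * 2 * p * (1 - p))
    rest <- 1 - p_het
    probs <- c(rest * (1 - p)^2 / ((1 - p)^2 + p^2), p_het,
               rest * p^2 / ((1 - p)^2 + p^2))
    calls[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
  }

  ## gene dropping ------------------------------------------------------
  if (!is.null(rel)) {
    for (i in seq_len(nrow(rel))) {
      a <- rel$sample_a[i]; b <- rel$sample_b[i]
      fk <- freq[auto_idx, match(pop[a], pops)]
      if (rel$degree[i] == "duplicate") {
        calls[b, ] <- calls[a, ]
      } else if (rel$degree[i] == "first") {
        p1 <- founder_row(fk); p2 <- founder_row(fk)
        calls[a, auto_idx] <- transmit(p1) + transmit(p2)
        calls[b, auto_idx] <- transmit(p1) + transmit(p2)
      } else if (rel$degree[i] == "second") {
        child <- transmit(calls[a, auto_idx]) + transmit(founder_row(fk))
        calls[b, auto_idx] <- transmit(child) + transmit(founder_row(fk))
      } else { # third degree
        child <- transmit(calls[a, auto_idx]) + transmit(founder_row(fk))
        gchild <- transmit(child) + transmit(founder_row(fk))
        calls[b, auto_idx] <- transmit(gchild) + transmit(founder_row(fk))
      }
    }
  }

  ## autozygosity tracts ------------------------------------------------
  auto_frac <- spec$autozygosity
  if (is.null(auto_frac)) {
    auto_frac <- runif(n, spec$autozygosity_range[1], spec$autozygosity_range[2])
  } else if (length(auto_frac) == 1) {
    auto_frac <- rep(auto_frac, n)
  }
  check_that(length(auto_frac) == n, "`autozygosity` must have length n_samples.")
  # dispersed-homozygosity samples carry no tracts: their excess homozygosity
  # must come without ROH, which is exactly the outlier signature
  if (!is.null(spec$dispersed_homozygosity)) {
    dh <- spec$dispersed_homozygosity
    dh_idx <- if (!is.null(names(dh))) as.integer(names(dh)) else which(dh > 0)
    auto_frac[dh_idx] <- 0
  }
  chrom_auto <- variants$chrom[auto_idx]
  pos_auto <- variants$bp_position[auto_idx]
  chrom_span <- tapply(pos_auto, chrom_auto, function(p) max(p) - min(p) + 1)
  genome_bp <- sum(chrom_span)
  # samples in planted pairs keep their gene-dropped genotypes untouched so
  # the pedigree kinship stays exact
  rel_samples <- if (is.null(rel)) integer() else unique(c(rel$sample_a, rel$sample_b))
  seg_rows <- list()
  for (s in seq_len(n)) {
    target <- auto_frac[s] * genome_bp
    if (target <= 0 || s %in% rel_samples) next
    fk <- freq[, match(pop[s], pops)]
    hom_code <- ifelse(fk >= 0.5, 2L, 0L)
    placed <- 0
    used <- rep(FALSE, length(auto_idx))
    tries <- 0
    while (placed < target && tries < 50) {
      tries <- tries + 1
      span <- if (target - placed < 3e6) target - placed else runif(1, 3e6, 6e6)
      ch <- sample(names(chrom_span), 1, prob = as.numeric(chrom_span))
      on_ch <- which(chrom_auto == ch)
      if (length(on_ch) < 2) next
      start_i <- sample(length(on_ch), 1)
      pos_ch <- pos_auto[on_ch]
      end_i <- max(which(pos_ch <= pos_ch[start_i] + span))
      if (end_i <= start_i) next
      run <- on_ch[start_i:end_i]
      if (any(used[run])) next
      used[run] <- TRUE
      cols <- auto_idx[run]
      calls[s, cols] <- hom_code[cols]
      seg_rows[[length(seg_rows) + 1]] <- tibble(
        sample_id = sample_id[s], chrom = ch,
        start_bp = pos_ch[start_i], end_bp = pos_ch[end_i],
        n_snps = length(run)
      )
      placed <- placed + (pos_ch[end_i] - pos_ch[start_i] + 1)
    }
  }
  true_roh <- if (length(seg_rows)) bind_rows(seg_rows) else
    tibble(sample_id = character(), chrom = character(),
           start_bp = integer(), end_bp = integer(), n_snps = integer())

  ## dispersed excess homozygosity (low-ROH outlier signature) ----------
  disp <- spec$dispersed_homozygosity
  disp_tbl <- tibble(sample_id = character(), n_variants = integer())
  if (!is.null(disp)) {
    disp_idx <- if (!is.null(names(disp))) as.integer(names(disp)) else
      which(disp > 0)
    disp_val <- if (!is.null(names(disp))) as.numeric(disp) else disp[disp_idx]
    for (i in seq_along(disp_idx)) {
      s <- disp_idx[i]
      if (s %in% rel_samples) next
      fk <- freq[, match(pop[s], pops)]
      hom_code <- ifelse(fk >= 0.5, 2L, 0L)
      k_n <- round(disp_val[i] * length(auto_idx))
      cols <- auto_idx[sample(length(auto_idx), k_n)]
      calls[s, cols] <- hom_code[cols]
      disp_tbl <- bind_rows(disp_tbl,
                            tibble(sample_id = sample_id[s], n_variants = k_n))
    }
  }

  ## self-report with planted clerical problems -------------------------
  self_sex <- true_sex
  if (length(spec$sex_swaps)) {
    self_sex[spec$sex_swaps] <- ifelse(true_sex[spec$sex_swaps] == "male",
                                       "female", "male")
  }
  self_group <- pop
  if (length(spec$group_mislabels)) {
    for (s in spec$group_mislabels) {
      others <- setdiff(pops, pop[s])
      self_group[s] <- others[1]
    }
  }

  samples <- tibble(
    sample_id = sample_id,
    self_reported_sex = self_sex,
    self_reported_group = self_group,
    specimen = specimen, site = site, batch_id = batch_id
  )
  ds <- geno_dataset(calls, samples, variants)

  kin_map <- c(duplicate = 0.5, first = 0.25, second = 0.125, third = 0.0625)
  true_kinship <- if (is.null(rel)) {
    tibble(sample_a = character(), sample_b = character(),
           degree = character(), kinship = numeric())
  } else {
    tibble(sample_a = sample_id[rel$sample_a], sample_b = sample_id[rel$sample_b],
           degree = rel$degree, kinship = unname(kin_map[rel$degree]))
  }

  freq_long <- as_tibble(freq) %>%
    mutate(variant_id = variants$variant_id) %>%
    tidyr::pivot_longer(-"variant_id", names_to = "population",
                        values_to = "frequency")

  structure(list(
    dataset = ds,
    true_calls = ds$calls,
    true_sex = setNames(true_sex, sample_id),
    true_ancestry = setNames(pop, sample_id),
    true_kinship = true_kinship,
    true_roh = true_roh,
    dispersed = disp_tbl,
    variant_defects = fr$defects,
    allele_freqs = freq_long,
    trait_specs = spec$trait_specs,
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples x %d variants; %d planted pair(s), %d ROH segment(s), %d defect variant(s)\n",
    nrow(x$dataset$samples), nrow(x$dataset$variants),
    nrow(x$true_kinship), nrow(x$true_roh), nrow(x$variant_defects)
  ))
  invisible(x)
}

#' Overlay specimen-, batch- and variant-driven missingness
#'
#' Each genotype is set missing independently with probability
#' `specimen_rate + batch_effect` (+ the extra rate of a planted low-call
#' variant), clipped to `[0, 1]`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param spec Defaults to the cohort's own spec.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The cohort with masked `dataset$calls` (`true_calls` untouched).
#' @export
apply_missingness <- function(cohort, spec = cohort$spec, seed = NULL) {
  with_optional_seed(seed, {
    ds <- cohort$dataset
    n <- nrow(ds$samples); m <- nrow(ds$variants)
    r <- unname(spec$specimen_missing_rates[ds$samples$specimen])
    r[is.na(r)] <- 0
    if (!is.null(spec$batch_effects)) {
      be <- spec$batch_effects[ds$samples$batch_id]
      be[is.na(be)] <- 0
      r <- r + unname(be)
    }
    v <- numeric(m)
    low_call <- cohort$variant_defects$variant_id[cohort$variant_defects$defect == "low_call"]
    v[match(low_call, ds$variants$variant_id)] <- spec$variant_defects$low_call_missing_rate
    calls <- ds$calls
    for (s in seq_len(n)) {
      pr <- clamp(r[s] + v, 0, 1)
      if (all(pr == 0)) next
      calls[s, runif(m) < pr] <- NA_integer_
    }
    cohort$dataset$calls <- calls
    cohort
  })
}

#' Overlay random genotype errors
#'
#' Each non-missing genotype is replaced, with probability
#' `spec$genotype_error_rate`, by a different code. Two error processes are
#' available: `"uniform"` (the replacement is drawn uniformly from the
#' remaining two codes - a maximally agnostic stand-in) and `"adjacent"`
#' (a single allele copy is miscalled, so homozygotes become heterozygous
#' and heterozygotes become either homozygote with equal probability - the
#' structure of real array miscalls, which essentially never jump between
#' opposite homozygotes). The choice matters for identity checks: uniform
#' errors create IBS0 events between duplicate copies and visibly depress
#' PI_HAT, adjacent errors do not. The pristine matrix stays in
#' `true_calls`.
#'
#' @inheritParams apply_missingness
#' @param error_rate Overrides the spec's rate when given.
#' @param error_model `"uniform"` or `"adjacent"`.
#' @return The cohort with perturbed `dataset$calls`.
#' @export
apply_genotype_errors <- function(cohort, spec = cohort$spec, seed = NULL,
                                  error_rate = NULL,
                                  error_model = c("uniform", "adjacent")) {
  e <- error_rate %||% spec$genotype_error_rate
  error_model <- match.arg(error_model)
  check_prob(e, "error_rate")
  with_optional_seed(seed, {
    calls <- cohort$dataset$calls
    if (e > 0) {
      hit <- which(runif(length(calls)) < e & !is.na(calls))
      if (length(hit)) {
        if (error_model == "uniform") {
          shift <- sample(1:2, length(hit), replace = TRUE)
          calls[hit] <- (calls[hit] + shift) %% 3L
        } else {
          old <- calls[hit]
          new <- ifelse(old == 1L,
                        sample(c(0L, 2L), length(hit), replace = TRUE), 1L)
          calls[hit] <- as.integer(new)
        }
      }
    }
    cohort$dataset$calls <- calls
    cohort
  })
}

#' Simulate quantitative traits with planted SNP effects
#'
#' Each row of `trait_specs` defines one trait:
#' `trait = effect_size * genotype + Normal(0, residual_sd)`, with the
#' genotype taken from the pristine call matrix.
#'
#' @inheritParams apply_missingness
#' @param trait_specs Defaults to the cohort's spec. Columns `variant_id`,
#'   `effect_size`, `residual_sd`, optional `trait` (name).
#' @return Tibble with `sample_id` and one column per trait.
#' @export
simulate_traits <- function(cohort, trait_specs = cohort$trait_specs, seed = NULL) {
  check_that(!is.null(trait_specs) && nrow(trait_specs) > 0,
             "no `trait_specs` supplied.")
  trait_specs <- as_tibble(trait_specs)
  vids <- trait_specs$variant_id
  idx <- match(vids, cohort$dataset$variants$variant_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown variant id(s) in trait_specs: %s",
                  paste(vids[is.na(idx)], collapse = ", ")))
  }
  with_optional_seed(seed, {
    n <- nrow(cohort$dataset$samples)
    out <- tibble(sample_id = cohort$dataset$samples$sample_id)
    nm <- trait_specs[["trait"]] %||% paste0("trait_", vids)
    for (i in seq_along(idx)) {
      g <- cohort$true_calls[, idx[i]]
      out[[nm[i]]] <- trait_specs$effect_size[i] * g +
        rnorm(n, 0, trait_specs$residual_sd[i])
    }
    out
  })
}
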