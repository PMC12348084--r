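#' Specification of a synthetic genotyping cohort
#'
#' Collects every parameter of the synthetic-cohort generator. Defaults
#' describe the study conditions the generator emulates: a two-population
#' cohort with strong ancestry structure (Fst 0.15, roughly 90/10 split),
#' blood specimens missing ~0.2% of genotypes versus ~2% for serum, array
#' batches of six to eight samples, a per-genotype error rate of 0.2%, and
#' per-sample autozygosity fractions of 0.5-4% of the genome.
#'
#' Planting hooks exist for every structure the QC pipeline is designed to
#' detect: relative pairs (`planted_relationships`), sex swaps (`sex_swaps`),
#' mislabelled ancestry (`group_mislabels`), excess batch missingness
#' (`batch_effects`), autozygosity tracts (`autozygosity`), dispersed excess
#' homozygosity without tracts (`dispersed_homozygosity`, the low-ROH outlier
#' signature), and defective variants (`variant_defects`).
#'
#' @param n_samples Number of samples.
#' @param n_autosomal_variants,n_x_variants Variant counts; autosomes are
#'   spread evenly over chromosomes 1-22 at `variant_spacing_bp` intervals.
#' @param n_populations Number of source populations.
#' @param fst Balding-Nichols differentiation between populations, in
#'   `[0, 1)`; must be positive when `n_populations > 1`.
#' @param ancestral_maf_range Interval within `(0, 0.5]` for the uniform draw
#'   of ancestral allele frequencies.
#' @param population_proportions Sampling proportions per population (sum 1).
#'   Default: `c(0.9, 0.1)` for two populations, equal otherwise.
#' @param planted_relationships Data frame `sample_a`, `sample_b` (integer
#'   sample indices), `degree` in `"duplicate"`, `"first"`, `"second"`,
#'   `"third"`. Pairs must be disjoint.
#' @param sex_ratio Fraction of females.
#' @param specimen_missing_rates Named per-genotype missing probability by
#'   specimen type.
#' @param specimen_proportions,site_proportions Named sampling proportions.
#' @param batch_effects Named numeric: batch label -> additive missing
#'   probability (a planted batch outlier).
#' @param batch_size_range Integer range of samples per array batch; batches
#'   are filled in enrollment order.
#' @param genotype_error_rate Per-genotype probability of miscall.
#' @param autozygosity Per-sample target fraction of the autosomal genome in
#'   runs of homozygosity; a single number, a vector of length `n_samples`,
#'   or `NULL` to draw uniformly from `autozygosity_range`.
#' @param autozygosity_range Interval for the default per-sample draw.
#' @param dispersed_homozygosity Named numeric (names = sample indices as
#'   character, or a vector of length `n_samples`): fraction of autosomal
#'   variants forced homozygous at scattered positions. Raises the inbreeding
#'   coefficient without creating tracts - the planted low-ROH outlier.
#' @param sex_swaps Integer sample indices whose self-reported sex is flipped
#'   relative to the genetic truth.
#' @param group_mislabels Integer sample indices whose self-reported group is
#'   switched to another population's label.
#' @param variant_defects List with any of `n_low_maf`, `n_low_call`,
#'   `n_hwe_het_excess` (counts of planted failing autosomal variants) and
#'   `low_call_missing_rate` (extra missing probability for the low-call set,
#'   default 0.2).
#' @param trait_specs Data frame `variant_id`, `effect_size`, `residual_sd`
#'   (and optionally `trait`) describing quantitative traits with planted
#'   SNP effects.
#' @param variant_spacing_bp Inter-variant spacing in base pairs.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 600,
                        n_autosomal_variants = 10000,
                        n_x_variants = 400,
                        n_populations = 2,
                        fst = 0.15,
                        ancestral_maf_range = c(0.05, 0.45),
                        population_proportions = NULL,
                        planted_relationships = NULL,
                        sex_ratio = 0.64,
                        specimen_missing_rates = c(blood = 0.002, serum = 0.02),
                        specimen_proportions = c(blood = 0.66, serum = 0.34),
                        site_proportions = c(site_A = 0.5, site_B = 0.5),
                        batch_effects = NULL,
                        batch_size_range = c(6, 8),
                        genotype_error_rate = 0.002,
                        autozygosity = NULL,
                        autozygosity_range = c(0.005, 0.04),
                        dispersed_homozygosity = NULL,
                        sex_swaps = integer(),
                        group_mislabels = integer(),
                        variant_defects = NULL,
                        trait_specs = NULL,
                        variant_spacing_bp = 25000,
                        seed = 1L) {
  if (is.null(population_proportions)) {
    population_proportions <- if (n_populations == 2) c(0.9, 0.1) else
      rep(1 / n_populations, n_populations)
  }
  check_that(length(population_proportions) == n_populations,
             "`population_proportions` length must equal `n_populations`.")
  check_that(abs(sum(population_proportions) - 1) <= 1e-9,
             "`population_proportions` must sum to 1.")
  check_that(fst >= 0 && fst < 1, "`fst` must lie in [0, 1).")
  if (n_populations > 1 && fst <= 0) {
    abort("degenerate structure: `fst` must be > 0 when `n_populations` > 1.")
  }
  check_that(length(ancestral_maf_range) == 2 &&
               ancestral_maf_range[1] > 0 && ancestral_maf_range[2] <= 0.5 &&
               ancestral_maf_range[1] <= ancestral_maf_range[2],
             "`ancestral_maf_range` must be an interval within (0, 0.5].")
  check_prob(sex_ratio, "sex_ratio")
  check_prob(specimen_missing_rates, "specimen_missing_rates")
  check_prob(genotype_error_rate, "genotype_error_rate")
  if (!is.null(batch_effects)) check_prob(batch_effects, "batch_effects")
  check_that(length(batch_size_range) == 2 && batch_size_range[1] >= 1 &&
               batch_size_range[1] <= batch_size_range[2],
             "`batch_size_range` must be an increasing integer range >= 1.")
  if (!is.null(planted_relationships)) {
    planted_relationships <- as_tibble(planted_relationships)
    check_that(all(c("sample_a", "sample_b", "degree") %in% names(planted_relationships)),
               "`planted_relationships` needs sample_a, sample_b, degree.")
    check_that(all(planted_relationships$degree %in%
                     c("duplicate", "first", "second", "third")),
               "unknown relationship degree.")
    ids <- c(planted_relationships$sample_a, planted_relationships$sample_b)
    check_that(all(ids >= 1 & ids <= n_samples), "relationship index out of range.")
    if (anyDuplicated(ids)) {
      abort("planted relationship pairs must be disjoint (each sample in at most one pair).")
    }
  }
  defaults <- list(n_low_maf = 0L, n_low_call = 0L, n_hwe_het_excess = 0L,
                   low_call_missing_rate = 0.2)
  variant_defects <- utils::modifyList(defaults, as.list(variant_defects %||% list()))
  if (!is.null(trait_specs)) trait_specs <- as_tibble(trait_specs)
  structure(list(
    n_samples = as.integer(n_samples),
    n_autosomal_variants = as.integer(n_autosomal_variants),
    n_x_variants = as.integer(n_x_variants),
    n_populations = as.integer(n_populations),
    fst = fst,
    ancestral_maf_range = ancestral_maf_range,
    population_proportions = population_proportions,
    planted_relationships = planted_relationships,
    sex_ratio = sex_ratio,
    specimen_missing_rates = specimen_missing_rates,
    specimen_proportions = specimen_proportions,
    site_proportions = site_proportions,
    batch_effects = batch_effects,
    batch_size_range = as.integer(batch_size_range),
    genotype_error_rate = genotype_error_rate,
    autozygosity = autozygosity,
    autozygosity_range = autozygosity_range,
    dispersed_homozygosity = dispersed_homozygosity,
    sex_swaps = as.integer(sex_swaps),
    group_mislabels = as.integer(group_mislabels),
    variant_defects = variant_defects,
    trait_specs = trait_specs,
    variant_spacing_bp = as.integer(variant_spacing_bp),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d samples, %d autosomal + %d X variants, %d population(s), Fst %.3g, seed %d\n",
    x$n_samples, x$n_autosomal_variants, x$n_x_variants, x$n_populations,
    x$fst, x$seed
  ))
  invisible(x)
}

population_labels <- function(spec) {
  if (spec$n_populations == 2) c("EUR", "AFR") else
    paste0("pop", seq_len(spec$n_populations))
}
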