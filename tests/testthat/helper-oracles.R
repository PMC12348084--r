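# Independent oracles and tiny fixture builders used across the suite.
# These deliberately take a different computational route from the package
# implementations they check.

# Minimal dataset constructor around a call matrix.
tiny_dataset <- function(calls, chrom = "1", pos = NULL, sex = NULL,
                         sample_ids = NULL, variant_prefix = "v") {
  n <- nrow(calls); m <- ncol(calls)
  chrom <- rep_len(chrom, m)
  pos <- pos %||% (unlist(lapply(split(seq_len(m), chrom)[unique(chrom)],
                                 seq_along), use.names = FALSE) * 10000L)
  samples <- tibble::tibble(sample_id = sample_ids %||% sprintf("s%02d", seq_len(n)))
  if (!is.null(sex)) samples$self_reported_sex <- sex
  geno_dataset(calls, samples,
               tibble::tibble(variant_id = paste0(variant_prefix, seq_len(m)),
                              chrom = chrom, bp_position = pos,
                              allele_A1 = "A", allele_A2 = "B"))
}

# Brute-force exact HWE p-value via factorials (valid for n <= ~80).
hwe_brute <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  prob <- vapply(hs, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    factorial(n) / (factorial(hom_r) * factorial(h) * factorial(hom_c)) *
      2^h * factorial(n_rare) * factorial(2 * n - n_rare) / factorial(2 * n)
  }, numeric(1))
  p_obs <- prob[match(n_het, hs)]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# Closed-form expected discordance for a duplicate pair with independent
# per-copy uniform-misassignment error, by enumeration of the 3x3 outcome
# table at each variant's genotype distribution (HWE given freq p).
dup_discordance_expected <- function(error_rate, p_vec) {
  e <- error_rate
  m_err <- function(obs, g) if (obs == g) 1 - e else e / 2
  per_variant <- vapply(p_vec, function(p) {
    fg <- c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
    pr_comp <- 0; pr_disc <- 0
    for (g in 0:2) for (a in 0:2) for (b in 0:2) {
      w <- fg[g + 1] * m_err(a, g) * m_err(b, g)
      if (a == 1 && b == 1) next # double het excluded
      pr_comp <- pr_comp + w
      if (a != b) pr_disc <- pr_disc + w
    }
    c(pr_comp, pr_disc)
  }, numeric(2))
  sum(per_variant[2, ]) / sum(per_variant[1, ])
}

# Double-loop GRM oracle.
grm_brute <- function(calls) {
  p <- colMeans(calls, na.rm = TRUE) / 2
  use_v <- is.finite(p) & p > 0 & p < 1
  n <- nrow(calls)
  out <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (i in which(use_v)) {
      x <- calls[j, i]; y <- calls[k, i]
      if (is.na(x) || is.na(y)) next
      acc <- acc + (x - 2 * p[i]) * (y - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
      cnt <- cnt + 1
    }
    out[j, k] <- if (cnt > 0) acc / cnt else NA_real_
  }
  dimnames(out) <- list(rownames(calls), rownames(calls))
  out
}

# Bit-level BED decoder, one genotype at a time (independent of the
# table-lookup codec in the package).
bed_decode_oracle <- function(bed_path, n_samples, n_variants) {
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  stopifnot(raw[1] == as.raw(0x6C), raw[2] == as.raw(0x1B), raw[3] == as.raw(0x01))
  payload <- as.integer(raw[-(1:3)])
  bpv <- ceiling(n_samples / 4)
  out <- matrix(NA_integer_, n_samples, n_variants)
  map <- c(2L, NA_integer_, 1L, 0L)
  for (v in seq_len(n_variants)) {
    for (s in seq_len(n_samples)) {
      byte <- payload[(v - 1) * bpv + ((s - 1) %/% 4) + 1]
      pair <- (byte %/% 4^((s - 1) %% 4)) %% 4
      out[s, v] <- map[pair + 1]
    }
  }
  out
}

# Direct rule check of one reported ROH segment: every rule the detector
# promises must hold on the segment's SNPs.
verify_roh_segment <- function(dataset, seg, min_snps = 100, min_kb = 1000,
                               max_density = 50, max_gap_kb = 1000) {
  v <- dataset$variants
  idx <- which(v$chrom == seg$chrom & v$bp_position >= seg$start_bp &
                 v$bp_position <= seg$end_bp)
  pos <- v$bp_position[idx]
  len_kb <- (seg$end_bp - seg$start_bp + 1) / 1000
  ok_counts <- length(idx) == seg$n_snps &&
    seg$n_snps >= min_snps && len_kb >= min_kb &&
    len_kb / seg$n_snps <= max_density
  ok_gap <- all(diff(pos) <= max_gap_kb * 1000)
  ok_counts && ok_gap
}
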