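# Internal helpers shared across modules.

# Normalise chromosome labels: "23" -> "X", everything else as character.
norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[chrom == "23"] <- "X"
  chrom
}

is_autosome <- function(chrom) norm_chrom(chrom) %in% as.character(1:22)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stopifnot with a readable message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(TRUE)
}

# Draw a fresh RNG substream when a seed is supplied, otherwise continue the
# current stream (so a cohort built under one seed is fully reproducible).
with_optional_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
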