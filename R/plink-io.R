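# PLINK 1 binary codec.
#
# BED layout (variant-major): 3 magic bytes 0x6C 0x1B 0x01, then for each
# variant ceil(n/4) bytes; each byte packs four samples, least-significant
# bit-pair first. Bit pairs: 00 = homozygous A1 (2 copies), 01 = missing,
# 10 = heterozygous, 11 = homozygous A2 (0 copies). Padding bits in the last
# byte of each variant are ignored on read and written as zero.

# byte -> 4 codes lookup, built once at load time
.plink_decode <- local({
  map <- c(2L, NA_integer_, 1L, 0L) # bit-pair values 0,1,2,3
  m <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    for (j in 0:3) m[b + 1L, j + 1L] <- map[bitwAnd(bitwShiftR(b, 2L * j), 3L) + 1L]
  }
  m
})

# genotype code -> bit-pair value (padding/NA -> 01)
.plink_encode_pair <- function(codes) {
  out <- rep(1L, length(codes)) # missing
  out[!is.na(codes) & codes == 2L] <- 0L
  out[!is.na(codes) & codes == 1L] <- 2L
  out[!is.na(codes) & codes == 0L] <- 3L
  out
}

#' Read a PLINK 1 binary fileset
#'
#' Decodes a variant-major `.bed` with its `.bim`/`.fam` companions into a
#' [geno_dataset()]. Only the variant-major dialect (mode byte `0x01`) is
#' supported; sample-major files raise an error. Sample and variant order are
#' taken from the FAM/BIM files; chromosome `23` is normalised to `"X"`.
#'
#' @param bed_path,bim_path,fam_path File paths. When `bim_path`/`fam_path`
#'   are omitted they are derived from `bed_path` by extension substitution.
#' @return A [geno_dataset()]. FAM sex codes 1/2/0 become
#'   `"male"`/`"female"`/`"unknown"` in `samples$self_reported_sex`.
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  bim_path <- bim_path %||% sub("\\.bed$", ".bim", bed_path)
  fam_path <- fam_path %||% sub("\\.bed$", ".fam", bed_path)
  fam <- read.table(fam_path, header = FALSE, colClasses = "character")
  check_that(ncol(fam) >= 6, sprintf("FAM file '%s' needs 6 columns.", fam_path))
  bim <- read.table(bim_path, header = FALSE, colClasses = "character")
  check_that(ncol(bim) >= 6, sprintf("BIM file '%s' needs 6 columns.", bim_path))
  n <- nrow(fam)
  m <- nrow(bim)
  bpv <- ceiling(n / 4)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  check_that(length(raw) >= 3 && raw[1] == as.raw(0x6C) && raw[2] == as.raw(0x1B),
             sprintf("'%s' is not a PLINK 1 BED file (bad magic bytes).", bed_path))
  if (raw[3] == as.raw(0x00)) {
    abort(sprintf("'%s' is sample-major (mode byte 0x00); only variant-major BED is supported.",
                  bed_path))
  }
  check_that(raw[3] == as.raw(0x01), sprintf("'%s': unknown BED mode byte.", bed_path))
  payload <- raw[-(1:3)]
  check_that(length(payload) == bpv * m,
             sprintf("'%s' is truncated: expected %d payload bytes, found %d.",
                     bed_path, bpv * m, length(payload)))

  dec <- .plink_decode[as.integer(payload) + 1L, , drop = FALSE] # (bpv*m) x 4
  slots <- array(t(dec), dim = c(4L * bpv, m))
  calls <- slots[seq_len(n), , drop = FALSE]

  sex <- c("unknown", "male", "female")[match(fam[[5]], c("0", "1", "2"))]
  sex[is.na(sex)] <- "unknown"
  samples <- tibble(sample_id = fam[[2]], family_id = fam[[1]],
                    self_reported_sex = sex)
  variants <- tibble(variant_id = bim[[2]], chrom = norm_chrom(bim[[1]]),
                     bp_position = as.integer(bim[[4]]),
                     allele_A1 = bim[[5]], allele_A2 = bim[[6]])
  geno_dataset(calls, samples, variants)
}

#' Write a PLINK 1 binary fileset
#'
#' Emits variant-major BED plus BIM/FAM readable by [read_plink()] and the
#' wider PLINK ecosystem. Chromosome X is written as `23`; sex is written
#' 1 = male, 2 = female, 0 = unknown; phenotype is `-9`.
#'
#' @param dataset A [geno_dataset()].
#' @param prefix Output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return Invisibly, the three paths written.
#' @export
write_plink <- function(dataset, prefix) {
  n <- nrow(dataset$samples)
  m <- nrow(dataset$variants)
  bpv <- ceiling(n / 4)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))

  slots <- matrix(1L, nrow = 4L * bpv, ncol = m) # padding bit-pairs
  slots[seq_len(n), ] <- apply(dataset$calls, 2, .plink_encode_pair)
  slots[seq(n + 1, length.out = 4L * bpv - n), ] <- 0L # zero padding bits
  dim(slots) <- c(4L, bpv * m)
  bytes <- as.raw(slots[1, ] + 4L * slots[2, ] + 16L * slots[3, ] + 64L * slots[4, ])
  con <- file(paths[1], "wb")
  on.exit(close(con), add = TRUE)
  tryCatch({
    writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
    writeBin(bytes, con)
  }, error = function(e) {
    abort(sprintf("failed writing BED to '%s': %s", paths[1], conditionMessage(e)))
  })

  chrom_out <- dataset$variants$chrom
  chrom_out[chrom_out == "X"] <- "23"
  bim <- data.frame(chrom_out, dataset$variants$variant_id, 0L,
                    dataset$variants$bp_position,
                    dataset$variants$allele_A1, dataset$variants$allele_A2)
  write.table(bim, paths[2], quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  sex_col <- dataset$samples[["self_reported_sex"]] %||% rep("unknown", n)
  sex_num <- match(sex_col, c("male", "female")) # 1, 2, NA
  sex_num[is.na(sex_num)] <- 0L
  fam <- data.frame(dataset$samples[["family_id"]] %||% dataset$samples$sample_id,
                    dataset$samples$sample_id, 0L, 0L, sex_num, -9L)
  write.table(fam, paths[3], quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(setNames(paths, c("bed", "bim", "fam")))
}

#' Read imputed dosages and per-variant quality from a VCF
#'
#' Parses a VCF 4.x with per-genotype `DS` (expected allele dosage in
#' `[0, 2]`) and a per-variant INFO key carrying imputation R-squared
#' (default `R2`). Multiallelic records are skipped with a count; records
#' missing the R2 key are kept with `r2 = NA` (and excluded from quality
#' stratification downstream).
#'
#' @param vcf_path Path to a VCF (optionally bgzipped).
#' @param r2_key INFO key holding imputation R2.
#' @return List with `info` (tibble: `variant_id`, `chrom`, `bp_position`,
#'   `alt_allele_frequency`, `r2`, `dosage_available`), `dosages` (numeric
#'   matrix samples x variants of ALT dosages) and `n_multiallelic_skipped`.
#' @export
read_imputed <- function(vcf_path, r2_key = "R2") {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_skip <- sum(multi)
  if (n_skip > 0) {
    message(sprintf("read_imputed: skipped %d multiallelic record(s).", n_skip))
  }
  keep <- which(!multi)
  fmt <- colnames(v@gt)[1]
  has_ds <- grepl("(^|:)DS(:|$)", v@gt[, 1])
  if (any(!has_ds[keep])) {
    bad <- keep[which(!has_ds[keep])[1]]
    abort(sprintf("record %s:%s (%s) has no DS field.",
                  fix$CHROM[bad], fix$POS[bad], fix$ID[bad]))
  }
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  ds <- ds[keep, , drop = FALSE]
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = r2_key)))[keep]
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "AF")))[keep]
  no_af <- is.na(af)
  if (any(no_af)) af[no_af] <- rowMeans(ds[no_af, , drop = FALSE], na.rm = TRUE) / 2
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[keep], ":", fix$POS[keep])[is.na(ids) | ids == "."]
  info <- tibble(
    variant_id = ids,
    chrom = norm_chrom(fix$CHROM[keep]),
    bp_position = as.integer(fix$POS[keep]),
    alt_allele_frequency = af,
    r2 = r2,
    dosage_available = TRUE
  )
  dosages <- t(ds)
  colnames(dosages) <- ids
  list(info = info, dosages = dosages, n_multiallelic_skipped = n_skip)
}

#' Attach sample metadata to a dataset
#'
#' Left-joins a metadata table (or TSV path with header columns `sample_id`,
#' `sex`, `group`, `specimen`, `site`, `batch`) onto the dataset's sample
#' table. Samples without metadata are flagged (`metadata_missing`); metadata
#' rows for unknown samples produce a warning and are ignored; duplicate
#' metadata keys are an error.
#'
#' @param dataset A [geno_dataset()].
#' @param metadata Data frame or TSV path.
#' @return The dataset with enriched `samples`.
#' @export
attach_metadata <- function(dataset, metadata) {
  if (is.character(metadata)) {
    metadata <- read.table(metadata, header = TRUE, sep = "\t",
                           colClasses = "character")
  }
  metadata <- as_tibble(metadata)
  check_that("sample_id" %in% names(metadata), "`metadata` needs a `sample_id` column.")
  check_that(!anyDuplicated(metadata$sample_id), "duplicate `sample_id` keys in metadata.")
  unknown <- setdiff(metadata$sample_id, dataset$samples$sample_id)
  if (length(unknown) > 0) {
    warn(sprintf("metadata for %d unknown sample(s) ignored (e.g. %s).",
                 length(unknown), unknown[1]))
  }
  ren <- c(self_reported_sex = "sex", self_reported_group = "group",
           specimen = "specimen", site = "site", batch_id = "batch")
  for (i in seq_along(ren)) {
    if (ren[i] %in% names(metadata)) {
      names(metadata)[names(metadata) == ren[i]] <- names(ren)[i]
    }
  }
  keep_cols <- intersect(c("sample_id", names(ren)), names(metadata))
  replaced <- setdiff(keep_cols, "sample_id")
  base <- dataset$samples[, setdiff(names(dataset$samples), replaced), drop = FALSE]
  joined <- left_join(base, metadata[, keep_cols, drop = FALSE], by = "sample_id")
  joined$metadata_missing <- !(joined$sample_id %in% metadata$sample_id)
  dataset$samples <- joined
  dataset
}
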