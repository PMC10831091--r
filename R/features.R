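## Per-call predictor extraction. Each called allele is represented by an
## ordered 41-entry numeric vector: 22 raw MuTect2 annotations, 4 derived
## quantities (SOB score, ref-vs-alt orientation cosine, allele lengths),
## a 3-way variant-class one-hot, and a 12-way substitution-type one-hot.
## The layout is versioned so retrained model bundles can detect schema
## drift.

## The 12 ordered single-nucleotide substitutions (strand-specific; C>T
## and G>A are distinct classes, which is what makes the deamination
## signature visible).
SUBSTITUTION_TYPES <- c(
  "A>C", "A>G", "A>T",
  "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T",
  "T>A", "T>C", "T>G"
)

FEATURE_SCHEMA_VERSION <- "ffpesieve-41/1"

#' The default 41-entry feature schema
#'
#' Ordered layout of the classifier input: raw MuTect2 outputs
#' (`DP`, `AD_ref`, `AD_alt`, `AF`, `F1R2_*`, `F2R1_*`, `MBQ_*`, `MFRL_*`,
#' `MMQ_*`, `MPOS`, `TLOD`, `ECNT`, `POPAF`, `GERMQ`, `SEQQ`, `STRANDQ`,
#' `ROQ`), derived scores (`SOB`, `orientation_cosine`, `ref_len`,
#' `alt_len`), a 3-way variant-class one-hot (`class_SNV`, `class_INS`,
#' `class_DEL`), and 12 substitution-type indicators.
#'
#' @return A list of class `feature_schema` with `names` (length 41),
#'   `numeric` (logical mask of entries subject to scaling/imputation;
#'   one-hot indicators are passed through), and `version`.
#' @export
default_feature_schema <- function() {
  names <- c(
    "DP", "AD_ref", "AD_alt", "AF",
    "F1R2_ref", "F1R2_alt", "F2R1_ref", "F2R1_alt",
    "MBQ_ref", "MBQ_alt", "MFRL_ref", "MFRL_alt",
    "MMQ_ref", "MMQ_alt", "MPOS", "TLOD", "ECNT",
    "POPAF", "GERMQ", "SEQQ", "STRANDQ", "ROQ",
    "SOB", "orientation_cosine", "ref_len", "alt_len",
    "class_SNV", "class_INS", "class_DEL",
    paste0("sub_", SUBSTITUTION_TYPES)
  )
  structure(
    list(
      names = names,
      numeric = !grepl("^(class_|sub_)", names),
      version = FEATURE_SCHEMA_VERSION
    ),
    class = "feature_schema"
  )
}

## Internal: stable one-line fingerprint binding a model to its schema.
schema_fingerprint <- function(schema) {
  paste(schema$version, paste(schema$names, collapse = "|"), sep = "::")
}

#' Mutation allele frequency
#'
#' `MAF = ad_alt / (ad_ref + ad_alt)` -- the fraction of informative reads
#' supporting the alternate allele. FFPE artifacts concentrate at low MAF.
#'
#' @param ad_ref,ad_alt non-negative allele depths (vectorised).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
compute_maf <- function(ad_ref, ad_alt) {
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE)) {
    stop("allele depths must be non-negative")
  }
  total <- ad_ref + ad_alt
  if (any(!is.na(total) & total == 0)) {
    stop("ad_ref + ad_alt must be positive for a called variant")
  }
  ad_alt / total
}

#' Strand orientation bias (SOB) score
#'
#' `SOB = |F1R2_alt - F2R1_alt| / (F1R2_alt + F2R1_alt)`: 0 means the
#' alternate allele is supported equally by both read-pair orientations,
#' 1 means support comes from a single orientation. Orientation-specific
#' damage (formalin-induced deamination) drives artifact calls towards 1.
#'
#' @param f1r2_alt,f2r1_alt non-negative orientation counts for the
#'   alternate allele (vectorised).
#' @return Numeric vector in `[0, 1]`; `NA` where both counts are zero
#'   (the score is undefined without orientation-resolved support).
#' @export
compute_sob <- function(f1r2_alt, f2r1_alt) {
  if (any(f1r2_alt < 0, na.rm = TRUE) || any(f2r1_alt < 0, na.rm = TRUE)) {
    stop("orientation counts must be non-negative")
  }
  total <- f1r2_alt + f2r1_alt
  out <- abs(f1r2_alt - f2r1_alt) / total
  out[!is.na(total) & total == 0] <- NA_real_
  out
}

#' Cosine similarity of ref and alt orientation profiles
#'
#' Treats the (F1R2, F2R1) counts of the reference and alternate alleles
#' as 2-vectors and returns their cosine. Reference reads are essentially
#' never orientation-biased, so a true variant's alt profile is parallel
#' to the ref profile (cosine near 1) while an orientation-damaged
#' artifact's is not.
#'
#' @param f1r2_ref,f2r1_ref,f1r2_alt,f2r1_alt non-negative orientation
#'   counts (vectorised).
#' @return Numeric vector in `[0, 1]`; `NA` where either allele's profile
#'   is the zero vector.
#' @export
compute_orientation_cosine <- function(f1r2_ref, f2r1_ref,
                                       f1r2_alt, f2r1_alt) {
  counts <- cbind(f1r2_ref, f2r1_ref, f1r2_alt, f2r1_alt)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("orientation counts must be non-negative")
  }
  dot <- f1r2_ref * f1r2_alt + f2r1_ref * f2r1_alt
  norm_ref <- sqrt(f1r2_ref^2 + f2r1_ref^2)
  norm_alt <- sqrt(f1r2_alt^2 + f2r1_alt^2)
  out <- dot / (norm_ref * norm_alt)
  zero <- !is.na(norm_ref) & !is.na(norm_alt) & (norm_ref == 0 | norm_alt == 0)
  out[zero] <- NA_real_
  out
}

#' Classify a ref/alt allele pair
#'
#' Single-base pairs map to one of the 12 ordered substitutions
#' (`"A>C"` ... `"T>G"`); a longer alt sharing the ref as prefix is
#' `"INS"`; a shorter alt is `"DEL"`; anything else (multi-nucleotide
#' substitutions, non-prefix insertions) is `"COMPLEX"`.
#'
#' @param ref,alt allele strings over A/C/G/T (vectorised).
#' @return Character vector of substitution labels.
#' @export
classify_substitution <- function(ref, alt) {
  ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  if (!all(ok)) stop("alleles must be non-empty uppercase A/C/G/T strings")
  nr <- nchar(ref)
  na_ <- nchar(alt)
  out <- rep("COMPLEX", length(ref))
  snv <- nr == 1L & na_ == 1L & ref != alt
  out[snv] <- paste0(ref[snv], ">", alt[snv])
  ins <- na_ > nr & substr(alt, 1L, nr) == ref
  out[ins] <- "INS"
  out[na_ < nr] <- "DEL"
  out
}

#' Build the feature matrix for a call table
#'
#' Computes the 41 predictors for every call. Missing annotations
#' (including SOB/cosine scores undefined for zero-support orientation
#' vectors) are kept as `NA` with a parallel missingness mask; imputation
#' happens when a fitted scaler is applied, using training-set medians,
#' so no statistic leaks from evaluation data.
#'
#' @param calls variant-call table.
#' @param schema feature schema; must have 41 entries for the default
#'   network architecture.
#' @return A list of class `feature_matrix`: `values` (numeric matrix,
#'   one row per call), `missing` (logical matrix), `schema`.
#' @export
build_feature_matrix <- function(calls, schema = default_feature_schema()) {
  validate_calls(calls)
  if (length(schema$names) != 41L) {
    stop("feature schema must have exactly 41 entries (got ",
         length(schema$names), ")")
  }
  n <- nrow(calls)
  sub <- classify_substitution(calls$ref, calls$alt)
  nr <- nchar(calls$ref)
  na_ <- nchar(calls$alt)
  ## variant class from allele lengths; equal-length multi-base
  ## substitutions count as the SNV class with no substitution-type flag
  class_ins <- as.numeric(na_ > nr)
  class_del <- as.numeric(na_ < nr)
  class_snv <- as.numeric(na_ == nr)

  values <- matrix(NA_real_, nrow = n, ncol = 41L,
                   dimnames = list(NULL, schema$names))
  values[, "DP"] <- calls$depth
  values[, "AD_ref"] <- calls$ad_ref
  values[, "AD_alt"] <- calls$ad_alt
  values[, "AF"] <- if (n > 0) compute_maf(calls$ad_ref, calls$ad_alt)
                    else numeric(0)
  values[, "F1R2_ref"] <- calls$f1r2_ref
  values[, "F1R2_alt"] <- calls$f1r2_alt
  values[, "F2R1_ref"] <- calls$f2r1_ref
  values[, "F2R1_alt"] <- calls$f2r1_alt
  values[, "MBQ_ref"] <- calls$mbq_ref
  values[, "MBQ_alt"] <- calls$mbq_alt
  values[, "MFRL_ref"] <- calls$mfrl_ref
  values[, "MFRL_alt"] <- calls$mfrl_alt
  values[, "MMQ_ref"] <- calls$mmq_ref
  values[, "MMQ_alt"] <- calls$mmq_alt
  values[, "MPOS"] <- calls$mpos
  values[, "TLOD"] <- calls$tlod
  values[, "ECNT"] <- calls$ecnt
  values[, "POPAF"] <- calls$popaf
  values[, "GERMQ"] <- calls$germq
  values[, "SEQQ"] <- calls$seqq
  values[, "STRANDQ"] <- calls$strandq
  values[, "ROQ"] <- calls$roq
  values[, "SOB"] <- compute_sob(calls$f1r2_alt, calls$f2r1_alt)
  values[, "orientation_cosine"] <- compute_orientation_cosine(
    calls$f1r2_ref, calls$f2r1_ref, calls$f1r2_alt, calls$f2r1_alt)
  values[, "ref_len"] <- nr
  values[, "alt_len"] <- na_
  values[, "class_SNV"] <- class_snv
  values[, "class_INS"] <- class_ins
  values[, "class_DEL"] <- class_del
  for (st in SUBSTITUTION_TYPES) {
    values[, paste0("sub_", st)] <- as.numeric(sub == st)
  }
  structure(
    list(values = values, missing = is.na(values), schema = schema),
    class = "feature_matrix"
  )
}

#' Fit a feature scaler on training data
#'
#' Stores, per numeric feature, the training-set median (used to impute
#' missing entries) and the post-imputation mean and standard deviation
#' (used to z-score). One-hot indicator features pass through untouched;
#' constant features map to 0.
#'
#' @param features `feature_matrix` built from training calls only.
#' @return A list of class `feature_scaler`.
#' @export
fit_scaler <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$values
  if (nrow(x) == 0) stop("cannot fit a scaler on an empty training set")
  num <- features$schema$numeric
  med <- apply(x[, num, drop = FALSE], 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0  # feature missing in every training call
  imputed <- x[, num, drop = FALSE]
  for (j in seq_along(med)) {
    imputed[is.na(imputed[, j]), j] <- med[j]
  }
  mu <- colMeans(imputed)
  sd_ <- apply(imputed, 2, stats::sd)
  sd_[is.na(sd_) | sd_ == 0] <- Inf  # constant feature -> scaled value 0
  structure(
    list(median = med, mean = mu, sd = sd_,
         numeric = num, schema_fingerprint = schema_fingerprint(features$schema)),
    class = "feature_scaler"
  )
}

#' Apply a fitted scaler
#'
#' Imputes missing numeric entries with stored training medians and
#' z-scores them with stored training moments; one-hot entries are passed
#' through. The result is always finite.
#'
#' @param scaler a `feature_scaler` from [fit_scaler()].
#' @param features `feature_matrix` (or bare numeric matrix in schema
#'   order) to transform.
#' @return Numeric matrix of scaled feature values.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- if (inherits(features, "feature_matrix")) {
    if (schema_fingerprint(features$schema) != scaler$schema_fingerprint) {
      stop("feature schema does not match the schema the scaler was fitted on")
    }
    features$values
  } else {
    as.matrix(features)
  }
  if (ncol(x) != length(scaler$numeric)) {
    stop("feature matrix width does not match the scaler")
  }
  num_idx <- which(scaler$numeric)
  for (k in seq_along(num_idx)) {
    j <- num_idx[k]
    col <- x[, j]
    col[is.na(col)] <- scaler$median[k]
    x[, j] <- (col - scaler$mean[k]) / scaler$sd[k]
  }
  x[is.na(x)] <- 0  # one-hot entries are never NA in practice; be safe
  x
}

#' Export a feature table
#'
#' Writes a tab-separated table with sample and variant-key columns, the
#' 41 raw (unscaled) feature values under their schema names, and a
#' `label` column when available.
#'
#' @param calls call table the features were built from (may carry
#'   `sample_id` and `label` columns).
#' @param features matching `feature_matrix`.
#' @param path output path (written atomically).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(calls, features, path) {
  stopifnot(inherits(features, "feature_matrix"),
            nrow(calls) == nrow(features$values))
  df <- data.frame(
    sample_id = if ("sample_id" %in% names(calls)) calls$sample_id else "sample",
    chrom = calls$chrom, pos = calls$pos, ref = calls$ref, alt = calls$alt,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(features$values, check.names = FALSE))
  if ("label" %in% names(calls)) df$label <- calls$label
  write_tsv_atomic(df, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path tab-separated feature table.
#' @param schema expected feature schema (validated against the header).
#' @return A list with `calls_meta` (sample/key columns), `features`
#'   (`feature_matrix`), and `labels` (character or `NULL`).
#' @export
read_feature_table <- function(path, schema = default_feature_schema()) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(schema$names, names(df))
  if (length(missing_cols) > 0) {
    stop("feature table is missing schema columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  values <- as.matrix(df[, schema$names, drop = FALSE])
  storage.mode(values) <- "double"
  list(
    calls_meta = df[, intersect(c("sample_id", "chrom", "pos", "ref", "alt"),
                                names(df)), drop = FALSE],
    features = structure(
      list(values = values, missing = is.na(values), schema = schema),
      class = "feature_matrix"
    ),
    labels = if ("label" %in% names(df)) df$label else NULL
  )
}

## Internal: atomic TSV write with stable number formatting.
write_tsv_atomic <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wb")
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  close(con)
  on.exit(NULL)
  if (!file.rename(tmp, path)) stop("cannot move output into place: ", path)
  invisible(path)
}
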