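## Truth labeling from matched FF/FFPE call sets, and the train/validation
## partition. The labeling rule is the benchmark's definition of truth: a
## call made in the FFPE sample is a true variant iff the same
## (chrom, pos, ref, alt) allele was also called in the matched
## fresh-frozen sample; FFPE-private calls are fixation artifacts. Calls
## private to the FF sample carry no FFPE evidence and are ignored.

#' Label FFPE calls against the matched fresh-frozen call set
#'
#' @param ffpe_calls variant-call table from the FFPE sample
#'   (PASS-filtered).
#' @param ff_calls variant-call table from the matched FF sample
#'   (PASS-filtered).
#' @param sample_id sample identifier attached to every labeled call.
#' @param cancer_type optional cancer-type annotation.
#' @return The FFPE call table with `label` (`"TRUE_VARIANT"` /
#'   `"FFPE_ARTIFACT"`), `sample_id`, and `cancer_type` columns appended.
#'   Every FFPE call receives exactly one label; the two label groups
#'   partition the FFPE call set.
#' @export
label_ffpe_calls <- function(ffpe_calls, ff_calls,
                             sample_id = "sample", cancer_type = NA_character_) {
  validate_calls(ffpe_calls)
  validate_calls(ff_calls)
  ffpe_keys <- check_unique_keys(ffpe_calls, "FFPE call set")
  ff_keys <- check_unique_keys(ff_calls, "FF call set")
  if (nrow(ffpe_calls) > 0 && nrow(ff_calls) > 0) {
    ffpe_chr <- grepl("^chr", ffpe_calls$chrom[1])
    ff_chr <- grepl("^chr", ff_calls$chrom[1])
    if (ffpe_chr != ff_chr) {
      warning("FF and FFPE call sets disagree on chromosome naming ",
              "('chr' prefix); keys are matched verbatim")
    }
  }
  out <- ffpe_calls
  out$label <- ifelse(ffpe_keys %in% ff_keys, LABEL_TRUE, LABEL_ARTIFACT)
  out$sample_id <- rep(sample_id, nrow(out))
  out$cancer_type <- rep(cancer_type, nrow(out))
  out
}

#' Split labeled calls into training and validation sets
#'
#' Partitions each source file's calls independently at the given ratio
#' (default 7:3), mirroring a per-VCF random split. The training size per
#' file is `round-half-up(train_fraction * n)`; the split is deterministic
#' given the seed, with files processed in sorted `sample_id` order.
#'
#' @param labeled labeled call table (output of [label_ffpe_calls()],
#'   possibly row-bound over samples).
#' @param train_fraction fraction of each file assigned to training, in
#'   `(0, 1]`; default 0.7.
#' @param seed integer seed; default 42.
#' @return A list with elements `train` and `validation`; their union is
#'   the input and they are disjoint.
#' @export
split_train_validation <- function(labeled, train_fraction = 0.7, seed = 42L) {
  if (!is.data.frame(labeled) || nrow(labeled) == 0) {
    stop("labeled must be a nonempty data.frame")
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction > 1) {
    stop("train_fraction must lie in (0, 1]")
  }
  sid <- if ("sample_id" %in% names(labeled)) labeled$sample_id
         else rep("sample", nrow(labeled))
  train_idx <- integer(0)
  with_seed(seed, {
    for (s in sort(unique(sid))) {
      idx <- which(sid == s)
      n_train <- floor(length(idx) * train_fraction + 0.5)  # round half up
      n_train <- min(n_train, length(idx))
      if (n_train > 0) {
        train_idx <- c(train_idx, sort(sample(idx, n_train)))
      }
    }
  })
  list(
    train = labeled[sort(train_idx), , drop = FALSE],
    validation = labeled[setdiff(seq_len(nrow(labeled)), train_idx), ,
                         drop = FALSE]
  )
}

#' Drop validation calls whose variant key was seen in training
#'
#' When technical replicates of one tumour are used as independent
#' samples, the same variant can land in one replicate's training split
#' and another's validation split; evaluating it would leak training
#' information. This removes, across all samples, any validation call
#' whose (chrom, pos, ref, alt) key occurs anywhere in the training set.
#'
#' @param validation labeled call table to be evaluated.
#' @param train labeled call table used for training.
#' @return The filtered validation table.
#' @export
exclude_training_overlap <- function(validation, train) {
  if (nrow(validation) == 0) return(validation)
  keep <- !(variant_key(validation) %in% variant_key(train))
  validation[keep, , drop = FALSE]
}

#' Read a manifest of matched FF/FFPE VCF pairs
#'
#' @param path tab-separated file with header columns `sample_id`,
#'   `cancer_type`, `ff_path`, `ffpe_path`, one row per sample. Relative
#'   VCF paths are resolved against the manifest's directory.
#' @return A data.frame with those four character columns.
#' @export
read_pair_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  m <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "cancer_type", "ff_path", "ffpe_path")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$ff_path <- resolve(m$ff_path)
  m$ffpe_path <- resolve(m$ffpe_path)
  m[need]
}

#' Label every sample in a manifest
#'
#' Reads each FF/FFPE VCF pair (PASS calls only), labels the FFPE calls
#' against the FF calls, and row-binds the result.
#'
#' @param manifest data.frame as returned by [read_pair_manifest()].
#' @return A labeled call table covering all samples.
#' @export
label_manifest <- function(manifest) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    ff <- read_mutect_vcf(manifest$ff_path[i], pass_only = TRUE)
    ffpe <- read_mutect_vcf(manifest$ffpe_path[i], pass_only = TRUE)
    label_ffpe_calls(ffpe, ff,
                     sample_id = manifest$sample_id[i],
                     cancer_type = manifest$cancer_type[i])
  })
  do.call(rbind, out)
}

## Internal: evaluate `code` under a fixed RNG seed, restoring the
## caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}
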