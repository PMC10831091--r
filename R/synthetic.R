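## Synthetic matched FF/FFPE call-set generator. Emulates, at the
## call-annotation level the classifier consumes (no read-level
## simulation), the documented statistical signatures of FFPE damage:
## artifact calls have low mutation allele frequency, strongly
## orientation-biased alternate-read support, a substitution spectrum
## dominated by C>T / G>A deamination, and come from samples with shorter
## insert fragments; true variants appear in both the FF and FFPE call
## sets with independently re-sampled read support.

#' Synthetic dataset configuration
#'
#' Defaults encode the separation the generator is meant to emulate:
#' artifact MAF drawn from a Beta with median near 0.10 versus near 0.25
#' for true variants; artifact alternate reads F1R2 with probability 0.9
#' versus unbiased 0.5; at least 70% of artifact substitutions C>T or
#' G>A versus a uniform spectrum for true variants; FF fragments around
#' 221 bp versus 147 bp for FFPE.
#'
#' @param n_true_variants,n_artifacts number of calls per class.
#' @param true_maf_shape,artifact_maf_shape `c(alpha, beta)` of the Beta
#'   MAF distributions (defaults: medians ~0.25 and ~0.10).
#' @param artifact_orientation_bias probability in `[0.5, 1]` that an
#'   artifact-supporting read is F1R2.
#' @param true_orientation_bias orientation probability for true-variant
#'   and reference reads (0.5 = unbiased).
#' @param artifact_substitution_weights,true_substitution_weights named
#'   probability vectors over the 12 substitution types.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (depths are floored at 10).
#' @param ff_fragment_mean,ffpe_fragment_mean,fragment_sd median-fragment
#'   -length models (bp) for the two preparations.
#' @param n_chroms,chrom_length abstract genome model: positions are
#'   drawn uniformly over `n_chroms` chromosomes of this length, without
#'   key collisions.
#' @param sample_id,cancer_type identifiers stamped on the output.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_true_variants = 2000L,
                             n_artifacts = 2000L,
                             true_maf_shape = c(2.6, 7),
                             artifact_maf_shape = c(1.8, 13),
                             artifact_orientation_bias = 0.9,
                             true_orientation_bias = 0.5,
                             artifact_substitution_weights = NULL,
                             true_substitution_weights = NULL,
                             depth_mean = 90,
                             depth_dispersion = 10,
                             ff_fragment_mean = 221,
                             ffpe_fragment_mean = 147,
                             fragment_sd = 25,
                             n_chroms = 22L,
                             chrom_length = 5e6,
                             sample_id = "synthetic_sample",
                             cancer_type = "synthetic",
                             seed = 42L) {
  if (is.null(artifact_substitution_weights)) {
    ## deamination-dominated spectrum: 75% of mass on C>T / G>A
    w <- stats::setNames(rep(0.025, 12), SUBSTITUTION_TYPES)
    w["C>T"] <- 0.40
    w["G>A"] <- 0.35
    artifact_substitution_weights <- w
  }
  if (is.null(true_substitution_weights)) {
    true_substitution_weights <- stats::setNames(rep(1 / 12, 12),
                                                 SUBSTITUTION_TYPES)
  }
  cfg <- structure(
    list(n_true_variants = as.integer(n_true_variants),
         n_artifacts = as.integer(n_artifacts),
         true_maf_shape = true_maf_shape,
         artifact_maf_shape = artifact_maf_shape,
         artifact_orientation_bias = artifact_orientation_bias,
         true_orientation_bias = true_orientation_bias,
         artifact_substitution_weights = artifact_substitution_weights,
         true_substitution_weights = true_substitution_weights,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         ff_fragment_mean = ff_fragment_mean,
         ffpe_fragment_mean = ffpe_fragment_mean,
         fragment_sd = fragment_sd,
         n_chroms = as.integer(n_chroms),
         chrom_length = chrom_length,
         sample_id = sample_id,
         cancer_type = cancer_type,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_true_variants >= 0, cfg$n_artifacts >= 0)
  probs <- c(cfg$artifact_orientation_bias, cfg$true_orientation_bias)
  if (any(probs < 0 | probs > 1)) stop("orientation biases must be in [0, 1]")
  for (w in list(cfg$artifact_substitution_weights,
                 cfg$true_substitution_weights)) {
    if (!setequal(names(w), SUBSTITUTION_TYPES) || any(w < 0) ||
        abs(sum(w) - 1) > 1e-8) {
      stop("substitution weights must be a probability vector over the 12 types")
    }
  }
  if (all(cfg$true_maf_shape > 0) && all(cfg$artifact_maf_shape > 0)) {
    invisible(cfg)
  } else stop("Beta shape parameters must be positive")
}

## Internal: truncated Binomial(n, p) conditioned on >= 1 success (a
## called variant must have alternate-read support), via inverse CDF.
rbinom_pos <- function(n_draws, size, prob) {
  p0 <- stats::pbinom(0, size, prob)
  u <- stats::runif(n_draws, p0, 1)
  pmin(stats::qbinom(u, size, prob), size)
}

## Internal: draw per-call annotation rows for one class within one
## sample preparation.
draw_calls <- function(keys, maf, bias, fragment_mean, fragment_sd, cfg) {
  n <- nrow(keys)
  if (n == 0) {
    return(variant_calls(character(0), integer(0), character(0), character(0)))
  }
  depth <- pmax(stats::rnbinom(n, size = cfg$depth_dispersion,
                               mu = cfg$depth_mean), 10L)
  ad_alt <- rbinom_pos(n, depth, maf)
  ad_ref <- depth - ad_alt
  f1r2_alt <- stats::rbinom(n, ad_alt, bias)
  f2r1_alt <- ad_alt - f1r2_alt
  f1r2_ref <- stats::rbinom(n, ad_ref, cfg$true_orientation_bias)
  f2r1_ref <- ad_ref - f1r2_ref
  mfrl <- round(stats::rnorm(n, fragment_mean, fragment_sd))
  variant_calls(
    chrom = keys$chrom, pos = keys$pos, ref = keys$ref, alt = keys$alt,
    depth = depth, ad_ref = ad_ref, ad_alt = ad_alt,
    f1r2_ref = f1r2_ref, f1r2_alt = f1r2_alt,
    f2r1_ref = f2r1_ref, f2r1_alt = f2r1_alt,
    mbq_ref = round(pmin(pmax(stats::rnorm(n, 32, 3), 20), 45)),
    mbq_alt = round(pmin(pmax(stats::rnorm(n, 31, 3), 20), 45)),
    mmq_ref = 60, mmq_alt = 60 - stats::rpois(n, 0.3),
    mfrl_ref = pmax(mfrl, 50),
    mfrl_alt = pmax(round(stats::rnorm(n, fragment_mean, fragment_sd)), 50),
    mpos = pmax(round(stats::rnorm(n, 38, 12)), 1),
    tlod = round(pmax(ad_alt * stats::rnorm(n, 3, 0.6), 2.5), 2),
    ecnt = 1 + stats::rpois(n, 0.15),
    popaf = round(stats::runif(n, 3, 6), 2),
    germq = 93, seqq = 93, strandq = 93, roq = round(stats::runif(n, 50, 93)),
    filter_status = "PASS"
  )
}

## Internal: draw n distinct (chrom, pos) slots and a substitution type
## per call; ref/alt alleles follow from the type.
draw_keys <- function(n, weights, cfg) {
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      substitution = character(0), stringsAsFactors = FALSE))
  }
  type <- sample(SUBSTITUTION_TYPES, n, replace = TRUE,
                 prob = weights[SUBSTITUTION_TYPES])
  data.frame(
    chrom = paste0("chr", sample.int(cfg$n_chroms, n, replace = TRUE)),
    pos = sample.int(cfg$chrom_length, n, replace = TRUE),
    ref = substr(type, 1, 1),
    alt = substr(type, 3, 3),
    substitution = type,
    stringsAsFactors = FALSE
  )
}

#' Generate a matched FF/FFPE call-set pair with ground truth
#'
#' Draws true variants and FFPE artifacts under the configured
#' distributions. Every call gets a depth from the negative-binomial
#' model, alternate support `Binomial(depth, MAF)` conditioned on at
#' least one read, and orientation counts split binomially at the class
#' bias. The FF call set contains exactly the true variants, re-drawn
#' with the same per-call MAF but independent sampling noise (and FF
#' fragment lengths); the FFPE set is the union of true variants and
#' artifacts. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_pair`: `ff_calls`, `ffpe_calls`,
#'   `truth` (data.frame with key columns, `label`, `drawn_maf`,
#'   `drawn_bias`, `substitution`), and `config`.
#' @export
generate_paired_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  n_slots <- config$n_chroms * config$chrom_length
  n_total <- config$n_true_variants + config$n_artifacts
  if (n_total > n_slots / 2) {
    stop("requested calls exceed half the available genome slots; ",
         "enlarge the genome model")
  }
  out <- NULL
  with_seed(config$seed, {
    repeat {
      keys_true <- draw_keys(config$n_true_variants,
                             config$true_substitution_weights, config)
      keys_art <- draw_keys(config$n_artifacts,
                            config$artifact_substitution_weights, config)
      all_pos <- paste(c(keys_true$chrom, keys_art$chrom),
                       c(keys_true$pos, keys_art$pos))
      if (!anyDuplicated(all_pos)) break  # collisions are ~never at defaults
    }
    maf_true <- stats::rbeta(config$n_true_variants,
                             config$true_maf_shape[1], config$true_maf_shape[2])
    maf_art <- stats::rbeta(config$n_artifacts,
                            config$artifact_maf_shape[1],
                            config$artifact_maf_shape[2])
    ## MAF of 0 would contradict conditioning on alt support; floor it
    maf_true <- pmax(maf_true, 1e-3)
    maf_art <- pmax(maf_art, 1e-3)

    ffpe_true <- draw_calls(keys_true, maf_true, config$true_orientation_bias,
                            config$ffpe_fragment_mean, config$fragment_sd,
                            config)
    ffpe_art <- draw_calls(keys_art, maf_art,
                           config$artifact_orientation_bias,
                           config$ffpe_fragment_mean, config$fragment_sd,
                           config)
    ff_calls <- draw_calls(keys_true, maf_true, config$true_orientation_bias,
                           config$ff_fragment_mean, config$fragment_sd,
                           config)
    ffpe_calls <- rbind(ffpe_true, ffpe_art)
    truth <- data.frame(
      sample_id = config$sample_id,
      chrom = c(keys_true$chrom, keys_art$chrom),
      pos = c(keys_true$pos, keys_art$pos),
      ref = c(keys_true$ref, keys_art$ref),
      alt = c(keys_true$alt, keys_art$alt),
      label = c(rep(LABEL_TRUE, config$n_true_variants),
                rep(LABEL_ARTIFACT, config$n_artifacts)),
      drawn_maf = c(maf_true, maf_art),
      drawn_bias = c(rep(config$true_orientation_bias,
                         config$n_true_variants),
                     rep(config$artifact_orientation_bias,
                         config$n_artifacts)),
      substitution = c(keys_true$substitution, keys_art$substitution),
      stringsAsFactors = FALSE
    )
    ## stable position order within each file
    ord_ffpe <- order(ffpe_calls$chrom, ffpe_calls$pos)
    ord_ff <- order(ff_calls$chrom, ff_calls$pos)
    out <- structure(
      list(ff_calls = ff_calls[ord_ff, , drop = FALSE],
           ffpe_calls = ffpe_calls[ord_ffpe, , drop = FALSE],
           truth = truth[order(truth$chrom, truth$pos), , drop = FALSE],
           config = config),
      class = "synthetic_pair"
    )
  })
  out$ff_calls <- `rownames<-`(out$ff_calls, NULL)
  out$ffpe_calls <- `rownames<-`(out$ffpe_calls, NULL)
  out$truth <- `rownames<-`(out$truth, NULL)
  out
}

#' Write a synthetic pair to disk
#'
#' Emits `ff.vcf` and `ffpe.vcf` (MuTect2 dialect) plus `truth.tsv`
#' (`sample_id`, key columns, `label`, `drawn_maf`, `drawn_bias`,
#' `substitution`) into a directory. Reading the two VCFs back through
#' [read_mutect_vcf()] and [label_ffpe_calls()] reproduces the truth
#' labels exactly; re-running with the same seed reproduces identical
#' bytes.
#'
#' @param pair a `synthetic_pair`.
#' @param directory output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_pair <- function(pair, directory) {
  stopifnot(inherits(pair, "synthetic_pair"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  sid <- pair$config$sample_id
  ff_path <- file.path(directory, "ff.vcf")
  ffpe_path <- file.path(directory, "ffpe.vcf")
  truth_path <- file.path(directory, "truth.tsv")
  write_lines_atomic(format_mutect_vcf(pair$ff_calls, sample_id = sid),
                     ff_path)
  write_lines_atomic(format_mutect_vcf(pair$ffpe_calls, sample_id = sid),
                     ffpe_path)
  truth <- pair$truth
  truth$drawn_maf <- sprintf("%.6f", truth$drawn_maf)
  truth$drawn_bias <- sprintf("%.3f", truth$drawn_bias)
  write_tsv_atomic(truth, truth_path)
  invisible(c(ff = ff_path, ffpe = ffpe_path, truth = truth_path))
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a synthetic pair, labels the FFPE calls against the FF
#' calls, splits 7:3, trains the classifier on the training split, and
#' evaluates on the overlap-excluded validation split. This is the
#' package's stand-in benchmark for matched-tissue data: it tests that
#' the pipeline recovers the class separation the generator encodes.
#'
#' @param config a [synthetic_config()].
#' @param clf_config a [classifier_config()].
#' @param train_fraction training fraction of the split.
#' @return A list with `metrics` (a `metric_set`), `confusion`,
#'   `probabilities`, `truth` (validation labels), `maf`, `substitution`,
#'   `model`, `n_train`, `n_validation`.
#' @export
parameter_recovery_experiment <- function(config = synthetic_config(),
                                          clf_config = classifier_config(),
                                          train_fraction = 0.7) {
  pair <- generate_paired_dataset(config)
  labeled <- label_ffpe_calls(pair$ffpe_calls, pair$ff_calls,
                              sample_id = config$sample_id,
                              cancer_type = config$cancer_type)
  split <- split_train_validation(labeled, train_fraction = train_fraction,
                                  seed = clf_config$seed)
  validation <- exclude_training_overlap(split$validation, split$train)

  schema <- default_feature_schema()
  train_fm <- build_feature_matrix(split$train, schema)
  valid_fm <- build_feature_matrix(validation, schema)
  model <- init_classifier(clf_config, schema)
  model <- train_classifier(model, train_fm, split$train$label)
  probs <- predict_proba(model, valid_fm)
  predicted <- ifelse(probs >= clf_config$threshold, LABEL_TRUE,
                      LABEL_ARTIFACT)
  cm <- build_confusion(validation$label, predicted)
  list(
    metrics = compute_metrics(cm),
    confusion = cm,
    probabilities = probs,
    truth = validation$label,
    maf = compute_maf(validation$ad_ref, validation$ad_alt),
    substitution = classify_substitution(validation$ref, validation$alt),
    model = model,
    n_train = nrow(split$train),
    n_validation = nrow(validation)
  )
}

#' Two-feature (MAF, SOB) reference rule
#'
#' A deliberately simple baseline classifier: a call is predicted to be
#' an artifact iff its MAF is below a cutoff and its SOB score above
#' another, with the two cutoffs chosen by exhaustive grid search
#' maximising F1 on the training data. Serves as an independent yardstick
#' the trained network must match on well-separated synthetic data.
#'
#' @param train_maf,train_sob,train_labels training data (`NA` SOB values
#'   are imputed with the training median).
#' @return A list of class `maf_sob_rule` with the chosen `maf_cut`,
#'   `sob_cut`, and training `f1`; apply with [predict_maf_sob()].
#' @export
fit_maf_sob_rule <- function(train_maf, train_sob, train_labels) {
  sob_med <- stats::median(train_sob, na.rm = TRUE)
  if (is.na(sob_med)) sob_med <- 0.5
  sob <- ifelse(is.na(train_sob), sob_med, train_sob)
  y <- train_labels == LABEL_TRUE
  maf_grid <- unique(stats::quantile(train_maf, probs = seq(0, 1, by = 0.02),
                                     names = FALSE))
  sob_grid <- unique(stats::quantile(sob, probs = seq(0, 1, by = 0.02),
                                     names = FALSE))
  best <- list(f1 = -1, maf_cut = maf_grid[1], sob_cut = sob_grid[1])
  for (m in maf_grid) {
    low_maf <- train_maf < m
    for (s in sob_grid) {
      pred_true <- !(low_maf & sob > s)
      tp <- sum(y & pred_true)
      fp <- sum(!y & pred_true)
      fn <- sum(y & !pred_true)
      f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      if (f1 > best$f1) best <- list(f1 = f1, maf_cut = m, sob_cut = s)
    }
  }
  structure(c(best, list(sob_impute = sob_med)), class = "maf_sob_rule")
}

#' Apply a fitted MAF/SOB rule
#'
#' @param rule a `maf_sob_rule` from [fit_maf_sob_rule()].
#' @param maf,sob per-call values.
#' @return Character label vector.
#' @export
predict_maf_sob <- function(rule, maf, sob) {
  sob <- ifelse(is.na(sob), rule$sob_impute, sob)
  artifact <- maf < rule$maf_cut & sob > rule$sob_cut
  ifelse(artifact, LABEL_ARTIFACT, LABEL_TRUE)
}
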