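## Confusion-matrix evaluation. Positive class = true variant, negative
## class = FFPE artifact, so specificity is the fraction of artifacts
## removed and sensitivity the fraction of true variants retained. The
## five metrics follow the standard definitions:
##   accuracy    = (TP + TN) / (TP + TN + FP + FN)
##   specificity = TN / (TN + FP)
##   sensitivity = TP / (TP + FN)
##   precision   = TP / (TP + FP)
##   F1          = 2 / (sensitivity^-1 + precision^-1)

#' Build a confusion matrix from truth and predicted labels
#'
#' @param truth,predicted character vectors over
#'   `c("TRUE_VARIANT", "FFPE_ARTIFACT")`, equal length.
#' @return A list of class `confusion_matrix` with integer `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
build_confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  valid <- variant_labels()
  if (!all(truth %in% valid) || !all(predicted %in% valid)) {
    stop("labels must be TRUE_VARIANT or FFPE_ARTIFACT")
  }
  t_pos <- truth == LABEL_TRUE
  p_pos <- predicted == LABEL_TRUE
  confusion_matrix(
    tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
    fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos)
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,tn,fp,fn non-negative integer counts (positive class = true
#'   variant).
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("confusion-matrix counts must be non-negative")
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' Compute the five performance metrics
#'
#' Zero-denominator conventions match benchmark-table practice: a metric
#' whose denominator is empty is reported as 0 and flagged in
#' `undefined`; F1 is 0 whenever sensitivity or precision is 0.
#'
#' @param cm a `confusion_matrix`.
#' @return A list of class `metric_set` with `accuracy`, `specificity`,
#'   `sensitivity`, `precision`, `f1`, and an `undefined` character
#'   vector naming flagged metrics.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("cannot compute metrics on an empty confusion matrix")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  accuracy <- (cm$tp + cm$tn) / total
  specificity <- ratio(cm$tn, cm$tn + cm$fp, "specificity")
  sensitivity <- ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  precision <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  f1 <- if (sensitivity > 0 && precision > 0) {
    2 / (1 / sensitivity + 1 / precision)
  } else 0
  structure(
    list(accuracy = accuracy, specificity = specificity,
         sensitivity = sensitivity, precision = precision, f1 = f1,
         undefined = undefined),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | specificity %.3f | sensitivity %.3f | precision %.3f | F1 %.3f\n",
    x$accuracy, x$specificity, x$sensitivity, x$precision, x$f1))
  if (length(x$undefined) > 0) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Round half up
#'
#' Decimal rounding with ties away from zero (`0.0005 -> 0.001` at three
#' digits), the convention used when comparing metrics against printed
#' benchmark tables; base R's `round()` rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' F1-maximising decision-threshold sweep
#'
#' Evaluates F1 (predicting true variant when `probability >= threshold`)
#' at every midpoint between consecutive distinct probabilities, plus the
#' 0 and 1 boundaries, and returns the maximiser. Ties are broken towards
#' the lowest threshold, i.e. towards retaining more true variants.
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param truth character labels, both classes present.
#' @return A list with `threshold` and `f1` (plus the evaluated
#'   `candidates` and their `f1_values`).
#' @export
sweep_threshold <- function(probabilities, truth) {
  if (length(probabilities) != length(truth)) {
    stop("probabilities and truth must have equal length")
  }
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes for an F1 sweep")
  }
  u <- sort(unique(probabilities))
  candidates <- c(0, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, 1)
  t_pos <- truth == LABEL_TRUE
  f1_at <- vapply(candidates, function(th) {
    p_pos <- probabilities >= th
    tp <- sum(t_pos & p_pos)
    fp <- sum(!t_pos & p_pos)
    fn <- sum(t_pos & !p_pos)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which(f1_at == max(f1_at))[1]  # ties -> lowest threshold
  list(threshold = candidates[best], f1 = f1_at[best],
       candidates = candidates, f1_values = f1_at)
}

#' Stratified benchmark report
#'
#' Evaluates the classifier overall and within the strata used for FFPE
#' benchmark tables: per cancer type, the deamination-driven transition
#' class `C:G>T:A` (calls whose substitution is `C>T` or `G>A`), the
#' oxidation-driven transversion class `G:C>T:A` (`G>T` or `C>A`), and
#' the low-frequency bin `0.01 < MAF < 0.05` (both bounds open) where
#' artifact/true discrimination is hardest.
#'
#' @param truth,predicted label vectors.
#' @param maf per-call mutation allele frequency.
#' @param substitution per-call [classify_substitution()] label.
#' @param cancer_type optional per-call cancer type.
#' @return A data.frame with one row per stratum: `stratum`, `tp`, `tn`,
#'   `fp`, `fn`, the five metrics, `n`, and `empty` (flag for strata with
#'   no calls, whose metric columns are `NA`).
#' @export
stratified_report <- function(truth, predicted, maf, substitution,
                              cancer_type = NULL) {
  n <- length(truth)
  stopifnot(length(predicted) == n, length(maf) == n,
            length(substitution) == n)
  strata <- list(All = rep(TRUE, n))
  if (!is.null(cancer_type)) {
    for (ct in sort(unique(cancer_type[!is.na(cancer_type)]))) {
      strata[[ct]] <- !is.na(cancer_type) & cancer_type == ct
    }
  }
  strata[["G:C>T:A"]] <- substitution %in% c("G>T", "C>A")
  strata[["C:G>T:A"]] <- substitution %in% c("C>T", "G>A")
  strata[["Low MAF variants"]] <- !is.na(maf) & maf > 0.01 & maf < 0.05
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    if (!any(sel)) {
      return(data.frame(stratum = nm, tp = 0L, tn = 0L, fp = 0L, fn = 0L,
                        specificity = NA_real_, sensitivity = NA_real_,
                        precision = NA_real_, f1 = NA_real_,
                        accuracy = NA_real_, n = 0L, empty = TRUE,
                        stringsAsFactors = FALSE))
    }
    cm <- build_confusion(truth[sel], predicted[sel])
    m <- compute_metrics(cm)
    data.frame(stratum = nm, tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
               specificity = m$specificity, sensitivity = m$sensitivity,
               precision = m$precision, f1 = m$f1, accuracy = m$accuracy,
               n = sum(sel), empty = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a stratified report as TSV
#'
#' Column order mirrors benchmark tables: counts first (TP, TN, FP, FN),
#' then specificity, sensitivity, precision, F1, accuracy.
#'
#' @param report data.frame from [stratified_report()].
#' @param path output path (written atomically).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- report[, c("stratum", "tp", "tn", "fp", "fn", "specificity",
                    "sensitivity", "precision", "f1", "accuracy")]
  num <- c("specificity", "sensitivity", "precision", "f1", "accuracy")
  out[num] <- lapply(out[num], function(v) sprintf("%.3f", v))
  write_tsv_atomic(out, path)
  invisible(path)
}
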