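test_that("confusion matrices count the four cells correctly", {
  t4 <- c("TRUE_VARIANT", "TRUE_VARIANT", "FFPE_ARTIFACT", "FFPE_ARTIFACT")
  p4 <- c("TRUE_VARIANT", "FFPE_ARTIFACT", "FFPE_ARTIFACT", "TRUE_VARIANT")
  cm <- build_confusion(t4, p4)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(1, 1, 1, 1))
  ident <- build_confusion(t4, t4)
  expect_equal(c(ident$fp, ident$fn), c(0, 0))
  all_art <- build_confusion(rep("TRUE_VARIANT", 3), rep("FFPE_ARTIFACT", 3))
  expect_equal(c(all_art$tp, all_art$fn), c(0, 3))
  expect_error(build_confusion(t4, p4[1:3]), "equal length")
  expect_error(build_confusion(c("yes"), c("no")), "label")
})

test_that("a perfect classifier scores 1 on all five metrics", {
  m <- compute_metrics(confusion_matrix(1, 1, 0, 0))
  expect_equal(unlist(m[c("accuracy", "specificity", "sensitivity",
                          "precision", "f1")]),
               c(accuracy = 1, specificity = 1, sensitivity = 1,
                 precision = 1, f1 = 1))
  expect_length(m$undefined, 0)
})

test_that("zero denominators are flagged and reported as 0", {
  m <- compute_metrics(confusion_matrix(0, 5, 0, 3))
  expect_equal(m$precision, 0)
  expect_true("precision" %in% m$undefined)
  expect_equal(m$f1, 0)  # sensitivity = 0 forces F1 = 0
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("the harmonic-mean F1 equals its count form to 1e-12", {
  set.seed(17)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(1:500, 1), sample(1:500, 1),
                           sample(0:200, 1), sample(0:200, 1))
    m <- compute_metrics(cm)
    count_form <- 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn)
    expect_equal(m$f1, count_form, tolerance = 1e-12)
  }
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(0.0005, 3), 0.001)
  expect_equal(round_half_up(0.7245, 3), 0.725)
  expect_equal(round_half_up(0.045, 2), 0.05)  # base round() gives 0.04
})

test_that("the threshold sweep finds the F1 maximiser with low-tie preference", {
  res <- sweep_threshold(c(0.9, 0.8, 0.2, 0.1),
                         c("TRUE_VARIANT", "TRUE_VARIANT",
                           "FFPE_ARTIFACT", "FFPE_ARTIFACT"))
  expect_equal(res$f1, 1.0)
  expect_equal(res$threshold, 0.5)  # the only candidate inside (0.2, 0.8)
  expect_error(sweep_threshold(c(0.1, 0.9), rep("TRUE_VARIANT", 2)),
               "both classes")
})

test_that("sweep results never fall below F1 at 0.5 and handle inversion", {
  set.seed(23)
  truth <- sample(variant_labels(), 40, replace = TRUE)
  probs <- runif(40)
  res <- sweep_threshold(probs, truth)
  pred_05 <- ifelse(probs >= 0.5, "TRUE_VARIANT", "FFPE_ARTIFACT")
  expect_gte(res$f1, compute_metrics(build_confusion(truth, pred_05))$f1)
  # perfectly inverted scores: best achievable is the all-positive F1
  inv_truth <- rep(c("TRUE_VARIANT", "FFPE_ARTIFACT"), each = 10)
  inv_probs <- c(seq(0.0, 0.45, length.out = 10), seq(0.55, 1, length.out = 10))
  inv <- sweep_threshold(inv_probs, inv_truth)
  all_pos_f1 <- 2 * 10 / (2 * 10 + 10 + 0)
  expect_equal(inv$f1, all_pos_f1)
})

test_that("the sweep is invariant under permutation of the input order", {
  set.seed(29)
  truth <- sample(variant_labels(), 60, replace = TRUE)
  probs <- round(runif(60), 2)
  ref <- sweep_threshold(probs, truth)
  perm <- sample.int(60)
  shuf <- sweep_threshold(probs[perm], truth[perm])
  expect_equal(shuf$threshold, ref$threshold)
  expect_equal(shuf$f1, ref$f1)
})

test_that("stratified reports bin by MAF, substitution class, and cancer", {
  truth <- rep(c("TRUE_VARIANT", "FFPE_ARTIFACT"), 4)
  pred <- truth
  maf <- c(0.03, 0.05, 0.01, 0.049, 0.2, 0.3, 0.011, 0.5)
  sub <- c("C>T", "G>A", "G>T", "C>A", "A>G", "T>C", "C>T", "INS")
  cancer <- rep(c("lung", "breast"), each = 4)
  rep_ <- stratified_report(truth, pred, maf, sub, cancer)
  low <- rep_[rep_$stratum == "Low MAF variants", ]
  # open interval: 0.03, 0.049, 0.011 qualify; 0.05, 0.01 do not
  expect_equal(low$n, 3)
  cgta <- rep_[rep_$stratum == "C:G>T:A", ]
  gcta <- rep_[rep_$stratum == "G:C>T:A", ]
  expect_equal(cgta$n, 3)  # the C>T and G>A calls
  expect_equal(gcta$n, 2)  # the G>T and C>A calls
  # cancer strata partition the data: per-cancer tp sums to overall tp
  overall <- rep_[rep_$stratum == "All", ]
  expect_equal(sum(rep_$tp[rep_$stratum %in% c("lung", "breast")]),
               overall$tp)
})

test_that("empty strata are flagged rather than erroring", {
  rep_ <- stratified_report(c("TRUE_VARIANT", "FFPE_ARTIFACT"),
                            c("TRUE_VARIANT", "FFPE_ARTIFACT"),
                            maf = c(0.2, 0.3),
                            substitution = c("A>G", "T>C"))
  low <- rep_[rep_$stratum == "Low MAF variants", ]
  expect_true(low$empty)
  expect_true(is.na(low$specificity))
})

test_that("report files use the benchmark column order", {
  rep_ <- stratified_report(rep("TRUE_VARIANT", 2), rep("TRUE_VARIANT", 2),
                            c(0.2, 0.3), c("C>T", "G>A"))
  path <- tempfile(fileext = ".tsv")
  write_report(rep_, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header, c("stratum", "tp", "tn", "fp", "fn", "specificity",
                         "sensitivity", "precision", "f1", "accuracy"))
})
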