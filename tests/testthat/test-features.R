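test_that("MAF is the alt fraction of informative reads", {
  expect_equal(compute_maf(90, 10), 0.10)
  expect_equal(compute_maf(0, 25), 1.0)
  expect_equal(round(compute_maf(343, 45), 4), 0.1160)
  expect_error(compute_maf(0, 0), "positive")
  expect_error(compute_maf(-1, 5), "non-negative")
})

test_that("SOB score measures orientation imbalance on [0, 1]", {
  expect_equal(compute_sob(10, 10), 0)
  expect_equal(compute_sob(10, 0), 1)
  expect_equal(compute_sob(15, 5), 0.5)
  expect_true(is.na(compute_sob(0, 0)))
  expect_error(compute_sob(-1, 3), "non-negative")
  # symmetry over random counts
  set.seed(4)
  a <- rpois(200, 8); b <- rpois(200, 8)
  keep <- a + b > 0
  expect_equal(compute_sob(a[keep], b[keep]), compute_sob(b[keep], a[keep]))
})

test_that("orientation cosine matches hand values and scale invariance", {
  expect_equal(compute_orientation_cosine(50, 50, 25, 25), 1.0)
  expect_equal(round(compute_orientation_cosine(50, 50, 10, 0), 4), 0.7071)
  expect_true(is.na(compute_orientation_cosine(0, 0, 5, 5)))
  expect_true(is.na(compute_orientation_cosine(5, 5, 0, 0)))
  expect_error(compute_orientation_cosine(-1, 1, 1, 1), "non-negative")
  # invariant under positive scaling of either profile
  set.seed(5)
  r1 <- rpois(100, 10) + 1; r2 <- rpois(100, 10) + 1
  a1 <- rpois(100, 5) + 1; a2 <- rpois(100, 5) + 1
  expect_equal(compute_orientation_cosine(3 * r1, 3 * r2, a1, a2),
               compute_orientation_cosine(r1, r2, 7 * a1, 7 * a2))
})

test_that("substitution classification covers all 12 types plus indels", {
  expect_equal(classify_substitution("C", "T"), "C>T")
  expect_equal(classify_substitution("A", "AT"), "INS")
  expect_equal(classify_substitution("ATG", "A"), "DEL")
  expect_equal(classify_substitution("AT", "GC"), "COMPLEX")
  expect_equal(classify_substitution("A", "TG"), "COMPLEX")  # no shared prefix
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  labels <- classify_substitution(pairs$ref, pairs$alt)
  expect_length(unique(labels), 12)
  expect_setequal(labels, paste0(pairs$ref, ">", pairs$alt))
  expect_error(classify_substitution("N", "T"), "A/C/G/T")
})

test_that("feature vectors have 41 entries with consistent one-hot blocks", {
  schema <- default_feature_schema()
  expect_length(schema$names, 41)
  calls <- rbind(make_call(pos = 1, ref = "C", alt = "T"),
                 make_call(pos = 2, ref = "A", alt = "AT"),
                 make_call(pos = 3, ref = "ATG", alt = "A"))
  fm <- build_feature_matrix(calls, schema)
  expect_equal(ncol(fm$values), 41)
  class_block <- fm$values[, c("class_SNV", "class_INS", "class_DEL")]
  expect_equal(rowSums(class_block), c(1, 1, 1))
  sub_block <- fm$values[, grepl("^sub_", colnames(fm$values))]
  expect_equal(rowSums(sub_block), c(1, 0, 0))  # indels carry no SNV flag
  expect_equal(fm$values[1, "sub_C>T"], c("sub_C>T" = 1))
  expect_equal(unname(fm$values[, "ref_len"]), c(1, 1, 3))
})

test_that("a schema of the wrong width is rejected", {
  bad <- structure(list(names = letters[1:5], numeric = rep(TRUE, 5),
                        version = "x"), class = "feature_schema")
  expect_error(build_feature_matrix(make_call(), bad), "41")
})

test_that("missing annotations stay NA with flags until a scaler imputes them", {
  call <- make_call(mmq_ref = NA, mmq_alt = NA, f1r2_alt = 0L, f2r1_alt = 0L,
                    ad_alt = 10L)
  fm <- build_feature_matrix(call)
  expect_true(is.na(fm$values[1, "MMQ_alt"]))
  expect_true(fm$missing[1, "MMQ_alt"])
  expect_true(is.na(fm$values[1, "SOB"]))  # zero orientation support
  # a scaler fitted on complete training data imputes with train medians
  train <- make_calls(20, mmq_ref = 60, mmq_alt = 55)
  scaler <- fit_scaler(build_feature_matrix(train))
  scaled <- apply_scaler(scaler, fm)
  expect_true(all(is.finite(scaled)))
})

test_that("scaler z-scores with training moments and zeroes constants", {
  # feature with train mean 5, sd 2 maps value 9 to 2.0
  vals <- c(3, 5, 7)  # mean 5, sd 2
  train <- do.call(rbind, lapply(vals, function(v) make_call(mpos = v)))
  scaler <- fit_scaler(build_feature_matrix(train))
  probe <- build_feature_matrix(make_call(mpos = 9))
  expect_equal(apply_scaler(scaler, probe)[1, "MPOS"], c(MPOS = 2.0))
  # constant features (MMQ etc. here) map to 0 for any input
  expect_equal(unname(apply_scaler(scaler, probe)[1, "MMQ_ref"]), 0)
  expect_error(fit_scaler(build_feature_matrix(make_call()[0, ])), "empty")
})

test_that("scaled training features have mean 0 and sd 1", {
  pair <- generate_paired_dataset(synthetic_config(
    n_true_variants = 150, n_artifacts = 150, seed = 2))
  fm <- build_feature_matrix(pair$ffpe_calls)
  scaler <- fit_scaler(fm)
  scaled <- apply_scaler(scaler, fm)
  num <- fm$schema$numeric & apply(scaled, 2, stats::sd) > 0
  mu <- colMeans(scaled[, num])
  sd_ <- apply(scaled[, num], 2, stats::sd)
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(sd_ - 1) < 1e-9))
})

test_that("feature tables round-trip through TSV export", {
  calls <- make_calls(5)
  calls$label <- rep(c("TRUE_VARIANT", "FFPE_ARTIFACT"), length.out = 5)
  calls$sample_id <- "s1"
  fm <- build_feature_matrix(calls)
  path <- tempfile(fileext = ".tsv")
  write_feature_table(calls, fm, path)
  back <- read_feature_table(path)
  expect_equal(back$features$values, fm$values)
  expect_equal(back$labels, calls$label)
  expect_equal(back$calls_meta$pos, calls$pos)
})

test_that("synthetic classes separate in the documented directions", {
  pair <- generate_paired_dataset(synthetic_config(seed = 8))
  lab <- label_ffpe_calls(pair$ffpe_calls, pair$ff_calls)
  maf <- compute_maf(lab$ad_ref, lab$ad_alt)
  sob <- compute_sob(lab$f1r2_alt, lab$f2r1_alt)
  art <- lab$label == "FFPE_ARTIFACT"
  expect_lt(median(maf[art]), median(maf[!art]))
  expect_gt(median(sob[art], na.rm = TRUE), median(sob[!art], na.rm = TRUE))
})
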