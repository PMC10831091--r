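test_that("the default architecture has exactly 2002 trainable parameters", {
  model <- init_classifier()
  expect_equal(n_parameters(model), 2002)
  # by block: 41*32+32, 2*32, 32*16+16, 2*16, 16*2+2
  expect_equal(1344 + 64 + 528 + 32 + 34, 2002)
})

test_that("initialisation is deterministic and schema-checked", {
  a <- init_classifier(classifier_config(seed = 5))
  b <- init_classifier(classifier_config(seed = 5))
  expect_identical(a$params, b$params)
  c_ <- init_classifier(classifier_config(seed = 6))
  expect_false(identical(a$params, c_$params))
  expect_error(init_classifier(classifier_config(layer_widths = c(40, 32, 16))),
               "schema")
})

test_that("an all-zero network outputs probability one half", {
  model <- init_classifier()
  model$params <- lapply(model$params, function(w) w * 0)
  x <- matrix(rnorm(5 * 41), 5, 41)
  expect_equal(predict_proba(model, x), rep(0.5, 5))
})

test_that("probabilities are valid and batch equals element-wise prediction", {
  model <- init_classifier(classifier_config(seed = 3))
  set.seed(9)
  x <- matrix(rnorm(20 * 41), 20, 41)
  p <- predict_proba(model, x)
  expect_true(all(p >= 0 & p <= 1))
  single <- vapply(seq_len(20), function(i) predict_proba(model, x[i, ]),
                   numeric(1))
  expect_equal(p, single, tolerance = 1e-12)
  # repeated calls agree exactly (pure function of weights and input)
  expect_identical(p, predict_proba(model, x))
  expect_error(predict_proba(model, x[, 1:40]), "width")
  expect_error(predict_proba(model, {x[1, 1] <- NA; x}), "finite")
})

test_that("training separates a linearly separable toy problem", {
  toy <- toy_separable(500)
  model <- init_classifier(classifier_config(seed = 1))
  model <- train_classifier(model, toy$x, toy$y)
  acc <- mean((predict_proba(model, toy$x) >= 0.5) == (toy$y == 1))
  expect_gte(acc, 0.95)
  expect_true(model$trained)
  expect_true(is.finite(model$meta$final_loss))
})

test_that("training is deterministic given the seed and rejects bad input", {
  toy <- toy_separable(120)
  m1 <- train_classifier(init_classifier(classifier_config(seed = 2, epochs = 10)),
                         toy$x, toy$y)
  m2 <- train_classifier(init_classifier(classifier_config(seed = 2, epochs = 10)),
                         toy$x, toy$y)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$running, m2$running)
  expect_error(train_classifier(init_classifier(), toy$x, rep(0, 120)),
               "both classes")
  expect_error(train_classifier(init_classifier(), toy$x[0, ], numeric(0)),
               "empty")
})

test_that("classification uses an inclusive threshold and is monotone", {
  model <- init_classifier()
  model$params <- lapply(model$params, function(w) w * 0)  # p = 0.5 exactly
  x <- matrix(0, 1, 41)
  expect_equal(classify_calls(model, x, threshold = 0.5), "TRUE_VARIANT")
  expect_equal(classify_calls(model, x, threshold = 0.51), "FFPE_ARTIFACT")
  expect_error(classify_calls(model, x, threshold = 0), "\\(0, 1\\)")

  # lowering the threshold never removes a true-variant prediction
  trained <- train_classifier(init_classifier(classifier_config(seed = 4, epochs = 20)),
                              toy_separable(200)$x, toy_separable(200)$y)
  p <- predict_proba(trained, toy_separable(200)$x)
  at_50 <- p >= 0.5
  at_425 <- p >= 0.425
  expect_true(all(at_425[at_50]))
})

test_that("model bundles round-trip predictions bit for bit", {
  pair <- generate_paired_dataset(synthetic_config(
    n_true_variants = 120, n_artifacts = 120, seed = 13))
  lab <- label_ffpe_calls(pair$ffpe_calls, pair$ff_calls)
  fm <- build_feature_matrix(lab)
  model <- train_classifier(init_classifier(classifier_config(epochs = 15)),
                            fm, lab$label)
  before <- predict_proba(model, fm)
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  loaded <- load_model(path)
  expect_identical(predict_proba(loaded, fm), before)
  expect_equal(loaded$config$threshold, 0.5)  # default carried in the bundle
  expect_equal(loaded$schema$names, model$schema$names)
})

test_that("a bundle whose schema width disagrees with the network is rejected", {
  model <- init_classifier()
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  bundle <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  bundle$schema$names <- bundle$schema$names[1:40]
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_model(path), "40")
})

test_that("the trained model dominates a majority-class predictor on F1", {
  res <- parameter_recovery_experiment(
    synthetic_config(n_true_variants = 400, n_artifacts = 600, seed = 21),
    classifier_config(epochs = 40, seed = 21))
  # majority class is artifact => majority predictor has F1 = 0
  majority <- rep("FFPE_ARTIFACT", length(res$truth))
  maj_f1 <- compute_metrics(build_confusion(res$truth, majority))$f1
  expect_gt(res$metrics$f1, maj_f1)
})
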