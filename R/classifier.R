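## The artifact classifier: a small feed-forward network mapping the
## 41-entry feature vector to the probability that a call is a true
## variant. Architecture: linear(41->32), batch norm, ReLU,
## linear(32->16), batch norm, ReLU, linear(16->2), softmax over
## {artifact, true variant}. Loss is binary cross entropy on the
## positive-class probability (equivalently two-class cross entropy);
## optimisation is Adam. Written as explicit matrix algebra with manual
## backpropagation: at 2002 parameters the model is deliberately small
## enough that this is both transparent and fast.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Classifier configuration
#'
#' @param layer_widths widths of the input layer and two hidden layers;
#'   the default `c(41, 32, 16)` matches the default feature schema.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param threshold decision threshold in `(0, 1)` on the true-variant
#'   probability; default 0.5.
#' @param seed integer seed controlling weight initialisation and epoch
#'   shuffling.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(layer_widths = c(41L, 32L, 16L),
                              learning_rate = 1e-3,
                              batch_size = 256L,
                              epochs = 100L,
                              threshold = 0.5,
                              seed = 42L) {
  if (length(layer_widths) != 3 || any(layer_widths < 1)) {
    stop("layer_widths must be three positive integers")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(
    list(layer_widths = as.integer(layer_widths),
         classes = 2L,
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         threshold = threshold,
         seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Initialise an untrained classifier
#'
#' Weights are drawn uniformly from `(-1/sqrt(fan_in), 1/sqrt(fan_in))`,
#' deterministically from the config seed; batch-norm scale/shift start
#' at 1/0 and running statistics at 0/1.
#'
#' @param config a [classifier_config()].
#' @param schema feature schema the model is bound to; its length must
#'   equal the input width.
#' @return A list of class `trained_classifier` (untrained: no scaler,
#'   `trained = FALSE`).
#' @export
init_classifier <- function(config = classifier_config(),
                            schema = default_feature_schema()) {
  if (config$layer_widths[1] != length(schema$names)) {
    stop("input width (", config$layer_widths[1],
         ") does not match the feature schema (", length(schema$names),
         " entries)")
  }
  d <- config$layer_widths
  init_linear <- function(n_in, n_out) {
    bound <- 1 / sqrt(n_in)
    list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
         b = stats::runif(n_out, -bound, bound))
  }
  params <- NULL
  with_seed(config$seed, {
    l1 <- init_linear(d[1], d[2])
    l2 <- init_linear(d[2], d[3])
    l3 <- init_linear(d[3], config$classes)
    params <- list(
      W1 = l1$W, b1 = l1$b, g1 = rep(1, d[2]), be1 = rep(0, d[2]),
      W2 = l2$W, b2 = l2$b, g2 = rep(1, d[3]), be2 = rep(0, d[3]),
      W3 = l3$W, b3 = l3$b
    )
  })
  structure(
    list(
      params = params,
      running = list(rm1 = rep(0, d[2]), rv1 = rep(1, d[2]),
                     rm2 = rep(0, d[3]), rv2 = rep(1, d[3])),
      config = config,
      schema = schema,
      scaler = NULL,
      trained = FALSE,
      meta = list()
    ),
    class = "trained_classifier"
  )
}

#' Number of trainable parameters
#'
#' Counts weights, biases, and batch-norm scale/shift (running statistics
#' are not trainable). The default 41-32-16-2 architecture has 2002.
#'
#' @param model a `trained_classifier`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "trained_classifier"))
  sum(vapply(model$params, length, integer(1)))
}

## Internal broadcast helpers (row-wise application of per-column vectors).
addrow <- function(m, v) sweep(m, 2, v, "+")
mulrow <- function(m, v) sweep(m, 2, v, "*")

## Internal: inference-mode forward pass using running BN statistics.
forward_eval <- function(model, x) {
  p <- model$params
  r <- model$running
  z1 <- addrow(x %*% p$W1, p$b1)
  a1 <- addrow(mulrow(sweep(addrow(z1, -r$rm1), 2, sqrt(r$rv1 + BN_EPS), "/"),
                      p$g1), p$be1)
  h1 <- pmax(a1, 0)
  z2 <- addrow(h1 %*% p$W2, p$b2)
  a2 <- addrow(mulrow(sweep(addrow(z2, -r$rm2), 2, sqrt(r$rv2 + BN_EPS), "/"),
                      p$g2), p$be2)
  h2 <- pmax(a2, 0)
  logits <- addrow(h2 %*% p$W3, p$b3)
  softmax_rows(logits)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Predict the true-variant probability
#'
#' Applies the model's bound scaler (imputation + z-scoring) and runs the
#' network in inference mode (batch-norm running statistics; no state is
#' updated), returning the softmax probability of the true-variant class.
#' Prediction is a pure function of (weights, input).
#'
#' @param model a `trained_classifier`.
#' @param features a `feature_matrix` (schema-checked against the model),
#'   or an already-scaled numeric matrix/vector of model input width.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "trained_classifier"))
  if (inherits(features, "feature_matrix")) {
    if (schema_fingerprint(features$schema) != schema_fingerprint(model$schema)) {
      stop("feature schema does not match the schema the model is bound to")
    }
    if (is.null(model$scaler)) {
      stop("model has no bound scaler; train it or supply scaled input")
    }
    x <- apply_scaler(model$scaler, features)
  } else {
    x <- features
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x <- as.matrix(x)
  }
  if (ncol(x) != model$config$layer_widths[1]) {
    stop("input width ", ncol(x), " does not match the model (",
         model$config$layer_widths[1], ")")
  }
  if (any(!is.finite(x))) stop("non-finite feature values after scaling")
  probs <- forward_eval(model, x)
  as.numeric(probs[, 2])
}

#' Train the classifier
#'
#' Minibatch Adam on binary cross entropy. When `features` is a raw
#' `feature_matrix`, a scaler is fitted on it (training data only) and
#' bound to the model. Batch-norm layers use batch statistics during
#' training and keep exponentially-smoothed running statistics, which are
#' frozen at the end; training is deterministic given the config seed.
#'
#' @param model an initialised `trained_classifier`.
#' @param features `feature_matrix` of training calls (or pre-scaled
#'   matrix, in which case a scaler must already be bound or supplied).
#' @param labels character vector of `"TRUE_VARIANT"` / `"FFPE_ARTIFACT"`
#'   (or a 0/1 numeric vector, 1 = true variant).
#' @param scaler optional pre-fitted [fit_scaler()] result to bind
#'   instead of fitting on `features`.
#' @param config optional override of the model's config.
#' @return The trained model, with `meta` recording seed, epochs, and the
#'   final-epoch mean loss.
#' @export
train_classifier <- function(model, features, labels, scaler = NULL,
                             config = NULL) {
  stopifnot(inherits(model, "trained_classifier"))
  cfg <- if (is.null(config)) model$config else config
  y <- if (is.numeric(labels)) as.numeric(labels)
       else as.numeric(labels == LABEL_TRUE)
  if (length(y) == 0) stop("training set is empty")
  if (length(unique(y)) < 2) {
    stop("training set must contain both classes (true variants and artifacts)")
  }
  if (inherits(features, "feature_matrix")) {
    if (is.null(scaler)) scaler <- fit_scaler(features)
    x <- apply_scaler(scaler, features)
  } else {
    x <- as.matrix(features)
  }
  if (nrow(x) != length(y)) stop("features and labels disagree in length")
  if (any(!is.finite(x))) stop("non-finite feature values after scaling")

  p <- model$params
  r <- model$running
  adam_m <- lapply(p, function(w) w * 0)
  adam_v <- lapply(p, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  final_loss <- NA_real_

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(nrow(x))
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      nb <- length(batches)
      if (nb > 1 && length(batches[[nb]]) < 2) {
        batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      epoch_loss <- 0
      for (b in batches) {
        xb <- x[b, , drop = FALSE]
        yb <- y[b]
        fb <- forward_train(p, xb)
        n <- length(b)
        ## running statistics (unbiased variance, PyTorch-style momentum)
        unb <- if (n > 1) n / (n - 1) else 1
        r$rm1 <- (1 - BN_MOMENTUM) * r$rm1 + BN_MOMENTUM * fb$mu1
        r$rv1 <- (1 - BN_MOMENTUM) * r$rv1 + BN_MOMENTUM * fb$v1 * unb
        r$rm2 <- (1 - BN_MOMENTUM) * r$rm2 + BN_MOMENTUM * fb$mu2
        r$rv2 <- (1 - BN_MOMENTUM) * r$rv2 + BN_MOMENTUM * fb$v2 * unb
        eps_p <- 1e-12
        epoch_loss <- epoch_loss - sum(yb * log(fb$probs[, 2] + eps_p) +
                                       (1 - yb) * log(fb$probs[, 1] + eps_p))
        grads <- backward(p, fb, xb, yb)
        step <- step + 1L
        for (nm in names(p)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          p[[nm]] <- p[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      final_loss <- epoch_loss / nrow(x)
    }
  })

  model$params <- p
  model$running <- r
  model$config <- cfg
  if (!is.null(scaler)) model$scaler <- scaler
  model$trained <- TRUE
  model$meta <- list(seed = cfg$seed, epochs = cfg$epochs,
                     final_loss = final_loss, n_train = nrow(x))
  model
}

## Internal: training-mode forward pass with cached intermediates.
forward_train <- function(p, x) {
  n <- nrow(x)
  z1 <- addrow(x %*% p$W1, p$b1)
  mu1 <- colMeans(z1)
  v1 <- pmax(colMeans(z1^2) - mu1^2, 0)
  xhat1 <- sweep(addrow(z1, -mu1), 2, sqrt(v1 + BN_EPS), "/")
  a1 <- addrow(mulrow(xhat1, p$g1), p$be1)
  h1 <- pmax(a1, 0)
  z2 <- addrow(h1 %*% p$W2, p$b2)
  mu2 <- colMeans(z2)
  v2 <- pmax(colMeans(z2^2) - mu2^2, 0)
  xhat2 <- sweep(addrow(z2, -mu2), 2, sqrt(v2 + BN_EPS), "/")
  a2 <- addrow(mulrow(xhat2, p$g2), p$be2)
  h2 <- pmax(a2, 0)
  logits <- addrow(h2 %*% p$W3, p$b3)
  list(xhat1 = xhat1, v1 = v1, mu1 = mu1, a1 = a1, h1 = h1,
       xhat2 = xhat2, v2 = v2, mu2 = mu2, a2 = a2, h2 = h2,
       probs = softmax_rows(logits))
}

## Internal: batch-norm backward (returns gradient wrt the layer input).
bn_backward <- function(dy, xhat, v, g) {
  n <- nrow(dy)
  dxhat <- mulrow(dy, g)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  num <- n * dxhat - matrix(s1, n, length(s1), byrow = TRUE) -
    mulrow(xhat, s2)
  list(dx = sweep(num, 2, n * sqrt(v + BN_EPS), "/"),
       dg = colSums(dy * xhat),
       dbe = colSums(dy))
}

## Internal: full backward pass; mean cross-entropy over the batch.
backward <- function(p, fb, x, y) {
  n <- nrow(x)
  dlogits <- (fb$probs - cbind(1 - y, y)) / n
  dW3 <- t(fb$h2) %*% dlogits
  db3 <- colSums(dlogits)
  dh2 <- dlogits %*% t(p$W3)
  da2 <- dh2 * (fb$a2 > 0)
  bn2 <- bn_backward(da2, fb$xhat2, fb$v2, p$g2)
  dW2 <- t(fb$h1) %*% bn2$dx
  db2 <- colSums(bn2$dx)
  dh1 <- bn2$dx %*% t(p$W2)
  da1 <- dh1 * (fb$a1 > 0)
  bn1 <- bn_backward(da1, fb$xhat1, fb$v1, p$g1)
  dW1 <- t(x) %*% bn1$dx
  db1 <- colSums(bn1$dx)
  list(W1 = dW1, b1 = db1, g1 = bn1$dg, be1 = bn1$dbe,
       W2 = dW2, b2 = db2, g2 = bn2$dg, be2 = bn2$dbe,
       W3 = dW3, b3 = db3)
}

#' Classify calls from predicted probabilities
#'
#' A call is a `"TRUE_VARIANT"` iff its probability is greater than or
#' equal to the threshold (inclusive boundary), so lowering the threshold
#' can only admit more true-variant predictions.
#'
#' @param model a `trained_classifier`.
#' @param features input accepted by [predict_proba()].
#' @param threshold optional override of the model's decision threshold,
#'   in `(0, 1)`.
#' @return Character vector of labels.
#' @export
classify_calls <- function(model, features, threshold = NULL) {
  th <- if (is.null(threshold)) model$config$threshold else threshold
  if (th <= 0 || th >= 1) stop("threshold must be in (0, 1)")
  probs <- predict_proba(model, features)
  ifelse(probs >= th, LABEL_TRUE, LABEL_ARTIFACT)
}

MODEL_BUNDLE_VERSION <- "ffpesieve-model/1"

## Internal: encode numerics as 17-significant-digit strings so the JSON
## bundle round-trips doubles bit for bit.
enc_num <- function(x) list(dim = dim(x), data = sprintf("%.17g", x))
dec_num <- function(obj) {
  v <- as.numeric(obj$data)
  if (!is.null(obj$dim) && length(obj$dim) == 2) {
    matrix(v, obj$dim[1], obj$dim[2])
  } else v
}

#' Save a model bundle
#'
#' Writes a single JSON bundle holding the weights, batch-norm running
#' statistics, feature schema, scaler statistics, decision threshold, and
#' training metadata. Numeric payloads are stored at full precision, so
#' save/load/predict reproduces predictions bit for bit.
#'
#' @param model a `trained_classifier`.
#' @param path output path (written atomically).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  bundle <- list(
    format_version = MODEL_BUNDLE_VERSION,
    schema = list(names = model$schema$names,
                  numeric = model$schema$numeric,
                  version = model$schema$version),
    config = unclass(model$config),
    params = lapply(model$params, enc_num),
    running = lapply(model$running, enc_num),
    scaler = if (is.null(model$scaler)) NULL else list(
      median = enc_num(model$scaler$median),
      mean = enc_num(model$scaler$mean),
      sd = enc_num(model$scaler$sd),
      numeric = model$scaler$numeric,
      schema_fingerprint = model$scaler$schema_fingerprint
    ),
    trained = model$trained,
    meta = model$meta
  )
  json <- jsonlite::toJSON(bundle, auto_unbox = TRUE, null = "null",
                           digits = NA)
  write_lines_atomic(json, path)
  invisible(path)
}

#' Load a model bundle
#'
#' @param path bundle written by [save_model()].
#' @return A `trained_classifier`. Loading fails if the bundle's schema
#'   width does not match its network input width.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model bundle: ", path)
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(b$format_version, MODEL_BUNDLE_VERSION)) {
    stop("unsupported model bundle version: ", b$format_version)
  }
  schema <- structure(
    list(names = b$schema$names, numeric = b$schema$numeric,
         version = b$schema$version),
    class = "feature_schema"
  )
  cfg <- structure(b$config, class = "classifier_config")
  cfg$layer_widths <- as.integer(cfg$layer_widths)
  if (cfg$layer_widths[1] != length(schema$names)) {
    stop("bundle schema has ", length(schema$names),
         " names but the network expects ", cfg$layer_widths[1], " inputs")
  }
  scaler <- NULL
  if (!is.null(b$scaler)) {
    scaler <- structure(
      list(median = dec_num(b$scaler$median),
           mean = dec_num(b$scaler$mean),
           sd = dec_num(b$scaler$sd),
           numeric = b$scaler$numeric,
           schema_fingerprint = b$scaler$schema_fingerprint),
      class = "feature_scaler"
    )
  }
  structure(
    list(
      params = lapply(b$params, dec_num),
      running = lapply(b$running, dec_num),
      config = cfg,
      schema = schema,
      scaler = scaler,
      trained = isTRUE(b$trained),
      meta = as.list(b$meta)
    ),
    class = "trained_classifier"
  )
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("Feed-forward artifact classifier (",
      paste(x$config$layer_widths, collapse = "-"), "-2), ",
      n_parameters(x), " trainable parameters, ",
      if (x$trained) "trained" else "untrained",
      "; threshold = ", x$config$threshold, "\n", sep = "")
  invisible(x)
}
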