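#' One-dimensional valid-mode convolution
#'
#' The sliding dot product at the heart of the 1D convolutional layers: the
#' kernel moves unidirectionally from the start of the series to its end,
#' and at each position the elementwise product with the underlying stretch
#' of the series is summed. Output position `i` is
#' `sum_j g[j] * f[i + j - 1]`, giving `length(f) - length(g) + 1` values.
#'
#' @param f Numeric input series of length `n`.
#' @param g Numeric kernel of length `m <= n`.
#' @return Numeric vector of length `n - m + 1`.
#' @examples
#' convolve1d(c(1, 2, 3), c(1, 1))  # 3 5
#' @export
convolve1d <- function(f, g) {
  if (!is.numeric(f) || !is.numeric(g)) abort("`f` and `g` must be numeric.")
  n <- length(f)
  m <- length(g)
  if (m > n) abort(sprintf("Kernel (length %d) longer than input (length %d).", m, n))
  vapply(seq_len(n - m + 1L), function(i) sum(g * f[i:(i + m - 1L)]), numeric(1))
}

#' Gradient reversal
#'
#' The backward rule of the gradient reversal layer (GRL) that couples the
#' domain head to the shared feature extractor: the forward pass is the
#' identity, and the backward pass multiplies the upstream gradient by
#' `-lambda`. With `lambda = 0` the domain head cannot influence the
#' extractor at all; larger `lambda` pushes the extractor harder toward
#' features on which the domain classifier fails.
#'
#' @param upstream_gradient Numeric gradient arriving from the domain head.
#' @param lambda Nonnegative reversal strength.
#' @return `-lambda * upstream_gradient`.
#' @export
grl_backward <- function(upstream_gradient, lambda) {
  assert_number(lambda, "lambda", 0)
  -lambda * upstream_gradient
}

#' Configuration of the 1D-CNN adherence classifier
#'
#' Two convolution blocks (convolution + maximum pooling) followed by a
#' dense layer and a 2-unit softmax output. Defaults are sized for 7-day
#' windows of the four daily play predictors and the small per-participant
#' training sets (23 windows from 30 training days): small kernels and
#' pools, few filters, Adam with early stopping on a chronological
#' validation split.
#'
#' @param kernel_size Convolution kernel length in days (both blocks).
#' @param pool_size Maximum-pooling width (both blocks).
#' @param filters Integer vector of length 2: filters per block.
#' @param dense_units Units of the dense layer feeding the output.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (0 disables early stopping).
#' @param validation_fraction Fraction of the target's training windows
#'   (chronologically last) held out for validation.
#' @param class_weights If `TRUE`, weight the label loss by inverse class
#'   frequency.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(kernel_size = 2, pool_size = 2, filters = c(8, 16),
                       dense_units = 16, epochs = 200, batch_size = 8,
                       learning_rate = 1e-3, early_stop_patience = 20,
                       validation_fraction = 0.2, class_weights = FALSE,
                       seed = 1L) {
  if (length(filters) != 2L) abort("`filters` must give two block sizes.")
  assert_number(validation_fraction, "validation_fraction", 0, 0.5)
  structure(
    list(
      kernel_size = as.integer(kernel_size),
      pool_size = as.integer(pool_size),
      filters = as.integer(filters),
      dense_units = as.integer(dense_units),
      epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      learning_rate = learning_rate,
      early_stop_patience = as.integer(early_stop_patience),
      validation_fraction = validation_fraction,
      class_weights = isTRUE(class_weights),
      seed = as.integer(seed)
    ),
    class = "cnn_config"
  )
}

#' Configuration of the domain-adversarial trainer
#'
#' Extends a [cnn_config()] with the adversarial machinery: a domain head
#' attached to the flattened extractor features through a gradient reversal
#' layer. The label head is trained on the labeled target and source
#' windows; the domain head is trained to tell source from target while the
#' reversed gradient drives the extractor toward domain-invariant features.
#'
#' @param base A [cnn_config()].
#' @param lambda Nonnegative gradient-reversal strength (default 1).
#' @param lambda_schedule `"fixed"` holds `lambda` constant; `"annealed"`
#'   ramps it from 0 to `lambda` along a logistic schedule over the epochs.
#' @param domain_head_units Hidden units of the domain head.
#' @param source_weight Relative weight of source windows in the label loss.
#' @return A list of class `dann_config`.
#' @export
dann_config <- function(base = cnn_config(), lambda = 1,
                        lambda_schedule = c("fixed", "annealed"),
                        domain_head_units = 8, source_weight = 1) {
  if (!inherits(base, "cnn_config")) abort("`base` must be a `cnn_config`.")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    abort("`lambda` must be a single nonnegative number.")
  }
  lambda_schedule <- match.arg(lambda_schedule)
  assert_number(source_weight, "source_weight", 0)
  structure(
    list(
      base = base,
      lambda = lambda,
      lambda_schedule = lambda_schedule,
      domain_head_units = as.integer(domain_head_units),
      source_weight = source_weight
    ),
    class = "dann_config"
  )
}

# Shape arithmetic of the two conv+pool blocks; errors name the failing layer.
cnn_shapes <- function(n, kernel, pool) {
  l1 <- n - kernel + 1L
  if (l1 < 1L) abort(sprintf(
    "Window size %d too small for convolution block 1 (kernel %d).", n, kernel
  ))
  l1p <- l1 %/% pool
  if (l1p < 1L) abort(sprintf(
    "Window size %d too small for pooling block 1 (pool %d).", n, pool
  ))
  l2 <- l1p - kernel + 1L
  if (l2 < 1L) abort(sprintf(
    "Window size %d too small for convolution block 2 (kernel %d).", n, kernel
  ))
  l2p <- l2 %/% pool
  if (l2p < 1L) abort(sprintf(
    "Window size %d too small for pooling block 2 (pool %d).", n, pool
  ))
  list(l1 = l1, l1p = l1p, l2 = l2, l2p = l2p)
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Build an untrained adherence CNN
#'
#' Instantiates the architecture for `n`-day windows of `n_features` daily
#' predictors and initializes the weights (Glorot-uniform, zero biases)
#' under the configuration seed. With `domain_head_units > 0` a domain head
#' is attached for adversarial training. The same configuration and seed
#' always produce identical initial parameters.
#'
#' @param cfg A [cnn_config()].
#' @param n Window size in days.
#' @param n_features Number of daily predictors (default 4).
#' @param domain_head_units Domain-head width; 0 (default) omits the head.
#' @return An object of class `adherence_cnn` holding the weights, the
#'   architecture description, and `cfg`.
#' @export
build_cnn <- function(cfg = cnn_config(), n = 7, n_features = 4,
                      domain_head_units = 0) {
  if (!inherits(cfg, "cnn_config")) abort("`cfg` must be a `cnn_config`.")
  n <- as.integer(n)
  shp <- cnn_shapes(n, cfg$kernel_size, cfg$pool_size)
  d <- cfg$filters[2] * shp$l2p
  arch <- list(
    n_days = n, n_features = as.integer(n_features),
    kernel_size = cfg$kernel_size, pool_size = cfg$pool_size,
    filters = cfg$filters, dense_units = cfg$dense_units,
    domain_head_units = as.integer(domain_head_units),
    has_domain = domain_head_units > 0,
    flatten_dim = d
  )
  weights <- local_seed(cfg$seed, {
    w <- list(
      W1 = glorot(n_features * cfg$kernel_size, cfg$filters[1]),
      b1 = numeric(cfg$filters[1]),
      W2 = glorot(cfg$filters[1] * cfg$kernel_size, cfg$filters[2]),
      b2 = numeric(cfg$filters[2]),
      Wd = glorot(d, cfg$dense_units),
      bd = numeric(cfg$dense_units),
      Wo = glorot(cfg$dense_units, 2L),
      bo = numeric(2L)
    )
    if (arch$has_domain) {
      w$Wdm <- glorot(d, arch$domain_head_units)
      w$bdm <- numeric(arch$domain_head_units)
      w$Wdo <- glorot(arch$domain_head_units, 2L)
      w$bdo <- numeric(2L)
    }
    w
  })
  structure(
    list(weights = weights, arch = arch, config = cfg, trained = FALSE),
    class = "adherence_cnn"
  )
}

#' @export
print.adherence_cnn <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf(
    "<adherence_cnn%s> %d-day x %d-feature windows, %d parameters%s\n",
    if (x$arch$has_domain) " + domain head" else "",
    x$arch$n_days, x$arch$n_features, np,
    if (isTRUE(x$trained)) sprintf(" (trained: %s arm)", x$arm) else " (untrained)"
  ))
  invisible(x)
}

windows_matrix <- function(wd) {
  d <- dim(wd$x)
  matrix(wd$x, d[1], d[2] * d[3])
}

# chronological head/tail split of a windowed dataset
window_slice <- function(wd, idx) {
  structure(
    list(
      x = wd$x[idx, , , drop = FALSE], y = wd$y[idx], day = wd$day[idx],
      feature_names = wd$feature_names, domain = wd$domain[idx]
    ),
    class = "windowed_dataset"
  )
}

n_windows <- function(wd) dim(wd$x)[1]

# Shared trainer behind the three arms. `dann` is NULL (baseline/pooled) or
# a dann_config. The validation split is always the chronologically last
# fraction of the *target's* training windows.
train_engine <- function(target_train, source_train, cfg, dann, arm) {
  if (!inherits(target_train, "windowed_dataset")) {
    abort("`target_train` must be a `windowed_dataset`.")
  }
  n_t <- n_windows(target_train)
  if (n_t < 2L) abort("Need at least 2 target training windows.")
  n_val <- max(1L, floor(cfg$validation_fraction * n_t))
  if (n_t - n_val < 1L) abort("Too few target windows to form train and validation sets.")
  fit_t <- window_slice(target_train, seq_len(n_t - n_val))
  val <- window_slice(target_train, (n_t - n_val + 1L):n_t)

  has_source <- !is.null(source_train) && n_windows(source_train) > 0
  n_s <- if (has_source) n_windows(source_train) else 0L
  x <- windows_matrix(fit_t)
  y <- fit_t$y
  dom <- rep(0L, n_windows(fit_t))
  w <- rep(1, n_windows(fit_t))
  if (has_source) {
    x <- rbind(x, windows_matrix(source_train))
    y <- c(y, source_train$y)
    dom <- c(dom, rep(1L, n_s))
    w <- c(w, rep(if (is.null(dann)) 1 else dann$source_weight, n_s))
  }
  if (length(unique(y)) < 2L) {
    warn(sprintf(
      "All training labels are class %d; the model may degenerate to a constant predictor.",
      y[1]
    ))
  }
  if (isTRUE(cfg$class_weights)) {
    freq <- tabulate(y + 1L, 2L) / length(y)
    cw <- ifelse(freq > 0, 1 / (2 * freq), 0)
    w <- w * cw[y + 1L]
  }

  use_domain <- !is.null(dann) && has_source
  model <- build_cnn(
    cfg, n = dim(target_train$x)[2], n_features = dim(target_train$x)[3],
    domain_head_units = if (use_domain) dann$domain_head_units else 0
  )
  lambda_per_epoch <- if (!use_domain) {
    rep(0, cfg$epochs)
  } else if (dann$lambda_schedule == "annealed") {
    prog <- seq_len(cfg$epochs) / cfg$epochs
    dann$lambda * (2 / (1 + exp(-10 * prog)) - 1)
  } else {
    rep(dann$lambda, cfg$epochs)
  }

  # balanced domain loss: inverse-frequency weights so the minority domain
  # (usually the target) contributes equally to the adversarial signal
  dw <- rep(1, length(dom))
  if (use_domain) {
    freq <- tabulate(dom + 1L, 2L) / length(dom)
    dwc <- ifelse(freq > 0, 1 / (2 * freq), 0)
    dw <- dwc[dom + 1L]
  }

  fit <- local_seed(derive_seed(cfg$seed, "shuffle"), {
    nn_train_cpp(
      model$weights, model$arch, x, as.integer(y), as.integer(dom),
      as.numeric(w), as.numeric(dw), windows_matrix(val), as.integer(val$y),
      as.numeric(lambda_per_epoch), cfg$batch_size, cfg$learning_rate,
      cfg$early_stop_patience
    )
  })

  model$weights <- fit$weights
  model$trained <- TRUE
  model$arm <- arm
  model$dann <- dann
  model$n_source_windows <- n_s
  model$history <- tibble(
    epoch = seq_along(fit$train_label_loss),
    train_label_loss = fit$train_label_loss,
    train_domain_loss = fit$train_domain_loss,
    val_loss = fit$val_loss
  )
  model$best_epoch <- fit$best_epoch
  model$best_val_loss <- fit$best_val_loss
  model
}

#' Train the target-only adherence classifier
#'
#' Trains the CNN on the target participant's training windows alone (the
#' "no source, no DA" arm), minimizing cross-entropy with Adam; the
#' checkpoint with the best validation label loss is returned. Training is
#' deterministic under a fixed configuration seed.
#'
#' @param target_train A `windowed_dataset` of the target's training
#'   windows (chronological order).
#' @param cfg A [cnn_config()].
#' @return A trained `adherence_cnn` with a per-epoch `history`.
#' @export
train_baseline <- function(target_train, cfg = cnn_config()) {
  train_engine(target_train, NULL, cfg, NULL, "baseline")
}

#' Train on pooled target and source windows without adaptation
#'
#' The "with source, no DA" arm: source participants' training windows are
#' concatenated with the target's and used directly — no attempt is made to
#' correct the distributional disparity between participants (each
#' participant's windows are expected to be standardized with their own
#' training statistics upstream; see [prepare_participant()]). With an
#' empty source pool this degrades to [train_baseline()] with a warning.
#'
#' @inheritParams train_baseline
#' @param source_train A `windowed_dataset` pooling the source
#'   participants' training windows, or `NULL`.
#' @return A trained `adherence_cnn`.
#' @export
train_pooled <- function(target_train, source_train, cfg = cnn_config()) {
  if (is.null(source_train) || n_windows(source_train) == 0L) {
    warn("Empty source pool; falling back to target-only training.")
    return(train_baseline(target_train, cfg))
  }
  train_engine(target_train, source_train, cfg, NULL, "pooled")
}

#' Train the domain-adversarial adherence classifier
#'
#' The "with source, with DA" arm: a shared feature extractor with two
#' heads. The label head minimizes cross-entropy on the labeled target and
#' source windows; the domain head is trained to distinguish source from
#' target windows, but its gradient is reversed (multiplied by `-lambda`)
#' before reaching the extractor, so the extractor learns features under
#' which the two domains are indistinguishable and the source windows
#' transfer to the target. The returned checkpoint is the one with the best
#' validation label loss on the target's held-out windows. With
#' `lambda = 0` the extractor and label head follow exactly the same
#' trajectory as [train_pooled()] under the same seed; with an empty source
#' pool the arm degrades to [train_baseline()] with a warning.
#'
#' @inheritParams train_pooled
#' @param cfg A [dann_config()].
#' @return A trained `adherence_cnn` with domain head.
#' @export
train_dann <- function(target_train, source_train, cfg = dann_config()) {
  if (!inherits(cfg, "dann_config")) abort("`cfg` must be a `dann_config`.")
  if (is.null(source_train) || n_windows(source_train) == 0L) {
    warn("Empty source pool; falling back to target-only training.")
    return(train_baseline(target_train, cfg$base))
  }
  train_engine(target_train, source_train, cfg$base, cfg, "dann")
}

#' Predict next-day adherence for a set of windows
#'
#' Runs the trained classifier on each window and returns the softmax
#' scores together with the argmax class (1 = adherent). Ties are resolved
#' to the nonadherent class.
#'
#' @param model A trained `adherence_cnn`.
#' @param windows A `windowed_dataset` with matching window geometry.
#' @return A tibble with columns `.pred` (0/1), `.score_nonadherent`,
#'   `.score_adherent` and, when the windows carry labels, `.truth`.
#' @export
predict_adherence <- function(model, windows) {
  if (!inherits(model, "adherence_cnn")) abort("`model` must be an `adherence_cnn`.")
  if (!inherits(windows, "windowed_dataset")) abort("`windows` must be a `windowed_dataset`.")
  d <- dim(windows$x)
  if (d[2] != model$arch$n_days || d[3] != model$arch$n_features) {
    abort(sprintf(
      "Window shape %d x %d does not match the model input %d x %d.",
      d[2], d[3], model$arch$n_days, model$arch$n_features
    ))
  }
  p <- nn_forward_cpp(model$weights, model$arch, windows_matrix(windows))
  pred <- as.integer(p[, 2] > p[, 1])
  out <- tibble(
    .pred = pred,
    .score_nonadherent = p[, 1],
    .score_adherent = p[, 2]
  )
  if (!is.null(windows$y)) out$.truth <- windows$y
  out
}

#' Extractor features of a set of windows
#'
#' Returns the flattened output of the convolutional feature extractor (the
#' layers before the flatten boundary) for each window — the representation
#' the domain head sees through the gradient reversal layer. Useful for
#' probing domain invariance of a trained model.
#'
#' @inheritParams predict_adherence
#' @return A numeric matrix, one row per window.
#' @export
model_features <- function(model, windows) {
  nn_features_cpp(model$weights, model$arch, windows_matrix(windows))
}

#' Losses and gradients of the adversarial objective
#'
#' Diagnostic access to the training objective for verification: the label
#' cross-entropy, the domain cross-entropy, and the analytic gradients as
#' used by the trainer — label-head parameters receive the label-loss
#' gradient, domain-head parameters the domain-loss gradient, and the
#' shared extractor receives `d(label)/dw - lambda * d(domain)/dw` via the
#' gradient reversal layer.
#'
#' @param model An `adherence_cnn` (with domain head for domain terms).
#' @param windows A `windowed_dataset`; its `domain` tags (`"target"` /
#'   `"source"`) define the domain labels.
#' @param lambda Gradient-reversal strength used for the extractor gradient.
#' @param sample_weights Optional per-window label-loss weights.
#' @param domain_weights Optional per-window domain-loss weights (the
#'   trainer uses inverse-domain-frequency weights; the default here is
#'   uniform).
#' @return For `model_losses()`, a list with `label_loss` and
#'   `domain_loss`; for `model_gradients()`, a named list of gradient
#'   arrays matching `model$weights`, with the losses as attributes.
#' @export
model_losses <- function(model, windows, lambda = 0, sample_weights = NULL,
                         domain_weights = NULL) {
  io <- loss_inputs(model, windows, sample_weights, domain_weights)
  nn_loss_cpp(model$weights, model$arch, io$x, io$y, io$dom, io$w, io$dw, lambda)
}

#' @rdname model_losses
#' @export
model_gradients <- function(model, windows, lambda = 0, sample_weights = NULL,
                            domain_weights = NULL) {
  io <- loss_inputs(model, windows, sample_weights, domain_weights)
  nn_grad_cpp(model$weights, model$arch, io$x, io$y, io$dom, io$w, io$dw, lambda)
}

loss_inputs <- function(model, windows, sample_weights, domain_weights = NULL) {
  n <- n_windows(windows)
  dom <- as.integer(!is.na(windows$domain) & windows$domain == "source")
  w <- sample_weights %||% rep(1, n)
  dw <- domain_weights %||% rep(1, n)
  list(
    x = windows_matrix(windows), y = as.integer(windows$y),
    dom = dom, w = as.numeric(w), dw = as.numeric(dw)
  )
}
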