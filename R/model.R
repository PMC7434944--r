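#' Model configuration
#'
#' Hyper-parameters of the revision networks. The defaults follow the
#' published configuration: 1x3 convolutions with 8 filters and stride 1 in
#' an identity block of three residual blocks on the signal branch, two
#' Bi-LSTM layers of state 16 with batch normalization on the feature
#' branch, a merged trunk of two Bi-LSTM layers of state 64 with dropout
#' 0.2, two dense layers, softmax output; loss = softmax cross-entropy +
#' 0.2 * center loss; Adam with initial learning rate 0.002, decay 0.05
#' (applied as `lr / (1 + decay * epoch)`), beta1 0.9, beta2 0.999; batch
#' size 256; 50 epochs; window size 13.
#'
#' @param num_classes 6 for the error-type model (A/C/G/T/I/D), 4 for the
#'   true-base model (A/C/G/T).
#' @param window odd window size (events per window).
#' @param feat_dim per-position feature dimension: 7, or 10 with the
#'   methylation channel.
#' @param signal_cap samples kept per event in the signal input.
#' @param conv_filters,n_res_blocks signal-branch convolution filters and
#'   number of residual blocks.
#' @param feat_lstm_state,n_feat_lstm feature-branch Bi-LSTM state size and
#'   layer count.
#' @param trunk_lstm_state,n_trunk_lstm trunk Bi-LSTM state size and layer
#'   count.
#' @param dense_units width of the first dense layer (the center-loss
#'   feature space).
#' @param dropout dropout rate before the dense layers.
#' @param lambda_center weight of the center loss in the total loss.
#' @param batch_size,epochs training mini-batch size and epoch count.
#' @param lr,decay,beta1,beta2,adam_epsilon Adam optimizer settings.
#' @param bn_epsilon,bn_momentum batch-normalization constants.
#' @param center_alpha center update rate per mini-batch.
#' @param use_shortcut keep the residual shortcut connections (an ablation
#'   switch; leave TRUE).
#' @param precision "single" or "double" floating arithmetic for the
#'   network engine.
#' @param seed integer seed controlling weight initialization, shuffling and
#'   dropout.
#' @return named list of class `nr_model_config`.
#' @export
nr_model_config <- function(num_classes = 6L, window = 13L, feat_dim = 7L,
                            signal_cap = 40L, conv_filters = 8L,
                            n_res_blocks = 3L, feat_lstm_state = 16L,
                            n_feat_lstm = 2L, trunk_lstm_state = 64L,
                            n_trunk_lstm = 2L, dense_units = 64L,
                            dropout = 0.2, lambda_center = 0.2,
                            batch_size = 256L, epochs = 50L,
                            lr = 0.002, decay = 0.05, beta1 = 0.9,
                            beta2 = 0.999, adam_epsilon = 1e-8,
                            bn_epsilon = 1e-5, bn_momentum = 0.9,
                            center_alpha = 0.5, use_shortcut = TRUE,
                            precision = c("double", "single"), seed = 1L) {
  precision <- match.arg(precision)
  if (!num_classes %in% c(4L, 6L)) {
    stop("num_classes must be 4 or 6", call. = FALSE)
  }
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (lambda_center < 0) stop("lambda_center must be >= 0", call. = FALSE)
  cfg <- list(num_classes = as.integer(num_classes), window = as.integer(window),
              feat_dim = as.integer(feat_dim), signal_cap = as.integer(signal_cap),
              conv_filters = as.integer(conv_filters),
              n_res_blocks = as.integer(n_res_blocks),
              feat_lstm_state = as.integer(feat_lstm_state),
              n_feat_lstm = as.integer(n_feat_lstm),
              trunk_lstm_state = as.integer(trunk_lstm_state),
              n_trunk_lstm = as.integer(n_trunk_lstm),
              dense_units = as.integer(dense_units),
              dropout = dropout, lambda_center = lambda_center,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              lr = lr, decay = decay, beta1 = beta1, beta2 = beta2,
              adam_epsilon = adam_epsilon, bn_epsilon = bn_epsilon,
              bn_momentum = bn_momentum, center_alpha = center_alpha,
              use_shortcut = use_shortcut, precision = precision,
              seed = as.integer(seed))
  class(cfg) <- "nr_model_config"
  cfg
}

#' Reduced model configuration for small CPU runs
#'
#' A scaled-down profile for desk-scale experiments: 8 filters in one
#' residual block, one feature-branch Bi-LSTM of state 16, one trunk
#' Bi-LSTM of state 32, dense width 32, 8 signal samples per event, batch
#' 64, 10 epochs, single-precision arithmetic. All training mechanics
#' (losses, optimizer, windowing) are identical to the full profile.
#'
#' @param num_classes 6 or 4.
#' @param ... overrides passed to [nr_model_config()].
#' @return an `nr_model_config`.
#' @export
nr_reduced_config <- function(num_classes = 6L, ...) {
  args <- list(num_classes = num_classes, n_res_blocks = 1L,
               n_feat_lstm = 1L, trunk_lstm_state = 32L, n_trunk_lstm = 1L,
               dense_units = 32L, signal_cap = 8L, batch_size = 64L,
               epochs = 10L, precision = "single")
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(nr_model_config, args)
}

#' Initialize an untrained model
#'
#' Weights use uniform Glorot-style initialization seeded from the config;
#' LSTM forget-gate biases start at 1, batch-norm scales at 1, class centers
#' at zero.
#'
#' @param config an `nr_model_config`.
#' @return object of class `nr_model` with elements `params`, `bn`,
#'   `centers`, `config` and `format_version`.
#' @export
nr_init_model <- function(config) {
  stopifnot(inherits(config, "nr_model_config"))
  spec <- cpp_param_spec(config)
  set.seed(config$seed)
  params <- vector("list", length(spec$names))
  names(params) <- spec$names
  for (i in seq_along(params)) {
    nr <- spec$dims[i, 1L]; nc <- spec$dims[i, 2L]
    nm <- spec$names[i]
    if (grepl("_g$", nm)) {                 # batch-norm scale
      params[[i]] <- matrix(1, nr, nc)
    } else if (grepl("_b$", nm)) {          # biases and batch-norm shifts
      params[[i]] <- matrix(0, nr, nc)
    } else {
      lim <- sqrt(6 / (nr + nc))
      params[[i]] <- matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
  }
  # LSTM forget-gate bias = 1 (gate order [i f g o], both directions)
  for (nm in grep("^(feat|trunk)[0-9]+_b$", names(params), value = TRUE)) {
    h <- ncol(params[[nm]]) / 8L
    params[[nm]][1L, c((h + 1L):(2L * h), (5L * h + 1L):(6L * h))] <- 1
  }
  bn <- replicate(spec$n_bn, NULL, simplify = FALSE)
  # channel counts per bn slot: bn0 and residual bns have conv_filters
  # channels, feature-layer bns have 2 * feat_lstm_state
  nbn_conv <- 1L + 2L * config$n_res_blocks
  for (i in seq_len(spec$n_bn)) {
    ch <- if (i <= nbn_conv) config$conv_filters else 2L * config$feat_lstm_state
    bn[[i]] <- rbind(mean = rep(0, ch), var = rep(1, ch))
  }
  centers <- matrix(0, config$num_classes, config$dense_units)
  structure(list(params = params, bn = bn, centers = centers,
                 config = config, history = NULL, format_version = 1L),
            class = "nr_model")
}

#' @export
print.nr_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<nr_model> %d classes, window %d, %s precision, %d parameters%s\n",
    x$config$num_classes, x$config$window, x$config$precision, np,
    if (is.null(x$history)) " (untrained)" else
      sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

windows_to_matrices <- function(windows, config, labels = NULL) {
  stopifnot(inherits(windows, "nr_windows"))
  if (windows$feat_dim != config$feat_dim) {
    stop("window feature dimension (", windows$feat_dim,
         ") does not match the model config (", config$feat_dim, ")",
         call. = FALSE)
  }
  if (windows$window != config$window) {
    stop("window size (", windows$window, ") does not match the model config (",
         config$window, ")", call. = FALSE)
  }
  sig <- windows$signal
  cap <- windows$signal_cap
  if (cap != config$signal_cap) {
    stop("signal cap (", cap, ") does not match the model config (",
         config$signal_cap, ")", call. = FALSE)
  }
  list(signal = sig, features = windows$features)
}

#' Train a model on labeled windows
#'
#' Runs `config$epochs` epochs of Adam on the total loss (cross-entropy +
#' lambda * center loss), shuffling the training windows at the start of
#' every epoch and updating class centers after each mini-batch. Windows
#' with missing labels (clipped or unlabeled events) are dropped.
#'
#' @param model an `nr_model` from [nr_init_model()].
#' @param windows an `nr_windows` set.
#' @param which_label 1 to train on the error-type labels, 2 for the
#'   true-base labels.
#' @return the trained `nr_model`; `$history` holds the per-epoch mean
#'   total/cross-entropy/center losses.
#' @export
nr_train <- function(model, windows, which_label = if (model$config$num_classes == 6L) 1L else 2L) {
  stopifnot(inherits(model, "nr_model"))
  cfg <- model$config
  y <- if (which_label == 1L) windows$label1 else windows$label2
  keep <- !is.na(y) & !windows$clipped
  if (!any(keep)) stop("empty training set: no labeled windows", call. = FALSE)
  mats <- windows_to_matrices(windows, cfg)
  res <- cpp_nn_train(model$params, model$bn, model$centers, unclass(cfg),
                      mats$signal[keep, , drop = FALSE],
                      mats$features[keep, , drop = FALSE],
                      as.integer(y[keep]) - 1L, cfg$seed)
  model$params <- res$params
  model$bn <- res$bn
  model$centers <- res$centers
  h <- as.data.frame(res$history)
  names(h) <- c("total", "ls", "lc")
  h <- cbind(epoch = seq_len(nrow(h)), h)
  model$history <- if (is.null(model$history)) h else rbind(model$history, h)
  model
}

#' Per-event class distributions
#'
#' One probability distribution per window (the center-event convention);
#' inference is deterministic and independent of batch composition (running
#' batch-norm statistics, no dropout).
#'
#' @param model a trained (or initialized) `nr_model`.
#' @param windows an `nr_windows` set.
#' @param return_features also return the penultimate-layer features.
#' @return matrix of probabilities (windows x classes), rows summing to 1;
#'   with `return_features`, a list with `probs` and `features`.
#' @export
nr_predict <- function(model, windows, return_features = FALSE) {
  stopifnot(inherits(model, "nr_model"))
  mats <- windows_to_matrices(windows, model$config)
  res <- cpp_nn_predict(model$params, model$bn, unclass(model$config),
                        mats$signal, mats$features, return_features)
  colnames(res$probs) <- if (model$config$num_classes == 6L) LABEL1_CLASSES else LABEL2_CLASSES
  if (return_features) res else res$probs
}

#' Softmax cross-entropy loss
#'
#' `Ls = -sum_i log softmax(logits_i)[y_i]`, optionally averaged over the
#' mini-batch.
#'
#' @param logits numeric matrix (batch x classes).
#' @param labels integer class labels in `1..ncol(logits)`.
#' @param reduce "mean" or "sum".
#' @return scalar loss.
#' @export
nr_softmax_ce <- function(logits, labels, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  cpp_softmax_ce(as.matrix(logits), as.integer(labels) - 1L, reduce)
}

#' Center loss
#'
#' `Lc = 1/2 sum_i ||x_i - c_{y_i}||^2`, optionally averaged over the
#' mini-batch: the intra-class compactness penalty added to the
#' cross-entropy during training.
#'
#' @param features numeric matrix (batch x feature dim), the penultimate
#'   dense-layer activations.
#' @param labels integer class labels in `1..nrow(centers)`.
#' @param centers numeric matrix (classes x feature dim).
#' @inheritParams nr_softmax_ce
#' @return scalar loss.
#' @export
nr_center_loss <- function(features, labels, centers, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  cpp_center_loss(as.matrix(features), as.integer(labels) - 1L,
                  as.matrix(centers), reduce)
}

#' Total training loss
#'
#' `L = Ls + lambda * Lc`.
#'
#' @inheritParams nr_center_loss
#' @param logits numeric matrix (batch x classes).
#' @param lambda non-negative center-loss weight.
#' @inheritParams nr_softmax_ce
#' @return scalar loss.
#' @export
nr_total_loss <- function(logits, features, labels, centers, lambda = 0.2,
                          reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  nr_softmax_ce(logits, labels, reduce) +
    lambda * nr_center_loss(features, labels, centers, reduce)
}

#' Loss and analytic gradients on one batch
#'
#' Evaluates the network in training mode (batch statistics, no dropout) at
#' double precision and returns the loss decomposition and, optionally, the
#' gradients of every parameter — the hook used by finite-difference
#' verification.
#'
#' @param model an `nr_model`.
#' @param windows an `nr_windows` batch.
#' @param labels integer labels (1-based) for the batch.
#' @param gradients compute gradients too.
#' @return list with `total`, `ls`, `lc`, `features`, `probs` and (optionally)
#'   `grads`.
#' @export
nr_loss_grads <- function(model, windows, labels, gradients = TRUE) {
  mats <- windows_to_matrices(windows, model$config)
  cpp_nn_loss_grads(model$params, model$bn, model$centers,
                    unclass(model$config), mats$signal, mats$features,
                    as.integer(labels) - 1L, gradients)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of the parameters, batch-norm
#' statistics, class centers, configuration and a format version.
#'
#' @param model an `nr_model`.
#' @param path checkpoint file.
#' @return `path` (save) or the restored `nr_model` (load).
#' @export
nr_save_model <- function(model, path) {
  stopifnot(inherits(model, "nr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname nr_save_model
#' @export
nr_load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nr_model") || is.null(model$format_version)) {
    stop("'", path, "' is not a model checkpoint", call. = FALSE)
  }
  if (model$format_version != 1L) {
    stop("unsupported checkpoint format version ", model$format_version,
         call. = FALSE)
  }
  model
}
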