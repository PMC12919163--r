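#' Training configuration for the stacked BiLSTM classifier
#'
#' The model is two sequential bidirectional LSTM layers, each followed by a
#' dropout layer, with a single sigmoid unit on the concatenated final hidden
#' states of both directions of layer 2; trained with mini-batch ADAM on
#' binary cross-entropy, early-stopped on validation loss.
#'
#' @param hidden_units Hidden units per direction in each BiLSTM layer.
#'   Default 32.
#' @param dropout_rate Dropout fraction in `[0, 1)` after each BiLSTM layer.
#'   Default 0.3.
#' @param batch_size Mini-batch size. Default 8.
#' @param learning_rate ADAM step size. Default 1e-3.
#' @param max_epochs Maximum training epochs. Default 100.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping. Default 10.
#' @param split_fractions Train/validation/test fractions, summing to 1.
#'   Default `c(0.70, 0.15, 0.15)`.
#' @param decision_threshold Probability threshold for the stimulus label.
#'   Default 0.5.
#' @param class_weight Weight multiplying the loss of stimulus-class
#'   examples; 1 (no weighting) by default, matching a plain
#'   cross-entropy fit.
#' @param rng_seed Integer seed for initialization, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(hidden_units = 32L,
                         dropout_rate = 0.3,
                         batch_size = 8L,
                         learning_rate = 1e-3,
                         max_epochs = 100L,
                         early_stop_patience = 10L,
                         split_fractions = c(0.70, 0.15, 0.15),
                         decision_threshold = 0.5,
                         class_weight = 1,
                         rng_seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (length(split_fractions) != 3L || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-9)
    stop("split_fractions must be 3 positive values summing to 1",
         call. = FALSE)
  structure(list(hidden_units = as.integer(hidden_units),
                 n_bilstm_layers = 2L,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 split_fractions = split_fractions,
                 decision_threshold = decision_threshold,
                 class_weight = class_weight,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

# Largest-remainder apportionment of n items into fractions, so the partition
# sizes are exact and deterministic (remainder ties resolved toward the
# earlier partition, i.e. train first).
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, -seq_along(fractions), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Split segments into train/validation/test sets
#'
#' Stratified-by-label random partition at the configured fractions:
#' each class is apportioned exactly (largest-remainder rounding), then
#' shuffled deterministically under `rng_seed`. A chronological mode (no
#' shuffling; earlier segments train, later ones test) is available for
#' sensitivity analyses.
#'
#' @param segment_set A `segment_set` containing both classes.
#' @param fractions Train/val/test fractions summing to 1.
#' @param rng_seed Integer seed.
#' @param chronological If `TRUE`, split each class by time order instead of
#'   at random.
#' @return List with `train`, `val`, `test` segment sets; disjoint and
#'   exhaustive.
#' @export
split_segments <- function(segment_set, fractions = c(0.70, 0.15, 0.15),
                           rng_seed = 1L, chronological = FALSE) {
  stopifnot(inherits(segment_set, "segment_set"))
  counts <- class_counts(segment_set)
  if (any(counts == 0))
    stop("both classes must be present to split; missing: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions <= 0))
    stop("fractions must be 3 positive values summing to 1", call. = FALSE)
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(rng_seed, {
    for (lab in c("stimulus", "non_stimulus")) {
      idx <- which(segment_set$info$label == lab)
      if (!chronological) idx <- sample(idx)
      sizes <- apportion(length(idx), fractions)
      parts$train <- c(parts$train, idx[seq_len(sizes[1])])
      parts$val <- c(parts$val, idx[sizes[1] + seq_len(sizes[2])])
      parts$test <- c(parts$test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
  })
  lapply(parts, function(ix) subset_segments(segment_set, sort(ix)))
}

# Segments as the classifier sees them: each a T x F matrix, timestep rows,
# one feature column per channel.
segments_to_inputs <- function(segment_set) {
  lapply(segment_set$segments, t)
}

segment_labels01 <- function(segment_set) {
  as.numeric(segment_set$info$label == "stimulus")
}

# Uniform(-k, k) initialization with k = 1/sqrt(H), the usual LSTM default.
init_params <- function(n_features, H) {
  k <- 1 / sqrt(H)
  rmat <- function(r, c) matrix(stats::runif(r * c, -k, k), r, c)
  list(W1f = rmat(4 * H, n_features), U1f = rmat(4 * H, H),
       b1f = stats::runif(4 * H, -k, k),
       W1b = rmat(4 * H, n_features), U1b = rmat(4 * H, H),
       b1b = stats::runif(4 * H, -k, k),
       W2f = rmat(4 * H, 2 * H), U2f = rmat(4 * H, H),
       b2f = stats::runif(4 * H, -k, k),
       W2b = rmat(4 * H, 2 * H), U2b = rmat(4 * H, H),
       b2b = stats::runif(4 * H, -k, k),
       w_out = stats::runif(2 * H, -k, k),
       b_out = stats::runif(1, -k, k))
}

#' Train the stacked BiLSTM segment classifier
#'
#' Fits the two-layer bidirectional LSTM on labeled 600-ms segments with
#' mini-batch ADAM, recording per-epoch train/validation loss and accuracy
#' and early-stopping on validation loss (the best-validation weights are
#' restored). Fully reproducible given `config$rng_seed`.
#'
#' @param train_set,val_set `segment_set`s; the training set must contain
#'   both classes.
#' @param config A [train_config()].
#' @return A `bilstm_classifier` with elements `params`, `history`,
#'   `config_used` and `channel_labels`.
#' @export
train_bilstm <- function(train_set, val_set, config = train_config()) {
  stopifnot(inherits(train_set, "segment_set"),
            inherits(val_set, "segment_set"),
            inherits(config, "train_config"))
  if (any(class_counts(train_set) == 0))
    stop("training set must contain both classes", call. = FALSE)
  if (!length(val_set$segments))
    stop("validation set must be non-empty", call. = FALSE)
  X <- segments_to_inputs(train_set)
  y <- segment_labels01(train_set)
  Xv <- segments_to_inputs(val_set)
  yv <- segment_labels01(val_set)
  H <- config$hidden_units
  thr <- config$decision_threshold

  with_seed(config$rng_seed, {
    params <- init_params(ncol(X[[1]]), H)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    history <- vector("list", config$max_epochs)
    best_val <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(X))
      batch_starts <- seq(1L, length(ord), by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0
      w_all <- ifelse(y == 1, config$class_weight, 1)
      for (bs in batch_starts) {
        ix <- ord[bs:min(bs + config$batch_size - 1L, length(ord))]
        drop_seed <- sample.int(2147483647L, 1L)
        res <- cpp_bilstm_batch(X[ix], y[ix], w_all[ix], params,
                                config$dropout_rate, TRUE, drop_seed, TRUE)
        g <- res$grads
        step <- step + 1L
        for (k in names(params)) {
          m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
          v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
          mhat <- m[[k]] / (1 - beta1^step)
          vhat <- v[[k]] / (1 - beta2^step)
          params[[k]] <- params[[k]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + res$loss * length(ix)
        ep_correct <- ep_correct + sum((res$probs >= thr) == (y[ix] == 1))
      }
      val <- cpp_bilstm_batch(Xv, yv, rep(1, length(Xv)), params, 0, FALSE,
                              0L, FALSE)
      history[[epoch]] <- data.frame(
        epoch = epoch,
        train_loss = ep_loss / length(X),
        train_acc = ep_correct / length(X),
        val_loss = val$loss,
        val_acc = mean((val$probs >= thr) == (yv == 1)))
      if (val$loss < best_val - 1e-9) {
        best_val <- val$loss; best_params <- params
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
  })

  structure(list(params = best_params,
                 history = do.call(rbind, history[!vapply(history, is.null,
                                                          logical(1))]),
                 best_epoch = best_epoch,
                 config_used = config,
                 channel_labels = train_set$channel_labels,
                 window_samples = train_set$window_samples),
            class = "bilstm_classifier")
}

#' @export
print.bilstm_classifier <- function(x, ...) {
  cat(sprintf(paste0("<bilstm_classifier> 2 BiLSTM layers x %d units/",
                     "direction, %d-channel input (%s), %d-sample window\n"),
              x$config_used$hidden_units, length(x$channel_labels),
              paste(x$channel_labels, collapse = ", "), x$window_samples))
  cat(sprintf("trained %d epochs (best %d), final val_acc %.3f\n",
              nrow(x$history), x$best_epoch,
              x$history$val_acc[nrow(x$history)]))
  invisible(x)
}

#' Predict stimulus probabilities for segments
#'
#' @param object A trained `bilstm_classifier`.
#' @param segment_set A `segment_set` whose channel labels and order match
#'   the training channels.
#' @param ... Unused.
#' @return Data frame with per-segment `segment_id`, `prob` and predicted
#'   `label` (probability `>= decision_threshold` reads stimulus).
#' @export
predict.bilstm_classifier <- function(object, segment_set, ...) {
  stopifnot(inherits(segment_set, "segment_set"))
  if (!identical(segment_set$channel_labels, object$channel_labels))
    stop("channel labels/order differ from those used in training: ",
         "expected ", paste(object$channel_labels, collapse = ", "),
         call. = FALSE)
  if (segment_set$window_samples != object$window_samples)
    stop("segment window length (", segment_set$window_samples,
         ") differs from training (", object$window_samples, ")",
         call. = FALSE)
  X <- segments_to_inputs(segment_set)
  probs <- as.numeric(cpp_bilstm_batch(X, numeric(length(X)),
                                       rep(1, length(X)), object$params,
                                       0, FALSE, 0L, FALSE)$probs)
  thr <- object$config_used$decision_threshold
  data.frame(segment_id = segment_set$info$segment_id,
             prob = probs,
             label = ifelse(probs >= thr, "stimulus", "non_stimulus"))
}

#' Save and load classifier checkpoints
#'
#' Checkpoints embed the fitted weights, the training configuration, the
#' expected channel labels and the window length, serialized as JSON at full
#' double precision.
#'
#' @param model A `bilstm_classifier`.
#' @param path File path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "bilstm_classifier"))
  payload <- list(
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
      else list(dim = NULL, values = as.numeric(p))),
    history = model$history,
    best_epoch = model$best_epoch,
    config_used = unclass(model$config_used),
    channel_labels = model$channel_labels,
    window_samples = model$window_samples)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(raw$params, function(p) {
    if (is.numeric(p$dim) && length(p$dim) == 2)
      matrix(p$values, p$dim[1], p$dim[2])
    else as.numeric(p$values)
  })
  cfg <- do.call(train_config, raw$config_used[setdiff(
    names(raw$config_used), "n_bilstm_layers")])
  structure(list(params = params,
                 history = raw$history,
                 best_epoch = raw$best_epoch,
                 config_used = cfg,
                 channel_labels = raw$channel_labels,
                 window_samples = raw$window_samples),
            class = "bilstm_classifier")
}

#' Export training history as CSV
#'
#' One row per epoch: train/validation loss and accuracy.
#'
#' @param model A `bilstm_classifier`.
#' @param path File path.
#' @export
write_history_csv <- function(model, path) {
  stopifnot(inherits(model, "bilstm_classifier"))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}

#' Read and write training configurations as YAML
#'
#' @param config A [train_config()].
#' @param path File path.
#' @export
write_train_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_train_config_yaml
#' @export
read_train_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(train_config, raw[setdiff(names(raw), "n_bilstm_layers")])
}
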