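#' Surrogate model configuration
#'
#' Hyperparameters of the many-to-one recurrent surrogate and its training
#' loop. Defaults follow the standard recipe for this problem: 100 hidden
#' units over an 18-step window, Adam with learning rate 0.001, beta1 0.9,
#' beta2 0.999, epsilon 1e-8, batch size 100, 5000 epochs.
#'
#' @param hidden_units LSTM hidden width.
#' @param n_steps input sequence length.
#' @param n_input_channels input channels (radiation effect + drug code).
#' @param n_outputs predicted volume-change slots.
#' @param learning_rate,beta1,beta2,epsilon Adam settings.
#' @param batch_size minibatch size.
#' @param epochs training epochs (full passes).
#' @param seed RNG seed governing initialization, the validation split and
#'   shuffling; fixed seed implies bit-reproducible training.
#' @param holdout_groups number of whole groups held out for the validation
#'   curve (0 trains on everything).
#' @param clip_norm global gradient-norm clip (NULL disables).
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_units = 100L, n_steps = 18L,
                         n_input_channels = 2L, n_outputs = 5L,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 100L, epochs = 5000L,
                         seed = 1L, holdout_groups = 2L, clip_norm = 5) {
  structure(list(
    hidden_units = stop_if_not_count(hidden_units, "hidden_units"),
    n_steps = stop_if_not_count(n_steps, "n_steps"),
    n_input_channels = stop_if_not_count(n_input_channels, "n_input_channels"),
    n_outputs = stop_if_not_count(n_outputs, "n_outputs"),
    learning_rate = stop_if_not_scalar(learning_rate, "learning_rate"),
    beta1 = stop_if_not_scalar(beta1, "beta1", 0, 1),
    beta2 = stop_if_not_scalar(beta2, "beta2", 0, 1),
    epsilon = stop_if_not_scalar(epsilon, "epsilon"),
    batch_size = stop_if_not_count(batch_size, "batch_size"),
    epochs = stop_if_not_count(epochs, "epochs"),
    seed = stop_if_not_count(seed, "seed", min = 0L),
    holdout_groups = stop_if_not_count(holdout_groups, "holdout_groups",
                                       min = 0L),
    clip_norm = if (is.null(clip_norm)) NULL else
      stop_if_not_scalar(clip_norm, "clip_norm")
  ), class = "model_config")
}

#' Masked squared-error loss
#'
#' Sum of squared prediction errors over the mask-true output slots only
#' (slots with no measured volume change contribute nothing). For matrix
#' arguments (one row per sample) the batch loss is the mean over samples
#' of the per-sample masked sums.
#'
#' @param predicted,target numeric vectors of equal length, or matrices of
#'   equal shape.
#' @param mask logical of the same shape; `TRUE` marks defined entries.
#' @return nonnegative scalar.
#' @export
#' @examples
#' masked_loss(c(1, 2, 0), c(1, 5, 9), c(TRUE, TRUE, FALSE))  # 9
masked_loss <- function(predicted, target, mask) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target) ||
      length(predicted) != length(mask)) {
    stop("predicted, target and mask must have identical shape",
         call. = FALSE)
  }
  sq <- (predicted - target)^2 * as.numeric(mask)
  if (is.matrix(predicted)) mean(rowSums(sq)) else sum(sq)
}

#' Train the many-to-one recurrent surrogate
#'
#' Fits the LSTM on the encoded dataset with the masked squared-error loss
#' (computed on targets divided by `dataset$target_scale`) using Adam. The
#' validation split holds out whole groups, never individual samples, so
#' the validation curve measures generalization to unseen schedules.
#'
#' @param dataset a `pulsim_dataset` from [build_dataset()].
#' @param config a [model_config()].
#' @param holdout_group_ids explicit group ids to hold out; if `NULL`,
#'   `config$holdout_groups` groups are drawn at random (under the config
#'   seed).
#' @return A `pulsim_train` list: `model` (a `pulsim_model`), `train_loss`
#'   and `val_loss` (per-epoch curves, scaled units), `holdout_group_ids`,
#'   `config`.
#' @export
train <- function(dataset, config = model_config(),
                  holdout_group_ids = NULL) {
  stopifnot(inherits(dataset, "pulsim_dataset"),
            inherits(config, "model_config"))
  N <- dim(dataset$inputs)[1]
  if (!N) stop("empty dataset", call. = FALSE)
  if (dim(dataset$inputs)[2] != config$n_steps ||
      dim(dataset$inputs)[3] != config$n_input_channels) {
    stop("dataset shape does not match model config", call. = FALSE)
  }

  withr::with_seed(config$seed, {
    gids <- unique(dataset$group_id)
    if (is.null(holdout_group_ids) && config$holdout_groups > 0) {
      if (config$holdout_groups >= length(gids)) {
        stop("cannot hold out every group", call. = FALSE)
      }
      holdout_group_ids <- sample(gids, config$holdout_groups)
    }
    val_idx <- which(dataset$group_id %in% holdout_group_ids)
    tr_idx <- setdiff(seq_len(N), val_idx)
    if (!length(tr_idx)) stop("no training samples left", call. = FALSE)

    scale <- dataset$target_scale
    y <- dataset$targets / scale
    msk <- dataset$mask
    x_steps_all <- array_to_steps(dataset$inputs)
    pick <- function(steps, idx) lapply(steps, function(m) {
      m[idx, , drop = FALSE]
    })
    x_tr <- pick(x_steps_all, tr_idx)
    y_tr <- y[tr_idx, , drop = FALSE]
    m_tr <- msk[tr_idx, , drop = FALSE]
    has_val <- length(val_idx) > 0
    if (has_val) {
      x_val <- pick(x_steps_all, val_idx)
      y_val <- y[val_idx, , drop = FALSE]
      m_val <- msk[val_idx, , drop = FALSE]
    }

    w <- lstm_init(config$n_input_channels, config$hidden_units,
                   config$n_outputs)
    opt <- adam_init(w)
    n_tr <- length(tr_idx)
    train_curve <- numeric(config$epochs)
    val_curve <- rep(NA_real_, config$epochs)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_tr)
      starts <- seq(1, n_tr, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- perm[s:min(s + config$batch_size - 1, n_tr)]
        xb <- pick(x_tr, bi)
        yb <- y_tr[bi, , drop = FALSE]
        mb <- m_tr[bi, , drop = FALSE]
        fwd <- lstm_forward(w, xb)
        diffm <- (fwd$pred - yb) * mb
        loss <- mean(rowSums(diffm^2))
        if (!is.finite(loss)) {
          stop(sprintf(
            "training diverged (non-finite loss at epoch %d); lower the learning rate or rescale the targets",
            epoch), call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(bi)
        dpred <- 2 * diffm / length(bi)
        grads <- lstm_backward(w, xb, fwd, dpred)
        upd <- adam_step(w, grads, opt, config$learning_rate, config$beta1,
                         config$beta2, config$epsilon, config$clip_norm)
        w <- upd$w
        opt <- upd$state
      }
      train_curve[epoch] <- ep_loss / n_tr
      if (has_val) {
        pv <- lstm_forward(w, x_val, keep_cache = FALSE)$pred
        val_curve[epoch] <- masked_loss(pv, y_val, m_val)
      }
    }

    model <- structure(
      list(weights = w, config = config, lq = dataset$lq,
           target_scale = scale, n_steps = config$n_steps),
      class = "pulsim_model")
    structure(
      list(model = model, train_loss = train_curve, val_loss = val_curve,
           holdout_group_ids = holdout_group_ids %||% character(0),
           config = config),
      class = "pulsim_train")
  })
}

#' @export
print.pulsim_train <- function(x, ...) {
  cat(sprintf(
    "<pulsim_train> %d epochs, final train loss %.4g%s\n",
    length(x$train_loss), x$train_loss[length(x$train_loss)],
    if (length(x$holdout_group_ids))
      sprintf(", val loss %.4g (holdout: %s)",
              x$val_loss[length(x$val_loss)],
              paste(x$holdout_group_ids, collapse = ", "))
    else ""))
  invisible(x)
}

#' Plot training and validation loss curves
#'
#' @param x a `pulsim_train`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pulsim_train <- function(x, ...) {
  graphics::matplot(cbind(x$train_loss, x$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "masked MSE (scaled)", ...)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict volume changes for encoded inputs
#'
#' @param object a `pulsim_model`.
#' @param inputs an `n_steps x 2` input matrix (see [encode_inputs()]) or
#'   an `N x n_steps x 2` array.
#' @param ... unused.
#' @return predicted volume changes in mm^3: a length-`n_outputs` vector
#'   for a single matrix, or an `N x n_outputs` matrix for an array.
#' @export
predict.pulsim_model <- function(object, inputs, ...) {
  single <- is.matrix(inputs)
  if (single) {
    inputs <- array(inputs, dim = c(1, nrow(inputs), ncol(inputs)))
  }
  d <- dim(inputs)
  if (length(d) != 3 || d[2] != object$config$n_steps ||
      d[3] != object$config$n_input_channels) {
    stop(sprintf("inputs must be [N x] %d x %d", object$config$n_steps,
                 object$config$n_input_channels), call. = FALSE)
  }
  pred <- lstm_forward(object$weights, array_to_steps(inputs),
                       keep_cache = FALSE)$pred * object$target_scale
  if (single) drop(pred) else pred
}

#' @export
print.pulsim_model <- function(x, ...) {
  cat(sprintf("<pulsim_model> LSTM %d hidden, %d steps -> %d outputs\n",
              x$config$hidden_units, x$config$n_steps, x$config$n_outputs))
  invisible(x)
}

#' Train replicate surrogates and select the best-converged one
#'
#' Recurrent surrogates of this size show noticeable run-to-run variation
#' with the random initialization; the standard remedy is to train a small
#' number of replicates and carry one forward for analysis. Replicate `r`
#' trains under seed `config$seed + r - 1`; the replicate with the lowest
#' final training loss is returned.
#'
#' @inheritParams train
#' @param n_replicates replicates to train (default 3).
#' @return the selected `pulsim_train`, with the vector of all replicates'
#'   final losses attached as field `replicate_losses`.
#' @export
train_replicates <- function(dataset, config = model_config(),
                             n_replicates = 3L) {
  n_replicates <- stop_if_not_count(n_replicates, "n_replicates")
  fits <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    train(dataset, cfg)
  })
  losses <- vapply(fits, function(f) f$train_loss[length(f$train_loss)],
                   numeric(1))
  best <- fits[[which.min(losses)]]
  best$replicate_losses <- losses
  best
}

#' Leave-groups-out cross-validation
#'
#' Repeatedly draws `n_holdout_groups` whole groups at random, trains a
#' fresh surrogate on the remainder, and scores the held-out groups with
#' the masked loss (reported in mm^3 units).
#'
#' @param dataset a `pulsim_dataset`.
#' @param n_repeats folds to run (default 5).
#' @param n_holdout_groups groups excluded per fold (default 2).
#' @param config a [model_config()]; fold `r` trains under seed
#'   `config$seed + r` so folds differ but the whole procedure is
#'   reproducible.
#' @return list of folds, each with `holdout_group_ids`, `result` (a
#'   `pulsim_train`), and `holdout_loss` (masked MSE, mm^3 scale).
#' @export
crossvalidate <- function(dataset, n_repeats = 5L, n_holdout_groups = 2L,
                          config = model_config()) {
  stopifnot(inherits(dataset, "pulsim_dataset"))
  n_repeats <- stop_if_not_count(n_repeats, "n_repeats")
  n_holdout_groups <- stop_if_not_count(n_holdout_groups,
                                        "n_holdout_groups", min = 0L)
  gids <- unique(dataset$group_id)
  if (length(gids) <= n_holdout_groups) {
    stop("dataset must contain more groups than the holdout size",
         call. = FALSE)
  }
  lapply(seq_len(n_repeats), function(r) {
    fold_cfg <- config
    fold_cfg$seed <- config$seed + r
    fold_cfg$holdout_groups <- n_holdout_groups
    res <- train(dataset, fold_cfg)
    hold <- res$holdout_group_ids
    if (length(hold)) {
      idx <- which(dataset$group_id %in% hold)
      pred <- predict(res$model, dataset$inputs[idx, , , drop = FALSE])
      hl <- masked_loss(pred, dataset$targets[idx, , drop = FALSE],
                        dataset$mask[idx, , drop = FALSE])
    } else {
      hl <- NA_real_
    }
    list(holdout_group_ids = hold, result = res, holdout_loss = hl)
  })
}
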