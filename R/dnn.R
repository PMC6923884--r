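# Small fully connected feed-forward networks for binary outcome
# prediction, trained by mini-batch gradient descent on the class-weighted
# cross-entropy.  The networks are deliberately tiny (1-4 hidden layers of
# 2-8 ReLU units, softmax output): the topological feature space has at
# most ~100 dimensions, so capacity is kept low and regularized by dropout.

DNN_OPTIMIZERS <- c("adam", "adadelta", "adagrad", "proximal_adagrad")

#' DNN hyper-parameter specification
#'
#' @param hidden_sizes integer vector, 1 to 4 hidden layers with widths in
#'   `{2, 4, 8}`.
#' @param dropout dropout probability on hidden activations, in
#'   `[0.15, 0.40]`.
#' @param optimizer one of `"adam"`, `"adadelta"`, `"adagrad"`,
#'   `"proximal_adagrad"`.
#' @param learning_rate initial learning rate in `[1e-4, 5e-2]`.
#' @param batch_size mini-batch size (default 32).
#' @param epochs training epochs (default 1000).
#' @param eval_every evaluate on the evaluation partition every this many
#'   epochs (default 10).
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param l1,l2 regularization strengths for the proximal-adagrad variant.
#' @param keep `"best_eval"` (checkpoint with the best evaluation-set
#'   balanced accuracy; default) or `"final"`.
#' @return a `dnn_spec` list.
#' @export
dnn_spec <- function(hidden_sizes, dropout = 0.3, optimizer = "adam",
                     learning_rate = 1e-3, batch_size = 32, epochs = 1000,
                     eval_every = 10, seed = 1, l1 = 0, l2 = 0,
                     keep = c("best_eval", "final")) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1 || length(hidden_sizes) > 4)
    stop("need 1 to 4 hidden layers")
  if (!all(hidden_sizes %in% c(2L, 4L, 8L)))
    stop("hidden widths must be in {2, 4, 8}")
  if (dropout < 0.15 || dropout > 0.40)
    stop("dropout must lie in [0.15, 0.40]")
  if (learning_rate < 1e-4 || learning_rate > 5e-2)
    stop("learning_rate must lie in [1e-4, 5e-2]")
  optimizer <- match.arg(optimizer, DNN_OPTIMIZERS)
  structure(list(hidden_sizes = hidden_sizes, dropout = dropout,
                 optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 eval_every = as.integer(eval_every), seed = as.integer(seed),
                 l1 = l1, l2 = l2, keep = match.arg(keep)),
            class = "dnn_spec")
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

dnn_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(w = matrix(rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

dnn_forward <- function(params, x, dropout = 0, training = FALSE) {
  h <- x
  acts <- list(h)
  masks <- list()
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- h %*% params[[l]]$w + rep(params[[l]]$b, each = nrow(h))
    if (l < n_layers) {
      h <- relu(z)
      if (training && dropout > 0) {
        m <- matrix(rbinom(length(h), 1, 1 - dropout), nrow(h)) / (1 - dropout)
        h <- h * m
        masks[[l]] <- m
      }
      acts[[l + 1]] <- h
    } else {
      h <- z
    }
  }
  list(logits = h, probs = softmax_rows(h), acts = acts, masks = masks)
}

# gradient of the weighted cross-entropy w.r.t. every parameter
dnn_backward <- function(params, fwd, y_onehot, sw) {
  n_layers <- length(params)
  n <- nrow(y_onehot)
  delta <- (fwd$probs - y_onehot) * (sw / sum(sw))   # dL/dlogits
  grads <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(w = crossprod(fwd$acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(params[[l]]$w)
      if (length(fwd$masks) >= l - 1 && !is.null(fwd$masks[[l - 1]]))
        delta <- delta * fwd$masks[[l - 1]]
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

optimizer_state <- function(params) {
  lapply(params, function(p) list(
    mw = p$w * 0, mb = p$b * 0, vw = p$w * 0, vb = p$b * 0, t = 0))
}

optimizer_step <- function(spec, params, grads, state) {
  lr <- spec$learning_rate
  for (l in seq_along(params)) {
    st <- state[[l]]
    g <- grads[[l]]
    st$t <- st$t + 1
    upd <- switch(spec$optimizer,
      adam = {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        st$mw <- b1 * st$mw + (1 - b1) * g$w
        st$mb <- b1 * st$mb + (1 - b1) * g$b
        st$vw <- b2 * st$vw + (1 - b2) * g$w^2
        st$vb <- b2 * st$vb + (1 - b2) * g$b^2
        corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
        list(w = lr * (st$mw / corr1) / (sqrt(st$vw / corr2) + eps),
             b = lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps))
      },
      adadelta = {
        rho <- 0.95; eps <- 1e-6
        st$vw <- rho * st$vw + (1 - rho) * g$w^2
        st$vb <- rho * st$vb + (1 - rho) * g$b^2
        dw <- sqrt(st$mw + eps) / sqrt(st$vw + eps) * g$w
        db <- sqrt(st$mb + eps) / sqrt(st$vb + eps) * g$b
        st$mw <- rho * st$mw + (1 - rho) * dw^2
        st$mb <- rho * st$mb + (1 - rho) * db^2
        list(w = lr * dw, b = lr * db)
      },
      adagrad = , proximal_adagrad = {
        eps <- 0.1    # initial accumulator value, stabilizes early steps
        st$vw <- st$vw + g$w^2
        st$vb <- st$vb + g$b^2
        list(w = lr * g$w / sqrt(st$vw + eps),
             b = lr * g$b / sqrt(st$vb + eps))
      })
    params[[l]]$w <- params[[l]]$w - upd$w
    params[[l]]$b <- params[[l]]$b - upd$b
    if (spec$optimizer == "proximal_adagrad" && (spec$l1 > 0 || spec$l2 > 0)) {
      eta <- lr / sqrt(st$vw + 0.1)
      pw <- params[[l]]$w
      pw <- sign(pw) * pmax(abs(pw) - eta * spec$l1, 0) / (1 + eta * spec$l2)
      params[[l]]$w <- pw
    }
    state[[l]] <- st
  }
  list(params = params, state = state)
}

#' Train a deep neural network on topological features
#'
#' Trains on the training partition with class-weighted cross-entropy,
#' scoring the evaluation partition every `eval_every` epochs; the
#' checkpoint with the best evaluation balanced accuracy is kept (or the
#' final one, per the spec's `keep` field).  The validation partition is
#' never touched during training.  Fully deterministic given the spec seed.
#'
#' @param features a standardized `topo_features` object covering all
#'   samples.
#' @param y named binary outcome vector.
#' @param split a `split_assignment`.
#' @param spec a [dnn_spec()].
#' @return a `dnn_model`: spec, fitted parameters, training log
#'   (`epoch`, `train_loss`, `eval_bacc`), scaler (if present on
#'   `features`), and feature names.
#' @export
train_dnn <- function(features, y, split, spec) {
  stopifnot(inherits(features, "topo_features"), inherits(spec, "dnn_spec"),
            inherits(split, "split_assignment"))
  if (!features$standardized)
    warning("features are not standardized; DNN training expects z-scored input")
  x <- features$values
  x_train <- x[split$train_ids, , drop = FALSE]
  y_train <- y[split$train_ids]
  x_eval <- x[split$eval_ids, , drop = FALSE]
  y_eval <- y[split$eval_ids]
  cw <- class_weights(y_train)
  sw_all <- cw[as.character(y_train)]
  y_onehot <- cbind(`0` = 1 - y_train, `1` = y_train)
  sizes <- c(ncol(x), spec$hidden_sizes, 2L)
  n_train <- nrow(x_train)

  with_seed(spec$seed, {
    params <- dnn_init(sizes)
    state <- optimizer_state(params)
    best <- list(bacc = -Inf, params = params)
    log_epoch <- integer(0); log_loss <- numeric(0); log_bacc <- numeric(0)
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n_train)
      starts <- seq(1, n_train, by = spec$batch_size)
      epoch_loss <- 0; epoch_w <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + spec$batch_size - 1, n_train)]
        fwd <- dnn_forward(params, x_train[idx, , drop = FALSE],
                           dropout = spec$dropout, training = TRUE)
        sw <- sw_all[idx]
        p_true <- rowSums(fwd$probs * y_onehot[idx, , drop = FALSE])
        loss <- -sum(sw * log(pmax(p_true, 1e-15))) / sum(sw)
        if (!is.finite(loss))
          stop(sprintf("NaN/Inf loss at epoch %d (lr = %g)", epoch,
                       spec$learning_rate))
        epoch_loss <- epoch_loss + loss * sum(sw); epoch_w <- epoch_w + sum(sw)
        grads <- dnn_backward(params, fwd, y_onehot[idx, , drop = FALSE], sw)
        stepped <- optimizer_step(spec, params, grads, state)
        params <- stepped$params; state <- stepped$state
      }
      if (epoch %% spec$eval_every == 0 || epoch == spec$epochs) {
        pred <- dnn_predict_raw(params, x_eval)
        bacc <- balanced_accuracy(y_eval, pred)
        log_epoch <- c(log_epoch, epoch)
        log_loss <- c(log_loss, epoch_loss / epoch_w)
        log_bacc <- c(log_bacc, bacc)
        if (bacc > best$bacc) best <- list(bacc = bacc, params = params)
      }
    }
    final_params <- if (spec$keep == "best_eval") best$params else params
    structure(list(spec = spec, params = final_params,
                   log = data.frame(epoch = log_epoch, train_loss = log_loss,
                                    eval_bacc = log_bacc),
                   feature_names = colnames(x),
                   scaler = features$scaler, family = "dnn"),
              class = c("dnn_model", "psn_model"))
  })
}

dnn_predict_raw <- function(params, x) {
  probs <- dnn_forward(params, x)$probs
  as.integer(probs[, 2] > probs[, 1])
}

#' @export
predict.dnn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "topo_features")) newdata <- newdata$values
  newdata <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  setNames(dnn_predict_raw(object$params, newdata), rownames(newdata))
}
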