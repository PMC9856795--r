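# Small fully connected feed-forward network for binary outcome
# classification: tanh hidden layers, sigmoid output, mean-squared-error
# loss, full-batch gradient descent with an adaptive step (grow on
# improvement, shrink and revert on worsening) and early stopping on
# validation MSE. Written for the tiny-cohort regime (tens of patients,
# <= two hidden layers of <= 8 neurons); everything is plain matrix algebra.

mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = 1 / sqrt(fan_in)),
                    fan_in, sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(x), length(layers[[l]]$b), byrow = TRUE)
    acts[[l + 1L]] <- if (l < L) tanh(z) else 1 / (1 + exp(-z))
  }
  acts
}

mlp_mse <- function(layers, x, y) {
  p <- mlp_forward(layers, x)[[length(layers) + 1L]]
  mean((p - y)^2)
}

mlp_gradients <- function(layers, acts, y) {
  L <- length(layers)
  n <- length(y)
  p <- acts[[L + 1L]]
  # dLoss/dz_out for MSE + sigmoid: 2(p - y) p (1 - p) / n
  delta <- 2 * (p - y) * p * (1 - p) / n
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
  }
  grads
}

#' Train a feed-forward network
#'
#' @param x training design matrix (standardized features).
#' @param y numeric 0/1 targets (1 = SF).
#' @param hidden integer vector of hidden-layer widths, e.g. `c(8, 8)`.
#' @param x_val,y_val validation fold for early stopping; if `NULL`,
#'   training runs to `max_epochs` monitoring training MSE.
#' @param max_epochs epoch budget.
#' @param lr initial learning rate (adapted multiplicatively: x1.05 after an
#'   improving step, x0.5 with rollback after a worsening one).
#' @param patience early-stopping patience in epochs without validation
#'   improvement.
#' @return object of class `hemiconn_mlp` (list of layers plus training
#'   trace). Training is deterministic given the R RNG state.
#' @export
mlp_train <- function(x, y, hidden = c(8, 8), x_val = NULL, y_val = NULL,
                      max_epochs = 300, lr = 0.5, patience = 6) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% c(0, 1)))
  y <- matrix(as.numeric(y), ncol = 1)
  layers <- mlp_init(ncol(x), hidden)
  has_val <- !is.null(x_val)
  if (has_val) y_val <- matrix(as.numeric(y_val), ncol = 1)

  monitor <- function(ls) if (has_val) mlp_mse(ls, x_val, y_val) else mlp_mse(ls, x, y)
  train_loss <- mlp_mse(layers, x, y)
  best <- layers
  best_val <- monitor(layers)
  stall <- 0L
  epochs_run <- 0L

  for (epoch in seq_len(max_epochs)) {
    acts <- mlp_forward(layers, x)
    grads <- mlp_gradients(layers, acts, y)
    prev <- layers
    for (l in seq_along(layers)) {
      layers[[l]]$W <- layers[[l]]$W - lr * grads[[l]]$W
      layers[[l]]$b <- layers[[l]]$b - lr * grads[[l]]$b
    }
    new_loss <- mlp_mse(layers, x, y)
    if (!is.finite(new_loss))
      stop("non-finite training loss at epoch ", epoch,
           " (lr = ", format(lr), ")")
    if (new_loss <= train_loss) {
      train_loss <- new_loss
      lr <- lr * 1.05
    } else {
      layers <- prev        # reject the step
      lr <- lr * 0.5
      if (lr < 1e-10) break
      next
    }
    epochs_run <- epoch
    v <- monitor(layers)
    if (v < best_val - 1e-12) {
      best_val <- v
      best <- layers
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(layers = best, hidden = hidden, val_mse = best_val,
                 train_mse = mlp_mse(best, x, y), epochs = epochs_run),
            class = "hemiconn_mlp")
}

#' Predict class probabilities from a trained network
#'
#' @param model a [mlp_train()] fit.
#' @param x design matrix on the same standardization as training.
#' @return numeric vector of sigmoid outputs in (0, 1); with a zero-epoch
#'   budget the untrained net returns outputs near the 0.5 prior.
#' @export
mlp_predict <- function(model, x) {
  as.numeric(mlp_forward(model$layers, x)[[length(model$layers) + 1L]])
}

# Number of trainable parameters; proxy for computational cost when breaking
# selection ties.
mlp_n_params <- function(hidden, n_in) {
  sizes <- c(n_in, hidden, 1L)
  sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
}
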