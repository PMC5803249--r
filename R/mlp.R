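#' Training hyperparameters for the network ensembles
#'
#' Optimizer and regularization settings shared by the energy regressor and
#' the low/high-energy classifier. The optimizer is Adam over minibatches of
#' 200 samples with an L2 weight penalty and early stopping on a validation
#' split: training stops once `patience` consecutive epochs fail to improve
#' the best validation loss by a relative `tol`, and the weights of the best
#' epoch are kept.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param l2 L2 penalty on weights (not biases).
#' @param max_epochs hard cap on training epochs.
#' @param patience early-stopping patience, in epochs.
#' @param tol relative improvement in validation loss that resets patience.
#' @return an object of class `training_control`.
#' @export
training_control <- function(batch_size = 200L, learning_rate = 1e-3,
                             beta1 = 0.9, beta2 = 0.999, l2 = 1e-4,
                             max_epochs = 200L, patience = 10L, tol = 1e-4) {
  stopifnot(batch_size >= 1, learning_rate > 0, l2 >= 0,
            max_epochs >= 1, patience >= 1, tol >= 0,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 l2 = l2, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), tol = tol),
            class = "training_control")
}

.logistic <- function(z) 1 / (1 + exp(-z))

# Glorot-uniform initial weights; layer_sizes includes input and output dims.
.mlp_init <- function(layer_sizes, seed) {
  with_seed(seed, {
    L <- length(layer_sizes) - 1L
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (layer_sizes[l] + layer_sizes[l + 1L]))
      W[[l]] <- matrix(runif(layer_sizes[l] * layer_sizes[l + 1L], -lim, lim),
                       layer_sizes[l], layer_sizes[l + 1L])
      b[[l]] <- numeric(layer_sizes[l + 1L])
    }
    list(W = W, b = b, layer_sizes = layer_sizes)
  })
}

# Forward pass. Hidden layers are logistic units h = 1/(1+exp(-x)) with
# x = b + W'h_prev; the output layer is linear (regression) or logistic
# (classification). Returns the output vector, or all activations when
# keep_activations = TRUE (for backprop).
.mlp_forward <- function(net, X, output = c("linear", "logistic"),
                         keep_activations = FALSE) {
  output <- match.arg(output)
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    H[[l + 1L]] <- if (l < L || output == "logistic") .logistic(Z) else Z
  }
  if (keep_activations) H else drop(H[[L + 1L]])
}

# One Adam minibatch update in place. delta_out = (activation - target)/n is
# the output-layer error for both squared loss (linear output) and log loss
# (logistic output).
.mlp_backprop <- function(net, H, y, output, l2) {
  L <- length(net$W)
  n <- nrow(H[[1L]])
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (H[[L + 1L]] - y) / n
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(H[[l]], delta) + l2 * net$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      A <- H[[l]]
      delta <- (delta %*% t(net$W[[l]])) * (A * (1 - A))
    }
  }
  list(W = gW, b = gb)
}

.mlp_loss <- function(pred, y, output) {
  if (output == "linear") mean((pred - y)^2) / 2
  else {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

# Train one network with Adam + minibatches + early stopping on (Xv, yv).
# X/y must already be scaled; y is a column vector (n x 1 matrix).
.mlp_train <- function(X, y, hidden, output = c("linear", "logistic"),
                       Xv, yv, control = training_control(), seed = 1L) {
  output <- match.arg(output)
  y <- matrix(y, ncol = 1L)
  yv <- matrix(yv, ncol = 1L)
  sizes <- c(ncol(X), as.integer(hidden), 1L)
  net <- .mlp_init(sizes, seed)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  tstep <- 0L
  best <- list(loss = Inf, W = net$W, b = net$b, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  n <- nrow(X)
  with_seed(seed, {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = control$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + control$batch_size - 1L, n)]
        H <- .mlp_forward(net, X[idx, , drop = FALSE], output,
                          keep_activations = TRUE)
        g <- .mlp_backprop(net, H, y[idx, , drop = FALSE], output, control$l2)
        tstep <- tstep + 1L
        c1 <- 1 - control$beta1^tstep
        c2 <- 1 - control$beta2^tstep
        for (l in seq_len(L)) {
          mW[[l]] <- control$beta1 * mW[[l]] + (1 - control$beta1) * g$W[[l]]
          vW[[l]] <- control$beta2 * vW[[l]] + (1 - control$beta2) * g$W[[l]]^2
          net$W[[l]] <- net$W[[l]] - control$learning_rate *
            (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + 1e-8)
          mb[[l]] <- control$beta1 * mb[[l]] + (1 - control$beta1) * g$b[[l]]
          vb[[l]] <- control$beta2 * vb[[l]] + (1 - control$beta2) * g$b[[l]]^2
          net$b[[l]] <- net$b[[l]] - control$learning_rate *
            (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + 1e-8)
        }
      }
      vl <- .mlp_loss(.mlp_forward(net, Xv, output), drop(yv), output)
      if (!is.finite(vl))
        stop("non-finite validation loss during network training",
             call. = FALSE)
      history <- c(history, vl)
      if (vl < best$loss * (1 - control$tol)) {
        best <- list(loss = vl, W = net$W, b = net$b, epoch = epoch)
        wait <- 0L
      } else {
        if (vl < best$loss) best[c("loss", "W", "b", "epoch")] <-
            list(vl, net$W, net$b, epoch)
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
  })
  net$W <- best$W
  net$b <- best$b
  list(net = net, output = output, hidden = as.integer(hidden),
       stopped_epoch = length(history), best_epoch = best$epoch,
       validation_loss = best$loss, history = history, seed = seed)
}
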