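#' Build a 1-D convolutional network for difference-curve classification
#'
#' Two architectures over a `input_len x 1` signal (the 30-point
#' antifragility difference curve):
#' * `"simple"`: Conv, Conv+ReLU, Pool, Flatten, FC, Out — two convolution
#'   layers and one pooling layer;
#' * `"complex"`: (Conv+ReLU) x2, Pool, (Conv+ReLU) x2, Pool, Flatten, FC,
#'   Out — four convolution layers and two pooling layers.
#'
#' Internals not fixed by the architecture names are package defaults:
#' kernel width 3 ('valid' convolutions), channels 16 then 32 (simple) and
#' 16, 16, 32, 32 (complex), max-pooling of width 2, one fully connected
#' ReLU layer of 64 units, softmax output, cross-entropy loss and an Adam
#' optimizer (learning rate 1e-3 in [train_cnn()]).
#'
#' @param architecture `"simple"` or `"complex"`.
#' @param input_len input signal length (default 30).
#' @param n_classes number of output classes (default 4).
#' @param seed seed for the random weight initialisation.
#' @param kernel convolution kernel width.
#' @param fc_units width of the fully connected layer.
#' @return an object of class `bn_cnn` (layer list with initialised
#'   weights).
#' @export
build_cnn <- function(architecture = c("simple", "complex"), input_len = 30L,
                      n_classes = 4L, seed = 1L, kernel = 3L,
                      fc_units = 64L) {
  architecture <- match.arg(architecture)
  plan <- if (architecture == "simple") {
    list(list("conv", 16L, FALSE), list("conv", 32L, TRUE), list("pool"))
  } else {
    list(list("conv", 16L, TRUE), list("conv", 16L, TRUE), list("pool"),
         list("conv", 32L, TRUE), list("conv", 32L, TRUE), list("pool"))
  }
  withr::with_seed(as.integer(seed), {
    layers <- list()
    L <- as.integer(input_len); C <- 1L
    for (p in plan) {
      if (p[[1]] == "conv") {
        cout <- p[[2]]
        if (L < kernel)
          stop("input too short for this architecture")
        W <- array(stats::rnorm(kernel * C * cout, sd = sqrt(2 / (kernel * C))),
                   dim = c(kernel, C, cout))
        layers[[length(layers) + 1L]] <-
          list(type = "conv", W = W, b = numeric(cout), relu = p[[3]])
        L <- L - kernel + 1L; C <- cout
      } else {
        layers[[length(layers) + 1L]] <- list(type = "pool", width = 2L)
        L <- L %/% 2L
      }
    }
    flat <- L * C
    layers[[length(layers) + 1L]] <- list(
      type = "dense", relu = TRUE,
      W = matrix(stats::rnorm(flat * fc_units, sd = sqrt(2 / flat)),
                 flat, fc_units),
      b = numeric(fc_units))
    layers[[length(layers) + 1L]] <- list(
      type = "dense", relu = FALSE,
      W = matrix(stats::rnorm(fc_units * n_classes, sd = sqrt(2 / fc_units)),
                 fc_units, n_classes),
      b = numeric(n_classes))
    structure(list(architecture = architecture, input_len = as.integer(input_len),
                   n_classes = as.integer(n_classes), layers = layers),
              class = "bn_cnn")
  })
}

#' @export
print.bn_cnn <- function(x, ...) {
  nconv <- sum(vapply(x$layers, function(l) l$type == "conv", logical(1)))
  npool <- sum(vapply(x$layers, function(l) l$type == "pool", logical(1)))
  cat(sprintf("1-D CNN (%s): %d conv, %d pool, input %d, %d classes\n",
              x$architecture, nconv, npool, x$input_len, x$n_classes))
  invisible(x)
}

# ---- forward / backward --------------------------------------------------

conv_cols <- function(x, k) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  Lout <- L - k + 1L
  Xc <- matrix(0, B * Lout, k * Cin)
  for (t in seq_len(k)) for (c in seq_len(Cin))
    Xc[, (t - 1L) * Cin + c] <- as.vector(x[, t:(t + Lout - 1L), c])
  Xc
}

cnn_forward <- function(model, X, keep_cache = FALSE) {
  B <- nrow(X)
  a <- array(as.numeric(X), dim = c(B, ncol(X), 1L))
  cache <- list()
  flat_dim <- NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      k <- dim(l$W)[1]; Cin <- dim(l$W)[2]; Cout <- dim(l$W)[3]
      Lout <- dim(a)[2] - k + 1L
      Xc <- conv_cols(a, k)
      Wmat <- matrix(aperm(l$W, c(2L, 1L, 3L)), k * Cin, Cout)
      z <- Xc %*% Wmat
      z <- z + rep(l$b, each = nrow(z))
      out <- array(z, dim = c(B, Lout, Cout))
      mask <- NULL
      if (l$relu) { mask <- out > 0; out <- out * mask }
      if (keep_cache)
        cache[[li]] <- list(Xc = Xc, in_dim = dim(a), mask = mask)
      a <- out
    } else if (l$type == "pool") {
      L <- dim(a)[2]; Lout <- L %/% 2L
      x1 <- a[, seq(1L, 2L * Lout, 2L), , drop = FALSE]
      x2 <- a[, seq(2L, 2L * Lout, 2L), , drop = FALSE]
      take1 <- x1 >= x2
      out <- pmax(x1, x2)
      if (keep_cache) cache[[li]] <- list(take1 = take1, in_dim = dim(a))
      a <- out
    } else {  # dense; flatten on first dense layer
      if (is.null(flat_dim) && length(dim(a)) == 3L) {
        flat_dim <- dim(a)
        a <- matrix(a, nrow = B)
      }
      z <- a %*% l$W
      z <- z + rep(l$b, each = B)
      mask <- NULL
      if (l$relu) { mask <- z > 0; z <- z * mask }
      if (keep_cache) cache[[li]] <- list(input = a, mask = mask)
      a <- z
    }
  }
  # softmax over logits
  logits <- a - apply(a, 1L, max)
  ez <- exp(logits)
  probs <- ez / rowSums(ez)
  list(probs = probs, cache = cache, flat_dim = flat_dim)
}

cnn_backward <- function(model, fwd, y_onehot) {
  B <- nrow(y_onehot)
  grads <- vector("list", length(model$layers))
  d <- (fwd$probs - y_onehot) / B
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cc <- fwd$cache[[li]]
    if (l$type == "dense") {
      if (!is.null(cc$mask)) d <- d * cc$mask
      grads[[li]] <- list(W = crossprod(cc$input, d), b = colSums(d))
      d <- d %*% t(l$W)
    } else if (l$type == "pool") {
      in_dim <- cc$in_dim
      if (is.matrix(d)) d <- array(d, dim = dim(cc$take1))
      dx <- array(0, dim = in_dim)
      Lout <- dim(cc$take1)[2]
      dx[, seq(1L, 2L * Lout, 2L), ] <- d * cc$take1
      dx[, seq(2L, 2L * Lout, 2L), ] <- d * !cc$take1
      d <- dx
    } else {  # conv
      k <- dim(l$W)[1]; Cin <- dim(l$W)[2]; Cout <- dim(l$W)[3]
      in_dim <- cc$in_dim
      Bn <- in_dim[1]; Lout <- in_dim[2] - k + 1L
      if (is.matrix(d)) d <- array(d, dim = c(Bn, Lout, Cout))
      if (!is.null(cc$mask)) d <- d * cc$mask
      dflat <- matrix(d, Bn * Lout, Cout)
      dWmat <- crossprod(cc$Xc, dflat)
      dW <- aperm(array(dWmat, dim = c(Cin, k, Cout)), c(2L, 1L, 3L))
      db <- colSums(dflat)
      Wmat <- matrix(aperm(l$W, c(2L, 1L, 3L)), k * Cin, Cout)
      dXc <- dflat %*% t(Wmat)
      dx <- array(0, dim = in_dim)
      for (t in seq_len(k)) for (c in seq_len(Cin))
        dx[, t:(t + Lout - 1L), c] <- dx[, t:(t + Lout - 1L), c] +
          matrix(dXc[, (t - 1L) * Cin + c], Bn, Lout)
      grads[[li]] <- list(W = dW, b = db)
      d <- dx
    }
  }
  grads
}

#' Train a CNN by minibatch Adam on cross-entropy
#'
#' @param model a [build_cnn()] model.
#' @param X feature matrix (`n x input_len`).
#' @param y class labels: a factor over [robustness_classes()] or integers
#'   `1..n_classes`.
#' @param epochs training epochs (default 128).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed seed controlling minibatch shuffling.
#' @return the trained model, with a `loss_history` attribute (mean
#'   cross-entropy per epoch).
#' @export
train_cnn <- function(model, X, y, epochs = 128L, batch_size = 32L,
                      lr = 1e-3, seed = 1L) {
  y <- label_index(y, model$n_classes)
  n <- nrow(X)
  stopifnot(length(y) == n)
  onehot <- diag(model$n_classes)[y, , drop = FALSE]
  mstate <- rapply(lapply(model$layers, function(l)
    if (l$type == "pool") NULL else list(W = l$W * 0, b = l$b * 0)),
    identity, how = "replace")
  vstate <- mstate
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  losses <- numeric(epochs)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fwd <- cnn_forward(model, X[idx, , drop = FALSE], keep_cache = TRUE)
        p <- fwd$probs[cbind(seq_along(idx), y[idx])]
        ep_loss <- ep_loss - sum(log(pmax(p, 1e-12)))
        grads <- cnn_backward(model, fwd, onehot[idx, , drop = FALSE])
        step <- step + 1L
        for (li in seq_along(model$layers)) {
          if (is.null(grads[[li]])) next
          for (par in c("W", "b")) {
            g <- grads[[li]][[par]]
            mstate[[li]][[par]] <- beta1 * mstate[[li]][[par]] + (1 - beta1) * g
            vstate[[li]][[par]] <- beta2 * vstate[[li]][[par]] +
              (1 - beta2) * g^2
            mhat <- mstate[[li]][[par]] / (1 - beta1^step)
            vhat <- vstate[[li]][[par]] / (1 - beta2^step)
            model$layers[[li]][[par]] <- model$layers[[li]][[par]] -
              lr * mhat / (sqrt(vhat) + eps)
          }
        }
      }
      losses[ep] <- ep_loss / n
    }
  })
  attr(model, "loss_history") <- losses
  model
}

label_index <- function(y, n_classes) {
  if (is.factor(y)) return(as.integer(y))
  if (is.character(y)) {
    idx <- match(y, robustness_classes())
    if (anyNA(idx)) stop("unknown class label")
    return(idx)
  }
  y <- as.integer(y)
  if (any(y < 1L | y > n_classes)) stop("labels out of range")
  y
}

#' Class probabilities from a trained CNN
#'
#' @param model a (trained) [build_cnn()] model.
#' @param X feature matrix (`n x input_len`).
#' @return an `n x n_classes` matrix of softmax probabilities (rows sum
#'   to 1), columns named by [robustness_classes()] when `n_classes` is 4.
#' @export
predict_proba <- function(model, X) {
  probs <- cnn_forward(model, as.matrix(X))$probs
  if (model$n_classes == 4L) colnames(probs) <- robustness_classes()
  probs
}
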