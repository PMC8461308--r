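# Multilayer perceptron classifier with softmax output, written against
# base BLAS matrix ops. Supports an arbitrary stack of hidden layers,
# tanh/relu activations and adam/sgd/lbfgs training, mirroring the grid
# the model suite searches over. nnet (single hidden layer) cannot express
# the two-hidden-layer architectures required here.

mlp_init <- function(dims, seed) {
  set.seed(seed)
  L <- length(dims) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

mlp_act <- function(z, activation) {
  switch(activation, relu = pmax(z, 0), tanh = tanh(z),
         stop("unknown activation: ", activation, call. = FALSE))
}

mlp_act_grad <- function(z, a, activation) {
  switch(activation, relu = (z > 0) * 1, tanh = 1 - a^2)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(par, x, activation) {
  L <- length(par$W)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  A[[1]] <- x
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) mlp_act(Z[[l]], activation) else Z[[l]]
  }
  list(A = A, Z = Z, probs = softmax_rows(A[[L + 1]]))
}

# Cross-entropy loss and gradients for one batch; y is a 0-based class
# vector, alpha the L2 penalty on weights.
mlp_loss_grad <- function(par, x, y, activation, alpha) {
  m <- nrow(x)
  fw <- mlp_forward(par, x, activation)
  L <- length(par$W)
  probs <- fw$probs
  idx <- cbind(seq_len(m), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12))) +
    alpha / 2 * sum(vapply(par$W, function(w) sum(w^2), numeric(1)))
  dZ <- probs
  dZ[idx] <- dZ[idx] - 1
  dZ <- dZ / m
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$A[[l]], dZ) + alpha * par$W[[l]]
    db[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- tcrossprod(dZ, par$W[[l]])
      dZ <- dA * mlp_act_grad(fw$Z[[l - 1]], fw$A[[l]], activation)
    }
  }
  list(loss = loss, dW = dW, db = db)
}

adam_state <- function(par_list) {
  lapply(par_list, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

mlp_flatten <- function(par) {
  unlist(c(lapply(par$W, as.numeric), lapply(par$b, as.numeric)))
}

mlp_unflatten <- function(theta, dims) {
  L <- length(dims) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  off <- 0
  for (l in seq_len(L)) {
    k <- dims[l] * dims[l + 1]
    W[[l]] <- matrix(theta[off + seq_len(k)], dims[l], dims[l + 1])
    off <- off + k
  }
  for (l in seq_len(L)) {
    k <- dims[l + 1]
    b[[l]] <- theta[off + seq_len(k)]
    off <- off + k
  }
  list(W = W, b = b)
}

#' Fit a multilayer perceptron classifier
#'
#' @param x Numeric feature matrix (rows = records), already normalized.
#' @param y Integer class vector, 0-based.
#' @param hidden Integer vector of hidden-layer sizes.
#' @param activation `"relu"` or `"tanh"`.
#' @param solver `"adam"`, `"sgd"` or `"lbfgs"` (full-batch via
#'   `stats::optim`).
#' @param lr Learning rate for adam/sgd.
#' @param epochs Training epochs for adam/sgd.
#' @param batch Mini-batch size.
#' @param alpha L2 penalty on weights.
#' @param n_classes Number of output classes.
#' @param maxit L-BFGS iteration cap.
#' @param seed RNG seed (initialization and batch order).
#' @return An `mlp_model` list with fitted parameters.
#' @keywords internal
#' @export
mlp_fit <- function(x, y, hidden = c(100, 100), activation = "relu",
                    solver = "adam", lr = 1e-3, epochs = 100, batch = 200,
                    alpha = 1e-4, n_classes = 5, maxit = 200, seed = 1) {
  x <- as.matrix(x)
  dims <- c(ncol(x), hidden, n_classes)
  par <- mlp_init(dims, seed)
  n <- nrow(x)

  if (solver == "lbfgs") {
    fn <- function(theta) {
      mlp_loss_grad(mlp_unflatten(theta, dims), x, y, activation, alpha)$loss
    }
    gr <- function(theta) {
      g <- mlp_loss_grad(mlp_unflatten(theta, dims), x, y, activation, alpha)
      mlp_flatten(list(W = g$dW, b = g$db))
    }
    opt <- stats::optim(mlp_flatten(par), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    par <- mlp_unflatten(opt$par, dims)
  } else if (solver %in% c("adam", "sgd")) {
    stW <- adam_state(par$W)
    stb <- adam_state(par$b)
    step <- 0
    batch <- min(batch, n)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch)
      for (s in starts) {
        rows <- ord[s:min(s + batch - 1, n)]
        g <- mlp_loss_grad(par, x[rows, , drop = FALSE], y[rows],
                           activation, alpha)
        step <- step + 1
        for (l in seq_along(par$W)) {
          if (solver == "adam") {
            up <- adam_update(par$W[[l]], g$dW[[l]], stW[[l]], lr, step)
            par$W[[l]] <- up$p; stW[[l]] <- up$st
            up <- adam_update(par$b[[l]], g$db[[l]], stb[[l]], lr, step)
            par$b[[l]] <- up$p; stb[[l]] <- up$st
          } else {
            par$W[[l]] <- par$W[[l]] - lr * g$dW[[l]]
            par$b[[l]] <- par$b[[l]] - lr * g$db[[l]]
          }
        }
      }
    }
  } else {
    stop("unknown solver: ", solver, call. = FALSE)
  }
  structure(list(par = par, dims = dims, activation = activation,
                 n_classes = n_classes),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  probs <- mlp_forward(object$par, as.matrix(newdata),
                       object$activation)$probs
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}
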