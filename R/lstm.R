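# Long short-term memory classifier for per-second stimulation records,
# implemented with base BLAS matrix ops (no recurrent-network package is
# available in R). Architecture: a stack of uni-directional LSTM layers
# followed by a dense softmax layer; the model predicts the stimulation
# class at every timestep. Training uses truncated backpropagation through
# time over fixed-length chunks with state reset per chunk, mini-batched
# across chunks, and Adam updates. Uni-directional by design: the
# controller must predict the next step from past data only.

sigmoid <- function(z) 1 / (1 + exp(-z))

lstm_init <- function(input_dim, hidden, layers, n_classes, seed) {
  set.seed(seed)
  layer_par <- vector("list", layers)
  d <- input_dim
  for (l in seq_len(layers)) {
    lim <- 1 / sqrt(hidden)
    layer_par[[l]] <- list(
      Wx = matrix(stats::runif(d * 4 * hidden, -lim, lim), d, 4 * hidden),
      Wh = matrix(stats::runif(hidden * 4 * hidden, -lim, lim),
                  hidden, 4 * hidden),
      b = c(rep(0, hidden), rep(1, hidden), rep(0, 2 * hidden))  # forget bias 1
    )
    d <- hidden
  }
  lim <- 1 / sqrt(hidden)
  list(layers = layer_par,
       Wo = matrix(stats::runif(hidden * n_classes, -lim, lim),
                   hidden, n_classes),
       bo = numeric(n_classes),
       hidden = hidden, n_layers = layers, n_classes = n_classes,
       input_dim = input_dim)
}

# One forward step for a batch: x (B x D), state = list per layer of
# list(h, c) (B x H each). Returns probs (B x K), new state, and the
# per-layer gate cache needed for BPTT.
lstm_forward_step <- function(par, x, state, cache = FALSE) {
  H <- par$hidden
  inp <- x
  caches <- if (cache) vector("list", par$n_layers) else NULL
  for (l in seq_len(par$n_layers)) {
    p <- par$layers[[l]]
    st <- state[[l]]
    G <- sweep(inp %*% p$Wx + st$h %*% p$Wh, 2, p$b, "+")
    i <- sigmoid(G[, 1:H, drop = FALSE])
    f <- sigmoid(G[, H + 1:H, drop = FALSE])
    g <- tanh(G[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(G[, 3 * H + 1:H, drop = FALSE])
    c_new <- f * st$c + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (cache) {
      caches[[l]] <- list(x = inp, h_prev = st$h, c_prev = st$c,
                          i = i, f = f, g = g, o = o, tc = tc)
    }
    state[[l]] <- list(h = h_new, c = c_new)
    inp <- h_new
  }
  logits <- sweep(inp %*% par$Wo, 2, par$bo, "+")
  list(probs = softmax_rows(logits), state = state, caches = caches)
}

lstm_zero_state <- function(par, batch) {
  lapply(seq_len(par$n_layers), function(l) {
    list(h = matrix(0, batch, par$hidden), c = matrix(0, batch, par$hidden))
  })
}

lstm_zero_grads <- function(par) {
  list(layers = lapply(par$layers, function(p) {
    list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0)
  }), Wo = par$Wo * 0, bo = par$bo * 0)
}

# Forward + BPTT over one chunk batch. xs: list over t of B x D matrices;
# ys: list over t of 0-based class vectors. Returns loss and gradients.
lstm_loss_grad <- function(par, xs, ys) {
  Tn <- length(xs)
  B <- nrow(xs[[1]])
  H <- par$hidden
  state <- lstm_zero_state(par, B)
  caches <- vector("list", Tn)
  probs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    stp <- lstm_forward_step(par, xs[[t]], state, cache = TRUE)
    state <- stp$state
    caches[[t]] <- stp$caches
    probs[[t]] <- stp$probs
  }
  m <- B * Tn
  loss <- 0
  grads <- lstm_zero_grads(par)
  dh_next <- lapply(seq_len(par$n_layers),
                    function(l) matrix(0, B, H))
  dc_next <- lapply(seq_len(par$n_layers),
                    function(l) matrix(0, B, H))
  for (t in rev(seq_len(Tn))) {
    P <- probs[[t]]
    idx <- cbind(seq_len(B), ys[[t]] + 1L)
    loss <- loss - sum(log(pmax(P[idx], 1e-12)))
    dlogits <- P
    dlogits[idx] <- dlogits[idx] - 1
    dlogits <- dlogits / m
    h_top <- caches[[t]][[par$n_layers]]$o * caches[[t]][[par$n_layers]]$tc
    grads$Wo <- grads$Wo + crossprod(h_top, dlogits)
    grads$bo <- grads$bo + colSums(dlogits)
    d_inp <- tcrossprod(dlogits, par$Wo)
    for (l in rev(seq_len(par$n_layers))) {
      cc <- caches[[t]][[l]]
      dh <- d_inp + dh_next[[l]]
      dc <- dc_next[[l]] + dh * cc$o * (1 - cc$tc^2)
      do_ <- dh * cc$tc
      di <- dc * cc$g
      df <- dc * cc$c_prev
      dg <- dc * cc$i
      dG <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do_ * cc$o * (1 - cc$o))
      p <- par$layers[[l]]
      grads$layers[[l]]$Wx <- grads$layers[[l]]$Wx + crossprod(cc$x, dG)
      grads$layers[[l]]$Wh <- grads$layers[[l]]$Wh + crossprod(cc$h_prev, dG)
      grads$layers[[l]]$b <- grads$layers[[l]]$b + colSums(dG)
      dh_next[[l]] <- tcrossprod(dG, p$Wh)
      dc_next[[l]] <- dc * cc$f
      d_inp <- tcrossprod(dG, p$Wx)
    }
  }
  list(loss = loss / m, grads = grads)
}

# Split one sequence into chunks of at most `chunk` timesteps.
chunk_sequence <- function(x, y, chunk) {
  Tn <- nrow(x)
  starts <- seq(1, Tn, by = chunk)
  lapply(starts, function(s) {
    e <- min(s + chunk - 1, Tn)
    list(x = x[s:e, , drop = FALSE], y = y[s:e])
  })
}

#' Fit an LSTM stimulation-class predictor
#'
#' @param sequences List of per-patient sequences, each a list with `x`
#'   (timestep-by-feature matrix, already normalized) and `y` (0-based
#'   class vector).
#' @param hidden Hidden units per layer.
#' @param layers Number of stacked LSTM layers.
#' @param n_classes Number of output classes.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch Chunks per mini-batch.
#' @param chunk Timesteps per truncated-BPTT chunk (state reset per
#'   chunk).
#' @param seed RNG seed (initialization and batch shuffling).
#' @return An `lstm_model` object.
#' @keywords internal
#' @export
lstm_fit <- function(sequences, hidden = 100, layers = 2, n_classes = 5,
                     lr = 1e-3, epochs = 30, batch = 32, chunk = 60,
                     seed = 1) {
  input_dim <- ncol(sequences[[1]]$x)
  par <- lstm_init(input_dim, hidden, layers, n_classes, seed)
  chunks <- unlist(lapply(sequences, function(s) {
    chunk_sequence(s$x, s$y, chunk)
  }), recursive = FALSE)

  st <- list(layers = lapply(par$layers, function(p) {
    list(Wx = adam_state(list(p$Wx))[[1]], Wh = adam_state(list(p$Wh))[[1]],
         b = adam_state(list(p$b))[[1]])
  }), Wo = adam_state(list(par$Wo))[[1]], bo = adam_state(list(par$bo))[[1]])
  step <- 0
  lens <- vapply(chunks, function(ch) nrow(ch$x), integer(1))
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(chunks))
    # batch together chunks of equal length so timesteps align
    for (len in unique(lens[ord])) {
      grp <- ord[lens[ord] == len]
      starts <- seq(1, length(grp), by = batch)
      for (s in starts) {
        ids <- grp[s:min(s + batch - 1, length(grp))]
        xs <- lapply(seq_len(len), function(t) {
          do.call(rbind, lapply(chunks[ids], function(ch) ch$x[t, ]))
        })
        ys <- lapply(seq_len(len), function(t) {
          vapply(chunks[ids], function(ch) ch$y[t], numeric(1))
        })
        lg <- lstm_loss_grad(par, xs, ys)
        step <- step + 1
        for (l in seq_len(par$n_layers)) {
          for (nm in c("Wx", "Wh", "b")) {
            up <- adam_update(par$layers[[l]][[nm]],
                              lg$grads$layers[[l]][[nm]],
                              st$layers[[l]][[nm]], lr, step)
            par$layers[[l]][[nm]] <- up$p
            st$layers[[l]][[nm]] <- up$st
          }
        }
        up <- adam_update(par$Wo, lg$grads$Wo, st$Wo, lr, step)
        par$Wo <- up$p; st$Wo <- up$st
        up <- adam_update(par$bo, lg$grads$bo, st$bo, lr, step)
        par$bo <- up$p; st$bo <- up$st
      }
    }
  }
  structure(list(par = par), class = "lstm_model")
}

#' Predict classes for a full sequence with an LSTM model
#'
#' Runs the network over the sequence in order (state carried across
#' timesteps) and returns the argmax class at each step.
#'
#' @param object An `lstm_model`.
#' @param newdata Timestep-by-feature matrix (normalized as in training).
#' @param ... Unused.
#' @return Integer vector of 0-based predicted classes, one per timestep.
#' @export
predict.lstm_model <- function(object, newdata, ...) {
  par <- object$par
  x <- as.matrix(newdata)
  state <- lstm_zero_state(par, 1)
  out <- integer(nrow(x))
  for (t in seq_len(nrow(x))) {
    stp <- lstm_forward_step(par, x[t, , drop = FALSE], state)
    state <- stp$state
    out[t] <- which.max(stp$probs[1, ]) - 1L
  }
  out
}

# Single-step API for the closed-loop controller: returns the predicted
# class and the updated recurrent state.
lstm_step <- function(model, x_row, state = NULL) {
  par <- model$par
  if (is.null(state)) state <- lstm_zero_state(par, 1)
  stp <- lstm_forward_step(par, matrix(x_row, nrow = 1), state)
  list(class = which.max(stp$probs[1, ]) - 1L, state = stp$state)
}
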