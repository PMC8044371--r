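#' Initialize one GRU parameter set
#'
#' Weight matrices for the reset gate (`W_r`, `U_r`), update gate
#' (`W_z`, `U_z`) and candidate state (`W`, `U`), plus bias vectors
#' (`b_r`, `b_z`, `b_h`). Biases are initialized to zero; with
#' `use_bias = FALSE` they stay frozen at zero so the bias-free printed
#' recurrences are recovered exactly. Weights draw from
#' uniform(-1/sqrt(H), 1/sqrt(H)) using the caller's RNG state.
#'
#' @param input_dim embedding dimension d.
#' @param hidden_dim hidden size H.
#' @param use_bias should bias vectors be trainable (default TRUE)?
#' @return A list of class `mt_gru_params`.
#' @export
init_gru_params <- function(input_dim, hidden_dim, use_bias = TRUE) {
  lim <- 1 / sqrt(hidden_dim)
  rmat <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -lim, lim), nrow = nr, ncol = nc)
  }
  p <- list(
    W_r = rmat(hidden_dim, input_dim), U_r = rmat(hidden_dim, hidden_dim),
    W_z = rmat(hidden_dim, input_dim), U_z = rmat(hidden_dim, hidden_dim),
    W   = rmat(hidden_dim, input_dim), U   = rmat(hidden_dim, hidden_dim),
    b_r = numeric(hidden_dim), b_z = numeric(hidden_dim),
    b_h = numeric(hidden_dim),
    use_bias = use_bias
  )
  class(p) <- "mt_gru_params"
  p
}

check_gru_params <- function(params) {
  H <- nrow(params$W_r)
  d <- ncol(params$W_r)
  for (nm in c("W_z", "W")) {
    if (!all(dim(params[[nm]]) == c(H, d))) stop("GRU weight ", nm, " has wrong shape")
  }
  for (nm in c("U_r", "U_z", "U")) {
    if (!all(dim(params[[nm]]) == c(H, H))) stop("GRU weight ", nm, " has wrong shape")
  }
  c(H = H, d = d)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU time step
#'
#' Applies the gated recurrence exactly in the convention used throughout
#' this package: reset gate r = sigmoid(W_r x + U_r h + b_r), update gate
#' z = sigmoid(W_z x + U_z h + b_z), candidate
#' h' = tanh(W x + r * (U h) + b_h), and new state
#' `h_t = z * h_prev + (1 - z) * h'`. Note the update gate multiplies the
#' PREVIOUS state — the mirror image of the convention in most deep-learning
#' libraries, where z gates the candidate; a stock fused GRU is therefore
#' not interchangeable with this cell without relabeling z as 1 - z.
#'
#' @param x input vector of length d, or a B x d matrix (one row per batch
#'   member).
#' @param h_prev previous hidden state, length H vector or B x H matrix.
#' @param params an `mt_gru_params`.
#' @return A list with `h` (new state), `r`, `z` (gate activations, each in
#'   (0,1)) and `candidate` (in (-1,1)), shaped like the input.
#' @export
gru_step <- function(x, h_prev, params) {
  dims <- check_gru_params(params)
  vec_in <- !is.matrix(x)
  X <- if (vec_in) matrix(x, nrow = 1L) else x
  Hp <- if (is.matrix(h_prev)) h_prev else matrix(h_prev, nrow = nrow(X),
                                                  ncol = length(h_prev),
                                                  byrow = TRUE)
  if (ncol(X) != dims["d"]) stop("input dimension ", ncol(X),
                                 " does not match GRU input size ", dims["d"])
  if (ncol(Hp) != dims["H"]) stop("hidden dimension mismatch")
  if (any(!is.finite(Hp))) stop("non-finite previous hidden state")
  r <- sigmoid(add_bias(X %*% t(params$W_r) + Hp %*% t(params$U_r), params$b_r))
  z <- sigmoid(add_bias(X %*% t(params$W_z) + Hp %*% t(params$U_z), params$b_z))
  cand <- tanh(add_bias(X %*% t(params$W) + r * (Hp %*% t(params$U)), params$b_h))
  h <- z * Hp + (1 - z) * cand
  if (vec_in) {
    list(h = drop(h), r = drop(r), z = drop(z), candidate = drop(cand))
  } else {
    list(h = h, r = r, z = z, candidate = cand)
  }
}

add_bias <- function(A, b) {
  if (all(b == 0)) A else sweep(A, 2L, b, "+")
}

#' Run a GRU over an embedded sequence
#'
#' Iterates [gru_step()] over the M rows of an embedding matrix with
#' `h_0 = 0`. The backward direction consumes the rows in reverse temporal
#' order and reports its hidden states re-aligned to the original
#' positions, so row i of the output is always the state at sequence
#' position i.
#'
#' @param rows M x d embedding matrix (one row per n-gram token).
#' @param params an `mt_gru_params`.
#' @param direction `"forward"` or `"backward"`.
#' @return M x H matrix of hidden states aligned to input positions.
#' @export
run_gru <- function(rows, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!is.matrix(rows)) rows <- matrix(rows, nrow = 1L)
  M <- nrow(rows)
  if (M < 1L) stop("empty input: at least one time step is required")
  dims <- check_gru_params(params)
  order_t <- if (direction == "forward") seq_len(M) else rev(seq_len(M))
  H <- matrix(0, nrow = M, ncol = dims["H"])
  h <- numeric(dims["H"])
  for (t in order_t) {
    h <- gru_step(rows[t, ], h, params)$h
    H[t, ] <- h
  }
  H
}

#' Encode a sequence with the bidirectional GRU + max-pooling
#'
#' Runs independent forward and backward GRUs over the embedding matrix,
#' concatenates the two states at each position, and takes the element-wise
#' maximum over positions. The result is one fixed-length vector of
#' dimension 2H per sequence, whatever the sequence length.
#'
#' @param rows M x d embedding matrix.
#' @param fwd,bwd `mt_gru_params` for the two directions (independent
#'   parameter sets).
#' @return Numeric vector of length 2H: the pooled shared representation.
#' @export
encode_sequence <- function(rows, fwd, bwd) {
  Hf <- run_gru(rows, fwd, "forward")
  Hb <- run_gru(rows, bwd, "backward")
  cc <- cbind(Hf, Hb)  # row i = (h_i^fwd, h_i^bwd)
  apply(cc, 2L, max)
}

## ---- batched internals (training/prediction hot path) ----
## One task minibatch: token matrix B x M (1-based vocab positions, 0 = pad)
## and mask B x M. Padded steps carry the state through unchanged and are
## excluded from pooling, so pad rows never contribute to the max.

bgru_direction_batch <- function(E, tok, mask, params, direction) {
  B <- nrow(tok); M <- ncol(tok)
  dims <- check_gru_params(params)
  Hdim <- as.integer(dims["H"])
  order_t <- if (direction == "forward") seq_len(M) else rev(seq_len(M))
  h <- matrix(0, B, Hdim)
  cache <- vector("list", M)
  Hs <- vector("list", M)
  for (t in order_t) {
    idx <- tok[, t]
    X <- E[pmax(idx, 1L), , drop = FALSE]
    st <- gru_step(X, h, params)
    m <- mask[, t]
    if (any(m == 0)) {
      h_new <- m * st$h + (1 - m) * h
    } else {
      h_new <- st$h
    }
    cache[[t]] <- list(X = X, idx = idx, h_prev = h, r = st$r, z = st$z,
                       cand = st$cand, m = m)
    h <- h_new
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache, order_t = order_t)
}

bgru_encode_batch <- function(E, tok, mask, fwd, bwd) {
  f <- bgru_direction_batch(E, tok, mask, fwd, "forward")
  b <- bgru_direction_batch(E, tok, mask, bwd, "backward")
  B <- nrow(tok); M <- ncol(tok); Hdim <- ncol(f$H[[1L]])
  neg <- -Inf
  y_f <- matrix(neg, B, Hdim); arg_f <- matrix(1L, B, Hdim)
  y_b <- matrix(neg, B, Hdim); arg_b <- matrix(1L, B, Hdim)
  for (t in seq_len(M)) {
    m <- mask[, t] == 1
    if (!any(m)) next
    cf <- f$H[[t]]; cb <- b$H[[t]]
    upd <- m & (cf > y_f)
    if (any(upd)) { y_f[upd] <- cf[upd]; arg_f[upd] <- t }
    upd <- m & (cb > y_b)
    if (any(upd)) { y_b[upd] <- cb[upd]; arg_b[upd] <- t }
  }
  list(Y = cbind(y_f, y_b), arg_f = arg_f, arg_b = arg_b, f = f, b = b)
}

## Backward pass through one GRU direction. dH: list over t of B x H
## gradients arriving at the hidden state of step t (from pooling).
## Returns gradients for params and the embedding table scatter list.
bgru_direction_backward <- function(E, tok, mask, params, fw, dH, embed_trainable) {
  B <- nrow(tok); M <- ncol(tok)
  dims <- check_gru_params(params)
  Hdim <- as.integer(dims["H"])
  g <- list(W_r = params$W_r * 0, U_r = params$U_r * 0,
            W_z = params$W_z * 0, U_z = params$U_z * 0,
            W = params$W * 0, U = params$U * 0,
            b_r = numeric(Hdim), b_z = numeric(Hdim), b_h = numeric(Hdim))
  dE <- if (embed_trainable) E * 0 else NULL
  dh <- matrix(0, B, Hdim)
  # walk time steps in reverse processing order
  for (t in rev(fw$order_t)) {
    cc <- fw$cache[[t]]
    dh <- dh + dH[[t]]
    m <- cc$m
    # masked rows pass gradient straight through to h_prev
    dh_step <- dh * m
    dh_carry <- dh * (1 - m)
    h_prev <- cc$h_prev; r <- cc$r; z <- cc$z; cand <- cc$cand; X <- cc$X
    dz <- dh_step * (h_prev - cand)
    dcand <- dh_step * (1 - z)
    dh_prev <- dh_step * z
    da_c <- dcand * (1 - cand^2)
    u <- h_prev %*% t(params$U)
    dr <- da_c * u
    du <- da_c * r
    g$W <- g$W + crossprod(da_c, X)
    g$U <- g$U + crossprod(du, h_prev)
    dh_prev <- dh_prev + du %*% params$U
    da_r <- dr * r * (1 - r)
    da_z <- dz * z * (1 - z)
    g$W_r <- g$W_r + crossprod(da_r, X)
    g$U_r <- g$U_r + crossprod(da_r, h_prev)
    g$W_z <- g$W_z + crossprod(da_z, X)
    g$U_z <- g$U_z + crossprod(da_z, h_prev)
    dh_prev <- dh_prev + da_r %*% params$U_r + da_z %*% params$U_z
    if (isTRUE(params$use_bias)) {
      g$b_r <- g$b_r + colSums(da_r)
      g$b_z <- g$b_z + colSums(da_z)
      g$b_h <- g$b_h + colSums(da_c)
    }
    if (embed_trainable) {
      dX <- da_r %*% params$W_r + da_z %*% params$W_z + da_c %*% params$W
      live <- which(m == 1)
      for (i in live) {
        j <- cc$idx[i]
        dE[j, ] <- dE[j, ] + dX[i, ]
      }
    }
    dh <- dh_prev + dh_carry
  }
  list(grads = g, dE = dE)
}
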