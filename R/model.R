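#' Assemble a multi-task BGRU model
#'
#' Builds the full network: a trainable word-embedding table (initialized to
#' the one-hot identity), a shared bidirectional GRU encoder with
#' max-pooling over time, and one fully connected stack per task ending in a
#' two-unit softmax. Hidden head layers apply affine -> batch normalization
#' -> ReLU; the output layer is affine -> softmax.
#'
#' By default each task's single hidden layer has width
#' `clamp(round(sqrt(n_train)), 16, 128)`, so heads scale with the amount of
#' task data; widths are overridable per task.
#'
#' @param registry an `mt_registry` defining the tasks.
#' @param hidden_dim shared-encoder hidden size H per direction (default 64).
#' @param ngram n-gram order for tokenization (default 2).
#' @param embed_dim word-embedding dimension d; default `4^ngram` (one-hot
#'   sized).
#' @param embed_mode `"trainable"` (one-hot initialized, learned) or
#'   `"frozen-one-hot"` (fixed identity embedding).
#' @param head_widths optional named list/vector: task name -> integer
#'   vector of hidden-layer widths for that head.
#' @param alpha per-task loss weights; scalar or named vector (default 1).
#' @param use_bias trainable GRU biases (default TRUE).
#' @param seed integer seed for parameter initialization.
#' @return An object of class `mt_model`.
#' @export
init_model <- function(registry, hidden_dim = 64L, ngram = 2L,
                       embed_dim = NULL, embed_mode = c("trainable", "frozen-one-hot"),
                       head_widths = NULL, alpha = 1, use_bias = TRUE,
                       seed = 1L) {
  stopifnot(inherits(registry, "mt_registry"))
  embed_mode <- match.arg(embed_mode)
  vocab <- build_vocabulary(ngram)
  V <- length(vocab$tokens)
  if (is.null(embed_dim)) embed_dim <- V
  if (embed_mode == "frozen-one-hot" && embed_dim != V) {
    stop("frozen-one-hot embedding requires embed_dim = ", V)
  }
  set.seed(as.integer(seed))
  E <- if (embed_dim == V) diag(V) else {
    matrix(stats::runif(V * embed_dim, -1 / sqrt(embed_dim), 1 / sqrt(embed_dim)),
           nrow = V)
  }
  rownames(E) <- vocab$tokens
  fwd <- init_gru_params(embed_dim, hidden_dim, use_bias = use_bias)
  bwd <- init_gru_params(embed_dim, hidden_dim, use_bias = use_bias)
  task_names <- names(registry$tasks)
  if (length(alpha) == 1L) alpha <- stats::setNames(rep(alpha, length(task_names)), task_names)
  if (any(alpha <= 0)) stop("task weights alpha must be positive")
  heads <- lapply(task_names, function(tn) {
    n_train <- nrow(registry$tasks[[tn]]$train)
    widths <- if (!is.null(head_widths) && !is.null(head_widths[[tn]])) {
      as.integer(head_widths[[tn]])
    } else {
      as.integer(min(max(round(sqrt(max(n_train, 1L))), 16L), 128L))
    }
    init_head(2L * hidden_dim, widths)
  })
  names(heads) <- task_names
  structure(list(
    version = 1L,
    vocab = vocab,
    embedding = E,
    embed_mode = embed_mode,
    fwd = fwd, bwd = bwd,
    heads = heads,
    alpha = alpha[task_names],
    hidden_dim = as.integer(hidden_dim),
    embed_dim = as.integer(embed_dim),
    seed = as.integer(seed),
    trained_steps = 0L
  ), class = "mt_model")
}

init_head <- function(input_dim, widths) {
  dims <- c(input_dim, widths)
  layers <- lapply(seq_along(widths), function(i) {
    fan_in <- dims[i]
    list(W = matrix(stats::runif(dims[i + 1L] * fan_in,
                                 -1 / sqrt(fan_in), 1 / sqrt(fan_in)),
                    nrow = dims[i + 1L]),
         b = numeric(dims[i + 1L]),
         gamma = rep(1, dims[i + 1L]),
         beta = numeric(dims[i + 1L]),
         run_mean = numeric(dims[i + 1L]),
         run_var = rep(1, dims[i + 1L]))
  })
  fan_in <- dims[length(dims)]
  list(layers = layers,
       out = list(W = matrix(stats::runif(2L * fan_in, -1 / sqrt(fan_in),
                                          1 / sqrt(fan_in)), nrow = 2L),
                  b = numeric(2L)),
       widths = widths)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

#' Task-head forward pass
#'
#' Applies a task's fully connected stack to pooled shared representations:
#' hidden layers affine -> batch-norm -> ReLU, then affine -> softmax. In
#' `"train"` mode batch statistics are used (and returned as updated running
#' statistics); in `"eval"` mode the stored running statistics are used, so
#' repeated calls are deterministic.
#'
#' @param y a length-2H vector or B x 2H matrix of shared representations.
#' @param head one element of `model$heads`.
#' @param mode `"eval"` (default) or `"train"`.
#' @param trained has the model taken at least one training step? Running
#'   statistics are undefined before training, so eval mode then errors.
#' @return A list with `p` (positive-class probability, length B), `probs`
#'   (B x 2 softmax matrix), `head` (with updated running stats in train
#'   mode) and `cache` (train mode only; used by backprop).
#' @export
head_forward <- function(y, head, mode = c("eval", "train"), trained = TRUE) {
  mode <- match.arg(mode)
  if (mode == "eval" && !isTRUE(trained)) {
    stop("eval mode requires batch-norm running statistics: ",
         "train the model for at least one step first")
  }
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  if (mode == "train" && nrow(Y) < 2L) {
    stop("batch normalization needs a minibatch of at least 2 in train mode")
  }
  cache <- list(input = Y, layers = vector("list", length(head$layers)))
  A <- Y
  for (i in seq_along(head$layers)) {
    ly <- head$layers[[i]]
    Z <- sweep(A %*% t(ly$W), 2L, ly$b, "+")
    if (mode == "train") {
      mu <- colMeans(Z)
      va <- colMeans(sweep(Z, 2L, mu)^2)
      B <- nrow(Z)
      head$layers[[i]]$run_mean <- (1 - bn_momentum) * ly$run_mean + bn_momentum * mu
      head$layers[[i]]$run_var <- (1 - bn_momentum) * ly$run_var +
        bn_momentum * va * B / max(B - 1L, 1L)
    } else {
      mu <- ly$run_mean
      va <- ly$run_var
    }
    ivar <- 1 / sqrt(va + bn_eps)
    xhat <- sweep(sweep(Z, 2L, mu), 2L, ivar, "*")
    Zbn <- sweep(sweep(xhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    Anew <- pmax(Zbn, 0)
    cache$layers[[i]] <- list(A_in = A, Z = Z, mu = mu, va = va, ivar = ivar,
                              xhat = xhat, Zbn = Zbn)
    A <- Anew
  }
  logits <- sweep(A %*% t(head$out$W), 2L, head$out$b, "+")
  probs <- softmax_rows(logits)
  cache$A_last <- A
  cache$logits <- logits
  cache$probs <- probs
  list(p = unname(probs[, 2L]), probs = probs, head = head, cache = cache)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  out <- ex / rowSums(ex)
  dimnames(out) <- NULL
  out
}

## Backprop through a head given dlogits (B x 2). Returns parameter grads
## and the gradient w.r.t. the head input (B x 2H).
head_backward <- function(head, cache, dlogits) {
  g <- list(layers = vector("list", length(head$layers)), out = NULL)
  g$out <- list(W = crossprod(dlogits, cache$A_last), b = colSums(dlogits))
  dA <- dlogits %*% head$out$W
  for (i in rev(seq_along(head$layers))) {
    ly <- head$layers[[i]]
    cc <- cache$layers[[i]]
    dZbn <- dA * (cc$Zbn > 0)
    dgamma <- colSums(dZbn * cc$xhat)
    dbeta <- colSums(dZbn)
    dxhat <- sweep(dZbn, 2L, ly$gamma, "*")
    B <- nrow(dxhat)
    sum_dxhat <- colSums(dxhat)
    sum_dxhat_xhat <- colSums(dxhat * cc$xhat)
    dZ <- sweep(B * dxhat, 2L, sum_dxhat) -
      sweep(cc$xhat, 2L, sum_dxhat_xhat, "*")
    dZ <- sweep(dZ, 2L, cc$ivar / B, "*")
    g$layers[[i]] <- list(W = crossprod(dZ, cc$A_in), b = colSums(dZ),
                          gamma = dgamma, beta = dbeta)
    dA <- dZ %*% ly$W
  }
  list(grads = g, dinput = dA)
}

## Tokenize a character vector of sequences into a padded token matrix +
## mask, using the model's vocabulary.
token_matrix <- function(seqs, vocab) {
  toks <- lapply(seqs, function(s) unname(tokenize(s, vocab)))
  M <- max(vapply(toks, length, 1L))
  B <- length(toks)
  tok <- matrix(0L, B, M)
  mask <- matrix(0, B, M)
  for (i in seq_len(B)) {
    m <- length(toks[[i]])
    tok[i, seq_len(m)] <- toks[[i]]
    mask[i, seq_len(m)] <- 1
  }
  list(tok = tok, mask = mask)
}

## Shared-encoder forward for a batch of sequences -> B x 2H matrix.
encode_batch <- function(model, seqs, keep_cache = FALSE) {
  tm <- token_matrix(seqs, model$vocab)
  enc <- bgru_encode_batch(model$embedding, tm$tok, tm$mask, model$fwd, model$bwd)
  if (keep_cache) c(enc, list(tok = tm$tok, mask = tm$mask)) else enc$Y
}

#' Predict modification-site probabilities
#'
#' Full eval-mode forward pass (validate -> tokenize -> embed -> BGRU+pool
#' -> task head -> softmax) for a batch of sequences routed through one
#' task's head.
#'
#' @param model a trained `mt_model`.
#' @param seqs character vector of A/C/G/T sequences.
#' @param task task name; must be one of the model's registered tasks.
#' @param threshold decision threshold for hard calls (default 0.5).
#' @return data.frame with columns `seq`, `task`, `p` (positive-class
#'   probability) and `call`.
#' @export
predict_sites <- function(model, seqs, task, threshold = 0.5) {
  stopifnot(inherits(model, "mt_model"))
  if (!task %in% names(model$heads)) {
    stop("unknown task '", task, "'; registered tasks: ",
         paste(names(model$heads), collapse = ", "))
  }
  seqs <- vapply(seqs, validate_seq, character(1L), USE.NAMES = FALSE)
  Y <- encode_batch(model, seqs)
  hf <- head_forward(Y, model$heads[[task]], mode = "eval",
                     trained = model$trained_steps > 0L)
  data.frame(seq = seqs, task = task, p = hf$p,
             call = as.integer(hf$p >= threshold), stringsAsFactors = FALSE)
}

#' Forward pass for one labeled sequence
#'
#' @param model a trained `mt_model`.
#' @param seq one A/C/G/T sequence.
#' @param task task name routing the sequence to its head.
#' @return Positive-class probability (scalar).
#' @export
forward_one <- function(model, seq, task) {
  predict_sites(model, seq, task)$p
}

#' @export
print.mt_model <- function(x, ...) {
  cat("Multi-task BGRU model: H =", x$hidden_dim, "per direction, d =",
      x$embed_dim, ", n-gram =", x$vocab$n, "\n")
  cat("Tasks:", paste(names(x$heads), collapse = ", "), "\n")
  cat("Trained steps:", x$trained_steps, "\n")
  invisible(x)
}

checkpoint_version <- 1L

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized archive carrying a format version,
#' all learnable parameters, batch-norm running statistics, the vocabulary
#' and every hyperparameter, so `load_checkpoint(save_checkpoint(m, p))`
#' reproduces predictions bit-identically.
#'
#' @param model an `mt_model`.
#' @param path file path.
#' @return `path` invisibly for save; the restored `mt_model` for load.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mt_model"))
  obj <- list(format = "methylMT-checkpoint", version = checkpoint_version,
              model = unclass(model))
  saveRDS(obj, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt checkpoint '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "methylMT-checkpoint")) {
    stop("corrupt checkpoint '", path, "': not a model checkpoint")
  }
  if (!identical(obj$version, checkpoint_version)) {
    stop("checkpoint version ", obj$version, " not supported (expected ",
         checkpoint_version, ")")
  }
  structure(obj$model, class = "mt_model")
}

## ---- flat parameter access (optimizer + gradient checks) ----

## Returns a named list of trainable leaf arrays in a fixed order.
trainable_params <- function(model) {
  out <- list()
  if (model$embed_mode == "trainable") out$embedding <- model$embedding
  for (dir in c("fwd", "bwd")) {
    p <- model[[dir]]
    nms <- c("W_r", "U_r", "W_z", "U_z", "W", "U")
    if (isTRUE(p$use_bias)) nms <- c(nms, "b_r", "b_z", "b_h")
    for (nm in nms) out[[paste0(dir, ".", nm)]] <- p[[nm]]
  }
  for (tn in names(model$heads)) {
    hd <- model$heads[[tn]]
    for (i in seq_along(hd$layers)) {
      for (nm in c("W", "b", "gamma", "beta")) {
        out[[paste0("head.", tn, ".L", i, ".", nm)]] <- hd$layers[[i]][[nm]]
      }
    }
    out[[paste0("head.", tn, ".out.W")]] <- hd$out$W
    out[[paste0("head.", tn, ".out.b")]] <- hd$out$b
  }
  out
}

set_trainable_params <- function(model, values) {
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (nm == "embedding") {
      dimnames(values[[nm]]) <- dimnames(model$embedding)
      model$embedding <- values[[nm]]
    } else if (parts[1L] %in% c("fwd", "bwd")) {
      model[[parts[1L]]][[parts[2L]]] <- values[[nm]]
    } else {
      tn <- paste(parts[2:(length(parts) - 2L)], collapse = ".")
      slot <- parts[length(parts) - 1L]
      leaf <- parts[length(parts)]
      if (slot == "out") {
        model$heads[[tn]]$out[[leaf]] <- values[[nm]]
      } else {
        i <- as.integer(sub("^L", "", slot))
        model$heads[[tn]]$layers[[i]][[leaf]] <- values[[nm]]
      }
    }
  }
  model
}

flatten_params <- function(values) unlist(values, use.names = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[pos + seq_len(n)]
    if (is.matrix(template[[nm]])) {
      out[[nm]] <- matrix(v, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      out[[nm]] <- v
    }
    pos <- pos + n
  }
  out
}

## Stable fingerprint of all trainable parameters (reproducibility checks).
param_hash <- function(model) {
  v <- flatten_params(trainable_params(model))
  paste0(format(sum(v), digits = 17), ":", format(sum(v^2), digits = 17),
         ":", length(v))
}
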