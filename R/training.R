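#' Binary cross-entropy loss
#'
#' Mean of `-[y log p + (1-y) log(1-p)]` with probabilities clipped to
#' `[eps, 1-eps]` to keep the logarithms finite.
#'
#' @param p predicted positive-class probabilities in `[0,1]`.
#' @param y binary labels (0/1), same length as `p`.
#' @param eps probability clip (default 1e-7).
#' @return Scalar loss (non-negative).
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y)) stop("p and y must have the same length")
  if (length(p) < 1L) stop("empty loss input")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  pt <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(pt) + (1 - y) * log(1 - pt))
}

#' Weighted global multi-task loss
#'
#' Linear combination `sum_k alpha_k * l_k` of per-task losses.
#'
#' @param task_losses numeric vector of per-task losses.
#' @param alpha positive per-task weights, same length.
#' @return Scalar.
#' @export
global_loss <- function(task_losses, alpha) {
  if (length(task_losses) != length(alpha)) {
    stop("task_losses and alpha must have the same length")
  }
  if (any(alpha <= 0)) stop("alpha weights must be positive")
  sum(alpha * task_losses)
}

#' Sample a task for one training step
#'
#' Uses the caller's RNG state: `"uniform"` picks each of the K tasks with
#' probability 1/K; `"proportional"` picks with probability proportional to
#' the task's training-set size.
#'
#' @param registry an `mt_registry` (or an integer K for uniform mode).
#' @param mode `"uniform"` (default) or `"proportional"`.
#' @return Integer task index in 1..K.
#' @export
sample_task <- function(registry, mode = c("uniform", "proportional")) {
  mode <- match.arg(mode)
  if (inherits(registry, "mt_registry")) {
    K <- length(registry$tasks)
    sizes <- vapply(registry$tasks, function(t) nrow(t$train), 1L)
  } else {
    K <- as.integer(registry)
    sizes <- rep(1L, K)
  }
  if (K < 1L) stop("registry has no tasks")
  prob <- if (mode == "uniform") rep(1 / K, K) else sizes / sum(sizes)
  sample.int(K, 1L, prob = prob)
}

#' Training configuration
#'
#' @param steps number of stochastic gradient steps; default
#'   `200 * ceiling(n_train_total / batch_size)` (an epochs-equivalent
#'   budget) when `NULL`.
#' @param batch_size minibatch size per step (default 32; must be at least
#'   2 because hidden head layers use batch normalization).
#' @param lr Adam learning rate (default 1e-3).
#' @param alpha per-task loss weights (scalar or named vector; default 1).
#' @param sampling task-sampling mode, `"uniform"` or `"proportional"`.
#' @param seed global RNG seed driving initialization, task sampling,
#'   minibatch sampling and the validation split.
#' @param eps BCE probability clip.
#' @param early_stopping keep the best-on-validation model (mean validation
#'   AUC over tasks, patience in evaluations)?
#' @param validation_frac fraction of each task's training split held out
#'   for validation when early stopping is on (default 0.1).
#' @param eval_every evaluate validation AUC every this many steps.
#' @param patience evaluations without improvement before stopping.
#' @return A list of class `mt_training_config`.
#' @export
training_config <- function(steps = NULL, batch_size = 32L, lr = 1e-3,
                            alpha = 1, sampling = c("uniform", "proportional"),
                            seed = 1L, eps = 1e-7, early_stopping = FALSE,
                            validation_frac = 0.1, eval_every = 100L,
                            patience = 10L) {
  sampling <- match.arg(sampling)
  if (batch_size < 2L) stop("batch_size must be at least 2 (batch normalization)")
  if (any(alpha <= 0)) stop("alpha weights must be positive")
  structure(list(steps = steps, batch_size = as.integer(batch_size), lr = lr,
                 alpha = alpha, sampling = sampling, seed = as.integer(seed),
                 eps = eps, early_stopping = isTRUE(early_stopping),
                 validation_frac = validation_frac,
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience)),
            class = "mt_training_config")
}

## Loss + gradients for one task minibatch. Returns list(loss, grads) with
## grads named like trainable_params(); only the shared parameters, the
## embedding (if trainable) and the selected task's head receive gradients.
minibatch_grads <- function(model, seqs, labels, task, alpha_k, eps) {
  enc <- encode_batch(model, seqs, keep_cache = TRUE)
  hf <- head_forward(enc$Y, model$heads[[task]], mode = "train")
  p <- hf$p
  loss <- alpha_k * bce_loss(p, labels, eps = eps)
  B <- length(labels)
  onehot <- cbind(1 - labels, labels)
  live <- as.numeric(p > eps & p < 1 - eps)  # clipped samples get zero grad
  dlogits <- alpha_k * (hf$probs - onehot) * live / B
  hb <- head_backward(model$heads[[task]], hf$cache, dlogits)
  Hdim <- model$hidden_dim
  M <- ncol(enc$tok)
  dY_f <- hb$dinput[, seq_len(Hdim), drop = FALSE]
  dY_b <- hb$dinput[, Hdim + seq_len(Hdim), drop = FALSE]
  scatter <- function(dY, arg) {
    dH <- lapply(seq_len(M), function(t) matrix(0, B, Hdim))
    for (j in seq_len(Hdim)) {
      for (i in seq_len(B)) {
        t <- arg[i, j]
        dH[[t]][i, j] <- dH[[t]][i, j] + dY[i, j]
      }
    }
    dH
  }
  dH_f <- scatter(dY_f, enc$arg_f)
  dH_b <- scatter(dY_b, enc$arg_b)
  trainable_emb <- model$embed_mode == "trainable"
  gb_f <- bgru_direction_backward(model$embedding, enc$tok, enc$mask,
                                  model$fwd, enc$f, dH_f, trainable_emb)
  gb_b <- bgru_direction_backward(model$embedding, enc$tok, enc$mask,
                                  model$bwd, enc$b, dH_b, trainable_emb)
  grads <- list()
  if (trainable_emb) grads$embedding <- gb_f$dE + gb_b$dE
  for (dir in c("fwd", "bwd")) {
    g <- if (dir == "fwd") gb_f$grads else gb_b$grads
    nms <- c("W_r", "U_r", "W_z", "U_z", "W", "U")
    if (isTRUE(model[[dir]]$use_bias)) nms <- c(nms, "b_r", "b_z", "b_h")
    for (nm in nms) grads[[paste0(dir, ".", nm)]] <- g[[nm]]
  }
  hg <- hb$grads
  for (i in seq_along(hg$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      grads[[paste0("head.", task, ".L", i, ".", nm)]] <- hg$layers[[i]][[nm]]
    }
  }
  grads[[paste0("head.", task, ".out.W")]] <- hg$out$W
  grads[[paste0("head.", task, ".out.b")]] <- hg$out$b
  list(loss = loss, grads = grads, head = hf$head)
}

#' Train the multi-task model
#'
#' The stochastic task-interleaved loop: at each step a task is sampled, a
#' minibatch is drawn from that task's training split, and one Adam step is
#' taken on that task's weighted binary cross-entropy. The shared encoder
#' (and embedding) receives gradients on every step; each head only on the
#' steps its task is sampled.
#'
#' @param registry an `mt_registry`.
#' @param config an `mt_training_config` (see [training_config()]).
#' @param model optionally, a pre-initialized `mt_model`; by default one is
#'   initialized from the registry and `config$seed`.
#' @param ... passed to [init_model()] when `model` is NULL (e.g.
#'   `hidden_dim`).
#' @return A list of class `mt_fit`: `model` (trained), `trace` (data.frame
#'   step/task/loss), `config`, and `validation` (data.frame of validation
#'   AUC evaluations when early stopping was on).
#' @export
fit <- function(registry, config = training_config(), model = NULL, ...) {
  stopifnot(inherits(registry, "mt_registry"))
  set.seed(config$seed)
  if (is.null(model)) {
    model <- init_model(registry, alpha = config$alpha, seed = config$seed, ...)
  }
  task_names <- names(registry$tasks)
  alpha <- model$alpha
  n_train <- vapply(registry$tasks, function(t) nrow(t$train), 1L)
  if (config$batch_size > min(n_train)) {
    stop("batch_size (", config$batch_size,
         ") exceeds the smallest task training size (", min(n_train), ")")
  }
  steps <- config$steps
  if (is.null(steps)) {
    steps <- 200L * as.integer(ceiling(sum(n_train) / config$batch_size))
  }
  # optional held-out validation split for early stopping
  train_idx <- lapply(registry$tasks, function(t) seq_len(nrow(t$train)))
  val_idx <- NULL
  if (config$early_stopping) {
    val_idx <- lapply(registry$tasks, function(t) {
      n <- nrow(t$train)
      sample.int(n, max(2L, floor(config$validation_frac * n)))
    })
    train_idx <- mapply(function(a, v) setdiff(a, v), train_idx, val_idx,
                        SIMPLIFY = FALSE)
    small <- min(vapply(train_idx, length, 1L))
    if (config$batch_size > small) {
      stop("batch_size exceeds the post-validation-split training size (",
           small, ")")
    }
  }
  opt <- list(m = NULL, v = NULL, t = 0L)
  trace <- data.frame(step = integer(steps), task = character(steps),
                      loss = numeric(steps), stringsAsFactors = FALSE)
  validation <- data.frame(step = integer(0), mean_auc = numeric(0))
  best <- list(model = NULL, auc = -Inf, since = 0L)
  for (s in seq_len(steps)) {
    k <- sample_task(registry, config$sampling)
    tn <- task_names[k]
    pool <- train_idx[[tn]]
    take <- sample(pool, config$batch_size)
    batch <- registry$tasks[[tn]]$train[take, , drop = FALSE]
    mg <- minibatch_grads(model, batch$seq, batch$label, tn,
                          alpha_k = alpha[[tn]], eps = config$eps)
    if (!is.finite(mg$loss)) {
      stop("non-finite loss at step ", s, " (task ", tn,
           "); try a smaller learning rate")
    }
    model$heads[[tn]] <- mg$head  # batch-norm running stats
    upd <- adam_update(trainable_params(model), mg$grads, opt, lr = config$lr)
    model <- set_trainable_params(model, upd$values)
    opt <- upd$opt
    model$trained_steps <- model$trained_steps + 1L
    trace$step[s] <- s
    trace$task[s] <- tn
    trace$loss[s] <- mg$loss
    if (config$early_stopping && s %% config$eval_every == 0L) {
      aucs <- vapply(task_names, function(tn2) {
        v <- registry$tasks[[tn2]]$train[val_idx[[tn2]], , drop = FALSE]
        if (length(unique(v$label)) < 2L) return(NA_real_)
        pr <- predict_sites(model, v$seq, tn2)
        roc_auc(v$label, pr$p)$auc
      }, numeric(1L))
      mauc <- mean(aucs, na.rm = TRUE)
      validation <- rbind(validation, data.frame(step = s, mean_auc = mauc))
      if (mauc > best$auc) {
        best$auc <- mauc
        best$model <- model
        best$since <- 0L
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$patience) break
      }
    }
  }
  done <- trace$step > 0
  trace <- trace[done, , drop = FALSE]
  if (config$early_stopping && !is.null(best$model)) model <- best$model
  structure(list(model = model, trace = trace, config = config,
                 validation = validation), class = "mt_fit")
}

#' Train a single-task baseline
#'
#' Identical machinery with K = 1: restricts the registry to one task and
#' calls [fit()]. This is the ablation baseline against which the
#' multi-task benefit is measured.
#'
#' @param registry an `mt_registry`.
#' @param task name of the task to keep.
#' @inheritParams fit
#' @return An `mt_fit`.
#' @export
fit_single_task <- function(registry, task, config = training_config(), ...) {
  if (!task %in% names(registry$tasks)) {
    stop("unknown task '", task, "'; registry has: ",
         paste(names(registry$tasks), collapse = ", "))
  }
  sub <- registry
  sub$tasks <- registry$tasks[task]
  sub$modification <- registry$modification[task]
  fit(sub, config = config, ...)
}

## One Adam step. Leaves without a gradient this step (other tasks' heads)
## are left untouched, mirroring per-parameter lazy optimizers.
adam_update <- function(values, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        adam_eps = 1e-8) {
  if (is.null(opt$m)) {
    opt$m <- lapply(values, function(v) v * 0)
    opt$v <- lapply(values, function(v) v * 0)
    opt$t <- 0L
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    values[[nm]] <- values[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
  }
  list(values = values, opt = opt)
}

#' Training loss of a fixed minibatch (diagnostic)
#'
#' Computes the weighted BCE of one minibatch without updating anything;
#' used by gradient checks and descent tests.
#'
#' @param model an `mt_model`.
#' @param seqs,labels the minibatch.
#' @param task task name.
#' @param alpha_k task weight.
#' @param eps BCE clip.
#' @return Scalar loss.
#' @export
minibatch_loss <- function(model, seqs, labels, task, alpha_k = 1, eps = 1e-7) {
  enc <- encode_batch(model, seqs)
  hf <- head_forward(enc, model$heads[[task]], mode = "train")
  alpha_k * bce_loss(hf$p, labels, eps = eps)
}
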