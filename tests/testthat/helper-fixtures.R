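# Shared fixtures and independent oracles used across the suite.

# Straight-line scalar-loop GRU: no vectorization, indexes every weight
# explicitly. Independent oracle for the production encoder.
naive_gru <- function(rows, p, direction = "forward") {
  M <- nrow(rows); H <- nrow(p$W_r); d <- ncol(p$W_r)
  ord <- if (direction == "forward") seq_len(M) else rev(seq_len(M))
  h <- rep(0, H)
  out <- matrix(0, M, H)
  for (t in ord) {
    x <- rows[t, ]
    r <- z <- cand <- hn <- numeric(H)
    for (j in seq_len(H)) {
      ar <- p$b_r[j]; az <- p$b_z[j]; ac <- p$b_h[j]; u <- 0
      for (q in seq_len(d)) {
        ar <- ar + p$W_r[j, q] * x[q]
        az <- az + p$W_z[j, q] * x[q]
        ac <- ac + p$W[j, q] * x[q]
      }
      for (q in seq_len(H)) {
        ar <- ar + p$U_r[j, q] * h[q]
        az <- az + p$U_z[j, q] * h[q]
        u <- u + p$U[j, q] * h[q]
      }
      r[j] <- 1 / (1 + exp(-ar))
      z[j] <- 1 / (1 + exp(-az))
      cand[j] <- tanh(ac + r[j] * u)
      hn[j] <- z[j] * h[j] + (1 - z[j]) * cand[j]
    }
    h <- hn
    out[t, ] <- h
  }
  out
}

random_gru_params <- function(d, H, with_bias = TRUE) {
  p <- init_gru_params(d, H, use_bias = with_bias)
  if (with_bias) {
    p$b_r <- stats::runif(H, -0.5, 0.5)
    p$b_z <- stats::runif(H, -0.5, 0.5)
    p$b_h <- stats::runif(H, -0.5, 0.5)
  }
  p
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

# small balanced two-task registry built in code
tiny_registry <- function(seed = 1L, n = 12L, len = 15L) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(c("tA", "tB"), function(tn) {
    do.call(rbind, lapply(c("train", "test"), function(sp) {
      data.frame(id = paste0(tn, "_", sp, "_", seq_len(2L * n)),
                 seq = random_dna(2L * n, len),
                 label = rep(c(0L, 1L), each = n),
                 task = tn, split = sp, stringsAsFactors = FALSE)
    }))
  }))
  multitask_registry(recs)
}

# tiny trained model + its registry (cached per session; several tests only
# need "a model with running batch-norm statistics")
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_tasks = 2L, n_train = 24L, n_test = 12L,
                             length = 15L, shared_motif = "GACG",
                             task_motifs = c("TTGA", "CCAT"), seed = 11L)
      ds <- generate_dataset(spec)
      res <- fit(ds$registry, training_config(steps = 40L, batch_size = 12L,
                                              seed = 11L), hidden_dim = 6L)
      cache <<- list(model = res$model, registry = ds$registry, fit = res)
    }
    cache
  }
})
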