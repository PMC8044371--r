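test_that("binary cross-entropy matches hand arithmetic", {
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(bce_loss(rep(0.5, 7), c(1, 0, 1, 0, 1, 0, 1)), log(2))
  expect_equal(bce_loss(0.25, 1), -log(0.25))
  set.seed(8)
  p <- stats::runif(50); y <- stats::rbinom(50, 1, 0.5)
  expect_equal(bce_loss(p, y),
               mean(-(y * log(p) + (1 - y) * log(1 - p))), tolerance = 1e-9)
  expect_error(bce_loss(c(0.2, 0.3), 1), "length")
  expect_error(bce_loss(1.2, 1), "0, 1")
})

test_that("global loss is the alpha-weighted sum of task losses", {
  expect_equal(global_loss(0.37, 1), 0.37)
  expect_equal(global_loss(c(0.5, 2), c(2, 0.5)), 2.0)
  set.seed(9)
  l <- stats::runif(6); a <- stats::runif(6, 0.1, 3)
  expect_equal(global_loss(l, a), sum(a * l))
  expect_error(global_loss(c(1, 2), 1), "length")
  expect_error(global_loss(1, -1), "positive")
})

test_that("task sampling is seeded and uniform across tasks", {
  reg <- tiny_registry()
  set.seed(10); a <- replicate(20, sample_task(reg))
  set.seed(10); b <- replicate(20, sample_task(reg))
  expect_identical(a, b)
  expect_equal(sample_task(1L), 1L)
  set.seed(11)
  draws <- replicate(40000, sample_task(4L))
  freq <- tabulate(draws, 4) / 40000
  expect_true(all(freq >= 0.24 & freq <= 0.26))
})

test_that("proportional sampling tracks training-set sizes", {
  spec <- synthetic_spec(n_tasks = 2L, n_train = c(30L, 10L), n_test = 5L,
                         length = 15L, shared_motif = "GACG", seed = 12L)
  reg <- generate_dataset(spec)$registry
  set.seed(12)
  draws <- replicate(20000, sample_task(reg, "proportional"))
  expect_equal(mean(draws == 1L), 0.75, tolerance = 0.02)
})

test_that("analytic gradients match finite differences on a tiny model", {
  ns <- asNamespace("methylMT")
  spec <- synthetic_spec(n_tasks = 1L, n_train = 8L, n_test = 4L,
                         length = 9L, shared_motif = "GAC",
                         task_motifs = "TTG", seed = 3L)
  ds <- generate_dataset(spec)
  model <- init_model(ds$registry, hidden_dim = 2L, embed_dim = 4L,
                      head_widths = list(task1 = 3L), seed = 5L)
  batch <- ds$registry$tasks$task1$train[1:6, ]
  mg <- ns$minibatch_grads(model, batch$seq, batch$label, "task1",
                           alpha_k = 1.3, eps = 1e-7)
  tp <- ns$trainable_params(model)
  analytic <- ns$flatten_params(mg$grads[names(tp)])
  flat <- ns$flatten_params(tp)
  h <- 1e-6
  numeric <- vapply(seq_along(flat), function(i) {
    up <- flat; up[i] <- up[i] + h
    dn <- flat; dn[i] <- dn[i] - h
    lu <- minibatch_loss(ns$set_trainable_params(model, ns$unflatten_params(up, tp)),
                         batch$seq, batch$label, "task1", alpha_k = 1.3)
    ld <- minibatch_loss(ns$set_trainable_params(model, ns$unflatten_params(dn, tp)),
                         batch$seq, batch$label, "task1", alpha_k = 1.3)
    (lu - ld) / (2 * h)
  }, numeric(1))
  rel <- sqrt(sum((numeric - analytic)^2)) / sqrt(sum(numeric^2))
  expect_lt(rel, 1e-4)
})

test_that("a small gradient step decreases the loss on a fixed minibatch", {
  ns <- asNamespace("methylMT")
  tt <- tiny_trained()
  reg <- tt$registry
  model <- init_model(reg, hidden_dim = 4L, seed = 6L)
  batch <- reg$tasks$task1$train[1:8, ]
  l0 <- minibatch_loss(model, batch$seq, batch$label, "task1")
  mg <- ns$minibatch_grads(model, batch$seq, batch$label, "task1",
                           alpha_k = 1, eps = 1e-7)
  tp <- ns$trainable_params(model)
  full <- lapply(stats::setNames(names(tp), names(tp)), function(nm) {
    if (is.null(mg$grads[[nm]])) tp[[nm]] * 0 else mg$grads[[nm]]
  })
  stepped <- ns$unflatten_params(
    ns$flatten_params(tp) - 1e-4 * ns$flatten_params(full), tp)
  m1 <- ns$set_trainable_params(model, stepped)
  expect_lt(minibatch_loss(m1, batch$seq, batch$label, "task1"), l0)
})

test_that("fit validates its inputs and is reproducible", {
  reg <- tiny_registry(n = 10L)  # 20 train per task
  expect_error(fit(reg, training_config(steps = 5L, batch_size = 32L, seed = 1L)),
               "smallest task")
  expect_error(training_config(batch_size = 1L), "at least 2")
  cfg <- training_config(steps = 15L, batch_size = 8L, seed = 7L)
  r1 <- fit(reg, cfg, hidden_dim = 4L)
  r2 <- fit(reg, cfg, hidden_dim = 4L)
  expect_identical(r1$trace, r2$trace)
  expect_equal(nrow(r1$trace), 15L)
  expect_true(all(is.finite(r1$trace$loss)) && all(r1$trace$loss >= 0))
  expect_equal(r1$model$trained_steps, 15L)
})

test_that("single-task fitting is fit() on the restricted registry", {
  reg <- tiny_registry(n = 10L)
  cfg <- training_config(steps = 10L, batch_size = 8L, seed = 8L)
  one <- reg
  one$tasks <- reg$tasks["tA"]
  one$modification <- reg$modification["tA"]
  ra <- fit_single_task(reg, "tA", cfg, hidden_dim = 4L)
  rb <- fit(one, cfg, hidden_dim = 4L)
  expect_identical(ra$trace, rb$trace)
  expect_length(ra$model$heads, 1L)
  expect_true(all(ra$trace$task == "tA"))
  ev <- evaluate_model(ra$model, reg)
  expect_true(all(is.finite(ev$AUC)))
  expect_error(fit_single_task(reg, "nope", cfg), "unknown task")
})

test_that("early stopping tracks validation AUC and can stop before budget", {
  spec <- synthetic_spec(n_tasks = 2L, n_train = 40L, n_test = 10L,
                         length = 15L, shared_motif = "GACG", seed = 13L)
  reg <- generate_dataset(spec)$registry
  cfg <- training_config(steps = 60L, batch_size = 8L, seed = 13L,
                         early_stopping = TRUE, eval_every = 10L,
                         patience = 2L)
  r <- fit(reg, cfg, hidden_dim = 4L)
  expect_gt(nrow(r$validation), 0L)
  expect_true(all(r$validation$mean_auc >= 0 & r$validation$mean_auc <= 1))
  expect_lte(nrow(r$trace), 60L)
})
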