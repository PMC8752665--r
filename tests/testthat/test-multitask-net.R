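small_cfg <- function(...) {
  args <- utils::modifyList(list(embedding_dim = 16, recurrent_units = 12,
                                 conv_filters = 8, shared_mlp_units = 16,
                                 epochs = 80, seed = 5), list(...))
  do.call(multitask_config, args)
}

fixture_tasks <- function(seed = 3) {
  set.seed(seed)
  tfx <- make_marker_texts(c("past", "present", "future"), 20)
  efx <- make_marker_texts(c("joy", "sadness", "anger", "fear"), 15)
  eint <- rep(c(0.8, 0.4, 0.3, 0.6), each = 15)
  list(temporal = list(tokens = tokenize_tweet(tfx$texts), label = tfx$labels),
       emotion = list(tokens = tokenize_tweet(efx$texts), emotion = efx$labels,
                      intensity = eint),
       tlab = tfx$labels, elab = efx$labels, eint = eint)
}

test_that("config validation rejects out-of-range settings", {
  expect_error(multitask_config(dropout = 1), "dropout")
  expect_error(multitask_config(embedding_dim = 0))
  expect_error(multitask_config(optimizer = "sgd"), "rmsprop")
})

test_that("embedding tables copy known vectors and seed the rest reproducibly", {
  vocab <- c("<pad>", "<unk>", "cat", "dog", "eel")
  p <- tempfile(fileext = ".txt")
  writeLines(c("cat 1 2 3", "dog 4 5 6", "yak 7 8 9"), p)
  E <- load_word_vectors(vocab, 3, path = p, seed = 2)
  expect_equal(E["cat", ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(E["dog", ], c(4, 5, 6), ignore_attr = TRUE)
  expect_equal(E["<pad>", ], rep(0, 3), ignore_attr = TRUE)
  E2 <- load_word_vectors(vocab, 3, path = p, seed = 2)
  expect_identical(E, E2)
  writeLines(c("cat 1 2 3", "dog 4 5"), p)
  expect_error(load_word_vectors(vocab, 3, path = p), "line 2")
})

test_that("the shared encoder honours shape, determinism and batch order", {
  fx <- fixture_tasks()
  cfg <- small_cfg(epochs = 2)
  m <- train_multitask(fx$temporal, fx$emotion, config = cfg)
  toks <- fx$temporal$tokens[1:4]
  s <- encode_batch(m, toks)
  expect_equal(dim(s), c(4L, 16L))
  expect_identical(encode_batch(m, toks), s)
  perm <- c(3, 1, 4, 2)
  expect_equal(encode_batch(m, toks[perm]), s[perm, ], tolerance = 1e-12)
  expect_error(encode_batch(m, list()), "empty")
})

test_that("analytic gradients match finite differences for both task heads", {
  ns <- asNamespace("tempemo")
  set.seed(9)
  cfg <- multitask_config(embedding_dim = 5, recurrent_units = 4,
                          conv_filters = 3, conv_filter_size = 3,
                          shared_mlp_units = 4, dropout = 0, seed = 2)
  vocab <- c("<pad>", "<unk>", letters[1:8])
  p <- ns$init_params(cfg, vocab)
  idx <- list(c(3L, 4L, 5L), c(6L, 7L), c(8L, 9L, 10L, 3L))
  y <- c(1L, 3L, 2L); ye <- c(2L, 4L, 1L); it <- c(0.3, 0.8, 0.5)
  loss_fn <- function(p, task) {
    fw <- ns$forward_shared(idx, p, cfg, NULL)
    hf <- ns$head_forward(fw$s, p, task)
    if (task == "temporal") -mean(log(hf$probs[cbind(1:3, y)]))
    else -mean(log(hf$probs[cbind(1:3, ye)])) + mean((hf$intensity - it)^2)
  }
  for (task in c("temporal", "emotion")) {
    fw <- ns$forward_shared(idx, p, cfg, NULL)
    hf <- ns$head_forward(fw$s, p, task)
    hb <- ns$head_loss_backward(fw$s, hf, p, task,
                                if (task == "temporal") y else ye, it)
    g <- c(hb$grads, ns$backward_shared(hb$ds, fw, p, cfg))
    for (nm in names(g)) {
      n_check <- min(length(p[[nm]]), 5)
      for (i in sample(seq_along(p[[nm]]), n_check)) {
        if (nm == "E" && (i - 1) %% nrow(p$E) + 1 == 1) next  # pad row frozen
        eps <- 1e-6
        p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (loss_fn(p1, task) - loss_fn(p2, task)) / (2 * eps)
        expect_equal(as.numeric(g[[nm]])[i], num, tolerance = 1e-5,
                     info = paste(task, nm, i))
      }
    }
  }
})

test_that("training overfits a separable fixture on both tasks and is seeded", {
  fx <- fixture_tasks()
  m <- train_multitask(fx$temporal, fx$emotion, config = small_cfg())
  pt <- predict_multitask(m, fx$temporal$tokens)
  pe <- predict_multitask(m, fx$emotion$tokens)
  expect_gte(mean(pt$temporal_label == fx$tlab), 0.95)
  expect_gte(mean(pe$emotion_label == fx$elab), 0.95)
  expect_true(all(abs(rowSums(pt[, paste0("p_", TEMPORAL_CLASSES)]) - 1) < 1e-6))
  expect_true(all(pe$intensity >= 0 & pe$intensity <= 1))
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  m2 <- train_multitask(fx$temporal, fx$emotion, config = small_cfg())
  expect_identical(predict_multitask(m2, fx$temporal$tokens), pt)
})

test_that("gradients from either task move the shared encoder parameters", {
  ns <- asNamespace("tempemo")
  fx <- fixture_tasks()
  cfg <- small_cfg(epochs = 1, dropout = 0)
  shared_names <- c("E", "f.Wz", "b.Wz", "C.W", "S.W")
  for (task in c("temporal", "emotion")) {
    set.seed(1)
    vocab <- build_vocab(c(fx$temporal$tokens, fx$emotion$tokens))
    p <- ns$init_params(cfg, vocab)
    vmap <- setNames(seq_along(vocab), vocab)
    dat <- if (task == "temporal") fx$temporal else fx$emotion
    idx <- lapply(dat$tokens[1:8], ns$tokens_to_idx, vocab_map = vmap)
    y <- if (task == "temporal") temporal_code(dat$label[1:8])
         else match(dat$emotion[1:8], c("joy", "sadness", "anger", "fear"))
    fw <- ns$forward_shared(idx, p, cfg, NULL)
    hf <- ns$head_forward(fw$s, p, task)
    hb <- ns$head_loss_backward(fw$s, hf, p, task, y, dat$intensity[1:8])
    g <- ns$backward_shared(hb$ds, fw, p, cfg)
    for (nm in shared_names)
      expect_gt(sum(abs(g[[nm]])), 0, label = paste(task, nm))
  }
})

test_that("the single-task ablation trains the same encoder with one head", {
  fx <- fixture_tasks()
  m <- train_multitask(fx$temporal, emotion_data = NULL,
                       config = small_cfg())
  expect_equal(m$tasks, "temporal")
  pt <- predict_multitask(m, fx$temporal$tokens)
  expect_gte(mean(pt$temporal_label == fx$tlab), 0.95)
  expect_false("emotion_hard" %in% names(pt))
})

test_that("evaluation metrics match hand-worked values", {
  perfect <- data.frame(temporal_hard = c(1, 2, 3), emotion_hard = c(1, 2, 4),
                        intensity = c(0.1, 0.5, 0.9))
  ev <- evaluate_predictions(perfect, list(temporal = c(1, 2, 3),
                                           emotion = c(1, 2, 4),
                                           intensity = c(0.1, 0.5, 0.9)))
  expect_equal(ev$temporal$accuracy, 1)
  expect_equal(unname(ev$emotion$f1[c(1, 2, 4)]), rep(1, 3))
  expect_equal(ev$intensity$pearson_r, 1)
  inv <- data.frame(temporal_hard = c(1, 1), intensity = c(1, 0))
  ev2 <- evaluate_predictions(inv, list(intensity = c(0, 1)))
  expect_equal(ev2$intensity$pearson_r, -1)
  # hand-computed 3x3 confusion: gold (1,1,2,2,3,3), pred (1,2,2,2,3,1)
  ev3 <- evaluate_predictions(data.frame(temporal_hard = c(1, 2, 2, 2, 3, 1)),
                              list(temporal = c(1, 1, 2, 2, 3, 3)))
  expect_equal(unname(ev3$temporal$precision), c(1/2, 2/3, 1))
  expect_equal(unname(ev3$temporal$recall), c(1/2, 1, 1/2))
  expect_equal(ev3$temporal$accuracy, 4/6)
  # degenerate gold intensity is flagged, not an error
  ev4 <- evaluate_predictions(data.frame(intensity = c(0.2, 0.4)),
                              list(intensity = c(0.5, 0.5)))
  expect_false(ev4$intensity$defined)
})
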