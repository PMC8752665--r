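test_that("factor features concatenate the three indicator blocks", {
  S <- correlation_set(rbind(c(1, 2)))
  f <- factor_features(c(1L, 1L), y = 1, S = S)
  expect_equal(unname(f), c(1, 1, 1, 1, 1))
  f2 <- factor_features(c(0L, 2L), y = 1, S = correlation_set())
  expect_equal(unname(f2), c(0, 0, 0, 1))
  f3 <- factor_features(c(0L, 0L, 0L), y = 2, S = correlation_set())
  expect_equal(unname(f3[1:6]), rep(0, 6))
})

test_that("zero-weight NLL equals the closed form M * L * log(K + 1)", {
  for (dims in list(c(1, 2), c(7, 3), c(13, 4))) {
    lam <- random_label_matrix(dims[1], dims[2])
    w0 <- factor_weights(rep(0, dims[2]))
    expect_equal(neg_log_marginal_likelihood(w0, lam),
                 dims[1] * dims[2] * log(4), tolerance = 1e-12)
  }
})

test_that("NLL and posteriors agree with brute-force joint enumeration", {
  set.seed(42)
  for (case in 1:25) {
    M <- sample(1:5, 1); L <- sample(1:4, 1)
    lam <- random_label_matrix(M, L)
    S <- if (L >= 2 && runif(1) < 0.5) correlation_set(rbind(c(1, 2))) else correlation_set()
    w_acc <- rnorm(L); w_lab <- rnorm(L, sd = 0.5); w_corr <- rnorm(nrow(S))
    w <- factor_weights(w_acc, w_lab, if (nrow(S)) w_corr else NULL, S)
    expect_equal(neg_log_marginal_likelihood(w, lam),
                 bf_nll(w_acc, w_lab, w_corr, S, lam), tolerance = 1e-8)
    post <- posterior_labels(w, lam)
    for (p in seq_len(M))
      expect_equal(unname(post$probs[p, ]),
                   bf_posterior_row(unclass(lam)[p, ], w_acc, w_lab, w_corr, S),
                   tolerance = 1e-10)
  }
})

test_that("posterior rows are normalised, uniform on abstains, monotone on accuracy", {
  lam <- label_matrix(rbind(c(0L, 0L, 0L), c(2L, 2L, 2L), c(1L, 2L, 0L)))
  w <- factor_weights(c(1, 1, 1), c(0.2, 0.2, 0.2))
  post <- posterior_labels(w, lam)
  expect_equal(rowSums(post$probs), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(post$probs[1, ]), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(post$hard[2], 2L)
  expect_false(post$informative[1])
})

test_that("fitting recovers accuracy ordering and beats majority vote", {
  set.seed(7)
  truth <- sample(1:3, 1000, TRUE)
  specs <- list(lf_spec(0.9, 0.9), lf_spec(0.7, 0.9), lf_spec(0.5, 0.9))
  lam <- simulate_lf_matrix(truth, specs, seed = 21)
  w <- fit_generative(lam)
  expect_true(w$acc[1] > w$acc[2] && w$acc[2] > w$acc[3])
  tr <- attr(w, "trace")
  expect_true(all(diff(tr) <= 1e-12))
  post <- posterior_labels(w, lam)
  expect_gte(mean(post$hard == truth), mean(majority_vote(lam) == truth) - 0.01)
})

test_that("a single perfect labeller is recovered exactly", {
  truth <- rep(1:3, each = 10)
  lam <- simulate_lf_matrix(truth, list(lf_spec(1, 1)), seed = 3)
  w <- fit_generative(lam)
  post <- posterior_labels(w, lam)
  expect_equal(post$hard, truth)
})

test_that("column permutation permutes weights and leaves posteriors unchanged", {
  set.seed(8)
  truth <- sample(1:3, 400, TRUE)
  lam <- simulate_lf_matrix(truth, list(lf_spec(0.85, 0.9), lf_spec(0.6, 0.8),
                                        lf_spec(0.7, 1)), seed = 4)
  perm <- c(3, 1, 2)
  lam_p <- label_matrix(unclass(lam)[, perm])
  w <- fit_generative(lam); w_p <- fit_generative(lam_p)
  expect_equal(unname(w_p$acc), unname(w$acc[perm]), tolerance = 1e-4)
  post <- posterior_labels(w, lam); post_p <- posterior_labels(w_p, lam_p)
  expect_equal(unname(post_p$probs), unname(post$probs), tolerance = 1e-4)
})

test_that("structure estimation finds planted agreement and skips independents", {
  set.seed(10)
  truth <- sample(1:3, 2000, TRUE)
  specs <- list(lf_spec(0.7, 0.9),
                lf_spec(0.7, 0.9, copy_of = 1, agreement = 0.95),
                lf_spec(0.6, 0.9), lf_spec(0.6, 0.9))
  lam <- simulate_lf_matrix(truth, specs, seed = 31)
  S <- estimate_structure(lam)
  has_pair <- function(S, q, r) any(S[, 1] == q & S[, 2] == r)
  expect_true(has_pair(S, 1, 2))
  expect_false(has_pair(S, 3, 4))
})

test_that("structure estimation degenerate cases return empty sets", {
  lam1 <- random_label_matrix(100, 1)
  expect_equal(nrow(estimate_structure(lam1)), 0L)
  small <- random_label_matrix(10, 3)
  expect_warning(S <- estimate_structure(small), "20 rows")
  expect_equal(nrow(S), 0L)
  m <- matrix(0L, 50, 3); m[1, 1] <- 1L
  expect_equal(nrow(estimate_structure(label_matrix(m))), 0L)
})

test_that("L is capped for the exact normaliser", {
  lam <- random_label_matrix(5, 11)
  expect_error(fit_generative(lam), "L <= 10")
})

test_that("balanced training selection honours counts, ranking and abstains", {
  probs <- rbind(c(0.8, 0.1, 0.1), c(0.7, 0.2, 0.1), c(0.1, 0.9, 0.0),
                 c(0.2, 0.6, 0.2), c(0.1, 0.1, 0.8), c(0.3, 0.1, 0.6),
                 c(1/3, 1/3, 1/3), c(0.9, 0.05, 0.05))
  lam <- label_matrix(rbind(1L, 1L, 2L, 2L, 3L, 3L, 0L, 1L))
  co <- tweet_corpus(paste0("t", 1:8), rep("x", 8))
  rownames(probs) <- co$id
  post <- posterior_labels(factor_weights(1), lam)
  post$probs <- probs
  post$hard <- max.col(probs, ties.method = "first")
  post$informative <- unclass(lam)[, 1] != 0
  sel <- select_balanced_training(post, co, 6)
  expect_equal(unname(table(sel$label)[TEMPORAL_CLASSES]), rep(2L, 3),
               ignore_attr = TRUE)
  # class-wise descending confidence; the all-abstain tweet t7 is excluded
  expect_false("t7" %in% sel$id)
  expect_equal(sel$id[sel$label == "past"], c("t8", "t1"))
  # remainder rule: n = 7 gives (3, 2, 2) by fixed class order
  sel7 <- select_balanced_training(post, co, 7)
  expect_equal(unname(table(sel7$label)[TEMPORAL_CLASSES]), c(3L, 2L, 2L),
               ignore_attr = TRUE)
  expect_error(select_balanced_training(post, co, 12), "achievable")
})

test_that("factor weights round-trip through JSON", {
  S <- correlation_set(rbind(c(1, 3), c(2, 3)))
  w <- factor_weights(c(0.5, -0.2, 1.1), c(0, 0.3, -0.1), c(0.9, 0.01), S)
  names(w$acc) <- names(w$lab) <- c("a", "b", "c")
  p <- tempfile(fileext = ".json")
  write_factor_weights(w, p)
  back <- read_factor_weights(p)
  expect_equal(back$acc, w$acc)
  expect_equal(back$lab, w$lab)
  expect_equal(back$corr, w$corr)
  expect_equal(unclass(back$S), unclass(w$S), ignore_attr = TRUE)
})
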