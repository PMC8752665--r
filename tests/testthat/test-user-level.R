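test_that("intensity bins honour the printed half-open boundaries", {
  expect_equal(as.character(bin_intensity(c(0, 0.2499, 0.25, 0.49, 0.5,
                                            0.749, 0.75, 0.875, 1))),
               c("VLI", "VLI", "LI", "LI", "MI", "MI", "HI", "HI", "HI"))
  expect_error(bin_intensity(1.2), "0,1")
  expect_error(bin_intensity(-0.1), "0,1")
})

test_that("ordinal conversion lands each class strictly inside its bin, in order", {
  expect_equal(as.character(bin_intensity(convert_ordinal_intensity(0:3))),
               c("VLI", "LI", "MI", "HI"))
})

test_that("user aggregation reproduces the fraction arithmetic", {
  pred <- data.frame(
    user_id = c(rep("u1", 10), rep("u2", 4)),
    temporal_hard = c(rep(1, 4), rep(2, 3), rep(3, 3), rep(1, 4)),
    emotion_hard = c(rep(1, 5), rep(2, 5), 1, 1, 3, 4),
    intensity = c(rep(0.5, 10), 0.3, 0.8, 0.1, 0.9))
  ua <- aggregate_users(pred)
  u1 <- ua[ua$user_id == "u1", ]
  expect_equal(c(u1$frac_past, u1$frac_present, u1$frac_future),
               c(0.4, 0.3, 0.3))
  u2 <- ua[ua$user_id == "u2", ]
  expect_equal(c(u2$frac_past, u2$frac_present, u2$frac_future), c(1, 0, 0))
  # 2 joy tweets at 0.3 and 0.8 out of 4 -> joy LI and joy HI each 0.25
  expect_equal(u2$frac_joy_LI, 0.25)
  expect_equal(u2$frac_joy_HI, 0.25)
  expect_equal(u2$frac_joy, 0.5)
  pred$user_id[1] <- NA
  expect_error(aggregate_users(pred), "user_id")
})

test_that("aggregation conserves mass on a simulated population", {
  sim <- simulate_corpus(population_spec(n_users = 40, tweets_per_user = c(3, 12),
                                         seed = 14))
  pred <- data.frame(user_id = sim$truth$user_id,
                     temporal_hard = temporal_code(sim$truth$temporal),
                     emotion_hard = match(sim$truth$emotion,
                                          c("joy", "sadness", "anger", "fear")),
                     intensity = sim$truth$intensity)
  ua <- aggregate_users(pred)
  expect_equal(nrow(ua), 40L)
  ofr <- as.matrix(ua[, paste0("frac_", TEMPORAL_CLASSES)])
  efr <- as.matrix(ua[, paste0("frac_", c("joy", "sadness", "anger", "fear"))])
  expect_true(all(abs(rowSums(ofr) - 1) < 1e-9))
  expect_true(all(abs(rowSums(efr) - 1) < 1e-9))
  for (e in c("joy", "sadness", "anger", "fear")) {
    bins <- as.matrix(ua[, paste0("frac_", e, "_", c("VLI", "LI", "MI", "HI"))])
    expect_true(all(abs(rowSums(bins) - ua[[paste0("frac_", e)]]) < 1e-9))
  }
})

test_that("pearson correlation matches the closed form and flags degeneracy", {
  users <- data.frame(user_id = letters[1:5],
                      frac_future = c(0.1, 0.3, 0.5, 0.6, 0.9),
                      frac_joy = c(0.2, 0.25, 0.45, 0.5, 0.8),
                      frac_fear = c(0.9, 0.7, 0.5, 0.4, 0.1),
                      flat = rep(0.2, 5))
  x <- users$frac_future; y <- users$frac_joy
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ct <- correlate(users, "frac_future", "frac_joy")
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  expect_equal(ct$n, 5L)
  # y = 1 - x is an exact negative
  expect_equal(correlate(users, "frac_future", "frac_fear")$r, -1,
               tolerance = 1e-9)
  expect_equal(correlate(users, "frac_future", "frac_future")$r, 1)
  # symmetry and affine invariance
  expect_equal(correlate(users, "frac_joy", "frac_future")$r, ct$r)
  users$scaled <- 3 * users$frac_joy - 1
  expect_equal(correlate(users, "frac_future", "scaled")$r, ct$r,
               tolerance = 1e-12)
  flagged <- correlate(users, "frac_future", "flat")
  expect_false(flagged$defined)
  expect_true(is.na(flagged$r))
})

test_that("significance follows the t distribution on n - 2 df", {
  set.seed(2)
  users <- data.frame(frac_future = rnorm(30))
  users$frac_joy <- 0.5 * users$frac_future + rnorm(30, sd = 0.5)
  ct <- correlate(users, "frac_future", "frac_joy")
  tt <- ct$r * sqrt((ct$n - 2) / (1 - ct$r^2))
  expect_equal(ct$p_value, 2 * pt(-abs(tt), df = ct$n - 2), tolerance = 1e-12)
})

test_that("the correlation matrix covers 3x4 class and 3x16 bin cells", {
  sim <- simulate_corpus(population_spec(n_users = 300, tweets_per_user = 20,
                                         seed = 15))
  pred <- data.frame(user_id = sim$truth$user_id,
                     temporal_hard = temporal_code(sim$truth$temporal),
                     emotion_hard = match(sim$truth$emotion,
                                          c("joy", "sadness", "anger", "fear")),
                     intensity = sim$truth$intensity)
  ua <- aggregate_users(pred)
  cm <- correlation_matrix(ua)
  expect_equal(nrow(cm), 3 * 4 + 3 * 16)
  jf <- cm[cm$x == "frac_future" & cm$y == "frac_joy", ]
  expect_gt(jf$r, 0)
  expect_true(jf$significant)
})

test_that("mcnemar utility compares paired classifiers on discordant errors", {
  gold <- rep(1:3, each = 20)
  pred_a <- gold; pred_a[1:5] <- 2          # 5 errors
  pred_b <- gold; pred_b[c(1, 21:35)] <- 3  # 16 errors
  ht <- mcnemar_compare(pred_a, pred_b, gold)
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.05)
})
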