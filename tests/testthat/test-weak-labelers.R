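test_that("lexicon labeller matches, abstains, and resolves conflicts", {
  lex <- make_lexicon(c("yesterday", "tomorrow"), c("past", "future"))
  co <- tweet_corpus(c("a", "b", "c"),
                     c("i loved yesterday", "hello world",
                       "yesterday and tomorrow"))
  expect_equal(lf_lexicon(co, lex), c(1L, 0L, 0L))
  # majority rule votes by count, ties abstain
  lex2 <- make_lexicon(c("yesterday", "ago", "tomorrow"),
                       c("past", "past", "future"))
  co2 <- tweet_corpus("a", "yesterday ago tomorrow")
  expect_equal(lf_lexicon(co2, lex2, conflict = "majority"), 1L)
  expect_equal(lf_lexicon(co2, lex2, conflict = "abstain"), 0L)
  expect_error(lf_lexicon(co, make_lexicon(character(0), character(0))), "empty")
})

test_that("keyword labeller validates disjoint lists and reuses lexicon semantics", {
  sets <- default_keyword_sets()
  expect_true(all(lengths(sets) == 30))
  co <- tweet_corpus(c("a", "b"), c("see you tomorrow", "just plain stuff"))
  expect_equal(lf_keyword(co, sets), c(3L, 0L))
  sets$past <- c(sets$past, "tomorrow")
  expect_error(lf_keyword(co, sets), "overlap")
})

test_that("verb-tense labeller follows the tag rule table with future precedence", {
  co <- tweet_corpus(c("a", "b", "c", "d", "e"),
                     c("i walked home", "we will go", "nice day",
                       "i am watching it", "she walked and will walk"))
  out <- lf_pos_verb(co)
  expect_equal(out, c(1L, 3L, 0L, 2L, 3L))
})

test_that("the rule tagger emits aligned Penn-style tags", {
  toks <- tokenize_tweet("i walked home !!")
  tags <- rule_pos_tag(toks)
  expect_length(tags, length(toks))
  expect_equal(tags[1:2], c("PRP", "VBD"))
  expect_equal(tags[4], ".")
})

test_that("weak classifiers memorise a separable seed corpus and never abstain", {
  set.seed(11)
  fx <- make_marker_texts(c("past", "present", "future"), 10)
  co <- tweet_corpus(sprintf("s%02d", seq_along(fx$texts)), fx$texts)
  m <- train_weak_model("svm", co, fx$labels)
  pred <- predict(m, co)
  expect_true(all(pred %in% 1:3))
  expect_equal(pred, temporal_code(fx$labels))
  # unseen tweets still get a non-abstain label
  co2 <- tweet_corpus("x", "filler01 filler02 filler03")
  expect_true(predict(m, co2) %in% 1:3)
  expect_error(train_weak_model("svm", co[1:20, ], fx$labels[1:20]), "future")
})

test_that("the recurrent weak model trains and predicts full labels", {
  set.seed(12)
  fx <- make_marker_texts(c("past", "present", "future"), 10)
  co <- tweet_corpus(sprintf("s%02d", seq_along(fx$texts)), fx$texts)
  m <- train_weak_model("birnn", co, fx$labels,
                        config = list(epochs = 30, seed = 3))
  pred <- predict(m, co)
  expect_true(all(pred %in% 1:3))
  expect_gte(mean(pred == temporal_code(fx$labels)), 0.9)
})

test_that("label matrix assembly preserves shape, order and determinism", {
  lex <- make_lexicon(c("yesterday", "tomorrow"), c("past", "future"))
  co <- tweet_corpus(c("a", "b"), c("i loved yesterday", "hello"))
  lfs <- list(lex = function(x) lf_lexicon(x, lex),
              pos = function(x) lf_pos_verb(x),
              mute = function(x) rep(0L, nrow(x)))
  lam <- build_label_matrix(co, lfs)
  expect_equal(dim(lam), c(2L, 3L))
  expect_equal(colnames(lam), c("lex", "pos", "mute"))
  expect_equal(unclass(lam)[, "mute"], c(a = 0L, b = 0L))
  expect_identical(unclass(build_label_matrix(co, lfs)), unclass(lam))
})

test_that("a failing labeling function records abstain with a warning", {
  co <- tweet_corpus(c("a", "b"), c("one", "two"))
  lfs <- list(bad = function(x) {
    if (any(x$text == "two")) stop("boom")
    rep(1L, nrow(x))
  })
  expect_warning(lam <- build_label_matrix(co, lfs), "boom")
  expect_equal(unname(unclass(lam)[, 1]), c(1L, 0L))
})

test_that("accuracy-1 simulated labellers equal the truth off their abstains", {
  set.seed(5)
  truth <- sample(1:3, 200, TRUE)
  lam <- simulate_lf_matrix(truth, list(lf_spec(1, 0.7), lf_spec(1, 1)), seed = 9)
  m <- unclass(lam)
  expect_true(all(m[m[, 1] != 0, 1] == truth[m[, 1] != 0]))
  expect_equal(unname(m[, 2]), truth)
})

test_that("label matrices round-trip through TSV with codes intact", {
  lam <- random_label_matrix(20, 3)
  p <- tempfile(fileext = ".tsv")
  write_label_matrix(lam, p)
  back <- read_label_matrix(p)
  expect_identical(unclass(back), unclass(lam))
  s <- label_matrix_summary(lam)
  expect_equal(unname(s$coverage), unname(colMeans(unclass(lam) != 0)))
  expect_equal(diag(s$agreement), rep(1, 3), ignore_attr = TRUE)
})
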