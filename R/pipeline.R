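# Pipeline orchestration: simulate -> weak-label -> fit-labels -> train ->
# predict -> aggregate -> correlate, driven by a single config document with
# one global seed. Each stage reads/writes the flat-file formats of corpus_io
# so a run is fully reproducible from its config.

#' Default pipeline configuration
#'
#' @param dir working directory for all pipeline artifacts.
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(dir = "pipeline_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    dir = dir,
    paths = list(
      tweets = "tweets.tsv", truth = "truth.tsv",
      emotion_train = "emotion_train.tsv",
      label_matrix = "label_matrix.tsv",
      posterior = "posterior.tsv", weights = "weights.json",
      train_set = "train_temporal.tsv",
      model = "model.rds", model_config = "model_config.json",
      metrics = "train_metrics.csv",
      predictions = "predictions.tsv", users = "users.csv",
      correlations = "correlations.csv"),
    simulate = list(n_users = 300L, tweets_per_user = 20L,
                    association = "planted"),
    weak = list(use_svm = TRUE, use_birnn = TRUE, seed_fraction = 0.05,
                conflict = "abstain"),
    fit = list(threshold = 0.15, learning_rate = 0.5, iterations = 300L,
               l2 = 0, train_n = 900L),
    model = list(embedding_dim = 32L, recurrent_units = 16L,
                 conv_filters = 12L, conv_filter_size = 7L,
                 shared_mlp_units = 24L, dropout = 0.2, batch_size = 64L,
                 epochs = 30L, emotion_n = 900L, single_task = FALSE),
    aggregate = list(min_tweets = 1L),
    correlate = list(alpha = 0.05)
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values in the file override the defaults of [default_pipeline_config()];
#' anything omitted keeps its default.
#' @param path config file (.yaml/.yml or .json).
#' @param seed optional seed override (e.g. from the command line).
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

p_path <- function(cfg, key) file.path(cfg$dir, cfg$paths[[key]])

#' Simulate a synthetic study population to disk
#'
#' Writes the tweet table, the latent truth table, and a balanced emotion
#' training file (per-emotion equal samples with true class and intensity,
#' standing in for an external emotion-annotated corpus).
#'
#' @param config pipeline configuration list.
#' @return invisibly, the simulated corpus and truth.
#' @export
pipeline_simulate <- function(config) {
  dir.create(config$dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$simulate
  emo <- switch(if (is.null(sc$association)) "planted" else sc$association,
                planted = planted_emotion_matrix(),
                independent = independent_emotion_matrix(),
                stop("unknown association scenario: ", sc$association))
  spec <- population_spec(n_users = sc$n_users,
                          tweets_per_user = sc$tweets_per_user,
                          emotion_given_orientation = emo,
                          seed = config$seed)
  sim <- simulate_corpus(spec)
  write_tweets(sim$corpus, p_path(config, "tweets"))
  utils::write.table(sim$truth, p_path(config, "truth"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # balanced per-emotion training sample from the truth
  n_e <- if (is.null(config$model$emotion_n)) 900L else config$model$emotion_n
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  per <- n_e %/% 4L
  sel <- unlist(lapply(EMOTION_CLASSES, function(e) {
    i <- which(sim$truth$emotion == e)
    sample(i, min(per, length(i)))
  }))
  er <- emotion_records(id = sim$truth$id[sel], text = sim$corpus$text[sel],
                        emotion = sim$truth$emotion[sel],
                        intensity = sim$truth$intensity[sel],
                        dialect = "real", user_id = sim$truth$user_id[sel])
  write_emotion_file(er, p_path(config, "emotion_train"))
  invisible(sim)
}

read_truth <- function(config) {
  utils::read.delim(p_path(config, "truth"), sep = "\t",
                    colClasses = c(intensity = "numeric"),
                    stringsAsFactors = FALSE)
}

require_artifact <- function(config, key, stage) {
  p <- p_path(config, key)
  if (!file.exists(p))
    stop("missing artifact '", cfg_name(key), "' (", p,
         "): run the '", stage, "' stage first")
  p
}
cfg_name <- function(key) key

#' Apply the weak labellers and write the label matrix
#'
#' Builds the five-source label matrix: two marker-lexicon heuristics (a
#' partially overlapping pair), the verb-tense heuristic, and (optionally) an
#' SVM and a bidirectional-RNN weak classifier trained on a small truth-
#' labeled seed sample. Logs per-function coverage and pairwise agreement.
#'
#' @param config pipeline configuration list.
#' @param verbose print coverage summary.
#' @return invisibly, the \code{label_matrix}.
#' @export
pipeline_weak_label <- function(config, verbose = FALSE) {
  require_artifact(config, "tweets", "simulate")
  corpus <- read_tweets(p_path(config, "tweets"))
  wk <- config$weak
  lfs <- list(
    lex_a = function(co) lf_lexicon(co, marker_lexicon(1:3), conflict = wk$conflict),
    lex_b = function(co) lf_lexicon(co, marker_lexicon(3:5), conflict = wk$conflict),
    pos_verb = function(co) lf_pos_verb(co))
  if (isTRUE(wk$use_svm) || isTRUE(wk$use_birnn)) {
    truth <- read_truth(config)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(config$seed + 2L)
    n_seed <- max(30L, ceiling(nrow(corpus) * wk$seed_fraction))
    sel <- sample(nrow(corpus), min(n_seed, nrow(corpus)))
    seed_corpus <- corpus[sel, , drop = FALSE]
    seed_labels <- truth$temporal[sel]
    if (isTRUE(wk$use_svm)) {
      svm_m <- train_weak_model("svm", seed_corpus, seed_labels)
      lfs$svm <- as_labeling_function(svm_m)
    }
    if (isTRUE(wk$use_birnn)) {
      rnn_m <- train_weak_model("birnn", seed_corpus, seed_labels,
                                config = list(seed = config$seed + 3L,
                                              epochs = 40))
      lfs$birnn <- as_labeling_function(rnn_m)
    }
  }
  lambda <- build_label_matrix(corpus, lfs)
  write_label_matrix(lambda, p_path(config, "label_matrix"))
  if (verbose) {
    s <- label_matrix_summary(lambda)
    message("coverage: ", paste(sprintf("%s=%.3f", names(s$coverage),
                                        s$coverage), collapse = " "))
  }
  invisible(lambda)
}

#' Fit the generative model and emit the balanced training set
#'
#' Runs structure estimation, marginal-likelihood fitting, posterior
#' computation and balanced training-set selection; writes the posterior
#' table, the fitted weights and the selected training records.
#'
#' @param config pipeline configuration list.
#' @return invisibly, a list with weights, posterior and training records.
#' @export
pipeline_fit_labels <- function(config) {
  require_artifact(config, "label_matrix", "weak-label")
  lambda <- read_label_matrix(p_path(config, "label_matrix"))
  corpus <- read_tweets(p_path(config, "tweets"))
  ft <- config$fit
  S <- estimate_structure(lambda, threshold = ft$threshold)
  w <- fit_generative(lambda, S, learning_rate = ft$learning_rate,
                      iterations = ft$iterations, l2 = ft$l2)
  post <- posterior_labels(w, lambda)
  train <- select_balanced_training(post, corpus, ft$train_n)
  write_factor_weights(w, p_path(config, "weights"))
  write_posterior(post, p_path(config, "posterior"))
  utils::write.table(train[, c("id", "user_id", "text", "label", "confidence")],
                     p_path(config, "train_set"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(weights = w, posterior = post, train = train))
}

#' Train the multi-task discriminator from pipeline artifacts
#'
#' Temporal task data are the generatively labeled balanced training set;
#' emotion task data are the emotion training file. \code{single_task = TRUE}
#' trains the temporal-only ablation with the same encoder.
#'
#' @param config pipeline configuration list.
#' @param single_task override the config's \code{model$single_task}.
#' @return invisibly, the trained model.
#' @export
pipeline_train <- function(config, single_task = NULL) {
  require_artifact(config, "train_set", "fit-labels")
  mc <- config$model
  if (is.null(single_task)) single_task <- isTRUE(mc$single_task)
  tr <- utils::read.delim(p_path(config, "train_set"), stringsAsFactors = FALSE)
  temporal <- list(tokens = tokenize_tweet(tr$text), label = tr$label)
  emotion <- NULL
  if (!single_task) {
    require_artifact(config, "emotion_train", "simulate")
    er <- read_emotion_file(p_path(config, "emotion_train"), dialect = "real")
    emotion <- list(tokens = er$tokens, emotion = er$emotion,
                    intensity = er$intensity)
  }
  cfg <- multitask_config(embedding_dim = mc$embedding_dim,
                          recurrent_units = mc$recurrent_units,
                          conv_filters = mc$conv_filters,
                          conv_filter_size = mc$conv_filter_size,
                          shared_mlp_units = mc$shared_mlp_units,
                          dropout = mc$dropout, batch_size = mc$batch_size,
                          epochs = mc$epochs, seed = config$seed + 4L)
  model <- train_multitask(temporal, emotion, config = cfg)
  saveRDS(model, p_path(config, "model"))
  jsonlite::write_json(unclass(cfg), p_path(config, "model_config"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$history, p_path(config, "metrics"), row.names = FALSE)
  invisible(model)
}

#' Predict all tweets with the trained model
#' @param config pipeline configuration list.
#' @return invisibly, the predictions data frame.
#' @export
pipeline_predict <- function(config) {
  require_artifact(config, "model", "train")
  model <- readRDS(p_path(config, "model"))
  corpus <- read_tweets(p_path(config, "tweets"))
  pred <- predict_multitask(model, corpus)
  pred$user_id <- corpus$user_id
  utils::write.table(pred, p_path(config, "predictions"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(pred)
}

#' Aggregate predictions to user level
#' @param config pipeline configuration list.
#' @return invisibly, the user aggregates.
#' @export
pipeline_aggregate <- function(config) {
  require_artifact(config, "predictions", "predict")
  pred <- utils::read.delim(p_path(config, "predictions"),
                            stringsAsFactors = FALSE)
  users <- aggregate_users(pred, min_tweets = config$aggregate$min_tweets)
  write_user_csv(users, p_path(config, "users"))
  invisible(users)
}

#' Correlate user-level orientation and emotion measures
#' @param config pipeline configuration list.
#' @return invisibly, the correlation report.
#' @export
pipeline_correlate <- function(config) {
  require_artifact(config, "users", "aggregate")
  users <- utils::read.csv(p_path(config, "users"), stringsAsFactors = FALSE)
  rep <- correlation_matrix(users, alpha = config$correlate$alpha)
  write_user_csv(rep, p_path(config, "correlations"))
  invisible(rep)
}

#' Run the full pipeline
#' @param config pipeline configuration list.
#' @param verbose print stage progress.
#' @return invisibly, a list with the final correlation report and paths.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulate"); pipeline_simulate(config)
  say("weak-label"); pipeline_weak_label(config, verbose = verbose)
  say("fit-labels"); pipeline_fit_labels(config)
  say("train"); pipeline_train(config)
  say("predict"); pipeline_predict(config)
  say("aggregate"); users <- pipeline_aggregate(config)
  say("correlate"); rep <- pipeline_correlate(config)
  invisible(list(users = users, correlations = rep, dir = config$dir))
}
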