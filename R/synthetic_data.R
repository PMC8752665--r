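# Synthetic-data generators: labeling-function outputs with controlled
# accuracy / propensity / pairwise agreement, and user populations of
# marker-token tweets with a configurable orientation-emotion association.
# They make every pipeline stage testable offline and provide the oracle for
# the user-level correlation analysis.

#' Specification of one simulated labeling function
#'
#' @param accuracy probability of emitting the true class when not abstaining,
#'   in (0, 1]; errors are uniform over the wrong classes.
#' @param propensity probability of not abstaining, in [0, 1].
#' @param copy_of optional index of an earlier labeling function whose
#'   emission this one reproduces with probability \code{agreement} (plants a
#'   pairwise correlation); otherwise it emits independently.
#' @param agreement copy probability when \code{copy_of} is set.
#' @return an \code{lf_spec} list.
#' @export
lf_spec <- function(accuracy, propensity = 1, copy_of = NULL, agreement = 0.95) {
  stopifnot(accuracy > 0, accuracy <= 1, propensity >= 0, propensity <= 1,
            agreement >= 0, agreement <= 1)
  structure(list(accuracy = accuracy, propensity = propensity,
                 copy_of = copy_of, agreement = agreement), class = "lf_spec")
}

#' Simulate a label matrix from latent truth
#'
#' Independent labeling functions abstain with probability
#' \code{1 - propensity}; otherwise they emit the true class with probability
#' \code{accuracy} and a uniformly chosen wrong class otherwise. A
#' \code{copy_of} function reproduces its source's emission with the stated
#' agreement probability and emits independently (per its own accuracy and
#' propensity) otherwise. A source must precede its copier in \code{specs}.
#'
#' @param truth integer vector of latent classes in 1..K.
#' @param specs list of [lf_spec()]s.
#' @param seed integer seed.
#' @param K number of classes (default 3).
#' @return a [label_matrix()].
#' @export
simulate_lf_matrix <- function(truth, specs, seed = 1L, K = 3L) {
  stopifnot(length(specs) >= 1, all(truth %in% seq_len(K)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- length(truth)
  emit_independent <- function(sp) {
    lab <- truth
    wrong <- stats::runif(M) > sp$accuracy
    if (any(wrong)) {
      shift <- sample(K - 1L, sum(wrong), replace = TRUE)
      lab[wrong] <- ((truth[wrong] - 1L + shift) %% K) + 1L
    }
    lab[stats::runif(M) > sp$propensity] <- 0L
    lab
  }
  cols <- vector("list", length(specs))
  for (q in seq_along(specs)) {
    sp <- specs[[q]]
    if (is.null(sp$copy_of)) {
      cols[[q]] <- emit_independent(sp)
    } else {
      if (sp$copy_of >= q)
        stop("copy_of must reference an earlier labeling function")
      own <- emit_independent(sp)
      copy <- stats::runif(M) < sp$agreement
      cols[[q]] <- ifelse(copy, cols[[sp$copy_of]], own)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- paste0("t", seq_len(M))
  label_matrix(m, num_classes = K)
}

#' Planted orientation-to-emotion mixing matrix
#'
#' Default conditional emotion distribution given the tweet's temporal class:
#' past tweets lean to sadness, future tweets to joy, present tweets are
#' spread — a strong, recoverable joy-future association.
#' @return 3 x 4 row-stochastic matrix (orientations x emotions).
#' @export
planted_emotion_matrix <- function() {
  m <- rbind(past    = c(0.05, 0.70, 0.15, 0.10),
             present = c(0.40, 0.20, 0.20, 0.20),
             future  = c(0.70, 0.05, 0.10, 0.15))
  colnames(m) <- EMOTION_CLASSES
  m
}

#' Orientation-independent emotion mixing matrix
#'
#' All three orientation rows share one marginal, so every user-level
#' orientation-emotion correlation is zero in the large-sample limit.
#' @return 3 x 4 row-stochastic matrix.
#' @export
independent_emotion_matrix <- function() {
  m <- matrix(rep(c(0.35, 0.25, 0.20, 0.20), each = 3), 3, 4,
              dimnames = list(TEMPORAL_CLASSES, EMOTION_CLASSES))
  m
}

#' Specification of a simulated user population
#'
#' Each user draws an orientation mixture from a Dirichlet; each tweet draws
#' its temporal class from that mixture, its emotion from the
#' orientation-conditional mixing matrix, its intensity from the emotion's
#' Beta distribution, and a token sequence of filler tokens seeded with
#' class-marker tokens (5 per temporal class and per emotion) injected with
#' probability \code{marker_prob}, so both the weak heuristics and the neural
#' model can learn the classes.
#'
#' @param n_users number of users.
#' @param tweets_per_user scalar count, or \code{c(min, max)} for a uniform
#'   range.
#' @param orientation_dirichlet three positive concentration parameters.
#' @param emotion_given_orientation 3 x 4 row-stochastic matrix; default
#'   [planted_emotion_matrix()].
#' @param intensity_beta 4 x 2 matrix of per-emotion Beta (alpha, beta).
#' @param marker_prob probability a tweet carries markers of its classes.
#' @param n_fillers size of the shared filler vocabulary.
#' @param seed integer seed.
#' @return a \code{population_spec} list.
#' @export
population_spec <- function(n_users = 300L, tweets_per_user = 20L,
                            orientation_dirichlet = c(2, 2, 2),
                            emotion_given_orientation = planted_emotion_matrix(),
                            intensity_beta = cbind(alpha = c(2, 3, 2, 4),
                                                   beta = c(2, 3, 4, 2)),
                            marker_prob = 0.9, n_fillers = 60L, seed = 1L) {
  stopifnot(n_users >= 1, all(tweets_per_user >= 1),
            length(tweets_per_user) %in% 1:2,
            length(orientation_dirichlet) == 3, all(orientation_dirichlet > 0),
            nrow(emotion_given_orientation) == 3,
            ncol(emotion_given_orientation) == 4,
            all(abs(rowSums(emotion_given_orientation) - 1) < 1e-8),
            nrow(intensity_beta) == 4, all(intensity_beta > 0),
            marker_prob >= 0, marker_prob <= 1)
  structure(list(n_users = as.integer(n_users),
                 tweets_per_user = as.integer(tweets_per_user),
                 orientation_dirichlet = orientation_dirichlet,
                 emotion_given_orientation = unname(as.matrix(emotion_given_orientation)),
                 intensity_beta = unname(as.matrix(intensity_beta)),
                 marker_prob = marker_prob, n_fillers = as.integer(n_fillers),
                 seed = as.integer(seed)),
            class = "population_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Marker tokens for a temporal class or emotion
#' @param class class name (e.g. "past", "joy").
#' @return five marker tokens.
#' @export
marker_tokens <- function(class) paste0(class, "mark", 1:5)

#' Lexicon of the synthetic temporal marker tokens
#'
#' @param which integer subset of the five markers per class to include
#'   (default all five) — subsets make partially overlapping heuristics.
#' @return a lexicon mapping marker tokens to their temporal class.
#' @export
marker_lexicon <- function(which = 1:5) {
  toks <- unlist(lapply(TEMPORAL_CLASSES, function(cl) marker_tokens(cl)[which]))
  make_lexicon(toks, rep(TEMPORAL_CLASSES, each = length(which)),
               name = paste0("markers", paste(range(which), collapse = "-")))
}

#' Simulate a user population corpus with latent truth
#'
#' @param spec a [population_spec()].
#' @return list with \code{corpus} (a \code{tweet_corpus}) and \code{truth}
#'   (data frame: id, user_id, temporal, emotion, intensity), plus the spec.
#' @export
simulate_corpus <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fillers <- sprintf("filler%02d", seq_len(spec$n_fillers))
  n_tw <- if (length(spec$tweets_per_user) == 1) rep(spec$tweets_per_user, spec$n_users)
          else sample(spec$tweets_per_user[1]:spec$tweets_per_user[2],
                      spec$n_users, replace = TRUE)
  total <- sum(n_tw)
  user_id <- rep(sprintf("u%04d", seq_len(spec$n_users)), n_tw)
  temporal <- integer(total); emotion <- integer(total)
  pos <- 1L
  for (u in seq_len(spec$n_users)) {
    pi_u <- rdirichlet1(spec$orientation_dirichlet)
    idx <- pos:(pos + n_tw[u] - 1L)
    temporal[idx] <- sample.int(3, n_tw[u], replace = TRUE, prob = pi_u)
    for (i in idx)
      emotion[i] <- sample.int(4, 1, prob = spec$emotion_given_orientation[temporal[i], ])
    pos <- pos + n_tw[u]
  }
  intensity <- stats::rbeta(total, spec$intensity_beta[emotion, 1],
                            spec$intensity_beta[emotion, 2])
  texts <- character(total)
  for (i in seq_len(total)) {
    len <- sample(6:10, 1)
    toks <- sample(fillers, len, replace = TRUE)
    if (stats::runif(1) < spec$marker_prob) {
      mk <- sample(marker_tokens(TEMPORAL_CLASSES[temporal[i]]), 2)
      toks[sample(len, 2)] <- mk
    }
    if (stats::runif(1) < spec$marker_prob) {
      mk <- sample(marker_tokens(EMOTION_CLASSES[emotion[i]]), 2)
      free <- which(!grepl("mark", toks))
      if (length(free) >= 2) toks[sample(free, 2)] <- mk
      else toks <- c(toks, mk)
    }
    texts[i] <- paste(toks, collapse = " ")
  }
  ids <- sprintf("t%06d", seq_len(total))
  corpus <- tweet_corpus(ids, texts, user_id)
  truth <- data.frame(id = ids, user_id = user_id,
                      temporal = TEMPORAL_CLASSES[temporal],
                      emotion = EMOTION_CLASSES[emotion],
                      intensity = intensity, stringsAsFactors = FALSE)
  list(corpus = corpus, truth = truth, spec = spec)
}

#' Large-sample oracle for the user-level orientation-emotion correlations
#'
#' Monte-Carlo on the latent propensities only (no text, no classifiers):
#' simulates many users' per-class tweet fractions under the population spec
#' and returns the implied Pearson correlation for every
#' (orientation, emotion) pair. Serves as the reference the full text
#' pipeline's estimates are compared against.
#'
#' @param spec a [population_spec()].
#' @param n_mc number of Monte-Carlo users (default 1e5).
#' @param seed integer seed (independent of the corpus seed).
#' @return 3 x 4 matrix of correlations (orientations x emotions).
#' @export
planted_correlation <- function(spec, n_mc = 1e5, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_tw <- if (length(spec$tweets_per_user) == 1) rep(spec$tweets_per_user, n_mc)
          else sample(spec$tweets_per_user[1]:spec$tweets_per_user[2],
                      n_mc, replace = TRUE)
  alpha <- spec$orientation_dirichlet
  # user orientation mixtures
  G <- matrix(stats::rgamma(n_mc * 3, shape = rep(alpha, each = n_mc)), n_mc, 3)
  P <- G / rowSums(G)
  # tweet counts per orientation: multinomial given the mixture
  counts <- matrix(0L, n_mc, 3)
  for (u in seq_len(n_mc))
    counts[u, ] <- stats::rmultinom(1, n_tw[u], P[u, ])
  ofrac <- counts / n_tw
  # emotion counts: sum of per-orientation multinomials through the mixing rows
  efrac <- matrix(0, n_mc, 4)
  for (o in 1:3) {
    has <- counts[, o] > 0
    if (any(has)) {
      em <- t(sapply(which(has), function(u)
        stats::rmultinom(1, counts[u, o], spec$emotion_given_orientation[o, ])))
      efrac[has, ] <- efrac[has, ] + em / n_tw[has]
    }
  }
  r <- matrix(NA_real_, 3, 4, dimnames = list(TEMPORAL_CLASSES, EMOTION_CLASSES))
  for (o in 1:3) for (e in 1:4) r[o, e] <- stats::cor(ofrac[, o], efrac[, e])
  r
}
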