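# Weak temporal labellers: heuristic labeling functions (lexicon, keyword
# lists, PoS verb rules) and trainable weak classifiers, assembled into the
# label matrix the generative model consumes.
#
# Weak-label codes: 0 = abstain, 1 = past, 2 = present, 3 = future.

ABSTAIN <- 0L

#' Encode temporal class names as weak-label codes
#' @param x character vector of class names (past/present/future).
#' @return integer codes 1, 2, 3.
#' @export
temporal_code <- function(x) {
  code <- match(x, TEMPORAL_CLASSES)
  if (anyNA(code)) stop("unknown temporal class: ",
                        paste(unique(x[is.na(code)]), collapse = ", "))
  code
}

#' Decode weak-label codes to class names
#' @param code integer vector in 0..3; 0 decodes to NA (abstain).
#' @export
temporal_label <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code %in% 1:3] <- TEMPORAL_CLASSES[code[code %in% 1:3]]
  out
}

match_classes <- function(tokens, lexicon) {
  # distinct temporal classes whose lexicon words occur among the tokens
  hit <- lexicon[intersect(tokens, names(lexicon))]
  unique(unname(hit))
}

#' Lexicon labeling function
#'
#' Labels a tweet with the temporal class whose lexicon words it contains and
#' abstains when none occur. When words of more than one class match, the
#' default rule abstains (precision over coverage); the alternative
#' \code{"majority"} rule votes by match count, abstaining on ties.
#'
#' @param corpus a \code{tweet_corpus}.
#' @param lexicon a lexicon from [make_lexicon()] / [read_lexicon()].
#' @param conflict \code{"abstain"} or \code{"majority"}.
#' @return integer vector of weak-label codes (0 = abstain).
#' @export
lf_lexicon <- function(corpus, lexicon, conflict = c("abstain", "majority")) {
  conflict <- match.arg(conflict)
  if (!length(lexicon)) stop("lexicon is empty")
  vapply(corpus$tokens, function(toks) {
    if (conflict == "abstain") {
      cls <- match_classes(toks, lexicon)
      if (length(cls) == 1L) temporal_code(cls) else ABSTAIN
    } else {
      hit <- lexicon[names(lexicon) %in% toks]
      if (!length(hit)) return(ABSTAIN)
      tab <- table(factor(unname(hit), levels = TEMPORAL_CLASSES))
      top <- which(tab == max(tab))
      if (length(top) == 1L) as.integer(top) else ABSTAIN
    }
  }, integer(1))
}

#' Keyword-list labeling function
#'
#' Same matching semantics as [lf_lexicon()] over three fixed keyword lists
#' (one per temporal class). The lists must be disjoint.
#'
#' @param corpus a \code{tweet_corpus}.
#' @param keyword_sets named list with elements \code{past}, \code{present},
#'   \code{future}, each a character vector of keywords.
#' @inheritParams lf_lexicon
#' @export
lf_keyword <- function(corpus, keyword_sets = default_keyword_sets(),
                       conflict = c("abstain", "majority")) {
  lf_lexicon(corpus, keywords_as_lexicon(keyword_sets), conflict = conflict)
}

keywords_as_lexicon <- function(keyword_sets) {
  stopifnot(all(TEMPORAL_CLASSES %in% names(keyword_sets)))
  all_words <- tolower(unlist(keyword_sets[TEMPORAL_CLASSES], use.names = FALSE))
  dup <- unique(all_words[duplicated(all_words)])
  if (length(dup)) stop("keyword lists overlap on: ", paste(dup, collapse = ", "))
  make_lexicon(all_words,
               rep(TEMPORAL_CLASSES, lengths(keyword_sets[TEMPORAL_CLASSES])),
               name = "keyword30")
}

#' Stand-in 30-word temporal keyword lists
#'
#' The published per-class keyword lists are external resources; this ships a
#' synthetic stand-in of thirty common English temporal markers per class so
#' the labeling function is exercisable. Real lists load through the lexicon
#' file format.
#' @return named list of three 30-word character vectors.
#' @export
default_keyword_sets <- function() {
  list(
    past = c("yesterday", "ago", "remembered", "remembering", "memories",
             "memory", "nostalgia", "nostalgic", "childhood", "past",
             "former", "formerly", "previously", "earlier", "once", "regret",
             "regrets", "missed", "was", "were", "had", "did", "happened",
             "history", "historic", "old", "gone", "lasted", "threw", "wept"),
    present = c("now", "today", "currently", "current", "present", "presently",
                "moment", "ongoing", "happening", "tonight", "nowadays",
                "live", "living", "staying", "stuck", "busy", "bored",
                "waiting", "watching", "working", "eating", "sitting", "here",
                "am", "is", "are", "doing", "right", "this", "meanwhile"),
    future = c("tomorrow", "soon", "future", "upcoming", "will", "shall",
               "gonna", "plan", "plans", "planning", "hope", "hopes",
               "hoping", "expect", "expecting", "forecast", "predict",
               "prediction", "next", "later", "ahead", "anticipate",
               "eventually", "someday", "forthcoming", "await", "goal",
               "goals", "dream", "dreams"))
}

# ---- miniature rule-based PoS tagger -----------------------------------

TAGGER_LEXICON <- c(
  i = "PRP", you = "PRP", he = "PRP", she = "PRP", we = "PRP", they = "PRP",
  it = "PRP", the = "DT", a = "DT", an = "DT", this = "DT", that = "DT",
  will = "MD", shall = "MD", would = "MD", could = "MD", can = "MD",
  may = "MD", might = "MD", must = "MD", gonna = "MD", wont = "MD",
  was = "VBD", were = "VBD", went = "VBD", had = "VBD", did = "VBD",
  said = "VBD", got = "VBD", saw = "VBD", made = "VBD", came = "VBD",
  took = "VBD", felt = "VBD", knew = "VBD", thought = "VBD", left = "VBD",
  gave = "VBD", told = "VBD", found = "VBD", met = "VBD", lost = "VBD",
  is = "VBZ", has = "VBZ", does = "VBZ", am = "VBP", are = "VBP",
  have = "VBP", do = "VBP", go = "VB", be = "VB", get = "VB",
  and = "CC", or = "CC", but = "CC", to = "TO", of = "IN", in_ = "IN",
  on = "IN", at = "IN", not = "RB", very = "RB"
)

#' Tag tokens with a miniature rule-based Penn-style tagger
#'
#' A small deterministic tagger sufficient to drive the verb-tense labeling
#' function in tests: a closed-class lexicon (pronouns, modals, irregular
#' verbs, auxiliaries) plus suffix rules (-ed -> VBD, -ing -> VBG,
#' -s after a pronoun-less context -> NNS). Everything else is NN. Any tagger
#' honouring the tag alphabet can be injected in its place (e.g. an adapter
#' over an external tweet tagger).
#'
#' @param tokens character vector of normalised tokens.
#' @return character vector of tags, same length as \code{tokens}.
#' @export
rule_pos_tag <- function(tokens) {
  vapply(tokens, function(tok) {
    if (tok == "in") return("IN")
    hit <- TAGGER_LEXICON[tok]
    if (!is.na(hit)) return(unname(hit))
    if (grepl("^[a-z']+ed$", tok)) return("VBD")
    if (grepl("^[a-z']+ing$", tok)) return("VBG")
    if (grepl("^[[:punct:]]+$", tok)) return(".")
    if (grepl("^[a-z']+s$", tok) && nchar(tok) > 3) return("NNS")
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

#' Verb-tense labeling function from PoS tags
#'
#' Past-tense verb tags (VBD, VBN) signal \emph{past}; the modals
#' will/shall/'ll/gonna signal \emph{future}; present-tense tags
#' (VBP, VBZ, VBG) signal \emph{present}. When several signals co-occur the
#' precedence is future > past > present (an explicit modal future marker is
#' the strongest cue). Tweets without any verb signal get an abstain. Unknown
#' tag symbols are treated as non-verbs.
#'
#' @param corpus a \code{tweet_corpus}.
#' @param tagger function mapping a token vector to a tag vector
#'   (default [rule_pos_tag()]).
#' @return integer vector of weak-label codes.
#' @export
lf_pos_verb <- function(corpus, tagger = rule_pos_tag) {
  future_modals <- c("will", "shall", "gonna", "'ll", "wont")
  vapply(corpus$tokens, function(toks) {
    if (!length(toks)) return(ABSTAIN)
    tags <- tagger(toks)
    if (length(tags) != length(toks))
      stop("tagger returned ", length(tags), " tags for ", length(toks), " tokens")
    if (any(tags == "MD" & toks %in% future_modals)) return(3L)
    if (any(tags %in% c("VBD", "VBN"))) return(1L)
    if (any(tags %in% c("VBP", "VBZ", "VBG"))) return(2L)
    ABSTAIN
  }, integer(1))
}

# ---- trainable weak models ---------------------------------------------

tfidf_features <- function(token_lists, vocab = NULL, idf = NULL) {
  if (is.null(vocab)) vocab <- sort(unique(unlist(token_lists)))
  n <- length(token_lists)
  tf <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    tab <- table(factor(token_lists[[i]], levels = vocab))
    tf[i, ] <- as.numeric(tab)
  }
  if (is.null(idf)) {
    df <- colSums(tf > 0)
    idf <- log((n + 1) / (df + 1)) + 1
  }
  list(x = sweep(tf, 2, idf, `*`), vocab = vocab, idf = idf)
}

#' Train a weak temporal classifier
#'
#' Two weak-model families mirror the two trainable sources feeding the label
#' matrix: a linear support-vector machine over tf-idf bag-of-words features,
#' and a bidirectional recurrent classifier reusing the shared-encoder
#' components of the multi-task network (embedding + Bi-GRU, softmax head).
#' Weak models are full classifiers: they never abstain.
#'
#' @param kind \code{"svm"} or \code{"birnn"}.
#' @param corpus a \code{tweet_corpus} of seed examples.
#' @param labels temporal class names or codes (1..3), one per tweet; every
#'   class must be represented.
#' @param config list of overrides for the birnn kind (epochs, sizes, seed);
#'   \code{cost} for the svm kind.
#' @return a \code{weak_model} with a [predict()] method returning codes 1..3.
#' @export
train_weak_model <- function(kind = c("svm", "birnn"), corpus, labels,
                             config = list()) {
  kind <- match.arg(kind)
  if (is.character(labels)) labels <- temporal_code(labels)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(corpus), all(labels %in% 1:3))
  missing <- setdiff(1:3, unique(labels))
  if (length(missing))
    stop("seed corpus lacks class(es): ",
         paste(TEMPORAL_CLASSES[missing], collapse = ", "))
  if (kind == "svm") {
    feats <- tfidf_features(corpus$tokens)
    fit <- e1071::svm(x = feats$x, y = factor(TEMPORAL_CLASSES[labels],
                                              levels = TEMPORAL_CLASSES),
                      kernel = "linear",
                      cost = if (is.null(config$cost)) 10 else config$cost,
                      scale = FALSE)
    structure(list(kind = "svm", fit = fit, vocab = feats$vocab,
                   idf = feats$idf), class = "weak_model")
  } else {
    cfg_defaults <- list(embedding_dim = 16, recurrent_units = 12,
                         conv_filters = 8, shared_mlp_units = 16,
                         epochs = 60, dropout = 0, seed = 7L)
    cfg <- utils::modifyList(cfg_defaults, config)
    cfg <- do.call(multitask_config, cfg)
    temporal <- list(tokens = corpus$tokens, label = labels)
    net <- train_multitask(temporal_data = temporal, emotion_data = NULL,
                           config = cfg)
    structure(list(kind = "birnn", fit = net), class = "weak_model")
  }
}

#' @export
predict.weak_model <- function(object, corpus, ...) {
  if (object$kind == "svm") {
    feats <- tfidf_features(corpus$tokens, vocab = object$vocab, idf = object$idf)
    temporal_code(as.character(stats::predict(object$fit, feats$x)))
  } else {
    pred <- predict_multitask(object$fit, corpus)
    pred$temporal_hard
  }
}

#' Wrap a weak model as a labeling function
#' @param model a \code{weak_model}.
#' @return function mapping a corpus to weak-label codes.
#' @export
as_labeling_function <- function(model) {
  force(model)
  function(corpus) predict(model, corpus)
}

# ---- label matrix -------------------------------------------------------

#' Assemble the label matrix
#'
#' Applies each labeling function to the corpus; entry (p, q) is function q's
#' weak label for tweet p. A labeling function that fails on a tweet records
#' an abstain for that tweet and raises a warning.
#'
#' @param corpus a \code{tweet_corpus}.
#' @param labeling_functions named list; each element maps a corpus to an
#'   integer code vector (see [lf_lexicon()], [as_labeling_function()]).
#' @return a \code{label_matrix}: integer matrix M x L, codes 0..3, tweet ids
#'   as row names and function names as column names.
#' @export
build_label_matrix <- function(corpus, labeling_functions) {
  if (!length(labeling_functions)) stop("at least one labeling function required")
  if (is.null(names(labeling_functions)) || any(!nzchar(names(labeling_functions))))
    names(labeling_functions) <- paste0("lf", seq_along(labeling_functions))
  M <- nrow(corpus)
  cols <- lapply(names(labeling_functions), function(nm) {
    lf <- labeling_functions[[nm]]
    out <- tryCatch(lf(corpus), error = function(e) {
      # column-level failure: retry tweet-by-tweet so one bad tweet only
      # abstains for itself
      vapply(seq_len(M), function(i) {
        tryCatch(as.integer(lf(corpus[i, , drop = FALSE])),
                 error = function(e2) {
                   warning("labeling function '", nm, "' failed on tweet ",
                           corpus$id[i], ": ", conditionMessage(e2),
                           call. = FALSE)
                   ABSTAIN
                 })
      }, integer(1))
    })
    out <- as.integer(out)
    if (length(out) != M)
      stop("labeling function '", nm, "' returned ", length(out),
           " labels for ", M, " tweets")
    if (any(is.na(out) | out < 0L | out > 3L))
      stop("labeling function '", nm, "' produced codes outside 0..3")
    out
  })
  lambda <- do.call(cbind, cols)
  dimnames(lambda) <- list(corpus$id, names(labeling_functions))
  label_matrix(lambda)
}

#' Construct a label_matrix from an integer matrix
#' @param x integer matrix with entries in 0..num_classes.
#' @param num_classes number of classes K (default 3).
#' @export
label_matrix <- function(x, num_classes = 3L) {
  x <- as.matrix(x); storage.mode(x) <- "integer"
  if (nrow(x) < 1L || ncol(x) < 1L) stop("label matrix must be at least 1 x 1")
  if (any(is.na(x) | x < 0L | x > num_classes))
    stop("label matrix entries must lie in 0..", num_classes)
  if (is.null(colnames(x))) colnames(x) <- paste0("lf", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  structure(x, num_classes = as.integer(num_classes),
            class = c("label_matrix", "matrix", "array"))
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("label_matrix:", nrow(x), "tweets x", ncol(x), "labeling functions (K =",
      attr(x, "num_classes"), ")\n")
  cat("coverage (non-abstain rate) per function:\n")
  print(round(colMeans(unclass(x) != 0L), 3))
  invisible(x)
}

#' Per-function coverage and pairwise agreement of a label matrix
#' @param lambda a \code{label_matrix}.
#' @return list with \code{coverage} (per-LF non-abstain rate) and
#'   \code{agreement} (L x L matrix of exact-match rates).
#' @export
label_matrix_summary <- function(lambda) {
  m <- unclass(lambda)
  L <- ncol(m)
  agree <- matrix(1, L, L, dimnames = list(colnames(m), colnames(m)))
  for (q in seq_len(L)) for (r in seq_len(L))
    agree[q, r] <- mean(m[, q] == m[, r])
  list(coverage = colMeans(m != 0L), agreement = agree)
}

#' Write / read a label matrix as TSV
#'
#' First column \code{id}, then one integer column per labeling function
#' (codes 0-3) with the function names as header.
#' @param lambda a \code{label_matrix}.
#' @param path file path.
#' @export
write_label_matrix <- function(lambda, path) {
  df <- data.frame(id = rownames(lambda), unclass(lambda),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  label_matrix(m)
}
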