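TEMPORAL_CLASSES <- c("past", "present", "future")
EMOTION_CLASSES  <- c("joy", "sadness", "anger", "fear")
URL_TOKEN  <- "<url>"
USER_TOKEN <- "<user>"

#' Tokenize and normalise a tweet
#'
#' Deterministic lower-casing tweet tokenizer: URLs collapse to a
#' \code{"<url>"} placeholder, user mentions to \code{"<user>"}, the hashtag
#' symbol is stripped while the hashtag word is kept, punctuation runs are kept
#' as single tokens, and emoji / other non-ASCII symbol runs survive as single
#' tokens. Idempotent on an already-normalised stream re-joined by spaces, so
#' tokenized text can round-trip through flat files.
#'
#' @param text character vector of raw tweet texts.
#' @return for a single string, a character vector of tokens; for a vector,
#'   a list of token vectors. Empty text gives an empty token vector.
#' @examples
#' tokenize_tweet("I MISS those days!!")
#' tokenize_tweet("@bob see http://x.co #fun")
#' @export
tokenize_tweet <- function(text) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    s <- gsub("(https?://\\S+|www\\.\\S+)", paste0(" ", URL_TOKEN, " "), s, perl = TRUE)
    s <- gsub("@\\w+", paste0(" ", USER_TOKEN, " "), s, perl = TRUE)
    s <- gsub("#(\\w)", " \\1", s, perl = TRUE)
    s <- tolower(s)
    # token classes: placeholders | word (letters/digits/underscore/apostrophe)
    # | ascii punctuation run | non-ascii symbol run (emoji etc.)
    pat <- "<url>|<user>|[\\p{L}\\p{N}_']+|[\\x21-\\x2f\\x3a-\\x40\\x5b-\\x60\\x7b-\\x7e]+|[^\\p{L}\\p{N}\\s\\x21-\\x7e]+"
    m <- gregexpr(pat, s, perl = TRUE)
    toks <- regmatches(s, m)[[1]]
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Construct a tweet corpus
#'
#' A corpus is a data frame with columns \code{id}, \code{user_id},
#' \code{text} and a list-column \code{tokens} derived deterministically from
#' \code{text} by [tokenize_tweet()].
#'
#' @param id,text character vectors of equal length; ids must be non-empty
#'   and unique.
#' @param user_id optional character vector (NA allowed).
#' @return a \code{tweet_corpus} data frame.
#' @export
tweet_corpus <- function(id, text, user_id = NA_character_) {
  id <- as.character(id); text <- as.character(text)
  stopifnot(length(id) == length(text))
  if (any(!nzchar(id) | is.na(id))) stop("tweet ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate tweet id(s): ", paste(unique(dup), collapse = ", "))
  user_id <- rep_len(as.character(user_id), length(id))
  out <- data.frame(id = id, user_id = user_id, text = text, stringsAsFactors = FALSE)
  out$tokens <- if (length(id)) lapply(text, tokenize_tweet) else list()
  class(out) <- c("tweet_corpus", "data.frame")
  out
}

#' Read a tweet table
#'
#' @param path file path.
#' @param format \code{"tsv"} (header columns id, user_id, text) or
#'   \code{"jsonl"} (one JSON object per line with the same keys).
#' @return a \code{tweet_corpus}.
#' @export
read_tweets <- function(path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                            colClasses = "character", na.strings = NULL,
                            check.names = FALSE, fileEncoding = "UTF-8")
    for (col in c("id", "text"))
      if (!col %in% names(df)) stop("missing required column '", col, "' in ", path)
    uid <- if ("user_id" %in% names(df)) df$user_id else NA_character_
    uid[!is.na(uid) & uid == ""] <- NA_character_
    tweet_corpus(df$id, df$text, uid)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed JSON on line ", i, ": ",
                                               conditionMessage(e)))
      if (is.null(rec$id) || is.null(rec$text))
        stop("missing required column 'id' or 'text' on line ", i)
      recs[[i]] <- data.frame(id = as.character(rec$id),
                              user_id = if (is.null(rec$user_id)) NA_character_
                                        else as.character(rec$user_id),
                              text = as.character(rec$text), stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs)
    if (is.null(df)) return(tweet_corpus(character(0), character(0)))
    tweet_corpus(df$id, df$text, df$user_id)
  }
}

#' Write a tweet table as TSV
#' @param corpus a \code{tweet_corpus}.
#' @param path output path.
#' @export
write_tweets <- function(corpus, path) {
  df <- data.frame(id = corpus$id,
                   user_id = ifelse(is.na(corpus$user_id), "", corpus$user_id),
                   text = corpus$text, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert an ordinal emotion-intensity annotation to the unit interval
#'
#' Ordinal intensity classes 0 (none), 1 (low), 2 (moderate), 3 (high) map to
#' the midpoints of the four quarter-unit intensity bins:
#' \code{intensity = ordinal * 0.25 + 0.125}, i.e. 0.125, 0.375, 0.625, 0.875.
#'
#' @param ei_oc integer vector with values in \{0,1,2,3\}.
#' @return numeric vector in [0,1].
#' @export
convert_ordinal_intensity <- function(ei_oc) {
  if (any(is.na(ei_oc)) || any(ei_oc != as.integer(ei_oc)) ||
      any(ei_oc < 0 | ei_oc > 3))
    stop("ordinal intensity must be an integer in {0,1,2,3}")
  ei_oc * 0.25 + 0.125
}

#' Read an emotion-annotated tweet file
#'
#' TSV with header columns id, text, emotion, intensity. In the
#' \code{"ordinal"} dialect the intensity column holds integers 0-3 which are
#' converted to [0,1] via [convert_ordinal_intensity()]; in the \code{"real"}
#' dialect it holds reals already in [0,1].
#'
#' @param path file path.
#' @param dialect \code{"ordinal"} or \code{"real"}.
#' @return a data frame of emotion records: id, user_id, text, tokens,
#'   emotion, intensity, intensity_ordinal (NA in the real dialect).
#' @export
read_emotion_file <- function(path, dialect = c("real", "ordinal")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, fileEncoding = "UTF-8")
  for (col in c("id", "text", "emotion", "intensity"))
    if (!col %in% names(df)) stop("missing required column '", col, "' in ", path)
  bad <- setdiff(unique(df$emotion), EMOTION_CLASSES)
  if (length(bad)) stop("unsupported emotion class(es): ", paste(bad, collapse = ", "))
  emotion_records(id = df$id, text = df$text, emotion = df$emotion,
                  intensity = as.numeric(df$intensity), dialect = dialect,
                  user_id = if ("user_id" %in% names(df)) df$user_id else NA)
}

#' Build emotion records in memory
#' @inheritParams read_emotion_file
#' @param id,text,emotion,intensity,user_id parallel vectors.
#' @export
emotion_records <- function(id, text, emotion, intensity,
                            dialect = c("real", "ordinal"), user_id = NA) {
  dialect <- match.arg(dialect)
  emotion <- as.character(emotion)
  if (!all(emotion %in% EMOTION_CLASSES))
    stop("unsupported emotion class(es): ",
         paste(setdiff(unique(emotion), EMOTION_CLASSES), collapse = ", "))
  corpus <- tweet_corpus(id, text, user_id)
  if (dialect == "ordinal") {
    ord <- intensity
    corpus$intensity_ordinal <- as.integer(ord)
    corpus$intensity <- convert_ordinal_intensity(ord)
  } else {
    if (any(is.na(intensity)) || any(intensity < 0 | intensity > 1))
      stop("real-dialect intensity must lie in [0,1]")
    corpus$intensity_ordinal <- NA_integer_
    corpus$intensity <- as.numeric(intensity)
  }
  corpus$emotion <- emotion
  class(corpus) <- c("emotion_records", class(corpus))
  corpus
}

#' Write emotion records (real dialect) as TSV
#' @param records emotion records data frame.
#' @param path output path.
#' @export
write_emotion_file <- function(records, path) {
  df <- data.frame(id = records$id,
                   user_id = ifelse(is.na(records$user_id), "", records$user_id),
                   text = records$text, emotion = records$emotion,
                   intensity = records$intensity, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a temporal lexicon
#'
#' Two-column TSV (no header): token, temporal class (past/present/future).
#' Lookup is case-insensitive: tokens are normalised to lower case on load.
#'
#' @param path file path.
#' @param name lexicon name (defaults to the file name).
#' @return a named character vector token -> class with attribute \code{name}.
#' @export
read_lexicon <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("lexicon file needs two tab-separated columns")
  make_lexicon(df[[1]], df[[2]], name = name)
}

#' Construct a temporal lexicon from vectors
#' @param token,class parallel character vectors.
#' @param name lexicon name.
#' @export
make_lexicon <- function(token, class, name = "lexicon") {
  class <- as.character(class)
  bad <- setdiff(unique(class), TEMPORAL_CLASSES)
  if (length(bad)) stop("lexicon classes must be past/present/future, got: ",
                        paste(bad, collapse = ", "))
  lex <- stats::setNames(class, tolower(as.character(token)))
  attr(lex, "name") <- name
  lex
}

#' Read a plain-text word-vector file
#'
#' GloVe-style dialect: one line per token, the token followed by D
#' whitespace-separated reals. All lines must share the same dimension.
#'
#' @param path file path.
#' @param vocab optional character vector; when given, only those tokens are
#'   retained (saves memory on large vector files).
#' @return numeric matrix with tokens as row names.
#' @export
read_word_vectors <- function(path, vocab = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  toks <- character(length(lines)); vecs <- vector("list", length(lines))
  dim0 <- NA_integer_; keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(parts) < 2) stop("malformed word-vector line ", i)
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v)) stop("non-numeric vector entries on line ", i)
    if (is.na(dim0)) dim0 <- length(v)
    if (length(v) != dim0)
      stop("inconsistent vector dimension on line ", i, ": expected ", dim0,
           ", got ", length(v))
    toks[i] <- parts[1]
    if (is.null(vocab) || parts[1] %in% vocab) { keep[i] <- TRUE; vecs[[i]] <- v }
  }
  mat <- do.call(rbind, vecs[keep])
  if (is.null(mat)) mat <- matrix(numeric(0), 0, max(dim0, 0, na.rm = TRUE))
  rownames(mat) <- toks[keep]
  mat
}

#' Write word vectors in the plain-text dialect
#' @param mat numeric matrix with token row names.
#' @param path output path.
#' @export
write_word_vectors <- function(mat, path) {
  lines <- vapply(seq_len(nrow(mat)), function(i)
    paste(rownames(mat)[i], paste(format(mat[i, ], trim = TRUE, scientific = FALSE),
                                  collapse = " ")), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
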