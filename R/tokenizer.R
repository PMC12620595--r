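# Subword tokenizer for the narrative text branch: greedy longest-match
# WordPiece over a fixed vocabulary file, with sentinel tokens and
# character-level continuation fallback for out-of-vocabulary words.

TOK_PAD <- "[PAD]"
TOK_UNK <- "[UNK]"
TOK_CLS <- "[CLS]"
TOK_SEP <- "[SEP]"

#' Load a tokenizer vocabulary
#'
#' Reads a plain-text vocabulary (one token per line; `##`-prefixed tokens
#' are word continuations) and returns a tokenizer object.  The packaged
#' default vocabulary covers the full closed vocabulary of the narrative
#' templates plus single-character fallbacks.
#'
#' @param path Path to the vocabulary file; default is the packaged
#'   vocabulary.
#' @return Object of class `wordpiece_tokenizer`.
#' @export
load_tokenizer <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocab.txt", package = "riskfusion")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("configuration error: vocabulary file not found: ", path)
  }
  vocab <- readLines(path, warn = FALSE)
  vocab <- vocab[nzchar(vocab)]
  for (tok in c(TOK_PAD, TOK_UNK, TOK_CLS, TOK_SEP)) {
    if (!tok %in% vocab) stop("vocabulary is missing sentinel token ", tok)
  }
  obj <- list(vocab = vocab,
              index = stats::setNames(seq_along(vocab), vocab),
              path = path)
  class(obj) <- "wordpiece_tokenizer"
  obj
}

#' @export
print.wordpiece_tokenizer <- function(x, ...) {
  cat(sprintf("wordpiece_tokenizer: %d tokens (%s)\n", length(x$vocab),
              x$path))
  invisible(x)
}

# lowercase and split into word / punctuation pre-tokens
pretokenize <- function(text) {
  text <- tolower(text)
  text <- gsub("([.,()/;:-])", " \\1 ", text)
  strsplit(trimws(gsub("\\s+", " ", text)), " ")[[1]]
}

# greedy longest-match WordPiece for a single pre-token
wordpiece_word <- function(word, index) {
  pieces <- character(0)
  start <- 1
  n <- nchar(word)
  while (start <= n) {
    end <- n
    piece <- NA_character_
    while (end >= start) {
      cand <- substr(word, start, end)
      if (start > 1) cand <- paste0("##", cand)
      if (!is.na(index[cand])) {
        piece <- cand
        break
      }
      end <- end - 1
    }
    if (is.na(piece)) return(TOK_UNK)
    pieces <- c(pieces, piece)
    start <- end + 1
  }
  pieces
}

#' Tokenize a narrative into padded subword ids
#'
#' Deterministic greedy longest-match subword tokenization, with `[CLS]`
#' and `[SEP]` sentinels, truncation to the token budget and `[PAD]`
#' right-padding.  Ids are 1-based indices into the vocabulary.
#'
#' @param text Narrative string.
#' @param tokenizer A `wordpiece_tokenizer` from [load_tokenizer()].
#' @param max_tokens Token budget including sentinels (default 128).
#' @return List with `ids` (integer vector of length `max_tokens`),
#'   `n_tokens` (number of non-pad positions) and `truncated` (logical).
#' @export
tokenize <- function(text, tokenizer, max_tokens = 128) {
  stopifnot(inherits(tokenizer, "wordpiece_tokenizer"))
  words <- if (nzchar(trimws(text))) pretokenize(text) else character(0)
  pieces <- unlist(lapply(words, wordpiece_word, index = tokenizer$index),
                   use.names = FALSE)
  truncated <- FALSE
  budget <- max_tokens - 2L
  if (length(pieces) > budget) {
    pieces <- pieces[seq_len(budget)]
    truncated <- TRUE
  }
  toks <- c(TOK_CLS, pieces, TOK_SEP)
  ids <- unname(tokenizer$index[toks])
  n_tok <- length(ids)
  if (n_tok < max_tokens) {
    ids <- c(ids, rep(tokenizer$index[[TOK_PAD]], max_tokens - n_tok))
  }
  list(ids = as.integer(ids), n_tokens = as.integer(n_tok),
       truncated = truncated)
}

#' Tokenize a vector of narratives into an id matrix
#'
#' Repeated narratives are tokenized once and the result reused, so cohorts
#' with recurring category combinations tokenize quickly.
#'
#' @inheritParams tokenize
#' @param texts Character vector.
#' @return List with `ids` (matrix, one row per text), `n_tokens`,
#'   `truncated`.
#' @export
tokenize_all <- function(texts, tokenizer, max_tokens = 128) {
  uniq <- unique(texts)
  res <- lapply(uniq, tokenize, tokenizer = tokenizer,
                max_tokens = max_tokens)
  pos <- match(texts, uniq)
  ids <- do.call(rbind, lapply(res, `[[`, "ids"))[pos, , drop = FALSE]
  list(ids = ids,
       n_tokens = vapply(res, `[[`, integer(1), "n_tokens")[pos],
       truncated = vapply(res, `[[`, logical(1), "truncated")[pos])
}
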