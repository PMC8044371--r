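#' n-gram vocabulary over the DNA alphabet
#'
#' Builds the vocabulary of all `4^n` overlapping n-gram nucleobase "words"
#' in lexicographic order over A < C < G < T. Token `i` (1-based position in
#' `tokens`) corresponds to the 0-based vocabulary index `i - 1`.
#'
#' @param n n-gram order (positive integer; default 2).
#' @return An object of class `mt_vocabulary`: a list with elements `n`,
#'   `tokens` (character vector of length `4^n`, lexicographic) and `index`
#'   (named integer vector mapping token to 0-based index).
#' @examples
#' v <- build_vocabulary(2)
#' v$tokens[c(1, 2, 16)]  # "AA" "AC" "TT"
#' @export
build_vocabulary <- function(n = 2L) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("n-gram order 'n' must be a positive integer, got: ", deparse(n))
  }
  n <- as.integer(n)
  bases <- c("A", "C", "G", "T")
  grids <- rev(rep(list(bases), n))
  grid <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; columns were reversed so the
  # leftmost base varies slowest, giving lexicographic order.
  tokens <- do.call(paste0, rev(grid))
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(n = n, tokens = tokens, index = index),
            class = "mt_vocabulary")
}

#' Tokenize a DNA sequence into overlapping n-gram words
#'
#' Splits a normalized A/C/G/T sequence of length L into its L - n + 1
#' overlapping windows of width n (stride 1, left to right) and maps each to
#' its vocabulary position.
#'
#' @param seq a single normalized DNA string over A/C/G/T.
#' @param vocab an `mt_vocabulary`, or an integer n-gram order (a vocabulary
#'   is built on the fly).
#' @return Integer vector of 1-based vocabulary positions, length L - n + 1,
#'   with the token strings as names.
#' @examples
#' tokenize("GTTGT", 2)  # GT TT TG GT
#' @export
tokenize <- function(seq, vocab = 2L) {
  if (!inherits(vocab, "mt_vocabulary")) vocab <- build_vocabulary(vocab)
  if (length(seq) != 1L || !is.character(seq)) {
    stop("'seq' must be a single character string")
  }
  n <- vocab$n
  L <- nchar(seq)
  if (L < n) {
    stop("sequence of length ", L, " is shorter than the n-gram order ", n)
  }
  starts <- seq_len(L - n + 1L)
  words <- substring(seq, starts, starts + n - 1L)
  pos <- match(words, vocab$tokens)
  if (anyNA(pos)) {
    bad <- words[which(is.na(pos))[1L]]
    stop("token not in vocabulary: '", bad,
         "' (sequence must be validated to A/C/G/T first)")
  }
  stats::setNames(pos, words)
}

#' Reconstruct a sequence from its overlapping n-gram tokens
#'
#' Inverse of [tokenize()]: concatenates the first token with the last base
#' of each subsequent token, checking overlap consistency.
#'
#' @param tokens integer vector of 1-based vocabulary positions (as returned
#'   by [tokenize()]) or a character vector of token strings.
#' @param vocab an `mt_vocabulary`.
#' @return The reconstructed DNA string.
#' @export
detokenize <- function(tokens, vocab) {
  if (!inherits(vocab, "mt_vocabulary")) vocab <- build_vocabulary(vocab)
  words <- if (is.character(tokens)) tokens else vocab$tokens[tokens]
  if (length(words) == 0L) stop("no tokens to detokenize")
  n <- vocab$n
  if (length(words) > 1L) {
    heads <- substring(words[-1L], 1L, n - 1L)
    tails <- substring(words[-length(words)], 2L, n)
    if (any(heads != tails)) stop("tokens are not overlap-consistent")
  }
  paste0(words[1L], paste(substring(words[-1L], n, n), collapse = ""))
}

#' One-hot embedding table for a vocabulary
#'
#' The identity table used to initialize (or freeze) the word-embedding
#' layer: row i is the one-hot vector of token i, so the embedding dimension
#' equals the vocabulary size `4^n`.
#'
#' @param vocab an `mt_vocabulary`.
#' @return A `4^n` x `4^n` identity matrix with token rownames.
#' @export
one_hot_table <- function(vocab) {
  if (!inherits(vocab, "mt_vocabulary")) vocab <- build_vocabulary(vocab)
  V <- length(vocab$tokens)
  tab <- diag(V)
  rownames(tab) <- vocab$tokens
  tab
}

#' Embed a token sequence
#'
#' Looks up each token's row in an embedding table, producing the M x d
#' matrix fed to the shared encoder.
#'
#' @param tokens integer vector of 1-based vocabulary positions.
#' @param table numeric matrix with one row per vocabulary token.
#' @return M x d numeric matrix; row i is the embedding of token i.
#' @export
embed_tokens <- function(tokens, table) {
  if (!is.matrix(table)) stop("'table' must be a matrix")
  if (any(tokens < 1L | tokens > nrow(table))) {
    stop("token index out of range for an embedding table with ",
         nrow(table), " rows")
  }
  table[tokens, , drop = FALSE]
}
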