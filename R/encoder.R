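# Pluggable token encoder.
#
# The encode() contract consumed by the NER and RE models is: given a word
# sequence, return one H-dimensional output vector per (sub-)token plus an
# alignment map from word positions to output rows.  In production such an
# encoder would be a pretrained biomedical transformer; this package ships a
# small trainable "window encoder" that honours the same contract and trains
# on a desk-scale budget: per-token embeddings are the sum of a word, a
# position and a segment component, and L local mixing layers (tanh over a
# +/-1 token window per layer) propagate boundary context.  All weights are
# seeded and updates are fully deterministic.

SPECIAL_TOKENS <- c("[CLS]", "[SEP]", "[UNK]", "<s>", "</s>", "<o>", "</o>")

#' Build a vocabulary from token sequences
#'
#' Special tokens (`[CLS]`, `[SEP]`, `[UNK]` and the four relation marker
#' tokens) always occupy the first ids; remaining tokens are ordered by
#' decreasing frequency, ties broken lexicographically, so the mapping is
#' deterministic.
#'
#' @param token_lists list of character vectors (or of objects with a
#'   `tokens` field, e.g. labeled sentences).
#' @return named integer vector mapping token to id.
#' @export
build_vocab <- function(token_lists) {
  toks <- unlist(lapply(token_lists, function(x) {
    if (is.list(x) && !is.null(x$tokens)) x$tokens else x
  }), use.names = FALSE)
  toks <- setdiff(toks, SPECIAL_TOKENS)
  tab <- table(toks)
  ord <- order(-as.integer(tab), names(tab))
  words <- names(tab)[ord]
  ids <- seq_len(length(SPECIAL_TOKENS) + length(words))
  names(ids) <- c(SPECIAL_TOKENS, words)
  ids
}

#' Create a small deterministic trainable encoder
#'
#' @param vocab named integer vector from [build_vocab()].
#' @param H hidden size (output dimension), default 32.
#' @param L number of mixing layers, default 2 (receptive field +/- L
#'   tokens).
#' @param max_len maximum sequence length including the `[CLS]`/`[SEP]`
#'   positions, default 64.
#' @param seed integer seed for weight initialization.
#' @param truncate if `TRUE` (default) over-length inputs are truncated
#'   with a warning; if `FALSE` they raise an error.
#' @return object of class `window_encoder`.
#' @export
test_encoder <- function(vocab, H = 32L, L = 2L, max_len = 64L, seed = 1L,
                         truncate = TRUE) {
  stopifnot(H >= 1L, L >= 1L, max_len >= 3L)
  V <- length(vocab)
  set.seed(seed)
  sd0 <- 1 / sqrt(H)
  params <- list(
    E_word = matrix(rnorm(V * H, sd = sd0), V, H),
    E_pos  = matrix(rnorm(max_len * H, sd = sd0), max_len, H),
    E_seg  = matrix(rnorm(2L * H, sd = sd0), 2L, H),
    layers = lapply(seq_len(L), function(l) {
      list(W = matrix(rnorm(H * 3L * H, sd = sd0 / sqrt(3)), H, 3L * H),
           b = numeric(H))
    }))
  structure(list(vocab = vocab, H = as.integer(H), L = as.integer(L),
                 max_len = as.integer(max_len), seed = as.integer(seed),
                 truncate = truncate, params = params),
            class = "window_encoder")
}

#' @export
print.window_encoder <- function(x, ...) {
  cat("<window_encoder H=", x$H, " L=", x$L, " |V|=", length(x$vocab),
      " max_len=", x$max_len, ">\n", sep = "")
  invisible(x)
}

# Map words to ids, adding [CLS]/[SEP]; unknown words -> [UNK].
encoder_ids <- function(enc, tokens) {
  if (length(tokens) == 0L) stop("empty input to encoder")
  ids <- unname(enc$vocab[tokens])
  ids[is.na(ids)] <- unname(enc$vocab[["[UNK]"]])
  ids <- c(enc$vocab[["[CLS]"]], ids, enc$vocab[["[SEP]"]])
  if (length(ids) > enc$max_len) {
    if (!enc$truncate) stop("input exceeds max_len (", enc$max_len, ")")
    warning("input truncated to max_len = ", enc$max_len)
    ids <- c(ids[seq_len(enc$max_len - 1L)], enc$vocab[["[SEP]"]])
  }
  as.integer(ids)
}

# Forward pass; returns the top-layer output and a cache for backprop.
encoder_forward <- function(enc, ids) {
  p <- enc$params
  n <- length(ids)
  X <- p$E_word[ids, , drop = FALSE] +
    p$E_pos[seq_len(n), , drop = FALSE] +
    matrix(p$E_seg[1L, ], n, enc$H, byrow = TRUE)
  acts <- vector("list", enc$L)
  Zs <- vector("list", enc$L)
  for (l in seq_len(enc$L)) {
    W <- p$layers[[l]]$W
    b <- p$layers[[l]]$b
    left <- rbind(0, X[-n, , drop = FALSE])
    right <- rbind(X[-1L, , drop = FALSE], 0)
    Z <- cbind(left, X, right)
    A <- tcrossprod(Z, W)
    A <- sweep(A, 2L, b, `+`)
    X <- tanh(A)
    Zs[[l]] <- Z
    acts[[l]] <- X
  }
  list(O = X, ids = ids, acts = acts, Zs = Zs)
}

# Backward pass: dO is the gradient at the top-layer output.  Returns a
# gradient list with the same shape as enc$params.
encoder_backward <- function(enc, cache, dO) {
  p <- enc$params
  n <- length(cache$ids)
  H <- enc$H
  g_layers <- vector("list", enc$L)
  dX <- dO
  for (l in rev(seq_len(enc$L))) {
    Xl <- cache$acts[[l]]
    Z <- cache$Zs[[l]]
    dA <- dX * (1 - Xl * Xl)
    gW <- crossprod(dA, Z)              # H x 3H
    gb <- colSums(dA)
    dZ <- dA %*% p$layers[[l]]$W        # n x 3H
    d_left <- dZ[, seq_len(H), drop = FALSE]
    d_mid <- dZ[, H + seq_len(H), drop = FALSE]
    d_right <- dZ[, 2L * H + seq_len(H), drop = FALSE]
    dX <- d_mid +
      rbind(d_left[-1L, , drop = FALSE], 0) +
      rbind(0, d_right[-n, , drop = FALSE])
    g_layers[[l]] <- list(W = gW, b = gb)
  }
  gE_word <- matrix(0, nrow(p$E_word), H)
  agg <- rowsum(dX, group = cache$ids, reorder = FALSE)
  gE_word[as.integer(rownames(agg)), ] <- agg
  gE_pos <- matrix(0, nrow(p$E_pos), H)
  gE_pos[seq_len(n), ] <- dX
  gE_seg <- matrix(0, 2L, H)
  gE_seg[1L, ] <- colSums(dX)
  list(E_word = gE_word, E_pos = gE_pos, E_seg = gE_seg, layers = g_layers)
}

#' Encode a word sequence
#'
#' Runs the encoder and returns one output vector per position (including
#' the `[CLS]`/`[SEP]` specials) together with the word-to-row alignment
#' map.  This encoder tokenizes at the word level, so the alignment is
#' one row per word; encoders that split words into several sub-tokens
#' must map every sub-token row to its word index.
#'
#' @param encoder a `window_encoder`.
#' @param tokens character vector of words.
#' @return list with `O` (matrix, rows = positions, cols = H), `alignment`
#'   (integer vector: row index of each word's first sub-token) and `ids`.
#' @export
encode <- function(encoder, tokens) {
  ids <- encoder_ids(encoder, tokens)
  fw <- encoder_forward(encoder, ids)
  n_words <- length(ids) - 2L
  list(O = fw$O, alignment = seq_len(n_words) + 1L, ids = ids)
}

# ---- Adam optimizer over nested parameter lists ----------------------------

new_adam <- function(params, lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  env <- new.env(parent = emptyenv())
  env$m <- zeros(params)
  env$v <- zeros(params)
  env$t <- 0L
  env$lr <- lr; env$beta1 <- beta1; env$beta2 <- beta2; env$eps <- eps
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p
      for (k in seq_along(p)) {
        r <- step(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p
        m[[k]] <- r$m
        v[[k]] <- r$v
      }
      return(list(p = out_p, m = m, v = v))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - opt$lr * (m / c1) / (sqrt(v / c2) + opt$eps)
    list(p = p, m = m, v = v)
  }
  r <- step(params, grads, opt$m, opt$v)
  opt$m <- r$m
  opt$v <- r$v
  r$p
}
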