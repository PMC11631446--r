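# Pointer-augmented NER.
#
# Three sigmoid heads sit on top of the encoder output: a token-label head
# over {O, B-BrainRegion, I-BrainRegion} and two binary position-pointer
# heads marking entity start and end tokens.  Training minimizes
#   (1/N) * [ label CE + lambda * (start CE + end CE) ]
# where each cross-entropy renormalizes the per-class sigmoid activations
# to a distribution.  Decoding pairs fired start pointers with the nearest
# subsequent fired end pointer ("paired-pointer" mode) or falls back to the
# BIO argmax path ("bio" mode).

NER_CLASSES <- c("O", "B-BrainRegion", "I-BrainRegion")

new_head <- function(K, H, sd = 0.1) {
  list(W = matrix(rnorm(K * H, sd = sd), K, H), b = numeric(K))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Run the three NER prediction heads over encoder outputs
#'
#' Each head is an affine map followed by an elementwise sigmoid; rows are
#' aligned to word positions (first sub-token pooling via the encoder's
#' alignment map).
#'
#' @param O matrix of encoder outputs for the word positions (n x H).
#' @param heads list with `label`, `start`, `end` heads (each `W`, `b`).
#' @return object of class `ner_prediction`: list of matrices `label`
#'   (n x 3), `start` (n x 2), `end` (n x 2) of sigmoid activations.
#' @export
predict_heads <- function(O, heads) {
  run <- function(h) {
    Z <- tcrossprod(O, h$W)
    sigmoid(sweep(Z, 2L, h$b, `+`))
  }
  structure(list(label = run(heads$label), start = run(heads$start),
                 end = run(heads$end)),
            class = "ner_prediction")
}

# Renormalize sigmoid activations row-wise to a distribution.
renorm_rows <- function(S) S / rowSums(S)

# Cross-entropy of renormalized rows at gold class indices.
ce_rows <- function(S, gold_idx, eps = 1e-12) {
  P <- renorm_rows(S)
  p <- P[cbind(seq_along(gold_idx), gold_idx)]
  if (any(p < eps)) p <- pmax(p, eps)
  -sum(log(p))
}

gold_indices <- function(gold) {
  list(label = match(gold$labels, NER_CLASSES),
       start = gold$start_tags + 1L,
       end = gold$end_tags + 1L)
}

#' Joint NER loss
#'
#' Mean over scored positions of the token-label cross-entropy plus
#' `lambda` times the start- and end-pointer cross-entropies.  Sigmoid
#' activations are renormalized per row before taking logs; probabilities
#' are clamped at `eps` so a zero at the gold class never yields NaN.
#'
#' @param pred a `ner_prediction` (see [predict_heads()]).
#' @param gold a [labeled_sentence()] aligned to the prediction rows.
#' @param lambda non-negative pointer-loss coefficient (default 1).
#' @param eps clamp inside logarithms, default 1e-12.
#' @return non-negative scalar.
#' @export
ner_loss <- function(pred, gold, lambda = 1, eps = 1e-12) {
  stopifnot(lambda >= 0)
  g <- gold_indices(gold)
  n <- length(g$label)
  if (nrow(pred$label) != n) stop("prediction/gold length mismatch")
  (ce_rows(pred$label, g$label, eps) +
      lambda * (ce_rows(pred$start, g$start, eps) +
                  ce_rows(pred$end, g$end, eps))) / n
}

# Gradient of the renormalized-sigmoid CE w.r.t. the pre-sigmoid logits.
# S: sigmoid activations (n x K); gold_idx: per-row gold class.
ce_sig_grad <- function(S, gold_idx, scale) {
  dZ <- S * (1 - S) / rowSums(S)
  at <- cbind(seq_along(gold_idx), gold_idx)
  dZ[at] <- dZ[at] - (1 - S[at])
  dZ * scale
}

#' Train the pointer-augmented NER model
#'
#' Stochastic training (one sentence per step, Adam updates) of the
#' encoder and the three heads under the joint loss of [ner_loss()].
#' Fully deterministic given `seed`.
#'
#' @param corpus list of [labeled_sentence()] objects.
#' @param encoder a `window_encoder`; defaults to a fresh [test_encoder()]
#'   over the corpus vocabulary.
#' @param lambda pointer-loss coefficient, default 1.
#' @param epochs passes over the corpus, default 6.
#' @param lr Adam learning rate, default 0.01.
#' @param seed integer seed controlling initialization and shuffling.
#' @param verbose print per-epoch mean loss.
#' @return object of class `ner_model` (fields `encoder`, `heads`,
#'   `lambda`).
#' @export
train_ner <- function(corpus, encoder = NULL, lambda = 1, epochs = 6L,
                      lr = 0.01, seed = 1L, verbose = FALSE) {
  if (length(corpus) == 0L) stop("empty training corpus")
  if (is.null(encoder)) encoder <- test_encoder(build_vocab(corpus), seed = seed)
  H <- encoder$H
  set.seed(seed)
  heads <- list(label = new_head(3L, H), start = new_head(2L, H),
                end = new_head(2L, H))
  params <- list(enc = encoder$params, heads = heads)
  opt <- new_adam(params, lr = lr)
  ids_list <- lapply(corpus, function(s) encoder_ids(encoder, s$tokens))
  gold_list <- lapply(corpus, gold_indices)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(corpus))
    ep_loss <- 0
    for (si in ord) {
      ids <- ids_list[[si]]
      g <- gold_list[[si]]
      n <- length(ids) - 2L
      if (length(g$label) != n) next  # truncated sentence; skip from loss
      encoder$params <- params$enc
      fw <- encoder_forward(encoder, ids)
      Ow <- fw$O[seq_len(n) + 1L, , drop = FALSE]
      pred <- predict_heads(Ow, params$heads)
      ep_loss <- ep_loss +
        (ce_rows(pred$label, g$label) +
           lambda * (ce_rows(pred$start, g$start) +
                       ce_rows(pred$end, g$end))) / n
      dOw <- matrix(0, n, H)
      grads_heads <- list()
      for (hn in c("label", "start", "end")) {
        scale <- if (hn == "label") 1 / n else lambda / n
        S <- pred[[hn]]
        dZ <- ce_sig_grad(S, g[[hn]], scale)
        h <- params$heads[[hn]]
        grads_heads[[hn]] <- list(W = crossprod(dZ, Ow), b = colSums(dZ))
        dOw <- dOw + dZ %*% h$W
      }
      dO <- matrix(0, n + 2L, H)
      dO[seq_len(n) + 1L, ] <- dOw
      g_enc <- encoder_backward(encoder, fw, dO)
      params <- adam_step(opt, params,
                          list(enc = g_enc, heads = grads_heads))
    }
    if (verbose) {
      message(sprintf("epoch %d: mean loss %.4f", ep, ep_loss / length(corpus)))
    }
  }
  encoder$params <- params$enc
  structure(list(encoder = encoder, heads = params$heads, lambda = lambda),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model H=", x$encoder$H, " L=", x$encoder$L,
      " lambda=", x$lambda, ">\n", sep = "")
  invisible(x)
}

#' Decode entity spans from NER head predictions
#'
#' Default `"pointer"` mode: threshold the renormalized start and end
#' pointer probabilities at `threshold`; scan starts left to right, pair
#' each fired start with the nearest fired end at or after it within
#' `max_entity_len` tokens; discard a pair if any covered token's best
#' BIO label is O; accept greedily without overlaps.  `"bio"` mode decodes
#' from the label head alone (argmax, orphan I repaired to B).
#'
#' @param pred a `ner_prediction`.
#' @param threshold pointer firing threshold, default 0.5.
#' @param max_entity_len maximum entity length in tokens, default 10.
#' @param mode `"pointer"` (default) or `"bio"`.
#' @return data.frame of 0-based half-open spans (`start`, `end`),
#'   non-overlapping, in left-to-right order.
#' @export
decode_entities <- function(pred, threshold = 0.5, max_entity_len = 10L,
                            mode = c("pointer", "bio")) {
  mode <- match.arg(mode)
  n <- nrow(pred$label)
  lab_idx <- max.col(renorm_rows(pred$label), ties.method = "first")
  if (mode == "bio") {
    labels <- bio_repair(NER_CLASSES[lab_idx])
    return(spans_from_labels(labels))
  }
  p_start <- renorm_rows(pred$start)[, 2L]
  p_end <- renorm_rows(pred$end)[, 2L]
  starts <- which(p_start >= threshold)
  ends <- which(p_end >= threshold)
  out_s <- integer(0)
  out_e <- integer(0)
  next_free <- 1L
  for (i in starts) {
    if (i < next_free) next
    cand <- ends[ends >= i & ends < i + max_entity_len]
    if (length(cand) == 0L) next
    j <- cand[1L]
    if (any(lab_idx[i:j] == 1L)) next   # covered token best-labeled O
    out_s <- c(out_s, i - 1L)
    out_e <- c(out_e, j)
    next_free <- j + 1L
  }
  data.frame(start = out_s, end = out_e)
}

#' Predict entities for unlabeled sentences
#'
#' @param model a trained `ner_model`.
#' @param sentences list of `labeled_sentence` objects or character token
#'   vectors.
#' @param mode decoding mode, see [decode_entities()].
#' @param threshold,max_entity_len decoding parameters.
#' @return list (one element per sentence) of lists with `spans`
#'   (data.frame), `labels` (BIO tags induced by the spans) and `pred`
#'   (the raw `ner_prediction`).
#' @export
predict_ner <- function(model, sentences, mode = "pointer", threshold = 0.5,
                        max_entity_len = 10L) {
  lapply(sentences, function(s) {
    toks <- if (is.list(s)) s$tokens else s
    en <- encode(model$encoder, toks)
    n <- length(en$alignment)
    Ow <- en$O[en$alignment, , drop = FALSE]
    pred <- predict_heads(Ow, model$heads)
    spans <- decode_entities(pred, threshold = threshold,
                             max_entity_len = max_entity_len, mode = mode)
    spans$surface <- vapply(seq_len(nrow(spans)), function(r) {
      span_surface(toks[seq_len(n)], spans$start[r], spans$end[r])
    }, character(1))
    list(spans = spans, labels = labels_from_spans(spans, n), pred = pred)
  })
}

#' Expand a training corpus by repetition
#'
#' @param corpus list of sentences.
#' @param factor integer >= 1; output has `factor` copies of every
#'   sentence.  `factor = 1` returns the corpus unchanged.
#' @param seed seed for the shuffle of the expanded corpus.
#' @return expanded corpus list.
#' @export
augment_by_repetition <- function(corpus, factor, seed = 1L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(corpus)
  out <- rep(corpus, factor)
  set.seed(seed)
  out[sample(length(out))]
}

#' Correct annotations against a gazetteer (dictionary-tree denoising)
#'
#' Every maximal longest match of a gazetteer surface form in a sentence
#' is labeled as one entity; existing annotated spans that overlap such a
#' match are extended/merged into it.  Sentences without dictionary hits
#' are untouched.  The operation is idempotent.
#'
#' @param corpus list of [labeled_sentence()] objects.
#' @param gazetteer a [gazetteer()] built from a brain-region dictionary.
#' @return corpus with adjusted labels (pointer tags re-derived).
#' @export
trie_denoise <- function(corpus, gazetteer) {
  if (gazetteer_empty(gazetteer)) {
    warning("empty gazetteer; trie_denoise is the identity")
    return(corpus)
  }
  lapply(corpus, function(s) {
    m <- gazetteer_scan(gazetteer, s$tokens)
    if (nrow(m) == 0L) return(s)
    existing <- spans_from_labels(s$labels)
    overlaps_match <- function(a, b, m) any(m$start < b & m$end > a)
    keep <- existing[!vapply(seq_len(nrow(existing)), function(r) {
      overlaps_match(existing$start[r], existing$end[r], m)
    }, logical(1)), , drop = FALSE]
    touched <- existing[vapply(seq_len(nrow(existing)), function(r) {
      overlaps_match(existing$start[r], existing$end[r], m)
    }, logical(1)), , drop = FALSE]
    iv <- rbind(m[, c("start", "end")], touched[, c("start", "end")])
    iv <- iv[order(iv$start), , drop = FALSE]
    merged_s <- integer(0)
    merged_e <- integer(0)
    for (r in seq_len(nrow(iv))) {
      if (length(merged_s) > 0L && iv$start[r] < merged_e[length(merged_e)]) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], iv$end[r])
      } else {
        merged_s <- c(merged_s, iv$start[r])
        merged_e <- c(merged_e, iv$end[r])
      }
    }
    spans <- rbind(data.frame(start = merged_s, end = merged_e),
                   keep[, c("start", "end")])
    labeled_sentence(s$tokens, labels_from_spans(spans, length(s$tokens)),
                     doc_id = s$doc_id, sent_id = s$sent_id)
  })
}
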