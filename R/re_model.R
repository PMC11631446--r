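# Marker-based relation classification.
#
# The two candidate entities of a sentence are wrapped in the boundary
# marker tokens <s> ... </s> (first mention) and <o> ... </o> (second
# mention).  The encoder output rows at the four marker positions are each
# passed through their own affine projection, concatenated, and mapped to
# class scores:
#   P(X) = Wo . Concat(W1s s1 + b1s, W2s s2 + b2s, W1e e1 + b1e, W2e e2 + b2e) + bo
# A softmax turns the scores into the distribution the multi-class
# cross-entropy is trained on.  One implementation serves both the 2-class
# connectivity task and the 4-class directional task.

#' Insert boundary marker tokens around the two entity spans
#'
#' @param instance a [relation_instance()]; the subject must be the
#'   earlier mention and spans must be disjoint.
#' @return object of class `marked_sequence`: list with `tokens` (original
#'   tokens with `<s>`, `</s>`, `<o>`, `</o>` inserted), `marker_positions`
#'   (named integer vector `s1`, `e1`, `s2`, `e2`, 1-based indices into
#'   `tokens`) and `original_map` (marked index to original index, `NA`
#'   at markers).
#' @export
insert_markers <- function(instance) {
  x <- instance
  n <- length(x$tokens)
  if (x$subj[2L] > x$obj[1L]) stop("overlapping entity spans")
  s1 <- x$subj[1L]; s2 <- x$subj[2L]   # 0-based half-open
  o1 <- x$obj[1L]; o2 <- x$obj[2L]
  toks <- c(x$tokens[seq_len(s1)],
            "<s>", x$tokens[(s1 + 1L):s2], "</s>",
            if (o1 > s2) x$tokens[(s2 + 1L):o1],
            "<o>", x$tokens[(o1 + 1L):o2], "</o>",
            if (o2 < n) x$tokens[(o2 + 1L):n])
  pos <- c(s1 = s1 + 1L, e1 = s2 + 2L, s2 = o1 + 3L, e2 = o2 + 4L)
  map <- rep(NA_integer_, n + 4L)
  orig <- setdiff(seq_len(n + 4L), unname(pos))
  map[orig] <- seq_len(n)
  structure(list(tokens = toks, marker_positions = pos, original_map = map),
            class = "marked_sequence")
}

#' Remove markers from a marked sequence
#'
#' Inverse of [insert_markers()]: recovers the original tokens in order.
#'
#' @param marked a `marked_sequence`.
#' @return character vector of the original tokens.
#' @export
strip_markers <- function(marked) {
  marked$tokens[!is.na(marked$original_map)]
}

#' Pool the encoder output rows at the four marker positions
#'
#' @param O encoder output matrix (rows aligned to marked tokens through
#'   `alignment`).
#' @param marked a `marked_sequence`.
#' @param alignment integer vector mapping marked-token index to row of
#'   `O` (from [encode()]).
#' @return list of four numeric H-vectors `s1`, `s2`, `e1`, `e2` (the
#'   rows at `<s>`, `<o>`, `</s>`, `</o>`).
#' @export
pool_marker_vectors <- function(O, marked, alignment) {
  p <- marked$marker_positions
  if (any(p > length(alignment))) stop("marker missing from alignment")
  rows <- setNames(alignment[p], names(p))
  list(s1 = O[rows[["s1"]], ], s2 = O[rows[["s2"]], ],
       e1 = O[rows[["e1"]], ], e2 = O[rows[["e2"]], ])
}

new_re_params <- function(M, H, use_cls = FALSE, sd = 0.1) {
  proj <- function() list(W = matrix(rnorm(M * H, sd = sd), M, H),
                          b = numeric(M))
  k <- if (use_cls) 5L else 4L
  out <- list(W1s = proj(), W2s = proj(), W1e = proj(), W2e = proj())
  if (use_cls) out$Wc <- proj()
  out$Wo <- matrix(rnorm(M * k * M, sd = sd), M, k * M)
  out$bo <- numeric(M)
  out
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Relation class scores and probabilities from marker vectors
#'
#' Implements the concatenated-projection head: the four marker vectors
#' are each affinely projected to M dimensions, concatenated (order s1,
#' s2, e1, e2), and mapped by the output weights to unnormalized scores;
#' a softmax yields the class distribution.
#'
#' @param s1,s2,e1,e2 numeric H-vectors (see [pool_marker_vectors()]).
#' @param params head parameters (see `new_re_params`); optionally a
#'   `cls` vector is projected too when the head was built with
#'   `use_cls = TRUE`.
#' @param cls optional `[CLS]` output row.
#' @return list with `scores` (length M), `probs` (softmax of scores)
#'   and `h` (the concatenated hidden vector).
#' @export
relation_logits <- function(s1, s2, e1, e2, params, cls = NULL) {
  H <- ncol(params$W1s$W)
  for (v in list(s1, s2, e1, e2)) {
    if (length(v) != H) stop("marker vector dimension mismatch")
  }
  h <- c(params$W1s$W %*% s1 + params$W1s$b,
         params$W2s$W %*% s2 + params$W2s$b,
         params$W1e$W %*% e1 + params$W1e$b,
         params$W2e$W %*% e2 + params$W2e$b,
         if (!is.null(params$Wc)) {
           if (is.null(cls)) stop("head expects a [CLS] vector")
           params$Wc$W %*% cls + params$Wc$b
         })
  z <- drop(params$Wo %*% h + params$bo)
  list(scores = z, probs = softmax(z), h = h)
}

#' Multi-class relation cross-entropy
#'
#' Mean over the batch of the negative log-probability of the gold class,
#' clamped at `eps`.
#'
#' @param probs matrix (n x M) of predicted class probabilities, or a
#'   single probability vector.
#' @param gold integer vector of gold class indices (1-based).
#' @param weights optional per-class loss weights.
#' @param eps clamp, default 1e-12.
#' @return non-negative scalar.
#' @export
re_loss <- function(probs, gold, weights = NULL, eps = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  p <- probs[cbind(seq_along(gold), gold)]
  w <- if (is.null(weights)) rep(1, length(gold)) else weights[gold]
  sum(w * -log(pmax(p, eps))) / length(gold)
}

#' Train the marker-based relation classifier
#'
#' @param instances list of labeled [relation_instance()] objects.
#' @param encoder a `window_encoder`; defaults to a fresh [test_encoder()]
#'   over the marked-token vocabulary (marker tokens are atomic special
#'   tokens, never split).
#' @param classes label set; `relation_classes()` (default, 4-way
#'   directional task) or e.g. `c("unconnected", "connected")` for the
#'   2-class connectivity task.
#' @param epochs,lr,seed training configuration (Adam, one instance per
#'   step, deterministic given `seed`).
#' @param class_weights if `TRUE`, inverse-frequency loss weights (off by
#'   default).
#' @param use_cls if `TRUE`, the `[CLS]` row joins the concatenated head
#'   as a fifth projected vector.
#' @param verbose print per-epoch mean loss.
#' @return object of class `re_model`.
#' @export
train_re <- function(instances, encoder = NULL, classes = relation_classes(),
                     epochs = 10L, lr = 0.005, seed = 1L,
                     class_weights = FALSE, use_cls = FALSE,
                     verbose = FALSE) {
  if (length(instances) == 0L) stop("empty training set")
  gold <- match(vapply(instances, `[[`, "", "label"), classes)
  if (anyNA(gold)) stop("instance label outside the class set")
  marked <- lapply(instances, insert_markers)
  if (is.null(encoder)) {
    encoder <- test_encoder(build_vocab(lapply(marked, `[[`, "tokens")),
                            seed = seed)
  }
  M <- length(classes)
  H <- encoder$H
  w_cls <- if (class_weights) {
    f <- tabulate(gold, nbins = M)
    w <- length(gold) / (M * pmax(f, 1L))
    w
  }
  set.seed(seed)
  params <- list(enc = encoder$params,
                 head = new_re_params(M, H, use_cls = use_cls))
  opt <- new_adam(params, lr = lr)
  ids_list <- lapply(marked, function(m) encoder_ids(encoder, m$tokens))
  for (ep in seq_len(epochs)) {
    ord <- sample(length(instances))
    ep_loss <- 0
    for (i in ord) {
      ids <- ids_list[[i]]
      mk <- marked[[i]]
      if (length(ids) - 2L < length(mk$tokens)) next  # truncated; skip
      encoder$params <- params$enc
      fw <- encoder_forward(encoder, ids)
      align <- seq_len(length(mk$tokens)) + 1L
      mv <- pool_marker_vectors(fw$O, mk, align)
      cls_vec <- if (use_cls) fw$O[1L, ]
      out <- relation_logits(mv$s1, mv$s2, mv$e1, mv$e2, params$head,
                             cls = cls_vec)
      wt <- if (is.null(w_cls)) 1 else w_cls[gold[i]]
      ep_loss <- ep_loss + wt * -log(max(out$probs[gold[i]], 1e-12))
      dz <- out$probs
      dz[gold[i]] <- dz[gold[i]] - 1
      dz <- dz * wt
      hd <- params$head
      dh <- drop(crossprod(hd$Wo, dz))
      vecs <- list(W1s = mv$s1, W2s = mv$s2, W1e = mv$e1, W2e = mv$e2)
      if (use_cls) vecs$Wc <- cls_vec
      dO <- matrix(0, nrow(fw$O), H)
      rows <- setNames(align[mk$marker_positions], names(mk$marker_positions))
      row_of <- c(W1s = rows[["s1"]], W2s = rows[["s2"]],
                  W1e = rows[["e1"]], W2e = rows[["e2"]],
                  if (use_cls) c(Wc = 1L))
      g_head <- list()
      for (k in seq_along(vecs)) {
        nm <- names(vecs)[k]
        dhk <- dh[(k - 1L) * M + seq_len(M)]
        g_head[[nm]] <- list(W = tcrossprod(dhk, vecs[[nm]]), b = dhk)
        dO[row_of[[nm]], ] <- dO[row_of[[nm]], ] +
          drop(crossprod(hd[[nm]]$W, dhk))
      }
      g_head$Wo <- tcrossprod(dz, out$h)
      g_head$bo <- dz
      g_enc <- encoder_backward(encoder, fw, dO)
      params <- adam_step(opt, params, list(enc = g_enc, head = g_head))
    }
    if (verbose) {
      message(sprintf("epoch %d: mean loss %.4f", ep,
                      ep_loss / length(instances)))
    }
  }
  encoder$params <- params$enc
  structure(list(encoder = encoder, head = params$head, classes = classes,
                 use_cls = use_cls),
            class = "re_model")
}

#' @export
print.re_model <- function(x, ...) {
  cat("<re_model classes=[", paste(x$classes, collapse = ", "),
      "] H=", x$encoder$H, ">\n", sep = "")
  invisible(x)
}

#' Classify the relation expressed by a candidate instance
#'
#' Deterministic: ties in the class probabilities resolve to the
#' lowest class index.
#'
#' @param model a trained `re_model`.
#' @param instance a [relation_instance()] (label may be `NA`).
#' @return object of class `relation_prediction`: list with named
#'   `class_probs`, `predicted_label`, `confidence`.
#' @export
predict_relation <- function(model, instance) {
  if (!inherits(model, "re_model")) stop("untrained or invalid model handle")
  mk <- insert_markers(instance)
  en <- encode(model$encoder, mk$tokens)
  mv <- pool_marker_vectors(en$O, mk, en$alignment)
  cls_vec <- if (isTRUE(model$use_cls)) en$O[1L, ]
  out <- relation_logits(mv$s1, mv$s2, mv$e1, mv$e2, model$head,
                         cls = cls_vec)
  probs <- setNames(out$probs, model$classes)
  k <- which.max(probs)   # first maximum = lowest class index on ties
  structure(list(class_probs = probs,
                 predicted_label = model$classes[k],
                 confidence = unname(probs[k])),
            class = "relation_prediction")
}

#' Classify a batch of relation instances
#'
#' @param model a trained `re_model`.
#' @param instances list of [relation_instance()] objects.
#' @return character vector of predicted labels (full predictions as the
#'   `"predictions"` attribute).
#' @export
predict_relations <- function(model, instances) {
  preds <- lapply(instances, function(x) predict_relation(model, x))
  structure(vapply(preds, `[[`, "", "predicted_label"),
            predictions = preds)
}
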