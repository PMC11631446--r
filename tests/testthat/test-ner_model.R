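# Independent oracle: per-position cross-entropy computed with plain loops
# over renormalized rows.
oracle_joint_loss <- function(pred, gold, lambda) {
  g <- list(label = match(gold$labels,
                          c("O", "B-BrainRegion", "I-BrainRegion")),
            start = gold$start_tags + 1L, end = gold$end_tags + 1L)
  ce <- function(S, idx) {
    tot <- 0
    for (i in seq_along(idx)) {
      row <- S[i, ] / sum(S[i, ])
      tot <- tot - log(row[idx[i]])
    }
    tot
  }
  (ce(pred$label, g$label) +
      lambda * (ce(pred$start, g$start) + ce(pred$end, g$end))) /
    length(g$label)
}

rand_gold <- function(n) {
  labeled_sentence(sprintf("t%d", seq_len(n)), rand_bio(n))
}

test_that("head outputs are sigmoids of the affine maps, with the right shapes", {
  H <- 6L
  O <- matrix(rnorm(2L * H), 2L, H)
  zero <- list(label = list(W = matrix(0, 3L, H), b = numeric(3L)),
               start = list(W = matrix(0, 2L, H), b = numeric(2L)),
               end = list(W = matrix(0, 2L, H), b = numeric(2L)))
  p0 <- predict_heads(O, zero)
  expect_true(all(p0$label == 0.5) && all(p0$start == 0.5) && all(p0$end == 0.5))
  set.seed(21)
  heads <- list(label = list(W = matrix(rnorm(3 * H), 3L, H), b = rnorm(3)),
                start = list(W = matrix(rnorm(2 * H), 2L, H), b = rnorm(2)),
                end = list(W = matrix(rnorm(2 * H), 2L, H), b = rnorm(2)))
  p <- predict_heads(O, heads)
  expect_equal(dim(p$label), c(2L, 3L))
  expect_equal(dim(p$start), c(2L, 2L))
  # hand-computed sigmoid of one affine value
  z12 <- sum(heads$label$W[2, ] * O[1, ]) + heads$label$b[2]
  expect_equal(p$label[1, 2], 1 / (1 + exp(-z12)), tolerance = 1e-12)
})

test_that("joint loss matches the brute-force oracle and its closed forms", {
  set.seed(22)
  for (rep in 1:300) {
    n <- sample.int(10L, 1L)
    pred <- rand_ner_pred(n)
    gold <- rand_gold(n)
    lambda <- sample(c(0, 0.5, 1, 2), 1L)
    expect_equal(ner_loss(pred, gold, lambda),
                 oracle_joint_loss(pred, gold, lambda), tolerance = 1e-9)
  }
  # uniform predictions, single token: ln 3 + lambda * 2 ln 2
  gold1 <- labeled_sentence("t", "B")
  unif <- structure(list(label = matrix(0.5, 1L, 3L),
                         start = matrix(0.5, 1L, 2L),
                         end = matrix(0.5, 1L, 2L)),
                    class = "ner_prediction")
  expect_equal(ner_loss(unif, gold1, lambda = 1), log(3) + 2 * log(2),
               tolerance = 1e-12)
  expect_equal(ner_loss(unif, gold1, lambda = 0), log(3), tolerance = 1e-12)
})

test_that("loss decomposes linearly in lambda and is 0 on one-hot gold", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample.int(8L, 1L)
    pred <- rand_ner_pred(n)
    gold <- rand_gold(n)
    base <- ner_loss(pred, gold, 0)
    ptr <- (ner_loss(pred, gold, 1) - base)
    for (lambda in c(0.5, 2)) {
      expect_equal(ner_loss(pred, gold, lambda), base + lambda * ptr,
                   tolerance = 1e-9)
    }
  }
  gold <- rand_gold(6L)
  onehot <- function(idx, K) {
    m <- matrix(1e-9, length(idx), K)
    m[cbind(seq_along(idx), idx)] <- 1 - 1e-9
    m
  }
  g <- list(label = match(gold$labels,
                          c("O", "B-BrainRegion", "I-BrainRegion")),
            start = gold$start_tags + 1L, end = gold$end_tags + 1L)
  perfect <- structure(list(label = onehot(g$label, 3L),
                            start = onehot(g$start, 2L),
                            end = onehot(g$end, 2L)),
                       class = "ner_prediction")
  expect_lt(ner_loss(perfect, gold, 1), 1e-6)
})

test_that("clamping keeps the loss finite at zero gold probability", {
  gold <- labeled_sentence("t", "B")
  p <- structure(list(label = matrix(c(1, 0, 0), 1L),  # gold class B has 0
                      start = matrix(c(0.5, 0.5), 1L),
                      end = matrix(c(0.5, 0.5), 1L)),
                 class = "ner_prediction")
  expect_true(is.finite(ner_loss(p, gold, 1)))
})

# Independent decode oracle: enumerate all candidate (start, end) pairs,
# then apply the selection rule declaratively.
oracle_decode <- function(pred, threshold = 0.5, max_len = 10L) {
  n <- nrow(pred$label)
  ps <- pred$start / rowSums(pred$start)
  pe <- pred$end / rowSums(pred$end)
  lab <- apply(pred$label / rowSums(pred$label), 1L, which.max)
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i || j - i + 1L > max_len) next
      if (ps[i, 2L] < threshold || pe[j, 2L] < threshold) next
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  chosen <- list()
  taken_upto <- 0L
  for (i in seq_len(n)) {
    if (ps[i, 2L] < threshold || i <= taken_upto) next
    js <- Filter(function(p) p[1L] == i, pairs)
    if (length(js) == 0L) next
    j <- min(vapply(js, `[[`, 0, 2L))
    if (any(lab[i:j] == 1L)) next
    chosen[[length(chosen) + 1L]] <- c(i - 1L, j)
    taken_upto <- j
  }
  if (length(chosen) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, chosen)
  data.frame(start = m[, 1L], end = m[, 2L])
}

test_that("pointer decoding matches the exhaustive oracle on short inputs", {
  set.seed(24)
  for (rep in 1:2000) {
    n <- sample.int(8L, 1L)
    pred <- rand_ner_pred(n)
    expect_equal(decode_entities(pred), oracle_decode(pred))
  }
})

test_that("one-hot gold predictions decode back to the gold spans", {
  onehot_pred <- function(gold) {
    g <- list(label = match(gold$labels,
                            c("O", "B-BrainRegion", "I-BrainRegion")),
              start = gold$start_tags + 1L, end = gold$end_tags + 1L)
    oh <- function(idx, K) {
      m <- matrix(0.01, length(idx), K)
      m[cbind(seq_along(idx), idx)] <- 0.99
      m
    }
    structure(list(label = oh(g$label, 3L), start = oh(g$start, 2L),
                   end = oh(g$end, 2L)), class = "ner_prediction")
  }
  set.seed(25)
  for (rep in 1:500) {
    gold <- rand_gold(sample.int(12L, 1L))
    sp <- decode_entities(onehot_pred(gold))
    expect_equal(sp, spans_from_labels(gold$labels))
  }
  # a fired start with no subsequent fired end emits nothing
  p <- structure(list(label = matrix(c(0.1, 0.9, 0.1,
                                       0.1, 0.1, 0.9), 2L, 3L, byrow = TRUE),
                      start = matrix(c(0.1, 0.9, 0.9, 0.1), 2L, 2L),
                      end = matrix(c(0.9, 0.9, 0.1, 0.1), 2L, 2L)),
                 class = "ner_prediction")
  expect_equal(nrow(decode_entities(p)), 0L)
})

test_that("bio-mode decoding follows the label argmax path", {
  p <- structure(list(label = matrix(c(0.9, 0.1, 0.1, 0.1,
                                       0.05, 0.8, 0.1, 0.1,
                                       0.05, 0.1, 0.8, 0.1), 4L, 3L),
                      start = matrix(0.1, 4L, 2L),
                      end = matrix(0.1, 4L, 2L)),
                 class = "ner_prediction")
  expect_equal(decode_entities(p, mode = "bio"),
               data.frame(start = 1L, end = 3L))
})

test_that("repetition augmentation preserves the multiset and the seed order", {
  corp <- lapply(1:10, function(i) labeled_sentence(sprintf("t%d", i), "O"))
  out <- augment_by_repetition(corp, 2L, seed = 6)
  expect_length(out, 20L)
  ids <- vapply(out, function(s) s$tokens[1], "")
  expect_equal(sort(table(ids)), sort(table(rep(sprintf("t%d", 1:10), 2))),
               ignore_attr = TRUE)
  expect_identical(augment_by_repetition(corp, 1L), corp)
  expect_identical(augment_by_repetition(corp, 3L, seed = 9),
                   augment_by_repetition(corp, 3L, seed = 9))
  expect_error(augment_by_repetition(corp, 0L), "factor")
})

test_that("gazetteer denoising extends conflicting spans and is idempotent", {
  dict <- rbind(ontology_entry("X:1", "anterior hypothalamic nucleus"),
                ontology_entry("X:2", "septal area"))
  gz <- gazetteer(dict)
  toks <- c("the", "anterior", "hypothalamic", "nucleus", "fired", ".")
  # gold marks only the 2-token tail; the 3-token dictionary form wins
  s <- labeled_sentence(toks, c("O", "O", "B-BrainRegion", "I-BrainRegion",
                                "O", "O"))
  out <- trie_denoise(list(s), gz)[[1]]
  expect_equal(spans_from_labels(out$labels), data.frame(start = 1L, end = 4L))
  # sentences without dictionary hits are untouched
  s2 <- labeled_sentence(c("no", "regions", "here"), c("O", "B-BrainRegion", "O"))
  expect_identical(trie_denoise(list(s2), gz)[[1]], s2)
  # idempotence over random synthetic sentences
  cfg <- synth_config(seed = 31, n_documents = 25L,
                      sentences_per_document = 20L, boundary_noise_rate = 0.5)
  ont <- generate_ontology(cfg)
  corp <- generate_corpus(cfg, ont)
  once <- trie_denoise(corp$ner_noisy, ont$gazetteer)
  twice <- trie_denoise(once, ont$gazetteer)
  expect_identical(twice, once)
  expect_warning(trie_denoise(list(s2), gazetteer(dict[0, ])), "empty gazetteer")
})
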