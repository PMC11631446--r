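test_that("marker insertion wraps the exact spans and round-trips", {
  toks <- c("Role", "of", "glutamatergic", "projections", "from",
            "ventral", "tegmental", "area", "to", "lateral", "habenula",
            "in", "aversive", "conditioning", ".")
  inst <- relation_instance(toks, subj = c(5, 8), obj = c(9, 11))
  mk <- insert_markers(inst)
  expect_equal(paste(mk$tokens, collapse = " "),
               paste("Role of glutamatergic projections from",
                     "<s> ventral tegmental area </s> to",
                     "<o> lateral habenula </o> in aversive conditioning ."))
  expect_equal(mk$tokens[mk$marker_positions],
               c("<s>", "</s>", "<o>", "</o>"))
  expect_identical(strip_markers(mk), toks)
})

test_that("adjacent spans and random instances round-trip through markers", {
  inst <- relation_instance(c("a", "t1", "t2", "b"), subj = c(1, 2),
                            obj = c(2, 3))
  expect_equal(insert_markers(inst)$tokens,
               c("a", "<s>", "t1", "</s>", "<o>", "t2", "</o>", "b"))
  set.seed(41)
  for (rep in 1:1000) {
    x <- rand_instance(sample(4:15, 1L))
    mk <- insert_markers(x)
    expect_identical(strip_markers(mk), x$tokens)
    # markers appear once each, in order, wrapping the right surfaces
    p <- mk$marker_positions
    expect_true(all(diff(p[c("s1", "e1", "s2", "e2")]) > 0))
    expect_equal(mk$tokens[(p[["s1"]] + 1L):(p[["e1"]] - 1L)],
                 x$tokens[(x$subj[1] + 1L):x$subj[2]])
    expect_equal(mk$tokens[(p[["s2"]] + 1L):(p[["e2"]] - 1L)],
                 x$tokens[(x$obj[1] + 1L):x$obj[2]])
  }
})

test_that("marker pooling returns the encoder rows at the marker positions", {
  set.seed(42)
  inst <- rand_instance(8L)
  mk <- insert_markers(inst)
  O <- matrix(rnorm(length(mk$tokens) * 4L), ncol = 4L)
  mv <- pool_marker_vectors(O, mk, seq_along(mk$tokens))
  p <- mk$marker_positions
  expect_equal(mv$s1, O[p[["s1"]], ])
  expect_equal(mv$s2, O[p[["s2"]], ])
  expect_equal(mv$e1, O[p[["e1"]], ])
  expect_equal(mv$e2, O[p[["e2"]], ])
  expect_error(pool_marker_vectors(O, mk, seq_len(3L)), "alignment")
})

# Brute-force recomputation of the concatenated-projection head with
# scalar loops.
oracle_logits <- function(s1, s2, e1, e2, params) {
  proj <- function(P, v) {
    M <- nrow(P$W)
    out <- numeric(M)
    for (m in seq_len(M)) out[m] <- sum(P$W[m, ] * v) + P$b[m]
    out
  }
  h <- c(proj(params$W1s, s1), proj(params$W2s, s2),
         proj(params$W1e, e1), proj(params$W2e, e2))
  z <- numeric(nrow(params$Wo))
  for (m in seq_along(z)) z[m] <- sum(params$Wo[m, ] * h) + params$bo[m]
  z
}

test_that("the classification head matches scalar recomputation", {
  set.seed(43)
  for (rep in 1:200) {
    H <- sample(2:6, 1L)
    M <- sample(2:4, 1L)
    params <- new_re_params(M, H)
    vs <- replicate(4, rnorm(H), simplify = FALSE)
    got <- relation_logits(vs[[1]], vs[[2]], vs[[3]], vs[[4]], params)
    want <- oracle_logits(vs[[1]], vs[[2]], vs[[3]], vs[[4]], params)
    expect_equal(got$scores, want, tolerance = 1e-9)
    expect_equal(sum(got$probs), 1, tolerance = 1e-9)
  }
  # all-zero weights give the uniform distribution
  z0 <- new_re_params(4L, 3L)
  z0$W1s$W[] <- 0; z0$W2s$W[] <- 0; z0$W1e$W[] <- 0; z0$W2e$W[] <- 0
  z0$Wo[] <- 0
  out <- relation_logits(rnorm(3), rnorm(3), rnorm(3), rnorm(3), z0)
  expect_equal(out$probs, rep(0.25, 4L), tolerance = 1e-12)
  expect_error(relation_logits(rnorm(2), rnorm(3), rnorm(3), rnorm(3), z0),
               "dimension")
})

test_that("relation loss matches an independent cross-entropy", {
  set.seed(44)
  for (rep in 1:300) {
    n <- sample.int(20L, 1L)
    M <- sample(2:4, 1L)
    P <- matrix(runif(n * M), n, M)
    P <- P / rowSums(P)
    gold <- sample.int(M, n, replace = TRUE)
    want <- mean(-log(P[cbind(seq_len(n), gold)]))
    expect_equal(re_loss(P, gold), want, tolerance = 1e-9)
  }
  expect_equal(re_loss(matrix(0.25, 1L, 4L), 2L), log(4), tolerance = 1e-12)
  perfect <- matrix(c(1, 0, 0, 0), 1L, 4L)
  expect_lt(re_loss(perfect, 1L), 1e-10)
  expect_true(is.finite(re_loss(perfect, 2L)))   # clamp at zero probability
})

test_that("relation prediction is deterministic with a low-index tie rule", {
  cfg <- synth_config(seed = 45, n_documents = 8L)
  corp <- generate_corpus(cfg)
  m <- train_re(corp$relations, epochs = 1L, seed = 45)
  p1 <- predict_relation(m, corp$relations[[1]])
  p2 <- predict_relation(m, corp$relations[[1]])
  expect_identical(p1, p2)
  expect_s3_class(p1, "relation_prediction")
  expect_equal(sum(p1$class_probs), 1, tolerance = 1e-9)
  expect_error(predict_relation(list(), corp$relations[[1]]), "model")
  # explicit tie: first maximum wins
  expect_equal(relation_classes()[which.max(c(0.4, 0.4, 0.1, 0.1))],
               "unconnected")
})

test_that("swapping the subject and object roles swaps the pooled vectors", {
  toks <- c("x", "A", "y", "B", "z")
  i1 <- relation_instance(toks, subj = c(1, 2), obj = c(3, 4))
  mk1 <- insert_markers(i1)
  # the mention order is fixed, but pooling follows the marker positions:
  # s1/e1 always wrap the first mention, s2/e2 the second
  O <- matrix(seq_len(length(mk1$tokens) * 2L), ncol = 2L)
  mv <- pool_marker_vectors(O, mk1, seq_along(mk1$tokens))
  expect_equal(mv$s1, O[2L, ])   # <s> before "A"
  expect_equal(mv$s2, O[6L, ])   # <o> before "B"
  expect_equal(mv$e1, O[4L, ])   # </s> after "A"
  expect_equal(mv$e2, O[8L, ])   # </o> after "B"
})
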