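# Evaluation: exact/lenient span matching for NER, multi-class metrics and
# normalized confusion matrices for relation extraction, and a k-fold
# cross-validation harness.
#
# Exact matching credits a predicted span only when its boundaries equal a
# gold span's.  Lenient matching credits a predicted span when it lies
# within (or equals) a gold span — predicted boundaries may be smaller or
# equal, never larger.  Each gold span is creditable at most once.

check_disjoint <- function(spans, what) {
  if (nrow(spans) < 2L) return(invisible())
  o <- order(spans$start)
  s <- spans[o, , drop = FALSE]
  if (any(s$start[-1L] < s$end[-nrow(s)])) {
    stop("overlapping ", what, " spans")
  }
  invisible()
}

#' Match predicted against gold spans
#'
#' @param gold,pred data.frames of 0-based half-open spans (`start`,
#'   `end`), each set non-overlapping within one sentence.
#' @param mode `"exact"` (boundaries must coincide) or `"lenient"`
#'   (predicted span contained in, or equal to, a gold span).  Matching is
#'   greedy in span order and each gold span is credited at most once.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
match_spans <- function(gold, pred, mode = c("exact", "lenient")) {
  mode <- match.arg(mode)
  check_disjoint(gold, "gold")
  check_disjoint(pred, "predicted")
  gold <- gold[order(gold$start), , drop = FALSE]
  pred <- pred[order(pred$start), , drop = FALSE]
  used <- logical(nrow(gold))
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    hit <- if (mode == "exact") {
      which(!used & gold$start == pred$start[i] & gold$end == pred$end[i])
    } else {
      which(!used & gold$start <= pred$start[i] & pred$end[i] <= gold$end)
    }
    if (length(hit) > 0L) {
      used[hit[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp)
}

#' Precision, recall and F1 from match counts
#'
#' Zero-denominator convention: a metric whose denominator is zero is
#' reported as 0.
#'
#' @param tp,fp,fn non-negative integers (or a single named vector as
#'   returned by [match_spans()] passed as `tp`).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(tp, fp = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 3L) {
    fn <- tp[["fn"]]; fp <- tp[["fp"]]; tp <- tp[["tp"]]
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Micro-averaged span evaluation over a corpus
#'
#' Pools tp/fp/fn across sentences before computing precision, recall and
#' F1.
#'
#' @param gold_list,pred_list lists of span data.frames, parallel by
#'   sentence.
#' @param mode `"exact"` or `"lenient"`.
#' @return named numeric vector with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_spans <- function(gold_list, pred_list, mode = "exact") {
  stopifnot(length(gold_list) == length(pred_list))
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(gold_list)) {
    tot <- tot + match_spans(gold_list[[i]], pred_list[[i]], mode)
  }
  c(tot, prf(tot))
}

#' Multi-class confusion matrix with row-normalized recalls
#'
#' @param gold,pred character vectors of labels, same length.
#' @param classes class order; defaults to [relation_classes()].
#' @return object of class `confusion_matrix`: list with `counts`
#'   (K x K integer matrix, gold rows x predicted columns) and
#'   `normalized` (rows divided by row sums; zero rows stay zero).
#' @export
confusion <- function(gold, pred, classes = relation_classes()) {
  stopifnot(length(gold) == length(pred))
  if (!all(gold %in% classes)) stop("unknown gold label")
  if (!all(pred %in% classes)) stop("unknown predicted label")
  counts <- table(factor(gold, levels = classes),
                  factor(pred, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(gold = classes, predicted = classes))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, normalized = normalized),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (gold rows x predicted columns):\n")
  print(x$counts)
  invisible(x)
}

#' Per-class and macro-averaged P/R/F1 for label vectors
#'
#' @param gold,pred character label vectors.
#' @param classes class order.
#' @return list with `per_class` (data.frame) and `macro` (named vector of
#'   macro-averaged precision, recall, f1) and `micro_accuracy`.
#' @export
classification_report <- function(gold, pred, classes = relation_classes()) {
  cm <- confusion(gold, pred, classes)$counts
  per <- t(vapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    prf(tp, sum(cm[, k]) - tp, sum(cm[k, ]) - tp)
  }, numeric(3)))
  per <- data.frame(class = classes, per)
  list(per_class = per,
       macro = c(precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1)),
       micro_accuracy = sum(diag(cm)) / max(sum(cm), 1L))
}

#' k-fold cross-validation harness
#'
#' Units (documents or sentences) are shuffled once with the seed and cut
#' into k rotating blocks (see [make_folds()]); every unit is tested
#' exactly once.  The pipeline is called per fold and must return a named
#' numeric vector of metrics.
#'
#' @param corpus corpus list.
#' @param k number of folds.
#' @param pipeline `function(train, test)` returning named metrics.
#' @param seed integer seed.
#' @param unit_level `"document"` or `"sentence"`.
#' @return object of class `eval_report`: list with `folds` (metric
#'   matrix, one row per fold), `mean`, `sd`.
#' @export
cross_validate <- function(corpus, k, pipeline, seed = 1L,
                           unit_level = "document") {
  folds <- make_folds(corpus, k, unit_level = unit_level, seed = seed)
  rows <- lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    train <- subset_units(corpus, c(f$train, f$validation), unit_level)
    test <- subset_units(corpus, f$test, unit_level)
    pipeline(train, test)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("fold", seq_len(k))
  structure(list(folds = m, mean = colMeans(m), sd = apply(m, 2L, sd)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Cross-validation over", nrow(x$folds), "folds (mean +/- SD):\n")
  for (nm in colnames(x$folds)) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  }
  invisible(x)
}
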