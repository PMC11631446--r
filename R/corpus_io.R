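# Corpus reading/writing and span plumbing.
#
# Conventions used throughout the package:
#   * token labels are "O", "B-BrainRegion", "I-BrainRegion" (short forms
#     "B"/"I" are accepted on input and normalized);
#   * entity spans are 0-based, half-open [start, end) at token level;
#   * a corpus is a list of labeled_sentence objects.

.B <- "B-BrainRegion"
.I <- "I-BrainRegion"
.O <- "O"

normalize_bio <- function(labels) {
  out <- as.character(labels)
  out[out == "B"] <- .B
  out[out == "I"] <- .I
  bad <- !(out %in% c(.O, .B, .I))
  if (any(bad)) {
    stop("illegal tag string(s): ", paste(unique(out[bad]), collapse = ", "))
  }
  out
}

short_bio <- function(labels) {
  substr(labels, 1L, 1L)
}

#' Check BIO validity of a label sequence
#'
#' A sequence is BIO-valid when no `I-BrainRegion` tag begins the sentence
#' or immediately follows an `O`.
#'
#' @param labels character vector of BIO tags.
#' @return `TRUE` or `FALSE`.
#' @export
bio_valid <- function(labels) {
  s <- short_bio(normalize_bio(labels))
  if (length(s) == 0L) return(TRUE)
  prev <- c("O", s[-length(s)])
  !any(s == "I" & prev == "O")
}

#' Repair orphan I tags by promoting them to B
#'
#' @param labels character vector of BIO tags.
#' @return a BIO-valid character vector.
#' @export
bio_repair <- function(labels) {
  lab <- normalize_bio(labels)
  s <- short_bio(lab)
  for (i in seq_along(s)) {
    if (s[i] == "I" && (i == 1L || s[i - 1L] == "O")) {
      s[i] <- "B"
      lab[i] <- .B
    }
  }
  lab
}

#' Construct a labeled sentence
#'
#' Bundles tokens with their BIO labels and the start/end pointer tags
#' derived from them.  Pointer tags mark, for every entity, its first (B)
#' token and its last token; they are the auxiliary supervision signal of
#' the pointer-augmented tagger.
#'
#' @param tokens character vector of words.
#' @param labels character vector of BIO tags, same length as `tokens`.
#' @param doc_id document identifier.
#' @param sent_id integer sentence index within the document.
#' @param repair if `TRUE`, orphan I tags are promoted to B instead of
#'   raising an error.
#' @return an object of class `labeled_sentence` with fields `doc_id`,
#'   `sent_id`, `tokens`, `labels`, `start_tags`, `end_tags`.
#' @export
labeled_sentence <- function(tokens, labels, doc_id = "d1", sent_id = 1L,
                             repair = FALSE) {
  tokens <- as.character(tokens)
  labels <- normalize_bio(labels)
  if (length(tokens) != length(labels)) {
    stop("tokens and labels differ in length (", length(tokens), " vs ",
         length(labels), ")")
  }
  if (!bio_valid(labels)) {
    if (repair) labels <- bio_repair(labels)
    else stop("BIO-invalid label sequence (orphan I tag); use repair = TRUE")
  }
  pt <- derive_pointer_tags(labels)
  structure(
    list(doc_id = doc_id, sent_id = as.integer(sent_id), tokens = tokens,
         labels = labels, start_tags = pt$start_tags, end_tags = pt$end_tags),
    class = "labeled_sentence")
}

#' @export
print.labeled_sentence <- function(x, ...) {
  cat("<labeled_sentence ", x$doc_id, ":", x$sent_id, "> ",
      paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Derive start/end pointer tags from BIO labels
#'
#' The start tag is 1 exactly on each B token; the end tag is 1 exactly on
#' the final token of each maximal B/I run; all other positions are 0.
#'
#' @param labels BIO-valid character vector.
#' @return list with integer vectors `start_tags` and `end_tags`.
#' @export
derive_pointer_tags <- function(labels) {
  labels <- normalize_bio(labels)
  if (!bio_valid(labels)) stop("BIO-invalid label sequence")
  sp <- spans_from_labels(labels)
  n <- length(labels)
  st <- integer(n)
  en <- integer(n)
  if (nrow(sp) > 0L) {
    st[sp$start + 1L] <- 1L
    en[sp$end] <- 1L          # end is exclusive; last token is end - 1 (0-based)
  }
  list(start_tags = st, end_tags = en)
}

#' Entity spans from BIO labels
#'
#' One span per maximal B/I run, as 0-based half-open token intervals.
#'
#' @param labels BIO-valid character vector.
#' @return data.frame with integer columns `start`, `end`.
#' @export
spans_from_labels <- function(labels) {
  labels <- normalize_bio(labels)
  if (!bio_valid(labels)) stop("BIO-invalid label sequence")
  s <- short_bio(labels)
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  n <- length(s)
  while (i <= n) {
    if (s[i] == "B") {
      j <- i + 1L
      while (j <= n && s[j] == "I") j <- j + 1L
      starts <- c(starts, i - 1L)   # 0-based
      ends <- c(ends, j - 1L)       # half-open
      i <- j
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

#' BIO labels from entity spans
#'
#' Inverse of [spans_from_labels()].
#'
#' @param spans data.frame with 0-based half-open `start`, `end` columns;
#'   spans must be non-overlapping.
#' @param n sentence length in tokens.
#' @return character vector of BIO tags of length `n`.
#' @export
labels_from_spans <- function(spans, n) {
  lab <- rep(.O, n)
  if (is.null(spans) || nrow(spans) == 0L) return(lab)
  if (any(spans$start < 0L) || any(spans$end > n) || any(spans$start >= spans$end)) {
    stop("span out of bounds or empty")
  }
  o <- order(spans$start)
  spans <- spans[o, , drop = FALSE]
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    stop("overlapping spans")
  }
  for (r in seq_len(nrow(spans))) {
    a <- spans$start[r] + 1L
    b <- spans$end[r]
    lab[a] <- .B
    if (b > a) lab[(a + 1L):b] <- .I
  }
  lab
}

span_surface <- function(tokens, start, end) {
  paste(tokens[(start + 1L):end], collapse = " ")
}

#' Read a CoNLL-format NER corpus
#'
#' Dialect: one token per line, a single separator (default TAB), the BIO
#' tag in the last column, blank line between sentences, optional
#' `-DOCSTART-` lines delimiting documents.
#'
#' @param path file path.
#' @param sep column separator (single character), default `"\t"`.
#' @param ncol expected number of columns (token line must have exactly
#'   this many fields); default 2.
#' @param repair BIO repair policy: `FALSE` (strict, default) rejects
#'   invalid I-after-O; `TRUE` promotes orphan I to B.
#' @return list of [labeled_sentence()] objects.
#' @export
read_conll <- function(path, sep = "\t", ncol = 2L, repair = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- list()
  toks <- character(0)
  labs <- character(0)
  doc_id <- "d1"
  doc_n <- 0L
  sent_id <- 0L
  flush <- function() {
    if (length(toks) > 0L) {
      sent_id <<- sent_id + 1L
      sentences[[length(sentences) + 1L]] <<-
        labeled_sentence(toks, labs, doc_id = doc_id, sent_id = sent_id,
                         repair = repair)
      toks <<- character(0)
      labs <<- character(0)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln)) { flush(); next }
    if (startsWith(ln, "-DOCSTART-")) {
      flush()
      doc_n <- doc_n + 1L
      doc_id <- sprintf("d%d", doc_n)
      sent_id <- 0L
      next
    }
    fields <- strsplit(ln, sep, fixed = TRUE)[[1L]]
    if (length(fields) != ncol) {
      stop("parse error at line ", i, ": expected ", ncol, " columns, got ",
           length(fields))
    }
    toks <- c(toks, fields[1L])
    labs <- c(labs, fields[length(fields)])
  }
  flush()
  sentences
}

#' Write a corpus in CoNLL format
#'
#' @param corpus list of [labeled_sentence()] objects.
#' @param path output file path.
#' @param sep column separator.
#' @param docstart write `-DOCSTART-` lines at document boundaries.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path, sep = "\t", docstart = FALSE) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  last_doc <- NULL
  for (s in corpus) {
    if (docstart && !identical(s$doc_id, last_doc)) {
      writeLines(c("-DOCSTART-", ""), con)
      last_doc <- s$doc_id
    }
    writeLines(paste(s$tokens, s$labels, sep = sep), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Build unlabeled relation instances from a sentence
#'
#' One instance per unordered pair of distinct non-overlapping entity
#' spans; the subject is always the earlier mention.  Sentences with
#' fewer than two entities yield an empty list.
#'
#' @param sentence a [labeled_sentence()].
#' @param spans optional data.frame of spans (0-based half-open); defaults
#'   to the sentence's gold spans.
#' @return list of `relation_instance` objects (fields `doc_id`, `sent_id`,
#'   `tokens`, `subj`, `obj`, `label`), `label` `NA` until classified.
#' @export
build_relation_instances <- function(sentence, spans = NULL) {
  if (is.null(spans)) spans <- spans_from_labels(sentence$labels)
  if (nrow(spans) < 2L) return(list())
  spans <- spans[order(spans$start), , drop = FALSE]
  out <- list()
  idx <- combn(nrow(spans), 2L)
  for (k in seq_len(ncol(idx))) {
    a <- spans[idx[1L, k], ]
    b <- spans[idx[2L, k], ]
    if (a$end > b$start && b$end > a$start) {
      warning("overlapping spans (", a$start, ",", a$end, ") and (",
              b$start, ",", b$end, "); instance skipped")
      next
    }
    out[[length(out) + 1L]] <- relation_instance(
      sentence$tokens, subj = c(a$start, a$end), obj = c(b$start, b$end),
      doc_id = sentence$doc_id, sent_id = sentence$sent_id)
  }
  out
}

#' Construct a relation instance
#'
#' @param tokens sentence tokens.
#' @param subj,obj length-2 integer vectors, 0-based half-open spans; the
#'   subject must be the earlier mention.
#' @param label one of `"unconnected"`, `"undirected"`, `"output"`,
#'   `"input"` (or `NA` for unlabeled candidates).
#' @param doc_id,sent_id provenance.
#' @return an object of class `relation_instance`.
#' @export
relation_instance <- function(tokens, subj, obj, label = NA_character_,
                              doc_id = "d1", sent_id = 1L) {
  subj <- as.integer(subj); obj <- as.integer(obj)
  n <- length(tokens)
  stopifnot(subj[1L] >= 0L, subj[1L] < subj[2L], subj[2L] <= n,
            obj[1L] >= 0L, obj[1L] < obj[2L], obj[2L] <= n)
  if (subj[1L] >= obj[1L]) stop("subject must be the earlier mention")
  if (subj[2L] > obj[1L]) stop("subject and object spans overlap")
  if (!is.na(label) && !label %in% relation_classes()) {
    stop("unknown relation label: ", label)
  }
  structure(
    list(doc_id = doc_id, sent_id = as.integer(sent_id),
         tokens = as.character(tokens), subj = subj, obj = obj,
         label = label),
    class = "relation_instance")
}

#' The four directional relation classes, in canonical order
#' @return character vector.
#' @export
relation_classes <- function() c("unconnected", "undirected", "output", "input")

#' Read / write relation corpora as TSV
#'
#' Columns: doc_id, sent_id, subj_start, subj_end, obj_start, obj_end,
#' label, sentence_text (tokens joined by single spaces).
#'
#' @param path file path.
#' @return list of `relation_instance` objects.
#' @export
read_relations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                   encoding = "UTF-8")
  lapply(seq_len(nrow(df)), function(i) {
    relation_instance(strsplit(df$sentence_text[i], " ", fixed = TRUE)[[1L]],
                      subj = c(df$subj_start[i], df$subj_end[i]),
                      obj = c(df$obj_start[i], df$obj_end[i]),
                      label = if ("label" %in% names(df)) df$label[i] else NA,
                      doc_id = df$doc_id[i], sent_id = df$sent_id[i])
  })
}

#' @rdname read_relations
#' @param instances list of `relation_instance` objects.
#' @export
write_relations <- function(instances, path) {
  df <- do.call(rbind, lapply(instances, function(x) {
    data.frame(doc_id = x$doc_id, sent_id = x$sent_id,
               subj_start = x$subj[1L], subj_end = x$subj[2L],
               obj_start = x$obj[1L], obj_end = x$obj[2L],
               label = x$label,
               sentence_text = paste(x$tokens, collapse = " "),
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

corpus_units <- function(corpus, unit_level) {
  if (unit_level == "document") unique(vapply(corpus, `[[`, "", "doc_id"))
  else seq_along(corpus)
}

# Largest-remainder apportionment of n units to parts with given ratios.
apportion <- function(n, ratios) {
  ratios <- ratios / sum(ratios)
  raw <- n * ratios
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0L) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  as.integer(cnt)
}

#' Split a corpus into train/validation/test sets
#'
#' Document-level splitting assigns whole documents to one part;
#' sentence-level splitting assigns sentences independently.  The split is
#' deterministic given the seed.
#'
#' @param corpus list of labeled sentences (or relation instances with
#'   `doc_id` fields).
#' @param ratios positive numeric vector of length 3 (train, validation,
#'   test); normalized internally.  NER corpora conventionally use 6:1:1,
#'   relation corpora 8:1:1.
#' @param unit_level `"document"` or `"sentence"`.
#' @param seed integer seed.
#' @return list with fields `train`, `validation`, `test` (unit ids) and
#'   `unit_level`.
#' @export
split_corpus <- function(corpus, ratios = c(6, 1, 1),
                         unit_level = c("document", "sentence"), seed = 1L) {
  unit_level <- match.arg(unit_level)
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  units <- corpus_units(corpus, unit_level)
  if (length(units) < 3L) stop("fewer units than split parts")
  cnt <- apportion(length(units), ratios)
  perm <- local({ set.seed(seed); sample(units) })
  structure(list(train = perm[seq_len(cnt[1L])],
                 validation = perm[cnt[1L] + seq_len(cnt[2L])],
                 test = perm[cnt[1L] + cnt[2L] + seq_len(cnt[3L])],
                 unit_level = unit_level),
            class = "corpus_split")
}

#' Select the sentences of a corpus belonging to a set of units
#'
#' @param corpus list of sentences/instances.
#' @param units unit ids as returned by [split_corpus()] or [make_folds()].
#' @param unit_level `"document"` or `"sentence"`.
#' @return sub-list of `corpus`.
#' @export
subset_units <- function(corpus, units, unit_level = "document") {
  if (unit_level == "document") {
    keep <- vapply(corpus, function(s) s$doc_id %in% units, logical(1))
    corpus[keep]
  } else corpus[sort(as.integer(units))]
}

#' k-fold assignments by rotating blocks over a seeded shuffle
#'
#' Units are shuffled once with the seed, cut into k blocks, and fold i
#' uses block i as the test set (and block i+1, cyclically, as validation
#' when requested).
#'
#' @param corpus corpus list.
#' @param k number of folds (>= 2).
#' @param unit_level `"document"` or `"sentence"`.
#' @param seed integer seed.
#' @return list of k lists with fields `train`, `test` (and `validation`).
#' @export
make_folds <- function(corpus, k, unit_level = c("document", "sentence"),
                       seed = 1L) {
  unit_level <- match.arg(unit_level)
  stopifnot(k >= 2L)
  units <- corpus_units(corpus, unit_level)
  if (k > length(units)) stop("k larger than unit count")
  perm <- local({ set.seed(seed); sample(units) })
  block <- rep(seq_len(k), length.out = length(perm))
  block <- sort(block)   # contiguous blocks of near-equal size
  lapply(seq_len(k), function(i) {
    test <- perm[block == i]
    vali <- perm[block == (i %% k) + 1L]
    list(train = setdiff(perm, c(test, vali)), validation = vali,
         test = test, unit_level = unit_level)
  })
}
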