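# Shared generators for property-style tests.  Everything is built in
# code under fixed seeds; no stored fixtures.

# A random BIO-valid label sequence of length n.
rand_bio <- function(n, p_entity = 0.4) {
  lab <- character(n)
  prev <- "O"
  for (i in seq_len(n)) {
    lab[i] <- if (prev %in% c("B-BrainRegion", "I-BrainRegion")) {
      sample(c("O", "B-BrainRegion", "I-BrainRegion"), 1L,
             prob = c(1 - p_entity, p_entity / 2, p_entity / 2))
    } else {
      sample(c("O", "B-BrainRegion"), 1L, prob = c(1 - p_entity, p_entity))
    }
    prev <- lab[i]
  }
  lab
}

# A random set of non-overlapping 0-based half-open spans in [0, n).
rand_spans <- function(n, max_spans = 3L, max_len = 4L) {
  starts <- integer(0); ends <- integer(0)
  i <- 0L
  while (i < n && length(starts) < max_spans) {
    if (runif(1) < 0.4) {
      len <- sample.int(min(max_len, n - i), 1L)
      starts <- c(starts, i); ends <- c(ends, i + len)
      i <- i + len
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

# Random sigmoid-style activation matrices for a sentence of length n.
rand_ner_pred <- function(n) {
  m <- function(k) matrix(runif(n * k, 0.01, 0.99), n, k)
  structure(list(label = m(3L), start = m(2L), end = m(2L)),
            class = "ner_prediction")
}

# A random relation instance over a filler vocabulary.
rand_instance <- function(n = 12L) {
  stopifnot(n >= 4L)
  toks <- sprintf("w%02d", sample.int(99L, n, replace = TRUE))
  s1 <- sample.int(n - 3L, 1L) - 1L
  e1 <- s1 + sample.int(min(3L, n - 2L - s1), 1L)
  s2 <- e1 + sample.int(n - e1 - 1L, 1L) - 1L
  s2 <- max(s2, e1)
  e2 <- s2 + sample.int(n - s2, 1L)
  relation_instance(toks, subj = c(s1, e1), obj = c(s2, e2),
                    label = sample(relation_classes(), 1L))
}

# A tiny handcrafted dictionary for linking tests.
toy_dict <- function() {
  rbind(
    ontology_entry("A:01", "ventral tegmental area", abbreviations = "VTA",
                   source = "allen"),
    ontology_entry("A:02", "lateral habenula", abbreviations = "LHb",
                   source = "allen"),
    ontology_entry("A:03", "paraventricular nucleus of the thalamus",
                   abbreviations = "PVT", synonyms = "paraventricular thalamic nucleus",
                   source = "allen"),
    ontology_entry("A:04", "hippocampus", source = "allen"),
    ontology_entry("A:05", "CA1", source = "allen"),
    ontology_entry("A:06", "geniculate nucleus", source = "allen"))
}
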