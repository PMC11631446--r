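# Synthetic ontologies and corpora with known ground truth.
#
# Region names are assembled from a closed vocabulary of anatomical-style
# tokens: a name-initial modifier, optional middle modifiers, and a head
# noun.  Connectivity sentences are instantiated from directional
# templates whose trigger words are distinct per class, so the tasks have
# a known achievable ceiling and parameter-recovery experiments measure
# model correctness rather than task hardness.  Boundary noise corrupts
# only training labels; ground truth stays clean.

SYN_FIRST <- c("paraventricular", "suprachiasmatic", "retrosplenial",
               "entopeduncular", "parabrachial", "habenular", "accumbal",
               "cuneate", "gracile", "rubral", "tegmental", "olivary",
               "pontine", "septal", "fastigial", "interpeduncular",
               "supramammillary", "subthalamic", "endopiriform",
               "claustral", "ambiguual", "arcuate", "incertal", "preoptic")

SYN_MID <- c("magnocellular", "parvicellular", "granular", "reticular",
             "compact", "gelatinous", "marginal", "principal",
             "accessory", "commissural", "intermediate", "oval")

SYN_HEAD <- c("nucleus", "area", "cortex", "field", "tract", "complex",
              "formation", "ganglion", "zone", "segment")

# head-noun alternates used to mint synonyms
SYN_HEAD_ALT <- c(nucleus = "center", area = "region", cortex = "mantle",
                  field = "sector", tract = "bundle", complex = "group",
                  formation = "body", ganglion = "plexus", zone = "belt",
                  segment = "division")

SYN_TEMPLATES <- list(
  output = list(
    c("the", "@S", "projects", "to", "the", "@O", "."),
    c("the", "@S", "sends", "dense", "projections", "to", "the", "@O", "."),
    c("anterograde", "tracing", "showed", "that", "the", "@S", "projects",
      "to", "the", "@O", ".")),
  input = list(
    c("the", "@S", "receives", "input", "from", "the", "@O", "."),
    c("the", "@S", "receives", "afferents", "from", "the", "@O", "."),
    c("the", "@S", "is", "innervated", "by", "the", "@O", ".")),
  undirected = list(
    c("the", "@S", "is", "reciprocally", "connected", "with", "the",
      "@O", "."),
    c("the", "@S", "shares", "connections", "with", "the", "@O", ".")),
  unconnected = list(
    c("the", "@S", "and", "the", "@O", "were", "examined", "in", "adult",
      "rats", "."),
    c("strong", "staining", "was", "observed", "in", "the", "@S", "and",
      "the", "@O", ".")))

SYN_FILLER_TEMPLATES <- list(
  c("the", "@S", "was", "lesioned", "."),
  c("neurons", "in", "the", "@S", "were", "labeled", "."),
  c("the", "@S", "showed", "strong", "staining", "."))

#' Configuration for the synthetic generator
#'
#' Defaults mirror the shape of the literature corpora the pipeline is
#' built for: multi-word region names (1-5 words), a 6:1:1-splittable
#' document corpus of 100 documents x 20 sentences, and a directional
#' class mix matching the published directional corpus frequencies
#' (unconnected 84.9%, undirected 5.3%, output 7.1%, input 2.7%).
#'
#' @param n_regions number of ontology entries (>= 2).
#' @param name_length_weights sampling weights for name lengths 1-5.
#' @param synonym_rate,abbreviation_rate per-entry probability of carrying
#'   a synonym / an abbreviation.
#' @param n_documents,sentences_per_document corpus dimensions.
#' @param relation_class_mix named proportions over the four relation
#'   classes (must sum to 1).
#' @param boundary_noise_rate fraction of multi-token training spans whose
#'   one boundary token is truncated (training labels only).
#' @param p_single_entity fraction of sentences holding a single mention
#'   (NER-only filler).
#' @param mention_form_probs probabilities of rendering a mention as
#'   canonical name / synonym / abbreviation.
#' @param seed mandatory integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_regions = 40L,
                         name_length_weights = c(0.15, 0.35, 0.30, 0.15, 0.05),
                         synonym_rate = 0.3, abbreviation_rate = 0.5,
                         n_documents = 100L, sentences_per_document = 20L,
                         relation_class_mix = c(unconnected = 0.849,
                                                undirected = 0.053,
                                                output = 0.071,
                                                input = 0.027),
                         boundary_noise_rate = 0,
                         p_single_entity = 0.15,
                         mention_form_probs = c(canonical = 0.7,
                                                synonym = 0.2,
                                                abbreviation = 0.1),
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_regions >= 2L, length(name_length_weights) == 5L,
            synonym_rate >= 0, synonym_rate <= 1,
            abbreviation_rate >= 0, abbreviation_rate <= 1,
            boundary_noise_rate >= 0, boundary_noise_rate <= 1)
  mix <- relation_class_mix[relation_classes()]
  if (anyNA(mix)) stop("relation_class_mix must name all four classes")
  if (abs(sum(mix) - 1) > 1e-6) stop("relation_class_mix must sum to 1")
  structure(list(n_regions = as.integer(n_regions),
                 name_length_weights = name_length_weights,
                 synonym_rate = synonym_rate,
                 abbreviation_rate = abbreviation_rate,
                 n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 relation_class_mix = mix,
                 boundary_noise_rate = boundary_noise_rate,
                 p_single_entity = p_single_entity,
                 mention_form_probs = mention_form_probs,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Mint a synonym by swapping the head noun for its alternate (or
# suffixing single-word names).
mint_synonym <- function(words) {
  k <- length(words)
  if (k == 1L) return(paste(c(words, "proper"), collapse = " "))
  alt <- SYN_HEAD_ALT[[words[k]]]
  paste(c(words[-k], alt), collapse = " ")
}

#' Generate a toy brain-region ontology
#'
#' Unique multi-word names from the closed anatomical-style vocabulary;
#' synonyms are head-noun variants, abbreviations are uppercase initials
#' (skipped on collision so every abbreviation stays unambiguous).
#' Deterministic given the config seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `dict` (dictionary data.frame, source `"synthetic"`)
#'   and `gazetteer` (a [gazetteer()] over it).
#' @export
generate_ontology <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_regions
  max_tuples <- length(SYN_FIRST) * length(SYN_HEAD) * (1 + length(SYN_MID))
  if (n > max_tuples) stop("vocabulary exhausted: cannot mint ", n,
                           " unique names")
  seen <- character(0)
  abbrs <- character(0)
  rows <- vector("list", n)
  i <- 0L
  guard <- 0L
  while (i < n) {
    guard <- guard + 1L
    if (guard > 50L * n) stop("vocabulary exhausted while sampling names")
    k <- sample.int(5L, 1L, prob = cfg$name_length_weights)
    words <- c(sample(SYN_FIRST, 1L),
               if (k >= 3L) sample(SYN_MID, k - 2L),
               if (k >= 2L) sample(SYN_HEAD, 1L))
    name <- paste(words, collapse = " ")
    if (name %in% seen) next
    seen <- c(seen, name)
    i <- i + 1L
    syn <- if (runif(1) < cfg$synonym_rate) mint_synonym(words)
    abbr <- if (runif(1) < cfg$abbreviation_rate) {
      a <- paste(toupper(substr(words, 1L, 1L)), collapse = "")
      if (a %in% abbrs) NULL else { abbrs <- c(abbrs, a); a }
    }
    rows[[i]] <- ontology_entry(sprintf("SYN:%03d", i), name,
                                abbreviations = abbr %||% character(0),
                                synonyms = syn %||% character(0),
                                species = "mouse", source = "synthetic")
  }
  dict <- do.call(rbind, rows)
  list(dict = dict, gazetteer = gazetteer(dict))
}

# Render a region mention; returns its tokens and the form used.
render_mention <- function(entry, probs) {
  forms <- c("canonical")
  p <- c(probs[["canonical"]])
  syn <- split_bar(entry$synonyms)
  abbr <- split_bar(entry$abbreviations)
  if (length(syn) > 0L) { forms <- c(forms, "synonym"); p <- c(p, probs[["synonym"]]) }
  if (length(abbr) > 0L) { forms <- c(forms, "abbreviation"); p <- c(p, probs[["abbreviation"]]) }
  form <- sample(forms, 1L, prob = p)
  surface <- switch(form, canonical = entry$name, synonym = syn[1L],
                    abbreviation = abbr[1L])
  list(tokens = strsplit(surface, " ", fixed = TRUE)[[1L]], form = form)
}

# Truncate one boundary token of a multi-token span (training noise).
corrupt_span <- function(labels, span) {
  len <- span$end - span$start
  if (len < 2L) return(labels)
  if (runif(1) < 0.5) {
    labels[span$start + 1L] <- "O"               # drop first token
    labels[span$start + 2L] <- "B-BrainRegion"
  } else {
    labels[span$end] <- "O"                      # drop last token
  }
  labels
}

#' Generate a labeled corpus with known ground truth
#'
#' Documents are filled with template sentences: a fraction hold a single
#' mention (NER filler), the rest hold two mentions and a relation label
#' drawn from the configured class mix.  Emits the clean NER corpus, a
#' boundary-noised copy of the training labels (when
#' `boundary_noise_rate > 0`), the labeled relation instances, and the
#' gold connectivity graph implied by the directed/undirected relations.
#'
#' @param cfg a [synth_config()].
#' @param ontology result of [generate_ontology()] (regenerated from `cfg`
#'   when omitted).
#' @return list with `ner` (clean [labeled_sentence()] list), `ner_noisy`
#'   (same tokens, noised labels), `relations` (labeled
#'   [relation_instance()] list), `gold_triples` (data.frame),
#'   `gold_graph` (a `conn_kg`) and `dict`.
#' @export
generate_corpus <- function(cfg, ontology = NULL) {
  if (is.null(ontology)) ontology <- generate_ontology(cfg)
  dict <- ontology$dict
  if (nrow(dict) < 2L) stop("ontology must hold at least two regions")
  set.seed(cfg$seed + 1L)
  classes <- relation_classes()
  ner <- list()
  ner_noisy <- list()
  relations <- list()
  triples <- list()
  for (d in seq_len(cfg$n_documents)) {
    doc_id <- sprintf("doc%03d", d)
    for (s in seq_len(cfg$sentences_per_document)) {
      if (runif(1) < cfg$p_single_entity) {
        tpl <- SYN_FILLER_TEMPLATES[[sample.int(length(SYN_FILLER_TEMPLATES), 1L)]]
        e1 <- dict[sample.int(nrow(dict), 1L), ]
        m1 <- render_mention(e1, cfg$mention_form_probs)
        at <- which(tpl == "@S")
        toks <- c(tpl[seq_len(at - 1L)], m1$tokens, tpl[-seq_len(at)])
        span1 <- data.frame(start = at - 1L, end = at - 1L + length(m1$tokens))
        labels <- labels_from_spans(span1, length(toks))
        cls <- NA_character_
        spans <- span1
        ids <- e1$id
      } else {
        cls <- sample(classes, 1L, prob = cfg$relation_class_mix)
        tpls <- SYN_TEMPLATES[[cls]]
        tpl <- tpls[[sample.int(length(tpls), 1L)]]
        pair <- sample.int(nrow(dict), 2L)
        e1 <- dict[pair[1L], ]; e2 <- dict[pair[2L], ]
        m1 <- render_mention(e1, cfg$mention_form_probs)
        m2 <- render_mention(e2, cfg$mention_form_probs)
        at1 <- which(tpl == "@S")
        at2 <- which(tpl == "@O")
        toks <- c(tpl[seq_len(at1 - 1L)], m1$tokens,
                  tpl[(at1 + 1L):(at2 - 1L)], m2$tokens,
                  tpl[-seq_len(at2)])
        st1 <- at1 - 1L
        st2 <- at2 - 2L + length(m1$tokens)
        spans <- data.frame(start = c(st1, st2),
                            end = c(st1 + length(m1$tokens),
                                    st2 + length(m2$tokens)))
        labels <- labels_from_spans(spans, length(toks))
        ids <- c(e1$id, e2$id)
      }
      sent <- labeled_sentence(toks, labels, doc_id = doc_id, sent_id = s)
      ner[[length(ner) + 1L]] <- sent
      noisy <- labels
      if (cfg$boundary_noise_rate > 0) {
        for (r in seq_len(nrow(spans))) {
          if (runif(1) < cfg$boundary_noise_rate) {
            noisy <- corrupt_span(noisy, spans[r, ])
          }
        }
      }
      ner_noisy[[length(ner_noisy) + 1L]] <-
        labeled_sentence(toks, noisy, doc_id = doc_id, sent_id = s)
      if (!is.na(cls)) {
        relations[[length(relations) + 1L]] <-
          relation_instance(toks, subj = c(spans$start[1L], spans$end[1L]),
                            obj = c(spans$start[2L], spans$end[2L]),
                            label = cls, doc_id = doc_id, sent_id = s)
        tr <- canonicalize(cls, ids[1L], ids[2L], pmid = doc_id, sent_id = s,
                           evidence = paste(toks, collapse = " "))
        if (!is.null(tr)) triples[[length(triples) + 1L]] <- tr
      }
    }
  }
  gold_triples <- if (length(triples) > 0L) do.call(rbind, triples) else NULL
  list(ner = ner, ner_noisy = ner_noisy, relations = relations,
       gold_triples = gold_triples, gold_graph = build_graph(gold_triples),
       dict = dict)
}

#' Perturbed-mention suite for linking experiments
#'
#' For each sampled ontology entry, emits the exact name plus controlled
#' perturbations targeting the staged matcher: case variants (exact
#' stage), a directional-word prefix (stripping stage), an appended
#' unknown word (nested stage), a word reordering (fuzzy stage) and
#' out-of-dictionary junk (must stay unlinked).
#'
#' @param ontology result of [generate_ontology()].
#' @param n number of base entries to sample.
#' @param seed integer seed.
#' @return data.frame with `mention`, `true_id` (`NA` for junk) and
#'   `kind`.
#' @export
perturb_mentions <- function(ontology, n = 25L, seed = 1L) {
  dict <- ontology$dict
  set.seed(seed)
  base <- dict[sample.int(nrow(dict), min(n, nrow(dict))), ]
  rows <- lapply(seq_len(nrow(base)), function(i) {
    e <- base[i, ]
    w <- strsplit(e$name, " ", fixed = TRUE)[[1L]]
    reordered <- paste(rev(w), collapse = " ")
    data.frame(
      mention = c(e$name,
                  paste(toupper(substr(e$name, 1L, 1L)),
                        substr(e$name, 2L, nchar(e$name)), sep = ""),
                  paste(sample(directional_lexicon(), 1L), e$name),
                  paste(e$name, "injections"),
                  reordered),
      true_id = e$id,
      kind = c("exact", "case", "directional", "nested", "reordered"),
      stringsAsFactors = FALSE)
  })
  junk <- data.frame(mention = sprintf("qq%02d zz%02d", seq_len(5L),
                                       seq_len(5L)),
                     true_id = NA_character_, kind = "junk",
                     stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), junk)
  rownames(out) <- NULL
  out
}
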