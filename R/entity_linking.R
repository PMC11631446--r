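# Ontology merging and entity normalization.
#
# A dictionary row holds one brain-region concept: stable id, canonical
# name, |-separated abbreviations and synonyms, species and source
# nomenclature tags.  Mentions are linked by staged matching: exact ->
# directional-word stripping -> nested sub-mention lookup -> word-level
# fuzzy scoring.  Abbreviations are matched exactly only (short forms are
# too collision-prone for fuzzy matching).

LINK_STOPWORDS <- c("of", "the", "a", "an")

#' Default lexicon of directional/positional words stripped before
#' fallback matching
#' @return character vector.
#' @export
directional_lexicon <- function() {
  c("rostral", "caudal", "dorsal", "ventral", "anterior", "posterior",
    "medial", "lateral", "superior", "inferior", "left", "right")
}

# Phrase normalization for linking: case-fold, strip punctuation, drop
# stopwords.
norm_phrase <- function(x, casefold = TRUE, drop_stopwords = TRUE) {
  if (casefold) x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  w <- strsplit(trimws(x), "\\s+")[[1L]]
  if (drop_stopwords) w <- w[!(w %in% LINK_STOPWORDS)]
  paste(w, collapse = " ")
}

norm_words <- function(x, casefold = TRUE) {
  unique(strsplit(norm_phrase(x, casefold = casefold), " ", fixed = TRUE)[[1L]])
}

split_bar <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, "|", fixed = TRUE)[[1L]]
}

#' Construct an ontology entry
#'
#' @param id stable identifier.
#' @param name canonical (full) name, nonempty.
#' @param abbreviations,synonyms character vectors (stored |-separated).
#' @param species species tag, e.g. `"mouse"`.
#' @param source nomenclature tag, e.g. `"allen"`.
#' @return one-row data.frame.
#' @export
ontology_entry <- function(id, name, abbreviations = character(0),
                           synonyms = character(0), species = "mouse",
                           source = "src") {
  stopifnot(nzchar(id), nzchar(name))
  data.frame(id = id, name = name,
             abbreviations = paste(abbreviations, collapse = "|"),
             synonyms = paste(synonyms, collapse = "|"),
             species = species, source = source,
             stringsAsFactors = FALSE)
}

#' Read / write an ontology dictionary
#'
#' TSV columns: id, name, abbreviations (|-separated), synonyms
#' (|-separated), species, source.  A `.json` path reads/writes the same
#' records as a JSON array.
#'
#' @param path file path (`.tsv` or `.json`).
#' @return data.frame dictionary.
#' @export
read_ontology <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE, quote = "",
               encoding = "UTF-8")
  }
  for (col in c("abbreviations", "synonyms", "species", "source")) {
    if (is.null(df[[col]])) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

#' @rdname read_ontology
#' @param dict dictionary data.frame.
#' @export
write_ontology <- function(dict, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(dict, path, auto_unbox = FALSE)
  } else {
    write.table(dict, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Merge ontology sources into one dictionary
#'
#' Entries from different sources are unified when their species match
#' and their normalized canonical names are exactly equal; the unified
#' entry keeps the first source's id and the union of abbreviations and
#' synonyms.  A cross-reference table records the source ids.
#' Abbreviations shared by entries that name different structures are a
#' collision: the entries stay separate and the collision is logged.
#'
#' @param sources list of dictionary data.frames (each with a `source`
#'   column), or a single combined data.frame.
#' @return unified dictionary data.frame with attributes `crossref`
#'   (unified_id, source, source_id) and `collisions` (abbreviation,
#'   ids).
#' @export
merge_ontologies <- function(sources) {
  if (is.data.frame(sources)) sources <- list(sources)
  if (length(sources) < 1L) stop("at least one source required")
  all_df <- do.call(rbind, sources)
  key <- paste(all_df$species, vapply(all_df$name, norm_phrase, ""), sep = "\r")
  groups <- split(seq_len(nrow(all_df)), key)
  # preserve first-appearance order of groups
  first <- vapply(groups, min, integer(1))
  groups <- groups[order(first)]
  rows <- lapply(groups, function(ix) {
    g <- all_df[ix, , drop = FALSE]
    abbr <- unique(unlist(lapply(g$abbreviations, split_bar)))
    syn <- unique(c(unlist(lapply(g$synonyms, split_bar)),
                    g$name[-1L][g$name[-1L] != g$name[1L]]))
    data.frame(id = g$id[1L], name = g$name[1L],
               abbreviations = paste(abbr, collapse = "|"),
               synonyms = paste(syn, collapse = "|"),
               species = g$species[1L],
               source = paste(unique(g$source), collapse = "|"),
               stringsAsFactors = FALSE)
  })
  dict <- do.call(rbind, rows)
  rownames(dict) <- NULL
  crossref <- do.call(rbind, lapply(seq_along(groups), function(k) {
    g <- all_df[groups[[k]], , drop = FALSE]
    data.frame(unified_id = dict$id[k], source = g$source,
               source_id = g$id, stringsAsFactors = FALSE)
  }))
  # abbreviation collisions across distinct unified entries
  ab <- lapply(dict$abbreviations, split_bar)
  pairs <- data.frame(
    abbr = unlist(ab),
    id = rep(dict$id, lengths(ab)), stringsAsFactors = FALSE)
  collisions <- if (nrow(pairs) > 0L) {
    tab <- split(pairs$id, pairs$abbr)
    tab <- tab[lengths(lapply(tab, unique)) > 1L]
    if (length(tab) > 0L) {
      message("abbreviation collision(s): ",
              paste(names(tab), collapse = ", "),
              " shared by distinct entries; entries kept separate")
    }
    data.frame(abbreviation = rep(names(tab), lengths(tab)),
               id = unlist(tab, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else data.frame(abbreviation = character(0), id = character(0))
  attr(dict, "crossref") <- crossref
  attr(dict, "collisions") <- collisions
  dict
}

# ---- Gazetteer -------------------------------------------------------------

#' Build a gazetteer (prefix-index over all dictionary surface forms)
#'
#' Canonical names and synonyms are stored under their case-folded
#' token form; abbreviations are stored verbatim (matched
#' case-sensitively).  Supports longest-match scanning over token
#' sequences.
#'
#' @param dict dictionary data.frame.
#' @param include_abbreviations store abbreviations too (default TRUE).
#' @return object of class `gazetteer`.
#' @export
gazetteer <- function(dict, include_abbreviations = TRUE) {
  env <- new.env(parent = emptyenv())
  maxw <- 0L
  add <- function(form, id, raw = FALSE) {
    key <- if (raw) paste0("\r", form)
    else paste(strsplit(norm_phrase(form, drop_stopwords = FALSE),
                        " ", fixed = TRUE)[[1L]], collapse = " ")
    if (!nzchar(key)) return()
    nw <- length(strsplit(key, " ", fixed = TRUE)[[1L]])
    maxw <<- max(maxw, nw)
    env[[key]] <- unique(c(env[[key]], id))
  }
  for (i in seq_len(nrow(dict))) {
    add(dict$name[i], dict$id[i])
    for (s in split_bar(dict$synonyms[i])) add(s, dict$id[i])
    if (include_abbreviations) {
      for (a in split_bar(dict$abbreviations[i])) add(a, dict$id[i], raw = TRUE)
    }
  }
  structure(list(index = env, max_words = maxw), class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat("<gazetteer forms=", length(ls(x$index)),
      " max_words=", x$max_words, ">\n", sep = "")
  invisible(x)
}

gazetteer_empty <- function(gz) length(ls(gz$index)) == 0L

#' Look up a single surface form in a gazetteer
#'
#' @param gz a [gazetteer()].
#' @param form surface string.
#' @return character vector of matching ids (empty when absent).
#' @export
gazetteer_lookup <- function(gz, form) {
  key <- paste(strsplit(norm_phrase(form, drop_stopwords = FALSE),
                        " ", fixed = TRUE)[[1L]], collapse = " ")
  hit <- gz$index[[key]]
  if (is.null(hit)) hit <- gz$index[[paste0("\r", form)]]
  if (is.null(hit)) character(0) else hit
}

#' Scan a token sequence for maximal longest gazetteer matches
#'
#' Greedy leftmost-longest: at each position the longest matching window
#' wins and scanning resumes after it, so reported matches never overlap.
#'
#' @param gz a [gazetteer()].
#' @param tokens character vector.
#' @return data.frame with 0-based half-open `start`, `end`, the matched
#'   `form`, and `ids` (list column).
#' @export
gazetteer_scan <- function(gz, tokens) {
  n <- length(tokens)
  norm <- vapply(tokens, function(t) {
    norm_phrase(t, drop_stopwords = FALSE)
  }, character(1), USE.NAMES = FALSE)
  out_s <- integer(0); out_e <- integer(0)
  out_f <- character(0); out_ids <- list()
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    hit_ids <- NULL
    for (len in rev(seq_len(min(gz$max_words, n - i + 1L)))) {
      key <- paste(norm[i:(i + len - 1L)], collapse = " ")
      ids <- if (nzchar(key)) gz$index[[key]]
      if (is.null(ids) && len == 1L && nzchar(tokens[i])) {
        ids <- gz$index[[paste0("\r", tokens[i])]]
      }
      if (!is.null(ids)) { hit_len <- len; hit_ids <- ids; break }
    }
    if (hit_len > 0L) {
      out_s <- c(out_s, i - 1L)
      out_e <- c(out_e, i + hit_len - 1L)
      out_f <- c(out_f, paste(tokens[i:(i + hit_len - 1L)], collapse = " "))
      out_ids[[length(out_ids) + 1L]] <- hit_ids
      i <- i + hit_len
    } else i <- i + 1L
  }
  df <- data.frame(start = out_s, end = out_e, form = out_f,
                   stringsAsFactors = FALSE)
  df$ids <- out_ids
  df
}

# ---- Staged linking --------------------------------------------------------

link_result <- function(mention, id = NA_character_, score = 0,
                        method = "none", trace = character(0)) {
  structure(list(mention = mention, id = id, score = score, method = method,
                 trace = trace),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat("<link_result '", x$mention, "' -> ",
      if (is.na(x$id)) "<none>" else x$id,
      " (", x$method, ", score ", format(x$score, digits = 3), ")>\n",
      sep = "")
  invisible(x)
}

# Internal exact lookup tables, built once per dictionary and cached on it.
link_tables <- function(dict) {
  tab <- attr(dict, ".link_tables")
  if (!is.null(tab)) return(tab)
  names_norm <- vapply(dict$name, norm_phrase, "", USE.NAMES = FALSE)
  syn <- lapply(dict$synonyms, split_bar)
  syn_norm <- lapply(syn, function(s) vapply(s, norm_phrase, "", USE.NAMES = FALSE))
  abbr <- lapply(dict$abbreviations, split_bar)
  list(names_norm = names_norm, syn_norm = syn_norm, abbr = abbr)
}

#' Exact dictionary lookup of a mention
#'
#' Matches the normalized mention against canonical names and synonyms
#' (case-folded, punctuation stripped, stopwords dropped) and the raw
#' mention against abbreviations (exact, case-sensitive).  Ambiguity is
#' resolved to the lexicographically smallest id.
#'
#' @param mention surface string.
#' @param dict dictionary data.frame.
#' @return a `link_result` (`id` `NA` on miss; score 1 and method
#'   `"exact"` on hit).
#' @export
exact_link <- function(mention, dict) {
  tab <- link_tables(dict)
  m <- norm_phrase(mention)
  hits <- dict$id[tab$names_norm == m]
  hits <- c(hits, dict$id[vapply(tab$syn_norm, function(s) m %in% s, logical(1))])
  raw <- trimws(mention)
  hits <- c(hits, dict$id[vapply(tab$abbr, function(a) raw %in% a, logical(1))])
  if (length(hits) == 0L) return(link_result(mention))
  link_result(mention, id = sort(unique(hits))[1L], score = 1,
              method = "exact")
}

#' Remove directional words from a mention
#'
#' Never empties the mention: if every word is directional the original
#' string is returned.
#'
#' @param mention surface string.
#' @param lexicon directional word list, default [directional_lexicon()].
#' @return reduced mention string.
#' @export
strip_directional <- function(mention, lexicon = directional_lexicon()) {
  w <- strsplit(trimws(mention), "\\s+")[[1L]]
  keep <- !(tolower(w) %in% lexicon)
  if (!any(keep)) return(mention)
  paste(w[keep], collapse = " ")
}

#' Nested sub-mention candidates from the gazetteer
#'
#' Maximal gazetteer longest-matches strictly inside the mention (a match
#' covering the whole mention is excluded), ordered by surface length
#' (characters) then position.
#'
#' @param mention surface string (>= 2 words for any candidates).
#' @param gz a [gazetteer()].
#' @return character vector of candidate sub-mention surfaces.
#' @export
nested_fallback <- function(mention, gz) {
  toks <- strsplit(trimws(mention), "\\s+")[[1L]]
  if (length(toks) < 2L) return(character(0))
  m <- gazetteer_scan(gz, toks)
  if (nrow(m) == 0L) return(character(0))
  m <- m[!(m$start == 0L & m$end == length(toks)), , drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  m <- m[order(-nchar(m$form), m$start), , drop = FALSE]
  m$form
}

#' Word-level fuzzy linking
#'
#' The mention is split into words (normalized, stopwords dropped) and
#' compared with every dictionary term (canonical name and synonyms).
#' For a term t and mention m the score is
#' `w * |m & t| / |m| + (1 - w) * |m & t| / |t|` over unique word sets;
#' an entry scores the best of its terms.  Candidates are ranked by score
#' (desc), then fewer term words, then lexicographic id.
#'
#' @param mention surface string.
#' @param dict dictionary data.frame.
#' @param w weight of the mention-side fraction, default 0.5.
#' @param threshold acceptance threshold on the top score, default 0.5.
#' @param max_results maximum candidates returned.
#' @return data.frame of ranked candidates (`id`, `term`, `score`,
#'   `n_term_words`, `accepted`); zero rows when nothing scores > 0.
#' @export
fuzzy_word_link <- function(mention, dict, w = 0.5, threshold = 0.5,
                            max_results = 5L) {
  mw <- norm_words(mention)
  if (length(mw) == 0L || nrow(dict) == 0L) {
    return(data.frame(id = character(0), term = character(0),
                      score = numeric(0), n_term_words = integer(0),
                      accepted = logical(0)))
  }
  rows <- lapply(seq_len(nrow(dict)), function(i) {
    terms <- c(dict$name[i], split_bar(dict$synonyms[i]))
    best <- NULL
    for (t in terms) {
      tw <- norm_words(t)
      if (length(tw) == 0L) next
      inter <- sum(mw %in% tw)
      sc <- w * inter / length(mw) + (1 - w) * sum(tw %in% mw) / length(tw)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && length(tw) < best$n)) {
        best <- list(term = t, score = sc, n = length(tw))
      }
    }
    if (is.null(best) || best$score <= 0) return(NULL)
    data.frame(id = dict$id[i], term = best$term, score = best$score,
               n_term_words = best$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(id = character(0), term = character(0),
                      score = numeric(0), n_term_words = integer(0),
                      accepted = logical(0)))
  }
  out <- out[order(-out$score, out$n_term_words, out$id), , drop = FALSE]
  out <- head(out, max_results)
  rownames(out) <- NULL
  out$accepted <- seq_len(nrow(out)) == 1L & out$score >= threshold
  out
}

#' Link a mention to the dictionary by staged matching
#'
#' Stages run in order: exact -> directional-word stripping + exact ->
#' nested sub-mention + exact -> word-level fuzzy.  The first success
#' wins; the `method` field records the stage and `trace` lists every
#' stage attempted.
#'
#' @param mention surface string.
#' @param dict dictionary data.frame.
#' @param gz optional [gazetteer()] over `dict` (built on the fly when
#'   omitted).
#' @param fuzzy_w,fuzzy_threshold fuzzy-stage parameters (see
#'   [fuzzy_word_link()]).
#' @param lexicon directional lexicon for the stripping stage.
#' @return a `link_result`; `id` is `NA` when every stage misses.
#' @export
link_mention <- function(mention, dict, gz = NULL, fuzzy_w = 0.5,
                         fuzzy_threshold = 0.5,
                         lexicon = directional_lexicon()) {
  trace <- "exact"
  r <- exact_link(mention, dict)
  if (!is.na(r$id)) { r$trace <- trace; return(r) }
  reduced <- strip_directional(mention, lexicon)
  if (!identical(reduced, mention)) {
    trace <- c(trace, "strip_directional")
    r2 <- exact_link(reduced, dict)
    if (!is.na(r2$id)) {
      return(link_result(mention, id = r2$id, score = 1,
                         method = "strip_directional", trace = trace))
    }
  }
  if (is.null(gz)) gz <- gazetteer(dict)
  cands <- nested_fallback(mention, gz)
  if (length(cands) > 0L) {
    trace <- c(trace, "nested")
    for (cm in cands) {
      r3 <- exact_link(cm, dict)
      if (!is.na(r3$id)) {
        return(link_result(mention, id = r3$id, score = 1,
                           method = "nested", trace = trace))
      }
    }
  }
  trace <- c(trace, "fuzzy_word")
  fz <- fuzzy_word_link(mention, dict, w = fuzzy_w,
                        threshold = fuzzy_threshold)
  if (nrow(fz) > 0L && fz$accepted[1L]) {
    return(link_result(mention, id = fz$id[1L], score = fz$score[1L],
                       method = "fuzzy_word", trace = trace))
  }
  link_result(mention, trace = trace)
}

#' Link a batch of mentions; report the mapping rate
#'
#' @param mentions character vector.
#' @param dict dictionary data.frame.
#' @param stages `"all"` (staged fallbacks) or `"exact"` (exact only).
#' @param ... passed to [link_mention()].
#' @return data.frame (mention, id, score, method) with attribute
#'   `mapping_rate` (fraction of mentions linked).
#' @export
link_mentions <- function(mentions, dict, stages = c("all", "exact"), ...) {
  stages <- match.arg(stages)
  gz <- if (stages == "all") gazetteer(dict)
  res <- lapply(mentions, function(m) {
    if (stages == "exact") exact_link(m, dict)
    else link_mention(m, dict, gz = gz, ...)
  })
  df <- data.frame(mention = mentions,
                   id = vapply(res, `[[`, "", "id"),
                   score = vapply(res, `[[`, 0, "score"),
                   method = vapply(res, `[[`, "", "method"),
                   stringsAsFactors = FALSE)
  attr(df, "mapping_rate") <- mean(!is.na(df$id))
  df
}
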