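# Directional connectivity knowledge graph.
#
# Canonicalization maps a 4-way relation label on a linked mention pair to
# a directed triple: "output" means the subject projects to the object,
# "input" means the object projects to the subject, "undirected" edges are
# stored separately in canonical id order, "unconnected" yields nothing.
# The graph is a multigraph keyed by (source, target, relation) whose
# edges carry literature evidence (document and sentence provenance),
# deduplicated per (pmid, sent_id, pair, label).

REL_DIRECTED <- "projects_to"
REL_UNDIRECTED <- "connected_undirected"

#' Canonicalize a classified, linked relation into a connectivity triple
#'
#' @param label one of `"unconnected"`, `"undirected"`, `"output"`,
#'   `"input"`.
#' @param subj_id,obj_id linked dictionary ids of the first and second
#'   mention.
#' @param pmid,sent_id provenance (document id and sentence index).
#' @param evidence sentence text.
#' @return a one-row data.frame triple (`source_id`, `target_id`,
#'   `relation`, `pmid`, `sent_id`, `evidence`, `extraction_label`), or
#'   `NULL` for `"unconnected"` and for self-links after normalization
#'   (dropped with a message).
#' @export
canonicalize <- function(label, subj_id, obj_id, pmid = "NA",
                         sent_id = NA_integer_, evidence = "") {
  if (!label %in% relation_classes()) stop("unknown relation label: ", label)
  if (label == "unconnected") return(NULL)
  if (identical(subj_id, obj_id)) {
    message("self-link after normalization (", subj_id, "); dropped")
    return(NULL)
  }
  st <- switch(label,
               output = c(subj_id, obj_id),
               input = c(obj_id, subj_id),
               undirected = sort(c(subj_id, obj_id)))
  data.frame(source_id = st[1L], target_id = st[2L],
             relation = if (label == "undirected") REL_UNDIRECTED
             else REL_DIRECTED,
             pmid = as.character(pmid), sent_id = as.integer(sent_id),
             evidence = evidence, extraction_label = label,
             stringsAsFactors = FALSE)
}

#' Assemble a connectivity knowledge graph from triples
#'
#' Identical (pmid, sent_id, pair, label) records are deduplicated;
#' surviving records are grouped into edges keyed by
#' (source, target, relation), each carrying its evidence list.
#'
#' @param triples data.frame of rows from [canonicalize()] (rbind-ed), or
#'   `NULL`/zero rows for an empty graph.
#' @return object of class `conn_kg`: list with `edges` (data.frame
#'   `source`, `target`, `relation`, `n_evidence`) and `evidence` (list of
#'   data.frames parallel to `edges` rows).
#' @export
build_graph <- function(triples) {
  empty <- list(edges = data.frame(source = character(0),
                                   target = character(0),
                                   relation = character(0),
                                   n_evidence = integer(0),
                                   stringsAsFactors = FALSE),
                evidence = list())
  if (is.null(triples) || nrow(triples) == 0L) {
    return(structure(empty, class = "conn_kg"))
  }
  dedup_key <- paste(triples$pmid, triples$sent_id, triples$source_id,
                     triples$target_id, triples$extraction_label, sep = "\r")
  triples <- triples[!duplicated(dedup_key), , drop = FALSE]
  edge_key <- paste(triples$source_id, triples$target_id, triples$relation,
                    sep = "\r")
  groups <- split(seq_len(nrow(triples)), edge_key)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  edges <- do.call(rbind, lapply(groups, function(ix) {
    t1 <- triples[ix[1L], ]
    data.frame(source = t1$source_id, target = t1$target_id,
               relation = t1$relation, n_evidence = length(ix),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  evidence <- lapply(groups, function(ix) {
    triples[ix, c("pmid", "sent_id", "evidence", "extraction_label"),
            drop = FALSE]
  })
  names(evidence) <- NULL
  structure(list(edges = edges, evidence = evidence), class = "conn_kg")
}

#' @export
print.conn_kg <- function(x, ...) {
  cat("<connectivity graph: ", nrow(x$edges), " edges, ",
      sum(x$edges$n_evidence), " evidence records>\n", sep = "")
  invisible(x)
}

#' Input/output circuit of one region
#'
#' Partitions the region's graph partners into inputs (regions projecting
#' to it), outputs (regions it projects to) and undirected partners, with
#' evidence counts.
#'
#' @param region_id dictionary id; must exist in `dict` when a dictionary
#'   is supplied, but need not appear in the graph (empty summary).
#' @param graph a `conn_kg`.
#' @param dict optional dictionary data.frame for id validation.
#' @return object of class `circuit_summary`: list with `region_id` and
#'   named count vectors `inputs`, `outputs`, `undirected`.
#' @export
circuit <- function(region_id, graph, dict = NULL) {
  if (!is.null(dict) && !(region_id %in% dict$id)) {
    stop("unknown region id: ", region_id)
  }
  e <- graph$edges
  pick <- function(rows, partner_col) {
    setNames(as.integer(rows$n_evidence), rows[[partner_col]])
  }
  outs <- e[e$relation == REL_DIRECTED & e$source == region_id, ]
  ins <- e[e$relation == REL_DIRECTED & e$target == region_id, ]
  und1 <- e[e$relation == REL_UNDIRECTED & e$source == region_id, ]
  und2 <- e[e$relation == REL_UNDIRECTED & e$target == region_id, ]
  und <- c(pick(und1, "target"), pick(und2, "source"))
  structure(list(region_id = region_id,
                 inputs = pick(ins, "source"),
                 outputs = pick(outs, "target"),
                 undirected = und),
            class = "circuit_summary")
}

#' @export
print.circuit_summary <- function(x, ...) {
  cat("<circuit ", x$region_id, ": ", length(x$inputs), " inputs, ",
      length(x$outputs), " outputs, ", length(x$undirected),
      " undirected>\n", sep = "")
  invisible(x)
}

#' Export / import a connectivity graph
#'
#' Writes `edges.tsv` (source, target, relation, n_evidence) and
#' `evidence.json` (per-edge evidence records); [import_graph()] loads
#' them back and round-trips the edge multiset.
#'
#' @param graph a `conn_kg`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_graph <- function(graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(graph$edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(graph$evidence, file.path(dir, "evidence.json"),
                       dataframe = "rows", auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname export_graph
#' @export
import_graph <- function(dir) {
  edges <- read.delim(file.path(dir, "edges.tsv"), stringsAsFactors = FALSE,
                      quote = "", encoding = "UTF-8")
  edges$n_evidence <- as.integer(edges$n_evidence)
  ev <- jsonlite::fromJSON(file.path(dir, "evidence.json"),
                           simplifyDataFrame = TRUE)
  evidence <- if (length(ev) == 0L) list() else lapply(ev, function(d) {
    d$sent_id <- as.integer(d$sent_id)
    d
  })
  structure(list(edges = edges, evidence = evidence), class = "conn_kg")
}

#' Run the full extraction pipeline over raw sentences
#'
#' NER -> candidate pairing -> relation classification -> entity linking
#' -> canonicalization.  Mentions that fail linking are collected in an
#' `unlinked` side table rather than dropped silently.
#'
#' @param sentences list of `labeled_sentence` objects or token vectors
#'   (labels, when present, are ignored).
#' @param ner a trained `ner_model`.
#' @param re a trained `re_model` (4-class directional).
#' @param dict dictionary data.frame.
#' @param gz optional [gazetteer()] over `dict`.
#' @return list with `graph` (a `conn_kg`), `triples` (data.frame) and
#'   `unlinked` (data.frame of unlinked mentions with provenance).
#' @export
extract_kg <- function(sentences, ner, re, dict, gz = NULL) {
  if (is.null(gz)) gz <- gazetteer(dict)
  preds <- predict_ner(ner, sentences)
  triples <- list()
  unlinked <- list()
  for (i in seq_along(sentences)) {
    s <- sentences[[i]]
    toks <- if (is.list(s)) s$tokens else s
    doc <- if (is.list(s)) s$doc_id else "d1"
    sid <- if (is.list(s)) s$sent_id else i
    spans <- preds[[i]]$spans
    if (nrow(spans) < 2L) next
    sent <- labeled_sentence(toks, labels_from_spans(spans, length(toks)),
                             doc_id = doc, sent_id = sid)
    cands <- build_relation_instances(sent, spans = spans)
    for (inst in cands) {
      pr <- predict_relation(re, inst)
      if (pr$predicted_label == "unconnected") next
      ls_ <- link_mention(span_surface(toks, inst$subj[1L], inst$subj[2L]),
                          dict, gz = gz)
      lo <- link_mention(span_surface(toks, inst$obj[1L], inst$obj[2L]),
                         dict, gz = gz)
      if (is.na(ls_$id) || is.na(lo$id)) {
        for (m in list(ls_, lo)) {
          if (is.na(m$id)) {
            unlinked[[length(unlinked) + 1L]] <-
              data.frame(mention = m$mention, pmid = doc, sent_id = sid,
                         stringsAsFactors = FALSE)
          }
        }
        next
      }
      tr <- canonicalize(pr$predicted_label, ls_$id, lo$id, pmid = doc,
                         sent_id = sid,
                         evidence = paste(toks, collapse = " "))
      if (!is.null(tr)) triples[[length(triples) + 1L]] <- tr
    }
  }
  triples <- if (length(triples) > 0L) do.call(rbind, triples) else NULL
  unlinked <- if (length(unlinked) > 0L) do.call(rbind, unlinked)
  else data.frame(mention = character(0), pmid = character(0),
                  sent_id = integer(0))
  list(graph = build_graph(triples), triples = triples, unlinked = unlinked)
}
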