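test_that("ontology merging unifies exact names and logs abbreviation collisions", {
  allen <- rbind(
    ontology_entry("AL:1", "paraventricular hypothalamic nucleus",
                   abbreviations = "PVH", source = "allen"),
    ontology_entry("AL:2", "anterior hypothalamic nucleus",
                   abbreviations = "AHN", source = "allen"))
  bams <- rbind(
    ontology_entry("BA:9", "paraventricular hypothalamic nucleus",
                   abbreviations = "PVN", synonyms = "PVH nucleus",
                   source = "bams"),
    ontology_entry("BA:7", "arcuate nucleus", abbreviations = "ARH",
                   source = "bams"))
  dict <- merge_ontologies(list(allen, bams))
  expect_equal(nrow(dict), 3L)
  pvh <- dict[dict$name == "paraventricular hypothalamic nucleus", ]
  expect_equal(pvh$id, "AL:1")
  expect_setequal(strsplit(pvh$abbreviations, "|", fixed = TRUE)[[1]],
                  c("PVH", "PVN"))
  xref <- attr(dict, "crossref")
  expect_setequal(xref$source_id[xref$unified_id == "AL:1"], c("AL:1", "BA:9"))

  # disjoint sources concatenate
  d2 <- merge_ontologies(list(allen, rbind(
    ontology_entry("HF:1", "subiculum", source = "hof"),
    ontology_entry("HF:2", "presubiculum", source = "hof"))))
  expect_equal(nrow(d2), 4L)

  # same abbreviation on different structures stays separate and is logged
  s1 <- ontology_entry("P:1", "anterior hypothalamic area",
                       abbreviations = "AH", source = "paxinos")
  s2 <- ontology_entry("H:1", "adenohypophysis", abbreviations = "AH",
                       source = "hof")
  expect_message(d3 <- merge_ontologies(list(s1, s2)), "collision")
  expect_equal(nrow(d3), 2L)
  expect_setequal(attr(d3, "collisions")$id, c("P:1", "H:1"))
})

test_that("exact linking covers names, synonyms, abbreviations and case", {
  dict <- toy_dict()
  r <- exact_link("ventral tegmental area", dict)
  expect_equal(r$id, "A:01")
  expect_equal(r$score, 1)
  expect_equal(r$method, "exact")
  expect_equal(exact_link("Ventral Tegmental Area", dict)$id, "A:01")
  expect_equal(exact_link("VTA", dict)$id, "A:01")
  expect_equal(exact_link("paraventricular thalamic nucleus", dict)$id, "A:03")
  expect_true(is.na(exact_link("cerebellum", dict)$id))
  # stopwords are transparent: "of the" forms collapse
  expect_equal(exact_link("paraventricular nucleus thalamus", dict)$id, "A:03")
})

test_that("directional stripping removes lexicon words but never empties", {
  expect_equal(strip_directional("rostral paraventricular nucleus"),
               "paraventricular nucleus")
  expect_equal(strip_directional("dorsal lateral geniculate nucleus"),
               "geniculate nucleus")
  expect_equal(strip_directional("hippocampus"), "hippocampus")
  expect_equal(strip_directional("dorsal ventral"), "dorsal ventral")
})

test_that("nested candidates are strict sub-spans, longest first", {
  dict <- toy_dict()
  gz <- gazetteer(dict)
  cands <- nested_fallback("CA1 field of the hippocampus", gz)
  expect_equal(cands, c("hippocampus", "CA1"))
  expect_equal(nested_fallback("unrelated words here", gz), character(0))
  # a full-mention match is excluded
  expect_equal(nested_fallback("lateral habenula", gz), character(0))
  expect_equal(nested_fallback("hippocampus", gz), character(0))
})

test_that("fuzzy word scoring is two-sided, self-consistent and thresholded", {
  dict <- toy_dict()
  # degenerate fuzzy == exact: a term scores 1 against itself
  top <- fuzzy_word_link("ventral tegmental area", dict)
  expect_equal(top$id[1], "A:01")
  expect_equal(top$score[1], 1)
  expect_true(top$accepted[1])
  # stopword-insensitive full word overlap also scores 1
  f <- fuzzy_word_link("paraventricular nucleus thalamus", dict)
  expect_equal(f$score[1], 1)
  expect_equal(f$id[1], "A:03")
  # disjoint words produce nothing above threshold
  miss <- fuzzy_word_link("qq zz ww", dict)
  expect_true(nrow(miss) == 0L || !any(miss$accepted))
  # scores stay in [0, 1]
  set.seed(61)
  for (m in c("lateral area", "nucleus", "tegmental habenula thalamus")) {
    sc <- fuzzy_word_link(m, dict)$score
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("staged linking records the first successful stage", {
  dict <- toy_dict()
  gz <- gazetteer(dict)
  r1 <- link_mention("lateral habenula", dict, gz)
  expect_equal(r1$method, "exact")
  expect_equal(r1$trace, "exact")     # later stages never ran
  r2 <- link_mention("rostral hippocampus", dict, gz)
  expect_equal(r2$method, "strip_directional")
  expect_equal(r2$id, "A:04")
  r3 <- link_mention("CA1 field next to fimbria", dict, gz)
  expect_equal(r3$method, "nested")
  expect_equal(r3$id, "A:05")
  r4 <- link_mention("thalamus paraventricular nucleus region", dict, gz)
  expect_equal(r4$method, "fuzzy_word")
  expect_equal(r4$id, "A:03")
  r5 <- link_mention("qq zz", dict, gz)
  expect_true(is.na(r5$id))
  expect_equal(r5$method, "none")
})

test_that("exact precedence: staged linking agrees with exact hits", {
  cfg <- synth_config(seed = 62, n_documents = 5L)
  ont <- generate_ontology(cfg)
  for (i in seq_len(nrow(ont$dict))) {
    nm <- ont$dict$name[i]
    ex <- exact_link(nm, ont$dict)
    st <- link_mention(nm, ont$dict, ont$gazetteer)
    expect_equal(st$id, ex$id)
    expect_equal(st$score, 1)
    expect_equal(st$method, "exact")
  }
})

test_that("fuzzy fallbacks never reduce the mapping rate", {
  cfg <- synth_config(seed = 63)
  ont <- generate_ontology(cfg)
  suite <- perturb_mentions(ont, n = 20L, seed = 63)
  ex <- link_mentions(suite$mention, ont$dict, stages = "exact")
  all_ <- link_mentions(suite$mention, ont$dict, stages = "all")
  expect_gte(attr(all_, "mapping_rate"), attr(ex, "mapping_rate"))
  # junk mentions stay unlinked even with fuzzy fallbacks
  expect_true(all(is.na(all_$id[suite$kind == "junk"])))
})

test_that("gazetteer lookups and scans find every stored surface form", {
  dict <- toy_dict()
  gz <- gazetteer(dict)
  expect_setequal(gazetteer_lookup(gz, "ventral tegmental area"), "A:01")
  expect_setequal(gazetteer_lookup(gz, "VTA"), "A:01")
  expect_equal(gazetteer_lookup(gz, "missing"), character(0))
  m <- gazetteer_scan(gz, c("the", "ventral", "tegmental", "area", "and",
                            "CA1", "fired", "."))
  expect_equal(m$start, c(1L, 5L))
  expect_equal(m$end, c(4L, 6L))
  expect_equal(m$form, c("ventral tegmental area", "CA1"))
})
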