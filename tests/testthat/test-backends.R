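# A tiny hand-checkable taxonomy used for the closed-form similarity tests:
# root (ic 0, depth 1) -> parent (ic 1, depth 2) -> a, b (ic 2, depth 3).
toy_taxonomy <- function() {
  taxonomy_backend(
    data.frame(
      synset_id = c("root", "parent", "a", "b"),
      parent = c(NA, "root", "parent", "parent"),
      depth = c(1L, 2L, 3L, 3L),
      ic = c(0, 1, 2, 2),
      category = c("noun.tops", "noun.animal", "noun.animal", "noun.animal"),
      gloss = c("top", "common ancestor", "gloss with shared words",
                "other gloss entirely"),
      stringsAsFactors = FALSE),
    data.frame(lemma = c("alpha", "alpha"), pos = "n", rank = c(1L, 2L),
               synset_id = c("a", "b"), stringsAsFactors = FALSE))
}

test_that("Lin similarity follows 2*IC(lcs)/(IC(a)+IC(b))", {
  tax <- toy_taxonomy()
  expect_equal(lin_similarity("a", "b", tax), 2 * 1 / (2 + 2))  # 0.5
  expect_equal(lin_similarity("a", "a", tax), 1)
  expect_equal(lin_similarity("root", "root", tax), 0)  # zero-IC denominator
  expect_equal(lin_similarity("a", "b", tax), lin_similarity("b", "a", tax))
  expect_error(lin_similarity("a", "nope", tax), "unknown synset")
})

test_that("Wu-Palmer similarity follows 2*depth(lcs)/(depth1+depth2)", {
  tax <- toy_taxonomy()
  expect_equal(wu_palmer_similarity("a", "b", tax), 2 * 2 / (3 + 3))
  expect_equal(wu_palmer_similarity("a", "a", tax), 1)
  # siblings under the root at depth 2, root depth 1 -> 2*1/(2+2) = 0.5
  tax2 <- taxonomy_backend(
    data.frame(synset_id = c("r", "x", "y"), parent = c(NA, "r", "r"),
               depth = c(1L, 2L, 2L), ic = c(0, 1, 1),
               category = "noun.tops", gloss = "g", stringsAsFactors = FALSE),
    data.frame(lemma = "w", pos = "n", rank = 1L, synset_id = "x",
               stringsAsFactors = FALSE))
  expect_equal(wu_palmer_similarity("x", "y", tax2), 0.5)
  expect_equal(lcs(tax, "a", "b"), lcs(tax, "b", "a"))
})

test_that("taxonomy invariants are enforced at construction", {
  bad <- data.frame(synset_id = c("r", "c"), parent = c(NA, "r"),
                    depth = c(1L, 2L), ic = c(2, 1),  # IC drops from parent
                    category = "noun.tops", gloss = "g",
                    stringsAsFactors = FALSE)
  senses <- data.frame(lemma = "w", pos = "n", rank = 1L, synset_id = "c")
  expect_error(taxonomy_backend(bad, senses), "IC must not decrease")
  bad2 <- bad; bad2$ic <- c(-1, 0)
  expect_error(taxonomy_backend(bad2, senses), "non-negative")
})

test_that("Lesk picks the gloss with the largest context overlap", {
  tax <- toy_taxonomy()
  # context overlaps the gloss of sense 1 ("shared words")
  s <- best_sense("alpha", c("shared", "words", "here"), tax)
  expect_equal(s$synset_id, "a")
  expect_equal(s$encoding, "alpha#n#1")
  # context engineered towards the rank-2 sense
  s2 <- best_sense("alpha", c("other", "entirely"), tax)
  expect_equal(s2$synset_id, "b")
  expect_equal(s2$encoding, "alpha#n#2")
  # no overlap at all: tie broken towards the lowest rank
  s3 <- best_sense("alpha", c("zzz"), tax)
  expect_equal(s3$rank, 1L)
  expect_null(best_sense("missing", "ctx", tax))
})

test_that("mini-lexicon is a pure function of the seed and well-formed", {
  bk1 <- build_mini_lexicon(1); bk2 <- build_mini_lexicon(1)
  expect_identical(bk1, bk2)
  bk3 <- build_mini_lexicon(2)
  expect_false(identical(bk1$dist$vectors, bk3$dist$vectors))
  syn <- bk1$taxonomy$synsets
  expect_gte(nrow(syn), 20)
  expect_gte(max(syn$depth), 3)
  expect_gte(length(unique(syn$category)), 5)
  expect_gte(length(unique(bk1$frames$frames$lemma)), 10)
  expect_gte(length(unique(bk1$frames$frames$frame_id)), 4)
  expect_gte(nrow(bk1$dist$vectors), 30)
  expect_equal(bk1$dist$dim, 8)
  # IC monotone along every hypernym path (invariant checker over the graph)
  for (i in seq_len(nrow(syn))) {
    p <- syn$parent[i]
    if (!is.na(p)) expect_gte(syn$ic[i], syn$ic[syn$synset_id == p])
  }
  # lcs symmetric over a sample of pairs
  ids <- syn$synset_id
  set.seed(3)
  for (k in 1:10) {
    ab <- sample(ids, 2)
    expect_equal(lcs(bk1$taxonomy, ab[1], ab[2]), lcs(bk1$taxonomy, ab[2], ab[1]))
  }
})

test_that("associated terms are deterministic nearest neighbours", {
  bk <- fix_backends()
  a1 <- associated_terms(bk$dist, "dog", 5)
  expect_length(a1, 5)
  expect_false("dog" %in% a1)
  expect_identical(a1, associated_terms(bk$dist, "dog", 5))
  expect_length(associated_terms(bk$dist, "notaword", 5), 0)
  expect_null(term_vector(bk$dist, "notaword"))
})

test_that("backend files round-trip through write/load", {
  bk <- fix_backends()
  d <- withr::local_tempdir()
  paths <- write_backends(bk, d)
  bk2 <- load_backends(paths["taxonomy"], paths["senses"], paths["frames"],
                       paths["vectors"])
  expect_equal(bk2$taxonomy$synsets$ic, bk$taxonomy$synsets$ic)
  expect_equal(frames_of(bk2$frames, "report"), frames_of(bk$frames, "report"))
  expect_equal(term_vector(bk2$dist, "dog"), term_vector(bk$dist, "dog"))
  expect_error(load_backends("nope.tsv", paths["senses"], paths["frames"],
                             paths["vectors"]), "missing resource")
  # dimension mismatch in the vector store is a specific error
  vl <- readLines(paths["vectors"])
  vl[3] <- paste(vl[3], "0.5")
  writeLines(vl, file.path(d, "bad.txt"))
  expect_error(load_backends(paths["taxonomy"], paths["senses"],
                             paths["frames"], file.path(d, "bad.txt")),
               "dimension mismatch")
  # IC override table is honoured
  ic <- data.frame(id = "dog.n.01", ic = 9.5)
  icp <- file.path(d, "ic.tsv")
  utils::write.table(ic, icp, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  bk3 <- load_backends(paths["taxonomy"], paths["senses"], paths["frames"],
                       paths["vectors"], ic_path = icp)
  expect_equal(synset_ic(bk3$taxonomy, "dog.n.01"), 9.5)
})
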