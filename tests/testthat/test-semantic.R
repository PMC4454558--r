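test_that("role similarity handles empty roles and identical bags", {
  bk <- fix_backends()
  sa <- fix_sentence(outcome_a); sb <- fix_sentence(outcome_b)
  # the second outcome statement has no post-verb component
  expect_equal(role_similarity(sa, sb, "post_verb", bk), 0)
  # identical single-word bags with the word in the taxonomy -> Lin = WP = 1
  d1 <- process_sentence("Dogs barked.")
  expect_equal(role_similarity(d1, d1, "pre_verb", bk), 1)
  # two predicates sharing a frame are conceptually identical
  r1 <- process_sentence("The group reported.")
  r2 <- process_sentence("The group said.")
  expect_equal(role_similarity(r1, r2, "predicate", bk), 1)
  # symmetry
  expect_equal(role_similarity(sa, sb, "pre_verb", bk),
               role_similarity(sb, sa, "pre_verb", bk))
})

test_that("sentence-wide semantic similarity equals its hand-built average", {
  bk <- fix_backends()
  s1 <- process_sentence("A dog watched a cat.")
  s2 <- process_sentence("A horse watched a bird.")
  # effective words: {dog, watch, cat} x {horse, watch, bird}; noun pairs by
  # Eq.-style Lin/WP average, the verb pair by frame overlap, mixed pairs 0
  tax_pair <- function(a, b) {
    sa <- synsets_of(bk$taxonomy, a); sb <- synsets_of(bk$taxonomy, b)
    max(vapply(sa, function(x) max(vapply(sb, function(y) {
      (lin_similarity(x, y, bk$taxonomy) +
         wu_palmer_similarity(x, y, bk$taxonomy)) / 2
    }, numeric(1))), numeric(1)))
  }
  manual <- (tax_pair("dog", "horse") + tax_pair("dog", "bird") +
             tax_pair("cat", "horse") + tax_pair("cat", "bird") + 1) / 9
  expect_equal(effective_semantic_similarity(s1, s2, bk), manual)
  # identical sentences with all words known score high and symmetric
  expect_equal(effective_semantic_similarity(s1, s2, bk),
               effective_semantic_similarity(s2, s1, bk))
  # no word of either sentence in the lexicon -> 0
  u1 <- process_sentence("Quixotic zymurgy flabbergasted.")
  expect_equal(suppressWarnings(effective_semantic_similarity(u1, u1, bk)), 0)
})

test_that("IC-vector cosine pads with zeros and matches hand arithmetic", {
  ic <- c(alpha = 2, beta = 1, gamma = 3)
  mk <- function(text) {
    s <- suppressWarnings(process_sentence(text))
    s
  }
  s3 <- mk("alpha beta gamma")
  s2 <- mk("alpha beta")
  # vectors (2,1,3) and (2,1,0): cos = 5 / (sqrt(14) * sqrt(5))
  expect_equal(ic_vector_cosine(s3, s2, ic), 5 / (sqrt(14) * sqrt(5)))
  expect_equal(ic_vector_cosine(s3, s3, ic), 1)
  expect_warning(v <- ic_vector_cosine(mk("delta epsilon"), s3, ic), "no IC")
  expect_equal(v, 0)
})

test_that("Needleman-Wunsch equals exhaustive alignment enumeration", {
  set.seed(21)
  for (i in 1:20) {
    a <- sample(c("N", "V", "J"), sample(1:5, 1), replace = TRUE)
    b <- sample(c("N", "V", "J"), sample(1:5, 1), replace = TRUE)
    expect_equal(needleman_wunsch(a, b), oracle_nw(a, b))
  }
  expect_equal(needleman_wunsch(c("N", "V"), c("N", "V")), 2)
})

test_that("role-based POS alignment is normalised and clipped", {
  bk <- fix_backends()
  s1 <- process_sentence("A dog watched a cat.")
  expect_equal(pos_alignment(s1, s1, "pre_verb"), 1)
  expect_equal(pos_alignment(s1, s1, "post_verb"), 1)
  # fully mismatching equal-length sequences clip to 0
  expect_equal(max(needleman_wunsch(c("N", "N"), c("J", "J")), 0) / 2, 0)
  # empty vs non-empty role -> 0
  sb <- fix_sentence(outcome_b)
  sa <- fix_sentence(outcome_a)
  expect_equal(pos_alignment(sa, sb, "post_verb"), 0)
})

test_that("synonym similarities find lexically disjoint synonyms", {
  bk <- fix_backends()
  k1 <- process_sentence("The kid played.")
  k2 <- process_sentence("The child played.")
  # "kid" and "child" map to the same synset in the lexicon
  expect_equal(wordnet_synonym_similarity(k1, k2, bk), 1)
  i1 <- process_sentence("An infection occurred.")
  i2 <- process_sentence("A disturbance occurred.")
  expect_equal(framenet_synonym_similarity(i1, i2, bk), 1)
  d1 <- process_sentence("The dog barked.")
  t1 <- process_sentence("The tree fell.")
  expect_equal(wordnet_synonym_similarity(d1, t1, bk), 0)
})

test_that("best-sense features disambiguate and compare sense sets", {
  bk <- fix_backends()
  # context pushes "mouse" to its animal sense ...
  m1 <- process_sentence("The mouse ran across the grass.")
  s <- best_sense("mouse", m1$lemmas, bk$taxonomy)
  expect_equal(s$encoding, "mouse#n#1")
  # ... or to the pointing-device sense
  m2 <- process_sentence("The mouse is a hand device for a computer.")
  s2 <- best_sense("mouse", m2$lemmas, bk$taxonomy)
  expect_equal(s2$encoding, "mouse#n#2")
  v <- best_sense_features(m1, m1, bk)
  expect_equal(unname(v), c(1, 1))
  # one shared sense between partially overlapping sentences
  a <- process_sentence("The dog watched the mouse near the grass.")
  b <- process_sentence("The cat watched the mouse near the grass.")
  vb <- best_sense_features(a, b, bk)
  expect_gt(vb[["sense_set"]], 0); expect_lt(vb[["sense_set"]], 1.0001)
  expect_equal(best_sense_features(a, b, bk), best_sense_features(b, a, bk))
})

test_that("category-level features compare lexicographer files", {
  bk <- fix_backends()
  a <- process_sentence("The dog watched the cat.")
  b <- process_sentence("The horse watched the bird.")
  v <- sense_category_features(a, b, bk)
  # all four animals share noun.animal -> identical category sets
  expect_equal(v[["category_set"]], 1)
  expect_equal(sense_category_features(a, a, bk),
               c(category_set = 1, category_cosine = 1))
  t1 <- process_sentence("The surgery helped.")
  expect_equal(sense_category_features(a, t1, bk)[["category_set"]], 0)
  # skipped bigrams over category sequences
  expect_equal(sense_skipped_bigram_similarity(a, b, bk), 1)
  expect_equal(sense_skipped_bigram_similarity(a, a, bk), 1)
  short <- process_sentence("The dog slept.")
  expect_warning(v2 <- sense_skipped_bigram_similarity(short, short, bk),
                 "fewer than 2")
  expect_equal(v2, 0)
})

test_that("distributional features follow their set and matrix definitions", {
  bk <- fix_backends()
  a <- process_sentence("The dog watched the cat.")
  expect_equal(associated_terms_set_similarity(a, a, bk), 1)
  u <- process_sentence("Zymurgy flabbergasted qwerty.")
  expect_equal(suppressWarnings(associated_terms_set_similarity(a, u, bk)), 0)
  # matrix cosine with crafted 2x3 vs 1x3 matrices, zero-padded
  vecs <- rbind(dog = c(1, 0, 0), cat = c(0, 1, 0), bird = c(1, 1, 0))
  bk2 <- backend_bundle(bk$taxonomy, bk$frames, dist_backend(vecs))
  s1 <- process_sentence("A dog watched a cat.")   # rows: dog, cat
  s2 <- process_sentence("A bird watched.")        # rows: bird
  manual <- sum(c(1, 0, 0, 0, 1, 0) * c(1, 1, 0, 0, 0, 0)) /
    (sqrt(2) * sqrt(2))
  expect_equal(term_matrix_cosine(s1, s2, bk2), manual)
  expect_equal(term_matrix_cosine(s1, s1, bk2), 1)
  # row-orthogonal matrices
  s3 <- process_sentence("A cat watched.")
  s4 <- process_sentence("A dog watched.")
  expect_equal(term_matrix_cosine(s3, s4, bk2), 0)
  expect_warning(v <- term_matrix_cosine(u, s1, bk2), "no in-vocabulary")
  expect_equal(v, 0)
})

test_that("words absent from all backends do not change semantic features", {
  bk <- fix_backends()
  a <- process_sentence("The dog watched the cat.")
  b <- process_sentence("The horse watched the bird.")
  b_plus <- process_sentence("The horse watched the bird qwerlix.")
  for (f in list(wordnet_synonym_similarity, framenet_synonym_similarity,
                 function(x, y, bk) best_sense_features(x, y, bk)[["sense_set"]],
                 associated_terms_set_similarity)) {
    # animal nouns have no frames, so the frame measure warns on both calls
    expect_equal(suppressWarnings(f(a, b, bk)),
                 suppressWarnings(f(a, b_plus, bk)))
  }
})
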