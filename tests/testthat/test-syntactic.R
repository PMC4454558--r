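test_that("bag overlap reproduces the worked example and edge cases", {
  sa <- fix_sentence(outcome_a); sb <- fix_sentence(outcome_b)
  expect_equal(bag_overlap(sa$tokens, sb$tokens), 0.7)       # 14 / 20
  expect_equal(bag_overlap(sa$lemmas, sb$lemmas), 0.7)
  expect_equal(bag_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(bag_overlap(c("a", "b"), c("c", "d")), 0)
  # multiset matching without replacement
  expect_equal(bag_overlap(c("a", "a", "b"), c("a", "c", "d")), 1 / 3)
  expect_error(bag_overlap(character(0), character(0)), "degenerate")
})

test_that("effective-word set similarity matches the printed sets", {
  s1 <- c("event", "retention", "disturbance", "wound", "infection", "be",
          "report", "group")
  s2 <- c("event", "retention", "disturbance", "wound", "infection", "be")
  expect_equal(effective_set_similarity(s1, s2), 0.75)
  expect_equal(effective_set_similarity(s1, s1), 1)
  expect_equal(effective_set_similarity(c("a", "b"), "c"), 0)
  expect_error(effective_set_similarity(character(0), character(0)), "degenerate")
  # computed from raw text under the content policy
  sa <- fix_sentence(outcome_a, "content"); sb <- fix_sentence(outcome_b, "content")
  expect_equal(effective_set_similarity(unique(sa$lemmas[sa$effective_indices]),
                                        unique(sb$lemmas[sb$effective_indices])),
               0.75)
})

test_that("jaccard agrees with a first-principles oracle", {
  sa <- fix_sentence(outcome_a); sb <- fix_sentence(outcome_b)
  expect_equal(jaccard(sa$tokens, sb$tokens), 14 / 25)
  set.seed(42)
  for (i in 1:25) {
    a <- sample(letters[1:6], sample(1:8, 1), replace = TRUE)
    b <- sample(letters[1:6], sample(1:8, 1), replace = TRUE)
    expect_equal(jaccard(a, b), oracle_jaccard(a, b))
  }
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("x", "y"), 0)
})

test_that("term-frequency cosine has its closed-form values", {
  expect_equal(lemma_vector_cosine(c("a", "b"), c("a", "b")), 1)
  expect_equal(lemma_vector_cosine(c("a", "b"), c("c", "d")), 0)
  # counts (1,1,0) vs (1,0,1)
  expect_equal(lemma_vector_cosine(c("a", "b"), c("a", "c")), 0.5)
})

test_that("window features equal the exhaustive enumeration oracle", {
  set.seed(7)
  for (s in random_seqs(40)) {
    t <- sample(c("a", "b", "c"), sample(2:8, 1), replace = TRUE)
    expect_equal(window_features(s, t), oracle_window(s, t),
                 info = paste(paste(s, collapse = ""), "vs",
                              paste(t, collapse = "")))
  }
  # identical sequences: longest shared window is the whole sequence
  x <- c("a", "b", "c", "a", "b")
  expect_equal(window_features(x, x)[["longest"]], 1)
  expect_equal(window_features(c("a", "b", "c"), c("c", "a", "d")),
               c(overlap = 0, longest = 0))
  expect_warning(window_features("a", c("a", "b")), "shorter than 2")
})

test_that("skipped-bigram ratio matches brute-force pair enumeration", {
  sa <- fix_sentence(outcome_a); sb <- fix_sentence(outcome_b)
  content <- function(s) s$tokens[grepl("^(NN|VB|JJ|RB)", s$pos_tags)]
  oa <- oracle_skip_bigrams(content(sa)); ob <- oracle_skip_bigrams(content(sb))
  expect_equal(skipped_bigram_ratio(sa, sb),
               length(intersect(oa, ob)) / max(length(oa), length(ob)))
  expect_equal(skipped_bigram_ratio(sa, sa), 1)
  toy1 <- process_sentence("Dogs chased cats yesterday.")
  toy2 <- process_sentence("Dogs chased birds yesterday.")
  o1 <- oracle_skip_bigrams(content(toy1)); o2 <- oracle_skip_bigrams(content(toy2))
  expect_equal(skipped_bigram_ratio(toy1, toy2),
               length(intersect(o1, o2)) / max(length(o1), length(o2)))
})

test_that("polarity feature and length ratio follow their definitions", {
  sa <- fix_sentence(outcome_a); sb <- fix_sentence(outcome_b)
  expect_equal(polarity_feature(sa$polarity, sb$polarity), 0)  # both negated
  expect_equal(polarity_feature(TRUE, FALSE), 1)
  expect_equal(polarity_feature(FALSE, FALSE), 0)
  expect_equal(length_ratio(19, 20), 0.95)
  expect_equal(length_ratio(7, 7), 1)
  expect_equal(length_ratio(5, 10), 0.5)
  expect_error(length_ratio(0, 5), "positive")
})

test_that("syntactic measures are symmetric, bounded and maximal on self", {
  set.seed(99)
  for (i in 1:20) {
    a <- sample(letters[1:5], sample(2:8, 1), replace = TRUE)
    b <- sample(letters[1:5], sample(2:8, 1), replace = TRUE)
    for (f in list(bag_overlap, effective_set_similarity, jaccard,
                   lemma_vector_cosine)) {
      v <- f(a, b)
      expect_equal(v, f(b, a))
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(f(a, a), 1)
    }
    w <- window_features(a, b)
    expect_equal(w, window_features(b, a))
    expect_true(all(w >= 0 & w <= 1))
  }
})
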