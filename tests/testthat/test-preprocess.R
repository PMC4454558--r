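test_that("tokeniser follows the stated dialect", {
  expect_equal(tokenize("A cat sat."), c("a", "cat", "sat"))
  expect_length(tokenize(outcome_a), 20)
  expect_length(tokenize(outcome_b), 19)
  # hyphenated compounds stay single tokens
  expect_true("m-adl" %in% tokenize(outcome_a))
  expect_true(all(c("intra-operative", "post-operative") %in% tokenize(outcome_b)))
  expect_error(tokenize(""), "empty sentence")
  expect_error(tokenize("   "), "empty sentence")
  expect_error(tokenize("?!..."), "empty sentence")
})

test_that("lemmatiser and stemmer map inflections to shared roots", {
  toks <- c("infections", "infection", "cat", "disturbances", "were", "observed")
  lem <- lemmatize(toks, tag_pos(toks))
  expect_equal(lem[1], lem[2])          # infections ~ infection
  expect_equal(lem[3], "cat")           # fixed point
  expect_equal(lem[4], "disturbance")
  expect_equal(lem[5], "be")
  expect_equal(lem[6], "observe")
  st <- stem_tokens(toks)
  expect_equal(st[1], st[2])
  expect_equal(st[1], "infect")
  expect_length(lem, length(toks))
  expect_length(st, length(toks))
})

test_that("per-token layers stay aligned for arbitrary sentences", {
  for (s in c(outcome_a, outcome_b,
              "A group of kids is playing in a yard and an old man is standing in the background.",
              "Dogs bark loudly.")) {
    ps <- process_sentence(s)
    n <- length(ps$tokens)
    expect_length(ps$lemmas, n)
    expect_length(ps$stems, n)
    expect_length(ps$pos_tags, n)
    expect_true(all(ps$effective_indices %in% seq_len(n)))
    expect_gte(length(ps$clauses), 1)
    expect_equal(sum(ps$clause_word_counts),
                 length(unlist(lapply(ps$clauses, `[[`, "idx"))))
  }
})

test_that("effective-word policies behave as documented", {
  sa <- fix_sentence(outcome_a, "content")
  sb <- fix_sentence(outcome_b, "content")
  ea <- unique(sa$lemmas[sa$effective_indices])
  eb <- unique(sb$lemmas[sb$effective_indices])
  expect_setequal(ea, c("event", "retention", "disturbance", "wound",
                        "infection", "be", "report", "group"))
  expect_true(all(c("event", "retention", "disturbance", "wound",
                    "infection", "be") %in% eb))
  # all-closed-class sentence has no effective words
  toks <- c("it", "is", "in", "the", "of")
  expect_length(mark_effective(toks, tag_pos(toks), "content"),
                1)  # "is" is a verb, kept under the content policy
  toks2 <- c("in", "the", "of", "and")
  expect_length(mark_effective(toks2, tag_pos(toks2), "stoplist"), 0)
  # content words survive the default stoplist policy
  toks3 <- tokenize("Dogs bark loudly.")
  expect_length(mark_effective(toks3, tag_pos(toks3), "stoplist"), 3)
})

test_that("negation detection flags NegEx-style triggers", {
  expect_true(detect_polarity(tokenize(outcome_a)))   # "No ..."
  expect_true(detect_polarity(tokenize(outcome_b)))   # "Neither ... nor"
  expect_false(detect_polarity(tokenize("The dog runs.")))
  expect_true(detect_polarity(tokenize("Neither complication was observed.")))
  expect_true(detect_polarity(tokenize("The wound was free of infection.")))
  expect_false(detect_polarity(tokenize("Not only the dog runs.")))
  # pure function of the token sequence
  expect_identical(detect_polarity(tokenize(outcome_a)),
                   detect_polarity(tokenize(outcome_a)))
})

test_that("clause extraction finds clause counts and role components", {
  sa <- fix_sentence(outcome_a)
  sb <- fix_sentence(outcome_b)
  expect_length(sa$clauses, 1)
  expect_length(sb$clauses, 1)
  # coordinated sentence with two finite verb groups -> 2 clauses
  fig1 <- process_sentence(paste("A group of kids is playing in a yard and",
                                 "an old man is standing in the background."))
  expect_length(fig1$clauses, 2)
  # the second outcome statement ends at its verb group: empty post-verb
  expect_length(sb$clauses[[1]]$post_verb, 0)
  expect_gt(length(sa$clauses[[1]]$post_verb), 0)
  expect_true("report" %in% sa$clauses[[1]]$predicate)
  # no finite verb -> single-clause fallback with a warning
  expect_warning(cl <- parse_clauses(c("green", "ideas"), c("JJ", "NNS")),
                 "no finite verb")
  expect_length(cl, 1)
  expect_length(cl[[1]]$predicate, 0)
})

test_that("reduced parse trees keep the clause scaffold and round-trip", {
  fig1 <- process_sentence(paste("A group of kids is playing in a yard and",
                                 "an old man is standing in the background."))
  tree <- fig1$reduced_tree
  expect_equal(tree$label, "ROOT")
  expect_length(tree$children, 2)        # one S node per clause
  s <- tree_to_string(tree)
  expect_identical(tree_to_string(tree_from_string(s)), s)
  # structurally identical clauses reduce to identical subtrees
  twin <- process_sentence(paste("A dog is running in a yard and",
                                 "a cat is sleeping in a house."))
  expect_identical(tree_to_string(twin$reduced_tree$children[[1]]),
                   tree_to_string(twin$reduced_tree$children[[2]]))
  # single content word -> one-leaf tree under its clause fallback
  one <- suppressWarnings(process_sentence("Dogs."))
  expect_gte(length(one$reduced_tree$children), 1)
  # determinism of the whole pipeline
  expect_identical(process_sentence(outcome_a), process_sentence(outcome_a))
})
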