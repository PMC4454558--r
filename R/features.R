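# The 34-feature registry and the pair featurizer.  Feature names are
# stable identifiers; the 8 groups mirror the feature-set taxonomy used in
# the ablation protocol (sizes 7/6/3/2/7/2/5/2).

.feature_groups <- list(
  naive = c("word_overlap", "lemma_overlap", "stem_overlap",
            "effective_set", "jaccard_words", "jaccard_lemmas",
            "effective_cosine"),
  window_based = c("win_words_overlap", "win_words_longest",
                   "win_effective_overlap", "win_effective_longest",
                   "win_pos_overlap", "win_pos_longest"),
  other_syntactic = c("skipped_bigram", "polarity", "length_ratio"),
  sentence_structure = c("clause_ratio", "tree_overlap"),
  basic_semantic = c("role_pre_verb", "role_predicate", "role_post_verb",
                     "effective_semantic", "ic_cosine",
                     "pos_align_pre", "pos_align_post"),
  words_synonymy = c("wordnet_synonyms", "framenet_synonyms"),
  word_sense = c("sense_set", "related_synsets", "category_set",
                 "category_cosine", "sense_skipped_bigram"),
  semantic_space = c("associated_terms", "matrix_cosine")
)

#' Feature registry
#'
#' @return `feature_registry()`: the 34 feature names in canonical order;
#'   `feature_groups()`: the named list of 8 feature groups partitioning
#'   them.
#' @export
feature_registry <- function() unlist(.feature_groups, use.names = FALSE)

#' @rdname feature_registry
#' @export
feature_groups <- function() .feature_groups

#' Construct a sentence pair
#'
#' Processes both sentences and canonicalises their order
#' (lexicographically by text) — all features are symmetric, so the
#' canonical order prevents accidental asymmetry from ever mattering.
#'
#' @param text_a,text_b sentence strings, or `processed_sentence` objects.
#' @param score optional gold relatedness in \[1, 5\].
#' @param pair_id optional identifier.
#' @param policy effective-word policy for processing raw text.
#' @return object of class `sentence_pair`.
#' @export
sentence_pair <- function(text_a, text_b, score = NA_real_, pair_id = NA,
                          policy = "stoplist") {
  if (!is.na(score) && (score < 1 || score > 5)) {
    stop("relatedness score must lie in [1, 5]", call. = FALSE)
  }
  a <- if (inherits(text_a, "processed_sentence")) text_a else process_sentence(text_a, policy)
  b <- if (inherits(text_b, "processed_sentence")) text_b else process_sentence(text_b, policy)
  if (a$text > b$text) { tmp <- a; a <- b; b <- tmp }
  structure(list(a = a, b = b, score = score, pair_id = pair_id),
            class = "sentence_pair")
}

#' Assemble the 34-dimensional feature vector of a sentence pair
#'
#' Computes every registered feature in canonical order.  Degenerate
#' features (e.g. both effective-word sets empty) fall back to 0 with a
#' warning naming the feature; the clipped tree overlap and matrix cosine
#' are entered clipped to \[0, 1\].
#'
#' @param pair a `sentence_pair`.
#' @param backends a `backend_bundle`.
#' @param quiet muffle degenerate-feature warnings (used by the batch
#'   featurizer).
#' @return named numeric vector of length 34.
#' @export
assemble_features <- function(pair, backends, quiet = FALSE) {
  a <- pair$a; b <- pair$b
  eff_a <- effective_lemma_bag(a); eff_b <- effective_lemma_bag(b)
  eff_tok_a <- a$tokens[a$effective_indices]; eff_tok_b <- b$tokens[b$effective_indices]
  f <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      warning("feature ", name, " degenerate (", conditionMessage(e),
              "); using 0", call. = FALSE)
      0
    })
    as.numeric(v)[1]
  }
  win <- function(x, y) {
    tryCatch(window_features(x, y),
             warning = function(w) c(overlap = 0, longest = 0))
  }
  compute <- function() {
    ww <- win(a$tokens, b$tokens)
    we <- win(eff_tok_a, eff_tok_b)
    wp <- win(a$pos_tags, b$pos_tags)
    bs <- best_sense_features(a, b, backends)
    sc <- sense_category_features(a, b, backends)
    out <- c(
      word_overlap = f("word_overlap", bag_overlap(a$tokens, b$tokens)),
      lemma_overlap = f("lemma_overlap", bag_overlap(a$lemmas, b$lemmas)),
      stem_overlap = f("stem_overlap", bag_overlap(a$stems, b$stems)),
      effective_set = f("effective_set",
                        effective_set_similarity(unique(eff_a), unique(eff_b))),
      jaccard_words = f("jaccard_words", jaccard(a$tokens, b$tokens)),
      jaccard_lemmas = f("jaccard_lemmas", jaccard(a$lemmas, b$lemmas)),
      effective_cosine = f("effective_cosine", lemma_vector_cosine(eff_a, eff_b)),
      win_words_overlap = ww[["overlap"]], win_words_longest = ww[["longest"]],
      win_effective_overlap = we[["overlap"]], win_effective_longest = we[["longest"]],
      win_pos_overlap = wp[["overlap"]], win_pos_longest = wp[["longest"]],
      skipped_bigram = f("skipped_bigram", skipped_bigram_ratio(a, b)),
      polarity = polarity_feature(a$polarity, b$polarity),
      length_ratio = length_ratio(length(a$tokens), length(b$tokens)),
      clause_ratio = clause_ratio(length(a$clauses), length(b$clauses)),
      tree_overlap = as.numeric(reduced_tree_overlap(
        a$reduced_tree, b$reduced_tree,
        a$clause_word_counts, b$clause_word_counts)),
      role_pre_verb = role_similarity(a, b, "pre_verb", backends),
      role_predicate = role_similarity(a, b, "predicate", backends),
      role_post_verb = role_similarity(a, b, "post_verb", backends),
      effective_semantic = effective_semantic_similarity(a, b, backends),
      ic_cosine = f("ic_cosine", ic_vector_cosine(a, b, backends$ic)),
      pos_align_pre = pos_alignment(a, b, "pre_verb"),
      pos_align_post = pos_alignment(a, b, "post_verb"),
      wordnet_synonyms = wordnet_synonym_similarity(a, b, backends),
      framenet_synonyms = framenet_synonym_similarity(a, b, backends),
      sense_set = bs[["sense_set"]], related_synsets = bs[["related_synsets"]],
      category_set = sc[["category_set"]], category_cosine = sc[["category_cosine"]],
      sense_skipped_bigram = sense_skipped_bigram_similarity(a, b, backends),
      associated_terms = associated_terms_set_similarity(a, b, backends),
      matrix_cosine = clip(term_matrix_cosine(a, b, backends), 0, 1)
    )
    names(out) <- feature_registry()
    out
  }
  if (quiet) suppressWarnings(compute()) else compute()
}

#' Featurize a batch of sentence pairs
#'
#' @param pairs list of `sentence_pair` objects, or a data frame with
#'   columns `sentence_a`, `sentence_b` (and optionally
#'   `relatedness`, `pair_id`).
#' @param backends a `backend_bundle`.
#' @param policy effective-word policy for raw text input.
#' @return list with `X` (n x 34 feature matrix) and `y` (gold scores,
#'   `NA` where absent).
#' @export
featurize_pairs <- function(pairs, backends, policy = "stoplist") {
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      sentence_pair(pairs$sentence_a[i], pairs$sentence_b[i],
                    score = if ("relatedness" %in% names(pairs)) pairs$relatedness[i] else NA_real_,
                    pair_id = if ("pair_id" %in% names(pairs)) pairs$pair_id[i] else i,
                    policy = policy)
    })
  }
  X <- t(vapply(pairs, function(p) assemble_features(p, backends, quiet = TRUE),
                numeric(34)))
  colnames(X) <- feature_registry()
  y <- vapply(pairs, function(p) p$score %||% NA_real_, numeric(1))
  list(X = X, y = y,
       pair_id = vapply(pairs, function(p) as.character(p$pair_id %||% NA), character(1)))
}
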