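# Semantic similarity features.  All operations take a backend bundle
# handle; word-pair lookups that fail contribute 0 (the denominators stay
# as defined, so missing knowledge lowers similarity rather than shrinking
# the comparison).

# Average of Lin and Wu-Palmer between the best-matching synsets of two
# lemmas (max over synset pairs); 0 when either lemma has no synset.
.word_pair_taxonomy_sim <- function(w1, w2, taxonomy) {
  s1 <- synsets_of(taxonomy, w1)
  s2 <- synsets_of(taxonomy, w2)
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  best <- 0
  for (a in s1) for (b in s2) {
    v <- (lin_similarity(a, b, taxonomy) + wu_palmer_similarity(a, b, taxonomy)) / 2
    if (v > best) best <- v
  }
  best
}

# Frame-overlap indicator: 1 when the two lemmas share any frame.
.word_pair_frame_sim <- function(w1, w2, frames) {
  f1 <- frames_of(frames, w1)
  f2 <- frames_of(frames, w2)
  as.numeric(length(intersect(f1, f2)) > 0L)
}

# Bag-level similarity: mean of word-pair similarities over the cross
# product (denominator |b| x |b'|); 0 when either bag is empty.
.bag_sim <- function(b1, b2, pair_fun) {
  if (length(b1) == 0L || length(b2) == 0L) return(0)
  total <- 0
  for (w1 in b1) for (w2 in b2) total <- total + pair_fun(w1, w2)
  total / (length(b1) * length(b2))
}

#' Role-based word-by-word similarity
#'
#' Compares the lemma bags of one clause role (pre-verb, predicate or
#' post-verb) across the two sentences: the mean over all clause-bag pairs
#' of a bag similarity, which is the word-pair average of Lin and Wu-Palmer
#' for pre-/post-verb roles and the frame-overlap indicator for predicates.
#' Returns 0 when either sentence has no non-empty bag for the role.
#'
#' @param sentence_a,sentence_b `processed_sentence` objects.
#' @param role `"pre_verb"`, `"predicate"` or `"post_verb"`.
#' @param backends a `backend_bundle`.
#' @return similarity in \[0, 1\].
#' @export
role_similarity <- function(sentence_a, sentence_b,
                            role = c("pre_verb", "predicate", "post_verb"),
                            backends) {
  role <- match.arg(role)
  bags_a <- lapply(sentence_a$clauses, `[[`, role)
  bags_b <- lapply(sentence_b$clauses, `[[`, role)
  if (all(lengths(bags_a) == 0L) || all(lengths(bags_b) == 0L)) return(0)
  pair_fun <- if (role == "predicate") {
    function(w1, w2) .word_pair_frame_sim(w1, w2, backends$frames)
  } else {
    function(w1, w2) .word_pair_taxonomy_sim(w1, w2, backends$taxonomy)
  }
  total <- 0
  for (b1 in bags_a) for (b2 in bags_b) {
    total <- total + .bag_sim(b1, b2, pair_fun)
  }
  clip(total / (length(bags_a) * length(bags_b)), 0, 1)
}

#' Sentence-wide semantic similarity of effective words
#'
#' The same word-pair averaging as the role-based measure, computed over
#' all cross-sentence effective-word pairs without role decomposition:
#' nominal words are compared through the taxonomy (Lin/Wu-Palmer average),
#' verbal words through frame overlap, mixed pairs contribute 0.
#'
#' @inheritParams role_similarity
#' @return similarity in \[0, 1\].
#' @export
effective_semantic_similarity <- function(sentence_a, sentence_b, backends) {
  eff <- function(s) {
    idx <- s$effective_indices
    list(lemma = s$lemmas[idx], verb = grepl("^VB", s$pos_tags[idx]))
  }
  a <- eff(sentence_a); b <- eff(sentence_b)
  if (length(a$lemma) == 0L || length(b$lemma) == 0L) return(0)
  total <- 0
  for (i in seq_along(a$lemma)) for (j in seq_along(b$lemma)) {
    total <- total + if (a$verb[i] && b$verb[j]) {
      .word_pair_frame_sim(a$lemma[i], b$lemma[j], backends$frames)
    } else if (!a$verb[i] && !b$verb[j]) {
      .word_pair_taxonomy_sim(a$lemma[i], b$lemma[j], backends$taxonomy)
    } else 0
  }
  clip(total / (length(a$lemma) * length(b$lemma)), 0, 1)
}

#' Cosine similarity of information-content vectors
#'
#' Maps each sentence to the ordered vector of IC values of its lemmas
#' (0 for lemmas absent from the IC table), zero-pads the shorter vector,
#' and returns the cosine.  All-zero vectors give 0 with a warning.
#'
#' @param sentence_a,sentence_b `processed_sentence` objects.
#' @param ic_table named numeric vector, lemma -> IC.
#' @return cosine in \[0, 1\].
#' @export
ic_vector_cosine <- function(sentence_a, sentence_b, ic_table) {
  vec <- function(s) {
    v <- ic_table[s$lemmas]
    v[is.na(v)] <- 0
    unname(v)
  }
  va <- vec(sentence_a); vb <- vec(sentence_b)
  n <- max(length(va), length(vb))
  va <- c(va, rep(0, n - length(va)))
  vb <- c(vb, rep(0, n - length(vb)))
  if (all(va == 0) || all(vb == 0)) {
    warning("no IC-known lemma in a sentence; IC-vector cosine 0")
    return(0)
  }
  cosine_sim(va, vb)
}

#' Needleman-Wunsch global alignment score
#'
#' Classic dynamic program with match = +1, mismatch = -1, gap = -1.
#'
#' @param seq_a,seq_b character sequences.
#' @return the optimal (unnormalised) alignment score.
#' @export
needleman_wunsch <- function(seq_a, seq_b,
                             match = 1, mismatch = -1, gap = -1) {
  n <- length(seq_a); m <- length(seq_b)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- gap * 0:n
  D[1L, ] <- gap * 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- D[i, j] + if (seq_a[i] == seq_b[j]) match else mismatch
    D[i + 1L, j + 1L] <- max(sub, D[i, j + 1L] + gap, D[i + 1L, j] + gap)
  }
  D[n + 1L, m + 1L]
}

#' Role-based POS-tag alignment
#'
#' Concatenates the POS tags of the effective words of one role (pre-verb
#' or post-verb) across clauses and aligns the two tag sequences with
#' Needleman-Wunsch; the score is normalised as
#' `max(score, 0) / max(|a|, |b|)`.  Two empty sequences align perfectly
#' (1); empty versus non-empty gives 0.
#'
#' @inheritParams role_similarity
#' @param role `"pre_verb"` or `"post_verb"`.
#' @return normalised alignment score in \[0, 1\].
#' @export
pos_alignment <- function(sentence_a, sentence_b,
                          role = c("pre_verb", "post_verb")) {
  role <- match.arg(role)
  tags <- function(s) {
    idx <- unlist(lapply(s$clauses, `[[`, sub("_verb", "", role)), use.names = FALSE)
    idx <- intersect(idx, s$effective_indices)
    s$pos_tags[idx]
  }
  ta <- tags(sentence_a); tb <- tags(sentence_b)
  if (length(ta) == 0L && length(tb) == 0L) return(1)
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  max(needleman_wunsch(ta, tb), 0) / max(length(ta), length(tb))
}

.norm_intersect_min <- function(a, b, warn_msg = NULL) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    if (!is.null(warn_msg) && length(a) == 0L && length(b) == 0L) warning(warn_msg)
    return(0)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Taxonomy-based synonym similarity
#'
#' Unions the synset identifiers of each sentence's effective lemmas and
#' returns the intersection size normalised by the smaller union.
#'
#' @inheritParams role_similarity
#' @return similarity in \[0, 1\].
#' @export
wordnet_synonym_similarity <- function(sentence_a, sentence_b, backends) {
  syns <- function(s) {
    unique(unlist(lapply(effective_lemmas(s), function(l) {
      synsets_of(backends$taxonomy, l)
    }), use.names = FALSE))
  }
  .norm_intersect_min(syns(sentence_a), syns(sentence_b),
                      "no synsets on either side; synonym similarity 0")
}

#' Frame-based synonym similarity
#'
#' The frame analogue of [wordnet_synonym_similarity()], restricted to the
#' noun family (verb frames already feed the role-based predicate measure).
#'
#' @inheritParams role_similarity
#' @return similarity in \[0, 1\].
#' @export
framenet_synonym_similarity <- function(sentence_a, sentence_b, backends) {
  frames <- function(s) {
    idx <- s$effective_indices[grepl("^NN", s$pos_tags[s$effective_indices])]
    unique(unlist(lapply(unique(s$lemmas[idx]), function(l) {
      frames_of(backends$frames, l)
    }), use.names = FALSE))
  }
  .norm_intersect_min(frames(sentence_a), frames(sentence_b),
                      "no frames on either side; frame synonym similarity 0")
}

# Best-sense annotations for the effective words of a sentence (Lesk over
# the whole sentence as context); undisambiguable words are skipped.
.best_senses_of <- function(s, backends) {
  lemmas <- effective_lemmas(s)
  out <- lapply(lemmas, function(l) best_sense(l, s$lemmas, backends$taxonomy))
  out[!vapply(out, is.null, logical(1))]
}

#' Best-sense set features
#'
#' Disambiguates every effective word with Lesk and compares (i) the sets
#' of best-sense encodings (`"lemma#pos#rank"`) and (ii) the unions of the
#' related-synset identifiers of the best senses, both normalised by the
#' smaller set.
#'
#' @inheritParams role_similarity
#' @return named numeric vector `c(sense_set, related_synsets)`.
#' @export
best_sense_features <- function(sentence_a, sentence_b, backends) {
  sa <- .best_senses_of(sentence_a, backends)
  sb <- .best_senses_of(sentence_b, backends)
  enc <- function(x) vapply(x, `[[`, character(1), "encoding")
  rel <- function(x) {
    unique(unlist(lapply(x, function(b) {
      related_synsets(backends$taxonomy, b$synset_id)
    }), use.names = FALSE))
  }
  c(sense_set = .norm_intersect_min(enc(sa), enc(sb)),
    related_synsets = .norm_intersect_min(rel(sa), rel(sb)))
}

#' Lexicographer-category features of best senses
#'
#' Compares (i) the sets of lexicographer-file categories of the best
#' senses (normalised by the smaller set) and (ii) the position-aligned
#' sequences of category names as one-hot vectors over the category
#' vocabulary, zero-padded to equal length, by cosine.
#'
#' @inheritParams role_similarity
#' @return named numeric vector `c(category_set, category_cosine)`.
#' @export
sense_category_features <- function(sentence_a, sentence_b, backends) {
  sa <- .best_senses_of(sentence_a, backends)
  sb <- .best_senses_of(sentence_b, backends)
  cats <- function(x) vapply(x, `[[`, character(1), "category")
  ca <- cats(sa); cb <- cats(sb)
  set_sim <- .norm_intersect_min(ca, cb)
  if (length(ca) == 0L || length(cb) == 0L) {
    return(c(category_set = set_sim, category_cosine = 0))
  }
  vocab <- union(ca, cb)
  onehot <- function(x, n) {
    m <- matrix(0, n, length(vocab))
    for (i in seq_along(x)) m[i, match(x[i], vocab)] <- 1
    m
  }
  n <- max(length(ca), length(cb))
  cos <- cosine_sim(as.vector(onehot(ca, n)), as.vector(onehot(cb, n)))
  c(category_set = set_sim, category_cosine = cos)
}

#' Skipped-bigram similarity of best-sense categories
#'
#' Forms skipped bigrams (ordered pairs, i < j) over each sentence's
#' sequence of best-sense categories and compares the sets, normalised by
#' the smaller one.
#'
#' @inheritParams role_similarity
#' @return similarity in \[0, 1\].
#' @export
sense_skipped_bigram_similarity <- function(sentence_a, sentence_b, backends) {
  bigrams <- function(s) {
    cats <- vapply(.best_senses_of(s, backends), `[[`, character(1), "category")
    if (length(cats) < 2L) return(character(0))
    pairs <- t(utils::combn(length(cats), 2))
    unique(paste(cats[pairs[, 1]], cats[pairs[, 2]], sep = "\r"))
  }
  ba <- bigrams(sentence_a); bb <- bigrams(sentence_b)
  if (length(ba) == 0L && length(bb) == 0L) {
    warning("fewer than 2 categorisable words on both sides; sense skipped-bigram similarity 0")
    return(0)
  }
  .norm_intersect_min(ba, bb)
}

#' Similarity of sets of distributionally associated terms
#'
#' Unions the top-k associated terms of each sentence's effective words and
#' normalises the intersection by the larger set.  Out-of-vocabulary words
#' contribute nothing.
#'
#' @inheritParams role_similarity
#' @param k neighbours per word (default 20).
#' @return similarity in \[0, 1\].
#' @export
associated_terms_set_similarity <- function(sentence_a, sentence_b, backends,
                                            k = 20L) {
  assoc <- function(s) {
    unique(unlist(lapply(effective_lemmas(s), function(l) {
      associated_terms(backends$dist, l, k)
    }), use.names = FALSE))
  }
  a <- assoc(sentence_a); b <- assoc(sentence_b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b)) / max(length(a), length(b))
}

#' Cosine similarity of matrices of term vectors
#'
#' Stacks the term vectors of the effective words row-wise in sentence
#' order, zero-pads the smaller matrix at the bottom to equal row count,
#' and returns the Frobenius cosine (Frobenius inner product over the
#' product of Frobenius norms).  All-zero matrices give 0 with a warning.
#'
#' @inheritParams role_similarity
#' @return cosine in \[-1, 1\] (clipped to \[0, 1\] in the feature vector).
#' @export
term_matrix_cosine <- function(sentence_a, sentence_b, backends) {
  mat <- function(s) {
    lemmas <- effective_lemma_bag(s)
    rows <- lapply(lemmas, function(l) term_vector(backends$dist, l))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, rows)
  }
  ma <- mat(sentence_a); mb <- mat(sentence_b)
  if (is.null(ma) || is.null(mb)) {
    warning("no in-vocabulary effective word in a sentence; matrix cosine 0")
    return(0)
  }
  n <- max(nrow(ma), nrow(mb))
  pad <- function(m) rbind(m, matrix(0, n - nrow(m), ncol(m)))
  cosine_sim(as.vector(pad(ma)), as.vector(pad(mb)))
}
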