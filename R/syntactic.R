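# Syntactic similarity features: naive bag/set measures, window-based
# measures, skipped bigrams, polarity agreement and length ratio.
# All are symmetric in the pair and bounded in [0,1].

.check_degenerate <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) {
    stop("degenerate pair: both sides empty", call. = FALSE)
  }
}

#' Naive bag-of-words overlap
#'
#' Counts tokens shared by the two bags (multiset matching without
#' replacement: each token can be matched at most once) and divides by the
#' size of the larger bag.  Applied in the feature vector to raw words,
#' lemmas and Porter stems.
#'
#' @param bag_a,bag_b character vectors (bags, duplicates meaningful).
#' @return similarity in \[0, 1\].
#' @export
bag_overlap <- function(bag_a, bag_b) {
  .check_degenerate(bag_a, bag_b)
  if (length(bag_a) == 0L || length(bag_b) == 0L) return(0)
  ta <- table(bag_a); tb <- table(bag_b)
  common <- intersect(names(ta), names(tb))
  matched <- sum(pmin(ta[common], tb[common]))
  matched / max(length(bag_a), length(bag_b))
}

#' Set similarity normalised by the larger set
#'
#' `|A intersect B| / max(|A|, |B|)`; used on the sets of lemmatised
#' effective words.
#'
#' @param set_a,set_b character vectors (coerced to sets).
#' @return similarity in \[0, 1\].
#' @export
effective_set_similarity <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  .check_degenerate(a, b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b)) / max(length(a), length(b))
}

#' Jaccard similarity of two sets
#' @param set_a,set_b character vectors (coerced to sets).
#' @return `|A intersect B| / |A union B|` in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  .check_degenerate(a, b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Cosine similarity of term-frequency vectors
#'
#' Builds term-frequency vectors over the union vocabulary of the two bags
#' and returns their cosine; 0 when either vector is all-zero.
#'
#' @param lemmas_a,lemmas_b lemma bags.
#' @return cosine in \[0, 1\].
#' @export
lemma_vector_cosine <- function(lemmas_a, lemmas_b) {
  .check_degenerate(lemmas_a, lemmas_b)
  vocab <- union(lemmas_a, lemmas_b)
  va <- as.numeric(table(factor(lemmas_a, levels = vocab)))
  vb <- as.numeric(table(factor(lemmas_b, levels = vocab)))
  cosine_sim(va, vb)
}

#' Window (shared word-block) features
#'
#' Slides windows of every size k from 2 up to the length of the shorter
#' sequence over both sequences and counts ordered window-position pairs
#' (i, j) whose k-grams are exactly equal.  The count is normalised by
#' `choose(n, 2)` with n the shorter length (and capped at 1, since the
#' normaliser is not a strict upper bound); the longest k with at least one
#' equal window is normalised by n.  Applied to word, effective-word and
#' POS-tag sequences.
#'
#' @param seq_a,seq_b token sequences.
#' @return named numeric vector `c(overlap, longest)`.
#' @export
window_features <- function(seq_a, seq_b) {
  n <- min(length(seq_a), length(seq_b))
  if (n < 2L) {
    warning("sequence shorter than 2; window features set to 0")
    return(c(overlap = 0, longest = 0))
  }
  total <- 0L
  longest <- 0L
  for (k in 2:n) {
    ga <- vapply(seq_len(length(seq_a) - k + 1L),
                 function(i) paste(seq_a[i:(i + k - 1L)], collapse = "\r"),
                 character(1))
    gb <- vapply(seq_len(length(seq_b) - k + 1L),
                 function(i) paste(seq_b[i:(i + k - 1L)], collapse = "\r"),
                 character(1))
    tb <- table(gb)
    hits <- sum(vapply(ga, function(g) {
      m <- tb[g]; if (is.na(m)) 0L else as.integer(m)
    }, integer(1)))
    if (hits > 0L) longest <- k
    total <- total + hits
  }
  c(overlap = min(1, total / choose(n, 2)), longest = longest / n)
}

#' Ratio of shared skipped bigrams
#'
#' Forms the set of ordered pairs (w_i, w_j), i < j, over the content words
#' (nouns, verbs, adjectives, adverbs) of each sentence and returns the
#' intersection size divided by the larger set size.
#'
#' @param sentence_a,sentence_b `processed_sentence` objects.
#' @return similarity in \[0, 1\].
#' @export
skipped_bigram_ratio <- function(sentence_a, sentence_b) {
  content <- function(s) {
    idx <- grepl("^(NN|VB|JJ|RB)", s$pos_tags)
    s$tokens[idx]
  }
  skip_set <- function(w) {
    n <- length(w)
    if (n < 2L) return(character(0))
    pairs <- t(utils::combn(n, 2))
    unique(paste(w[pairs[, 1]], w[pairs[, 2]], sep = "\r"))
  }
  sa <- skip_set(content(sentence_a))
  sb <- skip_set(content(sentence_b))
  if (length(sa) == 0L && length(sb) == 0L) {
    warning("fewer than 2 content words on both sides; skipped-bigram ratio 0")
    return(0)
  }
  if (length(sa) == 0L || length(sb) == 0L) return(0)
  length(intersect(sa, sb)) / max(length(sa), length(sb))
}

#' Pairwise polarity feature
#' @param flag_a,flag_b logical negation flags from [detect_polarity()].
#' @return 0 if both sentences share polarity, 1 otherwise.
#' @export
polarity_feature <- function(flag_a, flag_b) {
  as.numeric(xor(isTRUE(flag_a), isTRUE(flag_b)))
}

#' Ratio of sentence lengths
#' @param len_a,len_b positive token counts.
#' @return `min/max`, in (0, 1\].
#' @export
length_ratio <- function(len_a, len_b) {
  if (len_a <= 0L || len_b <= 0L) stop("sentence length must be positive", call. = FALSE)
  min(len_a, len_b) / max(len_a, len_b)
}
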