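# Shared fixtures: the two worked-example outcome statements, the offline
# mini-lexicon, and brute-force oracles used to cross-check the optimised
# feature implementations.

outcome_a <- paste("No clinically relevant adverse events, such as urinary",
                   "retention, respiratory disturbances, or wound infections",
                   "were reported in the M-ADL group.")
outcome_b <- paste("Neither intra-operative nor post-operative clinically",
                   "relevant adverse events, such as urinary retention,",
                   "respiratory disturbances, or wound infections, were",
                   "observed.")

# processed once per test run
.fix <- new.env()
fix_sentence <- function(text, policy = "stoplist") {
  key <- paste0(policy, "::", text)
  if (is.null(.fix[[key]])) .fix[[key]] <- process_sentence(text, policy)
  .fix[[key]]
}
fix_backends <- function() {
  if (is.null(.fix$bk)) .fix$bk <- build_mini_lexicon(1L)
  .fix$bk
}

# Featurized synthetic corpus reused by the model/acceptance tests
# (featurization dominates runtime, so it is computed once).
fix_synthetic <- function() {
  if (is.null(.fix$syn)) {
    syn <- generate_synthetic_pairs(750, noise_sd = 0.5, seed = 1)
    fz <- featurize_pairs(syn, fix_backends())
    .fix$syn <- list(pairs = syn, X = fz$X, y = fz$y,
                     train = seq_len(500), test = 501:750)
  }
  .fix$syn
}

# ---- independent oracles ---------------------------------------------------

# window features by exhaustive enumeration over all (k, i, j)
oracle_window <- function(a, b) {
  n <- min(length(a), length(b))
  if (n < 2) return(c(overlap = 0, longest = 0))
  total <- 0; longest <- 0
  for (k in 2:n) {
    for (i in seq_len(length(a) - k + 1)) {
      for (j in seq_len(length(b) - k + 1)) {
        if (all(a[i:(i + k - 1)] == b[j:(j + k - 1)])) {
          total <- total + 1
          longest <- max(longest, k)
        }
      }
    }
  }
  c(overlap = min(1, total / choose(n, 2)), longest = longest / n)
}

# Needleman-Wunsch by exhaustive recursion over all alignments
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (length(a) == 0) return(gap * length(b))
  if (length(b) == 0) return(gap * length(a))
  max(oracle_nw(a[-1], b[-1]) + if (a[1] == b[1]) match else mismatch,
      oracle_nw(a[-1], b) + gap,
      oracle_nw(a, b[-1]) + gap)
}

# all subtrees of a tree node as bracket strings, by direct recursion
oracle_subtrees <- function(node) {
  out <- tree_to_string(node)
  for (ch in node$children) out <- c(out, oracle_subtrees(ch))
  out
}

# Eq.-style tree overlap by explicit double loop over clause and subtree pairs
oracle_tree_overlap <- function(tree_a, tree_b, words_a, words_b) {
  ca <- tree_a$children; cb <- tree_b$children
  total <- 0
  for (i in seq_along(ca)) for (j in seq_along(cb)) {
    si <- oracle_subtrees(ca[[i]]); sj <- oracle_subtrees(cb[[j]])
    hits <- 0
    for (x in si) for (y in sj) if (x == y) hits <- hits + 1
    total <- total + hits / (words_a[i] * words_b[j])
  }
  total / (length(ca) * length(cb))
}

# jaccard by first-principles membership counting
oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(vapply(a, function(x) x %in% b, logical(1)))
  inter / (length(a) + length(b) - inter)
}

# skipped-bigram sets by explicit double loop
oracle_skip_bigrams <- function(words) {
  out <- character(0)
  n <- length(words)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    out <- c(out, paste(words[i], words[j], sep = "\r"))
  }
  unique(out)
}

random_seqs <- function(n, max_len = 8, alphabet = c("a", "b", "c")) {
  lapply(seq_len(n), function(i) {
    sample(alphabet, sample(2:max_len, 1), replace = TRUE)
  })
}
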