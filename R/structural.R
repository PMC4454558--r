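# Structural similarity features: clause-count ratio and reduced-parse-tree
# subtree overlap.

#' Clause-count ratio
#' @param count_a,count_b positive clause counts.
#' @return `min/max`, in (0, 1\].
#' @export
clause_ratio <- function(count_a, count_b) {
  if (count_a < 1L || count_b < 1L) stop("clause counts must be >= 1", call. = FALSE)
  min(count_a, count_b) / max(count_a, count_b)
}

# Enumerate the subtrees of a clause node as canonical bracket strings.
# By default every node (internal and leaf) roots one subtree; with
# maximal_only = TRUE only the clause root does.
.enumerate_subtrees <- function(node, maximal_only = FALSE) {
  if (maximal_only) return(tree_to_string(node))
  out <- tree_to_string(node)
  for (ch in node$children) {
    out <- c(out, .enumerate_subtrees(ch, FALSE))
  }
  out
}

#' Reduced-parse-tree overlap
#'
#' For every clause pair (C_i of sentence 1, C'_j of sentence 2) the number
#' of identical subtrees — recursive equality of node labels and child
#' order at the reduced-label level — is divided by the product of the two
#' clauses' word counts; the sum over clause pairs is divided by the product
#' of the clause counts.  Because the word-count normaliser does not bound
#' the sum, the raw value may leave \[0, 1\] (it is returned in the
#' `"raw"` attribute); the feature value is clipped to \[0, 1\].
#'
#' @param tree_a,tree_b `reduced_tree` ROOT nodes (one S child per clause),
#'   or bracketed-tree strings.
#' @param words_a,words_b integer vectors of per-clause word counts.
#' @param maximal_only count only whole-clause subtrees instead of subtrees
#'   rooted at every node.
#' @return clipped overlap in \[0, 1\] with attribute `raw`.
#' @export
reduced_tree_overlap <- function(tree_a, tree_b, words_a, words_b,
                                 maximal_only = FALSE) {
  if (is.character(tree_a)) tree_a <- tree_from_string(tree_a)
  if (is.character(tree_b)) tree_b <- tree_from_string(tree_b)
  ca <- tree_a$children; cb <- tree_b$children
  if (length(ca) == 0L || length(cb) == 0L) {
    warning("empty reduced tree; overlap 0")
    return(structure(0, raw = 0))
  }
  stopifnot(length(words_a) == length(ca), length(words_b) == length(cb))
  total <- 0
  for (i in seq_along(ca)) {
    sub_i <- .enumerate_subtrees(ca[[i]], maximal_only)
    for (j in seq_along(cb)) {
      sub_j <- .enumerate_subtrees(cb[[j]], maximal_only)
      ti <- table(sub_i); tj <- table(sub_j)
      common <- intersect(names(ti), names(tj))
      n_equal <- sum(as.numeric(ti[common]) * as.numeric(tj[common]))
      total <- total + n_equal / (words_a[i] * words_b[j])
    }
  }
  raw <- total / (length(ca) * length(cb))
  structure(clip(raw, 0, 1), raw = raw)
}
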