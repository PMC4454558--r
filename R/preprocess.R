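# Text preprocessing: every linguistic layer the similarity features consume.
# All components are deterministic rule-based systems over small bundled
# lexicons, so identical input text always yields an identical
# ProcessedSentence (no model downloads, no global state).

#' Tokenise one English sentence
#'
#' Lower-cases the sentence, keeps alphanumeric tokens and intra-word hyphens
#' and apostrophes (so compounds like "intra-operative" or "M-ADL" stay
#' single tokens), and drops punctuation-only material.
#'
#' @param text a single character string holding one sentence.
#' @return character vector of tokens.
#' @examples
#' tokenize("A cat sat.")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty sentence", call. = FALSE)
  }
  m <- gregexpr("[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*", text)
  toks <- tolower(regmatches(text, m)[[1]])
  if (length(toks) == 0L) stop("empty sentence", call. = FALSE)
  toks
}

.strip_plural <- function(w) {
  if (endsWith(w, "ies") && nchar(w) > 4L) return(sub("ies$", "y", w))
  if (grepl("(ses|xes|zes|ches|shes)$", w)) return(sub("es$", "", w))
  if (endsWith(w, "s") && !endsWith(w, "ss")) return(sub("s$", "", w))
  w
}

# Undo regular -ed / -ing morphology: undouble final consonants, restore a
# dropped final "e" after typical stems (slic+e, observ+e, chas+e, us+e).
.restore_base <- function(stem) {
  n <- nchar(stem)
  if (n >= 3L) {
    a <- substr(stem, n - 1L, n - 1L); b <- substr(stem, n, n)
    if (a == b && !b %in% c("l", "s", "e", "o")) {
      return(substr(stem, 1L, n - 1L))
    }
  }
  last <- substr(stem, n, n)
  if (last %in% c("v", "c", "u", "z") ||
      (last == "s" && !endsWith(stem, "ss"))) {
    return(paste0(stem, "e"))
  }
  stem
}

.verb_base_of <- function(tok) {
  if (tok %in% .verb_bases) return(list(base = tok, form = "VB"))
  s <- .strip_plural(tok)
  if (s != tok && s %in% .verb_bases) return(list(base = s, form = "VBZ"))
  if (endsWith(tok, "ed")) {
    stem <- sub("ed$", "", tok)
    for (cand in unique(c(stem, .restore_base(stem), paste0(stem, "e")))) {
      if (cand %in% .verb_bases) return(list(base = cand, form = "VBD"))
    }
  }
  if (endsWith(tok, "ing")) {
    stem <- sub("ing$", "", tok)
    for (cand in unique(c(stem, .restore_base(stem), paste0(stem, "e")))) {
      if (cand %in% .verb_bases) return(list(base = cand, form = "VBG"))
    }
  }
  NULL
}

#' Rule-based part-of-speech tagging
#'
#' Assigns coarse Penn-style tags from closed-class lists, small open-class
#' lexicons, morphology against a verb-base lexicon, and suffix rules.
#' Unknown hyphenated compounds are treated as adjectival modifiers; the
#' default tag is NN.
#'
#' @param tokens character vector from [tokenize()].
#' @return character vector of tags aligned with `tokens`.
#' @export
tag_pos <- function(tokens) {
  n <- length(tokens)
  tags <- character(n)
  for (i in seq_len(n)) {
    tok <- tokens[i]
    prev <- if (i > 1L) tags[i - 1L] else ""
    tags[i] <- local({
      j <- match(tok, .aux_table$word)
      if (!is.na(j)) return(.aux_table$tag[j])
      if (tok %in% .modals) return("MD")
      if (tok == "to") return("TO")
      if (tok %in% .determiners) return("DT")
      if (tok %in% .conjunctions) return("CC")
      if (tok %in% .prepositions) return("IN")
      if (tok %in% .pronouns) return("PRP")
      if (tok == "not") return("RB")
      if (grepl("^[0-9]+([.,][0-9]+)?$", tok)) return("CD")
      j <- match(tok, .irregular_verbs$word)
      if (!is.na(j)) return(.irregular_verbs$tag[j])
      if (tok %in% .irregular_nouns$word) return("NNS")
      if (tok %in% .noun_bases) return("NN")
      s <- .strip_plural(tok)
      if (s != tok && s %in% .noun_bases) return("NNS")
      vb <- .verb_base_of(tok)
      if (!is.null(vb)) {
        if (vb$form == "VBD" && prev %in% c("VBD", "VBZ", "VBP", "VB", "VBN", "MD", "RB")) {
          return("VBN")
        }
        return(vb$form)
      }
      if (tok %in% .adjective_bases) return("JJ")
      if (endsWith(tok, "ly") && nchar(tok) > 3L) return("RB")
      if (grepl("-", tok, fixed = TRUE)) return("JJ")
      for (sfx in .adjective_suffixes) {
        if (endsWith(tok, sfx) && nchar(tok) > nchar(sfx) + 2L) return("JJ")
      }
      if (endsWith(tok, "ed") && nchar(tok) > 3L) return("VBN")
      if (endsWith(tok, "ing") && nchar(tok) > 4L) return("VBG")
      if (endsWith(tok, "s") && !endsWith(tok, "ss") && nchar(tok) > 3L) return("NNS")
      "NN"
    })
  }
  tags
}

#' Lemmatise tokens given their POS tags
#'
#' Maps inflected forms to base forms using the auxiliary/irregular tables
#' and regular plural and -ed/-ing morphology ("infections" -> "infection",
#' "were" -> "be", "observed" -> "observe").  Unknown words map to
#' themselves.
#'
#' @param tokens,pos_tags aligned character vectors.
#' @return character vector of lemmas aligned with `tokens`.
#' @export
lemmatize <- function(tokens, pos_tags) {
  stopifnot(length(tokens) == length(pos_tags))
  vapply(seq_along(tokens), function(i) {
    tok <- tokens[i]; tag <- pos_tags[i]
    j <- match(tok, .aux_table$word)
    if (!is.na(j)) return(.aux_table$lemma[j])
    j <- match(tok, .irregular_verbs$word)
    if (!is.na(j)) return(.irregular_verbs$lemma[j])
    j <- match(tok, .irregular_nouns$word)
    if (!is.na(j)) return(.irregular_nouns$lemma[j])
    if (tag %in% c("NNS", "VBZ")) return(.strip_plural(tok))
    if (tag %in% c("VBD", "VBN") && endsWith(tok, "ed")) {
      stem <- sub("ed$", "", tok)
      vb <- .verb_base_of(tok)
      if (!is.null(vb)) return(vb$base)
      return(.restore_base(stem))
    }
    if (tag == "VBG" && endsWith(tok, "ing")) {
      stem <- sub("ing$", "", tok)
      vb <- .verb_base_of(tok)
      if (!is.null(vb)) return(vb$base)
      return(.restore_base(stem))
    }
    tok
  }, character(1))
}

#' Mark effective (content-bearing) token positions
#'
#' Two policies are available.  `"stoplist"` (default) removes the
#' closed-class layers only: determiners, prepositions and subordinating
#' conjunctions, coordinators, pronouns, modals and infinitival "to".
#' `"content"` keeps nouns and verbs only (so adjectives and adverbs are
#' also dropped); this stricter reading matches the worked effective-word
#' sets used in the set-similarity feature's documentation.
#'
#' @param tokens,pos_tags aligned character vectors.
#' @param policy `"stoplist"` or `"content"`.
#' @return integer vector of effective token positions.
#' @export
mark_effective <- function(tokens, pos_tags,
                           policy = c("stoplist", "content")) {
  stopifnot(length(tokens) == length(pos_tags))
  policy <- match.arg(policy)
  keep <- if (policy == "stoplist") {
    !(pos_tags %in% c("DT", "IN", "CC", "PRP", "MD", "TO", "EX"))
  } else {
    grepl("^(NN|VB)", pos_tags)
  }
  which(keep)
}

#' Detect sentence-level negation polarity
#'
#' NegEx-style trigger matching: the sentence is flagged negated when a
#' negation trigger (no, not, neither, nor, never, without, ...) or a
#' bigram trigger ("absence of", "free of", "negative for") occurs and is
#' not part of a pseudo-negation phrase ("not only", "no change", ...).
#' Polarity is a pure function of the token sequence.
#'
#' @param tokens character vector from [tokenize()].
#' @return `TRUE` if the sentence is negated, else `FALSE`.
#' @export
detect_polarity <- function(tokens) {
  single <- c("no", "not", "neither", "nor", "never", "without", "cannot",
              "none", "nobody", "nothing", "n't", "denies", "denied", "deny")
  bigram <- list(c("absence", "of"), c("free", "of"), c("negative", "for"))
  pseudo <- list(c("not", "only"), c("no", "change"), c("no", "increase"),
                 c("no", "further"), c("not", "necessarily"))
  n <- length(tokens)
  masked <- rep(FALSE, n)
  for (p in pseudo) {
    if (n < 2L) break
    hit <- which(tokens[-n] == p[1] & tokens[-1] == p[2])
    masked[hit] <- TRUE
  }
  if (any(tokens %in% single & !masked)) return(TRUE)
  for (b in bigram) {
    if (n >= 2L && any(tokens[-n] == b[1] & tokens[-1] == b[2])) return(TRUE)
  }
  FALSE
}

.finite_tags <- c("VBD", "VBZ", "VBP", "MD")
.verb_group_tags <- c("VBD", "VBZ", "VBP", "VB", "VBN", "VBG", "MD", "RB", "TO")

#' Split a sentence into clauses with pre-verb / predicate / post-verb spans
#'
#' Clause boundaries are placed at coordinating conjunctions ("and", "but")
#' that separate two finite verb groups.  Within each clause the predicate
#' is the verb group anchored at the first finite verb; everything to its
#' left is the pre-verb component and everything to its right the post-verb
#' component.  A sentence with no detectable finite verb falls back to a
#' single clause with an empty predicate (with a warning).
#'
#' @param tokens,pos_tags,lemmas aligned character vectors.
#' @return list of clauses; each clause is a list with integer index vectors
#'   `idx` (all clause positions), `pre`, `pred`, `post`, and lemma bags
#'   `pre_verb`, `predicate`, `post_verb`.
#' @export
parse_clauses <- function(tokens, pos_tags, lemmas = lemmatize(tokens, pos_tags)) {
  n <- length(tokens)
  finite <- which(pos_tags %in% .finite_tags)
  if (length(finite) == 0L) {
    warning("no finite verb found; falling back to a single clause")
    return(list(list(
      idx = seq_len(n), pre = seq_len(n), pred = integer(0), post = integer(0),
      pre_verb = lemmas, predicate = character(0), post_verb = character(0)
    )))
  }
  # boundaries: CC "and"/"but" with a finite verb on both sides
  bounds <- integer(0)
  last_cut <- 0L
  for (i in seq_len(n)) {
    if (pos_tags[i] == "CC" && tokens[i] %in% c("and", "but")) {
      if (any(finite > last_cut & finite < i) && any(finite > i)) {
        bounds <- c(bounds, i)
        last_cut <- i
      }
    }
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds - 1L, n)
  clauses <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- seq.int(starts[k], ends[k])
    fin <- finite[finite %in% idx]
    if (length(fin) == 0L) {
      pred <- integer(0)
    } else {
      v <- fin[1L]
      e <- v
      while (e < max(idx) && pos_tags[e + 1L] %in% .verb_group_tags) e <- e + 1L
      pred <- seq.int(v, e)
    }
    pre <- idx[idx < min(c(pred, Inf))]
    post <- idx[idx > max(c(pred, -Inf))]
    clauses[[k]] <- list(
      idx = idx, pre = pre, pred = pred, post = post,
      pre_verb = lemmas[pre], predicate = lemmas[pred], post_verb = lemmas[post]
    )
  }
  clauses
}

# ---- reduced parse trees ---------------------------------------------------

tree_node <- function(label, children = list()) {
  structure(list(label = label, children = children), class = "reduced_tree")
}

#' Serialise a reduced parse tree to Penn-style bracket notation
#' @param node a tree node built by the package or parsed from a string.
#' @return single character string, e.g. `"(S (NP) (VP (PP (NP))))"`.
#' @export
tree_to_string <- function(node) {
  if (length(node$children) == 0L) return(sprintf("(%s)", node$label))
  inner <- vapply(node$children, tree_to_string, character(1))
  sprintf("(%s %s)", node$label, paste(inner, collapse = " "))
}

#' Parse Penn-style bracket notation into a reduced tree
#' @param s bracketed-tree string.
#' @return tree node.
#' @export
tree_from_string <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 0L
  parse_node <- function() {
    pos <<- pos + 1L
    if (toks[pos] != "(") stop("malformed tree string", call. = FALSE)
    pos <<- pos + 1L
    lab <- toks[pos]
    kids <- list()
    while (pos < length(toks) && toks[pos + 1L] == "(") {
      kids[[length(kids) + 1L]] <- parse_node()
    }
    pos <<- pos + 1L
    if (toks[pos] != ")") stop("malformed tree string", call. = FALSE)
    tree_node(lab, kids)
  }
  parse_node()
}

# Chunk a span of clause positions into NP / PP(NP) leaves.
.chunk_span <- function(positions, pos_tags) {
  nodes <- list()
  i <- 1L
  nominal <- function(t) t %in% c("DT", "JJ", "NN", "NNS", "PRP", "CD", "RB")
  while (i <= length(positions)) {
    t <- pos_tags[positions[i]]
    if (t == "IN" || t == "TO") {
      j <- i + 1L
      while (j <= length(positions) && nominal(pos_tags[positions[j]])) j <- j + 1L
      if (j > i + 1L) {
        nodes[[length(nodes) + 1L]] <- tree_node("PP", list(tree_node("NP")))
      }
      i <- j
    } else if (nominal(t)) {
      j <- i
      while (j <= length(positions) && nominal(pos_tags[positions[j]])) j <- j + 1L
      nodes[[length(nodes) + 1L]] <- tree_node("NP")
      i <- j
    } else {
      i <- i + 1L  # CC and stray verb tags outside the predicate are skipped
    }
  }
  nodes
}

#' Build the reduced parse tree of a processed sentence
#'
#' Prunes the sentence to its major phrase scaffold: one S node per clause,
#' whose children are the pre-verb NP/PP chunks and a VP node carrying the
#' post-verb chunks.  Leaf labels come from the closed set
#' \{NP, VP, PP, S, ROOT\}.
#'
#' @param clauses output of [parse_clauses()].
#' @param pos_tags tag vector of the sentence.
#' @return a `reduced_tree` node with label ROOT and one S child per clause.
#' @export
reduce_parse_tree <- function(clauses, pos_tags) {
  s_nodes <- lapply(clauses, function(cl) {
    pre_chunks <- .chunk_span(cl$pre, pos_tags)
    vp <- if (length(cl$pred) > 0L || length(cl$post) > 0L) {
      list(tree_node("VP", .chunk_span(cl$post, pos_tags)))
    } else list()
    tree_node("S", c(pre_chunks, vp))
  })
  tree_node("ROOT", s_nodes)
}

#' Process one sentence into all derived linguistic layers
#'
#' Runs tokenisation, tagging, lemmatisation, Porter stemming, effective-word
#' marking, negation detection, clause extraction and parse-tree reduction.
#'
#' @param text one English sentence.
#' @param policy effective-word policy, see [mark_effective()].
#' @return an object of class `processed_sentence`: a list with elements
#'   `text`, `tokens`, `lemmas`, `stems`, `pos_tags`, `effective_indices`,
#'   `polarity`, `clauses`, `reduced_tree`, `clause_word_counts`.
#' @examples
#' s <- process_sentence("A group of kids is playing in a yard.")
#' s$tokens
#' @export
process_sentence <- function(text, policy = c("stoplist", "content")) {
  policy <- match.arg(policy)
  tokens <- tokenize(text)
  pos_tags <- tag_pos(tokens)
  lemmas <- lemmatize(tokens, pos_tags)
  stems <- stem_tokens(tokens)
  eff <- mark_effective(tokens, pos_tags, policy)
  polarity <- detect_polarity(tokens)
  clauses <- withCallingHandlers(
    parse_clauses(tokens, pos_tags, lemmas),
    warning = function(w) invokeRestart("muffleWarning")
  )
  tree <- reduce_parse_tree(clauses, pos_tags)
  structure(list(
    text = text, tokens = tokens, lemmas = lemmas, stems = stems,
    pos_tags = pos_tags, effective_indices = eff, polarity = polarity,
    clauses = clauses, reduced_tree = tree,
    clause_word_counts = vapply(clauses, function(cl) length(cl$idx), integer(1)),
    policy = policy
  ), class = "processed_sentence")
}

#' @export
print.processed_sentence <- function(x, ...) {
  cat("<processed_sentence> ", length(x$tokens), " tokens, ",
      length(x$clauses), " clause(s), polarity: ",
      if (x$polarity) "negated" else "affirmative", "\n", sep = "")
  cat(paste(x$tokens, x$pos_tags, sep = "/", collapse = " "), "\n")
  invisible(x)
}

effective_lemmas <- function(s) unique(s$lemmas[s$effective_indices])
effective_lemma_bag <- function(s) s$lemmas[s$effective_indices]
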