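# Lexical knowledge backends: a taxonomy with information content (IC),
# a frame lexicon, and a distributional term-vector space.  All semantic
# features take a backend bundle handle; there is no global state.

#' Construct a taxonomy backend
#'
#' @param synsets data frame with columns `synset_id`, `parent` (`NA` for the
#'   root), `depth` (root = 1), `ic` (non-negative; never smaller than the
#'   parent's), `category` (lexicographer-file name), `gloss`
#'   (space-separated definition tokens).
#' @param senses data frame with columns `lemma`, `pos` (`"n"`/`"v"`/...),
#'   `rank` (1 = most frequent sense) and `synset_id`.
#' @return object of class `taxonomy_backend`.
#' @export
taxonomy_backend <- function(synsets, senses) {
  need <- c("synset_id", "parent", "depth", "ic", "category", "gloss")
  if (!all(need %in% names(synsets))) {
    stop("taxonomy synset table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("lemma", "pos", "rank", "synset_id") %in% names(senses))) {
    stop("sense table must have columns lemma, pos, rank, synset_id", call. = FALSE)
  }
  if (any(synsets$ic < 0)) stop("IC values must be non-negative", call. = FALSE)
  rownames(synsets) <- synsets$synset_id
  # IC monotone non-increasing from leaf to root
  for (i in seq_len(nrow(synsets))) {
    p <- synsets$parent[i]
    if (!is.na(p)) {
      if (!p %in% synsets$synset_id) {
        stop("unknown parent synset: ", p, call. = FALSE)
      }
      if (synsets$ic[i] < synsets[p, "ic"]) {
        stop("IC must not decrease from parent to child (", synsets$synset_id[i],
             ")", call. = FALSE)
      }
    }
  }
  structure(list(synsets = synsets, senses = senses), class = "taxonomy_backend")
}

.tax_check <- function(taxonomy, id) {
  if (!id %in% taxonomy$synsets$synset_id) {
    stop("unknown synset: ", id, call. = FALSE)
  }
}

#' @rdname taxonomy_backend
#' @param taxonomy a `taxonomy_backend`.
#' @param lemma,pos lemma string and coarse POS (`pos = NULL` matches any).
#' @export
synsets_of <- function(taxonomy, lemma, pos = NULL) {
  s <- taxonomy$senses
  hit <- s$lemma == lemma
  if (!is.null(pos)) hit <- hit & s$pos == pos
  s <- s[hit, , drop = FALSE]
  s$synset_id[order(s$rank)]
}

#' @rdname taxonomy_backend
#' @param synset a synset id.
#' @export
synset_ic <- function(taxonomy, synset) {
  .tax_check(taxonomy, synset)
  taxonomy$synsets[synset, "ic"]
}

#' @rdname taxonomy_backend
#' @export
synset_depth <- function(taxonomy, synset) {
  .tax_check(taxonomy, synset)
  taxonomy$synsets[synset, "depth"]
}

#' @rdname taxonomy_backend
#' @export
synset_category <- function(taxonomy, synset) {
  .tax_check(taxonomy, synset)
  taxonomy$synsets[synset, "category"]
}

#' @rdname taxonomy_backend
#' @export
synset_gloss <- function(taxonomy, synset) {
  .tax_check(taxonomy, synset)
  strsplit(taxonomy$synsets[synset, "gloss"], " ", fixed = TRUE)[[1]]
}

.ancestors <- function(taxonomy, synset) {
  chain <- synset
  p <- taxonomy$synsets[synset, "parent"]
  while (!is.na(p)) {
    chain <- c(chain, p)
    p <- taxonomy$synsets[p, "parent"]
  }
  chain
}

#' Least common subsumer of two synsets
#' @rdname taxonomy_backend
#' @param s1,s2 synset ids.
#' @return the deepest shared ancestor (symmetric in its arguments).
#' @export
lcs <- function(taxonomy, s1, s2) {
  .tax_check(taxonomy, s1); .tax_check(taxonomy, s2)
  a1 <- .ancestors(taxonomy, s1)
  a2 <- .ancestors(taxonomy, s2)
  common <- intersect(a1, a2)
  if (length(common) == 0L) return(NA_character_)
  common[which.max(taxonomy$synsets[common, "depth"])]
}

#' Synsets related to a synset by semantic pointers
#'
#' All semantic pointers available in the taxonomy graph are included:
#' the parent (hypernym), the children (hyponyms) and the siblings.
#' @rdname taxonomy_backend
#' @export
related_synsets <- function(taxonomy, synset) {
  .tax_check(taxonomy, synset)
  tab <- taxonomy$synsets
  parent <- tab[synset, "parent"]
  children <- tab$synset_id[!is.na(tab$parent) & tab$parent == synset]
  sibs <- if (!is.na(parent)) {
    setdiff(tab$synset_id[!is.na(tab$parent) & tab$parent == parent], synset)
  } else character(0)
  unique(c(if (!is.na(parent)) parent, children, sibs))
}

#' Lin similarity of two synsets
#'
#' `2 * IC(lcs) / (IC(s1) + IC(s2))`: the information content of the most
#' informative common ancestor relative to the ICs of the two concepts.
#' Returns 1 for identical synsets with positive IC and 0 when the
#' denominator is zero.
#'
#' @param s1,s2 synset ids.
#' @param taxonomy a `taxonomy_backend`.
#' @return similarity in \[0, 1\].
#' @export
lin_similarity <- function(s1, s2, taxonomy) {
  .tax_check(taxonomy, s1); .tax_check(taxonomy, s2)
  denom <- synset_ic(taxonomy, s1) + synset_ic(taxonomy, s2)
  if (denom == 0) return(0)
  anc <- lcs(taxonomy, s1, s2)
  if (is.na(anc)) return(0)
  clip(2 * synset_ic(taxonomy, anc) / denom, 0, 1)
}

#' Wu-Palmer similarity of two synsets
#'
#' `2 * depth(lcs) / (depth(s1) + depth(s2))` with the root at depth 1.
#'
#' @inheritParams lin_similarity
#' @return similarity in (0, 1\].
#' @export
wu_palmer_similarity <- function(s1, s2, taxonomy) {
  .tax_check(taxonomy, s1); .tax_check(taxonomy, s2)
  anc <- lcs(taxonomy, s1, s2)
  if (is.na(anc)) return(0)
  2 * synset_depth(taxonomy, anc) /
    (synset_depth(taxonomy, s1) + synset_depth(taxonomy, s2))
}

#' Lesk best-sense disambiguation
#'
#' Picks, among the synsets of `word`, the one whose gloss shares the most
#' tokens with the sentence context; ties are broken towards the lowest
#' sense rank.  The chosen sense is encoded as `"word#pos#rank"`.
#'
#' @param word a lemma.
#' @param context character vector of context tokens (the whole sentence).
#' @param taxonomy a `taxonomy_backend`.
#' @param pos optional coarse POS restriction.
#' @return list with `word`, `pos`, `rank`, `synset_id`, `category`,
#'   `encoding`; or `NULL` when the word has no synset.
#' @export
best_sense <- function(word, context, taxonomy, pos = NULL) {
  s <- taxonomy$senses
  hit <- s$lemma == word
  if (!is.null(pos)) hit <- hit & s$pos == pos
  s <- s[hit, , drop = FALSE]
  if (nrow(s) == 0L) return(NULL)
  s <- s[order(s$rank), , drop = FALSE]
  ctx <- setdiff(unique(context), word)
  ov <- vapply(s$synset_id, function(id) {
    length(intersect(synset_gloss(taxonomy, id), ctx))
  }, integer(1))
  k <- which.max(ov)  # ties -> first, i.e. lowest rank
  list(word = word, pos = s$pos[k], rank = s$rank[k],
       synset_id = s$synset_id[k],
       category = synset_category(taxonomy, s$synset_id[k]),
       encoding = sprintf("%s#%s#%d", word, s$pos[k], s$rank[k]))
}

# ---- frame backend ---------------------------------------------------------

#' Construct a frame backend
#' @param frames data frame with columns `lemma` and `frame_id`.
#' @return object of class `frame_backend`.
#' @export
frame_backend <- function(frames) {
  if (!all(c("lemma", "frame_id") %in% names(frames))) {
    stop("frame table must have columns lemma, frame_id", call. = FALSE)
  }
  structure(list(frames = frames), class = "frame_backend")
}

#' Frames evoked by a lemma
#' @param backend a `frame_backend`.
#' @param lemma a lemma.
#' @return character vector of frame ids (possibly empty).
#' @export
frames_of <- function(backend, lemma) {
  unique(backend$frames$frame_id[backend$frames$lemma == lemma])
}

# ---- distributional backend ------------------------------------------------

#' Construct a distributional term-vector backend
#' @param vectors numeric matrix, one row per term (rownames = terms), a
#'   fixed number of columns (the vector dimension).
#' @return object of class `dist_backend`.
#' @export
dist_backend <- function(vectors) {
  if (is.null(rownames(vectors))) stop("vector matrix needs term rownames", call. = FALSE)
  structure(list(vectors = vectors, dim = ncol(vectors)), class = "dist_backend")
}

#' Term vector lookup
#' @param backend a `dist_backend`.
#' @param term a term.
#' @return numeric vector, or `NULL` for out-of-vocabulary terms.
#' @export
term_vector <- function(backend, term) {
  if (!term %in% rownames(backend$vectors)) return(NULL)
  backend$vectors[term, ]
}

#' Top associated terms of a term
#'
#' Nearest neighbours by cosine over the backend vocabulary (the term
#' itself excluded).
#' @param backend a `dist_backend`.
#' @param term a term.
#' @param k number of neighbours (default 20).
#' @return character vector of terms; empty for out-of-vocabulary input.
#' @export
associated_terms <- function(backend, term, k = 20L) {
  v <- term_vector(backend, term)
  if (is.null(v)) return(character(0))
  others <- setdiff(rownames(backend$vectors), term)
  sims <- vapply(others, function(t) cosine_sim(v, backend$vectors[t, ]),
                 numeric(1))
  names(sort(sims, decreasing = TRUE))[seq_len(min(k, length(others)))]
}

# ---- bundle and file I/O ---------------------------------------------------

#' Bundle the three knowledge backends
#' @param taxonomy a `taxonomy_backend`.
#' @param frames a `frame_backend`.
#' @param dist a `dist_backend`.
#' @param ic optional named numeric IC table for surface lemmas (used by the
#'   IC-vector feature); defaults to the maximum synset IC per lemma.
#' @return object of class `backend_bundle`.
#' @export
backend_bundle <- function(taxonomy, frames, dist, ic = NULL) {
  stopifnot(inherits(taxonomy, "taxonomy_backend"),
            inherits(frames, "frame_backend"),
            inherits(dist, "dist_backend"))
  if (is.null(ic)) {
    ic <- tapply(taxonomy$synsets[taxonomy$senses$synset_id, "ic"],
                 taxonomy$senses$lemma, max)
    ic <- stats::setNames(as.numeric(ic), names(ic))
  }
  structure(list(taxonomy = taxonomy, frames = frames, dist = dist, ic = ic),
            class = "backend_bundle")
}

#' Load backends from resource files
#'
#' Formats: the taxonomy dump is a TSV with the `taxonomy_backend` synset
#' columns; the sense table a TSV `lemma, pos, rank, synset_id`; the IC
#' table a TSV `synset_id<TAB>ic` overriding dump ICs when given; the frame
#' lexicon a TSV `lemma<TAB>frame_id`; the vector store a word2vec-style
#' text file (`term v1 ... vd` per line, optional count/dim header).
#'
#' @param taxonomy_path,senses_path,frames_path,vectors_path file paths.
#' @param ic_path optional IC table path.
#' @return a `backend_bundle`.
#' @export
load_backends <- function(taxonomy_path, senses_path, frames_path,
                          vectors_path, ic_path = NULL) {
  for (p in c(taxonomy_path, senses_path, frames_path, vectors_path, ic_path)) {
    if (!file.exists(p)) stop("missing resource file: ", p, call. = FALSE)
  }
  syn <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE,
                           na.strings = "NA", quote = "")
  senses <- utils::read.delim(senses_path, stringsAsFactors = FALSE, quote = "")
  if (!is.null(ic_path)) {
    ic_tab <- utils::read.delim(ic_path, header = FALSE,
                                col.names = c("synset_id", "ic"), quote = "")
    if (any(is.na(ic_tab$ic))) stop("malformed IC table record", call. = FALSE)
    m <- match(syn$synset_id, ic_tab$synset_id)
    syn$ic[!is.na(m)] <- ic_tab$ic[m[!is.na(m)]]
  }
  fr <- utils::read.delim(frames_path, header = FALSE,
                          col.names = c("lemma", "frame_id"), quote = "")
  lines <- readLines(vectors_path)
  if (grepl("^[0-9]+ [0-9]+$", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, " +")
  dims <- vapply(parts, length, integer(1)) - 1L
  if (length(unique(dims)) != 1L) {
    stop("vector store dimension mismatch across records", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (anyNA(mat)) stop("malformed vector store record", call. = FALSE)
  rownames(mat) <- vapply(parts, `[[`, character(1), 1L)
  backend_bundle(taxonomy_backend(syn, senses), frame_backend(fr),
                 dist_backend(mat))
}

#' Write a backend bundle to resource files
#'
#' Inverse of [load_backends()]; used by the `make-lexicon` CLI subcommand.
#' @param bundle a `backend_bundle`.
#' @param dir output directory.
#' @return invisibly, the named vector of file paths written.
#' @export
write_backends <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    taxonomy = file.path(dir, "taxonomy.tsv"),
    senses = file.path(dir, "senses.tsv"),
    frames = file.path(dir, "frames.tsv"),
    vectors = file.path(dir, "vectors.txt")
  )
  utils::write.table(bundle$taxonomy$synsets, paths["taxonomy"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$taxonomy$senses, paths["senses"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$frames$frames, paths["frames"],
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  v <- bundle$dist$vectors
  writeLines(c(paste(nrow(v), ncol(v)),
               vapply(rownames(v), function(t) {
                 paste(c(t, format(v[t, ], trim = TRUE)), collapse = " ")
               }, character(1))),
             paths["vectors"])
  invisible(paths)
}
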