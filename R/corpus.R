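# Pair-corpus I/O, same-class pair construction, sampling and the
# synthetic pair generator.

.piboso_classes <- c("Background", "Intervention", "Outcome", "Population",
                     "StudyDesign")

#' Read a sentence-pair corpus (SICK-dialect TSV)
#'
#' Expects a tab-separated file with header columns `pair_ID`,
#' `sentence_A`, `sentence_B`, `relatedness_score`,
#' `entailment_judgment` (the last two optional for unscored corpora).
#'
#' @param path file path.
#' @return data frame with columns `pair_id`, `sentence_a`, `sentence_b`,
#'   `relatedness`, `entailment`.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         check.names = FALSE)
  need <- c("pair_ID", "sentence_A", "sentence_B")
  if (!all(need %in% names(d))) {
    stop("missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  rel <- if ("relatedness_score" %in% names(d)) {
    as.numeric(d$relatedness_score)
  } else rep(NA_real_, nrow(d))
  bad <- which(!is.na(rel) & (rel < 1 | rel > 5))
  if (length(bad)) {
    stop("relatedness score outside [1, 5] on line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  blank <- which(!nzchar(trimws(d$sentence_A)) | !nzchar(trimws(d$sentence_B)))
  if (length(blank)) {
    stop("empty sentence on line(s): ", paste(blank + 1L, collapse = ", "),
         call. = FALSE)
  }
  data.frame(pair_id = as.character(d$pair_ID), sentence_a = d$sentence_A,
             sentence_b = d$sentence_B, relatedness = rel,
             entailment = if ("entailment_judgment" %in% names(d)) {
               d$entailment_judgment
             } else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a sentence-pair corpus (SICK-dialect TSV)
#' @param pairs data frame as returned by [read_pairs()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  out <- data.frame(pair_ID = pairs$pair_id, sentence_A = pairs$sentence_a,
                    sentence_B = pairs$sentence_b,
                    relatedness_score = pairs$relatedness,
                    entailment_judgment = pairs$entailment,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read class-labelled sentences (2-column TSV: text<TAB>class)
#'
#' Classes must come from the closed rhetorical-type set Background /
#' Intervention / Outcome / Population / StudyDesign; the residual "Other"
#' type is rejected.
#'
#' @param path file path.
#' @return data frame with columns `text`, `rhetorical_class`.
#' @export
read_labelled_sentences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         quote = "", col.names = c("text", "rhetorical_class"))
  bad <- which(!d$rhetorical_class %in% .piboso_classes)
  if (length(bad)) {
    stop("invalid rhetorical class on line(s): ",
         paste(bad, collapse = ", "), " (allowed: ",
         paste(.piboso_classes, collapse = ", "), ")", call. = FALSE)
  }
  d
}

#' Number of unordered same-class pairs
#' @param n number of sentences.
#' @return `choose(n, 2)`.
#' @export
pair_count <- function(n) choose(n, 2)

#' Build the same-class pair corpus
#'
#' Forms all unordered pairs of the sentences carrying `class` (all
#' `n * (n - 1) / 2` of them) in deterministic order.  With
#' `count_only = TRUE` only the pair count is returned — some classes
#' yield millions of pairs, so materialisation is opt-in.
#'
#' @param sentences data frame from [read_labelled_sentences()], or a
#'   character vector of sentences.
#' @param class rhetorical class to select (ignored for a character
#'   vector).
#' @param count_only return the count without materialising.
#' @return a pair data frame (`pair_id`, `sentence_a`, `sentence_b`,
#'   `relatedness = NA`, `entailment = NA`), or a count.
#' @export
build_pair_corpus <- function(sentences, class = NULL, count_only = FALSE) {
  texts <- if (is.data.frame(sentences)) {
    if (is.null(class)) stop("`class` is required for labelled input", call. = FALSE)
    if (!class %in% .piboso_classes) {
      stop("unknown rhetorical class: ", class, call. = FALSE)
    }
    sentences$text[sentences$rhetorical_class == class]
  } else as.character(sentences)
  n <- length(texts)
  if (n < 2L) stop("need at least 2 sentences of the class", call. = FALSE)
  if (count_only) return(pair_count(n))
  idx <- utils::combn(n, 2)
  data.frame(
    pair_id = paste0("p", seq_len(ncol(idx))),
    sentence_a = texts[idx[1, ]], sentence_b = texts[idx[2, ]],
    relatedness = NA_real_, entailment = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Sample pairs without replacement
#' @param pairs pair data frame.
#' @param k sample size (`k <= nrow(pairs)`).
#' @param seed integer seed; the sample is a pure function of
#'   (pairs, k, seed).
#' @return pair data frame with `k` rows.
#' @export
sample_pairs <- function(pairs, k, seed = 1L) {
  if (k > nrow(pairs)) stop("k exceeds the number of pairs", call. = FALSE)
  with_seed(derive_seed(seed, "sample-pairs"), {
    pairs[sort(sample.int(nrow(pairs), k)), , drop = FALSE]
  })
}

#' Generate a synthetic scored pair corpus
#'
#' Builds sentence pairs from the mini-lexicon vocabulary with a
#' controlled shared-content fraction rho per pair and a gold score that
#' is a noisy monotone function of the overlap:
#' `clip(1 + 4 * rho + eps, 1, 5)` with `eps ~ Normal(0, noise_sd)`.
#' Each sentence is a simple copula clause ("the w1 ... were w5 ...") over
#' `length` content tokens, so the full preprocessing pipeline applies;
#' the second sentence repeats `round(rho * length)` of the first
#' sentence's content tokens and draws the rest fresh.
#'
#' @param n number of pairs.
#' @param overlap_grid candidate rho values (default `seq(0, 1, 0.1)`).
#' @param noise_sd standard deviation of the score noise (default 0.5).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param length content tokens per sentence (default 10: a multiple of the
#'   default grid resolution, so `round(rho * length) / length` realises
#'   every grid value of rho exactly and the overlap control is faithful).
#' @param vocab content vocabulary (default: the mini-lexicon terms).
#' @return pair data frame with columns `pair_id`, `sentence_a`,
#'   `sentence_b`, `relatedness`, `entailment` (`NA`) and `rho`.
#' @export
generate_synthetic_pairs <- function(n, overlap_grid = seq(0, 1, by = 0.1),
                                     noise_sd = 0.5, seed = 1L,
                                     length = 10L, vocab = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(vocab)) {
    vocab <- rownames(build_mini_lexicon(1L)$dist$vectors)
  }
  make_sentence <- function(words) {
    half <- ceiling(base::length(words) / 2)
    paste("the", paste(words[seq_len(half)], collapse = " "), "were",
          paste(words[-seq_len(half)], collapse = " "))
  }
  with_seed(derive_seed(seed, "synthetic-pairs"), {
    rho <- sample(overlap_grid, n, replace = TRUE)
    rows <- lapply(seq_len(n), function(i) {
      wa <- sample(vocab, length)
      n_shared <- round(rho[i] * length)
      shared <- if (n_shared > 0) wa[seq_len(n_shared)] else character(0)
      fresh <- sample(setdiff(vocab, wa), length - n_shared)
      wb <- sample(c(shared, fresh))
      score <- clip(1 + 4 * rho[i] + stats::rnorm(1, 0, noise_sd), 1, 5)
      data.frame(pair_id = paste0("syn", i),
                 sentence_a = make_sentence(wa), sentence_b = make_sentence(wb),
                 relatedness = score, entailment = NA_character_,
                 rho = rho[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
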