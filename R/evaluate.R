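# Evaluation protocol: Pearson correlation, MSE, error-bin distribution,
# score-range split, and annotator-agreement statistics.

#' Pearson product-moment correlation
#' @param pred,gold equal-length numeric vectors (length >= 2, neither
#'   constant).
#' @return correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(pred, gold) {
  if (length(pred) != length(gold)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(gold) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(pred, gold)
}

#' Mean squared error
#' @param pred,gold equal-length numeric vectors.
#' @return non-negative mean squared deviation.
#' @export
mean_squared_error <- function(pred, gold) {
  if (length(pred) != length(gold)) stop("length mismatch", call. = FALSE)
  mean((pred - gold)^2)
}

#' Prediction-error distribution over half-unit bins
#'
#' Bins the deviations `pred - gold` into the ten intervals
#' `[-2.5, -2], (-2, -1.5], ..., (2, 2.5]` (so a deviation of exactly 0
#' falls in `(-0.5, 0]`).  Deviations outside \[-2.5, 2.5\] are counted in
#' flagged underflow/overflow bins with a warning.
#'
#' @param pred,gold equal-length numeric vectors.
#' @return data frame with columns `range`, `count`, `percent`; counts sum
#'   to `length(pred)`.
#' @export
error_distribution <- function(pred, gold) {
  if (length(pred) != length(gold)) stop("length mismatch", call. = FALSE)
  dev <- pred - gold
  edges <- seq(-2.5, 2.5, by = 0.5)
  labels <- c("[-2.5,-2]", paste0("(", utils::head(edges[-1], -1), ",",
                                  edges[-(1:2)], "]"))
  inside <- dev >= -2.5 & dev <= 2.5
  counts <- table(cut(dev[inside], breaks = edges, include.lowest = TRUE,
                      right = TRUE))
  out <- data.frame(range = labels, count = as.integer(counts))
  n_under <- sum(dev < -2.5); n_over <- sum(dev > 2.5)
  if (n_under + n_over > 0L) {
    warning(n_under + n_over, " deviation(s) outside [-2.5, 2.5]")
    out <- rbind(data.frame(range = "<-2.5", count = n_under), out,
                 data.frame(range = ">2.5", count = n_over))
  }
  out$percent <- 100 * out$count / length(dev)
  out
}

#' Evaluation split by gold-score range
#'
#' Splits the pairs into the score ranges `[1,2), [2,3), [3,4), [4,5]` and
#' reports per range: pair count, Pearson correlation (`NA` with a flag
#' when gold is constant within the range), the number of underestimated
#' (`pred < gold`) and overestimated (`pred >= gold`) pairs, and the lowest
#' and highest deviation.
#'
#' @param pred,gold equal-length numeric vectors; gold in \[1, 5\].
#' @return data frame with one row per range.
#' @export
range_split_analysis <- function(pred, gold) {
  if (length(pred) != length(gold)) stop("length mismatch", call. = FALSE)
  if (any(gold < 1 | gold > 5)) stop("gold scores must lie in [1, 5]", call. = FALSE)
  ranges <- list("[1,2)" = c(1, 2), "[2,3)" = c(2, 3),
                 "[3,4)" = c(3, 4), "[4,5]" = c(4, 5))
  rows <- lapply(names(ranges), function(rn) {
    r <- ranges[[rn]]
    inr <- if (rn == "[4,5]") gold >= r[1] & gold <= r[2] else gold >= r[1] & gold < r[2]
    p <- pred[inr]; g <- gold[inr]
    dev <- p - g
    data.frame(
      range = rn, count = sum(inr),
      pearson = if (sum(inr) >= 2L && stats::sd(g) > 0 && stats::sd(p) > 0) {
        stats::cor(p, g)
      } else NA_real_,
      n_under = sum(p < g), n_over = sum(p >= g),
      min_dev = if (length(dev)) min(dev) else NA_real_,
      max_dev = if (length(dev)) max(dev) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Annotator agreement statistics
#'
#' From a matrix of ratings (annotators in rows, items in columns) computes
#' the pairwise Pearson matrix (diagonal empty), each annotator's mean
#' off-diagonal agreement, the overall mean, and the inverse agreement:
#' the mean over items of the per-item standard deviation of ratings.
#'
#' @param scores numeric matrix, annotators x items (>= 2 each).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return list with `pairwise` (matrix), `per_annotator`, `average`,
#'   `inverse_agreement`.
#' @export
annotator_agreement <- function(scores, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  scores <- as.matrix(scores)
  na <- nrow(scores)
  if (na < 2L || ncol(scores) < 2L) {
    stop("need at least 2 annotators and 2 items", call. = FALSE)
  }
  pw <- matrix(NA_real_, na, na,
               dimnames = list(rownames(scores), rownames(scores)))
  for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
    v <- if (stats::sd(scores[i, ]) == 0 || stats::sd(scores[j, ]) == 0) {
      warning("constant annotator; agreement undefined for a pair")
      NA_real_
    } else stats::cor(scores[i, ], scores[j, ])
    pw[i, j] <- v; pw[j, i] <- v
  }
  per <- rowMeans(pw, na.rm = TRUE)
  upper <- pw[upper.tri(pw)]
  sds <- apply(scores, 2L, function(x) {
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((na - 1) / na) else s
  })
  list(pairwise = pw, per_annotator = per,
       average = mean(upper, na.rm = TRUE),
       inverse_agreement = mean(sds))
}

#' Full evaluation report
#'
#' @param pred,gold equal-length numeric vectors; gold in \[1, 5\].
#' @return object of class `evaluation_report`: list with `pearson`,
#'   `mse`, `error_bins`, `range_split`, `n`.
#' @export
evaluation_report <- function(pred, gold) {
  structure(list(
    n = length(pred),
    pearson = pearson_correlation(pred, gold),
    mse = mean_squared_error(pred, gold),
    error_bins = error_distribution(pred, gold),
    range_split = range_split_analysis(pred, gold)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d  Pearson = %.4f  MSE = %.4f\n",
              x$n, x$pearson, x$mse))
  cat("\nError distribution:\n")
  print(x$error_bins, row.names = FALSE)
  cat("\nScore-range split:\n")
  print(x$range_split, row.names = FALSE)
  invisible(x)
}
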