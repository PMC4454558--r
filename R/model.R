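# The relatedness regression ensemble: bagged reduced-error-style
# regression trees, a random-subspace distance-weighted kNN regressor
# (instance-based member), and regression by discretisation over a
# 150-tree random-forest classifier on 10 equal-width score bins.
# The ensemble prediction is the arithmetic mean of the three, clipped
# to [1, 5].

#' Default ensemble configuration
#'
#' @param bags bootstrap replicates for the bagged trees (default 50).
#' @param min_leaf minimum observations per tree leaf (default 2, the
#'   usual minimum-instances setting for small regression trees; trees are
#'   grown deep and then pruned back by cross-validated error).
#' @param subspaces random feature subspaces for the instance-based member
#'   (default 30).
#' @param subspace_frac fraction of features per subspace (default 0.5).
#' @param k neighbours for the distance-weighted kNN (default 10).
#' @param ntree classification trees for regression by discretisation
#'   (default 150).
#' @param bins equal-width score bins over \[1, 5\] (default 10).
#' @param folds cross-validation folds (default 10, stratified by bin).
#' @return named list of hyperparameters.
#' @export
ensemble_config <- function(bags = 50L, min_leaf = 2L, subspaces = 30L,
                            subspace_frac = 0.5, k = 10L, ntree = 150L,
                            bins = 10L, folds = 10L) {
  list(bags = bags, min_leaf = min_leaf, subspaces = subspaces,
       subspace_frac = subspace_frac, k = k, ntree = ntree, bins = bins,
       folds = folds)
}

.check_X <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) != 34L) {
    stop("feature matrix must have exactly 34 columns, got ", ncol(X),
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- feature_registry()
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  X
}

.score_bins <- function(y, bins) {
  edges <- seq(1, 5, length.out = bins + 1L)
  cut(y, breaks = edges, include.lowest = TRUE, right = TRUE)
}

#' Train the relatedness ensemble
#'
#' Fits the three sub-models on an n x 34 feature matrix and gold scores in
#' \[1, 5\].  The discretised member bins the scores into `config$bins`
#' equal-width intervals, fits a random-forest classifier, and predicts the
#' probability-weighted mean training score of each bin.  Training is a
#' pure function of (X, y, config, seed).
#'
#' @param X n x 34 numeric matrix (columns in registry order).
#' @param y gold scores in \[1, 5\], length n >= 10, not constant.
#' @param config list from [ensemble_config()].
#' @param seed integer seed.
#' @return object of class `relatedness_model`.
#' @export
train_relatedness_model <- function(X, y, config = ensemble_config(),
                                    seed = 1L) {
  X <- .check_X(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(y) < 10L) stop("need at least 10 training pairs", call. = FALSE)
  if (any(y < 1 | y > 5)) stop("scores must lie in [1, 5]", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant target: cannot fit a regressor", call. = FALSE)
  df <- data.frame(X, y = y, check.names = FALSE)
  n <- nrow(X)
  with_seed(derive_seed(seed, "train"), {
    # (a) bagging over small pruned regression trees
    trees <- lapply(seq_len(config$bags), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                          method = "anova",
                          control = rpart::rpart.control(
                            minbucket = config$min_leaf, cp = 1e-4, xval = 5))
      # reduced-error-style pruning: cut back to the smallest subtree within
      # one standard error of the cross-validated error minimum
      ct <- fit$cptable
      k <- which.min(ct[, "xerror"])
      thr <- ct[k, "xerror"] + ct[k, "xstd"]
      rpart::prune(fit, cp = ct[which(ct[, "xerror"] <= thr)[1], "CP"])
    })
    # (b) random-subspace distance-weighted kNN (instance-based member)
    p <- ncol(X)
    m <- max(2L, round(config$subspace_frac * p))
    subspaces <- lapply(seq_len(config$subspaces), function(s) {
      sort(sample.int(p, m))
    })
    # (c) regression by discretisation: RF classifier over score bins
    ybin <- droplevels(.score_bins(y, config$bins))
    bin_means <- tapply(y, ybin, mean)
    rf <- randomForest::randomForest(
      x = X, y = ybin, ntree = config$ntree)
    structure(list(
      trees = trees, train_X = X, train_y = y, subspaces = subspaces,
      rf = rf, bin_means = bin_means, config = config, seed = seed,
      registry = feature_registry()
    ), class = "relatedness_model")
  })
}

.predict_bagging <- function(model, X) {
  df <- data.frame(X, check.names = FALSE)
  preds <- vapply(model$trees, function(tr) {
    unname(stats::predict(tr, newdata = df))
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
}

.predict_subspace_knn <- function(model, X) {
  k <- model$config$k
  trX <- model$train_X; try_ <- model$train_y
  preds <- vapply(model$subspaces, function(cols) {
    A <- X[, cols, drop = FALSE]
    B <- trX[, cols, drop = FALSE]
    # squared Euclidean distances test x train
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    apply(d2, 1L, function(dr) {
      ord <- order(dr)[seq_len(min(k, length(dr)))]
      w <- 1 / (sqrt(dr[ord]) + 1e-6)
      sum(w * try_[ord]) / sum(w)
    })
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
}

.predict_discretised <- function(model, X) {
  prob <- stats::predict(model$rf, newdata = X, type = "prob")
  means <- model$bin_means[colnames(prob)]
  as.numeric(prob %*% means)
}

#' Predict relatedness scores
#'
#' Arithmetic mean of the three sub-model predictions, clipped to \[1, 5\].
#'
#' @param object a `relatedness_model`.
#' @param X n x 34 feature matrix.
#' @param components also return the per-sub-model predictions.
#' @param ... unused.
#' @return numeric scores in \[1, 5\] (or a data frame when
#'   `components = TRUE`).
#' @export
predict.relatedness_model <- function(object, X, components = FALSE, ...) {
  X <- .check_X(X)
  if (!identical(colnames(X), object$registry)) {
    X <- X[, object$registry, drop = FALSE]
  }
  p1 <- .predict_bagging(object, X)
  p2 <- .predict_subspace_knn(object, X)
  p3 <- .predict_discretised(object, X)
  pred <- clip((p1 + p2 + p3) / 3, 1, 5)
  if (components) {
    return(data.frame(bagging = p1, subspace_knn = p2, discretised = p3,
                      ensemble = pred))
  }
  pred
}

#' @export
print.relatedness_model <- function(x, ...) {
  cat("<relatedness_model> ensemble of", length(x$trees),
      "bagged trees +", length(x$subspaces),
      "kNN subspaces + RF-discretised (", x$config$ntree, "trees,",
      x$config$bins, "bins );", nrow(x$train_X), "training pairs\n")
  invisible(x)
}

#' Word-overlap baseline score
#'
#' Rescales the naive bag-of-words overlap to the \[1, 5\] score range via
#' `1 + 4 * overlap`.
#'
#' @param pair a `sentence_pair`.
#' @return score in \[1, 5\].
#' @export
baseline_score <- function(pair) {
  1 + 4 * bag_overlap(pair$a$tokens, pair$b$tokens)
}

#' Save / load a trained model
#'
#' The archive carries the sub-models, configuration, seed and feature
#' registry version; a reloaded model gives bit-identical predictions.
#' @param model a `relatedness_model`.
#' @param path file path.
#' @return `load_relatedness_model()` returns the model.
#' @export
save_relatedness_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_relatedness_model
#' @export
load_relatedness_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "relatedness_model")) {
    stop("file does not contain a relatedness model", call. = FALSE)
  }
  if (!identical(model$registry, feature_registry())) {
    stop("model was trained with an incompatible feature registry", call. = FALSE)
  }
  model
}

# Stratified CV folds by score bin, seeded.
.make_folds <- function(y, folds, bins, seed) {
  with_seed(derive_seed(seed, "folds"), {
    bin <- .score_bins(y, bins)
    fold <- integer(length(y))
    for (b in levels(bin)) {
      idx <- which(bin == b)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

#' Cross-validated Pearson correlation of the ensemble
#'
#' @param X,y feature matrix and gold scores.
#' @param config list from [ensemble_config()].
#' @param seed integer seed (controls folds and training).
#' @return list with `pearson`, `mse` and the out-of-fold `pred`.
#' @export
cv_ensemble <- function(X, y, config = ensemble_config(), seed = 1L) {
  X <- .check_X(X)
  fold <- .make_folds(y, config$folds, config$bins, seed)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    model <- train_relatedness_model(X[tr, , drop = FALSE], y[tr], config,
                                     seed = derive_seed(seed, paste0("cv", f)))
    pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  list(pearson = pearson_correlation(pred, y), mse = mean_squared_error(pred, y),
       pred = pred)
}

#' Leave-one-group-out and group-only feature ablation
#'
#' For each feature group, reports the cross-validated Pearson correlation
#' of the ensemble trained without the group and trained on the group
#' alone.  Groups must partition the 34 features exactly.
#'
#' @param X,y feature matrix and gold scores.
#' @param groups named list of feature-name vectors (default the 8
#'   registry groups).
#' @param config list from [ensemble_config()].
#' @param seed integer seed.
#' @return data frame with columns `group`, `n_features`, `leave_out`,
#'   `only`.
#' @export
ablation <- function(X, y, groups = feature_groups(),
                     config = ensemble_config(), seed = 1L) {
  X <- .check_X(X)
  all_feats <- unlist(groups, use.names = FALSE)
  if (!setequal(all_feats, feature_registry()) ||
      length(all_feats) != 34L) {
    stop("groups must partition the 34 registered features exactly once",
         call. = FALSE)
  }
  if (any(!all_feats %in% colnames(X))) stop("unknown group feature", call. = FALSE)
  # the ensemble requires 34 columns; ablated columns are zeroed so they
  # carry no information while the interface stays fixed
  run <- function(keep) {
    Xm <- X
    Xm[, setdiff(colnames(X), keep)] <- 0
    cv_ensemble(Xm, y, config, seed)$pearson
  }
  res <- lapply(names(groups), function(g) {
    data.frame(group = g, n_features = length(groups[[g]]),
               leave_out = run(setdiff(all_feats, groups[[g]])),
               only = run(groups[[g]]))
  })
  do.call(rbind, res)
}
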