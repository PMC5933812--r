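#' Train the extremely-randomized-trees window classifier
#'
#' Fits a probability forest of extremely randomized trees (random split
#' thresholds; `ranger` with `splitrule = "extratrees"`) on a table of
#' 31-statistic feature vectors. By default a cross-validated grid search
#' over the number of split-candidate features (`mtry`) and the minimum
#' node size is run first; the final ensemble has `num_trees` trees
#' (default 100).
#'
#' @param features data.frame or matrix with the canonical 31 feature
#'   columns ([feature_names()]).
#' @param labels factor or character vector of class labels (3 classes for
#'   the directional classifier, 2 for binary ROC work).
#' @param seed integer seed; with `num.threads = 1` training is fully
#'   reproducible.
#' @param num_trees ensemble size (default 100).
#' @param tune run the cross-validated grid search (default `TRUE`).
#' @param folds cross-validation folds for the grid search.
#' @param cutoff posterior cutoff on the no-introgression class stored with
#'   the model (default 0.05; see [calibrate_cutoff()]).
#' @param null_class label of the no-introgression class (default
#'   `"noMig"`).
#' @return an object of class `introscan_model`.
#' @export
train_classifier <- function(features, labels, seed, num_trees = 100L,
                             tune = TRUE, folds = 5L, cutoff = 0.05,
                             null_class = "noMig") {
  df <- as.data.frame(features)[, feature_names(), drop = FALSE]
  if (ncol(df) != 31L) stop("expected the 31 canonical features")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes in labels")
  if (any(table(y) == 0L)) stop("a class is missing from labels")
  p <- ncol(df)
  grid <- expand.grid(mtry = unique(c(1L, floor(sqrt(p)), floor(p / 2), p)),
                      min_node = c(1L, 10L))
  tuning <- NULL
  best <- list(mtry = floor(sqrt(p)), min_node = 1L)
  if (tune) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(derive_seed(seed, 3L))
    fold_id <- sample(rep_len(seq_len(folds), nrow(df)))
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      hits <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- ranger::ranger(
          x = df[tr, , drop = FALSE], y = y[tr],
          num.trees = num_trees, mtry = grid$mtry[g],
          min.node.size = grid$min_node[g], splitrule = "extratrees",
          num.random.splits = 1L, num.threads = 1L,
          seed = derive_seed(seed, g * 100L + f))
        pred <- stats::predict(fit, data = df[!tr, , drop = FALSE],
                               num.threads = 1L)$predictions
        hits <- hits + sum(pred == y[!tr])
      }
      acc[g] <- hits / nrow(df)
    }
    best <- grid[which.max(acc), ]
    names(best) <- c("mtry", "min_node")
    tuning <- cbind(grid, accuracy = acc)
  }
  fit <- ranger::ranger(
    x = df, y = y, probability = TRUE, num.trees = num_trees,
    mtry = best$mtry, min.node.size = best$min_node,
    splitrule = "extratrees", num.random.splits = 1L, num.threads = 1L,
    seed = derive_seed(seed, 1L))
  structure(list(fit = fit, feature_order = feature_names(),
                 classes = levels(y), null_class = null_class,
                 cutoff = cutoff, num_trees = num_trees, seed = seed,
                 tuning = tuning, best = best),
            class = "introscan_model")
}

#' @export
print.introscan_model <- function(x, ...) {
  cat(sprintf(
    "introscan_model: %d extremely randomized trees, classes [%s], cutoff %g\n",
    x$num_trees, paste(x$classes, collapse = ", "), x$cutoff))
  if (!is.null(x$best)) {
    cat(sprintf("  tuned: mtry = %d, min.node.size = %d\n",
                x$best$mtry, x$best$min_node))
  }
  invisible(x)
}

#' Posterior class probabilities and introgression calls
#'
#' A window is called introgressed when the posterior probability of the
#' no-introgression class falls below the cutoff; the direction is the
#' larger of the two introgression posteriors (ties broken toward the first
#' introgression class, deterministically).
#'
#' @param object an `introscan_model`.
#' @param features data.frame with the canonical 31 feature columns.
#' @param cutoff posterior cutoff overriding the model's stored one.
#' @param ... unused.
#' @return data.frame with one posterior column per class, `p_intro`
#'   (1 minus the no-introgression posterior), `call` (logical), and
#'   `direction` (class label or `NA`).
#' @export
predict.introscan_model <- function(object, features, cutoff = NULL, ...) {
  df <- as.data.frame(features)
  if (!all(object$feature_order %in% colnames(df))) {
    stop("feature columns do not match the model's canonical order")
  }
  df <- df[, object$feature_order, drop = FALSE]
  cutoff <- cutoff %||% object$cutoff
  post <- stats::predict(object$fit, data = df,
                         num.threads = 1L)$predictions
  post <- post[, object$classes, drop = FALSE]
  p_no <- post[, object$null_class]
  intro_classes <- setdiff(object$classes, object$null_class)
  call <- p_no < cutoff
  direction <- rep(NA_character_, nrow(df))
  if (length(intro_classes) >= 2L) {
    sub <- post[, intro_classes, drop = FALSE]
    dir_idx <- max.col(sub, ties.method = "first")
    direction[call] <- intro_classes[dir_idx[call]]
  } else if (length(intro_classes) == 1L) {
    direction[call] <- intro_classes
  }
  out <- data.frame(post, check.names = FALSE)
  out$p_intro <- 1 - p_no
  out$call <- call
  out$direction <- direction
  out
}

#' Gini feature importances from a 500-tree ensemble
#'
#' Trains an extremely randomized forest (default 500 trees, library
#' defaults otherwise) and returns impurity-based importances normalized to
#' sum to one, with the features ranked by descending score.
#'
#' @inheritParams train_classifier
#' @param num_trees ensemble size (default 500).
#' @return data.frame with columns `feature`, `importance` (sums to 1),
#'   ordered by descending importance.
#' @export
feature_importances <- function(features, labels, seed, num_trees = 500L) {
  df <- as.data.frame(features)[, feature_names(), drop = FALSE]
  y <- factor(labels)
  if (any(table(y) == 0L)) stop("a class is missing from labels")
  fit <- ranger::ranger(
    x = df, y = y, num.trees = num_trees, splitrule = "extratrees",
    num.random.splits = 1L, importance = "impurity", num.threads = 1L,
    seed = derive_seed(seed, 5L))
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out[order(-out$importance), , drop = FALSE]
}

#' Choose a posterior cutoff achieving a target false positive rate
#'
#' Given posteriors of the no-introgression class on a simulated null set
#' (no migration), returns the largest cutoff whose empirical false
#' positive rate (fraction of null windows with `P(no introgression) <
#' cutoff`) does not exceed the target.
#'
#' @param model an `introscan_model`.
#' @param null_features feature table of no-migration simulations.
#' @param target_fpr desired false positive rate in `[0, 1]`.
#' @return the cutoff (numeric scalar).
#' @export
calibrate_cutoff <- function(model, null_features, target_fpr) {
  if (NROW(null_features) == 0L) stop("empty null set")
  post <- stats::predict(model$fit,
                         data = as.data.frame(null_features)[
                           , model$feature_order, drop = FALSE],
                         num.threads = 1L)$predictions
  p_no <- post[, model$null_class]
  cand <- sort(unique(c(0, p_no, 1)))
  fpr <- vapply(cand, function(ct) mean(p_no < ct), numeric(1))
  max(cand[fpr <= target_fpr])
}
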