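# Feature selection: SVM recursive feature elimination with stratified
# cross-validation scored by support-weighted F1, and permutation feature
# importance. Elimination is driven by linear-SVM weights (squared weights
# summed over one-vs-rest class fits); the cross-validation curve decides
# the retained feature count.

# Stratified fold assignment: shuffles within each class (seeded) and
# deals fold ids round-robin, so every fold holds every class whenever a
# class has at least `k` members.
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  if (any(table(y) < k)) {
    stop_foldear(paste0(
      "a class has fewer members than folds; a fold would miss it - ",
      "reduce folds or change the split seed"), "foldear_bad_folds")
  }
  folds <- integer(length(y))
  for (ci in seq_along(sort(unique(y)))) {
    cl <- sort(unique(y))[ci]
    idx <- which(y == cl)
    idx <- with_seed(child_seed(seed, ci), sample(idx))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_svm <- function(X, y, kernel = "linear", cost = 1, gamma = NULL) {
  e1071::svm(x = X, y = factor(y), kernel = kernel, cost = cost,
             gamma = gamma %||% (1 / ncol(X)), scale = FALSE)
}

cv_weighted_f1 <- function(X, y, folds, kernel = "linear", cost = 1,
                           gamma = NULL) {
  scores <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    m <- fit_svm(X[tr, , drop = FALSE], y[tr], kernel, cost, gamma)
    weighted_f1(predict(m, X[!tr, , drop = FALSE]), y[!tr],
                classes = sort(unique(as.character(y))))
  }, numeric(1))
  mean(scores)
}

# Feature importance for elimination: for each class fit a binary linear
# SVM (class vs rest), recover its weight vector w = t(coefs) %*% SV, and
# sum squared weights over classes.
ovr_weight_importance <- function(X, y, cost = 1) {
  classes <- sort(unique(as.character(y)))
  imp <- numeric(ncol(X))
  for (cl in classes) {
    yb <- factor(as.character(y) == cl, levels = c("FALSE", "TRUE"))
    m <- e1071::svm(x = X, y = yb, kernel = "linear", cost = cost,
                    scale = FALSE)
    w <- as.numeric(t(m$coefs) %*% m$SV)
    imp <- imp + w^2
  }
  imp
}

#' SVM recursive feature elimination with cross-validation
#'
#' Starting from all features, one feature is eliminated per step (the one
#' with the smallest squared linear-SVM weight summed over one-vs-rest
#' class fits). At every surviving feature count, the mean support-weighted
#' F1 over stratified `folds`-fold cross-validation with a linear SVM is
#' recorded; the retained subset is the one at the count maximizing the
#' curve, ties going to the smallest count.
#'
#' @param X Standardized numeric matrix (`n x p`), column names used as
#'   feature identifiers.
#' @param y Class labels, length `n`.
#' @param folds Cross-validation folds (default 5); `n >= folds` required.
#' @param seed Seed controlling fold assignment.
#' @param cost Linear-SVM penalty used throughout (default 1).
#' @return A `"selection_result"`: `selected_names` (input order),
#'   `cv_curve` (named by feature count, mean CV F1 on the 0-1 scale),
#'   `best_count`, `ranking` (feature names in elimination order: first
#'   eliminated first, the longest survivor last), `seed`.
#' @export
svm_rfecv <- function(X, y, folds = 5L, seed = 1L, cost = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= folds, ncol(X) >= 1L)
  fold_id <- stratified_folds(y, folds, seed)
  surviving <- colnames(X)
  elim <- character(0)
  cv_curve <- numeric(ncol(X))
  names(cv_curve) <- seq_len(ncol(X))
  repeat {
    Xs <- X[, surviving, drop = FALSE]
    cv_curve[[as.character(length(surviving))]] <-
      cv_weighted_f1(Xs, y, fold_id, cost = cost)
    if (length(surviving) == 1L) break
    imp <- ovr_weight_importance(Xs, y, cost = cost)
    drop_i <- which.min(imp)
    elim <- c(elim, surviving[drop_i])
    surviving <- surviving[-drop_i]
  }
  ranking <- c(elim, surviving)
  counts <- as.integer(names(cv_curve))
  best <- max(cv_curve)
  best_count <- min(counts[cv_curve >= best - 1e-12])
  keep <- ranking[seq(ncol(X) - best_count + 1L, ncol(X))]
  structure(list(
    selected_names = colnames(X)[colnames(X) %in% keep],
    cv_curve = cv_curve[order(counts)],
    best_count = best_count,
    ranking = ranking,
    seed = seed),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "SVM-RFECV: kept %d of %d features (best mean CV F1 = %.4f)\n",
    x$best_count, length(x$ranking), max(x$cv_curve)))
  cat("  ", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of feature `j` is the mean drop in support-weighted F1 when
#' column `j` is randomly permuted, over `repeats` seeded permutations.
#'
#' @param model A fitted classifier accepted by [stats::predict()]
#'   (e.g. an `e1071::svm` fit).
#' @param X,y Evaluation data.
#' @param repeats Number of permutation repeats (>= 1).
#' @param seed Seed; the same seed reproduces the report exactly.
#' @return An `"importance_report"`: data frame `importance` with columns
#'   `feature`, `mean_drop`, `sd_drop`, plus `baseline_f1`, `repeats`,
#'   `seed`.
#' @export
permutation_importance <- function(model, X, y, repeats = 10L, seed = 1L) {
  if (!is_count(repeats)) {
    stop_foldear("repeats must be a positive integer", "foldear_bad_repeats")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  classes <- sort(unique(as.character(y)))
  baseline <- weighted_f1(predict(model, X), y, classes)
  drops <- matrix(0, repeats, ncol(X))
  for (j in seq_len(ncol(X))) {
    for (r in seq_len(repeats)) {
      Xp <- X
      perm <- with_seed(child_seed(seed, j * 1000L + r),
                        sample.int(nrow(X)))
      Xp[, j] <- X[perm, j]
      drops[r, j] <- baseline - weighted_f1(predict(model, Xp), y, classes)
    }
  }
  structure(list(
    importance = data.frame(feature = colnames(X),
                            mean_drop = colMeans(drops),
                            sd_drop = apply(drops, 2, sd)),
    baseline_f1 = baseline, repeats = as.integer(repeats),
    seed = as.integer(seed)),
    class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("Permutation importance (%d repeats, baseline F1 %.4f)\n",
              x$repeats, x$baseline_f1))
  ord <- order(-x$importance$mean_drop)
  print(utils::head(x$importance[ord, ], 10), row.names = FALSE)
  invisible(x)
}
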