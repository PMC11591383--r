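# Early feature fusion and the end-to-end classification protocol:
# stratified 80/20 split, per-representation CNN training and deep-feature
# taps, acoustic extraction with RFECV on the training split, column-wise
# fusion, a single standardizer fitted on the fused training rows, a
# grid-searched SVM (linear/RBF x C in {0.1, 1, 10}, 5-fold CV, weighted
# F1), and the held-out evaluation report.

#' Concatenate feature blocks (early fusion)
#'
#' Column-wise concatenation of row-aligned blocks in the given order,
#' recording each block's column span.
#'
#' @param blocks Named list of numeric matrices sharing the row count and
#'   row order (row `i` of every block describes the same segment).
#' @return A `"fused_features"`: `values` (`n x D`) and `blocks`
#'   (data frame `name`, `start`, `end`).
#' @export
early_fuse <- function(blocks) {
  if (!length(blocks)) stop_foldear("no blocks to fuse", "foldear_bad_fuse")
  blocks <- lapply(blocks, as.matrix)
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop_foldear("blocks differ in row count", "foldear_bad_fuse")
  }
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  values <- do.call(cbind, unname(blocks))
  structure(list(values = values,
                 blocks = data.frame(name = names(blocks) %||%
                                       paste0("block", seq_along(blocks)),
                                     start = ends - widths + 1L,
                                     end = ends, row.names = NULL)),
            class = "fused_features")
}

#' Stratified train/test split
#'
#' Disjoint stratified split; the held-out fraction is allocated per class
#' by largest remainder so class proportions are within one sample of the
#' target and the total test size is `round(test_fraction * n)`.
#'
#' @param y Class labels; every class needs at least 2 members.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Seed; the same seed reproduces the split.
#' @return List with sorted index vectors `train` and `test`.
#' @export
split_train_test <- function(y, test_fraction = 0.2, seed = 1L) {
  y <- as.character(y)
  if (any(table(y) < 2L)) {
    stop_foldear("every class needs at least 2 members to split",
                 "foldear_bad_split")
  }
  s <- stratified_holdout(y, test_fraction, seed)
  list(train = s$main, test = s$held)
}

svm_default_grid <- function() {
  data.frame(kernel = rep(c("linear", "radial"), each = 3),
             cost = rep(c(0.1, 1, 10), 2), stringsAsFactors = FALSE)
}

#' Grid-searched SVM on a training matrix
#'
#' Evaluates every grid point (default: linear and RBF kernels crossed
#' with C in 0.1, 1, 10) by stratified 5-fold cross-validation scored by
#' support-weighted F1, then refits the best point on the full training
#' matrix. RBF gamma is "auto": the reciprocal of the feature count.
#' Ties resolve to the first grid row (linear kernels, then ascending C).
#'
#' @param X Standardized training matrix (standardizer fitted on the
#'   training split only).
#' @param y Training labels.
#' @param grid Data frame with columns `kernel` (`"linear"`/`"radial"`)
#'   and `cost`; `NULL` skips the search and fits the fixed RBF, C = 1,
#'   gamma = auto setting.
#' @param folds,seed Cross-validation folds and seed.
#' @return A `"svm_grid_fit"`: fitted `model`, chosen `kernel` and
#'   `cost`, `gamma`, and the `cv_table` of mean CV F1 per grid row.
#' @export
grid_search_svm <- function(X, y, grid = svm_default_grid(), folds = 5L,
                            seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  gamma <- 1 / ncol(X)
  if (is.null(grid)) {
    best <- data.frame(kernel = "radial", cost = 1)
    cv_table <- NULL
  } else {
    fold_id <- stratified_folds(y, folds, seed)
    cv_table <- grid
    cv_table$mean_f1 <- vapply(seq_len(nrow(grid)), function(i) {
      cv_weighted_f1(X, y, fold_id, kernel = grid$kernel[i],
                     cost = grid$cost[i], gamma = gamma)
    }, numeric(1))
    best <- grid[which.max(cv_table$mean_f1), ]
  }
  model <- fit_svm(X, y, kernel = best$kernel, cost = best$cost,
                   gamma = gamma)
  structure(list(model = model, kernel = best$kernel, cost = best$cost,
                 gamma = gamma, cv_table = cv_table,
                 seed = as.integer(seed)),
            class = "svm_grid_fit")
}

fusion_block_names <- function() {
  c(paste0(rep(c("MEL", "STFT", "CQT"), each = 2), "_FC",
           rep(1:2, 3)), "ACOUSTIC")
}

parse_recipe <- function(recipe) {
  parts <- toupper(trimws(strsplit(recipe, "+", fixed = TRUE)[[1]]))
  bad <- setdiff(parts, fusion_block_names())
  if (length(bad)) {
    stop_foldear(paste0("unknown fusion block(s): ",
                        paste(bad, collapse = ", "), "; valid: ",
                        paste(fusion_block_names(), collapse = ", ")),
                 "foldear_bad_recipe")
  }
  parts
}

kind_index <- c(stft = 1L, cqt = 2L, mel = 3L)

#' Precompute every feature block of a corpus
#'
#' Runs the shared, recipe-independent part of the pipeline once: the
#' stratified 80/20 split, one SheepVGG-Lite training per requested
#' spectrogram representation (on the training split, internal 25%
#' validation), FC1/FC2 deep-feature taps for all segments, acoustic
#' feature extraction, and SVM-RFECV feature selection on the
#' (train-standardized) training rows. Sub-seeds are derived from `seed`
#' per stage and per representation, so a bank built once and reused
#' across recipes gives exactly the results of running each recipe from
#' scratch with the same seed.
#'
#' @param corpus List of labelled [audio_segment()]s, or a directory path
#'   accepted by [read_corpus()].
#' @param kinds Spectrogram representations to train
#'   (subset of `"stft"`, `"cqt"`, `"mel"`).
#' @param seed Master seed.
#' @param train_cfg A [train_config()]; its `seed` is overridden per
#'   representation.
#' @param test_fraction Held-out fraction of the split.
#' @param include_acoustic Compute the acoustic block and its RFECV
#'   selection.
#' @param rfecv_folds Folds for the acoustic RFECV.
#' @return A `"feature_bank"` used by [run_experiment()] /
#'   [predict.behavior_experiment()].
#' @export
build_feature_bank <- function(corpus, kinds = c("stft", "cqt"), seed = 7L,
                               train_cfg = train_config(),
                               test_fraction = 0.2,
                               include_acoustic = TRUE, rfecv_folds = 5L) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  y <- vapply(corpus, function(s) s$label %||% NA_character_, character(1))
  if (anyNA(y)) stop_foldear("corpus has unlabelled segments",
                             "foldear_bad_labels")
  kinds <- if (length(kinds)) {
    match.arg(kinds, c("stft", "cqt", "mel"), several.ok = TRUE)
  } else character(0)
  split <- split_train_test(y, test_fraction, child_seed(seed, 1))
  cnns <- list()
  deep <- list()
  for (k in kinds) {
    images <- lapply(corpus, spectrogram_image, kind = k)
    cfg <- train_cfg
    cfg$seed <- child_seed(seed, 10L + kind_index[[k]])
    cnn <- train_sheepvgg(sheepvgg_lite(seed = cfg$seed), images[split$train],
                          y[split$train], cfg)
    X <- images_to_matrix(images)
    fwd <- svgg_forward(cnn$params, X)
    cnns[[k]] <- cnn
    deep[[paste0(toupper(k), "_FC1")]] <- fwd$fc1
    deep[[paste0(toupper(k), "_FC2")]] <- fwd$logits
  }
  acoustic <- NULL
  selection <- NULL
  acoustic_standardizer <- NULL
  if (include_acoustic) {
    acoustic <- acoustic_feature_matrix(corpus)
    acoustic_standardizer <- fit_standardizer(acoustic[split$train, ,
                                                       drop = FALSE])
    selection <- svm_rfecv(
      apply_standardizer(acoustic_standardizer,
                         acoustic[split$train, , drop = FALSE]),
      y[split$train], folds = rfecv_folds, seed = child_seed(seed, 3))
  }
  structure(list(labels = y, split = split, kinds = kinds, cnns = cnns,
                 deep = deep, acoustic = acoustic, selection = selection,
                 acoustic_standardizer = acoustic_standardizer,
                 seed = as.integer(seed), train_cfg = train_cfg,
                 test_fraction = test_fraction),
            class = "feature_bank")
}

bank_blocks <- function(bank, parts) {
  blocks <- list()
  for (p in parts) {
    if (p == "ACOUSTIC") {
      if (is.null(bank$acoustic)) {
        stop_foldear("feature bank was built without the acoustic block",
                     "foldear_bad_recipe")
      }
      blocks[[p]] <- bank$acoustic[, bank$selection$selected_names,
                                   drop = FALSE]
    } else {
      if (is.null(bank$deep[[p]])) {
        stop_foldear(paste0("recipe needs untrained representation: ", p),
                     "foldear_bad_recipe")
      }
      blocks[[p]] <- bank$deep[[p]]
    }
  }
  blocks
}

#' Run a fusion classification experiment
#'
#' Executes the full pipeline for one fusion recipe (e.g.
#' `"CQT_FC1+STFT_FC1+ACOUSTIC"`): spectrogram rendering, CNN training
#' per representation, deep-feature extraction, acoustic extraction with
#' RFECV, early fusion, joint standardization fitted on the fused
#' training rows, grid-searched SVM, and evaluation on the held-out 20%.
#' All randomness is derived from `seed`, so identical inputs and seed
#' reproduce the report exactly.
#'
#' @param corpus List of labelled [audio_segment()]s or a corpus
#'   directory; ignored when `bank` is given.
#' @param recipe Fusion recipe: block names from
#'   `MEL_FC1, MEL_FC2, STFT_FC1, STFT_FC2, CQT_FC1, CQT_FC2, ACOUSTIC`
#'   joined by `+`.
#' @param seed Master seed.
#' @param bank Optional precomputed [build_feature_bank()] (trains each
#'   CNN once when several recipes are evaluated).
#' @param grid_search Use the kernel/C grid search (default); `FALSE`
#'   fits the fixed RBF, C = 1, gamma = "auto" setting.
#' @param train_cfg,test_fraction Passed to [build_feature_bank()] when
#'   no bank is given.
#' @return A `"behavior_experiment"` with the held-out
#'   `report` ([evaluate()]), the fitted `svm`, `bank`, `blocks` spans,
#'   `recipe` and `seed`.
#' @export
run_experiment <- function(corpus, recipe, seed = 7L, bank = NULL,
                           grid_search = TRUE, train_cfg = train_config(),
                           test_fraction = 0.2) {
  parts <- parse_recipe(recipe)
  if (is.null(bank)) {
    need_kinds <- tolower(unique(sub("_FC[12]$", "", setdiff(parts,
                                                             "ACOUSTIC"))))
    bank <- build_feature_bank(corpus, kinds = need_kinds, seed = seed,
                               train_cfg = train_cfg,
                               test_fraction = test_fraction,
                               include_acoustic = "ACOUSTIC" %in% parts)
  }
  fused <- early_fuse(bank_blocks(bank, parts))
  tr <- bank$split$train
  te <- bank$split$test
  std <- fit_standardizer(fused$values[tr, , drop = FALSE])
  Xtr <- apply_standardizer(std, fused$values[tr, , drop = FALSE])
  Xte <- apply_standardizer(std, fused$values[te, , drop = FALSE])
  fit <- grid_search_svm(Xtr, bank$labels[tr],
                         grid = if (grid_search) svm_default_grid() else NULL,
                         seed = child_seed(bank$seed, 2))
  pred <- as.character(predict(fit$model, Xte))
  report <- evaluate(pred, bank$labels[te],
                     classes = sort(unique(bank$labels)))
  structure(list(recipe = paste(parts, collapse = "+"), report = report,
                 svm = fit, standardizer = std, blocks = fused$blocks,
                 bank = bank, predictions = pred,
                 test_labels = bank$labels[te], seed = as.integer(seed)),
            class = "behavior_experiment")
}

#' @export
print.behavior_experiment <- function(x, ...) {
  cat(sprintf("Fusion experiment: %s (SVM %s, C = %g)\n", x$recipe,
              x$svm$kernel, x$svm$cost))
  cat(sprintf("  held-out: accuracy %.2f%%  recall %.2f%%  precision %.2f%%  F1 %.2f%%\n",
              x$report$accuracy, x$report$recall, x$report$precision,
              x$report$f1))
  invisible(x)
}

#' @export
summary.behavior_experiment <- function(object, ...) {
  print(object)
  cat("\nBlocks:\n")
  print(object$blocks, row.names = FALSE)
  if (!is.null(object$svm$cv_table)) {
    cat("\nGrid search (mean CV weighted F1):\n")
    print(object$svm$cv_table, row.names = FALSE)
  }
  cat("\n")
  print(object$report)
  invisible(object)
}

#' Predict behavior for new audio segments
#'
#' Pushes new segments through the experiment's frozen pipeline: the
#' stored CNNs, acoustic selection, fusion order and standardizer, then
#' the fitted SVM.
#'
#' @param object A `"behavior_experiment"`.
#' @param newdata List of [audio_segment()]s.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.behavior_experiment <- function(object, newdata, ...) {
  if (inherits(newdata, "audio_segment")) newdata <- list(newdata)
  parts <- parse_recipe(object$recipe)
  bank <- object$bank
  blocks <- list()
  for (p in parts) {
    if (p == "ACOUSTIC") {
      A <- acoustic_feature_matrix(newdata)
      blocks[[p]] <- A[, bank$selection$selected_names, drop = FALSE]
    } else {
      k <- tolower(sub("_FC[12]$", "", p))
      images <- lapply(newdata, spectrogram_image, kind = k)
      blocks[[p]] <- extract_deep_features(bank$cnns[[k]], images,
                                           sub("^.*_(FC[12])$", "\\1", p))
    }
  }
  fused <- early_fuse(blocks)
  X <- apply_standardizer(object$standardizer, fused$values)
  as.character(predict(object$svm$model, X))
}

#' Experiment report as reproducible JSON
#'
#' @param x A `"behavior_experiment"`.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
experiment_report_json <- function(x, path = NULL) {
  rep <- x$report
  out <- list(
    recipe = x$recipe, seed = x$seed,
    svm = list(kernel = x$svm$kernel, cost = x$svm$cost,
               gamma = x$svm$gamma),
    class_order = rep$classes,
    metrics = list(accuracy = rep$accuracy, recall = rep$recall,
                   precision = rep$precision, f1 = rep$f1),
    per_class = rep$per_class,
    confusion = rep$confusion,
    blocks = x$blocks)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10,
                           matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
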