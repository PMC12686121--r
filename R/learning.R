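#' Build a balanced, split labelled dataset
#'
#' Negatives are randomly subsampled to match the positive count, then each
#' class is split 80/20 into train and test (stratified), reproducibly under
#' the seed.
#'
#' @param pos character vector of positive (ZGA) gene ids.
#' @param neg_pool character vector of candidate negative (non-ZGA) ids; must
#'   be at least as large as `pos`.
#' @param seed integer seed.
#' @param train_frac training fraction (default 0.8).
#' @return a `labeled_dataset` skeleton: list with `genes`, `y` (named 0/1),
#'   `split` (named `"train"`/`"test"`), `seed`.
#' @export
balance_and_split <- function(pos, neg_pool, seed = 1, train_frac = 0.8) {
  pos <- unique(as.character(pos))
  neg_pool <- setdiff(unique(as.character(neg_pool)), pos)
  if (length(neg_pool) < length(pos)) {
    stop_zgakit("not enough negatives to balance the positive set",
                "zgakit_data_error")
  }
  with_seed(seed, {
    neg <- sample(neg_pool, length(pos))
    take_train <- function(ids) sample(ids, round(train_frac * length(ids)))
    tr <- c(take_train(pos), take_train(neg))
    genes <- c(pos, neg)
    y <- setNames(c(rep(1L, length(pos)), rep(0L, length(neg))), genes)
    split <- setNames(ifelse(genes %in% tr, "train", "test"), genes)
    structure(list(genes = genes, y = y, split = split, seed = seed),
              class = "labeled_dataset")
  })
}

#' Attach a feature matrix to a dataset skeleton
#'
#' @param skeleton output of [balance_and_split()].
#' @param X feature matrix with gene rownames covering `skeleton$genes`.
#' @return a `labeled_dataset` with an `X` field (rows ordered as `genes`).
#' @export
labeled_dataset <- function(skeleton, X) {
  missing <- setdiff(skeleton$genes, rownames(X))
  if (length(missing)) {
    stop_zgakit(sprintf("feature matrix lacks gene(s): %s",
                        paste(head(missing, 5), collapse = ", ")),
                "zgakit_data_error")
  }
  skeleton$X <- X[skeleton$genes, , drop = FALSE]
  skeleton
}

#' Maximal information coefficient against a binary label
#'
#' The MINE statistic with grid bound `B = n^alpha`; with a binary target the
#' label axis contributes exactly two rows, so the normaliser is 1 bit and
#' the statistic reduces to the maximal mutual information over x-axis
#' partitions with at most `B/2` bins, which is computed exactly by dynamic
#' programming over tie-respecting clumps (pre-merged to at most `c * B/2`
#' superclumps).
#'
#' @param x numeric feature column (>= 10 samples).
#' @param y 0/1 labels.
#' @param alpha grid-bound exponent (default 0.6).
#' @param c clump pre-merge factor (default 5).
#' @return MIC score in \[0, 1\]; exactly 0 for a constant column.
#' @export
mic_score <- function(x, y, alpha = 0.6, c = 5) {
  if (length(x) < 10) {
    stop_zgakit("mic_score needs at least 10 samples", "zgakit_data_error")
  }
  if (length(x) != length(y)) {
    stop_zgakit("x and y lengths differ", "zgakit_data_error")
  }
  .mic_binary_cpp(as.numeric(x), as.integer(y), alpha, c)
}

#' Rank features by MIC
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @inheritParams mic_score
#' @return integer vector of column indices, best first (ties keep column
#'   order), with the scores as a `scores` attribute.
#' @export
mic_rank <- function(X, y, alpha = 0.6, c = 5) {
  scores <- vapply(seq_len(ncol(X)), function(j) {
    mic_score(X[, j], y, alpha, c)
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  structure(ord, scores = setNames(scores, colnames(X)))
}

fit_classifier <- function(algorithm, params, X, y, seed = 1) {
  X <- as.matrix(X)
  fit <- switch(algorithm,
    SVM = {
      gamma <- params$gamma %||% "scale"
      if (identical(gamma, "scale")) {
        sx <- mean(apply(X, 2, var)) * ncol(X)
        gamma <- if (sx > 0) 1 / sx else 1 / ncol(X)
      }
      with_seed(seed, e1071::svm(
        x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
        cost = params$cost %||% 1, gamma = gamma, probability = TRUE
      ))
    },
    RF = with_seed(seed, ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees %||% 500,
      max.depth = params$max_depth %||% 0, # 0 = unlimited
      seed = seed, num.threads = 1, keep.inbag = TRUE
    )),
    LR = {
      lambda <- params$lambda %||% (1 / (nrow(X) * (params$C %||% 1)))
      glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = lambda)
    },
    GBM = {
      dtr <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.1,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = params$nrounds %||% 100, verbose = 0
      )
    },
    stop_zgakit(sprintf("unknown algorithm '%s'", algorithm),
                "zgakit_parameter_error")
  )
  list(algorithm = algorithm, fit = fit, features = colnames(X))
}

predict_prob <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  switch(model$algorithm,
    SVM = {
      pr <- attr(predict(model$fit, X, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    RF = unname(predict(model$fit, X,
                        num.threads = 1)$predictions[, "1"]),
    LR = unname(predict(model$fit, X, type = "response")[, 1]),
    GBM = unname(predict(model$fit, xgboost::xgb.DMatrix(X)))
  )
}

cv_accuracy <- function(X, y, algorithm, params, folds = 10, seed = 1) {
  fold_id <- stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) {
      stop_zgakit("degenerate CV fold (single class)", "zgakit_data_error")
    }
    m <- fit_classifier(algorithm, params, X[tr, , drop = FALSE], y[tr],
                        seed = seed + f)
    p <- predict_prob(m, X[!tr, , drop = FALSE])
    mean((p >= 0.5) == (y[!tr] == 1))
  }, numeric(1))
  mean(acc)
}

#' Incremental feature selection over a MIC ranking
#'
#' Evaluates nested prefixes of the ranking (sizes 1..`max_features`) by
#' stratified cross-validated accuracy and returns the prefix with the best
#' mean accuracy, breaking ties toward fewer features.
#'
#' @param X feature matrix (training split only).
#' @param y 0/1 labels.
#' @param ranking column-index ranking, best first; defaults to
#'   [mic_rank()] on `(X, y)`.
#' @param cv_folds folds for the inner CV (default 10).
#' @param max_features largest prefix evaluated (default 20; clipped to
#'   `ncol(X)` with a warning).
#' @param algorithm,params classifier used to score prefixes (default a
#'   100-tree random forest).
#' @param seed integer seed.
#' @return list with `selected` (feature names), `sizes`, `cv_accuracy`.
#' @export
incremental_feature_selection <- function(X, y, ranking = NULL,
                                          cv_folds = 10, max_features = 20,
                                          algorithm = "RF",
                                          params = list(num_trees = 100),
                                          seed = 1) {
  if (is.null(ranking)) ranking <- mic_rank(X, y)
  if (length(ranking) != ncol(X)) {
    stop_zgakit("ranking must cover all feature columns",
                "zgakit_parameter_error")
  }
  if (max_features > ncol(X)) {
    warning("max_features exceeds the number of columns; clipping")
    max_features <- ncol(X)
  }
  sizes <- seq_len(max_features)
  accs <- vapply(sizes, function(s) {
    cv_accuracy(X[, ranking[seq_len(s)], drop = FALSE], y,
                algorithm, params, cv_folds, seed)
  }, numeric(1))
  best <- which.max(accs) # first max = fewest features on ties
  list(
    selected = colnames(X)[ranking[seq_len(sizes[best])]],
    sizes = sizes,
    cv_accuracy = accs
  )
}

#' Default hyperparameter grids
#'
#' Conventional, config-overridable grids for the four supported algorithms;
#' rows are tried in order and ties in CV accuracy keep the earliest row.
#'
#' @param algorithm `"SVM"`, `"RF"`, `"LR"` or `"GBM"`.
#' @return data.frame, one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    RF = expand.grid(num_trees = c(100, 300, 500),
                     max_depth = c(0, 10, 20)),
    SVM = expand.grid(cost = c(0.1, 1, 10),
                      gamma = c("scale", "0.01"),
                      stringsAsFactors = FALSE),
    LR = data.frame(C = c(0.01, 0.1, 1, 10)),
    GBM = expand.grid(nrounds = c(100, 300), eta = c(0.1, 0.05),
                      max_depth = c(3, 6)),
    stop_zgakit(sprintf("unknown algorithm '%s'", algorithm),
                "zgakit_parameter_error")
  )
}

grid_row_params <- function(algorithm, row) {
  p <- as.list(row)
  if (algorithm == "SVM" && !identical(p$gamma, "scale")) {
    p$gamma <- as.numeric(p$gamma)
  }
  p
}

#' Grid-search hyperparameters with stratified 10-fold CV and fit
#'
#' Every grid row is scored by mean cross-validated accuracy on the training
#' split only (the test split is never touched), the best row is refit on the
#' full training split, and the fitted model is returned with its provenance.
#'
#' @param algorithm `"SVM"`, `"RF"`, `"LR"` or `"GBM"`.
#' @param dataset a [labeled_dataset()] with an `X` field (already reduced to
#'   the selected features).
#' @param grid hyperparameter data.frame (default [default_grid()]).
#' @param folds CV folds (default 10).
#' @param seed integer seed.
#' @return a `zga_classifier`: list with `algorithm`, `hyperparameters`,
#'   `selected_features`, `fit`, `cv_accuracy` (per grid row), `seed`,
#'   plus the training matrix and labels (kept for attribution baselines).
#' @export
grid_search_train <- function(algorithm, dataset, grid = NULL, folds = 10,
                              seed = 1) {
  grid <- grid %||% default_grid(algorithm)
  if (!nrow(grid)) stop_zgakit("empty grid", "zgakit_parameter_error")
  tr <- dataset$split == "train"
  Xtr <- dataset$X[tr, , drop = FALSE]
  ytr <- dataset$y[tr]
  accs <- vapply(seq_len(nrow(grid)), function(i) {
    cv_accuracy(Xtr, ytr, algorithm,
                grid_row_params(algorithm, grid[i, , drop = FALSE]),
                folds, seed)
  }, numeric(1))
  best <- which.max(accs)
  params <- grid_row_params(algorithm, grid[best, , drop = FALSE])
  model <- fit_classifier(algorithm, params, Xtr, ytr, seed)
  structure(list(
    algorithm = algorithm,
    hyperparameters = params,
    selected_features = colnames(dataset$X),
    fit = model$fit,
    features = model$features,
    cv_accuracy = accs,
    best_row = best,
    X_train = Xtr,
    y_train = ytr,
    seed = seed
  ), class = "zga_classifier")
}

#' Confusion-count evaluation metrics
#'
#' Sensitivity = TP/(TP+FN), precision = TP/(TP+FP), accuracy =
#' (TP+TN)/(TP+TN+FP+FN), F1 = 2TP/(2TP+FP+FN). A zero denominator yields
#' `NaN` and is flagged, never silently 0.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return list of the four metrics plus `undefined` (names of NaN metrics).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) if (den == 0) NaN else num / den
  m <- list(
    sensitivity = div(tp, tp + fn),
    precision = div(tp, tp + fp),
    accuracy = div(tp + tn, tp + tn + fp + fn),
    f1 = div(2 * tp, 2 * tp + fp + fn)
  )
  m$undefined <- names(m)[vapply(m, is.nan, logical(1))]
  m
}

#' ROC curve and trapezoidal AUC
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 truth.
#' @return list with `roc_points` (data.frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels == 1)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    return(list(roc_points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NaN))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE) # last index of each tied block
  tpr <- c(0, cumsum(l)[keep] / np)
  fpr <- c(0, cumsum(1 - l)[keep] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a classifier on the held-out test split
#'
#' Confusion counts at probability threshold 0.5; sensitivity, precision,
#' accuracy and F1 from the counts; ROC/AUC by trapezoidal integration over
#' all score thresholds.
#'
#' @param model a `zga_classifier` from [grid_search_train()].
#' @param dataset the [labeled_dataset()] it was trained on.
#' @param threshold probability cut for the confusion counts.
#' @return a `zga_eval` list: `tp`, `tn`, `fp`, `fn`, the four metrics,
#'   `undefined`, `roc_points`, `auc`, `scores`, `labels`.
#' @export
evaluate <- function(model, dataset, threshold = 0.5) {
  te <- dataset$split == "test"
  if (!any(te)) stop_zgakit("empty test split", "zgakit_data_error")
  X <- dataset$X[te, , drop = FALSE]
  y <- dataset$y[te]
  p <- score_genes(model, X)
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  m <- confusion_metrics(tp, tn, fp, fn)
  r <- roc_auc(p, y)
  structure(c(list(tp = tp, tn = tn, fp = fp, fn = fn), m,
              list(roc_points = r$roc_points, auc = r$auc,
                   scores = p, labels = unname(y))),
            class = "zga_eval")
}

#' Score genes with a trained classifier
#'
#' @param model a `zga_classifier`.
#' @param X feature matrix; must contain every selected feature (extra
#'   columns are ignored), otherwise an error names the missing columns.
#' @return named vector of probabilities in \[0, 1\].
#' @export
score_genes <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$features, colnames(X))
  if (length(missing)) {
    stop_zgakit(sprintf("feature column(s) missing: %s",
                        paste(missing, collapse = ", ")),
                "zgakit_schema_error")
  }
  p <- predict_prob(model, X[, model$features, drop = FALSE])
  setNames(p, rownames(X))
}

#' Serialize a classifier's provenance sidecar
#'
#' Writes algorithm, hyperparameters, selected features, seed and a digest of
#' the training data as JSON next to wherever the caller persists the fit.
#'
#' @param model a `zga_classifier`.
#' @param path output JSON path.
#' @export
write_model_sidecar <- function(model, path) {
  sidecar <- list(
    algorithm = model$algorithm,
    hyperparameters = model$hyperparameters,
    selected_features = model$selected_features,
    seed = model$seed,
    training_data_hash = sum(model$X_train) + length(model$y_train)
  )
  writeLines(to_json(sidecar), path)
  invisible(path)
}

# minimal JSON emitter for sidecars (jsonlite is only suggested)
to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  one <- function(v) {
    if (is.list(v)) {
      paste0("{", paste(sprintf('"%s": %s', esc(names(v)),
                                vapply(v, one, character(1))),
                        collapse = ", "), "}")
    } else if (is.character(v)) {
      if (length(v) == 1) sprintf('"%s"', esc(v))
      else paste0("[", paste(sprintf('"%s"', esc(v)), collapse = ", "), "]")
    } else {
      if (length(v) == 1) format(v, digits = 15)
      else paste0("[", paste(format(v, digits = 15), collapse = ", "), "]")
    }
  }
  one(x)
}
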