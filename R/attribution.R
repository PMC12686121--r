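# Parse a fitted ranger probability forest into the flat node-table layout
# consumed by the compiled Shapley kernel. Node covers are the bootstrap
# in-bag sample counts routed through each node, so leaf values (in-bag class
# fractions) and cover-weighted expectations are mutually consistent.
parse_ranger_forest <- function(model) {
  fit <- model$fit
  if (is.null(fit$inbag.counts)) {
    stop_zgakit("ranger fit lacks inbag counts; train via grid_search_train",
                "zgakit_parameter_error")
  }
  Xtr <- as.matrix(model$X_train)
  ntree <- fit$num.trees
  pos_col <- NULL
  lapply(seq_len(ntree), function(t) {
    ti <- ranger::treeInfo(fit, t)
    if (is.null(pos_col)) {
      pc <- grep("^pred", names(ti), value = TRUE)
      pos_col <<- pc[endsWith(pc, "1")]
    }
    m <- nrow(ti)
    left <- ifelse(is.na(ti$leftChild), -1L, ti$leftChild)
    right <- ifelse(is.na(ti$rightChild), -1L, ti$rightChild)
    feature <- ifelse(ti$terminal, -1L, ti$splitvarID)
    thr <- ifelse(ti$terminal, 0, ti$splitval)
    value <- ifelse(ti$terminal, ti[[pos_col]], 0)
    cover <- numeric(m)
    w <- fit$inbag.counts[[t]]
    route <- function(node, idx) {
      cover[node + 1L] <<- sum(w[idx])
      if (feature[node + 1L] >= 0L) {
        go_left <- Xtr[idx, feature[node + 1L] + 1L] <= thr[node + 1L]
        route(left[node + 1L], idx[go_left])
        route(right[node + 1L], idx[!go_left])
      }
    }
    route(0L, which(w > 0))
    list(left = as.integer(left), right = as.integer(right),
         feature = as.integer(feature), threshold = as.numeric(thr),
         value = as.numeric(value), cover = cover)
  })
}

#' Shapley attributions for a trained classifier
#'
#' Tree models get exact attributions: random forests through the package's
#' compiled path-dependent tree-Shapley kernel (probability scale), gradient
#' boosting through xgboost's built-in exact tree attribution (log-odds
#' margin scale). SVM and logistic models get sampling-based Shapley values
#' against the training-mean reference under a fixed seed; the permutation
#' average telescopes, so attributions sum exactly to
#' `prediction - f(reference)` even at small sample counts.
#'
#' @param model a `zga_classifier` from [grid_search_train()].
#' @param X feature matrix covering the model's selected features.
#' @param n_perm permutations for sampling-based Shapley (default 2048).
#' @param seed seed for sampling-based Shapley.
#' @return a `zga_shap` list: `contributions` (gene x feature matrix),
#'   `base_value`, `scale` (`"probability"` or `"margin"`), `algorithm`.
#' @export
compute_shap <- function(model, X, n_perm = 2048, seed = 1) {
  X <- as.matrix(X)
  missing <- setdiff(model$features, colnames(X))
  if (length(missing)) {
    stop_zgakit(sprintf("feature column(s) missing: %s",
                        paste(missing, collapse = ", ")),
                "zgakit_schema_error")
  }
  X <- X[, model$features, drop = FALSE]
  out <- switch(model$algorithm,
    RF = {
      forest <- parse_ranger_forest(model)
      m <- .treeshap_cpp(forest, X, TRUE)
      list(contributions = m[, -ncol(m), drop = FALSE],
           base_value = m[1, ncol(m)], scale = "probability")
    },
    GBM = {
      # xgboost appends the bias/expected-value as the last column
      m <- predict(model$fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
      list(contributions = m[, -ncol(m), drop = FALSE],
           base_value = unname(m[1, ncol(m)]), scale = "margin")
    },
    {
      ref <- colMeans(as.matrix(model$X_train))
      contrib <- shap_sampling(model, X, ref, n_perm, seed)
      f_ref <- predict_prob(model, matrix(ref, nrow = 1,
                                          dimnames = list(NULL, names(ref))))
      list(contributions = contrib, base_value = unname(f_ref),
           scale = "probability")
    }
  )
  contributions <- out$contributions
  dimnames(contributions) <- list(rownames(X), model$features)
  structure(list(
    contributions = contributions,
    base_value = out$base_value,
    scale = out$scale,
    algorithm = model$algorithm
  ), class = "zga_shap")
}

shap_sampling <- function(model, X, ref, n_perm, seed) {
  if (!length(ref)) {
    stop_zgakit("empty background/reference set", "zgakit_parameter_error")
  }
  p <- length(ref)
  phis <- matrix(0, nrow(X), p)
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(p))
  })
  for (r in seq_len(nrow(X))) {
    x <- X[r, ]
    states <- matrix(ref, n_perm * p, p, byrow = TRUE)
    for (j in seq_len(n_perm)) {
      cur <- ref
      base_row <- (j - 1L) * p
      for (i in seq_len(p)) {
        cur[perms[[j]][i]] <- x[perms[[j]][i]]
        states[base_row + i, ] <- cur
      }
    }
    colnames(states) <- names(ref)
    f <- predict_prob(model, states)
    f_ref <- predict_prob(model, matrix(ref, nrow = 1,
                                        dimnames = list(NULL, names(ref))))
    phi <- numeric(p)
    for (j in seq_len(n_perm)) {
      base_row <- (j - 1L) * p
      prev <- f_ref
      for (i in seq_len(p)) {
        cur <- f[base_row + i]
        phi[perms[[j]][i]] <- phi[perms[[j]][i]] + (cur - prev)
        prev <- cur
      }
    }
    phis[r, ] <- phi / n_perm
  }
  phis
}

#' Global attribution summary: importance ranking and predictor direction
#'
#' Features are ranked by mean absolute Shapley value. The direction of each
#' feature is the sign of the Pearson correlation between its values and its
#' attributions across samples: above `+threshold` marks a favourable
#' predictor (high values push predictions toward the ZGA class), below
#' `-threshold` an unfavourable one, anything else (including constant
#' features) indeterminate.
#'
#' @param shap a `zga_shap` from [compute_shap()].
#' @param X the feature matrix the attributions were computed on.
#' @param threshold correlation cut for direction calls (default 0.2).
#' @param min_samples minimum samples for direction calls (default 20; fewer
#'   samples yield indeterminate directions with a warning).
#' @return an `attribution_summary` data.frame: `feature`, `mean_abs_shap`,
#'   `rank`, `direction`, `direction_stat`, ordered by rank.
#' @export
summarize_attribution <- function(shap, X, threshold = 0.2,
                                  min_samples = 20) {
  A <- shap$contributions
  X <- as.matrix(X)[, colnames(A), drop = FALSE]
  mas <- colMeans(abs(A))
  enough <- nrow(A) >= min_samples
  if (!enough) warning("fewer samples than min_samples; directions set to indeterminate")
  stat <- vapply(seq_len(ncol(A)), function(j) {
    if (!enough || sd(X[, j]) == 0 || sd(A[, j]) == 0) return(NA_real_)
    cor(X[, j], A[, j])
  }, numeric(1))
  direction <- ifelse(is.na(stat), "indeterminate",
                      ifelse(stat > threshold, "favourable",
                             ifelse(stat < -threshold, "unfavourable",
                                    "indeterminate")))
  ord <- order(mas, decreasing = TRUE)
  structure(data.frame(
    feature = colnames(A)[ord],
    mean_abs_shap = unname(mas[ord]),
    rank = seq_along(ord),
    direction = direction[ord],
    direction_stat = stat[ord],
    stringsAsFactors = FALSE,
    row.names = NULL
  ), class = c("attribution_summary", "data.frame"))
}

#' Explain a single gene's prediction
#'
#' Decomposes one prediction into its base value plus signed per-feature
#' contributions (local accuracy: they sum to the model output on the
#' attribution scale).
#'
#' @param model a `zga_classifier`.
#' @param x named feature vector or single-row matrix for one gene.
#' @param top_n contributions to keep in the `top` table (default 10).
#' @inheritParams compute_shap
#' @return a `sample_explanation` list: `gene`, `base_value`,
#'   `contributions` (full named vector), `top` (data.frame of the
#'   largest-|value| contributions), `prediction` (on the attribution
#'   scale), `probability`, `scale`.
#' @export
explain_sample <- function(model, x, top_n = 10, n_perm = 2048, seed = 1) {
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list("sample", names(x)))
  }
  shap <- compute_shap(model, x, n_perm = n_perm, seed = seed)
  contrib <- shap$contributions[1, ]
  prob <- unname(score_genes(model, x))
  pred <- if (shap$scale == "margin") qlogis(prob) else prob
  ord <- order(abs(contrib), decreasing = TRUE)
  top <- data.frame(feature = names(contrib)[ord], value = unname(contrib[ord]),
                    stringsAsFactors = FALSE)[seq_len(min(top_n, length(ord))), ]
  structure(list(
    gene = rownames(x) %||% "sample",
    base_value = shap$base_value,
    contributions = contrib,
    top = top,
    prediction = pred,
    probability = prob,
    scale = shap$scale
  ), class = "sample_explanation")
}

#' Pairwise Shapley interaction values (tree models)
#'
#' Exact pairwise interaction attributions for tree models: the package's
#' compiled kernel (conditioned tree traversals) for random forests,
#' xgboost's built-in interaction attribution for gradient boosting. Other
#' algorithms raise an unsupported-operation error.
#'
#' @param model a `zga_classifier` (`RF` or `GBM`).
#' @param X feature matrix.
#' @param feature_a,feature_b optional feature names; when both are given a
#'   plot-ready per-sample table for that pair is included.
#' @return list with `mean_abs` (feature x feature mean |interaction|),
#'   `values` (sample x feature x feature array) and optionally `pair`
#'   (data.frame `value_a`, `value_b`, `interaction`).
#' @export
interaction_summary <- function(model, X, feature_a = NULL,
                                feature_b = NULL) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  p <- ncol(X)
  arr <- switch(model$algorithm,
    RF = {
      forest <- parse_ranger_forest(model)
      a <- .treeshap_interactions_cpp(forest, X, TRUE)
      dimnames(a) <- list(rownames(X), colnames(X), colnames(X))
      a
    },
    GBM = {
      a <- predict(model$fit, xgboost::xgb.DMatrix(X),
                   predinteraction = TRUE)
      a <- a[, seq_len(p), seq_len(p), drop = FALSE]
      dimnames(a) <- list(rownames(X), colnames(X), colnames(X))
      a
    },
    stop_zgakit(
      sprintf("interaction values require a tree model, not %s",
              model$algorithm),
      "zgakit_unsupported_error"
    )
  )
  out <- list(
    mean_abs = apply(abs(arr), c(2, 3), mean),
    values = arr
  )
  if (!is.null(feature_a) && !is.null(feature_b)) {
    out$pair <- data.frame(
      value_a = X[, feature_a],
      value_b = X[, feature_b],
      interaction = arr[, feature_a, feature_b],
      stringsAsFactors = FALSE
    )
  }
  out
}
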