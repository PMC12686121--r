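make_rf_model <- function(X, y, num_trees = 25, max_depth = 0, seed = 1) {
  sk <- list(genes = rownames(X), y = setNames(y, rownames(X)),
             split = setNames(rep("train", nrow(X)), rownames(X)), seed = seed)
  class(sk) <- "labeled_dataset"
  sk$split[seq(1, nrow(X), by = 5)] <- "test"
  ds <- labeled_dataset(sk, X)
  grid_search_train("RF", ds, grid = data.frame(num_trees = num_trees,
                                                max_depth = max_depth),
                    folds = 5, seed = seed)
}

test_that("tree attributions are exactly local-accurate and match exhaustive Shapley", {
  withr::with_seed(61, {
    n <- 50; p <- 4
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("g", 1:n), paste0("f", 1:p)))
    y <- as.integer(X[, 1] + X[, 2] * X[, 3] > 0)
    m <- make_rf_model(X, y, num_trees = 10, max_depth = 3)
    sh <- compute_shap(m, X)
    pred <- score_genes(m, X)
    expect_lt(max(abs(rowSums(sh$contributions) + sh$base_value - pred)),
              1e-10)
    expect_equal(sh$scale, "probability")

    forest <- zgakit:::parse_ranger_forest(m)
    for (r in c(3, 17, 42)) {
      expect_equal(unname(sh$contributions[r, ]),
                   brute_shapley(forest, X[r, ], p), tolerance = 1e-10)
    }
  })
})

test_that("a single-feature model attributes everything to its one player", {
  withr::with_seed(63, {
    n <- 60
    X <- matrix(rnorm(n), n, 1, dimnames = list(paste0("g", 1:n), "f1"))
    y <- as.integer(X[, 1] > 0)
    m <- make_rf_model(X, y, num_trees = 20, max_depth = 3)
    sh <- compute_shap(m, X)
    pred <- score_genes(m, X)
    expect_equal(unname(sh$contributions[, 1]),
                 unname(pred - sh$base_value), tolerance = 1e-10)
  })
})

test_that("identical duplicate features receive equal attribution in expectation", {
  withr::with_seed(65, {
    n <- 150
    x <- rnorm(n)
    X <- cbind(a = x, b = x, c = rnorm(n))
    rownames(X) <- paste0("g", 1:n)
    y <- as.integer(x > 0)
    m <- make_rf_model(X, y, num_trees = 400, max_depth = 4)
    sh <- compute_shap(m, X)
    # symmetry axiom, checked empirically across the forest
    expect_lt(abs(mean(abs(sh$contributions[, "a"])) -
                    mean(abs(sh$contributions[, "b"]))), 0.05)
  })
})

test_that("gradient-boosting attributions are local-accurate on the margin scale", {
  withr::with_seed(67, {
    n <- 80
    X <- matrix(sample(seq(-2, 2, by = 0.25), n * 3, replace = TRUE), n, 3,
                dimnames = list(paste0("g", 1:n), paste0("f", 1:3)))
    y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
    sk <- list(genes = rownames(X), y = setNames(y, rownames(X)),
               split = setNames(rep(c("train", "test"), c(64, 16)),
                                rownames(X)), seed = 1)
    class(sk) <- "labeled_dataset"
    ds <- labeled_dataset(sk, X)
    m <- grid_search_train("GBM", ds,
                           grid = data.frame(nrounds = 30, eta = 0.2,
                                             max_depth = 3),
                           folds = 5, seed = 1)
    sh <- compute_shap(m, X)
    expect_equal(sh$scale, "margin")
    margin <- qlogis(score_genes(m, X))
    expect_lt(max(abs(rowSums(sh$contributions) + sh$base_value - margin)),
              1e-5)
  })
})

test_that("sampling-based Shapley telescopes exactly and zeroes out at the reference", {
  withr::with_seed(69, {
    n <- 60
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(paste0("g", 1:n), paste0("f", 1:3)))
    y <- as.integer(X[, 1] > 0)
    sk <- list(genes = rownames(X), y = setNames(y, rownames(X)),
               split = setNames(rep(c("train", "test"), c(48, 12)),
                                rownames(X)), seed = 1)
    class(sk) <- "labeled_dataset"
    ds <- labeled_dataset(sk, X)
    m <- grid_search_train("LR", ds, grid = data.frame(C = 1), folds = 5,
                           seed = 1)
    sh <- compute_shap(m, X[1:5, ], n_perm = 64, seed = 2)
    pred <- score_genes(m, X[1:5, ])
    expect_lt(max(abs(rowSums(sh$contributions) + sh$base_value - pred)),
              1e-8)
    # explaining the reference itself gives exactly zero contributions
    ref <- matrix(colMeans(m$X_train), 1,
                  dimnames = list("ref", colnames(X)))
    shr <- compute_shap(m, ref, n_perm = 16, seed = 3)
    expect_equal(max(abs(shr$contributions)), 0)
    # determinism under the seed
    sh2 <- compute_shap(m, X[1:5, ], n_perm = 64, seed = 2)
    expect_identical(sh$contributions, sh2$contributions)
  })
})

test_that("direction calls recover the planted sign structure", {
  study <- make_small_study(n_genes = 60, seed = 71)
  gg_genes <- study$genes
  chip <- simulate_chip_signal(gg_genes, study$truth, seed = 71)
  pos <- names(study$truth$labels)[study$truth$labels == "ZGA"]
  neg <- names(study$truth$labels)[study$truth$labels == "nonZGA"]
  sk <- balance_and_split(pos, neg, seed = 71)
  ds <- labeled_dataset(sk, chip$matrix)
  m <- grid_search_train("RF", ds, grid = data.frame(num_trees = 300,
                                                     max_depth = 0),
                         folds = 5, seed = 71)
  sh <- compute_shap(m, ds$X)
  sm <- summarize_attribution(sh, ds$X)
  expect_identical(sm$feature[1:nrow(sm)], sm$feature[order(sm$rank)])
  expect_true(all(diff(sm$mean_abs_shap) <= 1e-12)) # non-increasing in rank
  act <- sm[sm$feature %in% paste0("H3K9ac_", 9:12), ]
  rep_ <- sm[sm$feature %in% paste0("H3K27me3_", 9:12), ]
  expect_true(all(act$direction == "favourable"))
  expect_true(all(rep_$direction == "unfavourable"))
  # constant feature is indeterminate
  Xc <- cbind(ds$X, konst = 1)
  shc <- sh; shc$contributions <- cbind(sh$contributions, konst = 0)
  smc <- summarize_attribution(shc, Xc)
  expect_equal(smc$direction[smc$feature == "konst"], "indeterminate")
})

test_that("sample explanations surface planted features and agree with scores", {
  study <- make_small_study(n_genes = 40, seed = 73)
  pos <- names(study$truth$labels)[study$truth$labels == "ZGA"]
  neg <- names(study$truth$labels)[study$truth$labels == "nonZGA"]
  sk <- balance_and_split(pos, neg, seed = 73)
  keep <- c(study$truth$planted_kmers, "AAAAAA", "CCCCCC", "GGGGGG")
  ds <- labeled_dataset(sk, study$X[, keep])
  m <- grid_search_train("RF", ds, grid = data.frame(num_trees = 100,
                                                     max_depth = 0),
                         folds = 5, seed = 73)
  g <- pos[1]
  ex <- explain_sample(m, ds$X[g, ])
  expect_equal(ex$base_value + sum(ex$contributions), ex$prediction,
               tolerance = 1e-10)
  expect_equal(ex$probability, unname(score_genes(m, ds$X)[g]),
               tolerance = 1e-12)
  expect_true(any(study$truth$planted_kmers %in% ex$top$feature[1:2]))
})

test_that("interaction values are symmetric, consistent, and flag non-tree models", {
  withr::with_seed(75, {
    n <- 120
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(paste0("g", 1:n), c("a", "b", "c")))
    # XOR-style rule on (a, b); c is noise
    y <- as.integer(xor(X[, "a"] > 0, X[, "b"] > 0))
    m <- make_rf_model(X, y, num_trees = 100, max_depth = 5)
    ia <- interaction_summary(m, X, feature_a = "a", feature_b = "b")
    # symmetry and consistency with the per-feature attributions
    expect_lt(max(abs(ia$values - aperm(ia$values, c(1, 3, 2)))), 1e-10)
    sh <- compute_shap(m, X)
    expect_lt(max(abs(apply(ia$values, c(1, 2), sum) - sh$contributions)),
              1e-10)
    # the planted pair dominates the off-diagonal interactions
    off <- ia$mean_abs
    diag(off) <- 0
    expect_equal(which(off == max(off), arr.ind = TRUE)[1, ],
                 c(row = 1, col = 2), ignore_attr = TRUE)
    expect_equal(nrow(ia$pair), n)

    # additive ground truth: interactions small relative to main effects
    # (finite forests estimate spurious interaction, hence the slack factor)
    ya <- as.integer(X[, "a"] + X[, "b"] > 0)
    ma <- make_rf_model(X, ya, num_trees = 100, max_depth = 5)
    iaa <- interaction_summary(ma, X)
    offa <- iaa$mean_abs
    diag(offa) <- 0
    expect_lt(max(offa), 0.3 * max(diag(iaa$mean_abs)))

    # non-tree models are rejected with a documented error
    sk <- list(genes = rownames(X), y = setNames(ya, rownames(X)),
               split = setNames(rep(c("train", "test"), c(96, 24)),
                                rownames(X)), seed = 1)
    class(sk) <- "labeled_dataset"
    ds <- labeled_dataset(sk, X)
    ml <- grid_search_train("LR", ds, grid = data.frame(C = 1), folds = 5,
                            seed = 1)
    expect_error(interaction_summary(ml, X),
                 class = "zgakit_unsupported_error")
  })
})
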