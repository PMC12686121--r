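test_that("balancing and splitting give equal classes and a reproducible 80/20 split", {
  pos <- paste0("p", 1:100)
  neg <- paste0("n", 1:500)
  ds <- balance_and_split(pos, neg, seed = 1)
  expect_equal(sum(ds$y == 1), 100)
  expect_equal(sum(ds$y == 0), 100)
  expect_equal(sum(ds$split == "train"), 160)
  expect_equal(sum(ds$split == "test"), 40)
  # stratified: 80/20 within each class
  expect_equal(sum(ds$split == "train" & ds$y == 1), 80)
  ds2 <- balance_and_split(pos, neg, seed = 1)
  expect_identical(ds, ds2)
  ds3 <- balance_and_split(pos, paste0("n", 1:100), seed = 2)
  expect_setequal(names(ds3$y)[ds3$y == 0], paste0("n", 1:100))
  expect_error(balance_and_split(pos, neg[1:50]), class = "zgakit_data_error")
})

test_that("MIC separates dependent from independent features and matches brute force", {
  withr::with_seed(3, {
    y <- rep(c(0L, 1L), each = 100)
    x_sep <- y + rnorm(200, sd = 0.05)     # essentially perfect separation
    expect_gt(mic_score(x_sep, y), 0.9)
    x_perm <- sample(x_sep)                # independence by permutation
    expect_lt(mic_score(x_perm, y), 0.3)
  })
  expect_equal(mic_score(rep(1, 50), rep(c(0L, 1L), 25)), 0)
  expect_error(mic_score(1:5, c(0, 1, 0, 1, 0)), class = "zgakit_data_error")

  # exact agreement with exhaustive partition enumeration on small inputs
  # (clump pre-merging disabled via a large c so both search the same space)
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(10:16, 1)
      x <- round(rnorm(n), 1) # coarse values force ties/clumps
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(mic_score(x, y, c = 1000), brute_mic_binary(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("incremental selection finds planted columns and respects its contract", {
  withr::with_seed(5, {
    n <- 120; p <- 20
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    X[, 1:3] <- X[, 1:3] + 1.2 * y  # three informative columns
    rk <- mic_rank(X, y)
    expect_setequal(colnames(X)[rk[1:3]], c("f1", "f2", "f3"))
    ifs <- incremental_feature_selection(X, y, rk, cv_folds = 5, seed = 5)
    expect_true(all(ifs$selected %in% colnames(X)[rk[seq_along(ifs$selected)]]))
    expect_gte(max(ifs$cv_accuracy), 0.8)

    one <- incremental_feature_selection(X, y, rk, cv_folds = 5,
                                         max_features = 1, seed = 5)
    expect_identical(one$selected, colnames(X)[rk[1]])

    # all-noise features: selected accuracy stays near chance (the max over
    # prefixes carries some selection bias; 0.7 is > 5 binomial s.d. above
    # chance at this n)
    nn <- 200
    yn <- rep(c(0L, 1L), each = nn / 2)
    Xn <- matrix(rnorm(nn * 10), nn, 10,
                 dimnames = list(NULL, paste0("z", 1:10)))
    null_ifs <- incremental_feature_selection(Xn, yn, cv_folds = 5,
                                              max_features = 3, seed = 5)
    expect_lt(max(null_ifs$cv_accuracy), 0.7)

    expect_warning(
      incremental_feature_selection(X, y, rk, cv_folds = 5,
                                    max_features = p + 5, seed = 5),
      "clipping"
    )
  })
})

test_that("grid search is deterministic, leak-free, and near chance on permuted labels", {
  withr::with_seed(9, {
    n <- 100
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("g", 1:n),
                                                    paste0("f", 1:6)))
    X[, 1] <- X[, 1] + 1.5 * y
    genes <- rownames(X)
    sk <- list(genes = genes, y = setNames(y, genes),
               split = setNames(rep(c("train", "test"), each = n / 2)[
                 sample(n)], genes), seed = 9)
    class(sk) <- "labeled_dataset"
    ds <- labeled_dataset(sk, X)

    grid <- data.frame(num_trees = c(50, 100), max_depth = c(0, 5))
    m1 <- grid_search_train("RF", ds, grid = grid, folds = 5, seed = 4)
    m2 <- grid_search_train("RF", ds, grid = grid, folds = 5, seed = 4)
    expect_identical(m1$hyperparameters, m2$hyperparameters)
    expect_identical(score_genes(m1, X), score_genes(m2, X))

    # no test-set leakage: changing test-split labels/features changes nothing
    ds_perm <- ds
    te <- ds_perm$split == "test"
    ds_perm$y[te] <- sample(ds_perm$y[te])
    ds_perm$X[te, ] <- ds_perm$X[sample(which(te)), ]
    m3 <- grid_search_train("RF", ds_perm, grid = grid, folds = 5, seed = 4)
    expect_identical(m1$hyperparameters, m3$hyperparameters)
    expect_identical(m1$cv_accuracy, m3$cv_accuracy)

    # label permutation kills test performance
    ds_null <- ds
    ds_null$y[] <- sample(ds_null$y)
    mn <- grid_search_train("RF", ds_null, grid = grid, folds = 5, seed = 4)
    expect_lt(evaluate(mn, ds_null)$auc, 0.75)
    expect_gt(evaluate(mn, ds_null)$auc, 0.25)
  })
})

test_that("all four algorithms train, tune and score probabilities", {
  withr::with_seed(15, {
    n <- 80
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("g", 1:n),
                                                    paste0("f", 1:4)))
    X[, 1] <- X[, 1] + 3 * y
    # stratified split: last 10 genes of each class held out
    split <- rep("train", n)
    split[c(31:40, 71:80)] <- "test"
    sk <- list(genes = rownames(X), y = setNames(y, rownames(X)),
               split = setNames(split, rownames(X)), seed = 1)
    class(sk) <- "labeled_dataset"
    ds <- labeled_dataset(sk, X)
    grids <- list(
      SVM = data.frame(cost = 1, gamma = "scale", stringsAsFactors = FALSE),
      RF = data.frame(num_trees = 100, max_depth = 0),
      LR = data.frame(C = 1),
      GBM = data.frame(nrounds = 50, eta = 0.1, max_depth = 3)
    )
    for (alg in names(grids)) {
      m <- grid_search_train(alg, ds, grid = grids[[alg]], folds = 5, seed = 2)
      p <- score_genes(m, X)
      expect_true(all(p >= 0 & p <= 1))
      expect_gt(evaluate(m, ds)$auc, 0.8)
    }
  })
})

test_that("evaluation metrics satisfy their defining identities", {
  # hand-evaluated example
  m <- confusion_metrics(tp = 8, tn = 9, fp = 1, fn = 2)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 16 / 19)
  expect_length(m$undefined, 0)

  # zero denominators surface as NaN with a flag
  m0 <- confusion_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.nan(m0$sensitivity))
  expect_true(all(c("sensitivity", "precision", "f1") %in% m0$undefined))

  # F1 is the harmonic mean of precision and sensitivity when both defined
  withr::with_seed(31, {
    for (i in 1:25) {
      cm <- as.list(sample(0:30, 4, replace = TRUE))
      names(cm) <- c("tp", "tn", "fp", "fn")
      mm <- do.call(confusion_metrics, cm)
      if (!is.nan(mm$precision) && !is.nan(mm$sensitivity) &&
          (mm$precision + mm$sensitivity) > 0) {
        expect_equal(mm$f1, 2 * mm$precision * mm$sensitivity /
                       (mm$precision + mm$sensitivity))
      }
    }
  })
})

test_that("the ROC is well-formed and its AUC matches rank statistics", {
  r1 <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r1$auc, 1)
  expect_true(any(r1$roc_points$fpr == 0 & r1$roc_points$tpr == 1))
  r2 <- roc_auc(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(r2$auc, 0.5)

  withr::with_seed(41, {
    for (i in 1:20) {
      n <- 60
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- rnorm(n) + y
      s[sample(n, 10)] <- round(s[sample(n, 10)], 1) # inject ties
      r <- roc_auc(s, y)
      expect_equal(r$roc_points$fpr[1], 0)
      expect_equal(r$roc_points$tpr[nrow(r$roc_points)], 1)
      expect_true(all(diff(r$roc_points$fpr) >= 0))
      # Mann-Whitney normalisation
      u <- sum(rank(s)[y == 1]) - sum(y == 1) * (sum(y == 1) + 1) / 2
      expect_equal(r$auc, u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-9)
      # independent implementation
      expect_equal(r$auc,
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                   tolerance = 1e-9)
    }
  })
})

test_that("scoring validates its feature schema", {
  withr::with_seed(51, {
    n <- 60
    y <- rep(c(0L, 1L), each = 30)
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(paste0("g", 1:n), c("a", "b", "c")))
    sk <- list(genes = rownames(X), y = setNames(y, rownames(X)),
               split = setNames(rep(c("train", "test"), c(48, 12)),
                                rownames(X)), seed = 1)
    class(sk) <- "labeled_dataset"
    ds <- labeled_dataset(sk, X)
    m <- grid_search_train("RF", ds, grid = data.frame(num_trees = 50,
                                                       max_depth = 0),
                           folds = 5, seed = 1)
    expect_error(score_genes(m, X[, c("a", "b")]), "c",
                 class = "zgakit_schema_error")
    # extra columns ignored; all-zero rows score without crashing
    Xe <- cbind(X, extra = 1)
    expect_silent(p <- score_genes(m, Xe))
    z <- matrix(0, 1, 3, dimnames = list("z", c("a", "b", "c")))
    pz <- score_genes(m, z)
    expect_true(pz >= 0 && pz <= 1)
  })
})
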