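# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# dictionary-style k-mer counting over explicit substrings
brute_count_kmers <- function(seq, k) {
  seq <- as.character(seq)
  nm <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  counts <- setNames(integer(length(nm)), nm)
  n <- nchar(seq)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# per-(gene, condition) evaluation of the ratio rules, written independently
brute_call_zga <- function(table, ruleset) {
  labels <- character(nrow(table))
  for (g in seq_len(nrow(table))) {
    any_fire <- FALSE
    for (ci in seq_len(nrow(ruleset$conditions))) {
      num <- table[g, ruleset$conditions$num[ci]]
      den <- table[g, ruleset$conditions$den[ci]]
      if (den < ruleset$maternal_floor) den <- ruleset$maternal_floor
      if (num / den > ruleset$conditions$threshold[ci]) any_fire <- TRUE
    }
    if (any_fire) {
      labels[g] <- "ZGA"
    } else {
      stages <- setdiff(intersect(ruleset$stages, colnames(table)),
                        ruleset$sum_excludes)
      s <- sum(table[g, stages])
      labels[g] <- if (s < ruleset$non_zga_sum_max) "nonZGA" else "unassigned"
    }
  }
  labels
}

random_stage_table <- function(n_genes, stages, seed) {
  withr::with_seed(seed, {
    vals <- sample(c(0, 0.1, 0.3, 0.5, 1, 2.5, 5, 20),
                   n_genes * length(stages), replace = TRUE)
    matrix(vals, n_genes, length(stages),
           dimnames = list(paste0("g", seq_len(n_genes)), stages))
  })
}

# exact Shapley values for a parsed forest by exhaustive subset enumeration,
# with the cover-weighted (path-dependent) conditional expectation
brute_tree_expvalue <- function(tree, x, S) {
  rec <- function(node) {
    f <- tree$feature[node + 1]
    if (f < 0) return(tree$value[node + 1])
    if ((f + 1) %in% S) {
      if (x[f + 1] <= tree$threshold[node + 1]) rec(tree$left[node + 1])
      else rec(tree$right[node + 1])
    } else {
      (tree$cover[tree$left[node + 1] + 1] * rec(tree$left[node + 1]) +
         tree$cover[tree$right[node + 1] + 1] * rec(tree$right[node + 1])) /
        tree$cover[node + 1]
    }
  }
  rec(0)
}

brute_shapley <- function(forest, x, p) {
  v <- function(S) mean(vapply(forest, brute_tree_expvalue, numeric(1),
                               x = x, S = S))
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (ssize in 0:length(others)) {
      combs <- if (ssize == 0) list(integer(0)) else
        asplit(utils::combn(others, ssize), 2)
      w <- factorial(ssize) * factorial(p - ssize - 1) / factorial(p)
      for (S in combs) phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  phi
}

# exhaustive partition search for the binary-target MINE statistic on tiny
# inputs: every way of cutting the sorted clumps into at most kmax bins
brute_mic_binary <- function(x, y, alpha = 0.6) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  bnd <- which(diff(xs) != 0) # clump boundaries (cut after these positions)
  if (!length(bnd)) return(0)
  kmax <- max(2, floor(max(4, n^alpha) / 2))
  hy <- {
    p1 <- mean(ys == 1)
    h <- 0
    if (p1 > 0) h <- h - p1 * log2(p1)
    if (p1 < 1) h <- h - (1 - p1) * log2(1 - p1)
    h
  }
  if (hy == 0) return(0)
  best <- 0
  for (nb in 1:min(kmax - 1, length(bnd))) { # nb internal cuts = nb+1 bins
    cuts <- if (nb == length(bnd)) list(bnd) else
      asplit(utils::combn(bnd, nb), 2)
    for (cc in cuts) {
      lo <- c(1, cc + 1); hi <- c(cc, n)
      s <- 0
      for (b in seq_along(lo)) {
        yy <- ys[lo[b]:hi[b]]
        n1 <- sum(yy == 1); n0 <- sum(yy == 0); nbn <- n1 + n0
        if (n1 > 0) s <- s + n1 * log2(n1 / nbn)
        if (n0 > 0) s <- s + n0 * log2(n0 / nbn)
      }
      best <- max(best, hy + s / n)
    }
  }
  min(1, best)
}

# shared small synthetic study used by several files
make_small_study <- function(n_genes = 40, seed = 1, enrich_pos = 8,
                             enrich_neg = 1, k = 6) {
  gg <- generate_genome(n_genes, seed = seed)
  truth <- synthetic_truth(gg$genes$id, enrich_pos = enrich_pos,
                           enrich_neg = enrich_neg, seed = seed)
  genome <- plant_motifs(gg$genome, gg$genes, truth, seed = seed)
  X <- featurize(gg$genes, genome, k = k)
  list(genes = gg$genes, genome = genome, truth = truth, X = X)
}

random_pwm <- function(w, seed, name = "rand") {
  withr::with_seed(seed, {
    m <- matrix(rexp(4 * w), 4, w)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "T")
    structure(list(name = name, mat = m, nsites = 20), class = "pwm")
  })
}
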