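#' End-to-end synthetic sequence-model study
#'
#' Generates a synthetic genome with planted class-differential k-mers,
#' simulates staged expression, re-derives the labels with the ratio caller,
#' builds the balanced 80/20 dataset over k-mer frequencies, ranks features
#' by MIC, runs incremental feature selection, tunes the classifier by
#' grid-searched cross-validation, and evaluates on the held-out split with
#' Shapley attribution.
#'
#' @param n_genes genes in the study (default 400: 200 ZGA / 200 non-ZGA).
#' @param seed integer seed driving every random stage.
#' @param enrich_pos,enrich_neg planted copies per positive/negative flank
#'   (Poisson means, defaults 8 and 1).
#' @param k k-mer length (default 6).
#' @param algorithm classifier (default `"RF"`).
#' @param max_features cap for incremental feature selection (default 20).
#' @param grid optional hyperparameter grid override.
#' @return list: `model`, `eval`, `attribution` (summary), `dataset`,
#'   `truth`, `selected`, `call_accuracy` (agreement of the ratio caller
#'   with the generator labels).
#' @export
run_sequence_study <- function(n_genes = 400, seed = 1, enrich_pos = 8,
                               enrich_neg = 1, k = 6, algorithm = "RF",
                               max_features = 20, grid = NULL) {
  gg <- generate_genome(n_genes, seed = seed)
  truth <- synthetic_truth(gg$genes$id, enrich_pos = enrich_pos,
                           enrich_neg = enrich_neg, seed = seed)
  genome <- plant_motifs(gg$genome, gg$genes, truth, seed = seed)
  tab <- simulate_expression(gg$genes, truth, seed = seed)
  calls <- call_zga(tab)
  call_accuracy <- mean(calls$label == unname(truth$labels[calls$gene]))

  X <- featurize(gg$genes, genome, k = k)
  pos <- calls$gene[calls$label == "ZGA"]
  neg <- call_non_zga(tab)
  sk <- balance_and_split(pos, neg, seed = seed)
  ds <- labeled_dataset(sk, X)

  tr <- ds$split == "train"
  ranking <- mic_rank(ds$X[tr, , drop = FALSE], ds$y[tr])
  ifs <- incremental_feature_selection(ds$X[tr, , drop = FALSE], ds$y[tr],
                                       ranking, max_features = max_features,
                                       seed = seed)
  ds$X <- ds$X[, ifs$selected, drop = FALSE]
  model <- grid_search_train(algorithm, ds, grid = grid, seed = seed)
  ev <- evaluate(model, ds)
  Xte <- ds$X[ds$split == "test", , drop = FALSE]
  sh <- compute_shap(model, Xte)
  sm <- summarize_attribution(sh, Xte)
  list(model = model, eval = ev, attribution = sm, dataset = ds,
       truth = truth, selected = ifs$selected,
       call_accuracy = call_accuracy, expression = tab, genes = gg$genes)
}

#' End-to-end synthetic epigenetic-model study
#'
#' Simulates class-specific chromatin bumps (active marks on ZGA genes,
#' repressive on non-ZGA), assembles the 20-bin FPKM matrix and trains a
#' classifier on the full mark x bin feature set (the binned chromatin model
#' keeps all features so that near-TSS bins of every mark stay inspectable),
#' then evaluates and attributes it.
#'
#' @param n_genes genes in the study (default 200).
#' @param seed integer seed.
#' @param algorithm classifier (default `"RF"`).
#' @param grid optional hyperparameter grid override.
#' @return list: `model`, `eval`, `attribution`, `dataset`, `truth`.
#' @export
run_epigenome_study <- function(n_genes = 200, seed = 1, algorithm = "RF",
                                grid = NULL) {
  gg <- generate_genome(n_genes, seed = seed)
  truth <- synthetic_truth(gg$genes$id, seed = seed)
  chip <- simulate_chip_signal(gg$genes, truth, seed = seed)
  pos <- names(truth$labels)[truth$labels == "ZGA"]
  neg <- names(truth$labels)[truth$labels == "nonZGA"]
  sk <- balance_and_split(pos, neg, seed = seed)
  ds <- labeled_dataset(sk, chip$matrix)
  model <- grid_search_train(algorithm, ds, grid = grid, seed = seed)
  ev <- evaluate(model, ds)
  Xte <- ds$X[ds$split == "test", , drop = FALSE]
  sh <- compute_shap(model, Xte)
  sm <- summarize_attribution(sh, Xte)
  list(model = model, eval = ev, attribution = sm, dataset = ds,
       truth = truth, genes = gg$genes)
}
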