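#' Assemble a genome-wide confidence report
#'
#' Merges sequence-model scores, optional epigenetic-model scores and any
#' number of per-dataset expression fold changes by gene id. Genes absent
#' from the epigenetic input are recorded as absent (`NA`), never as 0.
#'
#' @param seq_scores named numeric vector of sequence-model probabilities
#'   (one per reported gene, no duplicates).
#' @param epi_scores optional named numeric vector of epigenetic-model
#'   probabilities.
#' @param fold_change_tables named list of named numeric vectors, one per
#'   expression dataset (values from [fold_change()]).
#' @return a `confidence_report` data.frame: `gene`, `seq_score`,
#'   `epi_score`, one `fc_<dataset>` column per table, `high_confidence`
#'   (`NA` until [apply_high_confidence_rule()] runs) and `criteria_trace`.
#' @export
build_report <- function(seq_scores, epi_scores = NULL,
                         fold_change_tables = list()) {
  genes <- names(seq_scores)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop_zgakit("seq_scores must be uniquely named by gene id",
                "zgakit_data_error")
  }
  rpt <- data.frame(
    gene = genes,
    seq_score = unname(seq_scores),
    epi_score = if (is.null(epi_scores)) NA_real_
                else unname(epi_scores[genes]),
    stringsAsFactors = FALSE
  )
  for (ds in names(fold_change_tables)) {
    rpt[[paste0("fc_", ds)]] <- unname(fold_change_tables[[ds]][genes])
  }
  rpt$high_confidence <- NA
  rpt$criteria_trace <- ""
  structure(rpt, class = c("confidence_report", "data.frame"),
            datasets = names(fold_change_tables))
}

#' Flag high-confidence ZGA genes
#'
#' The default rule calls a gene high-confidence when its sequence-model
#' score is at least `seq_min` and its expression fold change reaches
#' `fc_min` in at least `min_datasets` datasets. The mouse rule additionally
#' requires an epigenetic-model score of at least `epi_min`; a gene with no
#' epigenetic score cannot pass the mouse rule, and the trace records the
#' missing clause.
#'
#' @param report a [build_report()] data.frame.
#' @param rule `"default"` or `"mouse"`.
#' @param seq_min,epi_min score thresholds (default 0.6).
#' @param fc_min fold-change threshold (default 2).
#' @param min_datasets datasets that must reach `fc_min` (default 2).
#' @return the report with `high_confidence` and `criteria_trace` filled in.
#' @export
apply_high_confidence_rule <- function(report, rule = c("default", "mouse"),
                                       seq_min = 0.6, epi_min = 0.6,
                                       fc_min = 2, min_datasets = 2) {
  rule <- match.arg(rule)
  fc_cols <- grep("^fc_", names(report), value = TRUE)
  for (i in seq_len(nrow(report))) {
    trace <- character(0)
    seq_ok <- !is.na(report$seq_score[i]) && report$seq_score[i] >= seq_min
    if (seq_ok) trace <- c(trace, sprintf("seq_score>=%g", seq_min))
    fc <- unlist(report[i, fc_cols])
    n_fc <- sum(!is.na(fc) & fc >= fc_min)
    fc_ok <- n_fc >= min_datasets
    if (fc_ok) {
      trace <- c(trace, sprintf("fold_change>=%g in %d datasets", fc_min,
                                n_fc))
    }
    ok <- seq_ok && fc_ok
    if (rule == "mouse") {
      epi_ok <- !is.na(report$epi_score[i]) && report$epi_score[i] >= epi_min
      if (epi_ok) {
        trace <- c(trace, sprintf("epi_score>=%g", epi_min))
      } else if (is.na(report$epi_score[i])) {
        trace <- c(trace, "epi_score absent")
      }
      ok <- ok && epi_ok
    }
    report$high_confidence[i] <- ok
    report$criteria_trace[i] <- paste(trace, collapse = ";")
  }
  report
}

#' Genes shared across per-species high-confidence reports
#'
#' A convenience set-intersection over reports that have been through
#' [apply_high_confidence_rule()]; entirely data-dependent, provided for
#' cross-species comparisons.
#'
#' @param reports list of `confidence_report` data.frames.
#' @return character vector of gene ids flagged in every report.
#' @export
intersect_high_confidence <- function(reports) {
  sets <- lapply(reports, function(r) r$gene[isTRUE_vec(r$high_confidence)])
  Reduce(intersect, sets)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write a confidence report as TSV
#'
#' @param report a `confidence_report`.
#' @param path output file.
#' @export
write_report_tsv <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
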