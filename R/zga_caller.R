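#' Species-specific ZGA calling rulesets
#'
#' A ruleset holds the ordered developmental stages of a staged expression
#' table, the ratio conditions that define ZGA genes for a species group, the
#' maternal TPM floor applied to ratio denominators, and the summed-TPM
#' ceiling that defines non-ZGA genes. Three presets cover the published
#' species groups: the major wave is at the 2-cell stage in mouse, the 4-8
#' cell stages in human and pig, and the 8-16 cell stages in bovine and goat,
#' so each group tests ratios between its own pre- and post-activation stages.
#'
#' @param species one of `"mouse"`, `"human_pig"`, `"bovine_goat"`.
#' @return an object of class `zga_ruleset` with fields `species`, `stages`
#'   (ordered stage labels), `conditions` (data.frame with columns `num`,
#'   `den`, `threshold`), `maternal_stages`, `maternal_floor` (TPM, default
#'   0.5), `non_zga_sum_max` (TPM, default 2) and `sum_excludes` (stages left
#'   out of the non-ZGA sum; the oocyte precedes preimplantation development).
#' @examples
#' rs <- zga_ruleset("mouse")
#' rs$conditions
#' @export
zga_ruleset <- function(species = c("mouse", "human_pig", "bovine_goat")) {
  species <- match.arg(species)
  cond <- function(num, den, thr) data.frame(
    num = num, den = den, threshold = thr, stringsAsFactors = FALSE
  )
  spec <- switch(species,
    mouse = list(
      stages = c("MII", "1C", "early2C", "late2C", "4C", "8C", "16C",
                 "morula", "blastocyst"),
      conditions = rbind(
        cond("early2C", "1C", 2.5),
        cond("late2C", "1C", 3),
        cond("early2C", "MII", 3),
        cond("late2C", "MII", 3),
        cond("late2C", "early2C", 3)
      ),
      maternal = c("MII", "1C")
    ),
    human_pig = list(
      stages = c("MII", "1C", "2C", "4C", "8C", "morula", "blastocyst"),
      conditions = rbind(
        cond("4C", "1C", 2.5),
        cond("8C", "1C", 3),
        cond("4C", "MII", 3),
        cond("8C", "MII", 3),
        cond("8C", "4C", 3)
      ),
      maternal = c("MII", "1C")
    ),
    bovine_goat = list(
      stages = c("MII", "1C", "2C", "4C", "8C", "16C", "morula",
                 "blastocyst"),
      conditions = rbind(
        cond("8C", "4C", 2.5),
        cond("16C", "4C", 3),
        cond("8C", "MII", 3),
        cond("16C", "MII", 3),
        cond("16C", "8C", 3)
      ),
      maternal = c("MII", "4C")
    )
  )
  structure(list(
    species = species,
    stages = spec$stages,
    conditions = spec$conditions,
    maternal_stages = spec$maternal,
    maternal_floor = 0.5,
    non_zga_sum_max = 2,
    sum_excludes = "MII"
  ), class = "zga_ruleset")
}

#' Ratio of two TPM values with a floored denominator
#'
#' Maternal transcripts at or near zero would make stage ratios blow up, so
#' denominators below the maternal floor (default 0.5 TPM) are raised to it
#' before dividing.
#'
#' @param numerator,denominator non-negative TPM values (vectorised).
#' @param floor positive TPM floor applied to the denominator.
#' @return `numerator / max(denominator, floor)`, always finite.
#' @examples
#' floored_ratio(10, 0.1, 0.5) # 20
#' @export
floored_ratio <- function(numerator, denominator, floor = 0.5) {
  if (floor <= 0) stop_zgakit("`floor` must be > 0", "zgakit_parameter_error")
  if (any(numerator < 0) || any(denominator < 0)) {
    stop_zgakit("TPM values must be non-negative", "zgakit_domain_error")
  }
  numerator / pmax(denominator, floor)
}

check_stage_table <- function(table, stages_needed) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (any(table < 0)) {
    stop_zgakit("TPM values must be non-negative", "zgakit_domain_error")
  }
  missing <- setdiff(stages_needed, colnames(table))
  if (length(missing)) {
    stop_zgakit(
      sprintf("stage(s) missing from expression table: %s",
              paste(missing, collapse = ", ")),
      "zgakit_config_error"
    )
  }
  table
}

#' Call ZGA genes from a staged expression table
#'
#' A gene is called ZGA when any ratio condition of the ruleset fires. Two
#' readings of the published maternal-TPM clause are supported: `"floor"`
#' (default) computes every ratio with the denominator floored at
#' `maternal_floor`; `"gate"` computes plain ratios but lets a condition count
#' only for genes whose maternal-stage TPM (any of the ruleset's maternal
#' stages) is below the floor. Genes not called ZGA are labelled `nonZGA`
#' when their TPM summed over preimplantation stages (excluding the oocyte)
#' stays below `non_zga_sum_max`, and `unassigned` otherwise.
#'
#' @param table numeric gene x stage matrix (TPM, rownames = gene ids,
#'   colnames = stage labels).
#' @param ruleset a [zga_ruleset()].
#' @param mode `"floor"` or `"gate"` (see Details).
#' @return a `zga_calls` data.frame with columns `gene`, `label`
#'   (`ZGA`/`nonZGA`/`unassigned`), `fired_rules` (comma-separated
#'   `num/den` strings) and `provenance` (`ratio_rule` or `""`).
#' @examples
#' rs <- zga_ruleset("mouse")
#' tab <- matrix(0.1, 2, length(rs$stages),
#'               dimnames = list(c("g1", "g2"), rs$stages))
#' tab["g1", "early2C"] <- 5
#' call_zga(tab, rs)
#' @export
call_zga <- function(table, ruleset = zga_ruleset("mouse"),
                     mode = c("floor", "gate")) {
  mode <- match.arg(mode)
  needed <- unique(c(ruleset$conditions$num, ruleset$conditions$den,
                     ruleset$maternal_stages))
  table <- check_stage_table(table, needed)
  n <- nrow(table)
  genes <- rownames(table) %||% as.character(seq_len(n))

  fired <- matrix(FALSE, n, nrow(ruleset$conditions))
  if (mode == "gate") {
    gate_open <- apply(
      table[, ruleset$maternal_stages, drop = FALSE] < ruleset$maternal_floor,
      1, any
    )
  }
  for (i in seq_len(nrow(ruleset$conditions))) {
    cnd <- ruleset$conditions[i, ]
    if (mode == "floor") {
      r <- floored_ratio(table[, cnd$num], table[, cnd$den],
                         ruleset$maternal_floor)
      fired[, i] <- r > cnd$threshold
    } else {
      r <- table[, cnd$num] / pmax(table[, cnd$den], 1e-12)
      fired[, i] <- gate_open & (r > cnd$threshold)
    }
  }
  is_zga <- rowSums(fired) > 0

  sum_stages <- setdiff(intersect(ruleset$stages, colnames(table)),
                        ruleset$sum_excludes)
  tpm_sum <- rowSums(table[, sum_stages, drop = FALSE])
  label <- ifelse(is_zga, "ZGA",
                  ifelse(tpm_sum < ruleset$non_zga_sum_max, "nonZGA",
                         "unassigned"))
  rule_names <- paste0(ruleset$conditions$num, "/", ruleset$conditions$den)
  fired_str <- vapply(seq_len(n), function(g) {
    paste(rule_names[fired[g, ]], collapse = ",")
  }, character(1))

  structure(data.frame(
    gene = genes,
    label = label,
    fired_rules = fired_str,
    provenance = ifelse(is_zga, "ratio_rule", ""),
    stringsAsFactors = FALSE,
    row.names = NULL
  ), class = c("zga_calls", "data.frame"), mode = mode,
  species = ruleset$species)
}

#' Non-ZGA gene set (near-silent throughout preimplantation development)
#'
#' Returns genes whose TPM summed across preimplantation stages (the oocyte
#' stage is excluded) is below the ruleset ceiling (default 2 TPM) and that
#' are not called ZGA by the ratio rules, so the ZGA and non-ZGA sets are
#' disjoint by construction.
#'
#' @inheritParams call_zga
#' @return character vector of gene ids.
#' @export
call_non_zga <- function(table, ruleset = zga_ruleset("mouse"),
                         mode = c("floor", "gate")) {
  if (nrow(as.matrix(table)) == 0) return(character(0))
  calls <- call_zga(table, ruleset, mode)
  calls$gene[calls$label == "nonZGA"]
}

#' Pseudocounted expression fold change between two stages
#'
#' @param table gene x stage TPM matrix.
#' @param stage_a,stage_b stage labels (fold change is a over b).
#' @param pseudo pseudocount added to both stages (TPM, default 0.01).
#' @return named numeric vector of fold changes.
#' @export
fold_change <- function(table, stage_a, stage_b, pseudo = 0.01) {
  table <- check_stage_table(table, c(stage_a, stage_b))
  fc <- (table[, stage_a] + pseudo) / (table[, stage_b] + pseudo)
  names(fc) <- rownames(table)
  fc
}

#' Merge externally curated ZGA candidates into a call result
#'
#' Candidate ZGA genes reported by other studies are unioned into the call
#' set; a ratio-rule call is never removed. Genes new to the table are
#' appended with provenance `external_list`; already-called genes gain the
#' `external_list` provenance tag.
#'
#' @param result a `zga_calls` data.frame from [call_zga()].
#' @param external character vector of gene ids.
#' @param known_genes optional universe of annotated gene ids; external genes
#'   outside it trigger a warning but are still included.
#' @return the updated `zga_calls` data.frame.
#' @export
merge_candidates <- function(result, external, known_genes = NULL) {
  external <- unique(as.character(external))
  if (!length(external)) return(result)
  if (!is.null(known_genes)) {
    unknown <- setdiff(external, known_genes)
    if (length(unknown)) {
      warning(sprintf("external candidate(s) absent from annotation: %s",
                      paste(unknown, collapse = ", ")))
    }
  }
  add_tag <- function(prov) {
    ifelse(prov == "", "external_list", paste0(prov, ";external_list"))
  }
  hit <- result$gene %in% external
  result$label[hit] <- "ZGA"
  result$provenance[hit] <- add_tag(result$provenance[hit])
  new <- setdiff(external, result$gene)
  if (length(new)) {
    result <- rbind(result, data.frame(
      gene = new, label = "ZGA", fired_rules = "",
      provenance = "external_list", stringsAsFactors = FALSE
    ))
  }
  result
}

#' Read / write staged expression tables
#'
#' TSV layout: first column `gene`, remaining columns one per stage, values
#' in TPM.
#'
#' @param path file path.
#' @return `read_expression_tsv`: numeric gene x stage matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param table gene x stage matrix to write.
#' @export
write_expression_tsv <- function(table, path) {
  df <- data.frame(gene = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
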