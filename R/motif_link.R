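#' Encode a consensus k-mer as a position weight matrix
#'
#' Each column places `match_prob` on the consensus base and splits the rest
#' evenly over the other three, so every entry stays positive.
#'
#' @param kmer uppercase ACGT word.
#' @param match_prob probability on the consensus base (default 0.997).
#' @param name motif name (defaults to the k-mer).
#' @param nsites pseudo-observation count recorded in MEME output.
#' @return a `pwm` list: `name`, `mat` (4 x width matrix, rows A/C/G/T,
#'   columns summing to 1), `nsites`.
#' @export
kmer_to_pwm <- function(kmer, match_prob = 0.997, name = kmer,
                        nsites = 20) {
  if (!grepl("^[ACGT]+$", kmer)) {
    stop_zgakit("k-mer must be an uppercase word over ACGT (no ambiguity codes)",
                "zgakit_parameter_error")
  }
  bases <- strsplit(kmer, "")[[1]]
  mat <- matrix((1 - match_prob) / 3, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(bases)) mat[bases[i], i] <- match_prob
  structure(list(name = name, mat = mat, nsites = nsites), class = "pwm")
}

#' Reverse-complement a PWM
#'
#' @param pwm a `pwm` object.
#' @return the reverse-complemented `pwm`.
#' @export
pwm_revcomp <- function(pwm) {
  m <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$mat))),
               drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(name = pwm$name, mat = m, nsites = pwm$nsites),
            class = "pwm")
}

#' Write motifs in MEME minimal format
#'
#' Emits a version line, `ALPHABET= ACGT`, strands, a uniform background and
#' one letter-probability block per motif; the output round-trips through
#' [read_meme()].
#'
#' @param pwms a `pwm` or list of `pwm` objects (non-empty).
#' @param path optional output file; omitted, the text is returned.
#' @return the MEME text, invisibly when written to a file.
#' @export
export_meme <- function(pwms, path = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!length(pwms)) {
    stop_zgakit("no motifs to export", "zgakit_parameter_error")
  }
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", ""
  )
  for (p in pwms) {
    w <- ncol(p$mat)
    lines <- c(lines,
      sprintf("MOTIF %s", p$name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              w, p$nsites),
      vapply(seq_len(w), function(j) {
        paste(sprintf("%.6f", p$mat[, j]), collapse = " ")
      }, character(1)),
      ""
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read motifs from MEME minimal format
#'
#' @param path file path, or a character vector of MEME lines.
#' @return list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else path
  idx <- grep("^MOTIF ", lines)
  if (!length(idx)) {
    stop_zgakit("no MOTIF blocks found", "zgakit_parameter_error")
  }
  lapply(idx, function(i) {
    name <- sub("^MOTIF +", "", lines[i])
    name <- strsplit(name, " +")[[1]][1]
    j <- i + 1
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    hdr <- lines[j]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites= *([0-9]+).*", "\\1", hdr))
    } else 20L
    rows <- lines[(j + 1):(j + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), " +")[[1]])
    }, numeric(4)))
    mat <- t(mat) # 4 x w
    rownames(mat) <- c("A", "C", "G", "T")
    structure(list(name = name, mat = mat, nsites = nsites), class = "pwm")
  })
}

# mean per-column Pearson correlation over the best overlap; columns with no
# variance contribute 0. Among alignments with (near-)equal mean correlation
# the longer overlap, then the smaller |offset|, wins: a full-length perfect
# match must outrank a shifted partial one.
pwm_align_score <- function(qm, tm, min_overlap) {
  wq <- ncol(qm); wt <- ncol(tm)
  best <- list(score = -Inf, offset = NA_integer_, overlap = 0L)
  for (s in seq(-(wq - min_overlap), wt - min_overlap)) {
    qcols <- max(1, 1 - s):min(wq, wt - s)
    if (length(qcols) < min_overlap) next
    tcols <- qcols + s
    cors <- vapply(seq_along(qcols), function(i) {
      a <- qm[, qcols[i]]; b <- tm[, tcols[i]]
      if (sd(a) == 0 || sd(b) == 0) return(0)
      cor(a, b)
    }, numeric(1))
    sc <- mean(cors)
    ov <- length(qcols)
    better <- (sc > best$score + 1e-12) ||
      (abs(sc - best$score) <= 1e-12 &&
         (ov > best$overlap ||
            (ov == best$overlap && abs(s) < abs(best$offset))))
    if (better) best <- list(score = sc, offset = s, overlap = ov)
  }
  best
}

#' Match a query PWM against a motif database (Tomtom-style)
#'
#' Every database motif is scored in both orientations at all offsets with
#' overlap at least `min_overlap`; the alignment score is the mean per-column
#' Pearson correlation over the overlap. Significance is an empirical p-value
#' from shuffling the query's columns (`n_perm` permutations) and rescoring
#' against the same target. Results are sorted by score, then overlap
#' length, then p-value: for short or internally repetitive queries (e.g.
#' `ATATAT`) the column-shuffle null is nearly degenerate — shuffled copies
#' score as well as the query — so p-values tie there and the alignment
#' score is the informative primary key.
#'
#' @param query a `pwm`.
#' @param database non-empty list of `pwm` objects.
#' @param min_overlap minimum aligned columns (default 5).
#' @param n_perm column-shuffle permutations for the null (default 1000).
#' @param seed integer seed for the permutations.
#' @return data.frame: `query`, `target`, `offset`, `orientation`
#'   (`forward`/`revcomp`), `overlap`, `score`, `empirical_p`.
#' @export
match_pwm <- function(query, database, min_overlap = 5, n_perm = 1000,
                      seed = 1) {
  if (!length(database)) {
    stop_zgakit("empty motif database", "zgakit_parameter_error")
  }
  qm <- query$mat
  wq <- ncol(qm)
  score_target <- function(mat, tm) {
    fw <- pwm_align_score(mat, tm, min_overlap)
    rv <- pwm_align_score(pwm_revcomp(list(name = "", mat = mat,
                                           nsites = 0))$mat,
                          tm, min_overlap)
    take_rv <- (rv$score > fw$score + 1e-12) ||
      (abs(rv$score - fw$score) <= 1e-12 && rv$overlap > fw$overlap)
    if (take_rv) {
      list(score = rv$score, offset = rv$offset, overlap = rv$overlap,
           orientation = "revcomp")
    } else {
      list(score = fw$score, offset = fw$offset, overlap = fw$overlap,
           orientation = "forward")
    }
  }
  perm_cols <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(wq))
  })
  rows <- lapply(database, function(target) {
    tm <- target$mat
    if (ncol(tm) < min_overlap) {
      warning(sprintf("target '%s' shorter than min_overlap; skipped",
                      target$name))
      return(NULL)
    }
    obs <- score_target(qm, tm)
    null_ge <- sum(vapply(perm_cols, function(pc) {
      score_target(qm[, pc, drop = FALSE], tm)$score >= obs$score
    }, logical(1)))
    data.frame(
      query = query$name, target = target$name,
      offset = obs$offset, orientation = obs$orientation,
      overlap = obs$overlap, score = obs$score,
      empirical_p = (1 + null_ge) / (1 + n_perm),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(query = character(0), target = character(0),
                      offset = integer(0), orientation = character(0),
                      overlap = integer(0), score = numeric(0),
                      empirical_p = numeric(0)))
  }
  out <- out[order(-out$score, -out$overlap, out$empirical_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
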