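#' Gene models anchoring all coordinate work
#'
#' A minimal transcription-unit record: 0-based TSS and TES positions on a
#' named chromosome with a strand. For a plus-strand gene `tss < tes`; for a
#' minus-strand gene `tss > tes` (positions are reference coordinates of the
#' transcribed start/end bases).
#'
#' @param id,chrom character vectors.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes 0-based positions.
#' @param biotype gene biotype label.
#' @return a `gene_models` data.frame.
#' @export
gene_models <- function(id, chrom, strand, tss, tes,
                        biotype = "protein_coding") {
  stopifnot(all(strand %in% c("+", "-")))
  bad <- (strand == "+" & tss >= tes) | (strand == "-" & tss <= tes)
  if (any(bad)) {
    stop_zgakit(sprintf("inconsistent tss/tes for gene(s): %s",
                        paste(id[bad], collapse = ", ")),
                "zgakit_parameter_error")
  }
  structure(data.frame(
    id = as.character(id), chrom = as.character(chrom), strand = strand,
    tss = as.integer(tss), tes = as.integer(tes),
    biotype = rep_len(biotype, length(id)),
    stringsAsFactors = FALSE
  ), class = c("gene_models", "data.frame"))
}

#' Read gene models from BED6
#'
#' BED intervals are 0-based half-open; the TSS is the interval start for
#' plus-strand genes and `end - 1` for minus-strand genes (and vice versa for
#' the TES).
#'
#' @param path BED6 file.
#' @return a `gene_models` data.frame.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*")) {
    stop_zgakit("BED6 gene records must be stranded", "zgakit_parameter_error")
  }
  s0 <- GenomicRanges::start(gr) - 1L # back to 0-based
  e0 <- GenomicRanges::end(gr)        # half-open end
  gene_models(
    id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = st,
    tss = ifelse(st == "+", s0, e0 - 1L),
    tes = ifelse(st == "+", e0 - 1L, s0)
  )
}

#' @rdname read_gene_bed
#' @param genes a `gene_models` data.frame to write.
#' @export
write_gene_bed <- function(genes, path) {
  s0 <- ifelse(genes$strand == "+", genes$tss, genes$tes)
  e0 <- ifelse(genes$strand == "+", genes$tes + 1L, genes$tss + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
    strand = genes$strand
  )
  gr$name <- genes$id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

# Map a gene-strand window [win[1], win[2]) anchored at `anchor` (0-based
# reference position of the anchor base) to a 0-based half-open reference
# interval.
flank_ref_interval <- function(anchor, win, strand) {
  if (strand == "+") {
    c(anchor + win[1], anchor + win[2])
  } else {
    # gene-strand offset o maps to reference position anchor - o
    c(anchor - win[2] + 1L, anchor - win[1] + 1L)
  }
}

#' Extract strand-aware TSS and TES flank sequences
#'
#' Windows are asymmetric in the direction of transcription: TSS
#' (-2 kb, +1 kb) and TES (-1 kb, +2 kb) by default, i.e. 3,000 nt each.
#' Minus-strand genes are returned reverse-complemented so the sequence reads
#' in the direction of transcription. Windows reaching past a chromosome end
#' are clipped with a warning.
#'
#' @param gene one row of a [gene_models()] data.frame (or a list with the
#'   same fields).
#' @param genome named [Biostrings::DNAStringSet].
#' @param tss_window,tes_window integer length-2 gene-strand offsets
#'   (half-open) around the TSS / TES.
#' @param orientation `"gene"` (default) returns transcription-oriented
#'   sequence; `"reference"` returns the reference strand slice.
#' @return list with `DNAString` elements `tss` and `tes` and a logical
#'   `clipped`.
#' @export
extract_flanks <- function(gene, genome,
                           tss_window = c(-2000L, 1000L),
                           tes_window = c(-1000L, 2000L),
                           orientation = c("gene", "reference")) {
  orientation <- match.arg(orientation)
  if (!gene$chrom %in% names(genome)) {
    stop_zgakit(sprintf("chromosome '%s' not in genome", gene$chrom),
                "zgakit_lookup_error")
  }
  chrom <- genome[[gene$chrom]]
  clen <- length(chrom)
  one <- function(anchor, win) {
    iv <- flank_ref_interval(anchor, win, gene$strand)
    lo <- max(iv[1], 0L)
    hi <- min(iv[2], clen)
    clipped <- (lo != iv[1]) || (hi != iv[2])
    if (clipped) {
      warning(sprintf("flank window clipped to chromosome bounds for '%s'",
                      gene$id))
    }
    if (hi <= lo) {
      return(list(seq = Biostrings::DNAString(""), clipped = TRUE))
    }
    s <- Biostrings::subseq(chrom, start = lo + 1L, end = hi)
    if (gene$strand == "-" && orientation == "gene") {
      s <- Biostrings::reverseComplement(s)
    }
    list(seq = s, clipped = clipped)
  }
  tss <- one(gene$tss, tss_window)
  tes <- one(gene$tes, tes_window)
  list(tss = tss$seq, tes = tes$seq, clipped = tss$clipped || tes$clipped)
}

#' Count k-mer words with a sliding window of step 1
#'
#' All `4^k` words over ACGT are counted in lexicographic order; windows
#' containing any other character (e.g. N) are skipped, so the counts sum to
#' the number of valid windows.
#'
#' @param seq a `DNAString` or character scalar.
#' @param k word length.
#' @return named integer vector of length `4^k`.
#' @examples
#' count_kmers("AAAA", 3) # AAA = 2
#' @export
count_kmers <- function(seq, k) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (k < 1) stop_zgakit("k must be >= 1", "zgakit_parameter_error")
  if (length(seq) < k) {
    warning("sequence shorter than k; returning zero counts")
    nm <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    return(setNames(integer(4^k), nm))
  }
  Biostrings::oligonucleotideFrequency(seq, width = k, step = 1)
}

#' Build a k-mer frequency feature matrix from gene flanks
#'
#' For each gene the TSS and TES flank sequences are extracted (strand
#' aware), their k-mer counts are summed into one spectrum and divided by the
#' total number of valid windows across both regions, yielding frequencies in
#' \[0, 1\] that sum to 1 for N-free sequences. Genes whose windows are fully
#' clipped get a zero row and are flagged.
#'
#' @param genes a [gene_models()] data.frame.
#' @param genome named [Biostrings::DNAStringSet].
#' @param k word length (the published models use k = 6; 4-8 is the scanned
#'   range, other values are accepted).
#' @inheritParams extract_flanks
#' @return numeric gene x `4^k` matrix with attributes `k` and `flagged`
#'   (ids of zero-count genes).
#' @export
featurize <- function(genes, genome, k = 6,
                      tss_window = c(-2000L, 1000L),
                      tes_window = c(-1000L, 2000L),
                      orientation = c("gene", "reference")) {
  orientation <- match.arg(orientation)
  if (!nrow(genes)) stop_zgakit("no genes supplied", "zgakit_parameter_error")
  seqs <- vector("list", 2L * nrow(genes))
  for (i in seq_len(nrow(genes))) {
    fl <- extract_flanks(genes[i, ], genome, tss_window, tes_window,
                         orientation)
    seqs[[2L * i - 1L]] <- fl$tss
    seqs[[2L * i]] <- fl$tes
  }
  ss <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(ss, width = k, step = 1)
  tot <- counts[seq(1, nrow(counts), by = 2), , drop = FALSE] +
    counts[seq(2, nrow(counts), by = 2), , drop = FALSE]
  n_windows <- rowSums(tot)
  freq <- tot / pmax(n_windows, 1)
  rownames(freq) <- genes$id
  flagged <- genes$id[n_windows == 0]
  if (length(flagged)) {
    warning(sprintf("gene(s) with no valid k-mer windows: %s",
                    paste(flagged, collapse = ", ")))
  }
  structure(freq, k = k, flagged = flagged)
}

#' Write a feature matrix as TSV
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output file.
#' @export
write_feature_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
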