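#' Read / write bedGraph signal tracks
#'
#' Tracks are held in memory as 0-based half-open data.frames with columns
#' `chrom`, `start`, `end`, `value`. File IO goes through rtracklayer, which
#' handles the 0/1-based conversion of the bedGraph format.
#'
#' @param path bedGraph file.
#' @return `read_bedgraph`: a track data.frame.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_bedgraph
#' @param track a track data.frame to write.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

as_track <- function(track) {
  if (methods::is(track, "GRanges")) {
    track <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(track)),
      start = GenomicRanges::start(track) - 1L,
      end = GenomicRanges::end(track),
      value = track$score,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  track
}

#' Sum base-level signal into bins around a gene's TSS
#'
#' The window spans `n_bins * bin_width` bases centred on the TSS (20 x
#' 300 bp = TSS +/- 3 kb by default). Bin 1 is always the most upstream bin
#' in the direction of transcription, so for minus-strand genes the
#' reference-order bins are reversed and bins 10/11 straddle the TSS on both
#' strands. Intervals absent from the track count as 0.
#'
#' @param gene one row of a [gene_models()] data.frame.
#' @param track a bedGraph-style track data.frame (see [read_bedgraph()]).
#' @param n_bins number of bins.
#' @param bin_width bin width in bp.
#' @return numeric vector of `n_bins` raw signal sums
#'   (sum over bases of the base-level value).
#' @export
bin_signal <- function(gene, track, n_bins = 20, bin_width = 300) {
  track <- as_track(track)
  half <- n_bins * bin_width / 2
  wstart <- gene$tss - half
  wend <- gene$tss + half
  tr <- track[track$chrom == gene$chrom & track$end > wstart &
                track$start < wend, , drop = FALSE]
  sums <- numeric(n_bins)
  if (nrow(tr)) {
    for (b in seq_len(n_bins)) {
      bs <- wstart + (b - 1) * bin_width
      be <- bs + bin_width
      ov <- pmax(0, pmin(tr$end, be) - pmax(tr$start, bs))
      sums[b] <- sum(ov * tr$value)
    }
  }
  if (gene$strand == "-") sums <- rev(sums)
  sums
}

#' FPKM-normalise binned signal
#'
#' Fragments (or base-level signal) per kilobase of bin per million mapped
#' fragments: `bin_sum / ((bin_width/1000) * (library_size/1e6))`.
#'
#' @param bin_sums raw bin sums from [bin_signal()].
#' @param bin_width bin width in bp.
#' @param library_size total mapped fragments in the library (> 0).
#' @return numeric vector of FPKM values.
#' @examples
#' fpkm_normalize(30, 300, 1e6) # 100
#' @export
fpkm_normalize <- function(bin_sums, bin_width = 300, library_size) {
  if (library_size <= 0) {
    stop_zgakit("library_size must be > 0", "zgakit_parameter_error")
  }
  bin_sums / ((bin_width / 1000) * (library_size / 1e6))
}

#' Assemble the binned epigenetic feature matrix
#'
#' Converts one signal track per mark (or a list of replicate tracks, whose
#' per-replicate FPKM values are averaged) into a gene x (mark x bin) matrix
#' with columns named `mark_i`, i = 1..n_bins, bin 1 most upstream of
#' transcription.
#'
#' @param genes a [gene_models()] data.frame.
#' @param tracks named list: mark label -> track data.frame, or mark label ->
#'   list of replicate track data.frames.
#' @param library_sizes named numeric (or named list of numerics for
#'   replicates) of mapped-fragment counts per mark; required when
#'   `normalize = TRUE`.
#' @param n_bins,bin_width binning scheme (default 20 x 300 bp).
#' @param normalize apply [fpkm_normalize()] per track.
#' @return numeric matrix with `n_bins * length(tracks)` columns and
#'   attributes `marks`, `n_bins`, `bin_width`.
#' @export
assemble_epi_matrix <- function(genes, tracks, library_sizes = NULL,
                                n_bins = 20, bin_width = 300,
                                normalize = !is.null(library_sizes)) {
  marks <- names(tracks)
  if (is.null(marks) || any(marks == "")) {
    stop_zgakit("tracks must be a named list of marks",
                "zgakit_config_error")
  }
  if (anyDuplicated(marks)) {
    stop_zgakit("duplicated mark label in tracks", "zgakit_config_error")
  }
  if (normalize && is.null(library_sizes)) {
    stop_zgakit("library_sizes required when normalize = TRUE",
                "zgakit_parameter_error")
  }
  out <- matrix(0, nrow(genes), n_bins * length(marks))
  rownames(out) <- genes$id
  colnames(out) <- unlist(lapply(marks, function(m) {
    paste0(m, "_", seq_len(n_bins))
  }))
  for (mi in seq_along(marks)) {
    m <- marks[[mi]]
    reps <- tracks[[m]]
    if (is.data.frame(reps) || methods::is(reps, "GRanges")) {
      reps <- list(reps)
    }
    libs <- if (normalize) {
      ls <- library_sizes[[m]]
      if (is.null(ls)) {
        stop_zgakit(sprintf("no library size for mark '%s'", m),
                    "zgakit_parameter_error")
      }
      rep_len(unlist(ls), length(reps))
    }
    acc <- matrix(0, nrow(genes), n_bins)
    for (ri in seq_along(reps)) {
      vals <- t(vapply(seq_len(nrow(genes)), function(g) {
        bin_signal(genes[g, ], reps[[ri]], n_bins, bin_width)
      }, numeric(n_bins)))
      if (normalize) vals <- fpkm_normalize(vals, bin_width, libs[ri])
      acc <- acc + vals
    }
    acc <- acc / length(reps)
    out[, (mi - 1) * n_bins + seq_len(n_bins)] <- acc
  }
  structure(out, marks = marks, n_bins = n_bins, bin_width = bin_width)
}
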