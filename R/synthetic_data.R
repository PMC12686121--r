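#' Ground truth for a synthetic ZGA study
#'
#' Describes the structure planted into a synthetic genome: which genes are
#' ZGA, which k-mers are enriched in ZGA flanks (the published models single
#' out TA-rich words such as TATATA and ATTAAT, which the defaults mirror),
#' and which chromatin marks carry class-specific TSS bumps.
#'
#' @param gene_ids character vector of gene ids the truth covers.
#' @param planted_kmers uppercase ACGT words planted into flanks.
#' @param enrich_pos expected planted copies per positive gene per k-mer
#'   (Poisson mean).
#' @param enrich_neg same for negative genes.
#' @param prop_pos fraction of genes labelled ZGA.
#' @param mark_profiles data.frame with columns `mark`, `class` (`ZGA` or
#'   `nonZGA`), `offset` (bump centre relative to the TSS, bp, gene strand),
#'   `width` (full width at half maximum, bp) and `amplitude` (signal units
#'   above background).
#' @param seed integer seed used for label assignment.
#' @return a `synthetic_truth` list with fields `planted_kmers`,
#'   `enrich_pos`, `enrich_neg`, `labels` (named `ZGA`/`nonZGA` vector),
#'   `mark_profiles`, `seed`.
#' @export
synthetic_truth <- function(gene_ids,
                            planted_kmers = c("TATATA", "ATTAAT"),
                            enrich_pos = 8, enrich_neg = 1,
                            prop_pos = 0.5,
                            mark_profiles = default_mark_profiles(),
                            seed = 1) {
  if (!all(grepl("^[ACGT]+$", planted_kmers))) {
    stop_zgakit("planted k-mers must be uppercase words over ACGT",
                "zgakit_parameter_error")
  }
  stopifnot(enrich_pos >= 0, enrich_neg >= 0)
  n <- length(gene_ids)
  n_pos <- round(prop_pos * n)
  labels <- with_seed(seed, {
    lab <- rep("nonZGA", n)
    lab[sample(n, n_pos)] <- "ZGA"
    setNames(lab, gene_ids)
  })
  structure(list(
    planted_kmers = planted_kmers,
    enrich_pos = enrich_pos,
    enrich_neg = enrich_neg,
    labels = labels,
    mark_profiles = mark_profiles,
    seed = seed
  ), class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @export
default_mark_profiles <- function() {
  data.frame(
    mark = c("H3K9ac", "H3K4me3", "PolII", "H3K27me3"),
    class = c("ZGA", "ZGA", "ZGA", "nonZGA"),
    offset = -150,
    width = 600,
    amplitude = 5,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic genome with non-overlapping gene slots
#'
#' One synthetic chromosome with one gene per fixed-size slot, i.i.d. bases
#' at a target GC content, strands alternating so both are exercised. The
#' slot margin guarantees that the TSS +/- 3 kb bin window and the
#' (-2,+1) / (-1,+2) kb flank windows of neighbouring genes never overlap.
#'
#' @param n_genes number of genes (>= 2).
#' @param flank_margin bp between a slot edge and the TSS/TES (>= 3000 so
#'   every analysis window fits inside the slot).
#' @param gc target GC fraction in (0, 1).
#' @param slot_size bp of chromosome per gene.
#' @param seed integer seed.
#' @return list with `genome` (named [Biostrings::DNAStringSet], one
#'   chromosome `chrS1`) and `genes` (a [gene_models()] data.frame).
#' @export
generate_genome <- function(n_genes, flank_margin = 4000, gc = 0.5,
                            slot_size = 20000, seed = 1) {
  if (n_genes < 2) stop_zgakit("n_genes must be >= 2", "zgakit_parameter_error")
  if (gc <= 0 || gc >= 1) stop_zgakit("gc must be in (0,1)",
                                      "zgakit_parameter_error")
  if (flank_margin < 3000) {
    stop_zgakit("flank_margin must be >= 3000 so analysis windows fit",
                "zgakit_parameter_error")
  }
  if (slot_size < 2 * flank_margin + 1000) {
    stop_zgakit("slot_size too small for the requested flank_margin",
                "zgakit_parameter_error")
  }
  chrom_len <- n_genes * slot_size
  seq <- with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chrS1"

  i <- seq_len(n_genes)
  slot_start <- (i - 1L) * slot_size
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  lo <- slot_start + flank_margin
  hi <- slot_start + slot_size - flank_margin
  genes <- gene_models(
    id = sprintf("g%04d", i),
    chrom = "chrS1",
    strand = strand,
    tss = ifelse(strand == "+", lo, hi),
    tes = ifelse(strand == "+", hi, lo)
  )
  list(genome = genome, genes = genes)
}

#' Plant k-mer copies into gene flank windows
#'
#' For each gene and each planted k-mer, a Poisson number of copies
#' (`enrich_pos` mean for ZGA genes, `enrich_neg` for non-ZGA) is written at
#' uniform, mutually non-overlapping positions inside the TSS (-2,+1 kb) and
#' TES (-1,+2 kb) windows, in gene-strand orientation (so a copy on a
#' minus-strand gene appears reverse-complemented on the reference strand).
#'
#' @param genome named [Biostrings::DNAStringSet] from [generate_genome()].
#' @param genes the matching [gene_models()] data.frame.
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @return the modified genome, with attribute `planted_total` (total copies
#'   written, which equals the sum of the Poisson draws).
#' @export
plant_motifs <- function(genome, genes, truth, seed = truth$seed) {
  kmers <- truth$planted_kmers
  kl <- nchar(kmers)
  if (any(kl >= 3000)) {
    stop_zgakit("planted k-mers must be shorter than the flank windows",
                "zgakit_parameter_error")
  }
  chars <- strsplit(as.character(genome[[1]]), "", fixed = TRUE)[[1]]
  total <- 0L
  with_seed(seed, {
    for (g in seq_len(nrow(genes))) {
      gene <- genes[g, ]
      lambda <- if (truth$labels[[gene$id]] == "ZGA") truth$enrich_pos
                else truth$enrich_neg
      occupied <- matrix(numeric(0), ncol = 2) # [start, end) reference
      for (ki in seq_along(kmers)) {
        k <- kl[ki]
        n_copies <- rpois(1, lambda)
        word <- strsplit(kmers[ki], "")[[1]]
        word_rc <- rev(chartr("ACGT", "TGCA", word))
        placed <- 0L
        tries <- 0L
        while (placed < n_copies) {
          tries <- tries + 1L
          if (tries > 1000L * max(1L, n_copies)) {
            stop_zgakit("could not place planted k-mers without overlap",
                        "zgakit_parameter_error")
          }
          # uniform over the two windows' admissible start offsets
          in_tss <- runif(1) < 0.5
          win <- if (in_tss) c(-2000L, 1000L) else c(-1000L, 2000L)
          anchor <- if (in_tss) gene$tss else gene$tes
          o <- sample(seq.int(win[1], win[2] - k), 1)
          ref <- if (gene$strand == "+") anchor + o else anchor - o - k + 1L
          if (nrow(occupied) &&
              any(ref < occupied[, 2] & (ref + k) > occupied[, 1])) next
          chars[(ref + 1L):(ref + k)] <-
            if (gene$strand == "+") word else word_rc
          occupied <- rbind(occupied, c(ref, ref + k))
          placed <- placed + 1L
        }
        total <- total + n_copies
      }
    }
  })
  out <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(out) <- names(genome)[1]
  structure(out, planted_total = total)
}

#' Simulate stage-resolved expression consistent with the truth labels
#'
#' ZGA-labelled genes follow a template that is near-silent (0.1 TPM) through
#' the maternal stages and strongly expressed (20 TPM) from the first
#' activation stage of the ruleset onward, clearing every ratio threshold
#' with margin; non-ZGA genes stay at 0.1 TPM throughout so their summed TPM
#' is well under the non-ZGA ceiling. Multiplicative lognormal noise is
#' applied, and any gene whose noisy profile no longer reproduces its label
#' under [call_zga()] is resampled (never silently emitted).
#'
#' @param genes a [gene_models()] data.frame.
#' @param truth a [synthetic_truth()].
#' @param ruleset a [zga_ruleset()].
#' @param noise_sd lognormal sd on the log scale (0 = deterministic
#'   templates).
#' @param seed integer seed.
#' @param max_tries resampling attempts before giving up with an error.
#' @return gene x stage TPM matrix.
#' @export
simulate_expression <- function(genes, truth,
                                ruleset = zga_ruleset("mouse"),
                                noise_sd = 0.1, seed = truth$seed,
                                max_tries = 50) {
  stages <- ruleset$stages
  first_on <- ruleset$conditions$num[1]
  on_from <- match(first_on, stages)
  template_pos <- ifelse(seq_along(stages) >= on_from, 20, 0.1)
  template_neg <- rep(0.1, length(stages))
  ids <- genes$id
  is_pos <- truth$labels[ids] == "ZGA"
  base <- matrix(rep(template_neg, each = length(ids)),
                 nrow = length(ids), dimnames = list(ids, stages))
  base[is_pos, ] <- matrix(rep(template_pos, each = sum(is_pos)),
                           nrow = sum(is_pos))
  tab <- with_seed(seed, {
    tab <- base * exp(matrix(rnorm(length(base), sd = noise_sd),
                             nrow = nrow(base)))
    for (try in seq_len(max_tries)) {
      calls <- call_zga(tab, ruleset)
      want <- ifelse(is_pos, "ZGA", "nonZGA")
      bad <- which(calls$label != want)
      if (!length(bad)) break
      if (try == max_tries) {
        stop_zgakit(
          "noise level flips truth labels; could not resample consistently",
          "zgakit_parameter_error"
        )
      }
      tab[bad, ] <- base[bad, , drop = FALSE] *
        exp(matrix(rnorm(length(bad) * ncol(base), sd = noise_sd),
                   nrow = length(bad)))
    }
    tab
  })
  structure(tab, species = ruleset$species)
}

#' Simulate binned ChIP signal with class-specific TSS bumps
#'
#' Each mark gets a Gaussian bump (centre `offset`, FWHM `width`, height
#' `amplitude` over the configured background) on the genes of its class and
#' background-only signal on the other class. Signal is laid down as
#' constant-value bedGraph intervals of `step` bp across each gene's TSS
#' window, then binned and FPKM-normalised through the same code path used
#' for real tracks, so the returned matrix round-trips exactly through
#' bedGraph files.
#'
#' @param genes a [gene_models()] data.frame.
#' @param truth a [synthetic_truth()] (its `mark_profiles` define the marks).
#' @param background baseline signal level.
#' @param noise_sd lognormal sd applied multiplicatively per interval
#'   (0 = deterministic).
#' @param step interval resolution in bp (must divide `bin_width`).
#' @param n_bins,bin_width binning scheme.
#' @param library_size mapped-fragment count used for FPKM normalisation.
#' @param seed integer seed.
#' @return list with `matrix` (the epigenetic feature matrix) and `tracks`
#'   (named list of bedGraph-style data.frames).
#' @export
simulate_chip_signal <- function(genes, truth, background = 0.5,
                                 noise_sd = 0.25, step = 50,
                                 n_bins = 20, bin_width = 300,
                                 library_size = 1e6, seed = truth$seed) {
  profiles <- truth$mark_profiles
  if (anyDuplicated(profiles$mark)) {
    stop_zgakit("duplicated mark in mark_profiles", "zgakit_config_error")
  }
  if (!all(profiles$class %in% c("ZGA", "nonZGA"))) {
    stop_zgakit(sprintf("unknown class in mark_profiles: %s",
                        paste(setdiff(profiles$class, c("ZGA", "nonZGA")),
                              collapse = ", ")),
                "zgakit_parameter_error")
  }
  if (bin_width %% step != 0) {
    stop_zgakit("step must divide bin_width", "zgakit_parameter_error")
  }
  half <- n_bins * bin_width / 2
  offsets <- seq(-half, half - step, by = step) + step / 2 # interval midpoints
  tracks <- with_seed(seed, {
    lapply(seq_len(nrow(profiles)), function(pi) {
      prof <- profiles[pi, ]
      sdv <- prof$width / (2 * sqrt(2 * log(2))) # FWHM -> sd
      rows <- lapply(seq_len(nrow(genes)), function(g) {
        gene <- genes[g, ]
        hit <- truth$labels[[gene$id]] == prof$class
        bump <- if (hit) {
          prof$amplitude * exp(-(offsets - prof$offset)^2 / (2 * sdv^2))
        } else 0
        vals <- background + bump
        if (noise_sd > 0) {
          vals <- vals * exp(rnorm(length(vals), sd = noise_sd))
        }
        # gene-strand offsets mapped to reference intervals
        if (gene$strand == "+") {
          starts <- gene$tss + offsets - step / 2
        } else {
          starts <- gene$tss - (offsets + step / 2) + 1
        }
        data.frame(chrom = gene$chrom, start = starts,
                   end = starts + step, value = vals,
                   stringsAsFactors = FALSE)
      })
      tr <- do.call(rbind, rows)
      tr[order(tr$chrom, tr$start), ]
    })
  })
  names(tracks) <- profiles$mark
  libs <- setNames(rep(library_size, nrow(profiles)), profiles$mark)
  mat <- assemble_epi_matrix(genes, tracks, library_sizes = libs,
                             n_bins = n_bins, bin_width = bin_width)
  list(matrix = mat, tracks = tracks)
}

#' Write truth labels as TSV
#'
#' @param truth a [synthetic_truth()].
#' @param path output file.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(
    data.frame(gene = names(truth$labels), label = unname(truth$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
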