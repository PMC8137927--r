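#' Configuration for the synthetic transcriptome and footprint generator
#'
#' The generator produces random yeast-like transcript annotations and
#' footprint libraries whose statistical structure matches what the
#' analysis assumes, with full ground truth recorded, so every stage
#' of the pipeline can be tested without sequencing data.
#'
#' Occupancy is a mixture over seven components per gene: `utr5`
#' (scanning background in the 5'UTR), `start` (initiation complex
#' stalled with its P site on the start codon), `orf` (ORF-internal
#' background; carries 3-nt periodicity for 80S libraries), `stop`
#' (post-termination complex stalled with its P site on the stop
#' codon), `utr3` (3'UTR background), `utr3_aug` (reinitiation
#' complexes at planted 3'UTR AUGs) and `queued` (80S ribosomes queued
#' behind a stalled stop-codon complex). Wild-type 40S weights are
#' anchored to published WT region proportions (5'UTR 8.9%, start
#' 59%), except that the stop-peak share defaults to 4% — above the
#' published WT 2.5% — so that per-gene stop-peak counts remain
#' informative at the simulated depths (see the methods vignette).
#'
#' The stalled components have fixed 5' ends (start: `A - 14` for 40S
#' and `A - 13` for 80S; stop: `S - 14` / `S - 13`): footprint length
#' variation is purely 3'-end variability. The queued-80S component
#' places 5' ends `queued_offset` nt upstream of the stop codon's
#' first nucleotide (default 46, i.e. -49 relative to the 3'UTR
#' start), with satellites 3 nt on either side.
#'
#' `stop_fold_change` is the planted per-gene rpm ratio of mutant to
#' wild-type stop peaks: in the `tma_dd` genotype the stop component
#' is multiplied by `stop_fold_change` times the gene's
#' penultimate-codon multiplier and the non-boosted components are
#' rescaled so the library still sums to one.
#'
#' @param n_genes Number of genes.
#' @param utr5_range,cds_range,utr3_range Length ranges (nt); CDS
#'   lengths are rounded to multiples of 3.
#' @param reads_per_sample Footprints per simulated library.
#' @param weights_ssu40,weights_ribo80 Named component weight vectors
#'   (must sum to 1).
#' @param stop_fold_change Planted mutant/WT stop-peak rpm ratio.
#' @param codon_multipliers Named vector of per-penultimate-codon
#'   multipliers applied on top of `stop_fold_change` (e.g.
#'   `c(AAA = 2, TGT = 0.5)`).
#' @param utr3_aug_fold Mutant enhancement of the 3'UTR AUG
#'   reinitiation component.
#' @param queued_fold Mutant enhancement of the queued-80S component
#'   (80S libraries only).
#' @param frame0_fraction Fraction of 80S ORF-background footprints
#'   whose shifted P site falls in frame 0.
#' @param start_fold Start-peak enhancement in the `rpl11b_d`
#'   genotype (default 79/59, the published WT to knockout shift).
#' @param length_mode_ssu40,length_mode_ribo80 Main footprint length
#'   modes (~32 nt for 40S, ~28 nt for 80S).
#' @param length_spread SD of the discretized 3'-end length jitter.
#' @param minor_21nt_fraction Fraction of footprints in the minor
#'   ~21-nt class.
#' @param queued_offset Queued-80S 5'-end offset upstream of the stop
#'   codon's first nucleotide (default 46).
#' @param satellite_probs Probabilities of the -3/0/+3 packing jitter
#'   of the queued component.
#' @param penultimate_design `"balanced"` cycles the 61 sense codons
#'   across genes (so each reaches the codon-count floor when
#'   `n_genes` is a multiple of 61); `"random"` samples them.
#' @param utr3_aug_frac Fraction of genes with a planted 3'UTR dORF
#'   (AUG + 2 codons + stop); accidental AUGs are scrubbed from 3'UTRs
#'   so planted positions are the ground truth.
#' @param expression_sdlog Log-SD of per-gene expression weights
#'   (0 = equal expression).
#' @param seed Generator seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200L,
                             utr5_range = c(50L, 150L),
                             cds_range = c(300L, 1500L),
                             utr3_range = c(120L, 250L),
                             reads_per_sample = 1e5,
                             weights_ssu40 = c(utr5 = 0.089, start = 0.59,
                                               orf = 0.255, stop = 0.04,
                                               utr3 = 0.016, utr3_aug = 0.01,
                                               queued = 0),
                             weights_ribo80 = c(utr5 = 0.01, start = 0.05,
                                                orf = 0.85, stop = 0.05,
                                                utr3 = 0.01, utr3_aug = 0.005,
                                                queued = 0.025),
                             stop_fold_change = 20,
                             codon_multipliers = c(AAA = 2, TGT = 0.5),
                             utr3_aug_fold = 3,
                             queued_fold = 10,
                             start_fold = 79 / 59,
                             length_mode_ssu40 = 32L,
                             length_mode_ribo80 = 28L,
                             length_spread = 2,
                             minor_21nt_fraction = 0.05,
                             queued_offset = 46L,
                             satellite_probs = c(0.2, 0.6, 0.2),
                             frame0_fraction = 0.9,
                             penultimate_design = c("balanced", "random"),
                             utr3_aug_frac = 0.5,
                             expression_sdlog = 0,
                             seed = 1L) {
  penultimate_design <- match.arg(penultimate_design)
  for (w in list(weights_ssu40, weights_ribo80)) {
    if (any(w < 0)) abort("component weights must be >= 0")
    if (abs(sum(w) - 1) > 1e-8) abort("component weights must sum to 1")
    if (!all(component_names() %in% names(w))) {
      abort(sprintf("weights need components %s",
                    paste(component_names(), collapse = ", ")))
    }
  }
  if (reads_per_sample <= 0) abort("reads_per_sample must be positive")
  if (diff(utr5_range) < 0 || diff(cds_range) < 0 || diff(utr3_range) < 0 ||
      cds_range[1] < 9) {
    abort("infeasible length ranges")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

component_names <- function() {
  c("utr5", "start", "orf", "stop", "utr3", "utr3_aug", "queued")
}

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# replace the G of any ATG occurrence until none remain
scrub_atg <- function(s) {
  repeat {
    hit <- regexpr("ATG", s, fixed = TRUE)
    if (hit < 0L) return(s)
    substr(s, hit + 2L, hit + 2L) <- sample(c("A", "C", "T"), 1L)
  }
}

#' Generate a synthetic transcriptome with recorded ground truth
#'
#' Builds `n_genes` random transcripts with valid start and stop
#' codons. CDSs are concatenations of random sense codons (so no
#' in-frame internal stops), the penultimate codon follows the
#' configured design, and a fraction of genes receives a planted 3'UTR
#' dORF (an AUG followed by two sense codons and a TAA) at a recorded
#' position, with accidental 3'UTR AUGs scrubbed so the planted
#' positions are exhaustive ground truth. Deterministic per
#' `(config, seed)`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return A list with `ann` (a `ribo_annotation` tibble) and `truth`
#'   (a tibble with per-gene `expression`, `penultimate`,
#'   `multiplier`, `utr3_aug_pos`, `dorf_stop_pos`).
#' @export
generate_transcriptome <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(as.integer(seed %||% cfg$seed), {
    n <- cfg$n_genes
    utr5 <- sample(seq.int(cfg$utr5_range[1], cfg$utr5_range[2]), n, replace = TRUE)
    utr3 <- sample(seq.int(cfg$utr3_range[1], cfg$utr3_range[2]), n, replace = TRUE)
    n_codons <- sample(seq.int(cfg$cds_range[1] %/% 3L, cfg$cds_range[2] %/% 3L),
                       n, replace = TRUE)
    codons <- sense_codons()
    pen <- if (cfg$penultimate_design == "balanced") {
      rep_len(codons, n)
    } else {
      sample(codons, n, replace = TRUE)
    }
    mult <- rep(1, n)
    hit <- pen %in% names(cfg$codon_multipliers)
    mult[hit] <- unname(cfg$codon_multipliers[pen[hit]])

    has_aug <- seq_len(n) %in% sample.int(n, round(cfg$utr3_aug_frac * n))
    aug_pos <- rep(NA_integer_, n)

    rows <- purrr::map(seq_len(n), function(i) {
      body <- if (n_codons[i] > 2L) {
        paste(sample(codons, n_codons[i] - 2L, replace = TRUE), collapse = "")
      } else ""
      cds <- paste0("ATG", body, pen[i], sample(c("TAA", "TAG", "TGA"), 1L))
      cds_len <- nchar(cds)   # (n_codons + 1) codons incl. stop
      u5 <- random_dna(utr5[i])
      u3 <- scrub_atg(random_dna(utr3[i]))
      if (has_aug[i] && utr3[i] >= 40L) {
        # plant a 9-nt dORF (ATG + 2 sense codons + TAA) mid-3'UTR and
        # scrub any ATG the junctions may have created
        at <- sample(seq.int(15L, utr3[i] - 23L), 1L)
        dorf <- paste0("ATG", sample(codons, 1L), "TAA")   # 9-nt dORF
        u3 <- paste0(substr(u3, 1L, at - 1L), dorf,
                     substr(u3, at + 9L, utr3[i]))
        repeat {
          hits <- gregexpr("ATG", u3, fixed = TRUE)[[1]]
          stray <- hits[hits > 0L & hits != at]
          if (length(stray) == 0L) break
          substr(u3, stray[1] + 2L, stray[1] + 2L) <- sample(c("A", "C", "T"), 1L)
        }
        aug_pos[i] <<- utr5[i] + cds_len + at - 1L   # 0-based transcript pos
      }
      tibble(gene_id = sprintf("SYN%04d", i),
             utr5_len = utr5[i], cds_len = cds_len, utr3_len = utr3[i],
             sequence = paste0(u5, cds, u3))
    }) |> bind_rows()

    expression <- if (cfg$expression_sdlog > 0) {
      stats::rlnorm(n, 0, cfg$expression_sdlog)
    } else rep(1, n)
    expression <- expression / sum(expression)

    ann <- annotation_tbl(rows$gene_id, rows$utr5_len, rows$cds_len,
                          rows$utr3_len, rows$sequence)
    truth <- tibble(
      gene_id = rows$gene_id,
      expression = expression,
      penultimate = pen,
      multiplier = mult,
      utr3_aug_pos = aug_pos,
      dorf_stop_pos = ifelse(is.na(aug_pos), NA_integer_, aug_pos + 6L)
    )
    list(ann = ann, truth = truth)
  })
}

# per-gene x component probability matrix for one genotype and assay
genotype_weights <- function(cfg, truth, genotype, assay) {
  base <- if (assay == "ssu40") cfg$weights_ssu40 else cfg$weights_ribo80
  base <- base[component_names()]
  n <- nrow(truth)
  W <- outer(truth$expression, base)          # rows genes, cols components
  colnames(W) <- component_names()
  has_aug <- !is.na(truth$utr3_aug_pos)
  if (!any(has_aug)) W[, "utr3_aug"] <- 0
  W[!has_aug, "utr3_aug"] <- 0
  # keep total utr3_aug mass at its configured share among eligible genes
  s <- sum(W[, "utr3_aug"])
  if (s > 0) W[, "utr3_aug"] <- W[, "utr3_aug"] * (base["utr3_aug"] / s)
  W <- W / sum(W)

  if (genotype == "wt") return(W)
  if (genotype == "rpl11b_d") {
    boosted <- W[, "start"] * cfg$start_fold
    other <- setdiff(component_names(), "start")
    scale <- (1 - sum(boosted)) / sum(W[, other])
    if (scale <= 0) abort("start_fold too large for the configured weights")
    W[, other] <- W[, other] * scale
    W[, "start"] <- boosted
    return(W)
  }
  if (genotype == "tma_dd") {
    if (assay == "ssu40") {
      # the unrecycled 40S accumulates on stop codons
      stop_b <- W[, "stop"] * cfg$stop_fold_change * truth$multiplier
      queued_b <- W[, "queued"]
    } else {
      # 80S libraries show queuing behind the stalled 40S, not a
      # 20-fold stop peak of their own
      stop_b <- W[, "stop"]
      queued_b <- W[, "queued"] * cfg$queued_fold
    }
    aug_b <- W[, "utr3_aug"] * cfg$utr3_aug_fold
    other <- setdiff(component_names(), c("stop", "utr3_aug", "queued"))
    boosted_total <- sum(stop_b) + sum(aug_b) + sum(queued_b)
    if (boosted_total >= 1) {
      abort("boosted stop/queued mass exceeds the library; lower stop_fold_change or the stop weight")
    }
    scale <- (1 - boosted_total) / sum(W[, other])
    W[, other] <- W[, other] * scale
    W[, "stop"] <- stop_b
    W[, "utr3_aug"] <- aug_b
    W[, "queued"] <- queued_b
    return(W)
  }
  abort(sprintf("unknown genotype '%s'", genotype))
}

draw_lengths <- function(n, cfg, assay) {
  mode <- if (assay == "ssu40") cfg$length_mode_ssu40 else cfg$length_mode_ribo80
  len <- mode + as.integer(round(rnorm(n, 0, cfg$length_spread)))
  minor <- runif(n) < cfg$minor_21nt_fraction
  len[minor] <- 21L + sample(c(-1L, 0L, 1L), sum(minor), replace = TRUE)
  pmin(pmax(len, 15L), 80L)
}

#' Simulate a footprint library for one genotype
#'
#' Draws `cfg$reads_per_sample` footprints from the per-gene,
#' per-component occupancy mixture of the requested genotype (see
#' [synthetic_config()]), with fixed 5' ends for stalled components
#' and stochastic lengths (3'-end variability only). Returns the
#' footprints, the corresponding [profile_set()], and the realized
#' per-gene component tallies as ground truth.
#'
#' @param ann Annotation from [generate_transcriptome()].
#' @param truth Ground-truth tibble from [generate_transcriptome()].
#' @param cfg A [synthetic_config()].
#' @param genotype `"wt"`, `"tma_dd"` or `"rpl11b_d"`.
#' @param assay `"ssu40"` or `"ribo80"`.
#' @param seed Seed for this library (default derives from
#'   `cfg$seed`).
#' @return A list with `footprints`, `profile` and `tallies` (tibble
#'   `gene_id`, `component`, `count`).
#' @export
simulate_footprints <- function(ann, truth, cfg,
                                genotype = c("wt", "tma_dd", "rpl11b_d"),
                                assay = c("ssu40", "ribo80"),
                                seed = NULL) {
  genotype <- match.arg(genotype)
  assay <- match.arg(assay)
  stopifnot(inherits(cfg, "synthetic_config"))
  seed <- as.integer(seed %||% (cfg$seed + match(genotype, c("wt", "tma_dd", "rpl11b_d")) * 101L +
                                  match(assay, c("ssu40", "ribo80"))))
  withr::with_seed(seed, {
    W <- genotype_weights(cfg, truth, genotype, assay)
    n_cells <- length(W)
    counts <- as.vector(stats::rmultinom(1, size = cfg$reads_per_sample, prob = as.vector(W)))
    cell_gene <- rep(seq_len(nrow(W)), times = ncol(W))
    cell_comp <- rep(colnames(W), each = nrow(W))
    nz <- counts > 0
    gene_idx <- rep(cell_gene[nz], counts[nz])
    comp <- rep(cell_comp[nz], counts[nz])
    n <- length(gene_idx)

    coords <- ann_coords(ann)
    A <- coords$start_nt[gene_idx]
    S <- coords$stop_nt[gene_idx]
    L <- coords$tx_len[gene_idx]
    shift <- assay_shift(assay)
    len <- draw_lengths(n, cfg, assay)
    fp <- integer(n)

    is <- comp == "start"
    fp[is] <- A[is] - shift
    is <- comp == "stop"
    fp[is] <- S[is] - shift
    is <- comp == "utr5"
    if (any(is)) fp[is] <- floor(runif(sum(is), 0, pmax(A[is], 1)))
    is <- comp == "utr3"
    if (any(is)) fp[is] <- S[is] + 3L + floor(runif(sum(is), 0, pmax(L[is] - (S[is] + 3L), 1)))
    is <- comp == "utr3_aug"
    if (any(is)) {
      aug <- truth$utr3_aug_pos[gene_idx[is]]
      fp[is] <- aug - shift
    }
    is <- comp == "queued"
    if (any(is)) {
      jit <- sample(c(-3L, 0L, 3L), sum(is), replace = TRUE, prob = cfg$satellite_probs)
      fp[is] <- S[is] - cfg$queued_offset + jit
    }
    is <- comp == "orf"
    if (any(is)) {
      m <- sum(is)
      if (assay == "ribo80") {
        # elongating ribosomes: shifted P site on a codon start with
        # probability frame0_fraction
        n_cod <- (S[is] - A[is]) %/% 3L
        k <- floor(runif(m, 0, pmax(n_cod, 1)))
        frame <- ifelse(runif(m) < cfg$frame0_fraction, 0L,
                        sample(c(1L, 2L), m, replace = TRUE))
        fp[is] <- A[is] + 3L * k + frame - shift
      } else {
        fp[is] <- A[is] + floor(runif(m, 0, pmax(S[is] - A[is], 1)))
      }
    }

    fp <- pmax(fp, 0L)
    len <- pmin(len, L - fp)
    keep <- len >= 15L
    out <- tibble(gene_id = coords$gene_id[gene_idx[keep]],
                  five_prime = as.integer(fp[keep]),
                  length = as.integer(len[keep]),
                  weight = 1L)
    tallies <- tibble(gene_id = coords$gene_id[gene_idx[keep]],
                      component = comp[keep]) |>
      count(gene_id, component, name = "count")
    list(
      footprints = out,
      profile = profile_set(out, sample = paste(genotype, assay, sep = "_"),
                            assay = assay),
      tallies = tallies
    )
  })
}

#' Render footprints as a FASTQ library with linkers, UMIs and planted
#' PCR duplicates
#'
#' Each footprint becomes a read laid out as
#' `2-nt RT UMI | insert | 5-nt UMI | 5-nt barcode | linker`, with the
#' insert taken from the transcript sequence. After rendering,
#' `round(duplicate_rate * n)` reads are resampled and appended as
#' exact PCR copies. The returned truth counts record, per sample, the
#' realized number of distinct (insert, UMI) keys — at peak positions
#' many reads share an insert, so random 7-nt UMIs can collide and the
#' distinct-key count is the quantity a perfect deduplicator recovers.
#'
#' @param fp Footprint tibble (`gene_id`, `five_prime`, `length`).
#' @param ann A `ribo_annotation` tibble.
#' @param spec A [linker_spec()]; `sample_name` must be one of its
#'   samples.
#' @param sample_name Sample (barcode) to emit the reads under.
#' @param duplicate_rate Fraction of planted PCR duplicates.
#' @param path Optional FASTQ output path; when `NULL` only the read
#'   tibble is returned.
#' @param seed RNG seed.
#' @return A list with `reads` (tibble `read_id`, `seq`, `qual`),
#'   `truth` (tibble `sample`, `n_reads`, `n_unique`), and `path`.
#' @export
emit_fastq <- function(fp, ann, spec, sample_name = names(spec$barcode_map)[1],
                       duplicate_rate = 0, path = NULL, seed = 1L) {
  stopifnot(inherits(spec, "linker_spec"))
  if (!sample_name %in% names(spec$barcode_map)) {
    abort(sprintf("sample '%s' not in the barcode map", sample_name))
  }
  withr::with_seed(as.integer(seed), {
    a <- as_tibble(ann)
    seqs <- setNames(a$sequence, a$gene_id)
    insert <- substr(seqs[fp$gene_id], fp$five_prime + 1L,
                     fp$five_prime + fp$length)
    n <- length(insert)
    rand_dna <- function(n, k) {
      m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    umi3 <- rand_dna(n, spec$umi3_len)
    umi5 <- rand_dna(n, spec$umi5_len)
    barcode <- unname(spec$barcode_map[sample_name])
    seq <- paste0(umi5, insert, umi3, barcode, spec$linker_constant)
    n_dup <- round(duplicate_rate * n)
    dup_idx <- if (n_dup > 0) sample.int(n, n_dup, replace = TRUE) else integer(0)
    all_seq <- c(seq, seq[dup_idx])
    reads <- tibble(
      read_id = sprintf("%s_read%06d", sample_name, seq_along(all_seq)),
      seq = all_seq,
      qual = strrep("I", nchar(all_seq))
    )
    n_unique <- dplyr::n_distinct(paste(insert, umi3, umi5, sep = "\r"))
    truth <- tibble(sample = sample_name, n_reads = nrow(reads),
                    n_unique = n_unique)
    if (!is.null(path)) write_fastq(reads, path)
    list(reads = reads, truth = truth, path = path)
  })
}

#' Write the synthetic annotation as GFF3 + FASTA + UTR table
#'
#' Emits the file set [load_annotation()] consumes: one contig per
#' transcript holding the full transcript sequence, a GFF3 with the
#' CDS feature placed after the 5'UTR, and the tab-separated UTR
#' length table. Useful for round-trip tests of the annotation loader.
#'
#' @param ann A `ribo_annotation` tibble.
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths.
#' @export
write_annotation_files <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- as_tibble(ann)
  fasta <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "cds.gff3")
  utr <- file.path(dir, "utr.tsv")
  seqs <- Biostrings::DNAStringSet(a$sequence)
  names(seqs) <- a$gene_id
  Biostrings::writeXStringSet(seqs, fasta)
  lines <- c("##gff-version 3",
             sprintf("%s\tribo40s\tCDS\t%d\t%d\t.\t+\t0\tID=%s_CDS;Parent=%s",
                     a$gene_id, a$utr5_len + 1L, a$utr5_len + a$cds_len,
                     a$gene_id, a$gene_id))
  writeLines(lines, gff)
  readr::write_tsv(tibble(gene_id = a$gene_id, utr5_len = a$utr5_len,
                          utr3_len = a$utr3_len,
                          utr5_intron = a$utr5_intron), utr)
  list(fasta = fasta, gff = gff, utr = utr)
}
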