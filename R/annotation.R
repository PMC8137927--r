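#' Transcript annotation tables
#'
#' The annotation is a tibble with one row per transcript and columns:
#'
#' * `gene_id` — unique transcript/gene identifier.
#' * `utr5_len`, `cds_len`, `utr3_len` — region lengths in nucleotides.
#'   The CDS length includes the stop codon (yeast GFF convention), so
#'   the first nucleotide of the stop codon sits at
#'   `utr5_len + cds_len - 3` in 0-based transcript coordinates.
#' * `sequence` — the full transcript sequence (5'UTR + spliced CDS +
#'   3'UTR) over `A/C/G/T`.
#' * `dubious`, `overlaps_other`, `utr5_intron` — exclusion flags.
#'
#' Transcript coordinates are 0-based throughout the package; position 0
#' is the first nucleotide of the annotated 5'UTR.
#'
#' @param gene_id Character vector of unique identifiers.
#' @param utr5_len,cds_len,utr3_len Integer region lengths (nt).
#' @param sequence Character vector of transcript sequences.
#' @param dubious,overlaps_other,utr5_intron Logical exclusion flags.
#' @return A tibble of class `ribo_annotation`.
#' @export
#' @examples
#' annotation_tbl("G1", 12, 9, 10,
#'                paste0(strrep("A", 12), "ATGAAATAA", strrep("C", 10)))
annotation_tbl <- function(gene_id, utr5_len, cds_len, utr3_len, sequence,
                           dubious = FALSE, overlaps_other = FALSE,
                           utr5_intron = FALSE) {
  ann <- tibble(
    gene_id = as.character(gene_id),
    utr5_len = as.integer(utr5_len),
    cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    sequence = toupper(as.character(sequence)),
    dubious = rep_len(as.logical(dubious), length(gene_id)),
    overlaps_other = rep_len(as.logical(overlaps_other), length(gene_id)),
    utr5_intron = rep_len(as.logical(utr5_intron), length(gene_id))
  )
  class(ann) <- c("ribo_annotation", class(tibble()))
  validate_annotation(ann)
  ann
}

#' Check annotation invariants
#'
#' Asserts that region lengths sum to the sequence length, that every
#' CDS is at least two codons long and a multiple of 3, that gene ids
#' are unique, and that the last CDS codon is a stop codon
#' (TAA/TAG/TGA). The start context is not constrained to AUG because
#' near-cognate starts occur.
#'
#' @param ann An annotation tibble.
#' @return `ann`, invisibly; errors describe the first offending gene.
#' @export
validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  if (nrow(ann) == 0L) return(invisible(ann))
  if (anyDuplicated(ann$gene_id)) {
    abort("annotation gene_ids must be unique")
  }
  bad <- nchar(ann$sequence) != ann$utr5_len + ann$cds_len + ann$utr3_len
  if (any(bad)) {
    abort(sprintf("sequence length does not match region lengths for gene '%s'",
                  ann$gene_id[which(bad)[1]]))
  }
  bad <- ann$cds_len < 6L | ann$cds_len %% 3L != 0L
  if (any(bad)) {
    abort(sprintf("CDS length must be >= 6 and divisible by 3 (gene '%s')",
                  ann$gene_id[which(bad)[1]]))
  }
  stop_codon <- substr(ann$sequence,
                       ann$utr5_len + ann$cds_len - 2L,
                       ann$utr5_len + ann$cds_len)
  bad <- !stop_codon %in% c("TAA", "TAG", "TGA")
  if (any(bad)) {
    abort(sprintf("CDS of gene '%s' does not end in a stop codon (got '%s')",
                  ann$gene_id[which(bad)[1]], stop_codon[which(bad)[1]]))
  }
  invisible(ann)
}

# 0-based anchor coordinates: start_nt = first nt of the start codon,
# stop_nt = first nt of the stop codon, tx_len = transcript length.
ann_coords <- function(ann) {
  tibble(
    gene_id = ann$gene_id,
    start_nt = ann$utr5_len,
    stop_nt = ann$utr5_len + ann$cds_len - 3L,
    tx_len = ann$utr5_len + ann$cds_len + ann$utr3_len
  )
}

#' Load a transcript annotation from GFF3 + UTR table + genome FASTA
#'
#' Builds the transcript coordinate frame used by every other stage.
#' CDS features are splice-joined per gene; flanking UTR sequence is
#' attached using the per-gene 5'/3'UTR lengths from `utr_table`, and
#' genes absent from the table get UTR lengths of 0. Genes whose summed
#' CDS length is not a multiple of 3 (or is shorter than two codons)
#' are skipped with a warning.
#'
#' Exclusion flags are populated from the annotation: a gene is marked
#' `dubious` when any of its features carries an `orf_classification`
#' qualifier equal to "Dubious", and `overlaps_other` when its genomic
#' span (CDS plus UTR extensions by default) intersects the span of
#' another gene on either strand. `utr5_intron` is read from an optional
#' fourth column of the UTR table.
#'
#' @param cds_file Path to a GFF3 file with CDS features. The gene key
#'   is taken from the `Parent`, `gene_id`, `Name` or `ID` attribute,
#'   in that order of preference.
#' @param utr_table Path to a tab-separated table with header columns
#'   `gene_id`, `utr5_len`, `utr3_len` and optionally `utr5_intron`.
#' @param fasta Path to the genome FASTA the GFF coordinates refer to.
#' @param utrs_in_overlap Should UTR extensions count when detecting
#'   overlapping genes? Default `TRUE`; the CDS-only alternative would
#'   silently admit antisense UTR overlaps.
#' @return A `ribo_annotation` tibble (see [annotation_tbl()]).
#' @export
load_annotation <- function(cds_file, utr_table, fasta, utrs_in_overlap = TRUE) {
  gff <- tryCatch(
    rtracklayer::import(cds_file),
    error = function(e) abort(sprintf("failed to parse GFF3 '%s': %s",
                                      cds_file, conditionMessage(e)))
  )
  genome <- tryCatch(
    Biostrings::readDNAStringSet(fasta),
    error = function(e) abort(sprintf("failed to parse FASTA '%s': %s",
                                      fasta, conditionMessage(e)))
  )
  names(genome) <- sub("\\s.*$", "", names(genome))
  utr <- read_utr_table(utr_table)

  mc <- S4Vectors::mcols(gff)
  key <- rep(NA_character_, length(gff))
  for (field in c("Parent", "gene_id", "Name", "ID")) {
    if (field %in% names(mc)) {
      v <- mc[[field]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
                    character(1))
      }
      v <- as.character(v)
      key[is.na(key) & !is.na(v)] <- v[is.na(key) & !is.na(v)]
    }
  }
  is_cds <- as.character(mc$type) == "CDS"
  if (!any(is_cds)) abort(sprintf("no CDS features found in '%s'", cds_file))

  dubious_ids <- character(0)
  if ("orf_classification" %in% names(mc)) {
    cls <- tolower(as.character(mc$orf_classification))
    dubious_ids <- unique(key[!is.na(cls) & cls == "dubious" & !is.na(key)])
  }

  cds <- gff[is_cds]
  cds_key <- key[is_cds]
  if (anyNA(cds_key)) abort(sprintf("CDS feature without a gene identifier in '%s'", cds_file))

  genes <- unique(cds_key)
  utr5 <- setNames(rep(0L, length(genes)), genes)
  utr3 <- setNames(rep(0L, length(genes)), genes)
  u5int <- setNames(rep(FALSE, length(genes)), genes)
  known <- utr$gene_id %in% genes
  if (any(!known)) {
    warn(sprintf("%d genes in the UTR table are absent from the GFF3 and were ignored",
                 sum(!known)))
  }
  utr5[utr$gene_id[known]] <- utr$utr5_len[known]
  utr3[utr$gene_id[known]] <- utr$utr3_len[known]
  u5int[utr$gene_id[known]] <- utr$utr5_intron[known]

  rows <- purrr::map(genes, function(g) {
    ex <- cds[cds_key == g]
    ex <- ex[order(GenomicRanges::start(ex))]
    chr <- as.character(GenomicRanges::seqnames(ex))[1]
    strand <- as.character(GenomicRanges::strand(ex))[1]
    if (!chr %in% names(genome)) {
      warn(sprintf("gene '%s' skipped: sequence '%s' absent from FASTA", g, chr))
      return(NULL)
    }
    chrseq <- genome[[chr]]
    cds_len <- sum(GenomicRanges::width(ex))
    if (cds_len < 6L || cds_len %% 3L != 0L) {
      warn(sprintf("gene '%s' skipped: CDS length %d not a multiple of 3", g, cds_len))
      return(NULL)
    }
    exon_seqs <- purrr::map(seq_along(ex), function(i) {
      Biostrings::subseq(chrseq, GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i])
    })
    spliced <- do.call(Biostrings::xscat, exon_seqs)
    u5 <- unname(utr5[g]); u3 <- unname(utr3[g])
    gstart <- min(GenomicRanges::start(ex))
    gend <- max(GenomicRanges::end(ex))
    # flanks in genomic orientation: on the minus strand the 5'UTR is
    # the right-hand flank and the 3'UTR the left-hand one
    left_len <- if (strand == "-") u3 else u5
    right_len <- if (strand == "-") u5 else u3
    left_rng <- c(gstart - left_len, gstart - 1L)
    right_rng <- c(gend + 1L, gend + right_len)
    clamp <- function(rng) c(max(rng[1], 1L), min(rng[2], Biostrings::nchar(chrseq)))
    grab <- function(rng, want) {
      if (want == 0L) return(Biostrings::DNAString(""))
      rng2 <- clamp(rng)
      if (rng2[1] > rng2[2]) return(Biostrings::DNAString(""))
      Biostrings::subseq(chrseq, rng2[1], rng2[2])
    }
    left <- grab(left_rng, left_len); right <- grab(right_rng, right_len)
    full <- Biostrings::xscat(left, spliced, right)
    if (strand == "-") full <- Biostrings::reverseComplement(full)
    got_u5 <- if (strand == "-") Biostrings::nchar(right) else Biostrings::nchar(left)
    got_u3 <- if (strand == "-") Biostrings::nchar(left) else Biostrings::nchar(right)
    if (got_u5 != u5 || got_u3 != u3) {
      warn(sprintf("gene '%s': UTRs truncated at a contig boundary", g))
    }
    tibble(gene_id = g, utr5_len = as.integer(got_u5), cds_len = as.integer(cds_len),
           utr3_len = as.integer(got_u3), sequence = as.character(full),
           strand = strand, chr = chr, gstart = gstart, gend = gend)
  })
  rows <- bind_rows(rows)
  if (nrow(rows) == 0L) abort("no usable genes could be constructed from the annotation")

  # Overlap detection on genomic spans (either strand).
  span_start <- rows$gstart
  span_end <- rows$gend
  if (isTRUE(utrs_in_overlap)) {
    up <- ifelse(rows$strand == "-", rows$utr3_len, rows$utr5_len)
    dn <- ifelse(rows$strand == "-", rows$utr5_len, rows$utr3_len)
    span_start <- pmax(span_start - up, 1L)
    span_end <- span_end + dn
  }
  spans <- GenomicRanges::GRanges(rows$chr,
                                  IRanges::IRanges(span_start, span_end))
  hits <- GenomicRanges::countOverlaps(spans, spans, ignore.strand = TRUE)
  overlaps <- hits > 1L

  annotation_tbl(
    gene_id = rows$gene_id,
    utr5_len = rows$utr5_len,
    cds_len = rows$cds_len,
    utr3_len = rows$utr3_len,
    sequence = rows$sequence,
    dubious = rows$gene_id %in% dubious_ids,
    overlaps_other = overlaps,
    utr5_intron = unname(u5int[rows$gene_id])
  )
}

read_utr_table <- function(path) {
  utr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "utr5_len", "utr3_len")
  if (!all(need %in% names(utr))) {
    abort(sprintf("UTR table '%s' must have header columns %s",
                  path, paste(need, collapse = ", ")))
  }
  probs <- readr::problems(utr)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed UTR table '%s' at line %d: %s",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  if (!"utr5_intron" %in% names(utr)) utr$utr5_intron <- FALSE
  bad <- !is.finite(utr$utr5_len) | !is.finite(utr$utr3_len) |
    utr$utr5_len < 0 | utr$utr3_len < 0
  if (any(bad)) {
    abort(sprintf("malformed UTR table '%s' at line %d: negative or missing UTR length",
                  path, which(bad)[1] + 1L))
  }
  mutate(utr,
         utr5_len = as.integer(.data$utr5_len),
         utr3_len = as.integer(.data$utr3_len),
         utr5_intron = as.logical(.data$utr5_intron))
}

#' Genes retained for downstream analysis
#'
#' Dubious ORFs and genes overlapping another transcript are always
#' excluded. Genes with a 5'UTR intron are additionally excluded for
#' quantitation and for motif position averages, where the intron makes
#' transcript-coordinate windows unreliable.
#'
#' @param ann A `ribo_annotation` tibble.
#' @param purpose `"quantitation"` or `"metacodon"`.
#' @return Sorted character vector of gene ids.
#' @export
usable_genes <- function(ann, purpose = c("quantitation", "metacodon")) {
  purpose <- match.arg(purpose)
  keep <- !ann$dubious & !ann$overlaps_other & !ann$utr5_intron
  sort(ann$gene_id[keep])
}

#' Write / read the consolidated annotation cache
#'
#' A single tab-separated file (documented header: `gene_id`,
#' `utr5_len`, `cds_len`, `utr3_len`, `dubious`, `overlaps_other`,
#' `utr5_intron`, `sequence`) holding everything [load_annotation()]
#' derives, for fast reuse.
#'
#' @param ann A `ribo_annotation` tibble.
#' @param path File path.
#' @return `write_annotation()` returns `path` invisibly;
#'   `read_annotation()` returns a `ribo_annotation` tibble.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(as_tibble(ann)[, c("gene_id", "utr5_len", "cds_len", "utr3_len",
                                      "dubious", "overlaps_other", "utr5_intron",
                                      "sequence")], path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  annotation_tbl(x$gene_id, x$utr5_len, x$cds_len, x$utr3_len, x$sequence,
                 x$dubious, x$overlaps_other, x$utr5_intron)
}
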