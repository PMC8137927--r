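#' Read aligned footprints in transcript coordinates
#'
#' Footprints enter the analysis already aligned in transcript space,
#' either as a BED-like tab-separated table (columns `gene_id`,
#' 0-based `start`, half-open `end`, `read_id`; no header) or as
#' SAM/BAM whose reference sequences are transcripts. One footprint is
#' produced per primary alignment; multimapping reads are expected to
#' have been excluded by the aligner, and every footprint carries
#' weight 1. Alignments to genes absent from the annotation are
#' dropped and counted, and the per-assay size filter is re-applied.
#'
#' @param path Alignment file. Format is chosen by extension
#'   (`.bed`-like text vs `.sam`/`.bam`) unless `format` is given.
#' @param ann A `ribo_annotation` tibble.
#' @param assay `"ssu40"` or `"ribo80"` (sets the size filter).
#' @param format `"bed"`, `"sam"` or `"bam"`; default guesses from the
#'   file extension.
#' @return A tibble with columns `gene_id`, `five_prime` (0-based),
#'   `length`, `weight`, plus attribute `"n_dropped"` (unknown gene or
#'   size-filtered counts).
#' @export
read_footprints <- function(path, ann, assay = c("ssu40", "ribo80"),
                            format = NULL) {
  assay <- match.arg(assay)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               sam = "sam", bam = "bam", "bed")
  fp <- switch(format,
    bed = read_footprints_bed(path),
    sam = ,
    bam = read_footprints_sam(path, format),
    abort(sprintf("unknown alignment format '%s'", format))
  )
  coords <- ann_coords(ann)
  known <- fp$gene_id %in% coords$gene_id
  rng <- if (assay == "ssu40") ribo40s_defaults()$size_range_ssu40
         else ribo40s_defaults()$size_range_ribo80
  in_size <- fp$length >= rng[1] & fp$length <= rng[2]
  out <- fp[known & in_size, c("gene_id", "five_prime", "length")]
  out$weight <- 1L
  bad_coord <- left_join(out, coords, by = "gene_id") |>
    with(five_prime < 0L | five_prime + length > tx_len)
  if (any(bad_coord)) {
    abort(sprintf("alignment record %d extends outside its transcript",
                  which(bad_coord)[1]))
  }
  attr(out, "n_dropped") <- c(unknown_gene = sum(!known),
                              size_filtered = sum(known & !in_size))
  out
}

read_footprints_bed <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("gene_id", "start", "end", "read_id"),
                       col_types = "ciic", progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed footprint record at line %d of '%s'",
                  probs$row[1], path))
  }
  if (any(x$end <= x$start)) {
    abort(sprintf("malformed footprint record at line %d of '%s': end <= start",
                  which(x$end <= x$start)[1], path))
  }
  tibble(gene_id = x$gene_id,
         five_prime = as.integer(x$start),
         length = as.integer(x$end - x$start))
}

read_footprints_sam <- function(path, format) {
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble(gene_id = as.character(a$rname),
         five_prime = as.integer(a$pos) - 1L,
         length = as.integer(a$qwidth))
}

#' Write footprints in the BED-like transcript-space dialect
#'
#' @param fp Footprint tibble (`gene_id`, `five_prime`, `length`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_footprints <- function(fp, path) {
  readr::write_tsv(
    tibble(gene_id = fp$gene_id,
           start = fp$five_prime,
           end = fp$five_prime + fp$length,
           read_id = sprintf("fp%07d", seq_len(nrow(fp)))),
    path, col_names = FALSE)
  invisible(path)
}

#' Shift footprint 5' ends to the P site
#'
#' Adds the assay-specific P-site offset (14 nt for 40S, 13 nt for 80S,
#' 0 for `"none"`) to 5'-end positions. Positions shifted beyond the
#' transcript are retained; callers decide whether windows include
#' them, and [shift_footprints()] flags them.
#'
#' @param five_prime Integer vector of 0-based 5'-end positions (or a
#'   footprint tibble for [shift_footprints()]).
#' @param assay `"ssu40"`, `"ribo80"` or `"none"`.
#' @return Shifted integer positions.
#' @export
#' @examples
#' psite_shift(0L, "ribo80")  # 13
psite_shift <- function(five_prime, assay = c("ssu40", "ribo80", "none")) {
  assay <- match.arg(assay)
  as.integer(five_prime) + assay_shift(assay)
}

#' @rdname psite_shift
#' @param fp Footprint tibble.
#' @param ann Annotation tibble, used to flag shifted positions that
#'   fall beyond the transcript end.
#' @export
shift_footprints <- function(fp, assay = c("ssu40", "ribo80", "none"), ann = NULL) {
  assay <- match.arg(assay)
  fp$psite <- psite_shift(fp$five_prime, assay)
  if (!is.null(ann)) {
    fp <- left_join(fp, ann_coords(ann)[, c("gene_id", "tx_len")], by = "gene_id")
    fp$psite_out_of_tx <- fp$psite >= fp$tx_len
    fp$tx_len <- NULL
  }
  fp
}

#' Bundle footprints into a per-sample profile
#'
#' A profile set holds one sample's footprints together with the
#' normalization denominator used for rpm scaling: the total number of
#' retained footprints mapped to annotated transcripts in that sample.
#'
#' @param fp Footprint tibble (`gene_id`, `five_prime`, `length`,
#'   optional `weight`).
#' @param sample Sample name.
#' @param assay `"ssu40"`, `"ribo80"` or `"none"`.
#' @param total_mapped Override for the rpm denominator; defaults to
#'   the summed footprint weight.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(fp, sample, assay = c("ssu40", "ribo80", "none"),
                        total_mapped = NULL) {
  assay <- match.arg(assay)
  if (!"weight" %in% names(fp)) fp$weight <- 1L
  total <- total_mapped %||% sum(fp$weight)
  if (total <= 0) abort("profile_set needs a positive total_mapped for rpm scaling")
  structure(
    list(sample = sample, assay = assay,
         footprints = as_tibble(fp), total_mapped = total),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> sample '%s', assay %s: %d footprints on %d genes (total_mapped %s)\n",
              x$sample, x$assay, nrow(x$footprints),
              dplyr::n_distinct(x$footprints$gene_id),
              format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' Per-transcript 5'-end count track
#'
#' Returns the per-nucleotide count vector of footprint end positions
#' for one gene, optionally P-site-shifted, as used by the metagene and
#' position-average machinery.
#'
#' @param profile A [profile_set()].
#' @param gene Gene id.
#' @param ann Annotation tibble.
#' @param end Which footprint end to count, `"five_prime"` or
#'   `"three_prime"` (last protected nucleotide).
#' @param shift Apply the assay P-site shift to 5' ends first?
#' @return Numeric vector of length `tx_len` (counts; positions beyond
#'   the transcript are dropped).
#' @export
track_counts <- function(profile, gene, ann, end = c("five_prime", "three_prime"),
                         shift = FALSE) {
  end <- match.arg(end)
  coords <- ann_coords(ann)
  L <- coords$tx_len[coords$gene_id == gene]
  if (length(L) != 1L) abort(sprintf("gene '%s' not in annotation", gene))
  fp <- profile$footprints[profile$footprints$gene_id == gene, ]
  pos <- if (end == "five_prime") fp$five_prime else fp$five_prime + fp$length - 1L
  if (shift) pos <- psite_shift(pos, profile$assay)
  ok <- pos >= 0L & pos < L
  if (all(fp$weight == 1L)) {
    as.numeric(tabulate(pos[ok] + 1L, nbins = L))
  } else {
    vapply(seq_len(L) - 1L,
           function(p) sum(fp$weight[ok][pos[ok] == p]), numeric(1))
  }
}
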