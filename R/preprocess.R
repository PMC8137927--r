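#' Describe the 3'-linker / barcode / UMI layout of a library
#'
#' Footprint libraries built with the dual-UMI protocol carry, on each
#' sequenced read: a randomized 2-nt UMI contributed by the RT primer at
#' the very 5' end, the footprint insert, a randomized 5-nt UMI, a 5-nt
#' internal sample barcode, and finally the constant linker sequence.
#' The two UMI segments together form the 7-nt key used for
#' PCR-duplicate removal.
#'
#' @param linker_constant Constant 3'-linker sequence (DNA string).
#' @param barcode_map Named character vector mapping each 5-nt barcode
#'   to a sample name (`c(sample = "ACGTA", ...)` or the reverse; names
#'   are the sample names, values the barcodes).
#' @param umi3_len,umi5_len Lengths of the linker-side and RT-side UMI
#'   segments. Their sum must be 7.
#' @return A list of class `linker_spec`.
#' @export
#' @examples
#' linker_spec(barcode_map = c(wt = "ACGTA", mut = "TGCAT"))
linker_spec <- function(linker_constant = "AGATCGGAAGAGCAC",
                        barcode_map = c(sample1 = "ACGTA"),
                        umi3_len = 5L, umi5_len = 2L) {
  barcode_map <- toupper(barcode_map)
  if (anyDuplicated(barcode_map)) abort("barcodes must be unique")
  if (is.null(names(barcode_map)) || any(names(barcode_map) == "")) {
    abort("barcode_map must be a named vector: c(sample = 'ACGTA', ...)")
  }
  if (length(unique(nchar(barcode_map))) != 1L) {
    abort("all barcodes must have the same length")
  }
  if (umi3_len + umi5_len != 7L) abort("umi3_len + umi5_len must equal 7")
  structure(
    list(linker_constant = toupper(linker_constant),
         barcode_map = barcode_map,
         barcode_len = unname(nchar(barcode_map[1])),
         umi3_len = as.integer(umi3_len),
         umi5_len = as.integer(umi5_len)),
    class = "linker_spec"
  )
}

#' Read / write FASTQ as a tibble
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] returning and
#' consuming a tibble with columns `read_id`, `seq`, `qual`.
#'
#' @param path FASTQ file path (plain or gzip).
#' @param reads Tibble with columns `read_id`, `seq` and optionally
#'   `qual` (a constant high quality is written when absent).
#' @return `read_fastq()` returns a tibble; `write_fastq()` returns
#'   `path` invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads) && !anyNA(reads$qual)) {
    reads$qual
  } else {
    strrep("I", nchar(reads$seq))
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

hamming_le <- function(a, b, k) {
  # TRUE where a and b (equal-length strings, vectorized over a) differ
  # at <= k positions
  if (k == 0L) return(a == b)
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE),
               nrow = length(a), byrow = TRUE)
  bm <- strsplit(b, "", fixed = TRUE)[[1]]
  rowSums(am != matrix(bm, nrow = length(a), ncol = length(bm), byrow = TRUE)) <= k
}

#' Trim linkers and demultiplex by sample barcode
#'
#' Strips the constant 3' linker from each read, assigns the read to a
#' sample via the 5-nt internal barcode, and concatenates the two UMI
#' segments (linker-side 5-mer first, then the RT-side 2-mer) into the
#' 7-nt UMI used downstream for duplicate collapse. Reads without a
#' recognizable linker, with an unknown barcode, or too short to
#' contain an insert are dropped and tallied.
#'
#' @param reads Tibble with columns `read_id`, `seq` (see
#'   [read_fastq()]).
#' @param spec A [linker_spec()].
#' @param max_linker_mismatch Number of mismatches tolerated in the
#'   constant linker suffix (default 0, exact match).
#' @return A tibble with columns `sample`, `read_id`, `insert`, `umi`.
#'   The attribute `"summary"` holds a tibble of per-category counts
#'   (one `assigned:<sample>` row per sample plus `no_linker`,
#'   `unknown_barcode`, `too_short`).
#' @export
demultiplex_trim <- function(reads, spec, max_linker_mismatch = 0L) {
  stopifnot(inherits(spec, "linker_spec"))
  lc <- spec$linker_constant
  lc_len <- nchar(lc)
  tail_len <- spec$umi3_len + spec$barcode_len + lc_len
  min_len <- spec$umi5_len + 1L + tail_len

  n <- nchar(reads$seq)
  long_enough <- n >= min_len
  suffix <- substr(reads$seq, n - lc_len + 1L, n)
  has_linker <- long_enough &
    hamming_le(ifelse(long_enough, suffix, strrep("N", lc_len)), lc,
               as.integer(max_linker_mismatch))

  barcode <- substr(reads$seq, n - lc_len - spec$barcode_len + 1L, n - lc_len)
  sample <- names(spec$barcode_map)[match(barcode, spec$barcode_map)]
  known <- !is.na(sample)

  keep <- has_linker & known
  umi3 <- substr(reads$seq, n - tail_len + 1L, n - tail_len + spec$umi3_len)
  umi5 <- substr(reads$seq, 1L, spec$umi5_len)
  insert <- substr(reads$seq, spec$umi5_len + 1L, n - tail_len)

  out <- tibble(
    sample = sample[keep],
    read_id = reads$read_id[keep],
    insert = insert[keep],
    umi = paste0(umi3[keep], umi5[keep])
  )
  summary <- bind_rows(
    count(out, sample, name = "count") |>
      mutate(category = paste0("assigned:", sample)) |>
      select(category, count),
    tibble(category = "too_short", count = sum(!long_enough)),
    tibble(category = "no_linker", count = sum(long_enough & !has_linker)),
    tibble(category = "unknown_barcode", count = sum(has_linker & !known))
  )
  attr(out, "summary") <- summary
  out
}

#' Collapse PCR duplicates by insert sequence and 7-nt UMI
#'
#' Within each sample, reads sharing an identical (insert, UMI) pair
#' are collapsed to the first occurrence; output order follows input
#' order, so the operation is deterministic and idempotent.
#'
#' Libraries built with the original (UMI-free) protocol should bypass
#' this step; the pipeline driver consults the per-sample `protocol`
#' field for that.
#'
#' @param reads Tibble with columns `sample`, `insert`, `umi` (from
#'   [demultiplex_trim()]).
#' @return The deduplicated tibble, with attribute `"n_removed"`.
#' @export
dedup_umi <- function(reads) {
  if (any(nchar(reads$umi) != 7L)) abort("UMIs must be exactly 7 nt")
  dup <- duplicated(paste(reads$sample, reads$insert, reads$umi, sep = "\r"))
  out <- reads[!dup, , drop = FALSE]
  attr(out, "summary") <- NULL
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Footprint size selection
#'
#' Retains inserts of 15-80 nt for 40S profiling and 25-34 nt for 80S
#' profiling (bounds inclusive).
#'
#' @param reads Tibble with an `insert` column (or a `length` column
#'   for already-aligned footprints).
#' @param assay `"ssu40"` or `"ribo80"`.
#' @return Filtered tibble with attribute `"n_discarded"`.
#' @export
size_select <- function(reads, assay = c("ssu40", "ribo80")) {
  assay <- match.arg(assay)
  rng <- if (assay == "ssu40") ribo40s_defaults()$size_range_ssu40
         else ribo40s_defaults()$size_range_ribo80
  len <- if ("insert" %in% names(reads)) nchar(reads$insert) else reads$length
  keep <- len >= rng[1] & len <= rng[2]
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_discarded") <- sum(!keep)
  out
}
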