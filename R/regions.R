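#' Assign footprints to transcript regions
#'
#' A footprint is assigned to the start codon if any portion of it
#' overlaps the 9-nt region centered on the start codon (the codon
#' plus 3 nt on each side), and otherwise to the stop codon if any
#' portion overlaps the 9-nt region whose 3' end is the last
#' nucleotide of the stop codon. Footprints touching neither window
#' are assigned to the region containing their unshifted 5' end
#' (5'UTR, ORF or 3'UTR, with the ORF spanning start through stop
#' codon inclusive). Start takes precedence over stop, which can only
#' matter for very short CDSs and is flagged when exercised.
#'
#' @param fp Footprint tibble (`gene_id`, `five_prime`, `length`).
#' @param ann A `ribo_annotation` tibble.
#' @return `fp` with an added factor column `region` with levels
#'   `UTR5`, `START`, `ORF`, `STOP`, `UTR3`.
#' @export
classify_region <- function(fp, ann) {
  coords <- ann_coords(ann)
  x <- left_join(fp, coords, by = "gene_id")
  if (anyNA(x$start_nt)) {
    abort(sprintf("footprint on gene '%s' absent from annotation",
                  x$gene_id[which(is.na(x$start_nt))[1]]))
  }
  A <- x$start_nt
  S <- x$stop_nt
  lo <- x$five_prime
  hi <- x$five_prime + x$length          # half-open end
  in_start <- lo < A + 6L & hi > A - 3L
  in_stop  <- lo < S + 3L & hi > S - 6L
  both <- in_start & in_stop
  if (any(both)) {
    inform(sprintf("%d footprints overlap both start and stop windows; assigned START",
                   sum(both)))
  }
  end_region <- dplyr::case_when(
    lo < A ~ "UTR5",
    lo < S + 3L ~ "ORF",
    TRUE ~ "UTR3"
  )
  region <- dplyr::case_when(
    in_start ~ "START",
    in_stop ~ "STOP",
    TRUE ~ end_region
  )
  fp$region <- factor(region, levels = region_levels())
  fp
}

region_levels <- function() c("UTR5", "START", "ORF", "STOP", "UTR3")

#' Proportion of footprints mapping to each transcript region
#'
#' Classifies footprints on the usable gene set and reports the count
#' and fraction of footprints per region (5'UTR, start codon, ORF,
#' stop codon, 3'UTR). Fractions are computed on counts and sum to 1.
#'
#' @param x A [profile_set()] or footprint tibble.
#' @param ann A `ribo_annotation` tibble.
#' @return A tibble with columns `region`, `count`, `fraction`.
#' @export
region_fractions <- function(x, ann) {
  fp <- if (inherits(x, "profile_set")) x$footprints else x
  fp <- fp[fp$gene_id %in% usable_genes(ann, "quantitation"), , drop = FALSE]
  if (!"weight" %in% names(fp)) fp$weight <- 1L
  fp <- classify_region(fp, ann)
  if (nrow(fp) == 0L || sum(fp$weight) == 0) {
    abort("no classifiable footprints on usable genes")
  }
  counts <- vapply(region_levels(),
                   function(r) sum(fp$weight[fp$region == r]), numeric(1))
  tibble(region = factor(region_levels(), levels = region_levels()),
         count = unname(counts),
         fraction = unname(counts) / sum(counts))
}

#' Footprint length histograms, optionally per region
#'
#' Counts footprints at each length from 15 to 80 nt, overall or split
#' by the transcript region they classify to.
#'
#' @param fp Footprint tibble.
#' @param ann A `ribo_annotation` tibble (needed when `by_region`).
#' @param by_region Split counts by region?
#' @return A tibble with columns `length`, `count` (and `region` when
#'   split); every length bin 15-80 is present, zero-filled.
#' @export
length_histogram <- function(fp, ann = NULL, by_region = FALSE) {
  lengths <- 15:80
  if (!"weight" %in% names(fp)) fp$weight <- 1L
  if (by_region) {
    if (is.null(ann)) abort("by_region = TRUE requires an annotation")
    fp <- classify_region(fp, ann)
    out <- fp |>
      group_by(region, length) |>
      summarise(count = sum(weight), .groups = "drop") |>
      tidyr::complete(region = factor(region_levels(), levels = region_levels()),
                      length = lengths, fill = list(count = 0)) |>
      arrange(region, length)
  } else {
    out <- fp |>
      group_by(length) |>
      summarise(count = sum(weight), .groups = "drop") |>
      tidyr::complete(length = lengths, fill = list(count = 0)) |>
      arrange(length)
  }
  filter(out, length >= 15L, length <= 80L)
}
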