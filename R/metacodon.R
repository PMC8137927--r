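#' Locate motif occurrences within UTRs
#'
#' Finds every exact occurrence of a motif inside the 5'UTR or 3'UTR
#' of each usable gene (genes with 5'UTR introns are removed). The
#' search is a plain substring scan, unconstrained by reading frame,
#' and occurrences may overlap. The special motif `"STOP"` searches
#' for TAA, TAG and TGA jointly. Occurrences must lie fully inside the
#' stated region.
#'
#' @param ann A `ribo_annotation` tibble.
#' @param motif DNA string (e.g. `"ATG"`), or `"STOP"`.
#' @param region `"UTR5"` or `"UTR3"`.
#' @return A tibble with columns `gene_id`, `position` (0-based
#'   transcript position of the motif's first nucleotide), `region`.
#' @export
motif_positions <- function(ann, motif, region = c("UTR5", "UTR3")) {
  region <- match.arg(region)
  motif <- toupper(motif)
  motifs <- if (identical(motif, "STOP")) c("TAA", "TAG", "TGA") else motif
  if (any(nchar(motifs) < 1L)) abort("motif length must be >= 1")
  genes <- usable_genes(ann, "metacodon")
  a <- as_tibble(ann) |> filter(gene_id %in% genes)
  if (nrow(a) == 0L) return(tibble(gene_id = character(), position = integer(),
                                   region = character()))
  # region substring bounds, 1-based within the transcript sequence
  from <- if (region == "UTR5") rep(1L, nrow(a)) else a$utr5_len + a$cds_len + 1L
  to <- if (region == "UTR5") a$utr5_len else a$utr5_len + a$cds_len + a$utr3_len
  sub <- substr(a$sequence, from, to)
  subs <- Biostrings::DNAStringSet(ifelse(to >= from, sub, ""))
  hits <- purrr::map(motifs, function(m) {
    mi <- Biostrings::vmatchPattern(m, subs)
    starts <- Biostrings::startIndex(mi)
    purrr::imap(starts, function(s, i) {
      if (is.null(s) || length(s) == 0L) return(NULL)
      tibble(gene_id = a$gene_id[i],
             position = s - 1L + (from[i] - 1L))
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(hits) == 0L) {
    return(tibble(gene_id = character(), position = integer(), region = character()))
  }
  hits |>
    mutate(region = region) |>
    distinct(gene_id, position, .keep_all = TRUE) |>
    arrange(gene_id, position)
}

#' Position-average ("metacodon") occupancy around motif occurrences
#'
#' Averages rpm-scaled, unshifted 5'-end counts in a window around
#' every motif occurrence. Occurrences whose window leaves the
#' transcript are dropped; genes with no reads in the occurrence's UTR
#' region are excluded; windows may extend into the CDS (set
#' `truncate_to_region` to clip them). With `normalize_to_orf`, each
#' gene's track is divided by its ORF rpkm and genes below
#' `min_orf_rpkm` are excluded.
#'
#' @param profile A [profile_set()].
#' @param ann A `ribo_annotation` tibble.
#' @param occurrences Tibble from [motif_positions()].
#' @param window `c(upstream_nt, downstream_nt)` around the motif's
#'   first nucleotide.
#' @param normalize_to_orf Divide by ORF density before averaging?
#' @param min_orf_rpkm ORF-density floor applied when normalizing.
#' @param truncate_to_region Drop window positions outside the
#'   occurrence's UTR region instead of letting them reach into the
#'   CDS.
#' @return A tibble with columns `offset`, `mean_value` (rpm, or
#'   rpm/orf_rpkm when normalized) and attribute `"n_occurrences"`.
#' @export
metacodon_average <- function(profile, ann, occurrences, window = c(50L, 50L),
                              normalize_to_orf = FALSE,
                              min_orf_rpkm = ribo40s_defaults()$min_orf_rpkm,
                              truncate_to_region = FALSE) {
  if (nrow(occurrences) == 0L) abort("no motif occurrences supplied")
  up <- window[1]; down <- window[2]
  coords <- ann_coords(ann)
  occ <- occurrences |>
    left_join(coords, by = "gene_id") |>
    filter(position - up >= 0L, position + down < tx_len)

  # exclude genes with no reads in the occurrence's UTR region
  fp <- profile$footprints
  fpx <- fp |> left_join(coords, by = "gene_id")
  utr5_reads <- fpx |> filter(five_prime < start_nt) |> distinct(gene_id)
  utr3_reads <- fpx |> filter(five_prime >= stop_nt + 3L) |> distinct(gene_id)
  occ <- occ |>
    filter((region == "UTR5" & gene_id %in% utr5_reads$gene_id) |
             (region == "UTR3" & gene_id %in% utr3_reads$gene_id))

  gene_scale <- NULL
  if (normalize_to_orf) {
    dens <- gene_densities(profile, ann)
    dens <- filter(dens, !is.na(orf_rpkm), orf_rpkm >= min_orf_rpkm)
    occ <- semi_join(occ, dens, by = "gene_id")
    gene_scale <- setNames(dens$orf_rpkm, dens$gene_id)
  }
  if (nrow(occ) == 0L) abort("all motif occurrences were filtered out")

  # sum 5'-end counts per (occurrence, offset) via a join on gene
  hits <- fp |>
    inner_join(occ |> mutate(.occ = row_number()) |>
                 select(gene_id, position, ".occ", region),
               by = "gene_id", relationship = "many-to-many") |>
    mutate(offset = five_prime - position) |>
    filter(offset >= -up, offset <= down)
  if (truncate_to_region) {
    hits <- hits |>
      left_join(coords, by = "gene_id") |>
      filter((region == "UTR5" & five_prime < start_nt) |
               (region == "UTR3" & five_prime >= stop_nt + 3L))
  }
  if (nrow(hits) > 0L && !is.null(gene_scale)) {
    hits <- mutate(hits, weight = weight / unname(gene_scale[gene_id]))
  }
  scale <- 1e6 / profile$total_mapped / nrow(occ)
  out <- hits |>
    group_by(offset) |>
    summarise(mean_value = sum(weight) * scale, .groups = "drop") |>
    tidyr::complete(offset = seq.int(-up, down), fill = list(mean_value = 0)) |>
    arrange(offset)
  attr(out, "n_occurrences") <- nrow(occ)
  out
}
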