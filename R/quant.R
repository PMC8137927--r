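#' Gene-level footprint densities (rpkm)
#'
#' Computes per-gene densities from P-site-shifted 5'-end positions.
#' The ORF window excludes the first and last 15 nt of the ORF (to
#' avoid initiation/termination pile-ups); the 3'UTR window runs from
#' the first nucleotide after the stop codon to 25 nt past the
#' annotated 3' end (so ribosomes partially protecting poly(A) are
#' captured); the 5'UTR window is the annotated 5'UTR. Densities are
#' reads per kilobase per million mapped (rpm divided by the window
#' length in kb); a region of non-positive length yields `NA` for that
#' gene and region.
#'
#' @param profile A [profile_set()].
#' @param ann A `ribo_annotation` tibble.
#' @param assay Override for the P-site shift; defaults to the
#'   profile's assay.
#' @return A tibble with columns `gene_id`, `orf_count`, `orf_rpkm`,
#'   `utr3_count`, `utr3_rpkm`, `utr5_count`, `utr5_rpkm` for usable
#'   genes.
#' @export
gene_densities <- function(profile, ann, assay = NULL) {
  assay <- assay %||% profile$assay
  d <- ribo40s_defaults()
  genes <- usable_genes(ann, "quantitation")
  coords <- ann_coords(ann) |>
    left_join(as_tibble(ann)[, c("gene_id", "utr3_len")], by = "gene_id") |>
    filter(gene_id %in% genes)

  fp <- profile$footprints |>
    filter(gene_id %in% genes) |>
    mutate(psite = psite_shift(five_prime, assay)) |>
    left_join(coords, by = "gene_id")

  trim <- d$orf_end_trim
  ext <- d$utr3_extension
  per_gene <- fp |>
    group_by(gene_id) |>
    summarise(
      orf_count = sum(weight[psite >= start_nt + trim & psite < stop_nt + 3L - trim]),
      utr3_count = sum(weight[psite >= stop_nt + 3L & psite < stop_nt + 3L + utr3_len + ext]),
      utr5_count = sum(weight[psite >= 0L & psite < start_nt]),
      .groups = "drop"
    )

  out <- coords |>
    left_join(per_gene, by = "gene_id") |>
    mutate(across(c(orf_count, utr3_count, utr5_count), ~ tidyr::replace_na(.x, 0)))

  rpkm <- function(count, len_nt) {
    ifelse(len_nt > 0L,
           (count / profile$total_mapped * 1e6) / (len_nt / 1000),
           NA_real_)
  }
  out |>
    mutate(
      orf_rpkm = rpkm(orf_count, stop_nt + 3L - 2L * trim - start_nt),
      utr3_rpkm = rpkm(utr3_count, utr3_len + ext),
      utr5_rpkm = rpkm(utr5_count, start_nt)
    ) |>
    select(gene_id, orf_count, orf_rpkm, utr3_count, utr3_rpkm,
           utr5_count, utr5_rpkm)
}

#' Peak quantitation at start or stop codons
#'
#' Shifts footprint 5' ends to the P site and, for every usable gene,
#' sums the shifted counts in the 5-nt window centered on the first
#' nucleotide of the anchor codon. A stalled complex whose P site sits
#' on the anchor codon contributes the center of this window.
#'
#' @param profile A [profile_set()].
#' @param ann A `ribo_annotation` tibble.
#' @param anchor `"start"` or `"stop"`.
#' @param assay Override for the P-site shift; defaults to the
#'   profile's assay.
#' @return A `peak_table` tibble with columns `gene_id`, `peak_count`,
#'   `peak_rpm`, `truncated` (window clipped by a transcript
#'   boundary); attributes `anchor`, `sample`, `assay`,
#'   `total_mapped`.
#' @export
peak_height <- function(profile, ann, anchor = c("start", "stop"), assay = NULL) {
  anchor <- match.arg(anchor)
  assay <- assay %||% profile$assay
  hw <- ribo40s_defaults()$peak_halfwidth
  genes <- usable_genes(ann, "quantitation")
  coords <- ann_coords(ann) |> filter(gene_id %in% genes)
  coords$anchor_nt <- if (anchor == "start") coords$start_nt else coords$stop_nt

  fp <- profile$footprints |>
    filter(gene_id %in% genes) |>
    mutate(psite = psite_shift(five_prime, assay)) |>
    left_join(coords[, c("gene_id", "anchor_nt")], by = "gene_id")

  per_gene <- fp |>
    group_by(gene_id) |>
    summarise(peak_count = sum(weight[psite >= anchor_nt - hw & psite <= anchor_nt + hw]),
              .groups = "drop")

  out <- coords |>
    left_join(per_gene, by = "gene_id") |>
    mutate(peak_count = tidyr::replace_na(peak_count, 0),
           peak_rpm = peak_count / profile$total_mapped * 1e6,
           truncated = anchor_nt - hw < 0L | anchor_nt + hw >= tx_len) |>
    select(gene_id, peak_count, peak_rpm, truncated)
  structure(out,
            anchor = anchor, sample = profile$sample, assay = assay,
            total_mapped = profile$total_mapped,
            class = c("peak_table", class(out)))
}

#' 3'UTR to ORF density ratios (80S readthrough / reinitiation signal)
#'
#' For an 80S profile, reports the ratio of 3'UTR rpkm to ORF rpkm for
#' genes passing both inclusion thresholds (defaults 5 rpkm in the ORF
#' and 0.5 rpkm in the 3'UTR, both inclusive); other genes are
#' omitted.
#'
#' @param profile80 A [profile_set()] with assay `"ribo80"`.
#' @param ann A `ribo_annotation` tibble.
#' @param min_orf_rpkm,min_utr3_rpkm Inclusion thresholds.
#' @return A tibble with `gene_id`, `orf_rpkm`, `utr3_rpkm`, `ratio`.
#' @export
utr3_orf_ratio <- function(profile80, ann,
                           min_orf_rpkm = ribo40s_defaults()$min_orf_rpkm,
                           min_utr3_rpkm = ribo40s_defaults()$min_utr3_rpkm) {
  if (profile80$assay != "ribo80") {
    warn("utr3_orf_ratio is defined for 80S profiles; shifting by the profile's assay offset")
  }
  gene_densities(profile80, ann) |>
    filter(!is.na(orf_rpkm), !is.na(utr3_rpkm),
           orf_rpkm >= min_orf_rpkm, utr3_rpkm >= min_utr3_rpkm) |>
    mutate(ratio = utr3_rpkm / orf_rpkm) |>
    select(gene_id, orf_rpkm, utr3_rpkm, ratio)
}

#' Reading-frame distribution of ORF-interior footprints
#'
#' Shifts 5' ends to the P site, restricts to ORF interiors (excluding
#' the first and last 15 nt), and tabulates the fraction of positions
#' in each frame relative to the start codon. Elongating 80S
#' footprints concentrate in frame 0; 40S scanning footprints do not.
#'
#' @param profile A [profile_set()].
#' @param ann A `ribo_annotation` tibble.
#' @return A tibble with columns `frame` (0, 1, 2), `count`,
#'   `fraction`.
#' @export
frame_fractions <- function(profile, ann) {
  trim <- ribo40s_defaults()$orf_end_trim
  genes <- usable_genes(ann, "quantitation")
  coords <- ann_coords(ann) |> filter(gene_id %in% genes)
  fp <- profile$footprints |>
    filter(gene_id %in% genes) |>
    mutate(psite = psite_shift(five_prime, profile$assay)) |>
    left_join(coords, by = "gene_id") |>
    filter(psite >= start_nt + trim, psite < stop_nt + 3L - trim)
  if (nrow(fp) == 0L) abort("no ORF-interior footprints")
  counts <- vapply(0:2, function(f)
    sum(fp$weight[(fp$psite - fp$start_nt) %% 3L == f]), numeric(1))
  tibble(frame = 0:2, count = counts, fraction = counts / sum(counts))
}

#' Correlate two peak tables on the log scale
#'
#' Joins two peak tables on gene id, drops genes below `min_count` in
#' either table (log of zero is undefined), and reports the squared
#' Pearson correlation of log-transformed peak counts.
#'
#' @param a,b `peak_table` tibbles from [peak_height()].
#' @param min_count Minimum peak count required in both tables
#'   (default 1).
#' @return A list with `r_squared`, `n`, and the joined `genes`
#'   tibble.
#' @export
correlate_peak_tables <- function(a, b, min_count = 1) {
  joined <- inner_join(as_tibble(a)[, c("gene_id", "peak_count")],
                       as_tibble(b)[, c("gene_id", "peak_count")],
                       by = "gene_id", suffix = c("_a", "_b")) |>
    filter(.data$peak_count_a >= min_count, .data$peak_count_b >= min_count)
  if (nrow(joined) < 3L) {
    abort("fewer than 3 shared genes pass the count filter")
  }
  r <- stats::cor(log(joined$peak_count_a), log(joined$peak_count_b),
                  method = "pearson")
  list(r_squared = r^2, n = nrow(joined), genes = joined)
}
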