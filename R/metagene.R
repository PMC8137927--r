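#' One-dimensional metagene (average occupancy) profiles
#'
#' Averages rpm-scaled footprint-end counts across genes after
#' aligning them at the start or stop codon. Offsets are in
#' nucleotides relative to the first nucleotide of the anchor codon;
#' footprint ends are used unshifted (5'-end alignment is the
#' package-wide convention, 3'-end alignment uses the last protected
#' nucleotide). Genes enter the average only when the flanking
#' features cover the whole window (by default 100 nt of UTR and
#' 300 nt of ORF), and genes with zero reads in the window still
#' contribute zeros, so the trace is a plain equal-weight mean of
#' per-gene rpm tracks.
#'
#' @param profile A [profile_set()].
#' @param ann A `ribo_annotation` tibble.
#' @param anchor `"start"` or `"stop"`.
#' @param align_end Count footprint `"five_prime"` or `"three_prime"`
#'   ends.
#' @param window `c(upstream_nt, downstream_nt)`; offsets run from
#'   `-upstream` to `+downstream`. Defaults to 100/300 around starts
#'   and 300/100 around stops.
#' @param length_range Optional `c(min, max)` footprint-length filter
#'   (e.g. `c(26, 45)` for focused 40S analyses).
#' @return A `ribo_metagene` object; its `trace` element is a tibble
#'   of `offset`, `mean_rpm`.
#' @export
metagene_1d <- function(profile, ann, anchor = c("start", "stop"),
                        align_end = c("five_prime", "three_prime"),
                        window = NULL, length_range = NULL) {
  anchor <- match.arg(anchor)
  align_end <- match.arg(align_end)
  d <- ribo40s_defaults()
  window <- window %||% (if (anchor == "start") d$metagene_window_start
                         else d$metagene_window_stop)
  metagene_core(profile, ann, anchor, align_end,
                up = window[1], down = window[2],
                length_range = length_range, per_length = FALSE)
}

#' Two-dimensional (length-resolved) metagene profiles
#'
#' Like [metagene_1d()] but the average is computed for each footprint
#' length (15-80 nt) separately, yielding a length-by-offset matrix.
#' Genes are included when the anchored feature has at least
#' `half_window` nt on both sides.
#'
#' @inheritParams metagene_1d
#' @param half_window Half-width of the symmetric window (default
#'   100 nt).
#' @return A `ribo_metagene` object with a `per_length` matrix
#'   (rownames are lengths, colnames offsets) whose column sums equal
#'   the 1-D trace.
#' @export
metagene_2d <- function(profile, ann, anchor = c("start", "stop"),
                        align_end = c("five_prime", "three_prime"),
                        half_window = ribo40s_defaults()$metagene2d_halfwindow,
                        length_range = NULL) {
  anchor <- match.arg(anchor)
  align_end <- match.arg(align_end)
  metagene_core(profile, ann, anchor, align_end,
                up = half_window, down = half_window,
                length_range = length_range, per_length = TRUE)
}

metagene_core <- function(profile, ann, anchor, align_end, up, down,
                          length_range, per_length) {
  genes <- usable_genes(ann, "quantitation")
  a <- as_tibble(ann) |> filter(gene_id %in% genes)
  included <- if (anchor == "start") {
    a$utr5_len >= up & a$cds_len >= down
  } else {
    a$cds_len >= up & a$utr3_len >= down
  }
  a <- a[included, , drop = FALSE]
  if (nrow(a) == 0L) abort("no gene satisfies the metagene inclusion rule")
  coords <- ann_coords(a)
  coords$anchor_nt <- if (anchor == "start") coords$start_nt else coords$stop_nt

  fp <- profile$footprints |> filter(gene_id %in% a$gene_id)
  if (!is.null(length_range)) {
    fp <- filter(fp, length >= length_range[1], length <= length_range[2])
  }
  fp <- fp |>
    left_join(coords[, c("gene_id", "anchor_nt")], by = "gene_id") |>
    mutate(pos = if (align_end == "five_prime") five_prime
                 else five_prime + length - 1L,
           offset = .data$pos - .data$anchor_nt) |>
    filter(offset >= -up, offset <= down)

  offsets <- seq.int(-up, down)
  scale <- 1e6 / profile$total_mapped / nrow(a)
  trace <- fp |>
    group_by(offset) |>
    summarise(mean_rpm = sum(weight) * scale, .groups = "drop") |>
    tidyr::complete(offset = offsets, fill = list(mean_rpm = 0)) |>
    arrange(offset)

  pl <- NULL
  if (per_length) {
    lens <- 15:80
    m <- matrix(0, nrow = length(lens), ncol = length(offsets),
                dimnames = list(lens, offsets))
    cell <- fp |>
      filter(length >= 15L, length <= 80L) |>
      group_by(length, offset) |>
      summarise(v = sum(weight) * scale, .groups = "drop")
    m[cbind(match(cell$length, lens), match(cell$offset, offsets))] <- cell$v
    pl <- m
  }

  structure(
    list(trace = trace, per_length = pl, anchor = anchor,
         align_end = align_end, window = c(up, down),
         n_genes = nrow(a), length_range = length_range,
         sample = profile$sample, assay = profile$assay),
    class = "ribo_metagene"
  )
}

#' @export
print.ribo_metagene <- function(x, ...) {
  cat(sprintf("<metagene> %s-anchored, %s ends, %d genes, offsets %d..%d%s\n",
              x$anchor, sub("_", " ", x$align_end), x$n_genes,
              -x$window[1], x$window[2],
              if (is.null(x$per_length)) "" else ", length-resolved"))
  peak <- x$trace$offset[which.max(x$trace$mean_rpm)]
  cat(sprintf("  max %.4g rpm at offset %+d nt\n", max(x$trace$mean_rpm), peak))
  invisible(x)
}

#' @method as_tibble ribo_metagene
#' @export
as_tibble.ribo_metagene <- function(x, ...) x$trace

#' Tidy a metagene into a long tibble
#'
#' Returns the per-offset trace; with `matrix = TRUE`, the
#' length-resolved matrix in long form (`length`, `offset`,
#' `mean_rpm`).
#'
#' @param x A `ribo_metagene`.
#' @param matrix Return the length-resolved values instead of the 1-D
#'   trace?
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ribo_metagene
#' @export
tidy.ribo_metagene <- function(x, matrix = FALSE, ...) {
  if (!matrix) return(x$trace)
  if (is.null(x$per_length)) abort("no length-resolved matrix in this metagene")
  as_tibble(as.data.frame.table(x$per_length, stringsAsFactors = FALSE),
            .name_repair = "minimal") |>
    setNames(c("length", "offset", "mean_rpm")) |>
    mutate(length = as.integer(length), offset = as.integer(offset))
}
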