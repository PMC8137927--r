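#' Per-gene mutant/WT stop-peak ratio records
#'
#' Joins a mutant and a wild-type stop-anchored peak table, keeps
#' genes whose wild-type peak count reaches `min_wt_count`, computes
#' the depth-normalized ratio `mut_rpm / wt_rpm`, and annotates each
#' gene with the codons found at positions -1 (penultimate) through
#' -6 upstream of the stop codon, read in frame from the coding
#' strand.
#'
#' The wild-type count floor exists because a ratio over a tiny count
#' is dominated by 1/count noise; the default of 4 balances that
#' variance against the selection bias a floor introduces (see the
#' methods vignette).
#'
#' @param mut,wt `peak_table` tibbles from [peak_height()], both
#'   anchored at the stop codon.
#' @param ann A `ribo_annotation` tibble (source of the codon
#'   sequence).
#' @param min_wt_count Wild-type peak-count floor (inclusive).
#' @param positions Codon positions to extract, negative integers
#'   counting back from the stop codon.
#' @return A tibble with `gene_id`, `wt_count`, `wt_rpm`, `mut_count`,
#'   `mut_rpm`, `ratio`, and one `codon_m<k>` column per requested
#'   position.
#' @export
peak_ratio_table <- function(mut, wt, ann,
                             min_wt_count = ribo40s_defaults()$min_wt_count,
                             positions = -1:-6) {
  if (!identical(attr(mut, "anchor"), attr(wt, "anchor"))) {
    abort("peak tables have different anchors")
  }
  if (!identical(attr(mut, "anchor"), "stop")) {
    abort("peak_ratio_table expects stop-anchored peak tables")
  }
  stopifnot(all(positions <= -1L))
  joined <- inner_join(
    as_tibble(wt) |> select(gene_id, wt_count = peak_count, wt_rpm = peak_rpm),
    as_tibble(mut) |> select(gene_id, mut_count = peak_count, mut_rpm = peak_rpm),
    by = "gene_id") |>
    filter(wt_count >= min_wt_count) |>
    mutate(ratio = mut_rpm / wt_rpm)

  all_genes <- as_tibble(wt)$gene_id
  a <- as_tibble(ann) |>
    filter(gene_id %in% all_genes) |>
    mutate(stop1 = utr5_len + cds_len - 2L)   # 1-based first nt of stop codon
  census <- list()
  for (k in sort(positions, decreasing = TRUE)) {
    cod <- substr(a$sequence, a$stop1 + 3L * k, a$stop1 + 3L * k + 2L)
    joined[[sprintf("codon_m%d", -k)]] <- cod[match(joined$gene_id, a$gene_id)]
    census[[sprintf("codon_m%d", -k)]] <- table(cod)
  }
  # codon occurrence counts across all quantified genes (pre-floor):
  # the codon eligibility rule counts transcriptome occurrences, not
  # surviving ratio records
  attr(joined, "codon_census") <- census
  joined
}

#' Bootstrap test for codon-dependent recycling ratios
#'
#' Tests, for each codon observed at a given position at least `min_n`
#' times, whether the mean mutant/WT stop-peak ratio of its genes
#' deviates from the transcriptome mean. The null distribution is
#' built by drawing, `n_boot` times, as many ratios (with replacement)
#' from the pooled all-gene ratio distribution as the codon has genes
#' and recording the mean. The two-sided percentile p-value with
#' add-one correction is
#' `p = (1 + #\{|null - mu| >= |mean_c - mu|\}) / (n_boot + 1)`, with
#' `mu` the pooled mean; a codon is significant when `p < alpha`
#' (default 0.01, i.e. the 99th percentile, both tails). No
#' multiple-testing correction is applied across codons. Resampling
#' draws indices, so results are bit-reproducible given `seed` and
#' invariant to a common positive scaling of the ratios.
#'
#' @param records Ratio records from [peak_ratio_table()].
#' @param position Codon position to test (default -1, the penultimate
#'   codon).
#' @param min_n Minimum codon occurrence count (default 10). When the
#'   records carry the codon census recorded by [peak_ratio_table()],
#'   eligibility counts occurrences across all quantified genes (the
#'   transcriptome), so the wild-type count floor does not silently
#'   drop codons; otherwise the surviving record count is used.
#' @param n_boot Bootstrap draws (default 20000).
#' @param alpha Two-sided significance level (default 0.01).
#' @param seed Integer seed for reproducible resampling.
#' @return A `codon_boot` tibble with columns `codon`, `position`,
#'   `n`, `mean_ratio`, `p_value`, `significant`; attributes
#'   `transcriptome_mean` (the pooled mean), `n_boot`, `alpha`,
#'   `n_genes`.
#' @export
codon_bootstrap <- function(records, position = -1L,
                            min_n = ribo40s_defaults()$min_codon_n,
                            n_boot = ribo40s_defaults()$n_boot,
                            alpha = ribo40s_defaults()$alpha,
                            seed = NULL) {
  col <- sprintf("codon_m%d", -position)
  if (!col %in% names(records)) {
    abort(sprintf("records carry no codon column for position %d", position))
  }
  pooled <- records$ratio
  if (length(pooled) == 0L) abort("no ratio records")
  mu <- mean(pooled)
  grp <- split(records$ratio, records[[col]])
  # eligibility by transcriptome occurrence when the census is
  # available (codons found >= min_n times among quantified genes);
  # otherwise by surviving record count
  census <- attr(records, "codon_census")[[col]]
  if (!is.null(census)) {
    eligible <- names(census)[census >= min_n]
    grp <- grp[names(grp) %in% eligible & vapply(grp, length, integer(1)) >= 2L]
  } else {
    grp <- grp[vapply(grp, length, integer(1)) >= min_n]
  }
  if (length(grp) == 0L) {
    warn("no codon reaches min_n occurrences")
    out <- tibble(codon = character(), position = integer(), n = integer(),
                  mean_ratio = numeric(), p_value = numeric(),
                  significant = logical())
    return(new_codon_boot(out, mu, n_boot, alpha, length(pooled)))
  }
  grp <- grp[order(names(grp))]
  sizes <- vapply(grp, length, integer(1))

  run <- function() {
    null_means <- lapply(unique(sizes), function(nc) {
      idx <- sample.int(length(pooled), nc * n_boot, replace = TRUE)
      .rowMeans(pooled[idx], n_boot, nc)
    })
    names(null_means) <- as.character(unique(sizes))
    purrr::imap(grp, function(r, cod) {
      m <- mean(r)
      nm <- null_means[[as.character(length(r))]]
      p <- (1 + sum(abs(nm - mu) >= abs(m - mu))) / (n_boot + 1)
      tibble(codon = cod, position = as.integer(position),
             n = length(r), mean_ratio = m, p_value = p,
             significant = p < alpha)
    }) |> bind_rows()
  }
  out <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  new_codon_boot(arrange(out, codon), mu, n_boot, alpha, length(pooled))
}

new_codon_boot <- function(x, mu, n_boot, alpha, n_genes) {
  structure(x,
            transcriptome_mean = mu, n_boot = n_boot, alpha = alpha,
            n_genes = n_genes,
            class = c("codon_boot", class(tibble())))
}

#' Sweep the codon bootstrap over positions upstream of the stop codon
#'
#' Runs [codon_bootstrap()] independently at each listed position and
#' stacks the rows; the per-position count of significant codons
#' summarizes where codon identity modulates the recycling defect.
#'
#' @inheritParams codon_bootstrap
#' @param positions Integer vector of codon positions (default
#'   `-6:-1`).
#' @return A `codon_boot` tibble covering all positions; attribute
#'   `"n_significant"` tabulates significant codons per position.
#' @export
position_sweep <- function(records, positions = -6:-1,
                           min_n = ribo40s_defaults()$min_codon_n,
                           n_boot = ribo40s_defaults()$n_boot,
                           alpha = ribo40s_defaults()$alpha,
                           seed = NULL) {
  if (length(positions) == 0L) {
    out <- new_codon_boot(
      tibble(codon = character(), position = integer(), n = integer(),
             mean_ratio = numeric(), p_value = numeric(), significant = logical()),
      NA_real_, n_boot, alpha, nrow(records))
    attr(out, "n_significant") <- tibble(position = integer(), n_significant = integer())
    return(out)
  }
  parts <- purrr::map(seq_along(positions), function(i) {
    codon_bootstrap(records, positions[i], min_n = min_n, n_boot = n_boot,
                    alpha = alpha,
                    seed = if (is.null(seed)) NULL else as.integer(seed) + i - 1L)
  })
  out <- bind_rows(purrr::map(parts, as_tibble))
  out <- new_codon_boot(out, attr(parts[[1]], "transcriptome_mean"),
                        n_boot, alpha, attr(parts[[1]], "n_genes"))
  attr(out, "n_significant") <- out |>
    group_by(position) |>
    summarise(n_significant = sum(significant), .groups = "drop")
  out
}

#' @export
print.codon_boot <- function(x, ...) {
  cat(sprintf("<codon_boot> %d codon/position rows, pooled mean ratio %.3g, alpha %.3g (n_boot %d)\n",
              nrow(x), attr(x, "transcriptome_mean"), attr(x, "alpha"),
              attr(x, "n_boot")))
  NextMethod()
}

#' Broom-style accessors for codon bootstrap results
#'
#' `tidy()` returns the per-codon rows as a plain tibble; `glance()`
#' returns a one-row summary (pooled mean ratio, number of ratio
#' records, codons tested, codons significant, settings).
#'
#' @param x A `codon_boot` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy codon_boot
#' @export
tidy.codon_boot <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.codon_boot
#' @method glance codon_boot
#' @export
glance.codon_boot <- function(x, ...) {
  tibble(
    transcriptome_mean = attr(x, "transcriptome_mean"),
    n_genes = attr(x, "n_genes"),
    n_codons = nrow(x),
    n_significant = sum(x$significant),
    n_boot = attr(x, "n_boot"),
    alpha = attr(x, "alpha")
  )
}
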