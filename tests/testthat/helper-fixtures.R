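# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# A deterministic toy transcript: utr5 50, cds 300 (incl. stop), utr3 100.
# CDS is ATG + 97 copies of AAA + penultimate + TAA by default.
toy_ann <- function(gene_id = "GENE1", utr5 = 50L, cds = 300L, utr3 = 100L,
                    penultimate = "AAA", ...) {
  n_body <- cds / 3L - 3L
  seqs <- paste0(
    strrep("C", utr5),
    "ATG", strrep("AAA", n_body), penultimate, "TAA",
    strrep("G", utr3)
  )
  annotation_tbl(gene_id, utr5, cds, utr3, seqs, ...)
}

# n_genes toy transcripts with distinct ids (same geometry)
toy_ann_multi <- function(n_genes, utr5 = 50L, cds = 300L, utr3 = 100L,
                          penultimate = "AAA") {
  n_body <- cds / 3L - 3L
  seqs <- paste0(strrep("C", utr5), "ATG", strrep("AAA", n_body),
                 penultimate, "TAA", strrep("G", utr3))
  annotation_tbl(sprintf("GENE%d", seq_len(n_genes)),
                 rep(utr5, n_genes), rep(cds, n_genes), rep(utr3, n_genes),
                 rep(seqs, n_genes))
}

toy_fp <- function(gene_id, five_prime, length = 30L, weight = 1L) {
  tibble::tibble(gene_id = gene_id,
                 five_prime = as.integer(five_prime),
                 length = as.integer(length),
                 weight = as.integer(weight))
}

# Brute-force region classification oracle: explicit interval
# intersection, one footprint at a time (independent of the vectorized
# implementation under test).
oracle_region <- function(five_prime, len, utr5, cds) {
  A <- utr5
  S <- utr5 + cds - 3L
  fp_iv <- c(five_prime, five_prime + len)          # half-open
  overlaps <- function(iv, lo, hi) fp_iv[1] < hi && fp_iv[2] > lo
  if (overlaps(fp_iv, A - 3L, A + 6L)) return("START")
  if (overlaps(fp_iv, S - 6L, S + 3L)) return("STOP")
  if (five_prime < A) return("UTR5")
  if (five_prime < S + 3L) return("ORF")
  "UTR3"
}

# Random reads laid out as UMI5 + insert + UMI3 + barcode + linker
make_reads <- function(n, spec, sample_names = names(spec$barcode_map),
                       insert_len = 30L) {
  rand <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = "")
  sm <- sample(sample_names, n, replace = TRUE)
  tibble::tibble(
    read_id = sprintf("r%05d", seq_len(n)),
    sample_truth = sm,
    insert = vapply(seq_len(n), function(i) rand(insert_len), ""),
    umi3 = vapply(seq_len(n), function(i) rand(spec$umi3_len), ""),
    umi5 = vapply(seq_len(n), function(i) rand(spec$umi5_len), ""),
    seq = NA_character_
  ) |>
    dplyr::mutate(seq = paste0(umi5, insert, umi3,
                               unname(spec$barcode_map[sm]),
                               spec$linker_constant))
}

# the 61 sense codons, for null-calibration fixtures
sense_codons_for_test <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}
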