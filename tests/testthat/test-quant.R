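# Densities, peak heights, ratios, frames, correlations

test_that("ORF rpkm matches the closed form for uniform occupancy", {
  ann <- toy_ann(utr5 = 50L, cds = 1032L, utr3 = 100L)
  # uniform 1 read/nt over the ORF interior [A+15, S+3-15): 1003 positions
  A <- 50L; S <- 50L + 1032L - 3L
  interior <- seq.int(A + 15L, S + 3L - 15L - 1L)
  fp <- toy_fp("GENE1", interior - 14L, length = 30L)   # psite = position
  pr <- profile_set(fp, "u", "ssu40", total_mapped = 1e6)
  d <- gene_densities(pr, ann)
  len_nt <- length(interior)
  expect_equal(d$orf_count, len_nt)
  expect_equal(d$orf_rpkm, (len_nt / 1e6 * 1e6) / (len_nt / 1000))
  expect_equal(d$orf_rpkm, 1000)   # 1 read/nt at depth 1e6 is 1000 rpkm
})

test_that("reads shifted into the first or last 15 nt of the ORF are excluded", {
  ann <- toy_ann()
  A <- 50L; S <- 347L
  fp <- toy_fp("GENE1",
               c(A + 14L - 14L,          # psite at A+14: inside trim
                 A + 15L - 14L,          # psite at A+15: first counted nt
                 S + 3L - 16L - 14L,     # psite at S-13: last counted nt
                 S + 3L - 15L - 14L),    # psite at S-12: trimmed
               length = 30L)
  pr <- profile_set(fp, "t", "ssu40")
  d <- gene_densities(pr, ann)
  expect_equal(d$orf_count, 2)
})

test_that("3'UTR density covers the 25-nt extension and can be zero", {
  ann <- toy_ann()
  S <- 347L
  pr <- profile_set(toy_fp("GENE1", c(S + 10L - 14L, 60L), length = 20L),
                    "t", "ssu40")
  d <- gene_densities(pr, ann)
  expect_equal(d$utr3_count, 1)
  expect_equal(d$utr3_rpkm, (1 / 2 * 1e6) / ((100 + 25) / 1000))

  no3 <- profile_set(toy_fp("GENE1", 100L, 30L), "t", "ssu40")
  expect_equal(gene_densities(no3, ann)$utr3_rpkm, 0)
})

test_that("peak heights sum the 5-nt shifted window around the anchor codon", {
  ann <- toy_ann()
  S <- 347L
  stalled <- toy_fp("GENE1", rep(S - 14L, 7), 32L)
  pk <- peak_height(profile_set(stalled, "m", "ssu40"), ann, "stop")
  expect_equal(pk$peak_count, 7)
  expect_equal(pk$peak_rpm, 1e6)
  expect_false(pk$truncated)

  outside <- toy_fp("GENE1", rep(S - 20L, 5), 32L)   # shifted to S - 6
  pk0 <- peak_height(profile_set(outside, "m", "ssu40"), ann, "stop")
  expect_equal(pk0$peak_count, 0)

  # uniform background of one read per position contributes the window width
  uni <- toy_fp("GENE1", seq.int(S - 40L, S + 10L) - 14L, 20L)
  pku <- peak_height(profile_set(uni, "m", "ssu40"), ann, "stop")
  expect_equal(pku$peak_count, 5)

  # translation equivariance: pad the 5'UTR by k and shift reads by k
  k <- 7L
  ann_k <- annotation_tbl("GENE1", 50L + k, 300L, 100L,
                          paste0(strrep("T", k), ann$sequence))
  stalled_k <- toy_fp("GENE1", rep(S - 14L, 7) + k, 32L)
  pk_k <- peak_height(profile_set(stalled_k, "m", "ssu40"), ann_k, "stop")
  expect_equal(pk_k$peak_count, pk$peak_count)
})

test_that("start-anchored peaks use the 40S -14 geometry", {
  ann <- toy_ann()
  fp <- toy_fp("GENE1", rep(50L - 14L, 3), 32L)
  pk <- peak_height(profile_set(fp, "m", "ssu40"), ann, "start")
  expect_equal(pk$peak_count, 3)
})

test_that("density ratios respect the inclusive 5 / 0.5 rpkm thresholds", {
  n <- 4L
  ann <- toy_ann_multi(n, utr5 = 50L, cds = 1032L, utr3 = 100L)
  A <- 50L; S <- 50L + 1032L - 3L
  interior <- seq.int(A + 15L, S + 3L - 15L - 1L)   # 1003 nt
  u3 <- seq.int(S + 3L, S + 3L + 124L)              # 125 nt incl. extension
  # per-gene ORF reads tuned to sit just around the 5-rpkm threshold at
  # the depth set below; gene 4 lacks 3'UTR reads entirely
  orf_reads <- c(120, 100, 20, 120)
  utr3_reads <- c(4, 4, 4, 0)
  fp <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
    dplyr::bind_rows(
      toy_fp(sprintf("GENE%d", i),
             sample(interior, orf_reads[i], replace = TRUE) - 13L, 30L),
      if (utr3_reads[i] > 0)
        toy_fp(sprintf("GENE%d", i),
               sample(u3, utr3_reads[i], replace = TRUE) - 13L, 30L)
    )
  }))
  pr <- profile_set(fp, "r", "ribo80", total_mapped = 1e7)
  d <- gene_densities(pr, ann)
  # at depth 1e7: gene1/2/4 ORFs ~ 10-12 rpkm, gene3 ~ 2 rpkm (fails the
  # 5-rpkm floor); 4 reads in the 125-nt extended 3'UTR ~ 3.2 rpkm
  rt <- utr3_orf_ratio(pr, ann)
  expect_false("GENE3" %in% rt$gene_id)
  expect_false("GENE4" %in% rt$gene_id)   # no 3'UTR reads
  expect_setequal(rt$gene_id, c("GENE1", "GENE2"))
  expect_equal(rt$ratio, rt$utr3_rpkm / rt$orf_rpkm)

  # boundary: a gene at exactly 0.5 rpkm in the 3'UTR is included
  d1 <- d[d$gene_id == "GENE1", ]
  rt_hi <- utr3_orf_ratio(pr, ann, min_utr3_rpkm = d1$utr3_rpkm)
  expect_true("GENE1" %in% rt_hi$gene_id)
  rt_over <- utr3_orf_ratio(pr, ann, min_utr3_rpkm = d1$utr3_rpkm + 1e-9)
  expect_false("GENE1" %in% rt_over$gene_id)
})

test_that("frame fractions recover planted periodicity", {
  ann <- toy_ann()
  A <- 50L; S <- 347L
  codon_starts <- seq.int(A + 15L, S - 15L, by = 3L)
  f0 <- toy_fp("GENE1", codon_starts - 13L, 28L)
  ff <- frame_fractions(profile_set(f0, "e", "ribo80"), ann)
  expect_equal(ff$fraction, c(1, 0, 0))

  set.seed(30)
  pos <- sample(seq.int(A + 15L, S - 15L), 10000, replace = TRUE)
  ffu <- frame_fractions(profile_set(toy_fp("GENE1", pos - 13L, 28L), "u", "ribo80"),
                         ann)
  expect_true(all(abs(ffu$fraction - 1 / 3) < 0.02))

  frame <- ifelse(runif(10000) < 0.9, 0L, sample(1:2, 10000, replace = TRUE))
  pos90 <- sample(codon_starts, 10000, replace = TRUE) + frame
  ff90 <- frame_fractions(profile_set(toy_fp("GENE1", pos90 - 13L, 28L), "p", "ribo80"),
                          ann)
  expect_equal(ff90$fraction[1], 0.9, tolerance = 0.02)
})

test_that("peak-table correlation is 1 for scaled copies and ~0 for permutations", {
  set.seed(31)
  n <- 500
  ann <- toy_ann_multi(n)
  counts <- rpois(n, exp(rnorm(n, 3, 1))) + 1L
  mk <- function(cnt, sample) {
    fp <- toy_fp(rep(sprintf("GENE%d", seq_len(n)), cnt), 347L - 14L, 32L)
    peak_height(profile_set(fp, sample, "ssu40"), ann, "stop")
  }
  a <- mk(counts, "a")
  b <- mk(counts * 2L, "b")
  expect_equal(correlate_peak_tables(a, b)$r_squared, 1)

  p <- mk(sample(counts), "p")
  r2 <- correlate_peak_tables(a, p)$r_squared
  expect_lt(r2, 0.05)

  disjoint <- a[1:100, ]; disjoint$gene_id <- sprintf("OTHER%d", 1:100)
  attr(disjoint, "anchor") <- "stop"
  expect_error(correlate_peak_tables(a[101:200, ], disjoint), "fewer than 3")
})

test_that("densities scale linearly with weight and are depth-invariant", {
  ann <- toy_ann()
  fp <- toy_fp("GENE1", c(100, 150, 360) - 14L, 30L)
  pr1 <- profile_set(fp, "x", "ssu40", total_mapped = 1000)
  fp2 <- fp; fp2$weight <- 2L
  pr2 <- profile_set(fp2, "x", "ssu40", total_mapped = 1000)
  d1 <- gene_densities(pr1, ann); d2 <- gene_densities(pr2, ann)
  expect_equal(d2$orf_count, 2 * d1$orf_count)
  expect_equal(d2$orf_rpkm, 2 * d1$orf_rpkm)
  # doubling counts and the denominator together leaves rpkm unchanged
  pr3 <- profile_set(fp2, "x", "ssu40", total_mapped = 2000)
  expect_equal(gene_densities(pr3, ann)$orf_rpkm, d1$orf_rpkm)
})
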