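# The synthetic transcriptome / footprint generator and its ground truth

test_that("transcriptome generation is deterministic and balanced", {
  cfg <- synthetic_config(n_genes = 100, seed = 1)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(tibble::as_tibble(a$ann), tibble::as_tibble(b$ann))
  expect_identical(a$truth, b$truth)

  cfg610 <- synthetic_config(n_genes = 610, seed = 2)
  tx <- generate_transcriptome(cfg610)
  expect_true(all(table(tx$truth$penultimate) == 10L))
  # penultimate codons are really at -1 in the sequences
  S1 <- tx$ann$utr5_len + tx$ann$cds_len - 2L
  expect_equal(substr(tx$ann$sequence, S1 - 3L, S1 - 1L), tx$truth$penultimate)
  validate_annotation(tx$ann)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(weights_ssu40 = c(utr5 = 1, start = 0.2,
                                                  orf = 0, stop = 0, utr3 = 0,
                                                  utr3_aug = 0, queued = 0)),
               "sum to 1")
  expect_error(synthetic_config(cds_range = c(3L, 6L)), "infeasible")
  expect_error(synthetic_config(reads_per_sample = 0), "positive")
})

test_that("a pure stop-peak mixture puts every 40S read at S - 14", {
  w <- c(utr5 = 0, start = 0, orf = 0, stop = 1, utr3 = 0, utr3_aug = 0,
         queued = 0)
  cfg <- synthetic_config(n_genes = 20, reads_per_sample = 2000,
                          weights_ssu40 = w, seed = 3)
  tx <- generate_transcriptome(cfg)
  lib <- simulate_footprints(tx$ann, tx$truth, cfg, "wt", "ssu40")
  coords <- tibble::as_tibble(tx$ann) |>
    dplyr::transmute(gene_id, S = utr5_len + cds_len - 3L)
  joined <- dplyr::left_join(lib$footprints, coords, by = "gene_id")
  expect_true(all(joined$five_prime == joined$S - 14L))

  pk <- peak_height(lib$profile, tx$ann, "stop")
  expect_equal(sum(pk$peak_count), nrow(lib$footprints))
})

test_that("the planted stop fold-change is recovered at simulation scale", {
  cfg <- synthetic_config(n_genes = 305, reads_per_sample = 5e4,
                          stop_fold_change = 10, codon_multipliers = c(GGG = 1),
                          seed = 4)
  tx <- generate_transcriptome(cfg)
  wt <- simulate_footprints(tx$ann, tx$truth, cfg, "wt", "ssu40")
  mut <- simulate_footprints(tx$ann, tx$truth, cfg, "tma_dd", "ssu40")
  pkw <- peak_height(wt$profile, tx$ann, "stop")
  pkm <- peak_height(mut$profile, tx$ann, "stop")
  agg <- (sum(pkm$peak_rpm)) / (sum(pkw$peak_rpm))
  expect_equal(agg, 10, tolerance = 0.06)
})

test_that("queued-80S reads land 49 nt upstream of the 3'UTR start", {
  w <- c(utr5 = 0, start = 0, orf = 0, stop = 0, utr3 = 0, utr3_aug = 0,
         queued = 1)
  cfg <- synthetic_config(n_genes = 30, reads_per_sample = 5000,
                          weights_ribo80 = w, seed = 5)
  tx <- generate_transcriptome(cfg)
  lib <- simulate_footprints(tx$ann, tx$truth, cfg, "wt", "ribo80")
  coords <- tibble::as_tibble(tx$ann) |>
    dplyr::transmute(gene_id, utr3_start = utr5_len + cds_len)
  off <- dplyr::left_join(lib$footprints, coords, by = "gene_id") |>
    dplyr::mutate(offset = five_prime - utr3_start) |>
    dplyr::count(offset)
  expect_setequal(off$offset, c(-52L, -49L, -46L))
  expect_equal(off$offset[which.max(off$n)], -49L)
})

test_that("80S ORF backgrounds carry 3-nt periodicity; 40S ones do not", {
  w <- c(utr5 = 0, start = 0, orf = 1, stop = 0, utr3 = 0, utr3_aug = 0,
         queued = 0)
  cfg <- synthetic_config(n_genes = 30, reads_per_sample = 2e4,
                          weights_ribo80 = w, weights_ssu40 = w, seed = 6)
  tx <- generate_transcriptome(cfg)
  lib80 <- simulate_footprints(tx$ann, tx$truth, cfg, "wt", "ribo80")
  ff80 <- frame_fractions(lib80$profile, tx$ann)
  expect_equal(ff80$fraction[1], 0.9, tolerance = 0.03)

  lib40 <- simulate_footprints(tx$ann, tx$truth, cfg, "wt", "ssu40")
  ff40 <- frame_fractions(lib40$profile, tx$ann)
  expect_true(all(abs(ff40$fraction - 1 / 3) < 0.05))
})

test_that("component tallies match the emitted footprints", {
  cfg <- synthetic_config(n_genes = 50, reads_per_sample = 1e4, seed = 7)
  tx <- generate_transcriptome(cfg)
  lib <- simulate_footprints(tx$ann, tx$truth, cfg, "wt", "ssu40")
  expect_equal(sum(lib$tallies$count), nrow(lib$footprints))
  # stop-component tallies equal the reads observed exactly at S - 14
  coords <- tibble::as_tibble(tx$ann) |>
    dplyr::transmute(gene_id, S = utr5_len + cds_len - 3L)
  at_stop <- dplyr::left_join(lib$footprints, coords, by = "gene_id") |>
    dplyr::filter(five_prime == S - 14L) |>
    dplyr::count(gene_id)
  stop_tally <- lib$tallies |> dplyr::filter(component == "stop")
  # every stop-component read is at S - 14 (other components can also
  # land there, so observed >= tally)
  merged <- dplyr::left_join(stop_tally, at_stop, by = "gene_id")
  expect_true(all(merged$n >= merged$count))
})

test_that("FASTQ emission round-trips through preprocessing with exact truth", {
  spec <- linker_spec(barcode_map = c(wt = "ACGTA", mut = "TGCAT"))
  cfg <- synthetic_config(n_genes = 30, reads_per_sample = 2000, seed = 8)
  tx <- generate_transcriptome(cfg)
  lib <- simulate_footprints(tx$ann, tx$truth, cfg, "wt", "ssu40")

  # duplicate_rate 0: dedup removes nothing beyond UMI collisions
  em0 <- emit_fastq(lib$footprints, tx$ann, spec, "wt", duplicate_rate = 0,
                    seed = 21)
  dm0 <- demultiplex_trim(em0$reads, spec)
  expect_equal(nrow(dedup_umi(dm0)), em0$truth$n_unique)
  expect_equal(em0$truth$n_reads, nrow(lib$footprints))

  # duplicate_rate 0.5: the distinct-key truth is recovered exactly
  em <- emit_fastq(lib$footprints, tx$ann, spec, "wt", duplicate_rate = 0.5,
                   seed = 22)
  expect_equal(nrow(em$reads),
               nrow(lib$footprints) + round(0.5 * nrow(lib$footprints)))
  dm <- demultiplex_trim(em$reads, spec)
  expect_equal(nrow(dm), nrow(em$reads))       # all reads demultiplex
  dd <- dedup_umi(dm)
  expect_equal(nrow(dd), em$truth$n_unique)

  # inserts equal the annotated transcript substrings
  seqs <- setNames(tx$ann$sequence, tx$ann$gene_id)
  want <- substr(seqs[lib$footprints$gene_id],
                 lib$footprints$five_prime + 1L,
                 lib$footprints$five_prime + lib$footprints$length)
  expect_setequal(unique(dm$insert), unique(unname(want)))
})
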