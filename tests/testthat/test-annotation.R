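# Annotation loading, coordinate frame and exclusion rules

write_toy_gff <- function(dir, genes) {
  # genes: data.frame with chr, start, end (single CDS), strand, id,
  # optional classification
  gff <- file.path(dir, "cds.gff3")
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(genes)), function(i) {
               g <- genes[i, ]
               attrs <- sprintf("ID=%s;Parent=%s", g$id, g$id)
               if (!is.null(g$classification) && !is.na(g$classification)) {
                 attrs <- paste0(attrs, ";orf_classification=", g$classification)
               }
               sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                       g$chr, g$start, g$end, g$strand, attrs)
             }, ""))
  writeLines(lines, gff)
  gff
}

test_that("a one-gene annotation reconstructs lengths, sequence and anchors", {
  dir <- withr::local_tempdir()
  set.seed(1)
  chr_seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                   collapse = "")
  # plant a clean 300-nt ORF at genomic 101..400
  substr(chr_seq, 101, 103) <- "ATG"
  substr(chr_seq, 398, 400) <- "TAA"
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(chr_seq), "chrI"),
    file.path(dir, "genome.fa"))
  write_toy_gff(dir, data.frame(chr = "chrI", start = 101, end = 400,
                                strand = "+", id = "G1",
                                classification = "Verified"))
  readr::write_tsv(tibble::tibble(gene_id = "G1", utr5_len = 50, utr3_len = 100),
                   file.path(dir, "utr.tsv"))

  ann <- load_annotation(file.path(dir, "cds.gff3"), file.path(dir, "utr.tsv"),
                         file.path(dir, "genome.fa"))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$utr5_len + ann$cds_len + ann$utr3_len, 450L)
  expect_equal(nchar(ann$sequence), 450L)
  expect_equal(substr(ann$sequence, 51, 53), "ATG")
  expect_equal(substr(ann$sequence, 348, 350), "TAA")
  expect_equal(ann$sequence, substr(chr_seq, 51, 500))
  expect_false(ann$dubious)
})

test_that("minus-strand and spliced CDSs are joined and reverse-complemented", {
  dir <- withr::local_tempdir()
  set.seed(2)
  chr_seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
  # minus-strand gene: mRNA = revcomp(genomic 201..350); make it a valid ORF
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  mrna <- paste0("ATG", strrep("GCT", 48), "TAA")   # 150 nt
  substr(chr_seq, 201, 350) <- rc(mrna)
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(chr_seq), "chrII"),
    file.path(dir, "genome.fa"))
  write_toy_gff(dir, data.frame(chr = "chrII", start = 201, end = 350,
                                strand = "-", id = "GM"))
  readr::write_tsv(tibble::tibble(gene_id = "GM", utr5_len = 20, utr3_len = 30),
                   file.path(dir, "utr.tsv"))
  ann <- load_annotation(file.path(dir, "cds.gff3"), file.path(dir, "utr.tsv"),
                         file.path(dir, "genome.fa"))
  cds_part <- substr(ann$sequence, 21, 170)
  expect_equal(cds_part, mrna)
  # the 5'UTR of a minus-strand gene is the revcomp of the downstream flank
  expect_equal(substr(ann$sequence, 1, 20), rc(substr(chr_seq, 351, 370)))

  # two-exon plus-strand gene: splice join skips the intron
  dir2 <- withr::local_tempdir()
  chr2 <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  exon1 <- "ATGGCTGCT"                       # 9 nt
  exon2 <- paste0(strrep("GAA", 29), "TAA")  # 90 nt
  substr(chr2, 101, 109) <- exon1
  substr(chr2, 150, 239) <- exon2
  Biostrings::writeXStringSet(setNames(Biostrings::DNAStringSet(chr2), "chrIII"),
                              file.path(dir2, "genome.fa"))
  writeLines(c("##gff-version 3",
               "chrIII\ttoy\tCDS\t101\t109\t.\t+\t0\tID=GS_1;Parent=GS",
               "chrIII\ttoy\tCDS\t150\t239\t.\t+\t0\tID=GS_2;Parent=GS"),
             file.path(dir2, "cds.gff3"))
  readr::write_tsv(tibble::tibble(gene_id = "GS", utr5_len = 10, utr3_len = 10),
                   file.path(dir2, "utr.tsv"))
  ann2 <- load_annotation(file.path(dir2, "cds.gff3"), file.path(dir2, "utr.tsv"),
                          file.path(dir2, "genome.fa"))
  expect_equal(ann2$cds_len, 99L)
  expect_equal(substr(ann2$sequence, 11, 109), paste0(exon1, exon2))
})

test_that("dubious qualifiers and genomic overlaps set the exclusion flags", {
  dir <- withr::local_tempdir()
  set.seed(3)
  chr_seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
  mk_orf <- function(at, len) {
    orf <- paste0("ATG", strrep("CAA", len / 3 - 2), "TAA")
    substr(chr_seq, at, at + len - 1) <<- orf
  }
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  mk_orf(101, 300)    # G1
  mk_orf(1001, 300)   # G2 (plus strand)
  # G3 on the minus strand at 1341..1640 with a 60-nt 3'UTR whose
  # genomic extension (1281..1340) reaches into G2's span
  orf3 <- paste0("ATG", strrep("CAA", 98), "TAA")
  substr(chr_seq, 1341, 1640) <- rc(orf3)
  mk_orf(1701, 150)   # G4 dubious
  Biostrings::writeXStringSet(setNames(Biostrings::DNAStringSet(chr_seq), "chrI"),
                              file.path(dir, "genome.fa"))
  write_toy_gff(dir, data.frame(
    chr = "chrI",
    start = c(101, 1001, 1341, 1701),
    end = c(400, 1300, 1640, 1850),
    strand = c("+", "+", "-", "+"),
    id = c("G1", "G2", "G3", "G4"),
    classification = c(NA, NA, NA, "Dubious")))
  readr::write_tsv(tibble::tibble(gene_id = "G3", utr5_len = 0L, utr3_len = 60L),
                   file.path(dir, "utr.tsv"))
  ann <- load_annotation(file.path(dir, "cds.gff3"), file.path(dir, "utr.tsv"),
                         file.path(dir, "genome.fa"))

  expect_true(ann$dubious[ann$gene_id == "G4"])
  # independent brute-force interval overlap on the UTR-extended spans
  spans <- list(G1 = c(101, 400), G2 = c(1001, 1300),
                G3 = c(1281, 1640), G4 = c(1701, 1850))
  brute <- vapply(names(spans), function(g) {
    any(vapply(setdiff(names(spans), g), function(h) {
      spans[[g]][1] <= spans[[h]][2] && spans[[h]][1] <= spans[[g]][2]
    }, logical(1)))
  }, logical(1))
  expect_equal(setNames(ann$overlaps_other, ann$gene_id), brute)
  expect_true(all(ann$overlaps_other[ann$gene_id %in% c("G2", "G3")]))
})

test_that("CDSs with length not divisible by 3 are skipped with a warning", {
  dir <- withr::local_tempdir()
  chr_seq <- strrep("ACGT", 300)
  substr(chr_seq, 101, 103) <- "ATG"
  substr(chr_seq, 398, 400) <- "TAA"
  Biostrings::writeXStringSet(setNames(Biostrings::DNAStringSet(chr_seq), "c"),
                              file.path(dir, "genome.fa"))
  write_toy_gff(dir, data.frame(chr = "c", start = c(101, 501),
                                end = c(400, 600), strand = "+",
                                id = c("OK", "BAD")))   # BAD: 100 nt
  readr::write_tsv(tibble::tibble(gene_id = "OK", utr5_len = 0, utr3_len = 0),
                   file.path(dir, "utr.tsv"))
  expect_warning(
    ann <- load_annotation(file.path(dir, "cds.gff3"), file.path(dir, "utr.tsv"),
                           file.path(dir, "genome.fa")),
    "not a multiple of 3")
  expect_equal(ann$gene_id, "OK")
})

test_that("usable_genes applies the exclusion flags and is order-invariant", {
  ann <- toy_ann_multi(3)
  ann$dubious[2] <- TRUE
  expect_equal(usable_genes(ann, "quantitation"), c("GENE1", "GENE3"))
  expect_equal(usable_genes(ann, "metacodon"), c("GENE1", "GENE3"))

  ann$dubious[2] <- FALSE
  ann$utr5_intron[3] <- TRUE
  expect_false("GENE3" %in% usable_genes(ann, "metacodon"))
  expect_false("GENE3" %in% usable_genes(ann, "quantitation"))

  shuffled <- ann[c(3, 1, 2), ]
  expect_equal(usable_genes(shuffled, "quantitation"),
               usable_genes(ann, "quantitation"))
  expect_true(all(usable_genes(ann, "quantitation") %in% ann$gene_id))

  empty <- ann[0, ]
  expect_equal(usable_genes(empty, "quantitation"), character(0))
})

test_that("annotation invariants are enforced and the cache round-trips", {
  expect_error(annotation_tbl("G", 10, 7, 5, strrep("A", 22)), "divisible by 3")
  expect_error(annotation_tbl("G", 10, 9, 5, strrep("A", 10)),
               "does not match")
  expect_error(annotation_tbl("G", 10, 9, 5,
                              paste0(strrep("A", 10), "ATGAAACCC", strrep("A", 5))),
               "stop codon")

  ann <- toy_ann_multi(5)
  ann$utr5_intron[4] <- TRUE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ann))
})
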