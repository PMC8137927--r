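#' Validate a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent list) with the
#' fields:
#'
#' ```yaml
#' outdir: runs/demo
#' seed: 1
#' annotation:             # either 'cache:' or the gff/fasta/utr trio
#'   gff: path/cds.gff3
#'   fasta: path/genome.fa
#'   utr_table: path/utr.tsv
#' samples:
#'   - {name: wt,  assay: ssu40, protocol: umi, alignments: wt.bed}
#'   - {name: mut, assay: ssu40, protocol: umi, alignments: mut.bed}
#' parameters:             # optional overrides of ribo40s_defaults()
#'   min_wt_count: 4
#'   n_boot: 20000
#' codonstats: {mutant: mut, wildtype: wt}
#' simulate: {n_genes: 200, reads_per_sample: 100000}
#' ```
#'
#' Every referenced path must exist at validation time (except
#' outputs). Validation failures list every offending field.
#'
#' @param config Path to a YAML file or a list.
#' @return The validated configuration list, invisibly classed
#'   `ribo40s_config`.
#' @export
load_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  problems <- character(0)
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  need(!is.null(cfg$outdir), "outdir: missing")
  has_sim <- !is.null(cfg$simulate)
  has_pp <- !is.null(cfg$preprocess)
  if (has_pp) {
    need(!is.null(cfg$preprocess$fastq) && file.exists(cfg$preprocess$fastq %||% ""),
         "preprocess.fastq: missing or not found")
    need(length(cfg$preprocess$barcodes) > 0, "preprocess.barcodes: missing")
  }
  if (!has_sim && !has_pp) {
    ann <- cfg$annotation
    need(!is.null(ann), "annotation: missing (and no simulate block)")
    if (!is.null(ann)) {
      if (!is.null(ann$cache)) {
        need(file.exists(ann$cache), sprintf("annotation.cache: '%s' not found", ann$cache))
      } else {
        for (f in c("gff", "fasta", "utr_table")) {
          need(!is.null(ann[[f]]), sprintf("annotation.%s: missing", f))
          if (!is.null(ann[[f]])) {
            need(file.exists(ann[[f]]), sprintf("annotation.%s: '%s' not found", f, ann[[f]]))
          }
        }
      }
    }
    need(length(cfg$samples) > 0, "samples: missing")
    for (s in cfg$samples) {
      need(!is.null(s$name), "samples[].name: missing")
      need(!is.null(s$assay) && s$assay %in% c("ssu40", "ribo80", "none"),
           sprintf("samples[%s].assay: must be ssu40/ribo80/none", s$name %||% "?"))
      if (!is.null(s$alignments)) {
        need(file.exists(s$alignments),
             sprintf("samples[%s].alignments: '%s' not found", s$name %||% "?", s$alignments))
      }
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid run configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  cfg$parameters <- utils::modifyList(ribo40s_defaults(), cfg$parameters %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  class(cfg) <- "ribo40s_config"
  invisible(cfg)
}

#' Run pipeline stages from a configuration
#'
#' Binds the package's stages into reproducible, file-based runs.
#' Available subcommands:
#'
#' * `simulate` — generate a synthetic annotation plus wild-type and
#'   mutant 40S libraries (and the annotation cache) under `outdir`.
#' * `preprocess` — demultiplex a raw FASTQ by sample barcode, collapse
#'   PCR duplicates on the 7-nt UMI (samples whose `protocol` is
#'   `"original"` bypass the UMI step), size-select per assay, and
#'   write one FASTQ per sample plus a demultiplexing summary.
#'   Requires a `preprocess:` block
#'   (`fastq`, `linker_constant`, `barcodes: {sample: ACGTA, ...}`).
#' * `quantify` — region fractions, gene densities and stop/start peak
#'   tables per sample.
#' * `metagene` — 1-D start- and stop-anchored metagene traces per
#'   sample.
#' * `metacodon` — 3'UTR AUG position averages per sample.
#' * `codonstats` — mutant/WT ratio records and the penultimate-codon
#'   bootstrap.
#' * `report` — a run log (parameters, seed, input checksums, package
#'   version) as JSON.
#'
#' Stages are idempotent: outputs already present are not recomputed
#' unless `force = TRUE`. All outputs are tab-separated tables with
#' headers; reruns with identical configuration and seed are
#' byte-identical.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [load_run_config()]).
#' @param subcommands Character vector of stages to run, in order.
#' @param force Recompute outputs that already exist?
#' @return Invisibly, a named list of the file paths each stage wrote.
#' @export
run_pipeline <- function(config,
                         subcommands = c("simulate", "preprocess", "quantify",
                                         "metagene", "metacodon", "codonstats",
                                         "report"),
                         force = FALSE) {
  cfg <- load_run_config(config)
  subcommands <- match.arg(subcommands, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  arte <- list()
  out <- function(...) file.path(cfg$outdir, paste0(...))
  fresh <- function(path) force || !file.exists(path)

  # ---- inputs -------------------------------------------------------
  sim <- NULL
  if ("simulate" %in% subcommands && !is.null(cfg$simulate)) {
    sim_cfg <- do.call(synthetic_config,
                       utils::modifyList(cfg$simulate, list(seed = cfg$seed)))
    tx <- generate_transcriptome(sim_cfg)
    if (fresh(out("annotation.tsv"))) write_annotation(tx$ann, out("annotation.tsv"))
    if (fresh(out("truth.tsv"))) readr::write_tsv(tx$truth, out("truth.tsv"))
    sim <- list(cfg = sim_cfg, tx = tx)
    for (g in c("wt", "tma_dd")) {
      f <- out(g, "_ssu40.bed")
      if (fresh(f)) {
        lib <- simulate_footprints(tx$ann, tx$truth, sim_cfg, g, "ssu40")
        write_footprints(lib$footprints, f)
      }
    }
    arte$simulate <- c(out("annotation.tsv"), out("truth.tsv"),
                       out("wt_ssu40.bed"), out("tma_dd_ssu40.bed"))
  }

  ann_cache <- NULL
  get_ann <- function() {
    if (!is.null(ann_cache)) return(ann_cache)
    ann_cache <<- if (!is.null(sim)) {
      sim$tx$ann
    } else if (!is.null(cfg$annotation$cache)) {
      read_annotation(cfg$annotation$cache)
    } else if (!is.null(cfg$annotation)) {
      load_annotation(cfg$annotation$gff, cfg$annotation$utr_table, cfg$annotation$fasta)
    } else if (file.exists(out("annotation.tsv"))) {
      read_annotation(out("annotation.tsv"))
    } else {
      abort("no annotation available; run the simulate stage or configure one")
    }
    ann_cache
  }

  samples <- cfg$samples
  if (is.null(samples) && (!is.null(sim) || file.exists(out("wt_ssu40.bed")))) {
    samples <- list(
      list(name = "wt", assay = "ssu40", alignments = out("wt_ssu40.bed")),
      list(name = "tma_dd", assay = "ssu40", alignments = out("tma_dd_ssu40.bed"))
    )
  }
  load_profile <- function(s) {
    fp <- read_footprints(s$alignments, get_ann(), s$assay)
    profile_set(fp, s$name, s$assay)
  }

  if ("preprocess" %in% subcommands && !is.null(cfg$preprocess)) {
    pp <- cfg$preprocess
    spec <- linker_spec(
      linker_constant = pp$linker_constant %||% "AGATCGGAAGAGCAC",
      barcode_map = unlist(pp$barcodes))
    raw <- read_fastq(pp$fastq)
    dm <- demultiplex_trim(raw, spec,
                           max_linker_mismatch = pp$max_linker_mismatch %||% 0L)
    readr::write_tsv(attr(dm, "summary"), out("demultiplex_summary.tsv"))
    protocol <- setNames(
      vapply(samples %||% list(), function(s) s$protocol %||% "umi", ""),
      vapply(samples %||% list(), `[[`, "", "name"))
    assays <- setNames(
      vapply(samples %||% list(), function(s) s$assay %||% "ssu40", ""),
      names(protocol))
    files <- out("demultiplex_summary.tsv")
    for (sm in unique(dm$sample)) {
      r <- dm[dm$sample == sm, , drop = FALSE]
      # libraries built with the original (UMI-free) protocol skip dedup
      if (!identical(unname(protocol[sm]), "original")) r <- dedup_umi(r)
      r <- size_select(r, if (identical(unname(assays[sm]), "ribo80"))
        "ribo80" else "ssu40")
      f <- out(sm, "_clean.fastq")
      write_fastq(tibble(read_id = r$read_id, seq = r$insert), f)
      files <- c(files, f)
    }
    arte$preprocess <- files
  }

  # ---- analysis stages ---------------------------------------------
  if ("quantify" %in% subcommands) {
    ann <- get_ann()
    files <- character(0)
    for (s in samples) {
      pr <- load_profile(s)
      f1 <- out(s$name, "_region_fractions.tsv")
      if (fresh(f1)) readr::write_tsv(region_fractions(pr, ann), f1)
      f2 <- out(s$name, "_gene_densities.tsv")
      if (fresh(f2)) readr::write_tsv(gene_densities(pr, ann), f2)
      f3 <- out(s$name, "_stop_peaks.tsv")
      if (fresh(f3)) readr::write_tsv(as_tibble(peak_height(pr, ann, "stop")), f3)
      f4 <- out(s$name, "_start_peaks.tsv")
      if (fresh(f4)) readr::write_tsv(as_tibble(peak_height(pr, ann, "start")), f4)
      files <- c(files, f1, f2, f3, f4)
    }
    arte$quantify <- files
  }

  if ("metagene" %in% subcommands) {
    ann <- get_ann()
    files <- character(0)
    for (s in samples) {
      pr <- load_profile(s)
      for (anchor in c("start", "stop")) {
        f <- out(s$name, "_metagene_", anchor, ".tsv")
        if (fresh(f)) {
          mg <- try(metagene_1d(pr, ann, anchor), silent = TRUE)
          if (!inherits(mg, "try-error")) readr::write_tsv(mg$trace, f)
        }
        files <- c(files, f)
      }
    }
    arte$metagene <- files
  }

  if ("metacodon" %in% subcommands) {
    ann <- get_ann()
    occ <- motif_positions(ann, "ATG", "UTR3")
    files <- character(0)
    for (s in samples) {
      f <- out(s$name, "_metacodon_utr3_aug.tsv")
      if (fresh(f)) {
        pr <- load_profile(s)
        mc <- try(metacodon_average(pr, ann, occ), silent = TRUE)
        if (!inherits(mc, "try-error")) readr::write_tsv(mc, f)
      }
      files <- c(files, f)
    }
    arte$metacodon <- files
  }

  if ("codonstats" %in% subcommands) {
    ann <- get_ann()
    pair <- cfg$codonstats %||% list(mutant = "tma_dd", wildtype = "wt")
    by_name <- setNames(samples, vapply(samples, `[[`, "", "name"))
    mut <- peak_height(load_profile(by_name[[pair$mutant]]), ann, "stop")
    wt <- peak_height(load_profile(by_name[[pair$wildtype]]), ann, "stop")
    p <- cfg$parameters
    records <- peak_ratio_table(mut, wt, ann, min_wt_count = p$min_wt_count)
    f1 <- out("ratio_records.tsv")
    if (fresh(f1)) readr::write_tsv(records, f1)
    f2 <- out("codon_stats.tsv")
    if (fresh(f2)) {
      boot <- codon_bootstrap(records, min_n = p$min_codon_n,
                              n_boot = p$n_boot, alpha = p$alpha,
                              seed = cfg$seed)
      readr::write_tsv(tidy(boot), f2)
    }
    arte$codonstats <- c(f1, f2)
  }

  if ("report" %in% subcommands) {
    inputs <- as.character(unlist(lapply(samples, `[[`, "alignments")))
    log <- list(
      package = "ribo40s",
      version = as.character(utils::packageVersion("ribo40s")),
      seed = cfg$seed,
      parameters = cfg$parameters,
      input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      timestamp_utc = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ")
    )
    f <- out("run_log.json")
    jsonlite::write_json(log, f, auto_unbox = TRUE, pretty = TRUE)
    arte$report <- f
  }

  invisible(arte)
}
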