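## End-to-end orchestration: simulate -> consensus -> quantify -> design
## -> off-target -> pharmacology, with a reproducibility manifest. All
## randomness derives from the single config seed; a fixed config yields
## byte-identical outputs.

#' Pipeline configuration
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @param depth,error_rate pileup simulation parameters.
#' @param psi_true per-sample true pseudoexon inclusion fractions.
#' @param junction_reads junction-spanning reads per sample.
#' @param lr_proportions named isoform proportions for long-read
#'   simulation.
#' @param lr_reads number of simulated long reads.
#' @param design_flank tiling window flank around the delins (nt).
#' @param doses dose grid for the dose-response stage.
#' @param drc_ec50,drc_hill,drc_noise_sd dose-response truth and noise.
#' @param transcriptome_fasta optional path to an external transcriptome
#'   FASTA for the off-target stage (a locus-derived toy transcriptome
#'   is used when NULL).
#' @param stages stages to run, in dependency order.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("spliceaso_run_"),
                            depth = 30L, error_rate = 0.01,
                            psi_true = c(0.028, 0.018, 0.0087, 0.013),
                            junction_reads = 5000L,
                            lr_proportions = c(canonical = 0.866,
                                               MT1 = 0.062, MT2 = 0.072),
                            lr_reads = 20000L,
                            design_flank = 60L,
                            doses = serial_dilution(20, 4, 5),
                            drc_ec50 = 2, drc_hill = 1.5,
                            drc_noise_sd = 5,
                            transcriptome_fasta = NULL,
                            stages = c("locus", "simulate", "consensus",
                                       "quantify", "design", "offtarget",
                                       "pharmacology")) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in dependency order and writes every
#' intermediate product plus a manifest (`manifest.json`: config echo,
#' package version, per-stage outputs with MD5 checksums). Idempotent
#' for a fixed config; any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   package_version =
                     as.character(utils::packageVersion("spliceaso")),
                   stages = list())
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    files <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))))
    invisible(NULL)
  }
  p <- function(...) file.path(config$out_dir, ...)

  run_stage("locus", function() {
    env$locus <- build_fixture_locus()
    write_locus_fasta(env$locus, p("locus.fasta"))
    write_locus_gff3(env$locus, p("transcripts.gff3"))
    write_delins_vcf(env$locus$delins, locus_anchor_base(env$locus),
                     p("delins.vcf"))
    p(c("locus.fasta", "transcripts.gff3", "delins.vcf"))
  })

  run_stage("simulate", function() {
    if (is.null(env$locus)) env$locus <- build_fixture_locus()
    env$pileup <- simulate_phased_pileup(
      env$locus, config$depth, config$error_rate,
      seed = .derive_seed(config$seed, 1L))
    write_pileup_tsv(env$pileup, p("pileup.tsv"))
    env$junctions <- lapply(seq_along(config$psi_true), function(i) {
      simulate_junction_counts(env$locus, config$psi_true[i],
                               config$junction_reads,
                               seed = .derive_seed(config$seed, 10L + i))
    })
    jt <- do.call(rbind, Map(function(tab, i) {
      tab$sample <- sprintf("Pt%d", i)
      tab
    }, env$junctions, seq_along(env$junctions)))
    write_table(jt, p("junctions.tsv"))
    env$reads <- simulate_long_reads(
      env$locus, config$lr_proportions, config$lr_reads,
      seed = .derive_seed(config$seed, 2L))
    write_table(env$reads, p("long_reads.tsv"))
    env$dose_tab <- simulate_dose_response(
      ec50 = config$drc_ec50, hill = config$drc_hill,
      doses = config$doses, noise_sd = config$drc_noise_sd,
      seed = .derive_seed(config$seed, 3L), mode = "stimulation",
      aso_id = "ASO_demo")
    write_table(env$dose_tab, p("dose_response.csv"))
    p(c("pileup.tsv", "junctions.tsv", "long_reads.tsv",
        "dose_response.csv"))
  })

  run_stage("consensus", function() {
    if (is.null(env$pileup)) stop("simulate stage output missing")
    report <- lapply(c(1L, 2L), function(h) {
      cons <- call_consensus(env$pileup, haplotype = h)
      truth <- if (h == 1L) env$locus$delins$ref_seq else
        env$locus$delins$alt_seq
      iv <- if (h == 1L) env$locus$meta$indel_ref else
        env$locus$meta$indel_alt
      keep <- cons$positions >= iv[1] & cons$positions <= iv[2]
      segment <- paste(.chars(cons$sequence)[keep], collapse = "")
      list(haplotype = h, consensus_full = cons$sequence,
           consensus_indel_segment = segment,
           matches_truth = identical(segment, truth),
           n_excluded = length(cons$excluded_positions))
    })
    jsonlite::write_json(report, p("consensus.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    p("consensus.json")
  })

  run_stage("quantify", function() {
    if (is.null(env$junctions)) stop("simulate stage output missing")
    psi <- lapply(env$junctions, function(tab) {
      est <- compute_psi(filter_junctions(tab, 0L), env$locus)
      list(psi_percent = 100 * est$psi,
           ci = c(100 * est$ci_low, 100 * est$ci_high),
           inclusion = est$inclusion_count,
           exclusion = est$exclusion_count)
    })
    quant <- assign_reads(env$reads, env$locus)
    orf <- lapply(names(env$locus$transcripts), function(id) {
      a <- annotate_orf(id, env$locus)
      a[c("transcript_id", "stop_codon", "stop_offset_in_pseudoexon",
          "distance_stop_to_last_junction", "nmd_predicted")]
    })
    jsonlite::write_json(
      list(psi = psi,
           isoform_counts = as.list(quant$counts),
           isoform_proportions = as.list(quant$proportions),
           orf = orf),
      p("quantification.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    p("quantification.json")
  })

  run_stage("design", function() {
    if (is.null(env$locus)) env$locus <- build_fixture_locus()
    env$candidates <- design_asos(env$locus, flank = config$design_flank)
    write_table(as.data.frame(env$candidates), p("aso_candidates.csv"))
    p("aso_candidates.csv")
  })

  run_stage("offtarget", function() {
    if (is.null(env$candidates)) stop("design stage output missing")
    if (!is.null(config$transcriptome_fasta)) {
      if (!file.exists(config$transcriptome_fasta)) {
        stop("transcriptome FASTA not found: ",
             config$transcriptome_fasta)
      }
      seqs <- read_fasta(config$transcriptome_fasta)
      txs <- lapply(names(seqs), function(id) {
        list(id = id, premrna = unname(seqs[id]),
             exons = data.frame(start = 1L, end = nchar(seqs[id])),
             gene = id, canonical = TRUE)
      })
    } else {
      txs <- locus_transcriptome(env$locus,
                                 seed = .derive_seed(config$seed, 4L))
    }
    index <- build_transcriptome_index(txs)
    env$offtargets <- summarize_offtargets(
      env$candidates, index, on_target_genes = env$locus$name)
    env$report <- design_report(env$candidates, env$offtargets)
    write_table(as.data.frame(env$report), p("design_report.csv"))
    p("design_report.csv")
  })

  run_stage("pharmacology", function() {
    if (is.null(env$dose_tab)) stop("simulate stage output missing")
    fit <- fit_dose_response(env$dose_tab, mode = "stimulation")
    top_dose <- max(config$doses)
    hits <- call_hits(env$dose_tab, threshold_percent = 140,
                      at_dose = top_dose)
    jsonlite::write_json(
      list(fit = fit[c("aso_id", "mode", "ec50_or_ic50", "hill",
                       "r_squared", "converged")],
           hits_over_140_at_top_dose = as.list(hits)),
      p("pharmacology.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    p("pharmacology.json")
  })

  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
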