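## 18-mer ASO candidate tiling across the target pre-mRNA window with
## GC, homopolymer and allele-specificity accounting.

#' Design configuration for ASO tiling and filtering
#'
#' @param aso_length oligo length (18-mers by default).
#' @param step tiling step in nt (1-nt resolution by default).
#' @param gc_min,gc_max inclusive GC-fraction bounds (candidates outside
#'   25--75\% are rejected by default).
#' @param max_run_allowed longest tolerated homopolymer run (runs of six
#'   or more are rejected by default).
#' @param alphabet report ASO sequences in `"RNA"` (U) or `"DNA"` (T).
#' @return a `design_config` list.
#' @export
design_config <- function(aso_length = 18L, step = 1L, gc_min = 0.25,
                          gc_max = 0.75, max_run_allowed = 5L,
                          alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(aso_length >= 1L, step >= 1L,
            gc_min >= 0, gc_min < gc_max, gc_max <= 1)
  structure(list(aso_length = as.integer(aso_length),
                 step = as.integer(step), gc_min = gc_min, gc_max = gc_max,
                 max_run_allowed = as.integer(max_run_allowed),
                 alphabet = alphabet),
            class = "design_config")
}

## GC fraction of a DNA string
.gc_fraction <- function(seq) {
  ch <- .chars(seq)
  sum(ch %in% c("G", "C")) / length(ch)
}

## longest single-base run
.max_run <- function(seq) {
  max(rle(.chars(seq))$lengths)
}

#' Tile ASO candidates across a window at fixed resolution
#'
#' Emits one candidate per start position (`window_len - aso_length + 1`
#' candidates at step 1), ordered 5' to 3' along the transcript-sense
#' target. Each candidate records its target site and the antisense
#' oligo sequence (reverse complement of the target, in the configured
#' alphabet), together with GC fraction and longest homopolymer run and
#' the corresponding pass flags.
#'
#' @param target_premrna transcript-sense pre-mRNA sequence (DNA string).
#' @param window `c(start, end)` 1-based inclusive positions within
#'   `target_premrna`; must be at least `aso_length` wide.
#' @param config a [design_config()].
#' @return an `aso_candidates` data frame: `id`, `target_start`,
#'   `target_end`, `target_seq`, `aso_seq`, `gc_fraction`,
#'   `max_homopolymer_run`, `pass_gc`, `pass_homopolymer`.
#' @export
tile_candidates <- function(target_premrna, window,
                            config = design_config()) {
  len <- config$aso_length
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > nchar(target_premrna)) {
    stop("window falls outside the target sequence")
  }
  if (window[2] - window[1] + 1L < len) {
    stop("window is shorter than the ASO length")
  }
  starts <- seq.int(window[1], window[2] - len + 1L, by = config$step)
  target_seq <- substring(target_premrna, starts, starts + len - 1L)
  aso_dna <- vapply(target_seq, reverse_complement, character(1),
                    USE.NAMES = FALSE)
  aso_seq <- if (config$alphabet == "RNA") chartr("T", "U", aso_dna) else
    aso_dna
  gc <- vapply(target_seq, .gc_fraction, numeric(1), USE.NAMES = FALSE)
  run <- vapply(target_seq, .max_run, integer(1), USE.NAMES = FALSE)
  out <- data.frame(
    id = sprintf("ASO_%05d", starts),
    target_start = starts,
    target_end = starts + len - 1L,
    target_seq = target_seq,
    aso_seq = aso_seq,
    gc_fraction = gc,
    max_homopolymer_run = run,
    stringsAsFactors = FALSE
  )
  out$pass_gc <- gc_filter(out, config$gc_min, config$gc_max)
  out$pass_homopolymer <- homopolymer_filter(out, config$max_run_allowed)
  class(out) <- c("aso_candidates", "data.frame")
  out
}

#' GC-content filter
#'
#' TRUE iff `gc_min <= gc_fraction <= gc_max` (inclusive bounds: a
#' candidate at exactly 25\% or 75\% GC passes).
#'
#' @param candidates an `aso_candidates` data frame (or any data frame
#'   with a `gc_fraction` column).
#' @param gc_min,gc_max inclusive bounds.
#' @return logical vector, one flag per candidate.
#' @export
gc_filter <- function(candidates, gc_min = 0.25, gc_max = 0.75) {
  candidates$gc_fraction >= gc_min & candidates$gc_fraction <= gc_max
}

#' Homopolymer-run filter
#'
#' FALSE iff any single-base run exceeds `max_run_allowed` (runs of
#' `max_run_allowed + 1` or more — six or more by default — are
#' rejected; a run of exactly five passes).
#'
#' @param candidates an `aso_candidates` data frame (or any data frame
#'   with a `max_homopolymer_run` column).
#' @param max_run_allowed longest tolerated run.
#' @return logical vector, one flag per candidate.
#' @export
homopolymer_filter <- function(candidates, max_run_allowed = 5L) {
  candidates$max_homopolymer_run <= max_run_allowed
}

#' Hamming mismatches of a candidate's target site against each allele
#'
#' Compares a candidate target sequence with the anchored windows on the
#' two alleles. A window given as `NA` (no anchored liftover exists, e.g.
#' the candidate overlaps the insertion breakpoints on the reference
#' allele) yields an `NA` count — the site is marked absent rather than
#' raising an error.
#'
#' @param target_seq candidate target sequence (transcript sense).
#' @param ref_allele_window,alt_allele_window anchored windows of the
#'   same length on each allele, or `NA` when anchoring is impossible.
#' @return named numeric vector `c(mismatches_vs_ref, mismatches_vs_alt)`.
#' @export
allele_specificity <- function(target_seq, ref_allele_window,
                               alt_allele_window) {
  hamming <- function(win) {
    if (length(win) != 1L || is.na(win)) return(NA_integer_)
    if (nchar(win) != nchar(target_seq)) {
      stop("allele window length differs from the candidate length")
    }
    sum(.chars(target_seq) != .chars(win))
  }
  c(mismatches_vs_ref = hamming(ref_allele_window),
    mismatches_vs_alt = hamming(alt_allele_window))
}

#' Design ASO candidates against the fixture locus
#'
#' Tiles the window `delins +/- flank` of the variant-haplotype pre-mRNA
#' (transcript sense) at 1-nt resolution and annotates each candidate
#' with allele-specificity counts. With `allele = "reported"` the design
#' target carries the previously reported insertion sequence (one
#' nucleotide different), reproducing a first design round made before
#' the allele was corrected; mismatch counts are still taken against the
#' true haplotypes.
#'
#' @param locus a `locus_model`.
#' @param flank nt of flanking sequence either side of the insertion.
#' @param allele design against the `"corrected"` (default) or
#'   `"reported"` insertion allele.
#' @param config a [design_config()].
#' @return an `aso_candidates` data frame with `mismatches_vs_ref` /
#'   `mismatches_vs_alt` columns added (coordinates are transcript-sense
#'   positions on the variant haplotype).
#' @export
design_asos <- function(locus, flank = 60L,
                        allele = c("corrected", "reported"),
                        config = design_config()) {
  allele <- match.arg(allele)
  ts_alt <- premrna_sense(locus, "alt")
  ins_start <- locus$meta$ins_ts_start
  ins_len <- nchar(locus$delins$alt_seq)
  ins_end <- ins_start + ins_len - 1L
  design_target <- ts_alt
  if (allele == "reported") {
    ins_true <- substr(ts_alt, ins_start, ins_end)
    reported <- ins_true
    substr(reported, 13L, 13L) <- "G"  # the historically reported base
    design_target <- .patch(design_target, ins_start, reported)
  }
  window <- c(max(1L, ins_start - as.integer(flank)),
              min(nchar(design_target), ins_end + as.integer(flank)))
  cand <- tile_candidates(design_target, window, config)

  shift <- locus$meta$shift
  mm <- t(vapply(seq_len(nrow(cand)), function(i) {
    s <- cand$target_start[i]
    e <- cand$target_end[i]
    alt_win <- substr(ts_alt, s, e)
    ## anchored ref window exists only for candidates clear of the
    ## insertion (no liftover across a breakpoint)
    ref_win <- if (e < ins_start) {
      substr(premrna_sense(locus, "ref"), s, e)
    } else if (s > ins_end) {
      substr(premrna_sense(locus, "ref"), s - shift, e - shift)
    } else {
      NA_character_
    }
    allele_specificity(cand$target_seq[i], ref_win, alt_win)
  }, c(mismatches_vs_ref = 0, mismatches_vs_alt = 0)))
  cand$mismatches_vs_ref <- as.integer(mm[, "mismatches_vs_ref"])
  cand$mismatches_vs_alt <- as.integer(mm[, "mismatches_vs_alt"])
  attr(cand, "allele") <- allele
  attr(cand, "ins_interval_ts") <- c(ins_start, ins_end)
  cand
}

#' Assemble the ranked design report
#'
#' Joins the candidate metrics with off-target results and computes the
#' overall pass flag as the conjunction of the GC, homopolymer and
#' off-target filters, with a `reason` column naming failed filters.
#' Rows keep their stable 5'-to-3' positional order.
#'
#' @param candidates an `aso_candidates` data frame.
#' @param offtarget_results data frame with `id` and `pass_offtarget`
#'   (e.g. from [summarize_offtargets()]); `NULL` if the off-target
#'   screen has not been run, in which case the overall flag uses the
#'   two sequence filters only.
#' @return a `design_report` data frame with `pass_offtarget`,
#'   `pass_overall` and `reason` columns.
#' @export
design_report <- function(candidates, offtarget_results = NULL) {
  out <- as.data.frame(candidates)
  if (!is.null(offtarget_results)) {
    idx <- match(out$id, offtarget_results$id)
    out$pass_offtarget <- offtarget_results$pass_offtarget[idx]
  } else {
    out$pass_offtarget <- NA
  }
  ot <- ifelse(is.na(out$pass_offtarget), TRUE, out$pass_offtarget)
  out$pass_overall <- out$pass_gc & out$pass_homopolymer & ot
  reason <- function(i) {
    r <- c(if (!out$pass_gc[i]) "gc",
           if (!out$pass_homopolymer[i]) "homopolymer",
           if (!ot[i]) "offtarget")
    if (length(r) == 0L) "" else paste(r, collapse = ",")
  }
  out$reason <- vapply(seq_len(nrow(out)), reason, character(1))
  out <- out[order(out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("design_report", "data.frame")
  out
}
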