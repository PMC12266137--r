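## Pseudoexon PSI from junction counts, long-read isoform assignment by
## junction-chain matching, and ORF/PTC annotation with an NMD prediction.

#' Filter a junction table by minimum read count
#'
#' Removes junctions supported by fewer than `min_count` reads (the
#' conventional sashimi-style display filter keeps junctions with at
#' least 3 reads). Row order is preserved.
#'
#' @param table a `junction_table` data frame (`donor`, `acceptor`,
#'   `count`, optional `label`).
#' @param min_count minimum retained read count.
#' @return the filtered table, same class and column order.
#' @export
filter_junctions <- function(table, min_count = 3L) {
  stopifnot(all(c("donor", "acceptor", "count") %in% names(table)))
  out <- table[table$count >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Count for one (donor, acceptor) pair; 0 when absent.
.junction_count <- function(table, pair) {
  hit <- table$donor == pair[["donor"]] &
    table$acceptor == pair[["acceptor"]]
  if (!any(hit)) 0L else sum(table$count[hit])
}

#' Pseudoexon percent spliced in (PSI) from a junction table
#'
#' PSI = inclusion / (inclusion + exclusion). The inclusion count is
#' taken from the acceptor-side junction (exon15 -> pseudoexon; shared by
#' both mutant isoforms) by default; `side = "donor"` pools the two
#' cryptic donor junctions instead, and `side = "mean"` averages the two
#' estimates. A Wilson score confidence interval is attached (computed
#' from the acceptor-side counts for `side = "mean"`).
#'
#' @param table a `junction_table`.
#' @param locus a `locus_model` defining the diagnostic junctions.
#' @param side `"acceptor"`, `"donor"` or `"mean"`.
#' @param conf confidence level for the Wilson interval.
#' @return a `psi_estimate`: `inclusion_count`, `exclusion_count`, `psi`
#'   (fraction), `ci_low`, `ci_high`, `side`, and `defined` (FALSE when
#'   the denominator is zero, in which case `psi` is NA rather than NaN).
#' @export
compute_psi <- function(table, locus, side = c("acceptor", "donor", "mean"),
                        conf = 0.95) {
  side <- match.arg(side)
  q <- locus_quant_junctions(locus)
  exc <- .junction_count(table, q$exclusion)
  inc_acc <- .junction_count(table, q$inclusion)
  inc_don <- .junction_count(table, q$donor_mt1) +
    .junction_count(table, q$donor_mt2)
  inc <- switch(side, acceptor = inc_acc, donor = inc_don, mean = inc_acc)
  psi_of <- function(i) if (i + exc > 0L) i / (i + exc) else NA_real_
  psi <- switch(side,
                acceptor = psi_of(inc_acc),
                donor = psi_of(inc_don),
                mean = mean(c(psi_of(inc_acc), psi_of(inc_don))))
  defined <- !is.na(psi)
  ci <- if (defined) .wilson_ci(inc, inc + exc, conf) else c(NA_real_,
                                                            NA_real_)
  structure(
    list(inclusion_count = as.integer(inc),
         exclusion_count = as.integer(exc),
         psi = psi, ci_low = ci[1], ci_high = ci[2],
         side = side, defined = defined),
    class = "psi_estimate"
  )
}

#' @export
print.psi_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("PSI (%s side): %.4g%% [%.4g%%, %.4g%%] (inc %d / exc %d)\n",
                x$side, 100 * x$psi, 100 * x$ci_low, 100 * x$ci_high,
                x$inclusion_count, x$exclusion_count))
  } else {
    cat("PSI undefined: zero inclusion + exclusion reads\n")
  }
  invisible(x)
}

## tokens of a chain string
.chain_tokens <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0)
  else strsplit(s, ",", fixed = TRUE)[[1]]
}

## is `sub` a contiguous subsequence of `full`?
.is_contiguous_subchain <- function(sub, full) {
  ns <- length(sub)
  nf <- length(full)
  if (ns == 0L || ns > nf) return(FALSE)
  for (i in seq_len(nf - ns + 1L)) {
    if (all(full[i:(i + ns - 1L)] == sub)) return(TRUE)
  }
  FALSE
}

#' Assign long reads to isoform models by junction-chain matching
#'
#' A read is assigned to the unique transcript model whose junction chain
#' contains the read's chain as a contiguous subchain, provided the read
#' covers at least `min_diagnostic_junctions` junctions that discriminate
#' among the models (junctions absent from at least one model). Reads
#' compatible with several models, or covering no diagnostic junction,
#' are counted as ambiguous and never fractionally allocated. Proportions
#' are computed over assigned reads.
#'
#' @param reads a `read_chains` data frame from [simulate_long_reads()]
#'   (columns `read_id`, `chain`).
#' @param locus a `locus_model` supplying the transcript models (their
#'   junction chains must be distinct).
#' @param min_diagnostic_junctions minimum discriminating junctions.
#' @return an `isoform_quant`: `counts` (named, including `ambiguous`),
#'   `proportions` (over assigned reads), `n_assigned`, `n_ambiguous`,
#'   and `assignments` (per-read data frame).
#' @export
assign_reads <- function(reads, locus, min_diagnostic_junctions = 1L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "chain") %in%
                                        names(reads)))
  ids <- names(locus$transcripts)
  model_chains <- lapply(ids, function(id) {
    .chain_tokens(.chain_to_string(
      transcript_junctions(locus, id, coords = "alt")))
  })
  names(model_chains) <- ids
  keys <- vapply(model_chains, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) {
    stop("configuration error: transcript models with identical junction ",
         "chains cannot be discriminated")
  }
  ## a junction discriminates unless every model contains it
  all_tokens <- unique(unlist(model_chains))
  in_all <- vapply(all_tokens, function(tk) {
    all(vapply(model_chains, function(mc) tk %in% mc, logical(1)))
  }, logical(1))
  diagnostic <- all_tokens[!in_all]

  uniq <- unique(reads$chain)
  assign_one <- function(s) {
    toks <- .chain_tokens(s)
    if (length(toks) == 0L) return("ambiguous")
    compat <- ids[vapply(model_chains, function(mc) {
      .is_contiguous_subchain(toks, mc)
    }, logical(1))]
    n_diag <- sum(toks %in% diagnostic)
    if (length(compat) == 1L && n_diag >= min_diagnostic_junctions) {
      compat
    } else {
      "ambiguous"
    }
  }
  uniq_assign <- vapply(uniq, assign_one, character(1))
  assigned <- unname(uniq_assign[match(reads$chain, uniq)])
  counts <- table(factor(assigned, levels = c(ids, "ambiguous")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_assigned <- sum(counts[ids])
  proportions <- if (n_assigned > 0L) counts[ids] / n_assigned else
    stats::setNames(rep(NA_real_, length(ids)), ids)
  structure(
    list(counts = counts, proportions = proportions,
         n_assigned = n_assigned, n_ambiguous = counts[["ambiguous"]],
         assignments = data.frame(read_id = reads$read_id,
                                  assigned_isoform = assigned,
                                  stringsAsFactors = FALSE)),
    class = "isoform_quant"
  )
}

#' @export
print.isoform_quant <- function(x, ...) {
  cat("isoform assignment:\n")
  for (id in names(x$counts)) {
    cat(sprintf("  %-10s %8d", id, x$counts[[id]]))
    if (id %in% names(x$proportions)) {
      cat(sprintf("  (%.3f%% of assigned)", 100 * x$proportions[[id]]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Infer internal exon lengths from a read's junction chain
#'
#' For a read covering consecutive junctions, every exon between two
#' observed junctions is fully determined: it spans from the acceptor of
#' one junction to the donor of the next. Returns the lengths of these
#' internal exons in transcript order; for a full-length mutant read the
#' last internal exon is the pseudoexon.
#'
#' @param chain a chain data frame (`donor`, `acceptor`) or encoded chain
#'   string, junctions in transcript order.
#' @param strand gene strand (`"-"` by default, matching the fixture).
#' @return integer vector of internal exon lengths (empty if < 2
#'   junctions).
#' @export
infer_exon_lengths <- function(chain, strand = "-") {
  if (is.character(chain)) chain <- .string_to_chain(chain)
  n <- nrow(chain)
  if (n < 2L) return(integer(0))
  if (strand == "-") {
    as.integer(chain$acceptor[-n] - chain$donor[-1L] + 1L)
  } else {
    as.integer(chain$donor[-1L] - chain$acceptor[-n] + 1L)
  }
}

#' ORF scan and NMD-rule annotation of a transcript
#'
#' Scans in-frame triplets of the spliced mRNA from the canonical start
#' codon to the first stop codon (UAA/UAG/UGA). When the stop falls
#' inside the transcript's pseudoexon, its offset is reported as the
#' number of pseudoexon nucleotides 5' of the stop triplet. NMD is
#' predicted by the canonical junction rule: the stop must lie upstream
#' of the last exon-exon junction by more than `nmd_threshold_nt`
#' nucleotides and must not be in the last exon.
#'
#' @param transcript_id transcript id in `locus$transcripts`.
#' @param locus a `locus_model` (supplies the spliced sequence and the
#'   canonical start position).
#' @param nmd_threshold_nt NMD distance threshold (50 nt by default).
#' @return an `orf_annotation`: `transcript_id`, `stop_codon` (RNA
#'   alphabet), `stop_position_mrna`, `stop_offset_in_pseudoexon` (NA for
#'   non-pseudoexon stops), `distance_stop_to_last_junction` (positive if
#'   the stop is upstream of the junction), `stop_in_last_exon`,
#'   `nmd_predicted`.
#' @export
annotate_orf <- function(transcript_id, locus, nmd_threshold_nt = 50L) {
  tx <- locus$transcripts[[transcript_id]]
  if (is.null(tx)) stop("unknown transcript: ", transcript_id)
  cds_start <- locus$meta$cds_start_mrna
  if (is.null(cds_start)) {
    stop("no canonical start codon defined for this locus")
  }
  mrna <- spliced_sequence(locus, transcript_id)
  if (substr(mrna, cds_start, cds_start + 2L) != "ATG") {
    stop("no start codon at the annotated canonical start position")
  }
  stop_at <- .first_stop(mrna, cds_start)
  if (is.na(stop_at)) {
    stop("no in-frame stop codon found downstream of the start codon")
  }
  stop_codon <- chartr("T", "U", substr(mrna, stop_at, stop_at + 2L))
  exon_lens <- tx$exons$end - tx$exons$start + 1L
  total <- sum(exon_lens)
  last_junction <- total - exon_lens[length(exon_lens)]  # mRNA pos of the
  # last base before the final junction
  distance <- as.integer(last_junction - (stop_at + 2L))
  stop_in_last_exon <- (stop_at + 2L) > last_junction
  offset_in_pe <- NA_integer_
  if (isTRUE(tx$is_mutant)) {
    pe_len <- pseudoexon_length(locus, transcript_id)
    pe_start <- locus$meta$mrna_pe_start  # nt upstream of the pseudoexon
    if (stop_at > pe_start && (stop_at + 2L) <= pe_start + pe_len) {
      offset_in_pe <- as.integer(stop_at - 1L - pe_start)
    }
  }
  structure(
    list(transcript_id = transcript_id,
         stop_codon = stop_codon,
         stop_position_mrna = as.integer(stop_at),
         stop_offset_in_pseudoexon = offset_in_pe,
         distance_stop_to_last_junction = distance,
         stop_in_last_exon = stop_in_last_exon,
         nmd_predicted = !stop_in_last_exon &&
           distance > nmd_threshold_nt),
    class = "orf_annotation"
  )
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("ORF annotation for %s: stop %s at mRNA %d\n",
              x$transcript_id, x$stop_codon, x$stop_position_mrna))
  if (!is.na(x$stop_offset_in_pseudoexon)) {
    cat(sprintf("  %d pseudoexon nt 5' of the stop\n",
                x$stop_offset_in_pseudoexon))
  }
  cat(sprintf("  distance to last junction: %d nt; NMD predicted: %s\n",
              x$distance_stop_to_last_junction, x$nmd_predicted))
  invisible(x)
}
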