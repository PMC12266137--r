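## Variant application and per-haplotype consensus reconstruction from
## phased pileups: the indel-resolution procedure for a complex delins.

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' Complements every base (including ambiguity codes) and reverses the
#' string. The operation is an involution.
#'
#' @param seq character scalar, uppercase DNA possibly containing IUPAC
#'   ambiguity codes.
#' @return character scalar of the same length.
#' @examples
#' reverse_complement("CCACCACAC")            # "GTGTGGTGG"
#' reverse_complement("ACCTGTAATGTAAAAAACA")  # "TGTTTTTTACATTACAGGT"
#' @export
reverse_complement <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  ch <- .chars(seq)
  comp <- .complement_map[ch]
  bad <- which(is.na(comp))
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' at position %d", ch[bad[1L]],
                 bad[1L]))
  }
  paste(rev(unname(comp)), collapse = "")
}

#' Construct a delins (deletion-insertion) variant description
#'
#' A delins replaces the reference bases in `[start, end]` (1-based
#' inclusive genomic coordinates, plus strand) with `alt_seq`.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive genomic interval of the replaced run.
#' @param ref_seq plus-strand reference bases at `[start, end]`.
#' @param alt_seq plus-strand replacement bases.
#' @param hgvs_label optional HGVS-style label carried as metadata.
#' @return an object of class `delins_variant`.
#' @export
delins_variant <- function(chrom, start, end, ref_seq, alt_seq,
                           hgvs_label = NULL) {
  .check_dna(ref_seq, what = "ref_seq")
  .check_dna(alt_seq, what = "alt_seq")
  stopifnot(start <= end)
  if (end - start + 1L != nchar(ref_seq)) {
    stop("end - start + 1 must equal nchar(ref_seq)")
  }
  structure(
    list(chrom = chrom, start = as.integer(start), end = as.integer(end),
         ref_seq = ref_seq, alt_seq = alt_seq, hgvs_label = hgvs_label),
    class = "delins_variant"
  )
}

#' @export
print.delins_variant <- function(x, ...) {
  cat(sprintf("delins %s:%d-%d %s>%s (%d nt -> %d nt)\n", x$chrom, x$start,
              x$end, x$ref_seq, x$alt_seq, nchar(x$ref_seq),
              nchar(x$alt_seq)))
  if (!is.null(x$hgvs_label)) cat(" ", x$hgvs_label, "\n")
  invisible(x)
}

#' Apply a delins variant to a genomic segment
#'
#' Replaces the variant's reference run inside a plus-strand segment with
#' the alternate run. The segment substring at the variant interval must
#' equal `variant$ref_seq`; a mismatch raises an error reporting expected
#' vs observed bases, which guards against coordinate-convention slips.
#'
#' @param ref plus-strand segment sequence.
#' @param variant a [delins_variant()].
#' @param segment_offset genomic position (1-based) of the first base of
#'   `ref`.
#' @return the edited segment; its length changes by
#'   `nchar(alt_seq) - nchar(ref_seq)`.
#' @export
apply_delins <- function(ref, variant, segment_offset = 1L) {
  stopifnot(inherits(variant, "delins_variant"))
  local_start <- variant$start - segment_offset + 1L
  local_end <- variant$end - segment_offset + 1L
  if (local_start < 1L || local_end > nchar(ref)) {
    stop("variant interval falls outside the segment")
  }
  observed <- substr(ref, local_start, local_end)
  if (!identical(observed, variant$ref_seq)) {
    stop(sprintf(
      "reference mismatch at %s:%d-%d: expected '%s', observed '%s'",
      variant$chrom, variant$start, variant$end, variant$ref_seq, observed))
  }
  paste0(substr(ref, 1L, local_start - 1L), variant$alt_seq,
         substr(ref, local_end + 1L, nchar(ref)))
}

#' Invert a delins variant
#'
#' Returns the variant that undoes `variant` when applied to the edited
#' (alt) segment: the alt run at the same left breakpoint is replaced by
#' the original reference run.
#'
#' @param variant a [delins_variant()].
#' @return a [delins_variant()] with ref and alt swapped.
#' @export
invert_delins <- function(variant) {
  delins_variant(variant$chrom, variant$start,
                 variant$start + nchar(variant$alt_seq) - 1L,
                 ref_seq = variant$alt_seq, alt_seq = variant$ref_seq)
}

#' Call a per-haplotype consensus sequence from a pileup
#'
#' At every column the majority base is emitted when its read support
#' reaches `min_support`; columns whose best base has fewer supporting
#' reads are excluded and recorded (single-read positions are excluded
#' under the default `min_support = 2`). Ties between bases are emitted as
#' the corresponding IUPAC ambiguity code (`tie_policy = "ambiguity"`,
#' with a warning) or raise an error (`tie_policy = "fail"`). A column
#' whose majority call is a deletion emits no base. An insertion observed
#' after a column is included in the consensus when its count exceeds half
#' the column depth (majority of reads carry it).
#'
#' @param pileup a `pileup_block` (see [simulate_phased_pileup()]) or a
#'   `phased_pileup` together with `haplotype`.
#' @param haplotype haplotype id to extract when `pileup` is phased.
#' @param min_support minimum supporting reads for an emitted base.
#' @param tie_policy `"ambiguity"` or `"fail"`.
#' @return an object of class `haplotype_consensus` with fields
#'   `haplotype_id`, `sequence`, `support` (per emitted base),
#'   `positions` (source column of each emitted base) and
#'   `excluded_positions`.
#' @export
call_consensus <- function(pileup, haplotype = NULL, min_support = 2L,
                           tie_policy = c("ambiguity", "fail")) {
  tie_policy <- match.arg(tie_policy)
  if (inherits(pileup, "phased_pileup")) {
    if (is.null(haplotype)) {
      stop("pileup is phased; supply haplotype = 1 or 2")
    }
    pileup <- pileup$haplotypes[[as.character(haplotype)]]
    if (is.null(pileup)) stop("no such haplotype in pileup")
  }
  cols <- pileup$columns
  if (is.null(cols) || nrow(cols) == 0L) stop("empty pileup")
  bases <- c("A", "C", "G", "T")
  out_base <- character(0)
  out_support <- integer(0)
  out_pos <- integer(0)
  excluded <- integer(0)
  for (i in seq_len(nrow(cols))) {
    counts <- c(A = cols$A[i], C = cols$C[i], G = cols$G[i], T = cols$T[i],
                DEL = cols$DEL[i])
    best <- max(counts)
    if (best < min_support) {
      excluded <- c(excluded, cols$pos[i])
    } else {
      winners <- names(counts)[counts == best]
      if (length(winners) > 1L) {
        if (tie_policy == "fail") {
          stop(sprintf("tie at position %d among {%s}", cols$pos[i],
                       paste(winners, collapse = ",")))
        }
        warning(sprintf("tie at position %d among {%s}; emitting IUPAC code",
                        cols$pos[i], paste(winners, collapse = ",")),
                call. = FALSE)
        winners <- setdiff(winners, "DEL")
        if (length(winners) == 0L) next  # deletion wins the tie outright
        emit <- .iupac_from_bases(winners)
      } else if (winners == "DEL") {
        next
      } else {
        emit <- winners
      }
      out_base <- c(out_base, emit)
      out_support <- c(out_support, unname(best))
      out_pos <- c(out_pos, cols$pos[i])
    }
    ## post-column insertion: included when a majority of reads carry it
    ins <- cols$INS[[i]]
    if (length(ins) > 0L) {
      depth <- sum(counts)
      top <- which.max(ins)
      if (ins[top] > depth / 2 && ins[top] >= min_support) {
        ins_seq <- names(ins)[top]
        out_base <- c(out_base, .chars(ins_seq))
        out_support <- c(out_support, rep(unname(ins[top]), nchar(ins_seq)))
        out_pos <- c(out_pos, rep(cols$pos[i], nchar(ins_seq)))
      }
    }
  }
  structure(
    list(haplotype_id = pileup$haplotype_id,
         sequence = paste(out_base, collapse = ""),
         support = out_support,
         positions = out_pos,
         excluded_positions = excluded),
    class = "haplotype_consensus"
  )
}

#' @export
print.haplotype_consensus <- function(x, ...) {
  cat(sprintf("haplotype %s consensus: %d nt (%d positions excluded)\n",
              x$haplotype_id, nchar(x$sequence),
              length(x$excluded_positions)))
  invisible(x)
}

#' Compare a consensus against reference and reported alleles
#'
#' Position-by-position (anchored, same orientation) comparison of a
#' consensus sequence against one or two comparator alleles, e.g. the
#' reference allele and a previously reported variant allele.
#'
#' @param consensus a `haplotype_consensus` or a plain character sequence.
#' @param reference_allele comparator sequence (same orientation).
#' @param reported_allele optional second comparator.
#' @return a list of class `allele_report`; per comparator a data frame of
#'   mismatch positions (`offset`, 1-based; `consensus`, `comparator`
#'   bases) and a summary count.
#' @export
compare_alleles <- function(consensus, reference_allele,
                            reported_allele = NULL) {
  seq <- if (inherits(consensus, "haplotype_consensus")) {
    consensus$sequence
  } else {
    consensus
  }
  cmp_one <- function(comparator, label) {
    if (nchar(seq) != nchar(comparator)) {
      stop(sprintf(
        "length mismatch vs %s (%d vs %d nt): anchor the comparison to a common interval first",
        label, nchar(seq), nchar(comparator)))
    }
    a <- .chars(seq)
    b <- .chars(comparator)
    idx <- which(a != b)
    data.frame(offset = idx, consensus = a[idx], comparator = b[idx],
               stringsAsFactors = FALSE)
  }
  out <- list(vs_reference = cmp_one(reference_allele, "reference_allele"))
  if (!is.null(reported_allele)) {
    out$vs_reported <- cmp_one(reported_allele, "reported_allele")
  }
  out$n_mismatches <- vapply(
    out[grepl("^vs_", names(out))], nrow, integer(1))
  class(out) <- "allele_report"
  out
}
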