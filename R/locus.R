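## Synthetic two-haplotype locus emulating a minus-strand gene whose
## intron 15 carries a 9 -> 19 nt delins that activates an ectopic splice
## acceptor, producing two pseudoexon-bearing mutant isoforms (MT1/MT2).
## All simulators and downstream stages take their ground truth from this
## fixture.

## Fixed fixture constants. Exon/intron lengths are package choices (all
## introns >= 300 nt so distance-to-exon rules see both sides of 200 nt);
## the delins sequences and coordinates, the pseudoexon lengths, and the
## PTC placement reproduce the modelled locus.
.locus_const <- list(
  chrom = "chr3",
  flank5 = 300L, flank3 = 300L,
  ## transcript order: exon11 .. exon16 (compact tail of a larger gene);
  ## the 5' UTR and start codon sit in exon11 so ORF scanning is exercised
  exon_len = c(exon11 = 180L, exon12 = 120L, exon13 = 150L, exon14 = 90L,
               exon15 = 132L, exon16 = 320L),
  intron_len = c(intron11 = 350L, intron12 = 350L, intron13 = 350L,
                 intron14 = 350L),
  i15_a = 400L,   # intron 15 upstream (transcript sense) of the delins
  i15_b = 600L,   # intron 15 downstream of the delins
  utr5 = 60L,
  cds_exon16 = 243L,  # coding nt in exon16 incl. the normal stop
  ins_ts_ref = "GTGTGGTGG",            # replaced run, transcript sense
  ins_ts_alt = "TGTTTTTTACATTACAGGT",  # inserted run, transcript sense
  delins_ref_start = 81493813L,        # genomic plus-strand coordinates
  delins_ref_end = 81493821L,
  internal_seed = 2053L,
  hgvs = "NM_000158.4(GBE1):c.2053-3358_2053-3350delinsTGTTTTTTACATTACAGGT"
)

#' Evaluate an expression under a temporary RNG seed
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a transcript model
#'
#' @param id transcript identifier.
#' @param exons data frame with `start`, `end` (1-based inclusive genomic
#'   plus-strand coordinates), rows ordered 5' to 3' in transcript
#'   orientation (descending coordinates for a minus-strand gene).
#' @param strand `"+"` or `"-"`.
#' @param is_mutant logical flag.
#' @param coords which haplotype coordinate system the exons live in
#'   (`"ref"` or `"alt"`).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(id, exons, strand, is_mutant = FALSE,
                             coords = c("ref", "alt")) {
  coords <- match.arg(coords)
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            all(exons$start <= exons$end), strand %in% c("+", "-"))
  ord <- if (strand == "-") order(-exons$start) else order(exons$start)
  if (!identical(ord, seq_len(nrow(exons)))) {
    stop("exons must be ordered 5' to 3' in transcript orientation")
  }
  ## non-overlap: in transcript order, consecutive exons must be disjoint
  if (nrow(exons) > 1L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      gap_ok <- if (strand == "-") exons$end[i + 1L] < exons$start[i]
                else exons$start[i + 1L] > exons$end[i]
      if (!gap_ok) stop("exons overlap or are unordered")
    }
  }
  structure(list(id = id, exons = exons, strand = strand,
                 is_mutant = isTRUE(is_mutant), coords = coords),
            class = "transcript_model")
}

#' Spliced length of a transcript model
#' @param tx a `transcript_model`.
#' @export
spliced_length <- function(tx) {
  sum(tx$exons$end - tx$exons$start + 1L)
}

#' Build the packaged fixture locus
#'
#' Constructs the synthetic locus: a minus-strand gene segment of ~4 kb in
#' which the plus-strand run `CCACCACAC` at chr3:81493813-81493821 is
#' replaced on the variant haplotype by the 19-nt run
#' `ACCTGTAATGTAAAAAACA` (transcript sense `TGTTTTTTACATTACAGGT`). The
#' insertion carries an ectopic splice acceptor (`AG` immediately 5' of
#' the pseudoexon start); its usage yields two mutant isoforms whose
#' pseudoexons share the acceptor and differ at the donor-side boundary
#' (241 nt and 206 nt by default). Both mutant isoforms retain canonical
#' exon 16 as their final exon, the pseudoexon being penultimate, and the
#' mRNA-sense triplet at pseudoexon positions 13-15 is the stop codon UAA.
#' Sequence not constrained by these facts is generated pseudo-randomly
#' from a fixed packaged seed and screened so no in-frame stop precedes
#' pseudoexon position 13.
#'
#' @param config optional named list of overrides:
#'   `pseudoexon_len_mt1`, `pseudoexon_len_mt2`, `internal_seed`.
#'   Overrides violating a fixture invariant raise a validation error
#'   naming the invariant.
#' @return an object of class `locus_model` with fields `name`,
#'   `sequence_ref`, `sequence_alt` (genomic plus strand),
#'   `gene_strand`, `delins`, `transcripts` (canonical, MT1, MT2),
#'   `coordinate_offset`, and a `meta` block of derived coordinates.
#' @examples
#' locus <- build_fixture_locus()
#' pseudoexon_length(locus, "MT1")  # 241
#' @export
build_fixture_locus <- function(config = list()) {
  k <- .locus_const
  pe1 <- as.integer(config$pseudoexon_len_mt1 %||% 241L)
  pe2 <- as.integer(config$pseudoexon_len_mt2 %||% 206L)
  seed <- as.integer(config$internal_seed %||% k$internal_seed)
  if (pe1 < 15L || pe2 < 15L) {
    stop("invariant violated: pseudoexon length must be >= 15 nt ",
         "(the PTC occupies pseudoexon positions 13-15)")
  }
  if (pe2 + 2L > pe1) {
    stop("invariant violated: MT2 pseudoexon must be shorter than MT1's ",
         "(donor-side boundary upstream of MT1's donor)")
  }
  if (pe1 > k$i15_b - 4L + 2L) {
    stop("invariant violated: pseudoexon must end inside intron 15")
  }

  pieces <- .with_seed(seed, .locus_sequences(k, pe1, pe2))
  ts_alt <- pieces$ts_alt
  ts_ref <- pieces$ts_ref
  L_alt <- nchar(ts_alt)
  L_ref <- nchar(ts_ref)

  ## transcript-sense coordinates of the delins run (ref: 9 nt, alt: 19 nt)
  ins_ts_start <- as.integer(unname(pieces$ins_ts_start))
  offset <- k$delins_ref_start -
    (L_ref - (ins_ts_start + nchar(k$ins_ts_ref) - 1L))

  ts2gen <- function(a, b, L) {
    ## transcript-sense interval -> genomic plus-strand interval
    c(offset + L - b, offset + L - a)
  }

  delins <- delins_variant(
    chrom = k$chrom,
    start = k$delins_ref_start, end = k$delins_ref_end,
    ref_seq = reverse_complement(k$ins_ts_ref),
    alt_seq = reverse_complement(k$ins_ts_alt),
    hgvs_label = k$hgvs)

  ex_ref <- lapply(pieces$exon_ts, function(iv) ts2gen(iv[1], iv[2], L_ref))
  shift <- nchar(k$ins_ts_alt) - nchar(k$ins_ts_ref)
  ex_alt <- lapply(pieces$exon_ts_alt,
                   function(iv) ts2gen(iv[1], iv[2], L_alt))
  pe_ts_start <- ins_ts_start + nchar(k$ins_ts_alt) - 2L  # "GT" of the ins
  pe1_gen <- ts2gen(pe_ts_start, pe_ts_start + pe1 - 1L, L_alt)
  pe2_gen <- ts2gen(pe_ts_start, pe_ts_start + pe2 - 1L, L_alt)

  mk_exdf <- function(ivs) {
    data.frame(start = as.integer(vapply(ivs, `[`, numeric(1), 1)),
               end = as.integer(vapply(ivs, `[`, numeric(1), 2)))
  }
  canonical <- transcript_model(
    "canonical", mk_exdf(ex_ref), strand = "-", is_mutant = FALSE,
    coords = "ref")
  mt_exons <- function(pe_gen) {
    mk_exdf(c(ex_alt[1:5], list(pe_gen), ex_alt[6]))
  }
  mt1 <- transcript_model("MT1", mt_exons(pe1_gen), strand = "-",
                          is_mutant = TRUE, coords = "alt")
  mt2 <- transcript_model("MT2", mt_exons(pe2_gen), strand = "-",
                          is_mutant = TRUE, coords = "alt")

  locus <- structure(
    list(
      name = "GBE1_synthetic",
      sequence_ref = reverse_complement(ts_ref),
      sequence_alt = reverse_complement(ts_alt),
      gene_strand = "-",
      delins = delins,
      transcripts = list(canonical = canonical, MT1 = mt1, MT2 = mt2),
      coordinate_offset = offset,
      meta = list(
        chrom = k$chrom,
        length_ref = L_ref, length_alt = L_alt,
        shift = shift,
        indel_ref = c(k$delins_ref_start, k$delins_ref_end),
        indel_alt = c(k$delins_ref_start,
                      k$delins_ref_start + nchar(delins$alt_seq) - 1L),
        pseudoexon = list(MT1 = pe1_gen, MT2 = pe2_gen),
        pseudoexon_len = c(MT1 = pe1, MT2 = pe2),
        ins_ts_start = ins_ts_start,
        pe_ts_start = pe_ts_start,
        cds_start_mrna = k$utr5 + 1L,
        mrna_pe_start = sum(k$exon_len[1:5])  # nt upstream of pseudoexon
      )
    ),
    class = "locus_model"
  )
  validate_locus(locus)
  locus
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Generate all sequence pieces in transcript sense; called under the
## packaged internal seed.
.locus_sequences <- function(k, pe1, pe2) {
  n_cod <- (sum(k$exon_len[1:5]) - k$utr5 + k$cds_exon16 - 6L) / 3L
  stopifnot(n_cod == floor(n_cod))  # frame bookkeeping must be exact
  mrna <- paste0(.random_dna(k$utr5), "ATG", .random_nonstop_codons(n_cod),
                 "TAA",
                 .random_dna(sum(k$exon_len) - k$utr5 - (3L * n_cod + 6L)))
  ## split mRNA into exon pieces
  stopifnot(nchar(mrna) == sum(k$exon_len))
  bounds <- cumsum(k$exon_len)
  exon_seq <- substring(mrna, c(1L, head(bounds, -1L) + 1L), bounds)

  intron <- function(n) {
    s <- .random_dna(n)
    s <- .patch(s, 1L, "GT")
    .patch(s, n - 1L, "AG")
  }
  i15a <- .patch(.random_dna(k$i15_a), 1L, "GT")
  ## B: first base free, then three non-stop codons, then the in-frame UAA
  ## (DNA TAA) at B[11..13]; cryptic donor GTs after each pseudoexon end;
  ## acceptor AG at the intron tail
  b_rest <- .random_dna(k$i15_b - 13L)
  b <- paste0(.random_dna(1L), .random_nonstop_codons(3L), "TAA", b_rest)
  b <- .patch(b, pe2 - 1L, "GT")
  b <- .patch(b, pe1 - 1L, "GT")
  b <- .patch(b, k$i15_b - 1L, "AG")

  introns <- vapply(k$intron_len, intron, character(1))
  flank5 <- .random_dna(k$flank5)
  flank3 <- .random_dna(k$flank3)
  assemble <- function(ins) {
    paste0(flank5,
           exon_seq[1], introns[1], exon_seq[2], introns[2], exon_seq[3],
           introns[3], exon_seq[4], introns[4], exon_seq[5],
           i15a, ins, b, exon_seq[6], flank3)
  }
  ts_alt <- assemble(k$ins_ts_alt)
  ts_ref <- assemble(k$ins_ts_ref)

  ## transcript-sense exon intervals
  lens_common <- c(k$flank5, k$exon_len[1], k$intron_len[1], k$exon_len[2],
                   k$intron_len[2], k$exon_len[3], k$intron_len[3],
                   k$exon_len[4], k$intron_len[4], k$exon_len[5])
  cum <- cumsum(lens_common)
  exon_iv <- function(ins_len) {
    i15_total <- k$i15_a + ins_len + k$i15_b
    starts <- c(cum[2] - k$exon_len[1] + 1L, cum[4] - k$exon_len[2] + 1L,
                cum[6] - k$exon_len[3] + 1L, cum[8] - k$exon_len[4] + 1L,
                cum[10] - k$exon_len[5] + 1L,
                cum[10] + i15_total + 1L)
    ends <- starts + k$exon_len - 1L
    Map(c, starts, ends)
  }
  list(ts_alt = ts_alt, ts_ref = ts_ref,
       exon_ts = exon_iv(nchar(k$ins_ts_ref)),
       exon_ts_alt = exon_iv(nchar(k$ins_ts_alt)),
       ins_ts_start = cum[10] + k$i15_a + 1L)
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("locus_model '%s' (%s strand), ref %d nt / alt %d nt\n",
              x$name, x$gene_strand, nchar(x$sequence_ref),
              nchar(x$sequence_alt)))
  print(x$delins)
  cat(sprintf("  transcripts: %s\n",
              paste(names(x$transcripts), collapse = ", ")))
  cat(sprintf("  pseudoexon lengths: MT1 %d nt, MT2 %d nt\n",
              x$meta$pseudoexon_len["MT1"], x$meta$pseudoexon_len["MT2"]))
  invisible(x)
}

#' Pseudoexon length of a mutant transcript
#' @param locus a `locus_model`.
#' @param id `"MT1"` or `"MT2"`.
#' @export
pseudoexon_length <- function(locus, id) {
  iv <- locus$meta$pseudoexon[[id]]
  if (is.null(iv)) stop("no pseudoexon recorded for transcript ", id)
  as.integer(unname(iv[2] - iv[1] + 1L))
}

#' Lift reference-haplotype coordinates to the variant haplotype
#'
#' Positions genomically above the delins shift by the length difference
#' of the two alleles; positions inside the replaced run have no image and
#' return `NA`.
#'
#' @param locus a `locus_model`.
#' @param pos integer vector of genomic positions.
#' @return integer vector of alt-haplotype positions (NA inside the indel).
#' @export
lift_ref_to_alt <- function(locus, pos) {
  iv <- locus$meta$indel_ref
  out <- ifelse(pos < iv[1], pos,
                ifelse(pos > iv[2], pos + locus$meta$shift, NA_real_))
  as.integer(out)
}

#' Lift variant-haplotype coordinates to the reference haplotype
#' @rdname lift_ref_to_alt
#' @export
lift_alt_to_ref <- function(locus, pos) {
  iv <- locus$meta$indel_alt
  out <- ifelse(pos < iv[1], pos,
                ifelse(pos > iv[2], pos - locus$meta$shift, NA_real_))
  as.integer(out)
}

#' Haplotype sequence by id
#' @param locus a `locus_model`.
#' @param haplotype `"ref"`/1 or `"alt"`/2.
#' @export
haplotype_sequence <- function(locus, haplotype) {
  if (haplotype %in% c("ref", "1", 1)) locus$sequence_ref
  else if (haplotype %in% c("alt", "2", 2)) locus$sequence_alt
  else stop("haplotype must be 'ref'/1 or 'alt'/2")
}

#' Pre-mRNA (transcript-sense) sequence of a haplotype
#' @param locus a `locus_model`.
#' @param haplotype `"ref"` or `"alt"`.
#' @export
premrna_sense <- function(locus, haplotype = "alt") {
  reverse_complement(haplotype_sequence(locus, haplotype))
}

#' Spliced (mature mRNA sense) sequence of a transcript
#'
#' Exon substrings are taken from the haplotype the transcript is defined
#' on (`sequence_ref` for canonical, `sequence_alt` for mutants) and
#' reverse-complemented for the minus-strand gene.
#'
#' @param locus a `locus_model`.
#' @param id transcript id in `locus$transcripts`.
#' @return character scalar, mRNA-sense DNA.
#' @export
spliced_sequence <- function(locus, id) {
  tx <- locus$transcripts[[id]]
  if (is.null(tx)) stop("unknown transcript: ", id)
  hap <- if (identical(tx$coords, "alt")) locus$sequence_alt
         else locus$sequence_ref
  pieces <- character(nrow(tx$exons))
  for (i in seq_len(nrow(tx$exons))) {
    a <- tx$exons$start[i] - locus$coordinate_offset + 1L
    b <- tx$exons$end[i] - locus$coordinate_offset + 1L
    piece <- substr(hap, a, b)
    pieces[i] <- if (tx$strand == "-") reverse_complement(piece) else piece
  }
  paste(pieces, collapse = "")
}

#' Splice-junction chain of a transcript model
#'
#' Each junction is the pair (donor, acceptor) of genomic positions: the
#' transcript-last base of the upstream exon and the transcript-first base
#' of the downstream exon. For the minus-strand gene the donor is the
#' exon's genomic `start` and the acceptor the next exon's genomic `end`.
#'
#' @param locus a `locus_model`.
#' @param id transcript id.
#' @param coords coordinate system for the returned chain; `"alt"` lifts
#'   reference-defined transcripts onto the variant haplotype so chains of
#'   all isoforms are comparable.
#' @return data frame with columns `donor`, `acceptor` in transcript order.
#' @export
transcript_junctions <- function(locus, id, coords = c("alt", "native")) {
  coords <- match.arg(coords)
  tx <- locus$transcripts[[id]]
  if (is.null(tx)) stop("unknown transcript: ", id)
  n <- nrow(tx$exons)
  if (n < 2L) {
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  }
  if (tx$strand == "-") {
    donor <- tx$exons$start[-n]
    acceptor <- tx$exons$end[-1L]
  } else {
    donor <- tx$exons$end[-n]
    acceptor <- tx$exons$start[-1L]
  }
  if (coords == "alt" && identical(tx$coords, "ref")) {
    donor <- lift_ref_to_alt(locus, donor)
    acceptor <- lift_ref_to_alt(locus, acceptor)
  }
  data.frame(donor = as.integer(donor), acceptor = as.integer(acceptor))
}

#' Diagnostic junctions of the fixture for PSI quantification
#'
#' @param locus a `locus_model`.
#' @return list with `inclusion` (exon15 -> pseudoexon, shared acceptor),
#'   `exclusion` (exon15 -> exon16), `donor_mt1`, `donor_mt2`
#'   (pseudoexon -> exon16 junctions of the two mutant isoforms); each a
#'   `c(donor, acceptor)` pair in alt-haplotype coordinates.
#' @export
locus_quant_junctions <- function(locus) {
  jc <- transcript_junctions(locus, "canonical", coords = "alt")
  j1 <- transcript_junctions(locus, "MT1", coords = "alt")
  j2 <- transcript_junctions(locus, "MT2", coords = "alt")
  n <- nrow(jc)
  list(
    exclusion = c(donor = jc$donor[n], acceptor = jc$acceptor[n]),
    inclusion = c(donor = j1$donor[n], acceptor = j1$acceptor[n]),
    donor_mt1 = c(donor = j1$donor[n + 1L], acceptor = j1$acceptor[n + 1L]),
    donor_mt2 = c(donor = j2$donor[n + 1L], acceptor = j2$acceptor[n + 1L])
  )
}

#' Validate every fixture invariant of a locus model
#'
#' Checks, in one place, that the locus honours all structural
#' constraints simultaneously: the delins applied to the reference
#' haplotype yields the variant haplotype; both mutant pseudoexons share
#' the acceptor-side boundary and end with the stop-containing geometry
#' (mRNA triplet UAA at pseudoexon positions 13-15); the ectopic acceptor
#' AG sits inside the insertion immediately 5' of the pseudoexon; exon 16
#' is the final exon of both mutant isoforms and matches the canonical
#' last exon; and the canonical ORF reaches its stop only in the last
#' exon.
#'
#' @param locus a `locus_model`.
#' @return `locus` invisibly; errors name the violated invariant.
#' @export
validate_locus <- function(locus) {
  fail <- function(which) stop("locus invariant violated: ", which,
                               call. = FALSE)
  ## delins consistency
  alt <- apply_delins(locus$sequence_ref, locus$delins,
                      segment_offset = locus$coordinate_offset)
  if (!identical(alt, locus$sequence_alt)) {
    fail("sequence_alt must equal sequence_ref with the delins applied")
  }
  ## pseudoexon geometry
  pe1 <- locus$meta$pseudoexon$MT1
  pe2 <- locus$meta$pseudoexon$MT2
  if (pe1[2] != pe2[2]) {
    fail("MT1 and MT2 pseudoexons must share the acceptor-side boundary")
  }
  mt1 <- locus$transcripts$MT1
  mt2 <- locus$transcripts$MT2
  can <- locus$transcripts$canonical
  n1 <- nrow(mt1$exons)
  same_iv <- function(a, b) all(as.numeric(a) == as.numeric(b))
  if (!same_iv(mt1$exons[n1, ], mt2$exons[n1, ]) ||
      !same_iv(mt1$exons[n1, ], can$exons[nrow(can$exons), ])) {
    fail("both MT isoforms must end with the canonical last exon (exon 16)")
  }
  if (!same_iv(mt1$exons[n1 - 1L, ], pe1)) {
    fail("the pseudoexon must be the penultimate exon of MT1")
  }
  ## mRNA-sense UAA at pseudoexon positions 13-15
  m1 <- spliced_sequence(locus, "MT1")
  ps <- locus$meta$mrna_pe_start
  if (!identical(substr(m1, ps + 13L, ps + 15L), "TAA")) {
    fail("mRNA triplet at pseudoexon positions 13-15 must be UAA")
  }
  ## ectopic acceptor AG inside the insertion, immediately 5' of the
  ## pseudoexon start (transcript sense)
  ts_alt <- premrna_sense(locus, "alt")
  pe_ts <- locus$meta$pe_ts_start
  if (!identical(substr(ts_alt, pe_ts - 2L, pe_ts - 1L), "AG")) {
    fail("ectopic acceptor AG must precede the pseudoexon start")
  }
  if (pe_ts - 2L < locus$meta$ins_ts_start) {
    fail("the ectopic acceptor must lie within the inserted allele")
  }
  ## spliced-length bookkeeping
  for (id in names(locus$transcripts)) {
    if (nchar(spliced_sequence(locus, id)) !=
        spliced_length(locus$transcripts[[id]])) {
      fail("spliced sequence length must equal the sum of exon lengths")
    }
  }
  ## canonical ORF: first in-frame stop must fall in the last exon
  can_mrna <- spliced_sequence(locus, "canonical")
  cds_start <- locus$meta$cds_start_mrna
  stop_at <- .first_stop(can_mrna, cds_start)
  last_exon_start_mrna <- spliced_length(can) -
    (can$exons$end[nrow(can$exons)] - can$exons$start[nrow(can$exons)])
  if (is.na(stop_at) || stop_at < last_exon_start_mrna) {
    fail("the canonical ORF must be stop-free until the last exon")
  }
  invisible(locus)
}

## mRNA position of the first base of the first in-frame stop codon at or
## after cds_start; NA if none.
.first_stop <- function(mrna, cds_start) {
  n <- nchar(mrna)
  pos <- seq(cds_start, n - 2L, by = 3L)
  for (p in pos) {
    if (substr(mrna, p, p + 2L) %in% .stop_codons) return(p)
  }
  NA_integer_
}
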