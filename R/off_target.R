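## Self-contained hybridization off-target search over a (desk-scale)
## transcriptome. An alignment is an off-target when it has at most one
## mismatch-or-gap or at least 16 contiguous matches, lies in the sense
## orientation (the ASO reverse-complementary to the transcript), and is
## within 200 nt of an exon.
##
## Completeness: the query (the ASO's complement) is partitioned into
## three disjoint seed blocks. Any alignment with <= 2 mismatches leaves
## one block exact (pigeonhole); any alignment containing a >= 16-nt
## exact run contains the middle block of an 18-mer exactly; a single
## 1-nt bulge splits the query into two exact blocks, the longer of
## which (>= 9 nt) contains a full seed block on a diagonal within +-1.
## Seed lookups at the three partitions, with candidate offsets expanded
## by one diagonal either side, therefore retrieve every qualifying
## alignment; each candidate is then verified directly.

#' Build a seed-indexed transcriptome for off-target searching
#'
#' Each transcript contributes two searchable records: its pre-mRNA and
#' its mature mRNA (spliced per the exon annotation). An exact k-mer
#' index over the sense sequences supports guaranteed-complete retrieval
#' of all 18-mer alignments with up to 2 mismatches, a 1-nt bulge, or a
#' 16-nt contiguous match (see the completeness note in the source).
#'
#' @param transcripts list of transcript descriptions, each a list with
#'   `id`, `premrna` (sense DNA string), `exons` (data frame of `start`,
#'   `end`, 1-based transcript-local coordinates), `gene` (gene id) and
#'   `canonical` (flag).
#' @param seed_length exact-seed length (6 guarantees completeness for
#'   18-mer queries at up to 2 mismatches).
#' @return a `transcriptome_index`.
#' @export
build_transcriptome_index <- function(transcripts, seed_length = 6L) {
  seed_length <- as.integer(seed_length)
  recs <- list()
  for (tx in transcripts) {
    stopifnot(!is.null(tx$id), !is.null(tx$premrna), !is.null(tx$exons))
    .check_dna(tx$premrna, what = paste0("premrna of ", tx$id))
    if (nrow(tx$exons) == 0L ||
        any(tx$exons$start < 1L | tx$exons$end > nchar(tx$premrna) |
              tx$exons$start > tx$exons$end)) {
      stop("annotation/sequence mismatch for transcript ", tx$id)
    }
    mature <- paste(substring(tx$premrna, tx$exons$start, tx$exons$end),
                    collapse = "")
    gene <- tx$gene %||% tx$id
    canonical <- isTRUE(tx$canonical)
    recs[[length(recs) + 1L]] <- list(
      transcript_id = tx$id, kind = "pre_mRNA", seq = tx$premrna,
      exons = tx$exons, gene = gene, canonical = canonical)
    recs[[length(recs) + 1L]] <- list(
      transcript_id = tx$id, kind = "mature", seq = mature,
      exons = data.frame(start = 1L, end = nchar(mature)),
      gene = gene, canonical = canonical)
  }
  ## exact k-mer index: kmer -> matrix of (record, position)
  env <- new.env(parent = emptyenv())
  for (r in seq_along(recs)) {
    s <- recs[[r]]$seq
    n <- nchar(s)
    if (n < seed_length) next
    kmers <- substring(s, 1:(n - seed_length + 1L), seed_length:n)
    by_kmer <- split(seq_along(kmers), kmers)
    for (km in names(by_kmer)) {
      entry <- cbind(rec = r, pos = by_kmer[[km]])
      prev <- get0(km, envir = env)
      assign(km, if (is.null(prev)) entry else rbind(prev, entry),
             envir = env)
    }
  }
  structure(list(records = recs, kmer = env, seed_length = seed_length),
            class = "transcriptome_index")
}

#' @export
print.transcriptome_index <- function(x, ...) {
  cat(sprintf("transcriptome_index: %d records (%d transcripts), seed %d\n",
              length(x$records), length(x$records) / 2L, x$seed_length))
  invisible(x)
}

## longest contiguous run of TRUE in a logical vector (0 if none)
.longest_true_run <- function(match_vec) {
  if (!any(match_vec)) return(0L)
  r <- rle(match_vec)
  max(r$lengths[r$values])
}

## one-gap, zero-mismatch check of query q against record sequence s
## anchored at offset o. Only internal bulges count: deleting a terminal
## base is merely a shifted exact/shorter match, and admitting it would
## report every exact site three times (once per diagonal). Returns the
## longest exact block length if a single internal 1-nt bulge alignment
## exists, else 0.
.one_gap_match <- function(q, s, o) {
  L <- nchar(q)
  n <- nchar(s)
  best <- 0L
  ## bulge in the ASO/query (target window L - 1)
  if (o >= 1L && o + L - 2L <= n) {
    win <- substr(s, o, o + L - 2L)
    for (g in 2:(L - 1L)) {
      qdel <- paste0(substr(q, 1L, g - 1L), substr(q, g + 1L, L))
      if (qdel == win) {
        best <- max(best, max(g - 1L, L - g))
      }
    }
  }
  ## bulge in the target (target window L + 1)
  if (o >= 1L && o + L <= n) {
    win <- substr(s, o, o + L)
    for (g in 2:L) {
      wdel <- paste0(substr(win, 1L, g - 1L), substr(win, g + 1L, L + 1L))
      if (wdel == q) {
        best <- max(best, max(g - 1L, L + 1L - g))
      }
    }
  }
  best
}

#' Search a transcriptome index for hybridization sites of an ASO
#'
#' Finds all sense-orientation alignments of the ASO's complement with at
#' most `max_mismatches` mismatches, all alignments containing a >= 16-nt
#' exact match regardless of mismatch count, and all single-bulge (1-nt
#' gap, no mismatch) alignments. Each alignment is annotated with its
#' longest contiguous match, exonic/intronic status and distance to the
#' nearest exon (using the gene's canonical transcript annotation where
#' one shares the record's coordinate space, else the record's own), and
#' classified by [classify_offtarget()]. The on-target site itself is
#' reported and labelled like any other hit.
#'
#' @param aso ASO sequence (RNA or DNA alphabet) or a single-row
#'   `aso_candidates` slice.
#' @param index a [build_transcriptome_index()] result.
#' @param max_mismatches mismatch ceiling for the mismatch arm.
#' @param min_contiguous contiguous-match threshold (16 nt).
#' @return data frame of alignments: `transcript_id`, `target_kind`,
#'   `start`, `mismatches`, `gaps`, `longest_contiguous_match`,
#'   `orientation`, `distance_to_exon`, `used_canonical`, `is_offtarget`.
#' @export
search_offtargets <- function(aso, index, max_mismatches = 2L,
                              min_contiguous = 16L) {
  stopifnot(inherits(index, "transcriptome_index"))
  if (is.data.frame(aso)) aso <- aso$aso_seq[1]
  aso_dna <- chartr("U", "T", aso)
  .check_dna(aso_dna, what = "aso sequence")
  q <- reverse_complement(aso_dna)  # the sense-strand target site
  L <- nchar(q)
  k <- index$seed_length
  if (L < 3L * k) {
    stop("query shorter than 3 seed blocks; decrease seed_length")
  }
  qc <- .chars(q)
  part_starts <- c(1L, k + 1L, 2L * k + 1L)
  cand <- list()
  for (p in part_starts) {
    hits <- get0(substr(q, p, p + k - 1L), envir = index$kmer)
    if (is.null(hits)) next
    o <- hits[, "pos"] - p + 1L
    cand[[length(cand) + 1L]] <-
      cbind(rec = rep(hits[, "rec"], 3L), off = c(o - 1L, o, o + 1L))
  }
  if (length(cand) == 0L) return(.empty_alignments())
  cand <- unique(do.call(rbind, cand))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, "rec"]
    o <- cand[i, "off"]
    rec <- index$records[[r]]
    n <- nchar(rec$seq)
    mm <- NA_integer_
    run <- 0L
    if (o >= 1L && o + L - 1L <= n) {
      wc <- .chars(substr(rec$seq, o, o + L - 1L))
      eq <- wc == qc
      mm <- L - sum(eq)
      run <- .longest_true_run(eq)
    }
    gaps <- 0L
    keep <- !is.na(mm) && (mm <= max_mismatches || run >= min_contiguous)
    if (!keep && (is.na(mm) || mm > 0L)) {
      gap_run <- .one_gap_match(q, rec$seq, o)
      if (gap_run > 0L) {
        keep <- TRUE
        mm <- 0L
        gaps <- 1L
        run <- gap_run
      }
    }
    if (!keep) next
    dist <- .distance_to_exon(index, r, o, o + L - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = rec$transcript_id, target_kind = rec$kind,
      start = o, mismatches = mm, gaps = gaps,
      longest_contiguous_match = run, orientation = "sense",
      distance_to_exon = dist$distance, used_canonical = dist$canonical,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(.empty_alignments())
  out <- do.call(rbind, rows)
  ## one alignment per (record sequence, offset): keep the best-scoring
  key <- paste(out$transcript_id, out$target_kind, out$start)
  out <- out[order(key, out$mismatches + out$gaps), , drop = FALSE]
  out <- out[!duplicated(paste(out$transcript_id, out$target_kind,
                               out$start)), , drop = FALSE]
  out <- out[order(out$transcript_id, out$target_kind, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$is_offtarget <- classify_offtarget(
    out$mismatches, out$gaps, out$longest_contiguous_match,
    out$distance_to_exon, out$orientation)
  out
}

.empty_alignments <- function() {
  data.frame(transcript_id = character(0), target_kind = character(0),
             start = integer(0), mismatches = integer(0),
             gaps = integer(0), longest_contiguous_match = integer(0),
             orientation = character(0), distance_to_exon = integer(0),
             used_canonical = logical(0), is_offtarget = logical(0),
             stringsAsFactors = FALSE)
}

## Distance from an alignment interval to the nearest exon, preferring
## the gene's canonical transcript annotation when it shares the
## record's pre-mRNA coordinate space. Distance is the number of
## nucleotides strictly between the alignment edge and the exon boundary
## (0 when the alignment overlaps or abuts an exon).
.distance_to_exon <- function(index, r, a_start, a_end) {
  rec <- index$records[[r]]
  if (rec$kind == "mature") {
    return(list(distance = 0L, canonical = rec$canonical))
  }
  exons <- rec$exons
  used_canonical <- rec$canonical
  if (!rec$canonical) {
    for (other in index$records) {
      if (other$kind == "pre_mRNA" && other$gene == rec$gene &&
          other$canonical && nchar(other$seq) == nchar(rec$seq)) {
        exons <- other$exons
        used_canonical <- TRUE
        break
      }
    }
  }
  d <- vapply(seq_len(nrow(exons)), function(i) {
    s <- exons$start[i]
    e <- exons$end[i]
    if (a_end < s) s - a_end - 1L
    else if (a_start > e) a_start - e - 1L
    else 0L
  }, integer(1))
  list(distance = min(d), canonical = used_canonical)
}

#' Off-target classification predicate
#'
#' An alignment is an off-target iff it has at most one mismatch-or-gap
#' in total or a contiguous exact match of at least `min_contiguous`
#' nucleotides, lies in the sense orientation, and is within
#' `max_distance` nucleotides of an exon (boundary inclusive: distance
#' exactly 200 qualifies). Monotone: decreasing mismatches or distance
#' never turns TRUE into FALSE.
#'
#' @param mismatches,gaps,longest_contiguous_match,distance_to_exon
#'   alignment metrics (vectorized).
#' @param orientation `"sense"` or `"antisense"`.
#' @param max_distance distance-to-exon ceiling (200 nt).
#' @param min_contiguous contiguous-match threshold (16 nt).
#' @return logical vector.
#' @export
classify_offtarget <- function(mismatches, gaps, longest_contiguous_match,
                               distance_to_exon, orientation = "sense",
                               max_distance = 200L, min_contiguous = 16L) {
  (mismatches + gaps <= 1L | longest_contiguous_match >= min_contiguous) &
    orientation == "sense" &
    distance_to_exon <= max_distance
}

#' Per-ASO off-target counts over a transcriptome
#'
#' Runs [search_offtargets()] for every candidate and counts classified
#' off-target alignments, excluding hits on the on-target gene(s). A
#' candidate passes the off-target filter when its count is zero.
#'
#' @param candidates an `aso_candidates` data frame (or character vector
#'   of ASO sequences).
#' @param index a `transcriptome_index`.
#' @param on_target_genes gene ids whose hits are excluded (the intended
#'   target locus).
#' @param max_mismatches forwarded to [search_offtargets()].
#' @return data frame `id`, `n_offtargets`, `pass_offtarget`.
#' @export
summarize_offtargets <- function(candidates, index,
                                 on_target_genes = character(0),
                                 max_mismatches = 2L) {
  if (is.character(candidates)) {
    candidates <- data.frame(id = paste0("ASO_", seq_along(candidates)),
                             aso_seq = candidates,
                             stringsAsFactors = FALSE)
  }
  gene_of <- vapply(index$records, function(r) r$gene, character(1))
  tx_gene <- stats::setNames(
    gene_of, vapply(index$records, function(r) r$transcript_id,
                    character(1)))
  n_ot <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    hits <- search_offtargets(candidates$aso_seq[i], index,
                              max_mismatches = max_mismatches)
    if (nrow(hits) > 0L) {
      off <- hits$is_offtarget &
        !(tx_gene[hits$transcript_id] %in% on_target_genes)
      n_ot[i] <- sum(off)
    }
  }
  data.frame(id = candidates$id, n_offtargets = n_ot,
             pass_offtarget = n_ot == 0L, stringsAsFactors = FALSE)
}

#' Toy transcriptome containing the fixture locus
#'
#' Builds a small transcriptome for off-target screening demonstrations:
#' the locus' variant-haplotype pre-mRNA with the canonical exon
#' annotation (the on-target gene), plus `n_decoys` unrelated
#' single-gene transcripts of random sequence with a central exon.
#'
#' @param locus a `locus_model`.
#' @param n_decoys number of decoy genes.
#' @param decoy_len decoy pre-mRNA length.
#' @param seed RNG seed for the decoy sequences.
#' @return a list of transcript descriptions for
#'   [build_transcriptome_index()].
#' @export
locus_transcriptome <- function(locus, n_decoys = 2L, decoy_len = 2000L,
                                seed = 100L) {
  L <- locus$meta$length_alt
  off <- locus$coordinate_offset
  gen2ts <- function(iv) c(off + L - iv[2], off + L - iv[1])
  can <- locus$transcripts$canonical
  ex_alt_gen <- data.frame(start = lift_ref_to_alt(locus, can$exons$start),
                           end = lift_ref_to_alt(locus, can$exons$end))
  ts_iv <- t(apply(ex_alt_gen, 1L, function(iv) gen2ts(c(iv[1], iv[2]))))
  exons <- data.frame(start = ts_iv[, 1], end = ts_iv[, 2])
  exons <- exons[order(exons$start), , drop = FALSE]
  on_target <- list(id = paste0(locus$name, "_canonical"),
                    premrna = premrna_sense(locus, "alt"),
                    exons = exons, gene = locus$name, canonical = TRUE)
  decoys <- .with_seed(seed, lapply(seq_len(n_decoys), function(i) {
    s <- .random_dna(decoy_len)
    mid <- as.integer(decoy_len / 2L)
    list(id = sprintf("decoy_%d", i), premrna = s,
         exons = data.frame(start = c(1L, mid),
                            end = c(200L, mid + 199L)),
         gene = sprintf("decoy_gene_%d", i), canonical = TRUE)
  }))
  c(list(on_target), decoys)
}
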