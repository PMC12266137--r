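## Readers and writers for the pipeline's on-disk formats. FASTA goes
## through Biostrings and GFF3 through rtracklayer; coordinates are
## 1-based inclusive throughout. The two haplotypes are written as
## separate seqids ("<name>_ref", "<name>_alt") so each transcript model
## lives on a single reference.

#' Write the two haplotype sequences of a locus as FASTA
#'
#' @param locus a `locus_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(locus, path) {
  seqs <- Biostrings::DNAStringSet(c(locus$sequence_ref,
                                     locus$sequence_alt))
  names(seqs) <- paste0(locus$name, c("_ref", "_alt"))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Write transcript models as GFF3
#'
#' Each transcript is emitted as an `mRNA` feature with child `exon`
#' features (`Parent` attribute), 1-based inclusive, on the seqid of the
#' haplotype the model is defined on.
#'
#' @param locus a `locus_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(locus, path) {
  rows <- list()
  for (id in names(locus$transcripts)) {
    tx <- locus$transcripts[[id]]
    seqid <- paste0(locus$name, "_", tx$coords)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = seqid, type = "mRNA", start = min(tx$exons$start),
      end = max(tx$exons$end), strand = tx$strand, ID = id,
      Parent = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = seqid, type = "exon", start = tx$exons$start,
      end = tx$exons$end, strand = tx$strand,
      ID = sprintf("%s:exon%d", id, seq_len(nrow(tx$exons))),
      Parent = id, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript exon structures from a GFF3 file
#'
#' @param path GFF3 file with `exon` features carrying `Parent`
#'   attributes.
#' @return named list (by transcript) of data frames with `seqid`,
#'   `start`, `end`, `strand`, exons ordered 5' to 3' in transcript
#'   orientation.
#' @export
read_gff3_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  parent <- as.character(S4Vectors::mcols(ex)$Parent)
  parent <- sub("^$", NA_character_, parent)
  out <- list()
  for (id in unique(parent)) {
    sel <- ex[parent == id]
    df <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(sel)),
      start = GenomicRanges::start(sel),
      end = GenomicRanges::end(sel),
      strand = as.character(GenomicRanges::strand(sel)),
      stringsAsFactors = FALSE)
    df <- if (df$strand[1] == "-") df[order(-df$start), , drop = FALSE]
          else df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
    out[[id]] <- df
  }
  out
}

#' Write a delins as a left-anchored single-record VCF
#'
#' The record is anchored one base 5' (plus strand) of the replaced run,
#' as VCF requires for length-changing variants: POS = start - 1,
#' REF = anchor + replaced run, ALT = anchor + inserted run.
#'
#' @param variant a [delins_variant()].
#' @param anchor_base the plus-strand base immediately before
#'   `variant$start` (supply `locus_anchor_base()` output for fixture
#'   loci).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_delins_vcf <- function(variant, anchor_base, path) {
  .check_dna(anchor_base, what = "anchor_base")
  stopifnot(nchar(anchor_base) == 1L)
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", variant$chrom),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
            variant$chrom, variant$start - 1L,
            if (is.null(variant$hgvs_label)) "." else variant$hgvs_label,
            paste0(anchor_base, variant$ref_seq),
            paste0(anchor_base, variant$alt_seq)))
  writeLines(lines, path)
  invisible(path)
}

#' Plus-strand anchor base immediately 5' of the locus delins
#' @param locus a `locus_model`.
#' @export
locus_anchor_base <- function(locus) {
  i <- locus$delins$start - locus$coordinate_offset
  substr(locus$sequence_ref, i, i)
}

#' Read a single-record delins VCF
#'
#' @param path VCF file written by [write_delins_vcf()].
#' @return a [delins_variant()] (anchor base stripped).
#' @export
read_delins_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) != 1L) {
    stop("expected exactly one VCF record, found ", length(body),
         " (line ", length(lines) - length(body) + 1L, ")")
  }
  f <- strsplit(body, "\t", fixed = TRUE)[[1]]
  if (length(f) < 5L) stop("malformed VCF record at line ", length(lines))
  pos <- as.integer(f[2])
  ref <- f[4]
  alt <- f[5]
  if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L)) {
    stop("VCF record is not left-anchored (REF/ALT share no anchor base)")
  }
  delins_variant(f[1], pos + 1L, pos + nchar(ref) - 1L,
                 ref_seq = substring(ref, 2L),
                 alt_seq = substring(alt, 2L),
                 hgvs_label = if (f[3] == ".") NULL else f[3])
}

#' Write/read a delimited table (TSV or CSV by extension)
#'
#' @param df data frame.
#' @param path file ending in `.tsv` (tab) or `.csv` (comma).
#' @return `path` invisibly (write) / data frame (read).
#' @export
write_table <- function(df, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a phased pileup as TSV
#'
#' One row per haplotype and position with base/deletion counts; the
#' `INS` column holds `;`-separated `sequence:count` insertion
#' observations (empty when none).
#'
#' @param pileup a `phased_pileup`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  rows <- lapply(pileup$haplotypes, function(h) {
    cols <- h$columns
    ins <- vapply(cols$INS, function(v) {
      if (length(v) == 0L) "" else
        paste(sprintf("%s:%d", names(v), v), collapse = ";")
    }, character(1))
    data.frame(haplotype = h$haplotype_id, pos = cols$pos, A = cols$A,
               C = cols$C, G = cols$G, T = cols$T, DEL = cols$DEL,
               INS = ins, stringsAsFactors = FALSE)
  })
  write_table(do.call(rbind, rows), path)
}

#' Read a phased pileup TSV
#'
#' @param path file written by [write_pileup_tsv()].
#' @return a `phased_pileup`.
#' @export
read_pileup_tsv <- function(path) {
  df <- read_table(path)
  need <- c("haplotype", "pos", "A", "C", "G", "T", "DEL")
  if (!all(need %in% names(df))) {
    stop("pileup TSV must have columns ", paste(need, collapse = ", "))
  }
  if (!"INS" %in% names(df)) df$INS <- ""
  df$INS[is.na(df$INS)] <- ""
  haps <- lapply(split(df, df$haplotype), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    ins <- lapply(d$INS, function(s) {
      if (!nzchar(s)) return(integer(0))
      parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      stats::setNames(
        as.integer(vapply(parts, `[`, character(1), 2L)),
        vapply(parts, `[`, character(1), 1L))
    })
    cols <- data.frame(pos = d$pos, A = d$A, C = d$C, G = d$G, T = d$T,
                       DEL = d$DEL)
    cols$INS <- ins
    structure(list(haplotype_id = d$haplotype[1], columns = cols),
              class = "pileup_block")
  })
  structure(list(haplotypes = haps), class = "phased_pileup")
}
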