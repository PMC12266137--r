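## Independent oracles and fixture generators used across the suite.
## These deliberately re-derive results by direct enumeration, never by
## calling the implementation under test.

fixture_locus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture_locus()
    cache
  }
})

## --- consensus oracle: per-column argmax by direct table lookup --------

oracle_consensus <- function(block, min_support = 2L) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  cols <- block$columns
  seq_out <- character(0)
  support <- integer(0)
  excluded <- integer(0)
  for (i in seq_len(nrow(cols))) {
    cnt <- c(A = cols$A[i], C = cols$C[i], G = cols$G[i], T = cols$T[i],
             DEL = cols$DEL[i])
    m <- max(cnt)
    if (m < min_support) {
      excluded <- c(excluded, cols$pos[i])
      next
    }
    win <- names(cnt)[cnt == m]
    if (identical(win, "DEL")) next
    win <- setdiff(win, "DEL")
    if (length(win) == 0L) next
    seq_out <- c(seq_out, iupac[[paste(sort(win), collapse = "")]])
    support <- c(support, m)
  }
  list(sequence = paste(seq_out, collapse = ""), support = support,
       excluded_positions = excluded)
}

random_pileup_block <- function(n_cols = 40L, max_depth = 12L,
                                haplotype_id = 1L) {
  counts <- matrix(rpois(n_cols * 5L, lambda = runif(1, 0.5, max_depth / 3)),
                   ncol = 5L)
  cols <- data.frame(pos = seq_len(n_cols) + 1000L,
                     A = counts[, 1], C = counts[, 2], G = counts[, 3],
                     T = counts[, 4], DEL = counts[, 5])
  cols$INS <- replicate(n_cols, integer(0), simplify = FALSE)
  structure(list(haplotype_id = haplotype_id, columns = cols),
            class = "pileup_block")
}

## --- off-target oracle: exhaustive sliding-window scan -----------------

## All offsets of record sequence s where query q aligns with
## <= max_mm mismatches, or a >= min_run contiguous match, or a single
## 1-nt bulge with no mismatch. Returns sorted unique offsets.
oracle_scan_offsets <- function(q, s, max_mm = 2L, min_run = 16L) {
  L <- nchar(q)
  n <- nchar(s)
  qc <- strsplit(q, "")[[1]]
  hits <- integer(0)
  if (n >= L) {
    for (o in seq_len(n - L + 1L)) {
      wc <- strsplit(substr(s, o, o + L - 1L), "")[[1]]
      eq <- wc == qc
      mm <- L - sum(eq)
      r <- rle(eq)
      run <- if (any(eq)) max(r$lengths[r$values]) else 0L
      if (mm <= max_mm || run >= min_run) hits <- c(hits, o)
    }
  }
  ## single internal-bulge alignments, zero mismatches (terminal gaps
  ## are shifted exact matches, not bulges)
  qdels <- vapply(2:(L - 1L), function(g) {
    paste0(substr(q, 1L, g - 1L), substr(q, g + 1L, L))
  }, character(1))
  if (n >= L - 1L) {
    for (o in seq_len(n - (L - 1L) + 1L)) {
      win <- substr(s, o, o + L - 2L)
      if (any(qdels == win)) hits <- c(hits, o)
    }
  }
  if (n >= L + 1L) {
    for (o in seq_len(n - (L + 1L) + 1L)) {
      win <- substr(s, o, o + L)
      for (g in 2:L) {
        wdel <- paste0(substr(win, 1L, g - 1L), substr(win, g + 1L, L + 1L))
        if (wdel == q) {
          hits <- c(hits, o)
          break
        }
      }
    }
  }
  sort(unique(hits))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_str <- function(s, k) {
  if (k == 0L) return(s)
  pos <- sample.int(nchar(s), k)
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

## A toy transcriptome with sites related to `q` planted at random
## positions: exact, mutated (1-3 mismatches), and single-bulge copies.
planted_transcriptome <- function(q) {
  plant <- function(host, site) {
    at <- sample.int(nchar(host) - nchar(site), 1L)
    paste0(substr(host, 1L, at - 1L), site,
           substr(host, at + nchar(site), nchar(host)))
  }
  mk <- function(i) {
    s <- random_dna_str(sample(600:1200, 1L))
    n_sites <- sample(0:3, 1L)
    for (j in seq_len(n_sites)) {
      kind <- sample(c("exact", "mm", "gap"), 1L)
      site <- switch(kind,
        exact = q,
        mm = mutate_str(q, sample(1:3, 1L)),
        gap = {
          g <- sample(2:(nchar(q) - 1L), 1L)  # internal bulge
          paste0(substr(q, 1L, g - 1L), substr(q, g + 1L, nchar(q)))
        })
      s <- plant(s, site)
    }
    mid <- as.integer(nchar(s) / 2L)
    list(id = sprintf("toy_%d", i), premrna = s,
         exons = data.frame(start = c(1L, mid), end = c(150L, mid + 149L)),
         gene = sprintf("toy_gene_%d", i), canonical = TRUE)
  }
  lapply(seq_len(sample(2:3, 1L)), mk)
}

## --- dose-response generator used as an independent data source -------

fpl_curve <- function(dose, ec50, hill) 100 / (1 + (ec50 / dose)^hill)
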