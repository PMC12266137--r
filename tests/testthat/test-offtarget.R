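test_that("a toy index returns exact substring hits at known offsets", {
  set.seed(11)
  s <- random_dna_str(400)
  q <- substr(s, 101L, 118L)
  tx <- list(list(id = "t1", premrna = s,
                  exons = data.frame(start = 1L, end = 400L),
                  gene = "g1", canonical = TRUE))
  idx <- build_transcriptome_index(tx)
  hits <- search_offtargets(reverse_complement(q), idx)
  pre <- hits[hits$target_kind == "pre_mRNA", ]
  expect_true(101L %in% pre$start)
  expect_identical(pre$mismatches[pre$start == 101L], 0L)
  expect_identical(pre$longest_contiguous_match[pre$start == 101L], 18L)
  ## empty transcriptome -> empty index and no hits
  idx0 <- build_transcriptome_index(list())
  expect_identical(nrow(search_offtargets(reverse_complement(q), idx0)),
                   0L)
  ## annotation/sequence mismatch is rejected
  bad <- list(list(id = "t2", premrna = "ACGT",
                   exons = data.frame(start = 1L, end = 99L),
                   gene = "g2", canonical = TRUE))
  expect_error(build_transcriptome_index(bad), "annotation")
})

test_that("classification reproduces every boundary behaviour", {
  ## 1 vs 2 mismatches
  expect_true(classify_offtarget(1L, 0L, 10L, 0L))
  expect_false(classify_offtarget(2L, 0L, 15L, 0L))
  ## 15 vs 16 contiguous matches rescue high-mismatch alignments
  expect_false(classify_offtarget(2L, 0L, 15L, 100L))
  expect_true(classify_offtarget(2L, 0L, 16L, 100L))
  ## 200 vs 201 nt distance, boundary inclusive
  expect_true(classify_offtarget(1L, 0L, 10L, 200L))
  expect_false(classify_offtarget(1L, 0L, 10L, 201L))
  expect_false(classify_offtarget(1L, 0L, 10L, 250L))
  ## gaps count toward the <=1 arm
  expect_true(classify_offtarget(0L, 1L, 9L, 0L))
  expect_false(classify_offtarget(1L, 1L, 9L, 0L))
  ## antisense alignments never qualify
  expect_false(classify_offtarget(0L, 0L, 18L, 0L, "antisense"))
  ## monotone in mismatches and distance
  set.seed(31)
  for (i in 1:50) {
    mm <- sample(0:3, 1)
    d <- sample(0:300, 1)
    run <- sample(5:18, 1)
    if (classify_offtarget(mm, 0L, run, d)) {
      expect_true(classify_offtarget(max(mm - 1L, 0L), 0L, run, d))
      expect_true(classify_offtarget(mm, 0L, run, max(d - 50L, 0L)))
    }
  }
})

test_that("seeded search equals the brute-force scan on planted toys", {
  set.seed(99)
  for (i in 1:12) {
    q <- random_dna_str(18)
    txs <- planted_transcriptome(q)
    idx <- build_transcriptome_index(txs)
    hits <- search_offtargets(reverse_complement(q), idx)
    for (tx in txs) {
      mature <- paste(substring(tx$premrna, tx$exons$start,
                                tx$exons$end), collapse = "")
      for (kind in c("pre_mRNA", "mature")) {
        s <- if (kind == "pre_mRNA") tx$premrna else mature
        want <- oracle_scan_offsets(q, s)
        got <- sort(hits$start[hits$transcript_id == tx$id &
                                 hits$target_kind == kind])
        expect_identical(got, as.integer(want))
      }
    }
  }
})

test_that("single-bulge sites are found and counted as one gap", {
  set.seed(12)
  host <- random_dna_str(500)
  q <- random_dna_str(18)
  site <- paste0(substr(q, 1L, 8L), substr(q, 10L, 18L))  # 1-nt bulge
  s <- paste0(substr(host, 1L, 199L), site, substr(host, 217L, 500L))
  tx <- list(list(id = "t1", premrna = s,
                  exons = data.frame(start = 180L, end = 260L),
                  gene = "g1", canonical = TRUE))
  idx <- build_transcriptome_index(tx)
  hits <- search_offtargets(reverse_complement(q), idx)
  hit <- hits[hits$target_kind == "pre_mRNA" & hits$start == 200L, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$gaps, 1L)
  expect_identical(hit$mismatches, 0L)
  expect_true(hit$is_offtarget)  # 1 gap, exonic
})

test_that("distance to exon prefers the canonical annotation", {
  set.seed(13)
  s <- random_dna_str(1000)
  q <- substr(s, 401L, 418L)
  exons_canon <- data.frame(start = c(1L, 650L), end = c(100L, 800L))
  exons_other <- data.frame(start = c(1L, 430L), end = c(100L, 520L))
  tx <- list(
    list(id = "canon", premrna = s, exons = exons_canon, gene = "g",
         canonical = TRUE),
    list(id = "other", premrna = s, exons = exons_other, gene = "g",
         canonical = FALSE))
  idx <- build_transcriptome_index(tx)
  hits <- search_offtargets(reverse_complement(q), idx)
  h_other <- hits[hits$transcript_id == "other" &
                    hits$target_kind == "pre_mRNA" & hits$start == 401L, ]
  ## canonical exons (650-800) give distance 231, not the transcript's
  ## own exon at 430
  expect_true(h_other$used_canonical)
  expect_identical(h_other$distance_to_exon, 650L - 418L - 1L)
})

test_that("summaries count planted off-targets and exclude the target", {
  set.seed(14)
  locus <- fixture_locus()
  q <- random_dna_str(18)
  aso <- reverse_complement(q)
  host <- function() random_dna_str(600)
  plant_at_distance <- function(d) {
    ## exon at [401, 460]; site ends d nt before the exon start
    s <- host()
    at <- 401L - d - 18L
    s <- paste0(substr(s, 1L, at - 1L), q, substr(s, at + 18L, 600L))
    list(premrna = s, exons = data.frame(start = 401L, end = 460L))
  }
  t150 <- plant_at_distance(150L)
  t201 <- plant_at_distance(201L)
  txs <- list(
    list(id = "near", premrna = t150$premrna, exons = t150$exons,
         gene = "g_near", canonical = TRUE),
    list(id = "far", premrna = t201$premrna, exons = t201$exons,
         gene = "g_far", canonical = TRUE))
  idx <- build_transcriptome_index(txs)
  hits <- search_offtargets(aso, idx)
  ## the planted 150-nt site qualifies; the 201-nt site does not
  near_hit <- hits[hits$transcript_id == "near" & hits$start == 233L &
                     hits$gaps == 0L, ]
  expect_identical(near_hit$distance_to_exon, 150L)
  expect_true(near_hit$is_offtarget)
  far_hit <- hits[hits$transcript_id == "far" & hits$start == 182L &
                    hits$gaps == 0L, ]
  expect_identical(far_hit$distance_to_exon, 201L)
  expect_false(far_hit$is_offtarget)
  ## every counted off-target respects the 200-nt rule; the candidate
  ## fails the filter because of the near site
  expect_true(all(hits$distance_to_exon[hits$is_offtarget] <= 200L))
  out <- summarize_offtargets(aso, idx)
  expect_gte(out$n_offtargets, 1L)
  expect_false(out$pass_offtarget)
  ## no homology at all -> zero off-targets
  clean <- list(list(id = "c", premrna = paste(rep("AC", 300),
                                               collapse = ""),
                     exons = data.frame(start = 1L, end = 600L),
                     gene = "g_c", canonical = TRUE))
  expect_identical(
    summarize_offtargets(aso, build_transcriptome_index(clean))$n_offtargets,
    0L)
  ## hits on the on-target gene are excluded from the count
  own <- locus_transcriptome(locus, n_decoys = 0L)
  idx_own <- build_transcriptome_index(own)
  cand <- design_asos(locus, flank = 20)
  res <- summarize_offtargets(cand[1:3, ], idx_own,
                              on_target_genes = locus$name)
  expect_true(all(res$n_offtargets == 0L))
})

test_that("shifting annotation coordinates shifts alignments equally", {
  set.seed(15)
  s0 <- random_dna_str(300)
  q <- substr(s0, 101L, 118L)
  shift <- 50L
  s1 <- paste0(random_dna_str(shift), s0)
  mk <- function(s, ex_start, ex_end) {
    list(list(id = "t", premrna = s,
              exons = data.frame(start = ex_start, end = ex_end),
              gene = "g", canonical = TRUE))
  }
  h0 <- search_offtargets(reverse_complement(q),
                          build_transcriptome_index(mk(s0, 1L, 50L)))
  h1 <- search_offtargets(reverse_complement(q),
                          build_transcriptome_index(mk(s1, 1L + shift,
                                                       50L + shift)))
  p0 <- h0[h0$target_kind == "pre_mRNA" & h0$start == 101L, ]
  p1 <- h1[h1$target_kind == "pre_mRNA" & h1$start == 101L + shift, ]
  expect_identical(nrow(p0), 1L)
  expect_identical(nrow(p1), 1L)
  expect_identical(p0$distance_to_exon, p1$distance_to_exon)
  expect_identical(p0$mismatches, p1$mismatches)
})
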