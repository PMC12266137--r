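test_that("tiling emits one candidate per start position", {
  set.seed(21)
  seqn <- random_dna_str(200)
  expect_identical(nrow(tile_candidates(seqn, c(1L, 18L))), 1L)
  expect_identical(nrow(tile_candidates(seqn, c(51L, 150L))), 83L)
  expect_error(tile_candidates(seqn, c(1L, 10L)), "shorter")
  expect_error(tile_candidates(seqn, c(190L, 210L)), "outside")
  cand <- tile_candidates(seqn, c(10L, 60L))
  ## antisense property holds for every emitted candidate
  expect_true(all(vapply(seq_len(nrow(cand)), function(i) {
    reverse_complement(chartr("U", "T", cand$aso_seq[i])) ==
      cand$target_seq[i]
  }, logical(1))))
  ## deterministic 5'->3' ordering
  expect_identical(cand$target_start, sort(cand$target_start))
})

test_that("GC filter uses inclusive 25-75% bounds", {
  gc18 <- function(s) sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 18
  site <- "TGTTTTTTACATTACAGG"  # head of the insertion, transcript sense
  df <- data.frame(gc_fraction = c(gc18(site), 0, 0.5, 0.25, 0.75,
                                   4 / 18, 14 / 18))
  expect_equal(df$gc_fraction[1], 5 / 18)
  expect_identical(gc_filter(df),
                   c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("homopolymer filter rejects runs of six or more", {
  run_of <- function(s) max(rle(strsplit(s, "")[[1]])$lengths)
  df <- data.frame(max_homopolymer_run = c(
    run_of("TGTTTTTTACATTACAGG"),   # 6 Ts -> fail
    run_of("ACACACACACACACACAC"),   # alternating -> pass
    5L,                             # boundary: exactly five passes
    6L))
  expect_identical(homopolymer_filter(df), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("allele specificity counts anchored Hamming mismatches", {
  ## reported vs corrected allele cores differ by exactly one base
  got <- allele_specificity("TGTTTTTTACATGACAGG",
                            ref_allele_window = NA,
                            alt_allele_window = "TGTTTTTTACATTACAGG")
  expect_identical(unname(got["mismatches_vs_alt"]), 1L)
  expect_true(is.na(got["mismatches_vs_ref"]))
  same <- allele_specificity("ACGTACGT", "ACGTACGT", "ACGTACGT")
  expect_identical(unname(same), c(0L, 0L))
  expect_error(allele_specificity("ACGT", "ACG", "ACGT"), "length")
})

test_that("fixture design annotates allele specificity by position", {
  locus <- fixture_locus()
  cand <- design_asos(locus, flank = 60)
  expect_identical(nrow(cand), 122L)  # (19 + 2*60) - 18 + 1
  ins <- attr(cand, "ins_interval_ts")
  over <- cand$target_end >= ins[1] & cand$target_start <= ins[2]
  ## candidates touching the insertion have no anchored ref window
  expect_true(all(is.na(cand$mismatches_vs_ref[over])))
  expect_true(all(cand$mismatches_vs_ref[!over] == 0L))
  ## designs against the corrected allele always match their target
  expect_true(all(cand$mismatches_vs_alt == 0L))

  ## the first design round (reported allele) mismatches the true
  ## haplotype at exactly one base for candidates covering position 13
  cand_r <- design_asos(locus, flank = 60, allele = "reported")
  snp_ts <- ins[1] + 12L
  covers <- cand_r$target_start <= snp_ts & cand_r$target_end >= snp_ts
  expect_true(all(cand_r$mismatches_vs_alt[covers] == 1L))
  expect_true(all(cand_r$mismatches_vs_alt[!covers] == 0L))
})

test_that("filter application is order-independent and monotone", {
  locus <- fixture_locus()
  cand <- design_asos(locus, flank = 60)
  a <- which(gc_filter(cand) & homopolymer_filter(cand))
  b <- which(homopolymer_filter(cand) & gc_filter(cand))
  expect_identical(a, b)
  ## tightening a filter never enlarges the passing set
  pass_wide <- which(gc_filter(cand, 0.25, 0.75))
  pass_narrow <- which(gc_filter(cand, 0.30, 0.60))
  expect_true(all(pass_narrow %in% pass_wide))
  run_tight <- which(homopolymer_filter(cand, 3L))
  run_loose <- which(homopolymer_filter(cand, 5L))
  expect_true(all(run_tight %in% run_loose))
})

test_that("design report joins filters with stable ordering and reasons", {
  locus <- fixture_locus()
  cand <- design_asos(locus, flank = 40)
  ot <- data.frame(id = cand$id,
                   pass_offtarget = rep(TRUE, nrow(cand)))
  ot$pass_offtarget[1] <- FALSE
  rep_tab <- design_report(cand, ot)
  expect_identical(nrow(rep_tab), nrow(cand))
  expect_identical(rep_tab$target_start, sort(cand$target_start))
  expect_true(all(rep_tab$pass_overall ==
                    (rep_tab$pass_gc & rep_tab$pass_homopolymer &
                       rep_tab$pass_offtarget)))
  i <- which(!rep_tab$pass_offtarget)
  expect_match(rep_tab$reason[i], "offtarget")
  gc_only <- which(!rep_tab$pass_gc & rep_tab$pass_homopolymer &
                     rep_tab$pass_offtarget)
  if (length(gc_only) > 0L) {
    expect_identical(unique(rep_tab$reason[gc_only]), "gc")
  }
  expect_true(any(rep_tab$pass_overall))
})
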