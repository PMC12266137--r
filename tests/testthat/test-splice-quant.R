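test_that("junction filtering applies the minimum-read rule", {
  tab <- data.frame(donor = 1:4, acceptor = 11:14, count = c(1L, 2L, 3L,
                                                             10L))
  kept <- filter_junctions(tab)
  expect_identical(kept$count, c(3L, 10L))
  expect_identical(filter_junctions(tab, 0L)$count, tab$count)
  empty <- tab[0, ]
  expect_identical(nrow(filter_junctions(empty)), 0L)
})

test_that("PSI arithmetic, CI bounds and the zero denominator", {
  locus <- fixture_locus()
  q <- locus_quant_junctions(locus)
  mk <- function(inc, exc) {
    data.frame(
      donor = c(q$inclusion["donor"], q$exclusion["donor"]),
      acceptor = c(q$inclusion["acceptor"], q$exclusion["acceptor"]),
      count = c(inc, exc))
  }
  expect_identical(compute_psi(mk(0L, 500L), locus)$psi, 0)
  est <- compute_psi(mk(2L, 98L), locus)
  expect_identical(est$psi, 0.02)
  expect_true(est$ci_low <= est$psi && est$psi <= est$ci_high)
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
  ## zero denominator: flagged undefined, no NaN
  und <- compute_psi(mk(0L, 0L), locus)
  expect_false(und$defined)
  expect_true(is.na(und$psi) && !is.nan(und$psi))
  ## donor side pools the two cryptic donors
  tab <- simulate_junction_counts(locus, 0.1, 2000L, seed = 8)
  acc <- compute_psi(tab, locus, side = "acceptor")
  don <- compute_psi(tab, locus, side = "donor")
  men <- compute_psi(tab, locus, side = "mean")
  expect_identical(don$inclusion_count,
                   sum(tab$count[grepl("inclusion_donor", tab$label)]))
  expect_equal(men$psi, mean(c(acc$psi, don$psi)))
})

test_that("PSI estimator is unbiased under binomial resimulation", {
  locus <- fixture_locus()
  p <- 0.017
  n <- 2000L
  psis <- vapply(1:500, function(i) {
    compute_psi(simulate_junction_counts(locus, p, n, seed = 5000L + i),
                locus)$psi
  }, numeric(1))
  se <- sqrt(p * (1 - p) / n) / sqrt(500)
  expect_lt(abs(mean(psis) - p), 2 * se)
})

test_that("read assignment is exact on diagnostic junction chains", {
  locus <- fixture_locus()
  ## uniquely diagnostic single junctions
  q <- locus_quant_junctions(locus)
  one <- function(j) {
    data.frame(read_id = "r1",
               chain = sprintf("%d:%d", j[["donor"]], j[["acceptor"]]))
  }
  expect_identical(
    assign_reads(one(q$exclusion), locus)$assignments$assigned_isoform,
    "canonical")
  expect_identical(
    assign_reads(one(q$donor_mt2), locus)$assignments$assigned_isoform,
    "MT2")
  ## the shared acceptor junction is diagnostic but not unique -> ambiguous
  expect_identical(
    assign_reads(one(q$inclusion), locus)$assignments$assigned_isoform,
    "ambiguous")
  ## a read with no junctions is ambiguous
  empt <- data.frame(read_id = "r2", chain = "")
  expect_identical(assign_reads(empt, locus)$n_ambiguous, 1L)
  ## constitutive-only reads are compatible with all models -> ambiguous
  jc <- transcript_junctions(locus, "canonical", coords = "alt")
  const <- data.frame(read_id = "r3",
                      chain = sprintf("%d:%d", jc$donor[1],
                                      jc$acceptor[1]))
  expect_identical(assign_reads(const, locus)$n_ambiguous, 1L)
})

test_that("full-length reads recover simulation proportions", {
  locus <- fixture_locus()
  p <- c(canonical = 0.988, MT1 = 0.006, MT2 = 0.006)
  rd <- simulate_long_reads(locus, p, 50000L, seed = 5)
  quant <- assign_reads(rd, locus)
  expect_identical(quant$n_ambiguous, 0L)
  for (id in names(p)) {
    sd3 <- 3 * sqrt(p[[id]] * (1 - p[[id]]) / 50000)
    expect_lt(abs(quant$proportions[[id]] - p[[id]]), sd3)
  }
  ## assignment never peeks at the truth labels
  expect_identical(unname(quant$counts[names(p)]),
                   as.integer(table(rd$true_isoform)[names(p)]))
})

test_that("ambiguous fraction rises monotonically with truncation", {
  locus <- fixture_locus()
  p <- c(canonical = 0.5, MT1 = 0.25, MT2 = 0.25)
  frac <- vapply(c(0, 0.4, 0.8), function(tf) {
    rd <- simulate_long_reads(locus, p, 3000L, seed = 17,
                              truncate_frac = tf)
    assign_reads(rd, locus)$n_ambiguous / nrow(rd)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_identical(frac[1], 0)
})

test_that("ORF annotation finds the pseudoexon PTC and applies the NMD rule", {
  locus <- fixture_locus()
  a1 <- annotate_orf("MT1", locus)
  expect_identical(a1$stop_codon, "UAA")
  expect_identical(a1$stop_offset_in_pseudoexon, 12L)
  expect_identical(a1$distance_stop_to_last_junction, 226L)
  expect_true(a1$nmd_predicted)

  a2 <- annotate_orf("MT2", locus)
  expect_identical(a2$stop_codon, "UAA")
  expect_identical(a2$stop_offset_in_pseudoexon, 12L)
  expect_identical(a2$distance_stop_to_last_junction, 191L)
  expect_true(a2$nmd_predicted)

  ac <- annotate_orf("canonical", locus)
  expect_true(ac$stop_in_last_exon)
  expect_false(ac$nmd_predicted)
  expect_true(is.na(ac$stop_offset_in_pseudoexon))

  ## threshold is exposed: an absurdly large one suppresses the call
  expect_false(annotate_orf("MT1", locus,
                            nmd_threshold_nt = 500L)$nmd_predicted)
  expect_error(annotate_orf("nope", locus), "unknown transcript")
})

test_that("exon structure reconstruction from junction chains", {
  locus <- fixture_locus()
  for (id in c("MT1", "MT2")) {
    chain <- transcript_junctions(locus, id, coords = "alt")
    lens <- infer_exon_lengths(chain)
    tx <- locus$transcripts[[id]]
    inner <- tx$exons$end - tx$exons$start + 1L
    inner <- inner[-c(1L, length(inner))]
    expect_identical(lens, as.integer(inner))
    ## the penultimate exon is the pseudoexon
    expect_identical(lens[length(lens)], pseudoexon_length(locus, id))
  }
  expect_identical(infer_exon_lengths(""), integer(0))
})
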