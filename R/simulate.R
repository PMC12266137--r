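## Simulators for every input data type the pipeline consumes: phased
## pileups with base-call errors, binomially split junction reads,
## multinomial long-read junction chains, and noisy dose-response plates.
## All draw from a caller-supplied seed and restore the global RNG state.

#' Simulate a phased pileup over the delins region
#'
#' Generates per-position base counts for both haplotypes (1 = reference
#' allele, 2 = indel allele) across the delins interval plus `window_pad`
#' flanking bases. Each of the `depth` reads reports the true base with
#' probability `1 - error_rate`, otherwise one of the three other bases
#' uniformly.
#'
#' @param locus a `locus_model`.
#' @param depth reads per column (>= 1).
#' @param error_rate per-base miscall fraction in `[0, 0.5)`; at 0.5 or
#'   above a majority vote is no longer meaningful and the call is refused.
#' @param seed integer seed; fully determines the output.
#' @param window_pad flanking bases on each side of the delins interval.
#' @return a `phased_pileup`: list with `haplotypes`, each a
#'   `pileup_block` carrying `haplotype_id` and a `columns` data frame
#'   (`pos`, `A`, `C`, `G`, `T`, `DEL`, `INS` list-column of named
#'   insertion counts).
#' @export
simulate_phased_pileup <- function(locus, depth, error_rate, seed,
                                   window_pad = 5L) {
  stopifnot(inherits(locus, "locus_model"))
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5): at 0.5 the majority base is no ",
         "longer meaningful")
  }
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    haps <- lapply(c(1L, 2L), function(h) {
      iv <- if (h == 1L) locus$meta$indel_ref else locus$meta$indel_alt
      seq <- haplotype_sequence(locus, h)
      pos <- seq.int(iv[1] - window_pad, iv[2] + window_pad)
      local <- pos - locus$coordinate_offset + 1L
      stopifnot(all(local >= 1L), all(local <= nchar(seq)))
      truth <- .chars(substr(seq, min(local), max(local)))
      counts <- matrix(0L, nrow = length(pos), ncol = 4L,
                       dimnames = list(NULL, bases))
      for (i in seq_along(pos)) {
        p <- rep(error_rate / 3, 4L)
        p[match(truth[i], bases)] <- 1 - error_rate
        counts[i, ] <- as.integer(stats::rmultinom(1L, depth, p))
      }
      cols <- data.frame(pos = pos, counts, DEL = 0L)
      cols$INS <- replicate(length(pos), integer(0), simplify = FALSE)
      structure(list(haplotype_id = h, columns = cols),
                class = "pileup_block")
    })
    names(haps) <- c("1", "2")
    structure(list(haplotypes = haps,
                   depth = depth, error_rate = error_rate),
              class = "phased_pileup")
  })
}

#' Simulate junction-spanning read counts at a true inclusion level
#'
#' Splits `total_junction_reads` binomially between the pseudoexon
#' inclusion junction (exon15 -> pseudoexon acceptor) and the canonical
#' exclusion junction (exon15 -> exon16) so that the expected
#' inclusion/total ratio equals `psi_true`. Inclusion reads are further
#' split evenly (binomially) between the two cryptic donor junctions.
#' Constitutive upstream junctions are emitted at the full read count and
#' three decoy junctions with counts 1, 2 and 3 are always appended to
#' exercise the minimum-read display filter.
#'
#' @param locus a `locus_model`.
#' @param psi_true true inclusion fraction in `[0, 1]`.
#' @param total_junction_reads total inclusion + exclusion reads (> 0).
#' @param seed integer seed.
#' @return a `junction_table` data frame with columns `donor`, `acceptor`,
#'   `count`, `label` (alt-haplotype coordinates).
#' @export
simulate_junction_counts <- function(locus, psi_true, total_junction_reads,
                                     seed) {
  stopifnot(inherits(locus, "locus_model"))
  if (psi_true < 0 || psi_true > 1) stop("psi_true must be in [0, 1]")
  n <- as.integer(total_junction_reads)
  if (n <= 0L) stop("total_junction_reads must be positive")
  q <- locus_quant_junctions(locus)
  .with_seed(seed, {
    inc <- stats::rbinom(1L, n, psi_true)
    exc <- n - inc
    d1 <- stats::rbinom(1L, inc, 0.5)
    d2 <- inc - d1
    const <- transcript_junctions(locus, "canonical", coords = "alt")
    const <- const[-nrow(const), , drop = FALSE]  # drop exon15->16 here
    off <- locus$coordinate_offset
    tab <- rbind(
      data.frame(donor = const$donor, acceptor = const$acceptor, count = n,
                 label = sprintf("constitutive_%d", seq_len(nrow(const)))),
      data.frame(donor = q$exclusion["donor"],
                 acceptor = q$exclusion["acceptor"],
                 count = exc, label = "exclusion"),
      data.frame(donor = q$inclusion["donor"],
                 acceptor = q$inclusion["acceptor"],
                 count = inc, label = "inclusion"),
      data.frame(donor = q$donor_mt1["donor"],
                 acceptor = q$donor_mt1["acceptor"],
                 count = d1, label = "inclusion_donor_mt1"),
      data.frame(donor = q$donor_mt2["donor"],
                 acceptor = q$donor_mt2["acceptor"],
                 count = d2, label = "inclusion_donor_mt2"),
      ## decoys below the display filter, at positions outside the gene
      data.frame(donor = off + c(60L, 40L, 20L),
                 acceptor = off + c(50L, 30L, 10L),
                 count = 1:3, label = sprintf("decoy_%d", 1:3))
    )
    rownames(tab) <- NULL
    class(tab) <- c("junction_table", "data.frame")
    tab
  })
}

## chain <-> string encoding ("donor:acceptor,donor:acceptor,...")
.chain_to_string <- function(df) {
  if (nrow(df) == 0L) return("")
  paste(sprintf("%d:%d", df$donor, df$acceptor), collapse = ",")
}

.string_to_chain <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  }
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(donor = as.integer(vapply(parts, `[`, character(1), 1L)),
             acceptor = as.integer(vapply(parts, `[`, character(1), 2L)))
}

#' Simulate long reads as junction chains
#'
#' Draws `n_reads` reads multinomially from the given isoform proportions;
#' each read carries the ordered splice-junction chain of its source
#' isoform (alt-haplotype coordinates; base-level errors are not
#' simulated, as isoform identification rests on junction chains). With
#' `truncate_frac > 0` a read is 5'-truncated with that probability,
#' dropping a uniform number of leading junctions — possibly all of them,
#' leaving an unassignable read.
#'
#' @param locus a `locus_model`.
#' @param proportions named fractions over `locus$transcripts`, summing
#'   to 1 (tolerance 1e-9).
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @param truncate_frac probability a read is 5'-truncated.
#' @return a `read_chains` data frame: `read_id`, `true_isoform`,
#'   `chain` (encoded `"donor:acceptor,..."`, possibly empty).
#' @export
simulate_long_reads <- function(locus, proportions, n_reads, seed,
                                truncate_frac = 0) {
  stopifnot(inherits(locus, "locus_model"))
  ids <- names(proportions)
  unknown <- setdiff(ids, names(locus$transcripts))
  if (length(unknown) > 0L) {
    stop("unknown isoform id(s): ", paste(unknown, collapse = ", "))
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1")
  }
  if (truncate_frac < 0 || truncate_frac > 1) {
    stop("truncate_frac must be in [0, 1]")
  }
  chains <- vapply(ids, function(id) {
    .chain_to_string(transcript_junctions(locus, id, coords = "alt"))
  }, character(1))
  .with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1L, n_reads, proportions))
    iso <- rep(ids, counts)
    chain <- rep(unname(chains), counts)
    ## permute so read order carries no isoform information
    ord <- sample.int(length(iso))
    iso <- iso[ord]
    chain <- chain[ord]
    if (truncate_frac > 0) {
      trunc <- stats::runif(length(iso)) < truncate_frac
      for (i in which(trunc)) {
        cj <- .string_to_chain(chain[i])
        nj <- nrow(cj)
        if (nj == 0L) next
        k <- sample.int(nj, 1L)  # drop k leading junctions (k may be all)
        chain[i] <- .chain_to_string(cj[-seq_len(k), , drop = FALSE])
      }
    }
    out <- data.frame(read_id = sprintf("read_%06d", seq_along(iso)),
                      true_isoform = iso, chain = chain,
                      stringsAsFactors = FALSE)
    class(out) <- c("read_chains", "data.frame")
    out
  })
}

#' Simulate a dose-response plate
#'
#' Responses follow the normalized variable-slope logistic model with a
#' 0-100 span and additive Gaussian noise. Stimulation plates are emitted
#' on the raw percent-of-mock scale (model value + 100), so the fitting
#' stage must perform the baseline subtraction itself; inhibition plates
#' are emitted directly on the percent-of-mock scale (100 at low dose
#' falling to 0).
#'
#' @param ec50 true EC50/IC50 (same units as `doses`, > 0).
#' @param hill true Hill slope (> 0).
#' @param doses dose grid (> 0), e.g. [serial_dilution()].
#' @param noise_sd Gaussian noise SD on the response scale (>= 0).
#' @param seed integer seed.
#' @param mode `"stimulation"` or `"inhibition"`.
#' @param replicates technical replicates per dose.
#' @param aso_id identifier carried into the table.
#' @return a `dose_table` data frame: `aso_id`, `dose`, `response`,
#'   `replicate`, with the mode stored in `attr(, "mode")`.
#' @export
simulate_dose_response <- function(ec50, hill, doses, noise_sd, seed,
                                   mode = c("stimulation", "inhibition"),
                                   replicates = 4L, aso_id = "ASO") {
  mode <- match.arg(mode)
  if (ec50 <= 0) stop("ec50 must be positive")
  if (hill <= 0) stop("hill must be positive")
  if (any(doses <= 0)) stop("doses must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  d <- rep(doses, each = replicates)
  norm <- 100 / (1 + (ec50 / d)^hill)
  mean_resp <- if (mode == "stimulation") norm + 100 else 100 - norm
  .with_seed(seed, {
    resp <- mean_resp + stats::rnorm(length(d), 0, noise_sd)
    out <- data.frame(aso_id = aso_id, dose = d, response = resp,
                      replicate = rep(seq_len(replicates), length(doses)),
                      stringsAsFactors = FALSE)
    attr(out, "mode") <- mode
    class(out) <- c("dose_table", "data.frame")
    out
  })
}
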