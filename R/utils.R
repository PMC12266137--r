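#' @keywords internal
"_PACKAGE"

## IUPAC complement table, uppercase DNA + ambiguity codes.
.complement_map <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

## IUPAC code for a set of bases (sorted, unique).
.iupac_from_bases <- local({
  tab <- c(
    A = "A", C = "C", G = "G", T = "T",
    AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
    ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
  )
  function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    code <- tab[[key]]
    if (is.null(code)) stop("no IUPAC code for base set: ", key)
    code
  }
})

.stop_codons <- c("TAA", "TAG", "TGA")

#' Split a DNA string into single characters
#' @noRd
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Assert a scalar DNA string over a given alphabet
#' @noRd
.check_dna <- function(seq, alphabet = c("A", "C", "G", "T"),
                       what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- .chars(seq)
  bad <- which(!ch %in% alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' in %s at position %d",
                 ch[bad[1L]], what, bad[1L]))
  }
  invisible(seq)
}

#' Draw a derived RNG seed below 2^31
#' @noRd
.derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483587L
}

#' Random DNA of length n from the current RNG stream
#' @noRd
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Random codons excluding stop codons
#' @noRd
.random_nonstop_codons <- function(n_codons) {
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- .random_dna(3L)
      if (!cod %in% .stop_codons) break
    }
    codons[i] <- cod
  }
  paste(codons, collapse = "")
}

#' Overwrite a substring in place
#' @noRd
.patch <- function(seq, at, replacement) {
  substr(seq, at, at + nchar(replacement) - 1L) <- replacement
  seq
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`.
#' @noRd
.wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}
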