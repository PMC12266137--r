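---
title: "Methods: models, parameters and design choices in spliceaso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in spliceaso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceaso)
```

# The synthetic locus

Everything in this package is testable because the fixture locus
(`build_fixture_locus()`) is constructed, not sampled from a genome. It
is a ~4 kb segment of a minus-strand gene with six canonical exons
(labelled exon 11–16, a compact tail of a larger gene model) whose
intron 15 carries the 9 → 19 nt delins: the plus-strand run
`CCACCACAC` at chr3:81493813–81493821 replaced by
`ACCTGTAATGTAAAAAACA`. Several constraints are imposed simultaneously,
and `validate_locus()` asserts all of them in one place:

* the inserted allele carries the ectopic acceptor `AG` immediately 5′
  of the pseudoexon start (transcript sense `…ACATTAC·AG·GT…`, the
  pseudoexon beginning with the insertion's final `GT`);
* the two mutant isoforms share that acceptor and differ only at the
  donor-side boundary — 241 nt (MT1) and 206 nt (MT2) pseudoexons by
  default, both followed by a canonical `GT` donor in the intron;
* the mRNA-sense triplet at pseudoexon positions 13–15 is the stop
  codon `UAA`, in frame with the canonical start codon (the cumulative
  coding length upstream of the pseudoexon is a multiple of 3, which
  the exon lengths are chosen to guarantee);
* both mutant isoforms retain canonical exon 16 as their final exon,
  making the pseudoexon penultimate;
* the canonical ORF reaches its stop codon only inside exon 16.

Sequence not pinned down by these constraints — UTRs, intron interiors,
codons between start and stop — is generated pseudo-randomly from a
fixed packaged seed (changeable via `config$internal_seed`) and
screened so that no in-frame stop precedes pseudoexon position 13. The
interior of intron 15 and the exact cryptic donor positions are
synthetic stand-ins: only the pseudoexon *lengths* are constrained, not
their genomic donor coordinates. Exon and intron lengths are package
constants chosen ≥300 nt so that the 200-nt distance-to-exon rule in
the off-target module sees sites on both sides of the boundary.

The gene is deliberately placed on the genomic minus strand.
Reverse-complement bookkeeping is the dominant failure mode in this
problem domain, so every module exercises it: the delins is described
on the plus strand (as in a VCF), transcripts run against it, and the
ASO tiling works in transcript sense.

## Two coordinate systems

The canonical transcript is modelled in reference-haplotype
coordinates, the mutant transcripts in variant-haplotype coordinates
(the pseudoexon partially overlaps the insertion, which has no
reference image). Positions genomically above the indel differ by the
10-nt length change between the systems; `lift_ref_to_alt()` /
`lift_alt_to_ref()` interconvert, returning `NA` inside the replaced
run where no liftover exists. All junction-level quantification lifts
canonical junctions into variant-haplotype coordinates so that shared
junctions coincide numerically. On disk the two haplotypes are separate
FASTA records / GFF3 seqids.

# Simulators: what they emulate, what they do not

`simulate_phased_pileup()` models a phased alignment as independent
per-column base draws: each of `depth` reads reports the true base with
probability $1-e$ and otherwise one of the other three bases uniformly.
Columns are independent; there is no read-level correlation, no indel
errors, and no mapping bias. `error_rate` ≥ 0.5 is refused because a
majority vote is then uninformative. The defaults used in the
demonstrations (depth 30, 1% error) are typical long-read WGS coverage
and accuracy after phasing.

`simulate_junction_counts()` draws inclusion reads binomially at
`psi_true` against exclusion reads, splits inclusion evenly between the
two cryptic donor junctions, and always appends decoy junctions with
counts 1, 2 and 3 so the ≥3-read display filter has something to
remove. Only mature-mRNA junction reads are modelled; real total-RNA
data also contains pre-mRNA reads, which the estimator would count in
neither class but which can contaminate real junction tables.

`simulate_long_reads()` draws read counts multinomially over isoform
proportions and gives every read the exact junction chain of its source
isoform. Base-level errors are not simulated: isoform identification
here rests entirely on junction chains, so error robustness is
delegated to the 5′-truncation knob (`truncate_frac`), which drops a
uniform number of leading junctions and can render reads unassignable.
Passing tests therefore demonstrate correctness of chain matching and
multinomial recovery, not robustness to splice-site wobble or
intra-exon deletions.

`simulate_dose_response()` draws Gaussian noise around the normalized
variable-slope logistic with a 0–100 span. Stimulation plates are
emitted as percent-of-mock (model + 100) so the fitting stage must
perform the baseline subtraction itself, mirroring how qPCR screen data
arrive.

# Quantification

**Consensus.** Per column, the majority base is emitted when its count
reaches `min_support` (default 2, encoding the exclusion of single-read
positions); ties become IUPAC ambiguity codes with a warning, or an
error under `tie_policy = "fail"`. A majority deletion emits nothing; a
post-column insertion is included when its count exceeds half the
column depth. The insertion rule is this package's decision — the
upstream procedure it reproduces did not need one, because the phased
alignment turns the insertion into ordinary columns, which is also how
the packaged simulator represents it.

**PSI.** PSI = inclusion/(inclusion+exclusion). The acceptor-side
junction is the default inclusion count because both mutant isoforms
share it; `side = "donor"` pools the two cryptic donors and
`side = "mean"` averages the two estimates (the convention is not
externally fixed, so it is a parameter). The attached 95% interval is
the Wilson score interval — preferable to Wald at the sub-3% inclusion
fractions this assay produces. A zero denominator yields a flagged
undefined estimate, never NaN.

**Isoform assignment.** A read is assigned to the unique transcript
model whose junction chain contains the read's chain as a contiguous
subchain with at least `min_diagnostic_junctions` discriminating
junctions (junctions absent from at least one model). Reads compatible
with several models are `ambiguous` and never fractionally allocated —
a deliberate simplification relative to EM-based isoform quantifiers,
chosen because it is exactly analyzable: with full-length error-free
reads the estimator is the multinomial MLE restricted to assigned
reads.

**ORF/NMD.** The ORF scan walks in-frame triplets from the canonical
start (`ATG` at a fixture-annotated mRNA position) to the first stop.
NMD is predicted by the canonical junction rule: stop more than
`nmd_threshold_nt` (default 50, the conventional 50–55 nt rule)
upstream of the last exon–exon junction and not in the last exon. For
the fixture this yields distances 226 nt (MT1 = 241 − 15) and 191 nt
(MT2 = 206 − 15): both mutant isoforms are NMD targets, while the
canonical transcript, with its stop in the last exon, is immune.

# ASO design

Candidates are 18-mers tiled at 1-nt resolution across the delins ±60
nt of the variant-haplotype pre-mRNA (window width is a package
default; it is not an externally fixed constant). Filters: GC fraction
within [0.25, 0.75] *inclusive* (a candidate at exactly 25% or 75%
passes — the boundary reading is this package's choice and is pinned by
tests); homopolymer runs of six or more rejected (a run of exactly five
passes). GC is counted on the DNA alphabet; the count is identical for
the RNA alphabet since U replaces T only.

`design_asos(allele = "reported")` reproduces a first design round made
against a mis-genotyped allele differing at insertion position 13
(G vs T): those candidates carry exactly one mismatch against the true
haplotype wherever they cover that base, and the mismatch accounting
(`mismatches_vs_alt`/`mismatches_vs_ref`) quantifies it. Candidates
overlapping the insertion have no anchored reference window and are
marked absent (`NA`) rather than given a fabricated count. Chemistry
(2′MOE, phosphorothioate) is metadata only; no thermodynamic or
immune-motif scoring is attempted.

# Off-target search

The search is self-contained and desk-scale, replacing external
aligners with a provably complete exact-seed scan. The query (the
ASO's reverse complement — its sense-strand hybridization site) is
partitioned into three disjoint 6-mer seed blocks:

* any ungapped alignment with ≤2 mismatches leaves one block exact
  (pigeonhole);
* any alignment containing a ≥16-nt exact run contains the middle
  block of an 18-mer in full;
* a single 1-nt bulge with no mismatch splits the query into two exact
  blocks, the longer of which (≥9 nt) contains a full seed block on a
  diagonal within ±1.

Seed lookups with candidate offsets expanded one diagonal either side
therefore retrieve every qualifying alignment, and each candidate is
verified directly. Classification follows the fixed rule: off-target
iff (mismatches + gaps ≤ 1 **or** ≥16 contiguous matches) **and**
sense orientation **and** distance to exon ≤200 nt (boundary
inclusive). Distance is the count of nucleotides strictly between the
nearest alignment edge and the nearest exon boundary, computed against
the gene's canonical transcript annotation when one shares the
record's coordinate space, else the record's own exons; mature-mRNA
hits are exonic by construction.

Two conventions deserve note. First, only *internal* bulges count as
gap alignments: deleting a terminal base is merely a shifted exact
match, and admitting it would report every exact site three times.
Second, when the query begins or ends with a repeated base, an
internal bulge adjacent to an exact site is a genuinely distinct
alignment (gap-placement ambiguity), so per-ASO counts can exceed the
number of physical sites; counts are of alignments, not loci. The test
suite checks the search set-equal to an exhaustive sliding-window scan
(including gap enumeration) on dozens of randomized transcriptomes
with planted exact, mismatched and bulged sites.

The packaged searches run on synthetic transcriptomes
(`locus_transcriptome()` or user-supplied FASTA+GFF3); genome-scale
annotation sets are out of scope.

# Pharmacology

**2^−ΔΔCT.** Technical replicates are averaged per sample before
calibration (the upstream averaging convention is unstated, so the
simplest one is used and exposed in the code); ΔCt = Ct(target) −
Ct(housekeeping), ΔΔCt subtracts the calibrator-condition mean, fold =
2^−ΔΔCt. Ct values must be positive and under the 40-cycle assay
ceiling.

**Hit calling** uses strict inequality at both screen thresholds
(>125% of mock single-dose, >140% at the top dose of a dose–response
screen), and named negative controls are excluded from the hit set
(with a warning if one exceeds the threshold, since that indicates an
assay problem).

**EC50/IC50.** Stimulation responses are first adjusted by subtracting
the mock baseline of 100 (values below mock go negative and are
retained). The default fit is the normalized variable-slope logistic
$y = 100/(1+(\mathrm{EC50}/x)^h)$ — two free parameters, EC50 and
Hill — estimated by Levenberg–Marquardt least squares over a
multi-start grid of seven log-spaced EC50 initials × three Hill
initials, with finite box constraints keeping the Hill slope positive.
The reported absolute EC50 is the dose at which the fitted curve
crosses 50 on the 0–100 span, which for this symmetric model equals
the EC50 parameter; relative and absolute EC50 coincide here by
construction. Fitting on log(EC50) makes the estimate exactly
scale-equivariant: multiplying all doses by $c$ multiplies the EC50 by
$c$.

The span was fixed rather than fitted after a design comparison: on
five-point four-fold plates with noise SD 10, the free-asymptote 4PL's
median |EC50 error| is ≈25% (EC50 trades off against a top plateau the
design never observes), versus ≈9% for the normalized model, and the
normalized model recovers noiseless curves exactly. Data whose plateau
is genuinely unknown can be fitted with `span = "free"`, which
estimates bottom and top as well. Non-convergence is always reported
(`converged = FALSE` with diagnostics), never silently dropped;
replicate-mean fitting is available via `replicate_means = TRUE`
because the upstream pooling convention is unstated.

# Problem sizes and determinism

The demonstration and test problem sizes — pileups at depth 30 over the
indel ±5 nt, 5 000 junction reads per simulated patient, 20 000 long
reads, 200-curve Monte-Carlo recovery studies, 50 randomized
toy transcriptomes for the search-equivalence property — were chosen so
that each stage's sampling error is small relative to the effects being
recovered (3-SD binomial/multinomial envelopes) while the whole suite
runs in well under a minute per module. Every simulator takes an
explicit seed and restores the caller's RNG state;
`run_pipeline()` derives per-stage seeds from a single master seed and
writes a manifest of MD5 checksums, so a fixed configuration is
byte-reproducible.

# Known limitations

* The locus is synthetic: intron interiors, donor-site positions and
  exon lengths are constructed, so sequence-dependent effects (splice
  site strength, RNA structure, real off-target homology) are outside
  what passing tests demonstrate.
* PSI is estimated from mature junction reads only; pre-mRNA
  contamination in total-RNA libraries is not modelled.
* Isoform assignment is exact chain containment — no error-tolerant
  junction matching and no novel-isoform discovery.
* The off-target search guarantees completeness for 18-mer queries
  with 6-mer seeds at ≤2 mismatches; other query lengths require
  rechecking the pigeonhole argument (the implementation enforces
  query length ≥ 3 × seed length).
* No thermodynamics, immunogenicity, kinetic NMD modelling, or
  wet-lab statistics (ANOVA/post-hoc) are included.
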