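---
title: "Alignment-free comparison of small viral genomes with pvgc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free comparison of small viral genomes with pvgc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvgc)
```

## The problem

Polyomaviruses (PyVs) are small non-enveloped viruses with circular dsDNA
genomes of roughly 5 kb. Public collections of complete PyV genomes span
everything from near-identical strains of one species to genera that share
no alignable stretch outside a handful of conserved protein domains.
Multiple sequence alignment across such a range is fragile: alignable
regions shrink as divergence grows, and the alignment itself becomes the
main source of uncertainty. `pvgc` implements an alignment-free
alternative: a whole-genome similarity statistic computed directly from
short sequence windows, an extreme-value significance model for that
statistic, graph clustering of genomes at significance cutoffs, and a
per-window conservation profile. Around this core it provides the
curation, annotation, surveillance-tally and simulation utilities needed
to run a complete small-virus comparative study from FASTA files.

## The similarity statistic S

Take every window (w-mer) of length $w$ from genome $A$ (start positions
$1, 2, \dots, L_A - w + 1$; step 1) and compare it, ungapped, with every
w-mer of genome $B$. A window pair *qualifies* when the number of
identical nucleotides in its alignment is strictly greater than a critical
value $n$. The similarity of the two genomes is

$$ S(A, B) = \#\{(i, j) : \mathrm{ident}(A_{i..i+w-1}, B_{j..j+w-1}) > n\}. $$

The defaults are $w = 50$ and $n = 30$, i.e. a window pair counts when
more than 60% of its 50 positions match. Qualifying pairs capture any
conserved feature longer than a window — protein domains, regulatory
elements, untranslated signals — without deciding in advance where genes
are. `S` is symmetric in its arguments, bounded by
$(L_A - w + 1)(L_B - w + 1)$, and at least $L - w + 1$ for self-comparison
(each diagonal pair matches at all $w > n$ positions).

Two counting modes exist. `all_pairs` (the default) counts every
qualifying ordered window pair; it is symmetric by construction and is the
mode all downstream defaults assume. `best_pair` counts query windows
whose best match qualifies, which caps the statistic at $L_A - w + 1$ and
is convenient when a per-window yes/no view is wanted. The statistic's
definition is ambiguous between the two readings ("statistics of best
pairs" vs "counted only pairs"); both are provided, the calibration
records which mode it was run under, and mixing a model with the other
mode's scores is refused by the default-model constructor.

Implementation: the naive count costs $O(L_A L_B w)$. `pvgc` sweeps each
diagonal of the $L_A \times L_B$ grid once, updating the identity count
incrementally (subtract the leaving position, add the entering one), for
$O(L_A L_B)$ total — a 5 kb × 5 kb comparison takes well under a second in
the compiled kernel. The test suite keeps two independent oracles (a
double-loop brute force and a cumulative-sum recount) and checks the
kernel against them across hundreds of random pairs.

Conventions that matter:

* **Threshold strictness.** Qualification is *strictly greater than* $n$
  (i.e. at least $n + 1$ identities), following the statistic's
  definition; `strict = FALSE` relaxes it to $\ge n$ for sensitivity
  analyses.
* **Ambiguity codes** (N, R, Y, ...) never match anything, themselves
  included. Unresolved positions therefore behave as guaranteed
  mismatches.
* **Linear by default.** PyV genomes are circular but are deposited
  linearized; with no principled junction treatment in the statistic's
  definition, linear is the default and `circular = TRUE` appends the
  first $w - 1$ bases so every rotational window exists.
* **Strands.** `best_orientation_score()` evaluates both strands of the
  second genome and keeps the larger score (ties keep forward). The
  all-vs-all matrix uses it by default.

## Significance: the extreme-value model

Between unrelated genomes, qualifying pairs arise by chance. Their
count is modeled by a Gumbel (type-I extreme-value) law:

$$ p(S \ge x) = 1 - \exp\!\left(-e^{-\lambda (x - u)}\right), $$

with characteristic value $u$ (location; dimension of a score) and scale
$\lambda$ (per score unit). The packaged default model carries
$u = 18$, $\lambda = 0.1$, fitted on comparisons of shuffled ~5-kb PyV
genomes under $w = 50$, $n = 30$. Those constants are setting-specific:
`default_evd_model()` refuses other parameter combinations unless
explicitly overridden, and `calibrate_evd()` refits the model for any
other setting.

Calibration shuffles each genome (uniform permutation of positions —
mononucleotide composition preserved exactly; a dinucleotide-preserving
shuffle was considered out of scope since the null model is stated only
as "randomized"), scores a configurable sample of shuffled pairs, and
fits by the method of moments
($\hat\lambda = \pi / \sqrt{6\,s^2}$, $\hat u = \bar x - \gamma/\hat\lambda$,
with $\gamma$ the Euler–Mascheroni constant and $s^2$ the $n-1$-denominator
sample variance) or by numerical maximum likelihood initialized at the
moments fit. Which pairs enter the fit (all pairs vs a random subset,
how many shuffle rounds) is explicit configuration, because the choice
genuinely affects small samples and no single plan is canonical.

Two numerical commitments run through the package:

* **log10 p everywhere.** Cutoffs of practical interest reach $10^{-86}$
  and below, far past double underflow ($\sim 10^{-308}$).
  `evd_pvalue()` returns both the linear $p$ (0 when it underflows) and
  a log-domain `log10p` computed via `-expm1`, accurate to within a few
  ulps over the whole score range; the clustering layer consumes only
  `log10p`. For scores far *below* $u$ the linear $p$ saturates at 1 in
  double precision — irrelevant in practice since $S \ge 0$ and
  interesting scores sit far above $u$.
* **Underflow sentinel.** Matrix entries below $\log_{10} p = -10{,}000$
  are clamped; that is orders of magnitude past any cutoff in use, and a
  finite sentinel keeps file round-trips exact.

The critical value $n$ itself can be chosen with
`select_critical_value()`: for candidate thresholds it tabulates the mean
null score (shuffled pairs) against the weakest real-pair score and
recommends the smallest $n$ keeping the background at or below 15% of the
weakest genuine signal — the "small fraction of meaningless hits" rule,
with the full table returned so users can apply their own ceiling.

## Clustering at p cutoffs

`pairwise_pmatrix()` computes $S$ for every unordered pair at the best
orientation and converts to $\log_{10} p$; `threshold_clusters()` draws
an edge wherever $\log_{10} p \le$ cutoff (smaller p = stronger
similarity) and reports connected components. Exact components replace
the force-directed dynamic clustering used interactively in this field:
component membership is the reproducible, testable content of such
figures, while the layout is presentation. A deterministic, seeded force
layout (`force_layout()`) and a CLANS-format export (`clans_export()`)
are provided for visual work. Component labels are the
lexicographically smallest member id, so outputs are diff-stable.

`cutoff_sweep()` clusters at a descending ladder of cutoffs (e.g.
$10^{-10}, 10^{-39}, 10^{-56}, 10^{-69}, 10^{-86}$) and reports, for
every genome pair, the loosest cutoff at which the pair first falls into
different components — the "separation level" at which two lineages
part. Because loosening a cutoff only ever adds edges, components are
nested along the sweep; the suite asserts this monotonicity on random
matrices, and checks components against a transitive-closure oracle.

Self-similarity is excluded from edges (the diagonal carries a $-\infty$
sentinel): self-links are uninformative for connectivity.

## Conservation profiles

`conservation_profile()` asks, for each query window start, what
percentage of database genomes contain at least one qualifying partner
window, searching both strands of each database genome by default (the
profile should not depend on deposition strand; forward-only is
available). Plotted along the genome this exposes the conserved cores —
in PyVs, the LTag helicase/ATPase region and the VP1 β-barrel — against
lineage-specific stretches like the NCCR.

## Curation of public genome sets

`curate_genomes()` composes the standard preparation steps:

* **Length filter** with inclusive bounds (defaults 3500–8000 nt):
  records at the boundary pass; shorter fragments and longer
  (host-integrated) records are dropped with reasons.
* **Ambiguity resolution**: each non-ACGT position is replaced by the
  base at the aligned center of the best-matching 41-nt context window
  in the other genomes, when that window exceeds 60% identity (the same
  proportion as the w-mer rule's 30/50); ties prefer the most frequent
  center base, then alphabetical order. Unresolved positions stay and
  act as mismatches downstream. Ambiguities inside the search context
  count as mismatches. The reference search runs on the forward strand
  by default (resolution precedes strand correspondence; a both-strands
  option exists).
* **Strand correspondence**: the first genome (or a configured
  reference) anchors the set; every other genome keeps whichever strand
  scores higher against it, ties forward. Deterministic and idempotent.
* **Exact deduplication** afterwards; circular *rotations* of one
  molecule are deliberately not collapsed (deduplication in the
  underlying workflow was exact-identity), so rotated deposits survive
  as distinct records.

Every action lands in a `curation_report` whose kept/dropped sets
partition the input ids.

## Annotation utilities

The annotation scanners reproduce the computations of a small-virus
genome report: `find_orfs()` (both strands, three frames, ATG/GTG
starts, first in-frame start after a stop opens the ORF, stop codon
included in the length — so a 162-bp ORF encodes a 53-aa protein, and
`length_bp = 3 (protein_length_aa + 1)` universally; `all_starts = TRUE`
reports nested starts; circular mode lets ORFs span the junction with
wrapped coordinates), `translate_cds()` (standard code, internal stops
flagged), `scan_motif()` (IUPAC-aware, overlapping hits, both strands —
e.g. the GAGGC LTag-binding pentanucleotides of the ORI),
`find_palindromes()` (maximal reverse-complement palindromes),
`at_rich_regions()` (merged qualifying windows), `splice_candidates()`
(exhaustive GT..AG enumeration with frame effect; consensus *scoring*
is out of scope), and the SNP pair `hamming_snps()` /
`classify_coding_snps()` (position-wise only — sequences with indels
must be pre-aligned; whole-genome SNP counts across indels are
explicitly not attempted). All coordinates are 1-based inclusive on the
forward strand, GenBank-style, and each scanner is tested against a
brute-force oracle on random sequences.

## The synthetic generator

`simulate_families()` plants a partition: independent random ancestors
(default 5000 nt, mildly AT-rich composition 30/20/20/30 to resemble PyV
genomes), members derived by uniform per-site substitution (default 5%,
roughly strain-to-species-level divergence; the ICTV species criterion
sits near 81–85% identity) plus optional geometric-length indels, and an
optional fraction stored reverse-complemented. Every mutation event is
logged so tests can replay the ground truth.

What it emulates: controlled identity levels, strand scrambling, indel
length variation, family structure with an unrelated background. What it
does not: real base composition skews beyond the global AT bias,
transition/transversion bias, recombination, gene content, or shared
ancestry *between* families. Passing the planted-partition tests
therefore shows that the statistic separates signal from a random
background at the stated divergences — not that any particular cutoff
generalizes to real taxa.

## Surveillance arithmetic

`infection_sign_union()` combines a two-tissue PCR screen with a
serological screen by inclusion–exclusion: PCR positives are counted
once across tissues, seropositives add only those not already counted.
The PCR∩serology overlap must be supplied, never inferred.
`prevalence_percent()` rounds half-away-from-zero at one decimal — fixed
for determinism (base R's `round` rounds half to even).

## Problem sizes and determinism

The shipped tests run on synthetic data sized for minutes, not hours:
oracle equivalence on 200+ random pairs of 100–400 nt, planted-partition
recovery on 12 × 5-kb genomes, Gumbel recovery on $10^5$ direct draws.
Every stochastic step takes an explicit seed, routed through a local RNG
scope that leaves the caller's RNG state untouched.

## Known limitations

* The statistic is exact, not heuristic — cost grows as $L_A L_B$, so
  all-vs-all on thousands of genomes is hours of CPU (embarrassingly
  parallel across pairs, but no parallelism is built in).
* The default Gumbel constants apply only to the default setting on
  ~5-kb genomes; everything else requires calibration.
* `best_pair` mode is not symmetric in its arguments; symmetric
  workflows should keep the default mode.
* No gapped alignment anywhere: SNP utilities require pre-equalized
  sequences, and the profile cannot distinguish absence of homology
  from indel displacement beyond the window tolerance (up to
  $w - n - 1$ mismatches absorbed per window).
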