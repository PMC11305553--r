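---
title: "Models and methods behind airrforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind airrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

airrforge is a self-contained toolkit for adaptive immune receptor
repertoire (AIRR) sequencing analysis. It couples a ground-truth simulator of
B-cell receptor (BCR) repertoires and Illumina-like reads with a
re-implementation of the standard bulk AIRR-seq processing chain — UMI
consensus error correction, V(D)J annotation, alignment QC, clonal inference
— plus truth-based benchmarking and cross-subject convergent-antibody
clustering. This vignette documents the models, the parameters that matter,
the numerical choices, and what the simulations do and do not establish
about real data.

## The synthetic germline reference

Real analyses align reads to curated germline databases. airrforge instead
generates a synthetic reference (`build_germline_reference()`) so that the
entire chain, including annotation, can be validated against a known answer.
Each V segment is a stop-free random coding sequence of 210 nt ending in a
conserved cysteine (TGT/TGC) anchor codon followed by three trimmable
codons; each J segment (48 nt) carries a tryptophan/phenylalanine anchor
followed by a glycine-rich in-frame tail, mimicking the [WF]GXG motif; D
segments (12–18 nt) avoid stop triplets in every frame so that random
junction frames are not forced non-productive. Anchor coordinates travel
with the reference, so recombination and annotation share one junction
definition: from the V cysteine codon through the end of the J
tryptophan/phenylalanine codon, i.e. the CDR3 plus both conserved flanks.

The 210-nt V (real IGHV segments run near 300 nt) is a deliberate
desk-scale choice: it shortens simulated amplicons to ~255–290 nt so a
160-nt read pair covers them with a guaranteed ≥ 15 nt mate overlap, while
leaving well over the 200 informative positions required by the alignment
QC filter. Nothing in the processing chain depends on these lengths.

## Repertoire simulation

`simulate_repertoire()` draws `n_clones` naive V(D)J recombinations —
random segment choice, up to `trim_max = 4` nt trimmed per junction-facing
segment end, untemplated N-regions up to `insert_max = 8` nt — and resamples
each until productive (in-frame junction, no stop codon). Clone sizes come
from one of three distributions: a power law with exponent 2.5 (repA-style),
uniform on 1–5 (repB-style; the uniform range is not pinned down by any
external constraint, so a modest range was fixed once), or an empirical
long-tailed table shipped as a plain-text fixture (repC-style: 6,381 clones,
77% singletons, mean size 1.56, generated once from the recipe
`floor(4907 * k^-2.6)`). `n_singletons` naive, unexpanded sequences are
appended as clones of size one, emulating the naive B-cell background.

Somatic hypermutation is simulated along a random bifurcating lineage tree
(iterated random-leaf splitting — a Yule process; the literature does not
prescribe a topology model) with independent per-site substitutions at
`shm_rate = 0.005` per edge. By default each edge is redrawn when its
mutations introduce a stop codon anywhere in the V-frame translation
(`keep_productive = TRUE`). This models selection for functional receptors
during affinity maturation and matches how benchmark truth sets are
analyzed after productive-only filtering; without it roughly 1% of clone
members carry SHM-induced stop codons and are correctly — but
uninformatively — discarded by the pipeline's productivity filter.
`keep_productive = FALSE` restores the pure binomial mutation process and is
what the mutation-calibration test uses, since conditioning on stop-free
draws slightly biases mutation counts downward.

## Read simulation

`simulate_reads()` gives every molecule `2 + Poisson(6)` read pairs (mean 8)
and, under the UMI protocol, one random 12-mer UMI prepended to read 1. The
minimum of two reads per molecule reflects libraries sequenced deeply enough
that the minimum-copy filter does not remove genuine molecules; the Poisson
mean was chosen so that per-UMI consensus has enough redundancy for
column-majority correction at the highest simulated error rate (with k ≥ 5
reads, a wrong consensus base needs three coincident errors at one column).
Errors are substitution-only — the matching semantics downstream are
substitution-oriented and indels are a non-goal — and follow a linear
positional ramp: the substitution probability rises from 0 at the first
sequencing cycle through the advertised midpoint rate ε at the middle cycle
to 2ε at the last, so the per-read mean equals ε. This is the one profile
consistent with both "increasing from zero" and a stated rate "in the
center of the reads". Quality strings decay linearly from Phred 40 to 30,
which also gives pair assembly a sensible tie-break: in the mate overlap the
later (noisier) cycles of one read meet the earlier (cleaner) cycles of the
other.

UMI collisions are not prevented; with 12-mer UMIs and desk-scale molecule
counts a couple of collisions per repertoire occur naturally, and the
cluster-set step is expected to resolve the dissimilar ones.

## The processing chain

Preprocessing mirrors the consensus-then-assemble flow of pRESTO-style
pipelines: mean-Phred ≥ 20 read-pair filter; UMI extraction (and optional
primer masking); single-linkage sub-clustering of each UMI group at 80%
identity to split UMI collisions between dissimilar source molecules;
column-wise consensus per mate (modal base emitted when its frequency is
≥ 0.6 — inclusive, since only columns *under* the threshold lack consensus —
and the mean column quality is ≥ 0, ties to N); best-overlap ungapped pair
assembly with quality-weighted conflict resolution; duplicate collapsing
with N treated as a wildcard (the merged sequence takes the called base);
and the minimum-copy filter (≥ 2). For UMI libraries the copy criterion is
the total read count behind a consensus (`consensus_count`); filtering on
collapsed duplicates would discard every unique molecule and cannot
reproduce the near-perfect zero-error recovery that deep UMI libraries
show. For sans-UMI libraries it is the collapsed duplicate count, which is
exactly why sensitivity collapses at 1% error: few error-free read pairs
recur identically.

Annotation scores each germline segment against the assembled sequence by
ungapped semi-global placement (match +1, mismatch −1, N scores 0), scanning
a ±10 offset window around the expected position (V at the 5' end, J at the
3' end — the amplicon model; `window = NULL` scans everything). D is scored
inside the V–J gap and reported as "None" when the gap is under 5 nt.
Equal-scoring calls are stored comma-separated and downstream grouping uses
the first call. Alignment QC drops records with a mismatched locus, fewer
than 200 informative positions (aligned non-N positions over the V, D and J
spans — a declared, desk-scale stand-in for an alignment-length
definition), more than 10% N, or non-productive transcripts, recording the
first failing reason in that fixed order. Chimera flagging (≥ 6 mismatches
to germline in any 10-position window) and cross-sample contamination
screening (> 5% identical sequences shared between cross-subject samples;
identical sequence + cell barcode for single-cell data) are provided but
off the benchmark path, as are the single-cell cell filters (multi-heavy,
light-only).

## Clonal inference

Records are partitioned by allele-stripped V gene, J gene and junction
length; within each partition clones are the connected components of the
graph linking junctions at length-normalized Hamming distance ≤ t
(inclusive — at junction length 15 a 0.2 threshold admits exactly 3
amino-acid edits), which is exactly single-linkage clustering at cutoff t
without materializing a dendrogram. T-cell data force t = 0. The threshold
is estimated from the distance-to-nearest distribution: Gaussian KDE with
Silverman's rule-of-thumb bandwidth (`stats::density`, `bw = "nrd0"`) on a
0.001 grid over [0, 1]; the threshold is the density minimum between the
two highest local maxima. The estimate is declared non-converged when there
are fewer than 50 distances, fewer than two maxima after discarding
numerical-noise bumps below 0.1% of the peak density, or when the valley
exceeds 90% of the lower peak (a sampling wiggle, not bimodality). Paired
single-cell data can further split clones by light-chain V/J/junction
length, with light-less cells following the majority sub-clone.

Clonal abundance uses bootstrap resampling: each of `n_boot = 200`
replicates draws `sample_size` sequences with replacement weighted by copy
number (`duplicate_count`), and the rank-abundance curve reports the mean,
minimum and maximum relative abundance per rank.

## Benchmarking and what it shows

`run_benchmark()` simulates one truth repertoire per configuration (shared
across all error levels and protocols, so curves are comparable), runs the
full chain per cell, and scores recovered full V(D)J sequences against the
deduplicated truth set: exact string matches, N-tolerant matches (N
wildcards), incorrect (neither), and missing truth sequences. The package's
acceptance checks run this at desk scale — three repertoires of ~2,000
expanded clones plus 2,000 singletons, ~5,000–8,000 molecules and
45,000–65,000 read pairs each, sizes chosen to keep a full grid in minutes
on one CPU — and verify: ≥ 99% exact recovery at zero error and ≥ 97%
exact / ≥ 98% N-tolerant across midpoint error rates up to 1% with UMIs;
collapse below 50% without UMIs at 1% error; clone-count recovery within
the benchmark bounds; and truth rank-abundance inside the bootstrap
envelope.

The simulator emulates clonal structure, SHM along lineages, UMI-tagged
paired reads and a positional error ramp. It does not emulate indels,
quality miscalibration, primer/adapter artifacts, amplification bias beyond
the reads-per-molecule distribution, chimera formation, or allele-level
germline variation — so passing benchmarks demonstrate the correctness and
error-correction behavior of the chain under its stated error model, not
performance on any particular instrument's failure modes.

## Convergent antibody clustering

`cluster_convergent()` partitions junction amino-acid sequences by V gene, J
gene and junction length (partitioning on all three is slightly stricter
than thresholding per V gene alone; the stricter variant was chosen for
symmetry with clonal inference) and single-links them at normalized AA
Hamming ≤ 0.2. Filters keep clusters spanning at least two subjects with no
control-status member; ranking is by distinct case subjects, then size,
then identifier. Hamming distances are used inside clusters because
partitions fix the length; unit-cost Levenshtein (`junction_edit_distance()`,
via `utils::adist`) serves for cross-length comparison to reference
antibodies. Sequence logos report per-position information content
`R_p = max(0, log2(20) − (H_p + e_n))` with the small-sample correction
`e_n = 19 / (2 ln 2 · n)`; the correction is what makes a position uniform
over six residues among six sequences carry exactly 0 bits, and values are
clamped at zero.

Because the real public-repository case study requires external data, the
packaged validation is a planted-recovery experiment: a convergent group
spread over several case subjects, surrounded by distant background
junctions attributable to single subjects or controls, must be recovered
exactly — and alone — by cluster + filter + rank.

## Numerical and engineering notes

* Hot inner loops (consensus columns, overlap scoring, placement scanning,
  Hamming matrices, error injection, translation lookup) are in C++ via
  Rcpp; the genetic-code table itself comes from `Biostrings::GENETIC_CODE`.
* Threshold comparisons in single-linkage clustering add a 1e-9 epsilon so
  inclusive boundaries (e.g. 3/15 = 0.2) are immune to floating-point
  representation of thresholds like `1 - 0.8`; normalized distances are
  quantized at 1/length, far above the epsilon.
* All randomness flows through R's RNG (including the C++ error injection),
  so a seed makes repertoires, reads and bootstrap curves byte-reproducible;
  seeded constructors save and restore the caller's RNG state.
* Consensus groups with ragged read lengths are truncated to the common
  minimum length; modal-base ties are called N; a column at exactly the
  frequency threshold passes.
* Duplicate collapsing processes records in descending count order and
  merges each N-containing sequence into its first wildcard match, making
  the (non-transitive) N-merge deterministic.
* Clone labels are the sanitized partition key plus a component index
  ordered by smallest member `sequence_id`, so labels are unique across
  partitions and stable across runs.

## Known limitations

The simplified aligner assumes amplicon-style sequences (V near the 5' end,
J at the 3' end) unless the full offset scan is enabled, does not model
indels or IMGT gap numbering, and calls D segments only inside the V–J gap
computed from full-segment placements, which can clip short D matches.
Threshold estimation implements the density method only. The empirical
clone-size fixture is synthetic, labelled as such, and stands in for a
donor-derived table. TCR repertoire simulation is out of scope (clonal
inference handles TCR rules on user-supplied data).
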