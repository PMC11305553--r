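# airrforge

Adaptive immune receptor repertoire (AIRR) sequencing reads out the B-cell
and T-cell receptor diversity of a sample, but between the sequencer and any
biological statement stand several error-prone steps: correcting sequencing
errors (ideally with unique molecular identifiers, UMIs), assembling read
pairs, assigning V(D)J germline segments, filtering questionable alignments,
and grouping sequences into clones — the descendants of single ancestral
rearrangements. airrforge is an R toolkit for people who build or validate
such pipelines: it simulates ground-truth BCR repertoires and Illumina-like
reads, re-implements the bulk processing chain, scores the chain against the
simulated truth, and detects convergent antibody clusters across subjects.

## What it computes

* **Simulation.** Naive rearrangements are trimmed-and-joined V/D/J segments
  with untemplated N-regions, junctions anchored at the conserved Cys (V)
  and Trp/Phe (J) codons. Clones grow on random bifurcating lineage trees
  with per-site, per-edge somatic hypermutation. Reads follow a linear
  positional error ramp: substitution probability `2ε·(p−1)/(L−1)` at cycle
  `p`, i.e. 0 at the first cycle, ε at the midpoint, 2ε at the last.
* **UMI consensus.** Within each UMI group (after single-linkage splitting
  of UMI collisions at 80% identity), the consensus base at a column is the
  modal base if its frequency is ≥ 0.6 and mean quality ≥ 0, else N.
  Assembled consensus sequences are collapsed with N as a wildcard and
  filtered at ≥ 2 supporting reads.
* **Clonal inference.** Sequences are partitioned by V gene, J gene and
  junction length; clones are single-linkage clusters of junctions at
  length-normalized Hamming distance ≤ t (t = 0 for TCR). t is estimated as
  the density valley of the distance-to-nearest distribution (Gaussian KDE,
  Silverman bandwidth). Clonal abundance curves come from `n = 200`
  bootstrap replicates weighted by copy number.
* **Benchmarking.** Recovered full V(D)J sequences are scored against the
  deduplicated truth set: exact matches, N-tolerant matches, incorrect and
  missing sequences, plus clone-count recovery `(inferred − true)/true`.
* **Convergence.** Junction amino-acid sequences are clustered across
  subjects at normalized Hamming ≤ 0.2 within V/J/length partitions;
  clusters from a single subject or containing healthy-control sequences
  are excluded; sequence logos report small-sample-corrected information
  content `R_p = max(0, log2 20 − (H_p + 19/(2 ln 2 · n)))`.

## Worked example

```r
library(airrforge)

ref   <- build_germline_reference(n_v = 15, n_d = 6, n_j = 4, seed = 99)
cfg   <- benchmark_repertoire_config("repA", n_clones = 300,
                                     n_singletons = 300, seed = 7)
truth <- simulate_repertoire(cfg, ref)
nrow(truth)                      # 804 molecules in 600 true clones

res <- run_pipeline(truth, ref, protocol = "umi",
                    center_rate = 0.005, seed = 8)
unlist(res$match)
#>           n_truth       n_recovered           n_exact      n_n_tolerant
#>               795               795               789               795
#>       n_incorrect         n_missing sensitivity_exact     sensitivity_n
#>                 0                 0         0.9924528         1.0000000
round(res$threshold_used, 3)     # 0.11  (estimated clonal distance threshold)
c(res$inferred_clones, res$true_clones)   # 599 600
round(res$clone_count_error, 4)           # -0.0017
```

Read as: of 795 distinct truth sequences (804 molecules contain a few exact
clonal duplicates), all were recovered after UMI consensus at a 0.5%
midpoint error rate; 789 exactly and 6 with N positions where the per-UMI
reads disagreed below the 0.6 consensus threshold. The estimated clonal
threshold (0.11) separates the within-clone from the between-clone
distance-to-nearest modes, and single-linkage clustering recovers 599 of
the 600 simulated clones (−0.17%).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/airrforge.R simulate  --outdir out/sim --seed 3
Rscript inst/cli/airrforge.R preprocess --r1 out/sim/reads_R1.fastq.gz \
    --r2 out/sim/reads_R2.fastq.gz --outdir out/pp
Rscript inst/cli/airrforge.R annotate  --input out/pp/sequences.tsv \
    --reference-fasta out/sim/germline.fasta \
    --reference-anchors out/sim/germline_anchors.tsv --outdir out/ann
Rscript inst/cli/airrforge.R clonal    --input out/ann/annotated.tsv \
    --outdir out/cl --threshold auto
```

## Package layout

* `R/simulate.R`, `R/germline.R` — germline, repertoire and read simulation
* `R/preprocess.R` — quality filter, UMI consensus, assembly, collapse
* `R/annotate.R` — simplified V(D)J annotation and alignment QC
* `R/clonal.R` — partitioning, threshold estimation, clone assignment,
  bootstrap abundance
* `R/benchmark.R` — truth matching and the benchmark grid
* `R/convergence.R` — convergent clusters, edit distances, logos
* `R/io_airr.R` — AIRR TSV, FASTA/FASTQ, samplesheets, step reports
* `vignettes/airrforge-methods.Rmd` — models, parameter rationale and
  limitations
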