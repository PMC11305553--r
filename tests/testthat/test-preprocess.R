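# Read assembly chain: quality filter, UMI handling, consensus, assembly,
# collapse and copy filter.

make_pair <- function(mol, read_len = 60) {
  list(mate1 = substr(mol, 1, read_len),
       mate2 = as.character(reverse_complement(
         substr(mol, nchar(mol) - read_len + 1, nchar(mol)))),
       qual = strrep("I", read_len))
}

test_that("quality filter keeps/removes pairs by mean Phred and conserves
           counts", {
  q40 <- strrep(rawToChar(as.raw(40 + 33)), 10)
  q2 <- strrep(rawToChar(as.raw(2 + 33)), 10)
  reads <- data.frame(mate1 = strrep("A", 10), qual1 = c(q40, q2, q40),
                      mate2 = strrep("C", 10), qual2 = c(q40, q2, q2),
                      stringsAsFactors = FALSE)
  out <- filter_reads_quality(reads, 20)
  expect_equal(nrow(out$reads), 1)  # only the all-Q40 pair survives
  expect_equal(out$report$kept + out$report$removed, 3)
  expect_error(mean_phred("\x01"), "malformed")
})

test_that("UMI extraction and primer masking handle hits, mismatches and
           misses", {
  primer <- "GGTACCTT"
  rest <- strrep("ACGT", 10)
  reads <- data.frame(
    mate1 = c(paste0("AAAA", primer, rest),          # exact primer at pos 1
              paste0("CCCC", "TTTTTTTT", rest),      # no primer
              paste0("GGGG", "GGTACGTT", rest)),     # one mismatch
    qual1 = strrep("I", 4 + 8 + 40),
    stringsAsFactors = FALSE)
  out <- extract_umi_and_mask_primers(reads, umi_length = 4,
                                      primers = primer, max_mismatch = 1)
  expect_equal(out$report$primer_not_found, 1)
  expect_equal(out$reads$umi, c("AAAA", "GGGG"))
  expect_true(all(substr(out$reads$mate1, 1, 8) == strrep("N", 8)))
  expect_identical(substr(out$reads$mate1, 9, 48), c(rest, rest))
})

test_that("UMI sub-clustering separates dissimilar molecules of origin", {
  g1 <- data.frame(umi = "AAAA", mate1 = rep(strrep("ACGT", 10), 5),
                   stringsAsFactors = FALSE)
  expect_length(cluster_umi_group(g1), 1)

  set.seed(42)
  a <- strrep("A", 40)
  b <- mutate_string(a, sample(40, 16))  # 40% divergent
  g2 <- data.frame(umi = "CCCC", mate1 = c(a, a, b, b),
                   stringsAsFactors = FALSE)
  subs <- cluster_umi_group(g2, identity_threshold = 0.8)
  expect_length(subs, 2)
  expect_setequal(vapply(subs, function(s) s$mate1[1], character(1)),
                  c(a, b))
  expect_true(all(grepl("-", vapply(subs, function(s) s$umi[1],
                                    character(1)))))
  g3 <- g2[1, , drop = FALSE]
  expect_identical(cluster_umi_group(g3), list(g3))
})

test_that("UMI sub-clustering equals brute-force connected components", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(2:12, 1)
    base <- random_junctions(1, 30)
    seqs <- vapply(seq_len(n), function(i) {
      mutate_string(base, sample(30, sample(0:12, 1)))
    }, character(1))
    g <- data.frame(umi = "TTTT", mate1 = seqs, stringsAsFactors = FALSE)
    subs <- cluster_umi_group(g, identity_threshold = 0.8)
    d <- outer(seqs, seqs, Vectorize(function(x, y) oracle_hamming(x, y)))
    want <- oracle_components(d, 0.2)
    expect_equal(length(subs), max(want))
    expect_equal(sort(vapply(subs, nrow, integer(1))),
                 sort(unname(as.integer(table(want)))))
  }
})

test_that("consensus matches hand-computed column frequencies", {
  p <- consensus_params(min_freq = 0.6)
  c1 <- build_consensus(c("ACGT", "ACGT", "ACGA"), params = p)
  expect_identical(c1$sequence, "ACGT")  # final column 2/3 = 0.667 >= 0.6
  expect_equal(c1$consensus_count, 3)
  c2 <- build_consensus(c("ACGT", "ACGA"), params = p)
  expect_identical(c2$sequence, "ACGN")  # 0.5 < 0.6
  c3 <- build_consensus(rep("TTAACC", 7), params = p)
  expect_identical(c3$sequence, "TTAACC")
  expect_equal(c3$consensus_count, 7)
  # boundary: frequency exactly at min_freq passes (3/5 = 0.6)
  c4 <- build_consensus(c("A", "A", "A", "C", "G"), params = p)
  expect_identical(c4$sequence, "A")
  # a tie for the mode is always N
  c5 <- build_consensus(c("A", "C"), params = consensus_params(0.5))
  expect_identical(c5$sequence, "N")
  expect_error(build_consensus(character(0)), "empty")
})

test_that("lowering min_freq never increases the number of N columns", {
  set.seed(19)
  for (trial in 1:30) {
    k <- sample(2:9, 1)
    base <- random_junctions(1, 50)
    seqs <- vapply(seq_len(k), function(i) {
      mutate_string(base, sample(50, sample(0:10, 1)))
    }, character(1))
    n_at <- function(f) {
      s <- build_consensus(seqs, params = consensus_params(f))$sequence
      nchar(gsub("[^N]", "", s))
    }
    expect_lte(n_at(0.5), n_at(0.7))
    expect_lte(n_at(0.7), n_at(0.9))
  }
})

test_that("pair assembly round-trips molecules and resolves conflicts by
           quality", {
  set.seed(23)
  mol <- random_junctions(1, 100)
  p <- make_pair(mol, 60)  # 20 bp overlap
  asm <- assemble_pair(p$mate1, p$qual, p$mate2, p$qual, min_overlap = 10)
  expect_identical(asm$sequence, mol)
  expect_equal(asm$status, "ok")
  expect_equal(asm$overlap, 20)

  # overlap below min_overlap fails
  p2 <- make_pair(mol, 55)  # 10 bp overlap
  asm2 <- assemble_pair(p2$mate1, p2$qual, p2$mate2, p2$qual,
                        min_overlap = 15)
  expect_equal(asm2$status, "assembly_failed")

  # a disagreement in the overlap resolves toward the higher-quality base
  m1 <- p$mate1
  substr(m1, 55, 55) <- if (substr(mol, 55, 55) == "A") "C" else "A"
  q_low <- p$qual
  substr(q_low, 55, 55) <- rawToChar(as.raw(10 + 33))
  asm3 <- assemble_pair(m1, q_low, p$mate2, p$qual, min_overlap = 10)
  expect_identical(asm3$sequence, mol)  # Q40 mate2 base wins over Q10
})

test_that("duplicate collapse merges N-wildcard matches and sums counts", {
  x <- data.frame(sequence = c("ACGT", "ACGT"), stringsAsFactors = FALSE)
  out <- collapse_duplicates(x)
  expect_equal(nrow(out), 1)
  expect_equal(out$duplicate_count, 2)

  y <- data.frame(sequence = c("ACNT", "ACGT"), stringsAsFactors = FALSE)
  out2 <- collapse_duplicates(y)
  expect_equal(nrow(out2), 1)
  expect_identical(out2$sequence, "ACGT")  # non-N base wins
  expect_equal(out2$duplicate_count, 2)

  z <- data.frame(sequence = c("ACGT", "ACGA"), stringsAsFactors = FALSE)
  expect_equal(nrow(collapse_duplicates(z)), 2)

  # N-vs-N merge fills wildcards from both sides
  w <- data.frame(sequence = c("ANGT", "ACGN"), stringsAsFactors = FALSE)
  out4 <- collapse_duplicates(w)
  expect_equal(nrow(out4), 1)
  expect_identical(out4$sequence, "ACGT")
})

test_that("minimum-copy filter applies the inclusive >= 2 boundary", {
  x <- data.frame(sequence = c("A", "C", "G"),
                  duplicate_count = c(1L, 2L, 5L),
                  consensus_count = c(1L, 2L, 5L), stringsAsFactors = FALSE)
  out <- filter_min_copies(x, 2)
  expect_identical(out$sequences$sequence, c("C", "G"))
  expect_equal(out$report$removed, 1)
  expect_equal(nrow(filter_min_copies(x, 1)$sequences), 3)
})

test_that("zero-error preprocessing recovers the truth molecule set exactly
           and accounts for every read pair", {
  ref <- small_reference(11)
  truth <- simulate_repertoire(
    sim_config(n_clones = 10, clone_sizes = clone_sizes_uniform(1, 3),
               n_singletons = 15, seed = 31), ref)
  for (protocol in c("umi", "sans_umi")) {
    lib <- library_config(protocol)
    sim <- simulate_reads(truth, lib, error_model(0), seed = 32)
    pp <- preprocess_reads(sim$reads, protocol = protocol,
                           umi_length = lib$umi_length)
    expect_setequal(pp$sequences$sequence, unique(truth$sequence))
    r <- pp$report
    expect_equal(r$quality_filtered + r$primer_not_found +
                   r$assembly_failed + r$low_copy + r$kept, r$input)
  }
})
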