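# Repertoire and read simulation.

test_that("germline references satisfy anchor and uniqueness invariants", {
  ref <- build_germline_reference(5, 3, 2, seed = 1)
  s <- ref$segments
  expect_equal(nrow(s), 10)
  expect_equal(unname(table(s$kind)[c("V", "D", "J")]), c(5L, 3L, 2L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(s$name) > 0)
  expect_false(any(grepl("[^ACGT]", s$sequence)))
  vj <- s[s$kind != "D", ]
  anchors <- translate_nt(substr(vj$sequence, vj$anchor, vj$anchor + 2))
  expect_true(all(anchors[vj$kind == "V"] == "C"))
  expect_true(all(anchors[vj$kind == "J"] %in% c("W", "F")))
  # deterministic for a fixed seed, and does not disturb the caller's RNG
  set.seed(123)
  before <- runif(1)
  ref2 <- build_germline_reference(5, 3, 2, seed = 1)
  expect_identical(ref, ref2)
  set.seed(123)
  expect_identical(before, runif(1))
  expect_error(build_germline_reference(0, 1, 1, seed = 1), ">= 1")
})

test_that("recombination respects anchors and the degenerate no-trim limit", {
  ref <- build_germline_reference(1, 1, 1, seed = 7,
                                  d_length_range = c(12L, 12L))
  set.seed(1)
  rec <- recombine(ref, trim_max = 0, insert_max = 0)
  s <- ref$segments
  expect_identical(rec$sequence,
                   paste0(s$sequence[s$kind == "V"],
                          s$sequence[s$kind == "D"],
                          s$sequence[s$kind == "J"]))
  expect_true(substr(rec$junction, 1, 3) %in% c("TGT", "TGC"))

  # anchors hold for arbitrary draws; junction is a substring of the sequence
  ref2 <- build_germline_reference(4, 2, 2, seed = 3)
  set.seed(5)
  for (i in 1:25) {
    r <- recombine(ref2)
    expect_identical(substr(r$junction_aa, 1, 1), "C")
    expect_true(substr(r$junction_aa, nchar(r$junction_aa),
                       nchar(r$junction_aa)) %in% c("W", "F"))
    expect_true(grepl(r$junction, r$sequence, fixed = TRUE))
    expect_equal(nchar(r$junction) %% 3, 0)
  }
})

test_that("junction lengths vary when N-insertions are allowed", {
  ref <- small_reference(2)
  set.seed(9)
  lens <- replicate(200, nchar(recombine(ref, insert_max = 8)$junction))
  expect_gt(length(unique(lens)), 1)
})

test_that("clone expansion: identity, zero-rate and member invariants", {
  ref <- small_reference(4)
  set.seed(2)
  naive <- recombine(ref)
  one <- simulate_clone(naive, 1, shm_rate = 0)
  expect_identical(one$sequence, naive$sequence)
  five <- simulate_clone(naive, 5, shm_rate = 0)
  expect_equal(nrow(five), 5)
  expect_true(all(five$sequence == naive$sequence))
  shm <- simulate_clone(naive, 20, shm_rate = 0.01)
  expect_true(all(shm$v_call == naive$v_call))
  expect_true(all(shm$j_call == naive$j_call))
  expect_true(all(nchar(shm$junction) == nchar(naive$junction)))
})

test_that("accumulated SHM matches the binomial edge expectation", {
  ref <- small_reference(6)
  set.seed(31)
  rate <- 0.01
  tot_mut <- 0
  tot_expected <- 0
  for (i in 1:100) {
    naive <- recombine(ref)
    L <- nchar(naive$sequence)
    cl <- simulate_clone(naive, 8, shm_rate = rate, keep_productive = FALSE)
    tot_mut <- tot_mut + sum(attr(cl, "leaf_mutations"))
    tot_expected <- tot_expected + sum(attr(cl, "leaf_depth")) * L * rate
  }
  # sum of binomials: SE ~ sqrt(expected) (rate is small)
  expect_lt(abs(tot_mut - tot_expected), 3 * sqrt(tot_expected))
  expect_gt(tot_mut, 0)
})

test_that("repertoire simulation: clone counts, singletons, determinism", {
  ref <- small_reference(1)
  cfg <- sim_config(n_clones = 100, clone_sizes = clone_sizes_power_law(2.5),
                    n_singletons = 5000, seed = 21)
  rep1 <- simulate_repertoire(cfg, ref)
  expect_equal(length(unique(rep1$clone_id)), 5100)
  expect_equal(sum(rep1$is_singleton), 5000)
  # clone-size conservation: clone sizes sum to the record count
  expect_equal(sum(table(rep1$clone_id)), nrow(rep1))
  rep2 <- simulate_repertoire(cfg, ref)
  expect_identical(rep1, rep2)

  only_singles <- simulate_repertoire(
    sim_config(n_clones = 0, n_singletons = 10, seed = 2), ref)
  expect_equal(nrow(only_singles), 10)
  expect_true(all(only_singles$is_singleton))

  degenerate <- simulate_repertoire(
    sim_config(n_clones = 3, clone_sizes = clone_sizes_uniform(10, 10),
               n_singletons = 0, seed = 3), ref)
  expect_equal(nrow(degenerate), 30)
  expect_equal(unname(table(degenerate$clone_id)), rep(10L, 3),
               ignore_attr = TRUE)

  expect_error(clone_sizes_empirical(data.frame()), "non-empty")
})

test_that("positional error rate ramps linearly with mean equal to the
           midpoint rate", {
  m <- error_model(0.01)
  expect_equal(positional_error_rate(1, 101, m), 0)
  expect_equal(positional_error_rate(51, 101, m), 0.01)
  expect_equal(positional_error_rate(101, 101, m), 0.02)
  m2 <- error_model(0.0025)
  expect_equal(mean(positional_error_rate(1:160, 160, m2)), 0.0025,
               tolerance = 1e-12)
  expect_error(positional_error_rate(0, 10, m), "out of range")
  expect_error(error_model(0.6), ">=|<")
})

test_that("zero-error reads reconstruct their truth molecules exactly", {
  ref <- small_reference(3)
  truth <- simulate_repertoire(
    sim_config(n_clones = 5, clone_sizes = clone_sizes_uniform(1, 2),
               n_singletons = 5, seed = 8), ref)
  truth <- truth[1:10, ]
  lib <- library_config("umi", reads_min = 3, reads_lambda = 0)
  sim <- simulate_reads(truth, lib, error_model(0), seed = 4)
  expect_equal(nrow(sim$reads), 30)
  expect_lte(length(unique(sim$reads$umi)), 10)
  mol <- truth$sequence[match(sim$reads$truth_id, truth$truth_id)]
  insert1 <- substr(sim$reads$mate1, lib$umi_length + 1, lib$read_length)
  expect_true(all(insert1 == substr(mol, 1, lib$read_length - lib$umi_length)))
  m2 <- reverse_complement(sim$reads$mate2)
  expect_true(all(m2 == substr(mol, nchar(mol) - lib$read_length + 1,
                               nchar(mol))))
  expect_true(all(nchar(sim$reads$qual1) == nchar(sim$reads$mate1)))
  # determinism: same seed, byte-identical output
  sim2 <- simulate_reads(truth, lib, error_model(0), seed = 4)
  expect_identical(sim$reads, sim2$reads)
  expect_error(simulate_reads(truth[0, ], lib, error_model(0)), "empty")
})

test_that("observed substitution rate matches the linear ramp", {
  ref <- small_reference(5)
  truth <- simulate_repertoire(
    sim_config(n_clones = 0, n_singletons = 400, seed = 13), ref)
  lib <- library_config("sans_umi", reads_min = 2, reads_lambda = 0)
  eps <- 0.01
  sim <- simulate_reads(truth, lib, error_model(eps), seed = 14)
  L <- lib$read_length
  mol <- truth$sequence[match(sim$reads$truth_id, truth$truth_id)]
  clean <- substr(mol, 1, L)
  obs <- matrix(unlist(strsplit(sim$reads$mate1, "")), ncol = L,
                byrow = TRUE) !=
    matrix(unlist(strsplit(clean, "")), ncol = L, byrow = TRUE)
  n_bases <- length(obs)
  expect_gte(n_bases, 1e5)
  # overall rate within 3 binomial standard errors of eps
  p <- mean(obs)
  expect_lt(abs(p - eps), 3 * sqrt(eps * (1 - eps) / n_bases))
  # per-position frequency regresses onto the ramp with slope within 10%
  freq <- colMeans(obs)
  fit <- stats::lm(freq ~ seq_len(L))
  slope <- unname(coef(fit)[2])
  expect_lt(abs(slope - 2 * eps / (L - 1)) / (2 * eps / (L - 1)), 0.10)
})
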