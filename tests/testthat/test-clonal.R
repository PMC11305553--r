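# Clonal inference: distances, partitioning, threshold estimation, clustering
# and abundance.

test_that("normalized Hamming distance handles wildcards and errors", {
  expect_equal(normalized_hamming("AAAA", "AAAT"), 0.25)
  expect_equal(normalized_hamming("ACGTACGT", "ACGTACGT"), 0)
  expect_equal(normalized_hamming("ACNT", "ACGA"), 0.25)  # N matches G
  expect_equal(normalized_hamming("CARDX", "CARDY", wildcard = "X"), 0)
  expect_error(normalized_hamming("AA", "AAA"), "equal")
  # oracle cross-check on random pairs
  set.seed(71)
  for (i in 1:30) {
    a <- random_junctions(1, 20)
    b <- mutate_string(a, sample(20, sample(0:20, 1)))
    expect_equal(normalized_hamming(a, b), oracle_hamming(a, b))
  }
})

test_that("partitioning groups by allele-stripped gene and junction length", {
  recs <- data.frame(
    sequence_id = paste0("s", 1:4),
    v_call = c("IGHV1-S3*01", "IGHV1-S3*02", "IGHV1-S3*01", "IGHV2-S4*01"),
    j_call = "IGHJ1*01",
    junction = c(strrep("A", 45), strrep("C", 45), strrep("G", 48),
                 strrep("T", 45)),
    stringsAsFactors = FALSE)
  parts <- partition_records(recs)
  expect_length(parts, 3)
  sizes <- sort(vapply(parts, nrow, integer(1)))
  expect_equal(unname(sizes), c(1L, 1L, 2L))  # alleles *01/*02 share a group

  recs$light_v_call <- c("IGKV1-S1*01", "IGKV2-S2*01", "IGKV1-S1*01",
                         "IGKV1-S1*01")
  recs$light_j_call <- "IGKJ1*01"
  recs$light_junction <- strrep("A", 33)
  parts2 <- partition_records(recs, use_light = TRUE)
  expect_length(parts2, 4)  # same heavy key, different light V separates
})

test_that("distance-to-nearest matches the brute-force pairwise minimum", {
  two <- data.frame(sequence_id = c("a", "b"), v_call = "IGHV1-S1*01",
                    j_call = "IGHJ1*01", junction = strrep("A", 10),
                    stringsAsFactors = FALSE)
  expect_equal(distance_to_nearest(two), c(0, 0))

  singles <- data.frame(sequence_id = c("a", "b"), v_call = "IGHV1-S1*01",
                        j_call = "IGHJ1*01",
                        junction = c(strrep("A", 9), strrep("A", 12)),
                        stringsAsFactors = FALSE)
  expect_length(distance_to_nearest(singles), 0)

  # pairwise distances {0.1, 0.2, 0.3} -> nearest {0.1, 0.1, 0.2}
  a <- strrep("A", 10)
  b <- "CAAAAAAAAA"                       # d(a,b) = 0.1
  cc <- "ATTAAAAAAA"                      # d(a,c) = 0.2, d(b,c) = 0.3
  three <- data.frame(sequence_id = c("a", "b", "c"), v_call = "IGHV1*01",
                      j_call = "IGHJ1*01", junction = c(a, b, cc),
                      stringsAsFactors = FALSE)
  expect_equal(sort(distance_to_nearest(three)), c(0.1, 0.1, 0.2))

  set.seed(72)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    js <- vapply(seq_len(n), function(k) {
      mutate_string(strrep("A", 12), sample(12, sample(0:12, 1)))
    }, character(1))
    recs <- data.frame(sequence_id = paste0("s", seq_len(n)),
                       v_call = "V*01", j_call = "J*01", junction = js,
                       stringsAsFactors = FALSE)
    d <- outer(js, js, Vectorize(oracle_hamming))
    diag(d) <- NA
    expect_equal(sort(distance_to_nearest(recs)),
                 sort(apply(d, 1, min, na.rm = TRUE)))
  }
})

test_that("threshold estimation finds the valley of a bimodal mixture", {
  set.seed(11)
  d <- pmin(pmax(c(rnorm(1000, 0.02, 0.01), rnorm(1000, 0.30, 0.05)), 0), 1)
  est <- estimate_threshold(d)
  expect_true(est$converged)
  expect_gt(est$threshold, 0.05)
  expect_lt(est$threshold, 0.25)
  est2 <- estimate_threshold(d)
  expect_identical(est$threshold, est2$threshold)

  set.seed(12)
  uni <- pmin(pmax(rnorm(500, 0.2, 0.03), 0), 1)
  expect_false(estimate_threshold(uni)$converged)
  expect_false(estimate_threshold(runif(10))$converged)  # too few
})

test_that("clone assignment follows single linkage and the TCR zero rule", {
  mk <- function(juncs) {
    data.frame(sequence_id = sprintf("s%02d", seq_along(juncs)),
               v_call = "TRBV1*01", j_call = "TRBJ1*01", junction = juncs,
               stringsAsFactors = FALSE)
  }
  tcr <- assign_clones(mk(c(strrep("A", 9), strrep("A", 9), strrep("C", 9))),
                       threshold = 0.5, cell_type = "T")
  expect_equal(length(unique(tcr$clone_id)), 2)  # identical-only for TCR

  a <- strrep("A", 10)
  b <- mutate_string(a, 1)                        # d(a,b) = 0.1
  cc <- mutate_string(b, 2)                       # d(b,c) = 0.1, d(a,c) = 0.2
  chain <- assign_clones(mk(c(a, b, cc)), threshold = 0.1)
  expect_equal(length(unique(chain$clone_id)), 1)  # single linkage chains

  sat <- assign_clones(mk(random_junctions(8, 12)), threshold = 1)
  expect_equal(length(unique(sat$clone_id)), 1)
})

test_that("clone assignment equals the brute-force connected components", {
  set.seed(73)
  for (trial in 1:200) {
    n <- sample(2:30, 1)
    js <- vapply(seq_len(n), function(k) {
      mutate_string(strrep("G", 15), sample(15, sample(0:6, 1)))
    }, character(1))
    thr <- sample(c(0.1, 0.15, 0.2, 0.3), 1)
    recs <- data.frame(sequence_id = sprintf("s%02d", seq_len(n)),
                       v_call = "IGHV1*01", j_call = "IGHJ1*01",
                       junction = js, stringsAsFactors = FALSE)
    got <- assign_clones(recs, thr)
    got <- got[match(recs$sequence_id, got$sequence_id), ]
    d <- outer(js, js, Vectorize(oracle_hamming))
    want <- oracle_components(d, thr)
    expect_identical(canon_labels(got$clone_id), canon_labels(want))
  }
})

test_that("raising the threshold never increases the clone count", {
  set.seed(74)
  js <- vapply(1:60, function(k) {
    mutate_string(strrep("T", 18), sample(18, sample(0:9, 1)))
  }, character(1))
  recs <- data.frame(sequence_id = sprintf("s%02d", 1:60),
                     v_call = "IGHV1*01", j_call = "IGHJ1*01", junction = js,
                     stringsAsFactors = FALSE)
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4, 1), function(t) {
    length(unique(assign_clones(recs, t)$clone_id))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("light-chain refinement splits clones and applies the majority
           rule", {
  recs <- data.frame(
    sequence_id = paste0("s", 1:5), cell_id = paste0("c", 1:5),
    clone_id = "CL1",
    light_v_call = c("IGKV1-S1*01", "IGKV1-S1*01", "IGKV1-S1*01",
                     "IGKV2-S2*01", NA),
    light_j_call = c("IGKJ1*01", "IGKJ1*01", "IGKJ1*01", "IGKJ1*01", NA),
    light_junction = c(rep(strrep("A", 33), 4), NA),
    stringsAsFactors = FALSE)
  out <- refine_by_light_chain(recs)
  expect_equal(length(unique(out$clone_id)), 2)
  # the light-less cell joins the 3-member majority sub-clone
  expect_identical(out$clone_id[5], out$clone_id[1])

  same <- recs[1:3, ]
  out2 <- refine_by_light_chain(same)
  expect_equal(length(unique(out2$clone_id)), 1)
})

test_that("bootstrap abundance curves behave like the sampling model", {
  single <- data.frame(clone_id = rep("CL1", 5), duplicate_count = 1L)
  ab <- clonal_abundance(single, n_boot = 20, seed = 1)
  expect_true(all(ab$mean[1] == 1))

  two <- data.frame(clone_id = c("big", "small"),
                    duplicate_count = c(90L, 10L))
  ab2 <- clonal_abundance(two, n_boot = 200, sample_size = 1000, seed = 2)
  expect_gt(ab2$mean[1], 0.88)
  expect_lt(ab2$mean[1], 0.92)
  # abundances sum to one and are non-increasing in rank
  expect_equal(sum(ab2$mean), 1, tolerance = 1e-9)
  expect_true(all(diff(ab2$mean) <= 0))

  ab3 <- clonal_abundance(two, n_boot = 1, sample_size = 50, seed = 9)
  ab4 <- clonal_abundance(two, n_boot = 1, sample_size = 50, seed = 9)
  expect_identical(ab3$mean, ab4$mean)
  expect_error(clonal_abundance(two[0, ]), "empty")
})
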