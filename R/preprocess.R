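# Bulk-read assembly chain: quality filtering, UMI extraction and sub-
# clustering, per-UMI consensus, pair assembly, duplicate collapsing and the
# minimum-copy filter. The chain mirrors the standard UMI-consensus error
# correction flow for bulk AIRR-seq libraries: consensus is built per mate
# within each UMI group first, then the consensus mates are assembled.

#' Consensus parameters
#'
#' @param min_freq minimum column frequency for the modal base; a column at
#'   exactly `min_freq` passes (inclusive threshold). Default 0.6.
#' @param min_qual minimum mean column Phred quality. Default 0.
#' @return an object of class `consensus_params`.
#' @export
consensus_params <- function(min_freq = 0.6, min_qual = 0) {
  stopifnot(min_freq > 0, min_freq <= 1, min_qual >= 0)
  structure(list(min_freq = min_freq, min_qual = min_qual),
            class = "consensus_params")
}

#' Filter read pairs on mean Phred quality
#'
#' Keeps pairs where both mates have mean Phred >= `min_mean_phred`.
#'
#' @param reads data.frame with columns mate1, qual1, mate2, qual2.
#' @param min_mean_phred quality threshold (default 20).
#' @return list with `reads` (kept rows) and `report` (kept/removed counts).
#' @export
filter_reads_quality <- function(reads, min_mean_phred = 20) {
  ok <- cpp_mean_phred(reads$qual1) >= min_mean_phred &
    cpp_mean_phred(reads$qual2) >= min_mean_phred
  list(reads = reads[ok, , drop = FALSE],
       report = list(kept = sum(ok), removed = sum(!ok)))
}

# Best primer placement within the first `window` bases; returns list(primer
# index, start, mismatches) or NULL when nothing is within max_mismatch.
locate_primer <- function(seq, primers, max_mismatch, window) {
  best <- NULL
  for (k in seq_along(primers)) {
    p <- primers[k]
    lp <- nchar(p)
    hit <- cpp_best_placement(substr(seq, 1L, window + lp - 1L), p,
                              0L, max(0L, window - 1L))
    if (is.na(hit[1])) next
    mism <- hit[3] - hit[4]
    if (mism <= max_mismatch && (is.null(best) || mism < best$mismatches)) {
      best <- list(primer = k, start = hit[2] + 1L, mismatches = mism,
                   length = lp)
    }
  }
  best
}

#' Extract UMIs and mask primers
#'
#' The UMI is read off the first `umi_length` bases of mate 1 and removed from
#' the sequence (and quality). When primers are given, the best-matching
#' primer within the first `window` bases of the trimmed mate 1 is located and
#' either masked with N or cut off; reads without a primer hit within
#' `max_mismatch` are dropped with reason `primer_not_found`.
#'
#' @param reads data.frame with columns mate1, qual1 (and any others).
#' @param umi_length number of UMI bases at the 5' end of mate 1 (0 for
#'   sans-UMI libraries).
#' @param primers optional character vector of primer sequences.
#' @param max_mismatch maximum primer mismatches.
#' @param window search window (primer start offset) in bases.
#' @param mode `"mask"` replaces the primer match with N; `"cut"` removes
#'   everything through the primer end.
#' @return list with `reads` (kept rows, `umi` column filled, mate1 trimmed)
#'   and `report` (kept/primer_not_found counts).
#' @export
extract_umi_and_mask_primers <- function(reads, umi_length, primers = NULL,
                                         max_mismatch = 1L, window = 30L,
                                         mode = c("mask", "cut")) {
  mode <- match.arg(mode)
  if (umi_length > 0) {
    if (any(nchar(reads$mate1) <= umi_length)) {
      stop("mate1 shorter than umi_length")
    }
    reads$umi <- substr(reads$mate1, 1L, umi_length)
    reads$mate1 <- substr(reads$mate1, umi_length + 1L, nchar(reads$mate1))
    reads$qual1 <- substr(reads$qual1, umi_length + 1L, nchar(reads$qual1))
  }
  dropped <- 0L
  if (!is.null(primers) && length(primers) > 0 && nrow(reads) > 0) {
    keep <- logical(nrow(reads))
    for (i in seq_len(nrow(reads))) {
      hit <- locate_primer(reads$mate1[i], primers, max_mismatch, window)
      if (is.null(hit)) next
      keep[i] <- TRUE
      if (mode == "mask") {
        substr(reads$mate1[i], hit$start, hit$start + hit$length - 1L) <-
          strrep("N", hit$length)
      } else {
        cut_at <- hit$start + hit$length
        reads$mate1[i] <- substr(reads$mate1[i], cut_at,
                                 nchar(reads$mate1[i]))
        reads$qual1[i] <- substr(reads$qual1[i], cut_at,
                                 nchar(reads$qual1[i]))
      }
    }
    dropped <- sum(!keep)
    reads <- reads[keep, , drop = FALSE]
  }
  list(reads = reads,
       report = list(kept = nrow(reads), primer_not_found = dropped))
}

# Connected components of the graph with edges where dist <= threshold.
# A 1e-9 epsilon keeps inclusive boundaries (e.g. 3 mismatches over length 15
# at threshold 0.2) immune to floating-point representation of the threshold;
# normalized distances are quantized at 1/length, far above the epsilon.
single_linkage_components <- function(distmat, threshold) {
  threshold <- threshold + 1e-9
  n <- nrow(distmat)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (distmat[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Split a UMI group into sub-clusters of similar sequences
#'
#' Single-linkage clustering of the group members at normalized Hamming
#' distance <= 1 - `identity_threshold`, computed over the aligned prefix of
#' common length of the concatenated mates. Groups whose members stem from
#' dissimilar molecules (UMI collisions) are thereby separated; each
#' sub-cluster gets the parent UMI with a numeric suffix.
#'
#' @param group data.frame of reads sharing one UMI (columns umi, mate1 and
#'   optionally mate2).
#' @param identity_threshold minimum within-cluster identity (default 0.8).
#' @return list of data.frames, one per sub-cluster.
#' @export
cluster_umi_group <- function(group, identity_threshold = 0.8) {
  if (nrow(group) == 0) stop("empty UMI group")
  if (nrow(group) == 1) return(list(group))
  key <- if (!is.null(group$mate2)) {
    paste0(group$mate1, group$mate2)
  } else {
    group$mate1
  }
  key <- substr(key, 1L, min(nchar(key)))
  comp <- single_linkage_components(cpp_pairwise_norm_hamming(key, "N"),
                                    1 - identity_threshold)
  if (max(comp) == 1L) return(list(group))
  lapply(seq_len(max(comp)), function(k) {
    sub <- group[comp == k, , drop = FALSE]
    sub$umi <- paste0(sub$umi, "-", k)
    sub
  })
}

#' Build a column-wise consensus sequence
#'
#' Members are truncated to the common minimum length. Per column the modal
#' base is emitted when its frequency over the group size is >= `min_freq`
#' and the mean column quality is >= `min_qual`; otherwise (including ties for
#' the mode) the column is N.
#'
#' @param seqs character vector of member sequences (same orientation).
#' @param quals optional Phred+33 quality strings (constant Q40 assumed when
#'   missing).
#' @param params a [consensus_params()].
#' @return list with sequence, quality and consensus_count (= group size).
#' @export
build_consensus <- function(seqs, quals = NULL, params = consensus_params()) {
  if (length(seqs) == 0) stop("empty group")
  if (is.null(quals)) {
    quals <- strrep("I", nchar(seqs))
  }
  cpp_consensus(seqs, quals, params$min_freq, params$min_qual)
}

#' Assemble a read pair by ungapped overlap
#'
#' Mate 2 is supplied in sequencing orientation and reverse-complemented
#' internally. The maximal-scoring ungapped overlap of at least `min_overlap`
#' bases with mismatch fraction <= `max_mismatch_frac` is used; disagreements
#' resolve to the higher-quality base (N always loses to a called base).
#'
#' @param mate1,qual1 forward read and quality.
#' @param mate2,qual2 reverse read (sequencing orientation) and quality.
#' @param min_overlap minimum acceptable overlap (default 10).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @return list with sequence, quality, overlap, mismatches and status
#'   (`"ok"` or `"assembly_failed"`).
#' @export
assemble_pair <- function(mate1, qual1, mate2, qual2, min_overlap = 10L,
                          max_mismatch_frac = 0.2) {
  s2 <- cpp_revcomp(mate2)
  q2 <- paste(rev(strsplit(qual2, "", fixed = TRUE)[[1]]), collapse = "")
  m <- cpp_merge_pair(mate1, qual1, s2, q2, min_overlap, max_mismatch_frac)
  m$status <- if (m$overlap == 0) "assembly_failed" else "ok"
  m
}

#' Collapse duplicate sequences with N-wildcard matching
#'
#' Sequences identical up to N wildcards are merged: N matches any base and
#' the merged sequence takes the called base where one member has N.
#' `duplicate_count` and `consensus_count` are summed over members. Records
#' are processed in descending `duplicate_count` (ties broken
#' lexicographically), and each N-containing sequence merges into the first
#' match, so the collapse is deterministic.
#'
#' @param seqs data.frame with columns sequence, duplicate_count,
#'   consensus_count (missing count columns default to 1) and optionally
#'   sequence_id, umi.
#' @return collapsed data.frame.
#' @export
collapse_duplicates <- function(seqs) {
  if (nrow(seqs) == 0) return(seqs)
  if (is.null(seqs$duplicate_count)) seqs$duplicate_count <- 1L
  if (is.null(seqs$consensus_count)) seqs$consensus_count <- 1L
  count_cols <- intersect(c("duplicate_count", "consensus_count", "n_reads"),
                          names(seqs))

  # exact collapse first
  key <- seqs$sequence
  first <- !duplicated(key)
  out <- seqs[first, , drop = FALSE]
  for (cc in count_cols) {
    agg <- rowsum(seqs[[cc]], key, reorder = FALSE)
    out[[cc]] <- agg[match(out$sequence, rownames(agg)), 1L]
  }

  has_n <- grepl("N", out$sequence, fixed = TRUE)
  if (!any(has_n)) return(out)

  ord <- order(-out$duplicate_count, out$sequence)
  out <- out[ord, , drop = FALSE]
  has_n <- has_n[ord]

  clean <- out[!has_n, , drop = FALSE]
  ncase <- out[has_n, , drop = FALSE]
  merged_n <- logical(nrow(ncase))

  if (nrow(clean) > 0 && nrow(ncase) > 0) {
    hit <- cpp_wildcard_match(ncase$sequence, clean$sequence, "N")
    for (i in which(hit > 0)) {
      j <- hit[i]
      for (cc in count_cols) {
        clean[[cc]][j] <- clean[[cc]][j] + ncase[[cc]][i]
      }
      merged_n[i] <- TRUE
    }
  }

  # remaining N-containing records: greedy merge among themselves
  rest <- ncase[!merged_n, , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(rest))) {
    placed <- FALSE
    for (k in seq_along(kept)) {
      if (nchar(kept[[k]]$sequence) == nchar(rest$sequence[i]) &&
          cpp_wildcard_equal(kept[[k]]$sequence, rest$sequence[i], "N")) {
        a <- strsplit(kept[[k]]$sequence, "", fixed = TRUE)[[1]]
        b <- strsplit(rest$sequence[i], "", fixed = TRUE)[[1]]
        a[a == "N"] <- b[a == "N"]
        kept[[k]]$sequence <- paste(a, collapse = "")
        for (cc in count_cols) {
          kept[[k]][[cc]] <- kept[[k]][[cc]] + rest[[cc]][i]
        }
        placed <- TRUE
        break
      }
    }
    if (!placed) kept[[length(kept) + 1L]] <- rest[i, , drop = FALSE]
  }
  res <- rbind(clean, if (length(kept)) do.call(rbind, kept))
  rownames(res) <- NULL
  res
}

#' Filter sequences with insufficient copy support
#'
#' Drops records whose support count is below `min_copies` (default 2). For
#' sans-UMI libraries the support is the number of collapsed duplicate reads
#' (`duplicate_count`); for UMI libraries it is the total number of reads
#' behind the consensus (`consensus_count`).
#'
#' @param seqs data.frame with the chosen count column.
#' @param min_copies minimum support (default 2).
#' @param count_field `"duplicate_count"` or `"consensus_count"`.
#' @return list with `sequences` (kept rows) and `report`.
#' @export
filter_min_copies <- function(seqs, min_copies = 2L,
                              count_field = c("duplicate_count",
                                              "consensus_count")) {
  count_field <- match.arg(count_field)
  ok <- seqs[[count_field]] >= min_copies
  list(sequences = seqs[ok, , drop = FALSE],
       report = list(kept = sum(ok), removed = sum(!ok)))
}

#' Run the full preprocessing chain
#'
#' UMI protocol: quality filter, UMI extraction (and optional primer
#' masking), UMI-group sub-clustering, per-mate consensus, pair assembly,
#' duplicate collapse, minimum-copy filter on the consensus read count.
#' Sans-UMI protocol: quality filter, per-pair assembly, duplicate collapse,
#' minimum-copy filter on the duplicate count.
#'
#' @param reads data.frame from [simulate_reads()] (or equivalent with
#'   columns read_id, mate1, qual1, mate2, qual2).
#' @param protocol `"umi"` or `"sans_umi"`.
#' @param umi_length UMI length (UMI protocol).
#' @param primers optional primer set for masking.
#' @param min_mean_phred read quality threshold.
#' @param params a [consensus_params()].
#' @param identity_threshold UMI sub-clustering identity (default 0.8).
#' @param min_overlap,max_mismatch_frac assembly parameters.
#' @param min_copies minimum-copy filter threshold.
#' @return list with `sequences` (data.frame sequence_id, sequence, quality,
#'   consensus_count, duplicate_count, umi) and `report` (per-step read-pair
#'   accounting: kept, quality_filtered, primer_not_found, assembly_failed,
#'   low_copy).
#' @export
preprocess_reads <- function(reads, protocol = c("umi", "sans_umi"),
                             umi_length = 12L, primers = NULL,
                             min_mean_phred = 20,
                             params = consensus_params(),
                             identity_threshold = 0.8,
                             min_overlap = 10L, max_mismatch_frac = 0.2,
                             min_copies = 2L) {
  protocol <- match.arg(protocol)
  n_input <- nrow(reads)
  report <- list(input = n_input)

  qf <- filter_reads_quality(reads, min_mean_phred)
  reads <- qf$reads
  report$quality_filtered <- qf$report$removed

  report$primer_not_found <- 0L
  if (protocol == "umi") {
    ex <- extract_umi_and_mask_primers(reads, umi_length, primers)
    reads <- ex$reads
    report$primer_not_found <- ex$report$primer_not_found
    recs <- consensus_stage(reads, params, identity_threshold)
  } else {
    if (!is.null(primers)) {
      ex <- extract_umi_and_mask_primers(reads, 0L, primers)
      reads <- ex$reads
      report$primer_not_found <- ex$report$primer_not_found
    }
    recs <- data.frame(mate1 = reads$mate1, qual1 = reads$qual1,
                       mate2 = reads$mate2, qual2 = reads$qual2,
                       umi = NA_character_, consensus_count = 1L,
                       n_reads = 1L, stringsAsFactors = FALSE)
  }

  n <- nrow(recs)
  seqs <- character(n)
  qual <- character(n)
  ok <- logical(n)
  m2rc <- cpp_revcomp(recs$mate2)
  q2r <- vapply(strsplit(recs$qual2, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1))
  for (i in seq_len(n)) {
    m <- cpp_merge_pair(recs$mate1[i], recs$qual1[i], m2rc[i], q2r[i],
                        min_overlap, max_mismatch_frac)
    if (m$overlap > 0) {
      seqs[i] <- m$sequence
      qual[i] <- m$quality
      ok[i] <- TRUE
    }
  }
  report$assembly_failed <- sum(recs$n_reads[!ok])

  asm <- data.frame(sequence = seqs[ok], quality = qual[ok],
                    umi = recs$umi[ok],
                    consensus_count = recs$consensus_count[ok],
                    duplicate_count = 1L,
                    n_reads = recs$n_reads[ok],
                    stringsAsFactors = FALSE)
  coll <- collapse_duplicates(asm)

  count_field <- if (protocol == "umi") "consensus_count" else
    "duplicate_count"
  fc <- filter_min_copies(coll, min_copies, count_field)
  out <- fc$sequences
  report$low_copy <- sum(coll$n_reads) - sum(out$n_reads)
  report$kept <- sum(out$n_reads)

  if (nrow(out) > 0) {
    out$sequence_id <- sprintf("SEQ%06d", seq_len(nrow(out)))
  } else {
    out$sequence_id <- character(0)
  }
  out <- out[, c("sequence_id", "sequence", "quality", "consensus_count",
                 "duplicate_count", "umi", "n_reads")]
  list(sequences = out, report = report)
}

# UMI grouping + sub-clustering + per-mate consensus. Returns one row per
# sub-cluster with consensus mates; n_reads tracks read-pair accounting.
consensus_stage <- function(reads, params, identity_threshold) {
  groups <- split(seq_len(nrow(reads)), reads$umi)
  out_m1 <- character(0); out_q1 <- character(0)
  out_m2 <- character(0); out_q2 <- character(0)
  out_umi <- character(0); out_cc <- integer(0)
  res_i <- 0L
  n_groups <- length(groups)
  out_m1 <- vector("character", n_groups * 2L)
  out_q1 <- out_m1; out_m2 <- out_m1; out_q2 <- out_m1; out_umi <- out_m1
  out_cc <- integer(n_groups * 2L)

  push <- function(m1, q1, m2, q2, umi, cc) {
    res_i <<- res_i + 1L
    if (res_i > length(out_m1)) {
      grow <- function(x) c(x, vector(mode(x), length(x)))
      out_m1 <<- grow(out_m1); out_q1 <<- grow(out_q1)
      out_m2 <<- grow(out_m2); out_q2 <<- grow(out_q2)
      out_umi <<- grow(out_umi); out_cc <<- grow(out_cc)
    }
    out_m1[res_i] <<- m1; out_q1[res_i] <<- q1
    out_m2[res_i] <<- m2; out_q2[res_i] <<- q2
    out_umi[res_i] <<- umi; out_cc[res_i] <<- cc
  }

  for (g in groups) {
    sub <- reads[g, , drop = FALSE]
    subclusters <- if (nrow(sub) == 1L ||
                       (length(unique(sub$mate1)) == 1L &&
                        length(unique(sub$mate2)) == 1L)) {
      list(sub)
    } else {
      cluster_umi_group(sub, identity_threshold)
    }
    for (sc in subclusters) {
      if (nrow(sc) == 1L) {
        push(sc$mate1, sc$qual1, sc$mate2, sc$qual2, sc$umi[1], 1L)
      } else if (length(unique(sc$mate1)) == 1L &&
                 length(unique(sc$mate2)) == 1L) {
        push(sc$mate1[1], sc$qual1[1], sc$mate2[1], sc$qual2[1],
             sc$umi[1], nrow(sc))
      } else {
        c1 <- cpp_consensus(sc$mate1, sc$qual1, params$min_freq,
                            params$min_qual)
        c2 <- cpp_consensus(sc$mate2, sc$qual2, params$min_freq,
                            params$min_qual)
        push(c1$sequence, c1$quality, c2$sequence, c2$quality,
             sc$umi[1], nrow(sc))
      }
    }
  }
  idx <- seq_len(res_i)
  data.frame(mate1 = out_m1[idx], qual1 = out_q1[idx],
             mate2 = out_m2[idx], qual2 = out_q2[idx],
             umi = out_umi[idx], consensus_count = out_cc[idx],
             n_reads = out_cc[idx], stringsAsFactors = FALSE)
}
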