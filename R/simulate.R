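# Ground-truth repertoire and read simulation.
#
# The simulator produces (1) naive V(D)J rearrangements from a synthetic
# germline reference, (2) clonally expanded repertoires where somatic
# hypermutation accumulates along random bifurcating lineage trees, and
# (3) Illumina-like paired-end reads with an optional UMI and a linear
# positional substitution-error profile. Every simulated molecule keeps its
# ground-truth identity so downstream benchmarking can score the processing
# chain against a known answer.

#' Clone-size distribution constructors
#'
#' `clone_sizes_power_law()` draws sizes k with probability proportional to
#' k^-exponent on 1..max_size; `clone_sizes_uniform()` draws uniformly on
#' min..max; `clone_sizes_empirical()` resamples a size table (columns `size`
#' and `n_clones`), e.g. the packaged long-tailed donor-derived table from
#' [repc_clone_sizes()].
#'
#' @param exponent power-law exponent (> 1).
#' @param max_size largest drawable clone size for the power law.
#' @param min,max inclusive uniform range.
#' @param table data.frame with columns `size` and `n_clones`.
#' @return an object of class `clone_size_distribution`.
#' @export
clone_sizes_power_law <- function(exponent = 2.5, max_size = 500L) {
  stopifnot(exponent > 1, max_size >= 1)
  structure(list(type = "power_law", exponent = exponent,
                 max_size = as.integer(max_size)),
            class = "clone_size_distribution")
}

#' @rdname clone_sizes_power_law
#' @export
clone_sizes_uniform <- function(min, max) {
  stopifnot(min >= 1, max >= min)
  structure(list(type = "uniform", min = as.integer(min),
                 max = as.integer(max)),
            class = "clone_size_distribution")
}

#' @rdname clone_sizes_power_law
#' @export
clone_sizes_empirical <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0 ||
      !all(c("size", "n_clones") %in% names(table))) {
    stop("empirical clone-size table must be a non-empty data.frame ",
         "with columns 'size' and 'n_clones'")
  }
  structure(list(type = "empirical", table = table),
            class = "clone_size_distribution")
}

draw_clone_sizes <- function(dist, n) {
  if (n == 0L) return(integer(0))
  switch(dist$type,
    power_law = {
      k <- seq_len(dist$max_size)
      sample(k, n, replace = TRUE, prob = k^(-dist$exponent))
    },
    uniform = {
      k <- seq(dist$min, dist$max)
      k[sample.int(length(k), n, replace = TRUE)]
    },
    empirical = {
      if (length(dist$table$size) == 1L) {
        rep(as.integer(dist$table$size), n)
      } else {
        sample(as.integer(dist$table$size), n, replace = TRUE,
               prob = dist$table$n_clones)
      }
    },
    stop("unknown clone-size distribution type: ", dist$type)
  )
}

#' Packaged empirical clone-size table
#'
#' A long-tailed clone-size histogram emulating a real donor B-cell
#' repertoire: about 6,300 clones, roughly 80% of them singletons, with a
#' power-law-like tail of expanded clones. The table is synthetic (generated
#' from a fixed recipe) and ships with the package as a plain-text fixture.
#'
#' @return data.frame with columns `size` and `n_clones`.
#' @export
repc_clone_sizes <- function() {
  path <- system.file("extdata", "repc_clone_sizes.tsv", package = "airrforge")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Repertoire simulation configuration
#'
#' @param n_clones number of expanded clones.
#' @param clone_sizes a `clone_size_distribution`.
#' @param shm_rate per-site, per-lineage-edge substitution probability of
#'   somatic hypermutation.
#' @param n_singletons number of naive singleton sequences appended as
#'   unexpanded clones of size one.
#' @param trim_max maximum nucleotides trimmed from each segment end at the
#'   junction (V 3', D 5'/3', J 5').
#' @param insert_max maximum length of each untemplated N-region insertion.
#' @param seed optional integer seed making the repertoire deterministic.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_clones = 100L,
                       clone_sizes = clone_sizes_power_law(2.5),
                       shm_rate = 0.005,
                       n_singletons = 5000L,
                       trim_max = 4L,
                       insert_max = 8L,
                       seed = NULL) {
  stopifnot(n_clones >= 0, n_singletons >= 0,
            shm_rate >= 0, shm_rate <= 1,
            trim_max >= 0, trim_max <= 9, insert_max >= 0)
  structure(list(n_clones = as.integer(n_clones), clone_sizes = clone_sizes,
                 shm_rate = shm_rate, n_singletons = as.integer(n_singletons),
                 trim_max = as.integer(trim_max),
                 insert_max = as.integer(insert_max), seed = seed),
            class = "sim_config")
}

# Vectorized draw of n candidate recombinations (no productivity filtering).
recombine_batch <- function(reference, n, trim_max, insert_max) {
  vs <- segments_of(reference, "V")
  ds <- segments_of(reference, "D")
  js <- segments_of(reference, "J")
  vi <- sample.int(nrow(vs), n, replace = TRUE)
  di <- sample.int(nrow(ds), n, replace = TRUE)
  ji <- sample.int(nrow(js), n, replace = TRUE)
  tv <- sample.int(trim_max + 1L, n, replace = TRUE) - 1L
  td5 <- sample.int(trim_max + 1L, n, replace = TRUE) - 1L
  td3 <- sample.int(trim_max + 1L, n, replace = TRUE) - 1L
  tj <- sample.int(trim_max + 1L, n, replace = TRUE) - 1L
  n1l <- sample.int(insert_max + 1L, n, replace = TRUE) - 1L
  n2l <- sample.int(insert_max + 1L, n, replace = TRUE) - 1L

  make_inserts <- function(lens) {
    out <- character(length(lens))
    tot <- sum(lens)
    if (tot > 0) {
      chars <- sample(DNA_BASES, tot, replace = TRUE)
      idx <- rep.int(seq_along(lens), lens)
      nz <- lens > 0
      out[nz] <- vapply(split(chars, idx), paste, character(1), collapse = "")
    }
    out
  }
  n1 <- make_inserts(n1l)
  n2 <- make_inserts(n2l)

  v_seq <- vs$sequence[vi]
  d_seq <- ds$sequence[di]
  j_seq <- js$sequence[ji]
  v_len <- nchar(v_seq) - tv
  d_part <- substr(d_seq, 1L + td5, nchar(d_seq) - td3)
  j_part <- substr(j_seq, 1L + tj, nchar(j_seq))
  v_part <- substr(v_seq, 1L, v_len)
  sequence <- paste0(v_part, n1, d_part, n2, j_part)

  v_anchor <- vs$anchor[vi]
  j_anchor <- js$anchor[ji]
  jct_start <- v_anchor
  jct_end <- v_len + n1l + nchar(d_part) + n2l + (j_anchor - tj) + 2L
  junction <- substr(sequence, jct_start, jct_end)
  junction_aa <- translate_nt(junction)
  productive <- nchar(junction) %% 3L == 0L & !has_stop(junction_aa)

  data.frame(sequence = sequence,
             v_call = vs$name[vi], d_call = ds$name[di], j_call = js$name[ji],
             junction = junction, junction_aa = junction_aa,
             junction_start = jct_start, junction_end = jct_end,
             productive = productive,
             stringsAsFactors = FALSE)
}

#' Simulate one naive V(D)J recombination
#'
#' Draws random V, D and J segments, trims up to `trim_max` nucleotides from
#' each junction-facing segment end, inserts untemplated N-regions of up to
#' `insert_max` nucleotides, and extracts the junction from the conserved
#' anchors. Draws are resampled (up to `max_attempts`) until the
#' rearrangement is productive: in-frame junction and no stop codon.
#'
#' @param reference a `germline_reference`.
#' @param trim_max,insert_max trimming/insertion bounds (see [sim_config()]).
#' @param max_attempts resampling bound before failing.
#' @return one-row data.frame with columns sequence, v_call, d_call, j_call,
#'   junction, junction_aa, junction_start, junction_end, productive.
#' @export
recombine <- function(reference, trim_max = 4L, insert_max = 8L,
                      max_attempts = 100L) {
  for (i in seq_len(max_attempts)) {
    cand <- recombine_batch(reference, 1L, trim_max, insert_max)
    if (cand$productive) return(cand)
  }
  stop("no productive rearrangement after ", max_attempts,
       " attempts; reference/config may be incompatible")
}

# Substitute m ~ Binom(L, rate) positions of seq with random alternatives.
mutate_edge <- function(seq, rate) {
  L <- nchar(seq)
  m <- rbinom(1L, L, rate)
  if (m == 0L) return(list(seq = seq, n_mut = 0L))
  pos <- sample.int(L, m)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), n_mut = m)
}

#' Expand a naive rearrangement into a simulated clone
#'
#' Grows a random bifurcating lineage tree with `size` leaves by iterated
#' random-leaf splitting (a Yule process). Each edge accumulates independent
#' per-site substitutions at `shm_rate`; leaf sequences carry all mutations on
#' their root-to-leaf path. With `keep_productive = TRUE` (the default) each
#' edge is redrawn (up to `max_attempts`) when its mutations introduce a stop
#' codon or break the junction frame, modeling selection for functional
#' receptors during affinity maturation.
#'
#' @param naive one-row data.frame from [recombine()].
#' @param size number of clone members (leaves), >= 1.
#' @param shm_rate per-site per-edge substitution probability.
#' @param keep_productive redraw edges whose mutations make the sequence
#'   non-productive.
#' @param max_attempts per-edge redraw bound.
#' @return data.frame with `size` rows (columns as [recombine()]); attributes
#'   `leaf_depth` and `leaf_mutations` record the root-to-leaf edge count and
#'   accumulated mutation count per member.
#' @export
simulate_clone <- function(naive, size, shm_rate, keep_productive = TRUE,
                           max_attempts = 100L) {
  stopifnot(size >= 1)
  if (size == 1L) {
    out <- naive
    attr(out, "leaf_depth") <- 0L
    attr(out, "leaf_mutations") <- 0L
    return(out)
  }
  jct_start <- naive$junction_start
  jct_end <- naive$junction_end

  frame_off <- (jct_start - 1L) %% 3L
  is_ok <- function(seq) {
    if (!keep_productive) return(TRUE)
    !has_stop(translate_nt(substr(seq, frame_off + 1L, nchar(seq))))
  }
  grow_edge <- function(seq) {
    for (i in seq_len(max_attempts)) {
      m <- mutate_edge(seq, shm_rate)
      if (is_ok(m$seq)) return(m)
    }
    stop("could not draw productive mutations after ", max_attempts,
         " attempts")
  }

  seqs <- naive$sequence
  depth <- 0L
  nmut <- 0L
  while (length(seqs) < size) {
    i <- sample.int(length(seqs), 1L)
    a <- grow_edge(seqs[i])
    b <- grow_edge(seqs[i])
    seqs <- c(seqs[-i], a$seq, b$seq)
    depth <- c(depth[-i], depth[i] + 1L, depth[i] + 1L)
    nmut <- c(nmut[-i], nmut[i] + a$n_mut, nmut[i] + b$n_mut)
  }
  out <- naive[rep(1L, size), , drop = FALSE]
  rownames(out) <- NULL
  out$sequence <- seqs
  out$junction <- substr(seqs, jct_start, jct_end)
  out$junction_aa <- translate_nt(out$junction)
  attr(out, "leaf_depth") <- depth
  attr(out, "leaf_mutations") <- nmut
  out
}

#' Simulate a clonally structured ground-truth repertoire
#'
#' Draws `n_clones` naive rearrangements, expands each into a clone with sizes
#' from the configured distribution, and appends `n_singletons` naive
#' singleton clones (unexpanded, naive B cells). The total number of
#' ground-truth clones is `n_clones + n_singletons`.
#'
#' @param config a [sim_config()].
#' @param reference a `germline_reference`.
#' @return data.frame of truth records with columns truth_id, clone_id,
#'   sequence, v_call, d_call, j_call, junction, junction_aa, junction_start,
#'   junction_end, is_singleton.
#' @export
simulate_repertoire <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "germline_reference"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(config$seed)) set.seed(config$seed)

  sizes <- draw_clone_sizes(config$clone_sizes, config$n_clones)
  n_naive <- config$n_clones + config$n_singletons

  naives <- NULL
  if (n_naive > 0) {
    need <- n_naive
    parts <- list()
    guard <- 0L
    while (need > 0) {
      cand <- recombine_batch(reference, max(need * 2L, 16L),
                              config$trim_max, config$insert_max)
      cand <- cand[cand$productive, , drop = FALSE]
      if (nrow(cand) > 0) {
        parts[[length(parts) + 1L]] <- head(cand, need)
        need <- need - min(nrow(cand), need)
      }
      guard <- guard + 1L
      if (guard > 200L) {
        stop("productive rearrangements too rare for this reference/config")
      }
    }
    naives <- do.call(rbind, parts)
    rownames(naives) <- NULL
  }

  members <- vector("list", config$n_clones + config$n_singletons)
  for (i in seq_len(config$n_clones)) {
    cl <- simulate_clone(naives[i, , drop = FALSE], sizes[i], config$shm_rate)
    cl$clone_id <- sprintf("C%05d", i)
    cl$is_singleton <- FALSE
    members[[i]] <- cl
  }
  for (s in seq_len(config$n_singletons)) {
    cl <- naives[config$n_clones + s, , drop = FALSE]
    cl$clone_id <- sprintf("S%05d", s)
    cl$is_singleton <- TRUE
    members[[config$n_clones + s]] <- cl
  }
  truth <- do.call(rbind, members)
  rownames(truth) <- NULL
  if (is.null(truth)) {
    truth <- recombine_batch(reference, 0L, 0L, 0L)
    truth$clone_id <- character(0)
    truth$is_singleton <- logical(0)
  }
  truth$truth_id <- sprintf("T%06d", seq_len(nrow(truth)))
  cols <- c("truth_id", "clone_id", "sequence", "v_call", "d_call", "j_call",
            "junction", "junction_aa", "junction_start", "junction_end",
            "is_singleton")
  truth[, cols]
}

#' Linear positional error model
#'
#' Substitution probability ramps linearly along the read, from zero at the
#' first cycle through `center_rate` at the middle cycle to twice
#' `center_rate` at the last; the mean over positions equals `center_rate`.
#'
#' @param center_rate per-base substitution probability at the read midpoint.
#' @return an object of class `error_model`.
#' @export
error_model <- function(center_rate = 0) {
  stopifnot(center_rate >= 0, center_rate < 0.5)
  structure(list(center_rate = center_rate, profile = "linear"),
            class = "error_model")
}

#' Positional substitution rate under the linear error model
#'
#' @param pos 1-based read position(s).
#' @param read_len read length.
#' @param model an [error_model()].
#' @return numeric vector: `2 * center_rate * (pos - 1) / (read_len - 1)`.
#' @export
positional_error_rate <- function(pos, read_len, model) {
  if (any(pos < 1 | pos > read_len)) stop("pos out of range")
  if (read_len == 1L) return(rep(0, length(pos)))
  2 * model$center_rate * (pos - 1) / (read_len - 1)
}

#' Sequencing library configuration
#'
#' @param protocol `"umi"` (a random UMI is prepended to read 1) or
#'   `"sans_umi"`.
#' @param umi_length UMI length in nt.
#' @param read_length sequencing read length.
#' @param reads_min,reads_lambda reads per molecule are
#'   `reads_min + Poisson(reads_lambda)`; the default minimum of 2 reflects
#'   libraries sequenced deep enough that the minimum-copy filter retains
#'   correct molecules.
#' @param overlap minimum guaranteed overlap between mates on the molecule.
#' @param quality_high,quality_low Phred scores at the first/last cycle used
#'   to synthesize quality strings (linear decay).
#' @return an object of class `library_config`.
#' @export
library_config <- function(protocol = c("umi", "sans_umi"),
                           umi_length = 12L,
                           read_length = 160L,
                           reads_min = 2L,
                           reads_lambda = 6,
                           overlap = 15L,
                           quality_high = 40L,
                           quality_low = 30L) {
  protocol <- match.arg(protocol)
  if (protocol == "umi" && read_length <= umi_length + overlap) {
    stop("read_length must exceed umi_length + overlap")
  }
  stopifnot(reads_min >= 1, reads_lambda >= 0)
  structure(list(protocol = protocol, umi_length = as.integer(umi_length),
                 read_length = as.integer(read_length),
                 reads_min = as.integer(reads_min),
                 reads_lambda = reads_lambda, overlap = as.integer(overlap),
                 quality_high = as.integer(quality_high),
                 quality_low = as.integer(quality_low)),
            class = "library_config")
}

random_umis <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate paired-end reads from truth molecules
#'
#' Each truth molecule receives `reads_min + Poisson(reads_lambda)` read
#' pairs; under the UMI protocol one random UMI per molecule is prepended to
#' read 1 (UMI collisions are allowed to occur naturally). Read 1 covers the
#' molecule 5' end, read 2 is the reverse complement of the 3' end; the mates
#' always overlap by at least `overlap` bases. Substitution errors are applied
#' independently per read with the linear positional profile of `model` (the
#' UMI bases are subject to the same profile). Quality strings decay linearly
#' from `quality_high` to `quality_low`.
#'
#' @param truth truth data.frame from [simulate_repertoire()].
#' @param lib a [library_config()].
#' @param model an [error_model()].
#' @param seed optional integer seed.
#' @return list with `reads` (data.frame read_id, mate1, qual1, mate2, qual2,
#'   umi, truth_id) and `truth_map` (read_id -> truth_id sidecar).
#' @export
simulate_reads <- function(truth, lib, model = error_model(0), seed = NULL) {
  if (nrow(truth) == 0) stop("truth repertoire is empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)

  n_mol <- nrow(truth)
  mol <- truth$sequence
  mol_len <- nchar(mol)
  umi_len <- if (lib$protocol == "umi") lib$umi_length else 0L
  cov1 <- lib$read_length - umi_len
  cov2 <- lib$read_length
  if (any(cov1 > mol_len) || any(cov2 > mol_len)) {
    stop("read_length exceeds the shortest truth molecule")
  }
  if (any(cov1 + cov2 - mol_len < lib$overlap)) {
    stop("read_length too short to guarantee mate overlap of ", lib$overlap)
  }

  k <- lib$reads_min + rpois(n_mol, lib$reads_lambda)
  idx <- rep.int(seq_len(n_mol), k)

  insert1 <- substr(mol, 1L, cov1)
  insert2 <- cpp_revcomp(substr(mol, mol_len - cov2 + 1L, mol_len))
  umi <- if (lib$protocol == "umi") {
    random_umis(n_mol, lib$umi_length)
  } else {
    rep(NA_character_, n_mol)
  }

  r1 <- if (lib$protocol == "umi") {
    paste0(umi[idx], insert1[idx])
  } else {
    insert1[idx]
  }
  r2 <- insert2[idx]

  L <- lib$read_length
  rates <- positional_error_rate(seq_len(L), L, model)
  if (model$center_rate > 0) {
    r1 <- cpp_apply_errors(r1, rates)
    r2 <- cpp_apply_errors(r2, rates)
  }
  qual <- phred_string(seq(lib$quality_high, lib$quality_low,
                           length.out = L))
  reads <- data.frame(
    read_id = sprintf("R%07d", seq_along(idx)),
    mate1 = r1, qual1 = qual,
    mate2 = r2, qual2 = qual,
    umi = umi[idx],
    truth_id = truth$truth_id[idx],
    stringsAsFactors = FALSE
  )
  list(reads = reads,
       truth_map = reads[, c("read_id", "truth_id")])
}
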