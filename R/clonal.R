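# Clonal inference: V/J/junction-length partitioning, length-normalized
# Hamming distances, distance-to-nearest threshold estimation, single-linkage
# clone assignment and bootstrap clonal abundance.

#' Length-normalized Hamming distance
#'
#' Fraction of differing positions between two equal-length strings. The
#' wildcard symbol (N for nucleotides, X for amino acids) matches anything.
#'
#' @param a,b equal-length strings.
#' @param wildcard wildcard character (default "N").
#' @return distance in [0, 1].
#' @export
normalized_hamming <- function(a, b, wildcard = "N") {
  cpp_norm_hamming(a, b, wildcard)
}

partition_key <- function(records, use_light = FALSE) {
  key <- paste(gene_of(records$v_call), gene_of(records$j_call),
               nchar(records$junction), sep = "|")
  if (use_light) {
    key <- paste(key, gene_of(records$light_v_call),
                 gene_of(records$light_j_call),
                 nchar(records$light_junction), sep = "|")
  }
  key
}

#' Partition records by V gene, J gene and junction length
#'
#' Gene labels are allele-stripped (first call on ambiguity). Records without
#' a junction are excluded and reported in the `excluded` attribute.
#'
#' @param records AIRR-style data.frame with v_call, j_call, junction.
#' @param use_light also partition by light/alpha-chain V gene, J gene and
#'   junction length (columns light_v_call, light_j_call, light_junction).
#' @return named list of data.frames, one per partition; attribute
#'   `excluded` holds the records lacking a junction.
#' @export
partition_records <- function(records, use_light = FALSE) {
  bad <- is.na(records$junction) | records$junction == ""
  kept <- records[!bad, , drop = FALSE]
  parts <- split(kept, partition_key(kept, use_light))
  attr(parts, "excluded") <- records[bad, , drop = FALSE]
  parts
}

#' Distance to the nearest junction neighbor
#'
#' For every sequence with at least one partner in its V/J/length partition,
#' the minimum length-normalized Hamming distance to any other junction in
#' the partition. Sequences alone in their partition contribute nothing.
#'
#' @param records AIRR-style data.frame (see [partition_records()]), or a
#'   list of partitions.
#' @return numeric vector of nearest-neighbor distances.
#' @export
distance_to_nearest <- function(records) {
  parts <- if (is.data.frame(records)) partition_records(records) else records
  out <- lapply(parts, function(p) {
    n <- nrow(p)
    if (n < 2) return(numeric(0))
    d <- cpp_pairwise_norm_hamming(p$junction, "N")
    diag(d) <- NA
    apply(d, 1L, min, na.rm = TRUE)
  })
  unname(unlist(out))
}

#' Estimate the clonal distance threshold from the distance-to-nearest
#' distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth) on a
#' fixed grid over [0, 1] and returns the grid position of the minimum
#' density between the two highest-density local maxima. The estimate does
#' not converge when there are fewer than `min_n` distances, fewer than two
#' local maxima, or the valley is not prominent (valley density above
#' `max_valley_frac` of the lower peak — the sampling wiggle of a unimodal
#' density, not genuine bimodality).
#'
#' @param distances numeric vector of nearest-neighbor distances.
#' @param min_n minimum number of distances required (default 50).
#' @param grid_step density grid step (default 0.001).
#' @param max_valley_frac maximum valley/lower-peak density ratio (default
#'   0.9).
#' @return object of class `threshold_estimate`: list with threshold, method,
#'   converged, and the density grid (`grid`, `density`).
#' @export
estimate_threshold <- function(distances, min_n = 50L, grid_step = 0.001,
                               max_valley_frac = 0.9) {
  grid_n <- round(1 / grid_step) + 1L
  failed <- function() {
    structure(list(threshold = NA_real_, method = "density",
                   converged = FALSE, grid = NULL, density = NULL),
              class = "threshold_estimate")
  }
  distances <- distances[!is.na(distances)]
  if (length(distances) < min_n) return(failed())
  dens <- density(distances, bw = "nrd0", from = 0, to = 1, n = grid_n)
  y <- dens$y
  n <- length(y)
  # interior local maxima (plateaus count once, at their first point)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  is_max <- y > left & y >= right
  peaks <- which(is_max)
  peaks <- peaks[y[peaks] >= 0.001 * max(y)]  # drop numerical-noise bumps
  if (length(peaks) < 2) return(failed())
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  if (y[valley] > max_valley_frac * min(y[top2])) return(failed())
  structure(list(threshold = dens$x[valley], method = "density",
                 converged = TRUE, grid = dens$x, density = y),
            class = "threshold_estimate")
}

#' Assign clones by single-linkage clustering of junction distances
#'
#' Within each V gene / J gene / junction length partition, clones are the
#' connected components of the graph linking junction pairs at normalized
#' Hamming distance <= `threshold` (inclusive). For T cells the threshold is
#' forced to 0 (identical junctions). Clone labels are unique across
#' partitions and deterministic: partitions are processed in sorted key order
#' and components are numbered by their smallest member sequence_id.
#'
#' @param records AIRR-style data.frame with sequence_id, v_call, j_call,
#'   junction.
#' @param threshold normalized Hamming distance threshold, or a
#'   `threshold_estimate`.
#' @param cell_type `"B"` or `"T"`.
#' @param use_light see [partition_records()].
#' @return `records` with a `clone_id` column added (NA for records without a
#'   junction).
#' @export
assign_clones <- function(records, threshold, cell_type = c("B", "T"),
                          use_light = FALSE) {
  cell_type <- match.arg(cell_type)
  if (inherits(threshold, "threshold_estimate")) {
    if (!threshold$converged) stop("threshold estimate did not converge")
    threshold <- threshold$threshold
  }
  if (cell_type == "T") threshold <- 0
  stopifnot(threshold >= 0, threshold <= 1)

  parts <- partition_records(records, use_light)
  keys <- sort(names(parts))
  out <- vector("list", length(parts))
  clone_counter <- 0L
  for (ki in seq_along(keys)) {
    p <- parts[[keys[ki]]]
    n <- nrow(p)
    comp <- if (n == 1L) {
      1L
    } else if (threshold == 0) {
      match(p$junction, unique(p$junction))
    } else {
      single_linkage_components(cpp_pairwise_norm_hamming(p$junction, "N"),
                                threshold)
    }
    # renumber components by smallest member sequence_id for determinism
    first_id <- tapply(p$sequence_id, comp, min)
    rank <- match(comp, as.integer(names(sort(first_id))))
    p$clone_id <- sprintf("%s_%04d", gsub("[|]", "_", keys[ki]), rank)
    clone_counter <- clone_counter + max(rank)
    out[[ki]] <- p
  }
  res <- do.call(rbind, out)
  excluded <- attr(parts, "excluded")
  if (!is.null(excluded) && nrow(excluded) > 0) {
    excluded$clone_id <- NA_character_
    res <- rbind(res, excluded)
  }
  rownames(res) <- NULL
  res
}

#' Refine heavy-chain clones by light-chain partitions
#'
#' Splits each heavy-chain clone by the members' light-chain V gene, J gene
#' and junction length; cells without a light chain stay with the largest
#' (majority) sub-clone of their original clone.
#'
#' @param records clone-assigned data.frame with cell_id and light-chain
#'   columns light_v_call, light_j_call, light_junction (NA when missing).
#' @return `records` with refined `clone_id`.
#' @export
refine_by_light_chain <- function(records) {
  has_light <- !is.na(records$light_v_call) & records$light_v_call != ""
  light_key <- rep(NA_character_, nrow(records))
  light_key[has_light] <- paste(gene_of(records$light_v_call[has_light]),
                                gene_of(records$light_j_call[has_light]),
                                nchar(records$light_junction[has_light]),
                                sep = "|")
  new_id <- records$clone_id
  for (cl in unique(records$clone_id)) {
    idx <- which(records$clone_id == cl)
    keys <- light_key[idx]
    if (all(is.na(keys))) next
    tab <- sort(table(keys[!is.na(keys)]), decreasing = TRUE)
    uk <- names(tab)
    sub <- match(keys, uk)
    sub[is.na(sub)] <- 1L  # no light chain: join the majority sub-clone
    new_id[idx] <- sprintf("%s.%d", cl, sub)
  }
  records$clone_id <- new_id
  records
}

#' Bootstrap clonal rank-abundance curve
#'
#' Each bootstrap replicate draws `sample_size` sequences with replacement,
#' weighted by `duplicate_count` (copy number), computes relative clone
#' abundances and sorts them in decreasing order. The curve reports the mean,
#' minimum and maximum relative abundance per rank over replicates.
#'
#' @param records clone-assigned data.frame (clone_id, duplicate_count;
#'   a missing duplicate_count counts each record once).
#' @param n_boot number of bootstrap replicates (default 200).
#' @param sample_size sequences drawn per replicate (default: total copies).
#' @param seed optional integer seed.
#' @return object of class `abundance_curve`: data.frame rank, mean, min,
#'   max, with attributes n_boot and sample_size.
#' @export
clonal_abundance <- function(records, n_boot = 200L, sample_size = NULL,
                             seed = NULL) {
  if (nrow(records) == 0) stop("empty input")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)

  w <- records$duplicate_count %||% rep(1L, nrow(records))
  if (is.null(records$duplicate_count)) w <- rep(1L, nrow(records))
  total <- sum(w)
  if (is.null(sample_size)) sample_size <- total
  stopifnot(sample_size >= 1)

  clones <- records$clone_id
  uclones <- unique(clones)
  ci <- match(clones, uclones)
  n_ranks <- length(uclones)
  mat <- matrix(0, nrow = n_boot, ncol = n_ranks)
  for (b in seq_len(n_boot)) {
    draw <- sample.int(length(ci), sample_size, replace = TRUE, prob = w)
    ab <- tabulate(ci[draw], nbins = n_ranks) / sample_size
    mat[b, ] <- sort(ab, decreasing = TRUE)
  }
  curve <- data.frame(rank = seq_len(n_ranks),
                      mean = colMeans(mat),
                      min = apply(mat, 2L, min),
                      max = apply(mat, 2L, max))
  structure(curve, class = c("abundance_curve", "data.frame"),
            n_boot = n_boot, sample_size = sample_size)
}
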