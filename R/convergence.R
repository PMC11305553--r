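# Cross-subject convergent antibody clustering: junction amino-acid
# single-linkage clusters within V gene / J gene / junction-length
# partitions, subject/status filtering, ranking, edit distances to reference
# antibodies and information-content sequence logos.

#' Cluster junction amino-acid sequences into convergent groups
#'
#' Within each (V gene, J gene, junction AA length) partition, convergent
#' clusters are the connected components of the graph linking junction pairs
#' at length-normalized amino-acid Hamming distance <= `threshold`
#' (inclusive; X is a wildcard). At junction length 15 the default threshold
#' of 0.2 admits up to 3 amino-acid differences per link.
#'
#' @param records data.frame with junction_aa, v_call, j_call, subject_id,
#'   status and optionally sequence_id, sample_id.
#' @param threshold normalized AA Hamming threshold (default 0.2).
#' @return data.frame of clusters: cluster_id, v_gene, j_gene,
#'   junction_aa_length, n_sequences, n_unique_junctions, n_subjects,
#'   n_case_subjects, has_control; attribute `members` maps rows of `records`
#'   to cluster_id (also returned as a `cluster_id` column on the attribute
#'   data.frame `records`).
#' @export
cluster_convergent <- function(records, threshold = 0.2) {
  stopifnot(all(c("junction_aa", "v_call", "j_call", "subject_id",
                  "status") %in% names(records)))
  ok <- !is.na(records$junction_aa) & records$junction_aa != ""
  recs <- records[ok, , drop = FALSE]
  key <- paste(gene_of(recs$v_call), gene_of(recs$j_call),
               nchar(recs$junction_aa), sep = "|")
  parts <- split(seq_len(nrow(recs)), key)
  keys <- sort(names(parts))

  recs$cluster_id <- NA_character_
  clusters <- list()
  counter <- 0L
  for (k in keys) {
    idx <- parts[[k]]
    n <- length(idx)
    comp <- if (n == 1L) {
      1L
    } else {
      single_linkage_components(
        cpp_pairwise_norm_hamming(recs$junction_aa[idx], "X"), threshold)
    }
    for (ci in seq_len(max(comp))) {
      counter <- counter + 1L
      cid <- sprintf("CC%05d", counter)
      mem <- idx[comp == ci]
      recs$cluster_id[mem] <- cid
      subj <- recs$subject_id[mem]
      case_subj <- unique(subj[recs$status[mem] == "case"])
      clusters[[counter]] <- data.frame(
        cluster_id = cid,
        v_gene = gene_of(recs$v_call[mem[1]]),
        j_gene = gene_of(recs$j_call[mem[1]]),
        junction_aa_length = nchar(recs$junction_aa[mem[1]]),
        n_sequences = length(mem),
        n_unique_junctions = length(unique(recs$junction_aa[mem])),
        n_subjects = length(unique(subj)),
        n_case_subjects = length(case_subj),
        has_control = any(recs$status[mem] == "control"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, clusters)
  rownames(out) <- NULL
  attr(out, "records") <- recs
  out
}

#' Filter convergent clusters on subject support and control absence
#'
#' Keeps clusters with members from at least `min_subjects` distinct subjects
#' and no control-status member.
#'
#' @param clusters cluster table from [cluster_convergent()].
#' @param min_subjects minimum distinct subjects (default 2).
#' @return filtered cluster table (the `records` attribute is subset too).
#' @export
filter_clusters <- function(clusters, min_subjects = 2L) {
  keep <- clusters$n_subjects >= min_subjects & !clusters$has_control
  out <- clusters[keep, , drop = FALSE]
  recs <- attr(clusters, "records")
  if (!is.null(recs)) {
    attr(out, "records") <- recs[recs$cluster_id %in% out$cluster_id, ,
                                 drop = FALSE]
  }
  out
}

#' Rank convergent clusters
#'
#' Descending by number of distinct case subjects, ties broken by descending
#' sequence count, then ascending cluster_id.
#'
#' @param clusters cluster table.
#' @return reordered cluster table with a `rank` column.
#' @export
rank_clusters <- function(clusters) {
  ord <- order(-clusters$n_case_subjects, -clusters$n_sequences,
               clusters$cluster_id)
  out <- clusters[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "records") <- attr(clusters, "records")
  out
}

#' Levenshtein edit distance between junction amino-acid sequences
#'
#' Standard unit-cost edit distance; handles unequal lengths (used to compare
#' cluster junctions against reference antibodies).
#'
#' @param a,b amino-acid strings (vectorized with recycling).
#' @return integer vector of edit distances.
#' @export
junction_edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

#' Position-wise information-content matrix for a sequence logo
#'
#' For equal-length junction amino-acid sequences, computes per-position
#' residue frequencies and the information content
#' `R_p = max(0, log2(20) - (H_p + e_n))`, where `H_p` is the Shannon entropy
#' in bits and `e_n = 19 / (2 ln(2) n)` is the small-sample correction.
#' Letter heights for plotting are `frequency * R_p`.
#'
#' @param junctions character vector of equal-length AA strings.
#' @return object of class `logo_matrix`: list with `freq` (20 x L frequency
#'   matrix over the standard amino acids), `bits` (length-L information
#'   content), `n` (number of sequences).
#' @export
logo_matrix <- function(junctions) {
  stopifnot(length(junctions) >= 1)
  L <- unique(nchar(junctions))
  if (length(L) != 1) stop("junction sequences must have equal length")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- matrix(unlist(strsplit(junctions, "", fixed = TRUE)),
                  ncol = L, byrow = TRUE)
  n <- length(junctions)
  freq <- vapply(seq_len(L), function(p) {
    counts <- table(factor(chars[, p], levels = aa))
    as.numeric(counts) / sum(counts)
  }, numeric(length(aa)))
  rownames(freq) <- aa
  e_n <- 19 / (2 * log(2) * n)
  bits <- vapply(seq_len(L), function(p) {
    f <- freq[, p]
    f <- f[f > 0]
    h <- -sum(f * log2(f))
    max(0, log2(20) - (h + e_n))
  }, numeric(1))
  structure(list(freq = freq, bits = bits, n = n), class = "logo_matrix")
}
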