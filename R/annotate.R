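# Simplified V(D)J annotation and post-alignment QC.
#
# Assembled sequences are annotated by best ungapped semi-global placement of
# each germline segment (match +1, mismatch -1, N scores 0). For amplicon-
# style data the V segment starts near the sequence 5' end and the J segment
# ends at the 3' end, so placements are scanned within a window around those
# expected offsets; `window = NULL` scans all offsets. The junction is cut
# from the aligned V anchor through the end of the aligned J anchor codon.

#' Alignment QC parameters
#'
#' @param min_informative minimum aligned non-N positions (default 200).
#' @param max_n_frac maximum fraction of N nucleotides (default 0.10).
#' @param productive_only drop non-productive records (default TRUE).
#' @return an object of class `alignment_qc_params`.
#' @export
alignment_qc_params <- function(min_informative = 200L, max_n_frac = 0.10,
                                productive_only = TRUE) {
  stopifnot(min_informative >= 0, max_n_frac >= 0, max_n_frac <= 1)
  structure(list(min_informative = as.integer(min_informative),
                 max_n_frac = max_n_frac,
                 productive_only = isTRUE(productive_only)),
            class = "alignment_qc_params")
}

count_n <- function(x) {
  nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))
}

# Best placement of each segment of one kind; returns the winning call(s),
# score and query span. Ties are comma-separated in reference order.
best_segment_call <- function(query, segs, center, window) {
  qlen <- nchar(query)
  n <- nrow(segs)
  scores <- integer(n)
  offs <- integer(n)
  lens <- integer(n)
  for (k in seq_len(n)) {
    rlen <- nchar(segs$sequence[k])
    ctr <- if (is.function(center)) center(rlen) else center
    if (is.null(window)) {
      dmin <- -(rlen - 1L)
      dmax <- qlen - 1L
    } else {
      dmin <- ctr - window
      dmax <- ctr + window
    }
    hit <- cpp_best_placement(query, segs$sequence[k], dmin, dmax)
    scores[k] <- if (is.na(hit[1])) -.Machine$integer.max else hit[1]
    offs[k] <- hit[2]
    lens[k] <- hit[3]
  }
  best <- max(scores)
  winners <- which(scores == best)
  list(call = paste(segs$name[winners], collapse = ","),
       idx = winners[1], score = best, offset = offs[winners[1]],
       aligned_len = lens[winners[1]])
}

#' Annotate sequences with V(D)J segment calls and junctions
#'
#' @param seqs character vector of sequences, or data.frame with columns
#'   `sequence_id` and `sequence` (extra columns are carried through).
#' @param reference a `germline_reference`.
#' @param window maximum shift around the expected segment offset (V at the
#'   sequence start, J at the end); `NULL` scans all offsets.
#' @param min_score_frac minimum alignment score as a fraction of segment
#'   length for a V/J call to be accepted.
#' @return data.frame in AIRR rearrangement style: sequence_id, sequence,
#'   locus, v_call, d_call, j_call, junction, junction_length, junction_aa,
#'   productive, informative_positions, n_fraction, plus alignment spans
#'   (v_qstart, v_qend, j_qstart, j_qend) and an `annotated` flag (FALSE when
#'   no V or J scored above the minimum).
#' @export
annotate_rearrangements <- function(seqs, reference, window = 10L,
                                    min_score_frac = 0.4) {
  if (is.data.frame(seqs)) {
    df <- seqs
    if (is.null(df$sequence_id)) {
      df$sequence_id <- sprintf("SEQ%06d", seq_len(nrow(df)))
    }
  } else {
    df <- data.frame(sequence_id = sprintf("SEQ%06d", seq_along(seqs)),
                     sequence = as.character(seqs), stringsAsFactors = FALSE)
  }
  vs <- segments_of(reference, "V")
  ds <- segments_of(reference, "D")
  js <- segments_of(reference, "J")

  n <- nrow(df)
  v_call <- j_call <- d_call <- junction <- junction_aa <-
    rep(NA_character_, n)
  locus <- rep(NA_character_, n)
  productive <- annotated <- rep(FALSE, n)
  informative <- junction_length <- rep(NA_integer_, n)
  v_qs <- v_qe <- j_qs <- j_qe <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    q <- df$sequence[i]
    qlen <- nchar(q)
    vhit <- best_segment_call(q, vs, 0L, window)
    jhit <- best_segment_call(q, js, function(rlen) qlen - rlen, window)
    v_len <- nchar(vs$sequence[vhit$idx])
    j_len <- nchar(js$sequence[jhit$idx])
    if (vhit$score < min_score_frac * v_len ||
        jhit$score < min_score_frac * j_len) {
      next
    }
    annotated[i] <- TRUE
    v_call[i] <- vhit$call
    j_call[i] <- jhit$call
    locus[i] <- substr(gene_of(vhit$call), 1L, 3L)
    v_qs[i] <- vhit$offset + 1L
    v_qe[i] <- min(qlen, vhit$offset + v_len)
    j_qs[i] <- max(1L, jhit$offset + 1L)
    j_qe[i] <- min(qlen, jhit$offset + j_len)

    # D within the V-J gap
    gap_from <- v_qe[i] + 1L
    gap_to <- j_qs[i] - 1L
    d_call[i] <- "None"
    d_span <- 0L
    if (gap_to - gap_from + 1L >= 5L && nrow(ds) > 0) {
      gap <- substr(q, gap_from, gap_to)
      dbest <- -1L
      for (k in seq_len(nrow(ds))) {
        dl <- nchar(ds$sequence[k])
        hit <- cpp_best_placement(gap, ds$sequence[k], -(dl - 1L),
                                  nchar(gap) - 1L)
        if (!is.na(hit[1]) && hit[1] > dbest && hit[1] >= 5L) {
          dbest <- hit[1]
          d_call[i] <- ds$name[k]
          d_span <- hit[3]
        }
      }
    }

    v_anchor_q <- vhit$offset + vs$anchor[vhit$idx]
    j_anchor_q <- jhit$offset + js$anchor[jhit$idx]
    if (v_anchor_q >= 1L && j_anchor_q + 2L <= qlen &&
        j_anchor_q + 2L > v_anchor_q) {
      junction[i] <- substr(q, v_anchor_q, j_anchor_q + 2L)
      junction_length[i] <- nchar(junction[i])
      if (junction_length[i] %% 3L == 0L) {
        junction_aa[i] <- translate_nt(junction[i])
        full <- translate_nt(substr(q, vhit$offset + 1L, qlen))
        productive[i] <- !has_stop(junction_aa[i]) && !has_stop(full)
      }
    }

    spans <- c(substr(q, v_qs[i], v_qe[i]), substr(q, j_qs[i], j_qe[i]))
    informative[i] <- sum(nchar(spans) - count_n(spans)) + d_span
  }

  df$locus <- locus
  df$v_call <- v_call
  df$d_call <- d_call
  df$j_call <- j_call
  df$junction <- junction
  df$junction_length <- junction_length
  df$junction_aa <- junction_aa
  df$productive <- productive
  df$informative_positions <- informative
  df$n_fraction <- count_n(df$sequence) / nchar(df$sequence)
  df$v_qstart <- v_qs; df$v_qend <- v_qe
  df$j_qstart <- j_qs; df$j_qend <- j_qe
  df$annotated <- annotated
  df
}

#' Post-alignment QC filter
#'
#' Drops records failing any of: locus mismatch against the expected locus,
#' fewer than `min_informative` aligned non-N positions, N fraction above
#' `max_n_frac`, or non-productive when `productive_only`. The first failing
#' reason (in that fixed order) is recorded; records flagged unannotatable
#' fail with reason `"unannotatable"`.
#'
#' @param rearr annotated data.frame from [annotate_rearrangements()].
#' @param params an [alignment_qc_params()].
#' @param expected_locus locus label (e.g. "IGH"); `NULL` skips the check.
#' @return list with `records` (kept rows), `dropped` (rows + reason) and
#'   `report` (reason histogram).
#' @export
qc_filter_alignment <- function(rearr, params = alignment_qc_params(),
                                expected_locus = NULL) {
  n <- nrow(rearr)
  reason <- rep(NA_character_, n)
  unann <- !isTRUE_vec(rearr$annotated)
  reason[unann] <- "unannotatable"
  if (!is.null(expected_locus)) {
    bad <- is.na(reason) & !is.na(rearr$locus) &
      rearr$locus != expected_locus
    reason[bad] <- "locus_mismatch"
  }
  bad <- is.na(reason) & rearr$informative_positions < params$min_informative
  reason[bad & !is.na(bad)] <- "min_informative"
  bad <- is.na(reason) & rearr$n_fraction > params$max_n_frac
  reason[bad & !is.na(bad)] <- "max_n_frac"
  if (params$productive_only) {
    bad <- is.na(reason) & !rearr$productive
    reason[bad & !is.na(bad)] <- "non_productive"
  }
  keep <- is.na(reason)
  dropped <- rearr[!keep, , drop = FALSE]
  dropped$qc_reason <- reason[!keep]
  list(records = rearr[keep, , drop = FALSE],
       dropped = dropped,
       report = as.list(table(reason[!keep])))
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(TRUE)
  !is.na(x) & x
}

#' Reconstruct the aligned germline string for a record
#'
#' Builds a query-coordinate germline string from the stored V and J
#' alignment spans (positions outside any aligned segment are N, so they are
#' skipped in mismatch counting).
#'
#' @param rearr one-row annotated data.frame.
#' @param reference the `germline_reference` used for annotation.
#' @return character germline string of the same length as the sequence.
#' @export
germline_alignment_string <- function(rearr, reference) {
  q <- rearr$sequence
  germ <- rep("N", nchar(q))
  segs <- reference$segments
  place <- function(call, qstart, qend) {
    name <- sub(",.*$", "", call)
    ref <- segs$sequence[segs$name == name]
    if (length(ref) != 1 || is.na(qstart)) return()
    rstart <- 1L
    n <- qend - qstart + 1L
    germ[qstart:qend] <<- strsplit(substr(ref, rstart, rstart + n - 1L),
                                   "")[[1]]
  }
  place(rearr$v_call, rearr$v_qstart, rearr$v_qend)
  place(rearr$j_call, rearr$j_qstart, rearr$j_qend)
  paste(germ, collapse = "")
}

#' Flag likely PCR chimeras
#'
#' A record is flagged when any sliding window of `window` aligned positions
#' contains at least `max_mut` mismatches to the germline (a local mutation
#' pile-up typical of template switching).
#'
#' @param sequence query sequence.
#' @param germline aligned germline string (same coordinates; N skipped).
#' @param window window width (default 10).
#' @param max_mut mismatch count that triggers the flag (default 6).
#' @return logical flag.
#' @export
detect_chimera <- function(sequence, germline, window = 10L, max_mut = 6L) {
  cpp_max_window_mismatch(sequence, germline, window) >= max_mut
}

#' Detect likely cross-sample contamination
#'
#' Bulk mode: for every pair of samples from different subjects, the fraction
#' of shared identical full V(D)J sequences over the smaller sample's unique
#' sequence count is computed; pairs above `overlap_frac` are flagged.
#' Single-cell mode: sequences sharing an identical V(D)J sequence and cell
#' barcode across samples are flagged and removed.
#'
#' @param records data.frame with columns sample_id, subject_id, sequence and
#'   (single-cell mode) cell_id.
#' @param mode `"bulk"` or `"single_cell"`.
#' @param overlap_frac bulk flagging threshold (default 0.05).
#' @return bulk: data.frame sample_a, sample_b, overlap, flagged.
#'   single-cell: list with `records` (cleaned) and `flagged` (removed rows).
#' @export
detect_cross_contamination <- function(records,
                                       mode = c("bulk", "single_cell"),
                                       overlap_frac = 0.05) {
  mode <- match.arg(mode)
  if (mode == "single_cell") {
    key <- paste(records$sequence, records$cell_id, sep = "|")
    tab <- tapply(records$sample_id, key, function(x) length(unique(x)))
    bad_keys <- names(tab)[tab > 1]
    bad <- key %in% bad_keys
    return(list(records = records[!bad, , drop = FALSE],
                flagged = records[bad, , drop = FALSE]))
  }
  samples <- split(records, records$sample_id)
  ids <- names(samples)
  out <- list()
  if (length(ids) < 2) stop("need at least two samples")
  for (a in seq_len(length(ids) - 1L)) {
    for (b in seq(a + 1L, length(ids))) {
      sa <- samples[[a]]; sb <- samples[[b]]
      if (length(unique(sa$subject_id)) == 1 &&
          length(unique(sb$subject_id)) == 1 &&
          sa$subject_id[1] == sb$subject_id[1]) {
        next  # same subject: overlap expected
      }
      ua <- unique(sa$sequence); ub <- unique(sb$sequence)
      shared <- length(intersect(ua, ub))
      frac <- shared / min(length(ua), length(ub))
      out[[length(out) + 1L]] <- data.frame(
        sample_a = ids[a], sample_b = ids[b], overlap = frac,
        flagged = frac > overlap_frac, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample_a = character(0), sample_b = character(0),
                      overlap = numeric(0), flagged = logical(0)))
  }
  do.call(rbind, out)
}

#' Cell-level QC for single-cell data
#'
#' Drops all records of cells with two or more heavy-chain records
#' (`multi_heavy`) or with no heavy chain (`light_only`).
#'
#' @param records data.frame with columns cell_id and locus.
#' @return list with `records` (kept), `dropped_cells` (cell_id -> reason).
#' @export
filter_single_cells <- function(records) {
  heavy <- records$locus %in% c("IGH", "TRB")
  n_heavy <- tapply(heavy, records$cell_id, sum)
  reason <- ifelse(n_heavy >= 2, "multi_heavy",
                   ifelse(n_heavy == 0, "light_only", NA))
  bad_cells <- names(n_heavy)[!is.na(reason)]
  keep <- !(records$cell_id %in% bad_cells)
  list(records = records[keep, , drop = FALSE],
       dropped_cells = data.frame(cell_id = bad_cells,
                                  reason = reason[!is.na(reason)],
                                  stringsAsFactors = FALSE))
}
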