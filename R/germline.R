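# Synthetic germline segment references.
#
# Real repertoire work aligns against curated V/D/J germline databases. For a
# self-contained toolkit we instead generate a synthetic reference whose
# segments carry the two structural features clonal analysis depends on: a
# conserved cysteine codon near the V 3' end and a conserved
# tryptophan/phenylalanine codon in J followed by an in-frame [WF]GXG-like
# tail. Anchor coordinates are stored explicitly, so recombination and
# annotation share one definition of the junction.

#' Build a synthetic germline V/D/J reference
#'
#' Generates random germline segments with conserved junction anchors. V
#' segments are stop-free in their reading frame and end in a Cys (TGT/TGC)
#' anchor codon followed by three codons of trimmable tail; J segments carry a
#' Trp/Phe anchor followed by a glycine-rich in-frame tail; D segments are
#' stop-free in every frame so that random junction frames do not force
#' non-productive rearrangements.
#'
#' @param n_v,n_d,n_j number of V, D and J segments (each >= 1).
#' @param seed integer seed; the reference is deterministic given the seed.
#' @param v_length V segment length in nt (anchor placed 12 nt before the end).
#' @param d_length_range integer range of D segment lengths.
#' @param j_length J segment length in nt.
#' @param locus locus label used in segment names (default "IGH").
#' @return object of class `germline_reference`: a list with element
#'   `segments`, a data.frame with columns name, kind, sequence, anchor
#'   (1-based start of the anchor codon; NA for D), frame and locus.
#' @examples
#' ref <- build_germline_reference(5, 3, 2, seed = 1)
#' table(ref$segments$kind)
#' @export
build_germline_reference <- function(n_v, n_d, n_j, seed,
                                     v_length = 210L,
                                     d_length_range = c(12L, 18L),
                                     j_length = 48L,
                                     locus = "IGH") {
  if (n_v < 1 || n_d < 1 || n_j < 1) {
    stop("n_v, n_d and n_j must all be >= 1")
  }
  if (v_length %% 3L != 0L || v_length < 30L) {
    stop("v_length must be a multiple of 3 and >= 30")
  }
  if (j_length %% 3L != 0L || j_length < 36L) {
    stop("j_length must be a multiple of 3 and >= 36")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  v_anchor <- v_length - 11L               # anchor codon occupies [a, a+2]
  v_seqs <- vapply(seq_len(n_v), function(i) {
    paste0(random_codons((v_anchor - 1L) / 3L),
           sample(c("TGT", "TGC"), 1L),
           random_codons(3L))
  }, character(1))
  v_names <- sprintf("%sV%d-S%d*01", locus, (seq_len(n_v) - 1L) %% 7L + 1L,
                     seq_len(n_v))

  d_choices <- seq(d_length_range[1], d_length_range[2])
  d_lens <- d_choices[sample.int(length(d_choices), n_d, replace = TRUE)]
  d_seqs <- vapply(d_lens, random_dna_no_stop_any_frame, character(1))
  d_names <- sprintf("%sD%d-S%d*01", sub("H$", "H", locus),
                     (seq_len(n_d) - 1L) %% 6L + 1L, seq_len(n_d))

  j_anchor <- 22L                          # 7 head codons, anchor is codon 8
  j_seqs <- vapply(seq_len(n_j), function(i) {
    g <- function() sample(c("GGT", "GGC", "GGA", "GGG"), 1L)
    paste0(random_codons((j_anchor - 1L) / 3L),
           sample(c("TGG", "TTT", "TTC"), 1L, prob = c(0.7, 0.15, 0.15)),
           g(), random_codons(1L), g(),
           random_codons((j_length - j_anchor - 2L - 9L) / 3L))
  }, character(1))
  j_names <- sprintf("%sJ%d*01", locus, seq_len(n_j))

  segments <- data.frame(
    name = c(v_names, d_names, j_names),
    kind = rep(c("V", "D", "J"), c(n_v, n_d, n_j)),
    sequence = c(v_seqs, d_seqs, j_seqs),
    anchor = c(rep(v_anchor, n_v), rep(NA_integer_, n_d),
               rep(j_anchor, n_j)),
    frame = 0L,
    locus = locus,
    stringsAsFactors = FALSE
  )
  ref <- structure(list(segments = segments), class = "germline_reference")
  validate_germline_reference(ref)
  ref
}

#' Validate a germline reference
#'
#' Checks the structural invariants: at least one segment per kind, unique
#' names, ACGT-only sequences, anchor codons inside their segment, V anchors
#' translating to C and J anchors translating to W or F.
#'
#' @param ref a `germline_reference`.
#' @return `ref`, invisibly; errors on violation.
#' @export
validate_germline_reference <- function(ref) {
  s <- ref$segments
  stopifnot(is.data.frame(s))
  if (!all(c("V", "D", "J") %in% s$kind)) {
    stop("reference must contain at least one segment of each kind")
  }
  if (anyDuplicated(s$name)) stop("segment names must be unique")
  if (any(grepl("[^ACGT]", s$sequence))) {
    stop("segment sequences must contain only ACGT")
  }
  vj <- s[s$kind %in% c("V", "J"), ]
  if (any(is.na(vj$anchor)) || any(vj$anchor + 2L > nchar(vj$sequence))) {
    stop("anchor codon must lie within the segment")
  }
  anc <- translate_nt(substr(vj$sequence, vj$anchor, vj$anchor + 2L))
  bad_v <- vj$kind == "V" & anc != "C"
  bad_j <- vj$kind == "J" & !anc %in% c("W", "F")
  if (any(bad_v)) stop("V anchor codon must encode Cys")
  if (any(bad_j)) stop("J anchor codon must encode Trp or Phe")
  invisible(ref)
}

segments_of <- function(ref, kind) {
  ref$segments[ref$segments$kind == kind, , drop = FALSE]
}

#' Strip the allele suffix from segment calls
#'
#' Converts allele-level calls such as `"IGHV1-S3*01"` to gene-level labels
#' (`"IGHV1-S3"`). For ambiguous comma-separated calls the first call is used.
#'
#' @param call character vector of segment calls.
#' @return character vector of gene labels.
#' @export
gene_of <- function(call) {
  first <- sub(",.*$", "", call)
  sub("\\*.*$", "", first)
}

# Save/restore the global RNG state so seeded constructors do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
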