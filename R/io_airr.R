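# Shared I/O: AIRR rearrangement TSV, FASTA/FASTQ, germline references with
# anchor sidecars, samplesheets and per-step count reports.
#
# Dialect: lowercase snake_case columns, logicals written as T/F, tab
# separation, required columns first and extra columns in alphabetical order,
# so files round-trip deterministically.

AIRR_COLUMN_ORDER <- c(
  "sequence_id", "sequence", "locus", "v_call", "d_call", "j_call",
  "junction", "junction_aa", "junction_length", "productive",
  "duplicate_count", "consensus_count", "clone_id", "cell_id",
  "sample_id", "subject_id", "status"
)

#' Read an AIRR rearrangement TSV
#'
#' @param path file path.
#' @return data.frame with typed columns; `productive` is logical,
#'   `junction_length`, `duplicate_count` and `consensus_count` integer.
#'   Unknown columns are preserved. Errors when `sequence_id` or `sequence`
#'   is missing.
#' @export
read_airr_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = character(0))
  required <- c("sequence_id", "sequence")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in intersect(c("productive", "is_singleton", "annotated"),
                        names(df))) {
    df[[col]] <- df[[col]] %in% c("T", "TRUE", "true")
  }
  for (col in intersect(c("junction_length", "duplicate_count",
                          "consensus_count", "informative_positions"),
                        names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in intersect(c("n_fraction"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df[df == ""] <- NA
  df
}

#' Write an AIRR rearrangement TSV
#'
#' @param records data.frame of rearrangements.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(records, path) {
  first <- intersect(AIRR_COLUMN_ORDER, names(records))
  rest <- sort(setdiff(names(records), first))
  out <- records[, c(first, rest), drop = FALSE]
  for (col in names(out)) {
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           ifelse(out[[col]], "T", "F"))
    }
  }
  out[is.na(out)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings with named character vectors as the R-side
#' representation.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta`: named character vector; `write_fasta`: the path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ
#'
#' Phred+33 quality encoding; a `.gz` suffix triggers compression.
#'
#' @param path file path.
#' @param ids,seqs,quals read names, sequences and quality strings.
#' @return `read_fastq`: data.frame id, sequence, quality.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a simulated read set as paired FASTQ plus truth sidecar
#'
#' @param sim result of [simulate_reads()].
#' @param r1_path,r2_path FASTQ output paths (`.gz` compresses).
#' @param map_path truth-map TSV path (read_id, truth_id).
#' @return invisible list of the three paths.
#' @export
write_fastq_pair <- function(sim, r1_path, r2_path, map_path = NULL) {
  reads <- sim$reads
  write_fastq(reads$read_id, reads$mate1, reads$qual1, r1_path)
  write_fastq(reads$read_id, reads$mate2, reads$qual2, r2_path)
  if (!is.null(map_path)) {
    write.table(sim$truth_map, map_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(r1 = r1_path, r2 = r2_path, map = map_path))
}

#' Read paired FASTQ files into a read table
#'
#' @param r1_path,r2_path mate FASTQ paths (records in matching order).
#' @return data.frame read_id, mate1, qual1, mate2, qual2, umi (NA).
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (nrow(r1) != nrow(r2)) stop("mate files differ in read count")
  data.frame(read_id = sub(" .*$", "", r1$id),
             mate1 = r1$sequence, qual1 = r1$quality,
             mate2 = r2$sequence, qual2 = r2$quality,
             umi = NA_character_, stringsAsFactors = FALSE)
}

#' Write and read a germline reference (FASTA + anchor sidecar TSV)
#'
#' @param ref a `germline_reference`.
#' @param fasta_path segment FASTA path.
#' @param anchors_path sidecar TSV path (name, kind, anchor, frame, locus).
#' @return `read_germline_reference`: a `germline_reference`.
#' @export
write_germline_reference <- function(ref, fasta_path, anchors_path) {
  write_fasta(setNames(ref$segments$sequence, ref$segments$name), fasta_path)
  write.table(ref$segments[, c("name", "kind", "anchor", "frame", "locus")],
              anchors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, anchors = anchors_path))
}

#' @rdname write_germline_reference
#' @export
read_germline_reference <- function(fasta_path, anchors_path) {
  seqs <- read_fasta(fasta_path)
  meta <- read.delim(anchors_path, stringsAsFactors = FALSE)
  if (!all(meta$name %in% names(seqs))) {
    stop("anchor sidecar references segments absent from the FASTA")
  }
  segments <- data.frame(name = meta$name, kind = meta$kind,
                         sequence = unname(seqs[meta$name]),
                         anchor = as.integer(meta$anchor),
                         frame = as.integer(meta$frame),
                         locus = meta$locus, stringsAsFactors = FALSE)
  ref <- structure(list(segments = segments), class = "germline_reference")
  validate_germline_reference(ref)
  ref
}

#' Read a samplesheet
#'
#' Minimal MiAIRR-inspired TSV with columns sample_id, subject_id, species,
#' locus (IG or TR), status (case or control) and optional file path columns
#' (`filename`, `filename_r2`), which are checked for existence when present.
#'
#' @param path samplesheet TSV path.
#' @param check_files verify referenced files exist (default TRUE).
#' @return data.frame of samples.
#' @export
read_samplesheet <- function(path, check_files = TRUE) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "species", "locus", "status")
  missing <- setdiff(required, names(ss))
  if (length(missing) > 0) {
    stop("samplesheet missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ss$sample_id)) stop("sample_id values must be unique")
  if (!all(ss$locus %in% c("IG", "TR"))) {
    stop("locus must be IG or TR")
  }
  if (!all(ss$status %in% c("case", "control"))) {
    stop("status must be case or control")
  }
  if (check_files) {
    for (col in intersect(c("filename", "filename_r2"), names(ss))) {
      missing_files <- ss[[col]][!file.exists(ss[[col]])]
      if (length(missing_files) > 0) {
        stop("referenced file(s) not found: ",
             paste(missing_files, collapse = ", "))
      }
    }
  }
  ss
}

#' Build a validated per-step sequence-count report
#'
#' @param steps list of steps, each a list with `name`, `n_in`, `n_out` and
#'   optionally `reasons` (named counts for removed records).
#' @return object of class `step_report` (a data.frame); errors when a step
#'   outputs more than it reads or consecutive steps do not chain.
#' @export
build_step_report <- function(steps) {
  if (length(steps) == 0) {
    return(structure(data.frame(step = character(0), n_in = integer(0),
                                n_out = integer(0)),
                     class = c("step_report", "data.frame"), reasons = list()))
  }
  df <- data.frame(
    step = vapply(steps, `[[`, character(1), "name"),
    n_in = vapply(steps, function(s) as.integer(s$n_in), integer(1)),
    n_out = vapply(steps, function(s) as.integer(s$n_out), integer(1)),
    stringsAsFactors = FALSE
  )
  if (any(df$n_out > df$n_in)) {
    stop("step outputs more sequences than it reads: ",
         paste(df$step[df$n_out > df$n_in], collapse = ", "))
  }
  if (nrow(df) > 1 && any(df$n_in[-1] != df$n_out[-nrow(df)])) {
    stop("step counts do not chain: input of each step must equal the ",
         "previous step's output")
  }
  structure(df, class = c("step_report", "data.frame"),
            reasons = lapply(steps, function(s) s$reasons %||% list()))
}

#' Write a step report (or any configuration echo) as JSON
#'
#' @param x a `step_report`, list or data.frame.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
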