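#' Read a sample metadata table
#'
#' The metadata sidecar is a TSV with header columns `sample_id`, `species`,
#' `genus`, `family`. `sample_id` must be unique and `genus` must equal the
#' first token of `species`.
#'
#' @param path path to the TSV file.
#' @return data.frame of sample records.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, header = TRUE, sep = "\t",
                     colClasses = "character", check.names = FALSE)
  validate_records(meta)
}

#' Validate a sample-records table
#'
#' @param records data.frame with columns `sample_id`, `species`, `genus`,
#'   `family`.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_records <- function(records) {
  required <- c("sample_id", "species", "genus", "family")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(records$sample_id[duplicated(records$sample_id)]),
               collapse = ", "))
  first_tok <- vapply(strsplit(records$species, "[ _]"), `[[`, character(1), 1L)
  bad <- records$genus != first_tok
  if (any(bad))
    stop("genus does not match first token of species for: ",
         paste(records$sample_id[bad], collapse = ", "))
  records[, required]
}

#' Read one aligned FASTA file as a marker alignment
#'
#' @param path FASTA file; headers (up to first whitespace) are sample ids.
#' @param marker marker name to attach.
#' @return a [marker_alignment()].
#' @export
read_marker_fasta <- function(path, marker) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  marker_alignment(marker, setNames(as.character(set), ids))
}

#' Write a marker alignment to FASTA
#'
#' Round-trips byte-identically through [read_marker_fasta()]: sample order
#' and sequences are preserved.
#'
#' @param alignment a [marker_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_fasta <- function(alignment, path) {
  set <- Biostrings::BStringSet(alignment$seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a full dataset: one aligned FASTA per marker plus metadata
#'
#' Every FASTA header must be a `sample_id` present in the metadata; unknown
#' samples and ragged rows are rejected, never silently dropped. A marker
#' need not cover every sample (samples missing a marker are simply absent
#' from that alignment and from any concatenation).
#'
#' @param fasta_paths named character vector, `marker = path`.
#' @param metadata_path path to the metadata TSV (see [read_metadata()]).
#' @return list with elements `records` (data.frame) and `alignments`
#'   (named list of [marker_alignment()]).
#' @export
read_dataset <- function(fasta_paths, metadata_path) {
  if (is.null(names(fasta_paths)) || any(!nzchar(names(fasta_paths))))
    stop("'fasta_paths' must be named by marker")
  records <- read_metadata(metadata_path)
  alignments <- lapply(names(fasta_paths), function(m) {
    aln <- read_marker_fasta(fasta_paths[[m]], m)
    unknown <- setdiff(aln$samples, records$sample_id)
    if (length(unknown))
      stop("FASTA for marker '", m, "' contains sample(s) absent from ",
           "metadata: ", paste(unknown, collapse = ", "))
    aln
  })
  names(alignments) <- names(fasta_paths)
  list(records = records, alignments = alignments)
}

#' Write a report table as TSV (and optionally CSV)
#'
#' Numeric columns are written at full precision; `NA` becomes the `n.d.`
#' sentinel used throughout the human-readable reports.
#'
#' @param x data.frame.
#' @param path output TSV path.
#' @param csv also write a sibling `.csv` file. Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, csv = FALSE) {
  out <- x
  for (j in seq_along(out)) {
    v <- out[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "n.d."
    out[[j]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (csv) {
    csv_path <- sub("\\.tsv$", ".csv", path)
    if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
    write.table(out, csv_path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
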