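#' Build a validated marker alignment
#'
#' A `marker_alignment` holds equal-length aligned sequences for one barcode
#' marker over a set of samples. Sequences are uppercase-normalized, `U` is
#' mapped to `T`, and the alphabet is restricted to IUPAC nucleotide codes,
#' `N` and the gap character `-`.
#'
#' @param marker single marker name, e.g. `"rbcL"`.
#' @param seqs named character vector of aligned sequences; names are
#'   sample ids and must be unique.
#' @return An object of class `marker_alignment` with fields `marker`,
#'   `samples`, `seqs` and `length` (alignment columns).
#' @examples
#' aln <- marker_alignment("rbcL", c(s1 = "ACGT", s2 = "ACGA"))
#' aln$length
#' @export
marker_alignment <- function(marker, seqs) {
  if (!is.character(marker) || length(marker) != 1L || !nzchar(marker))
    stop("'marker' must be a single non-empty string")
  if (length(seqs) == 0L)
    stop("alignment for marker '", marker, "' has no sequences")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must be named by sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) {
    bad <- ids[nchar(seqs) != nchar(seqs)[1L]][1L]
    stop("ragged alignment for marker '", marker, "': row '", bad,
         "' has length ", nchar(seqs[bad]), ", expected ", nchar(seqs)[1L])
  }
  if (len < 1L) stop("alignment length must be >= 1")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  bad <- setdiff(chars, BV_ALPHABET)
  if (length(bad))
    stop("invalid characters in alignment '", marker, "': ",
         paste(bad, collapse = " "))
  allgap <- vapply(seqs, function(s) s == strrep("-", len), logical(1))
  if (any(allgap))
    stop("all-gap row(s) in alignment '", marker, "': ",
         paste(ids[allgap], collapse = ", "))
  structure(
    list(marker = marker, samples = ids, seqs = seqs, length = as.integer(len)),
    class = "marker_alignment"
  )
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("<", paste(class(x), collapse = "/"), "> marker=", x$marker,
      " samples=", length(x$samples), " columns=", x$length, "\n", sep = "")
  invisible(x)
}

# alignment rows as a samples x columns character matrix
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(m) <- alignment$samples
  m
}

#' Concatenate marker alignments over their common samples
#'
#' Joins two or more alignments end to end, keeping only samples present in
#' every input (no gap-padding of missing markers: padding would fabricate
#' haplotypes). Per-marker column spans are recorded (0-based, half-open).
#'
#' @param alignments list of [marker_alignment()] objects, in the desired
#'   concatenation order.
#' @param marker name for the combined alignment; default joins the source
#'   names with `+`.
#' @return A `combined_alignment` (inherits `marker_alignment`) with extra
#'   fields `source_markers` and `spans` (named list of `c(start, end)`).
#' @examples
#' a <- marker_alignment("m1", c(s1 = "ACGT", s2 = "ACGA"))
#' b <- marker_alignment("m2", c(s1 = "TT", s2 = "TC", s3 = "TT"))
#' concatenate_markers(list(a, b))$length  # 6; s3 dropped
#' @export
concatenate_markers <- function(alignments, marker = NULL) {
  if (length(alignments) < 2L)
    stop("need at least two alignments to concatenate")
  ok <- vapply(alignments, inherits, logical(1), "marker_alignment")
  if (!all(ok)) stop("all inputs must be marker_alignment objects")
  sources <- vapply(alignments, `[[`, character(1), "marker")
  common <- Reduce(intersect, lapply(alignments, `[[`, "samples"))
  if (length(common) == 0L)
    stop("no sample is present in all markers: ",
         paste(sources, collapse = ", "))
  # keep the sample order of the first alignment
  common <- alignments[[1L]]$samples[alignments[[1L]]$samples %in% common]
  rows <- vapply(common, function(id) {
    paste(vapply(alignments, function(a) unname(a$seqs[id]), character(1)),
          collapse = "")
  }, character(1))
  lens <- vapply(alignments, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  spans <- Map(function(s, e) c(start = s, end = e), ends - lens, ends)
  names(spans) <- sources
  if (is.null(marker)) marker <- paste(sources, collapse = "+")
  out <- marker_alignment(marker, rows)
  out$source_markers <- sources
  out$spans <- spans
  class(out) <- c("combined_alignment", class(out))
  out
}

# check that every sample in the alignment has exactly one metadata record
check_alignment_records <- function(alignment, records) {
  missing <- setdiff(alignment$samples, records$sample_id)
  if (length(missing))
    stop("sample(s) without metadata record: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

# species -> genus lookup for a records table (first token of the binomial)
species_genus <- function(records) {
  sp <- unique(records[, c("species", "genus")])
  setNames(sp$genus, sp$species)
}
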