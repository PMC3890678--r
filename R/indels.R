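#' Maximal gap runs in an alignment
#'
#' Scans every row for maximal runs of the gap character `-`. Intervals are
#' 0-based, half-open; a run is maximal (flanked by non-gap characters or
#' the sequence ends).
#'
#' @param alignment a [marker_alignment()].
#' @return data.frame sorted by (`sample_id` input order, `start`) with
#'   columns `sample_id`, `start`, `end`, `length`, `terminal` (run touches
#'   either alignment end).
#' @examples
#' aln <- marker_alignment("m", c(a = "AC--GT", b = "ACGTGT"))
#' gap_runs(aln)
#' @export
gap_runs <- function(alignment) {
  L <- alignment$length
  rows <- lapply(seq_along(alignment$samples), function(i) {
    r <- rle(strsplit(alignment$seqs[[i]], "")[[1L]] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values
    if (!any(sel)) return(NULL)
    data.frame(sample_id = alignment$samples[i],
               start = starts[sel], end = ends[sel],
               length = r$lengths[sel],
               terminal = starts[sel] == 0L | ends[sel] == L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      terminal = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Species-diagnostic indels
#'
#' An indel (gap run) is diagnostic when it is fixed in at least one species
#' (present, at the identical column interval, in every sample of that
#' species) and fixed-absent in at least one congeneric species (present in
#' none of its samples). Runs that vary within a species are never
#' diagnostic. "Same indel" means the identical interval: the inputs share
#' one alignment, so homologous gaps share coordinates; overlapping but
#' unequal intervals are distinct events. Terminal runs are excluded by
#' default because alignment trimming makes them artefact-prone.
#'
#' @param alignment a [marker_alignment()].
#' @param records sample metadata covering every sample.
#' @param min_length minimum run length to consider. Default 20: in typical
#'   plastid spacer data shorter gaps are intraspecifically variable noise.
#' @param include_terminal also consider runs touching the alignment ends.
#'   Default `FALSE`.
#' @return data.frame with columns `marker`, `start`, `end`, `length`,
#'   `genus`, `carrier_species`, `absent_species` (comma-separated lists);
#'   zero rows when nothing is diagnostic.
#' @export
diagnostic_indels <- function(alignment, records, min_length = 20L,
                              include_terminal = FALSE) {
  check_alignment_records(alignment, records)
  empty <- data.frame(marker = character(), start = integer(),
                      end = integer(), length = integer(),
                      genus = character(), carrier_species = character(),
                      absent_species = character(), stringsAsFactors = FALSE)
  runs <- gap_runs(alignment)
  if (!include_terminal) runs <- runs[!runs$terminal, , drop = FALSE]
  runs <- runs[runs$length >= min_length, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  sp_of <- setNames(records$species, records$sample_id)
  gn_of <- species_genus(records)
  samples_of <- split(records$sample_id[records$sample_id %in%
                                          alignment$samples],
                      records$species[records$sample_id %in%
                                        alignment$samples])
  intervals <- unique(runs[, c("start", "end")])
  key <- function(s, e) paste(s, e, sep = ":")
  run_key <- key(runs$start, runs$end)

  rows <- lapply(seq_len(nrow(intervals)), function(r) {
    iv <- intervals[r, ]
    carriers_by_sample <- unique(runs$sample_id[run_key == key(iv$start,
                                                               iv$end)])
    # species where the run is fixed / fixed-absent
    fixed <- names(samples_of)[vapply(samples_of, function(ids)
      all(ids %in% carriers_by_sample), logical(1))]
    absent <- names(samples_of)[vapply(samples_of, function(ids)
      !any(ids %in% carriers_by_sample), logical(1))]
    if (!length(fixed)) return(NULL)
    per_genus <- lapply(unique(gn_of[fixed]), function(g) {
      carr <- fixed[gn_of[fixed] == g]
      abs_g <- absent[gn_of[absent] == g]
      if (!length(abs_g)) return(NULL)
      data.frame(marker = alignment$marker,
                 start = iv$start, end = iv$end,
                 length = iv$end - iv$start, genus = g,
                 carrier_species = paste(sort(carr), collapse = ","),
                 absent_species = paste(sort(abs_g), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_genus)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$end, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}
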