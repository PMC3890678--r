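#' Uncorrected p-distance matrix
#'
#' Computes pairwise uncorrected p-distances (proportion of differing sites
#' among compared sites, no multiple-hit correction). Only the four
#' unambiguous bases are compared; gaps, `N` and IUPAC ambiguity codes count
#' as missing data. Under `complete_deletion` every column containing
#' missing data in ANY row is removed before comparison (so indels
#' contribute nothing to the distances); under `pairwise_deletion` columns
#' are removed per pair.
#'
#' @param alignment a [marker_alignment()].
#' @param gap_policy `"complete_deletion"` (default) or
#'   `"pairwise_deletion"`.
#' @return object of class `p_distance`: list with `marker`, `samples`,
#'   `d` (symmetric distance matrix), `sites` (per-pair compared-site
#'   counts), `gap_policy`.
#' @examples
#' aln <- marker_alignment("m", c(a = "ACGT", b = "ACGA"))
#' p_distance_matrix(aln)$d["a", "b"]  # 0.25
#' @export
p_distance_matrix <- function(alignment,
                              gap_policy = c("complete_deletion",
                                             "pairwise_deletion")) {
  gap_policy <- match.arg(gap_policy)
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  good <- matrix(m %in% BV_BASES, nrow = n)
  if (gap_policy == "complete_deletion") {
    keep <- colSums(good) == n
    if (!any(keep))
      stop("complete deletion leaves zero comparable columns for marker '",
           alignment$marker, "'")
    m <- m[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(alignment$samples, alignment$samples))
  sites <- matrix(ncol(m), n, n,
                  dimnames = list(alignment$samples, alignment$samples))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        cmp <- good[i, ] & good[j, ]
        ns <- sum(cmp)
        if (ns == 0L)
          stop("zero comparable sites between '", alignment$samples[i],
               "' and '", alignment$samples[j], "'")
        mism <- sum(m[i, cmp] != m[j, cmp])
        d[i, j] <- d[j, i] <- mism / ns
        sites[i, j] <- sites[j, i] <- ns
      }
    }
  }
  structure(list(marker = alignment$marker, samples = alignment$samples,
                 d = d, sites = sites, gap_policy = gap_policy),
            class = "p_distance")
}

#' Barcoding gap from a species' distance extremes
#'
#' The barcoding gap is the species' minimum interspecific (congeneric)
#' distance minus its maximum intraspecific distance; a species "has a gap"
#' only when the difference is strictly positive (a gap of exactly zero is
#' no gap). Undefined inputs (`NA`: singleton species or genus without a
#' second sampled species) propagate to an undefined gap, never a silent
#' zero. Vectorized.
#'
#' @param max_intra numeric vector, maximum intraspecific p-distance
#'   (`NA` when fewer than 2 conspecific samples).
#' @param min_inter numeric vector, minimum congeneric interspecific
#'   p-distance (`NA` when no congeneric species was sampled).
#' @return data.frame with columns `gap` (full precision) and `has_gap`
#'   (`NA` when the gap is undefined).
#' @examples
#' barcoding_gap(c(0, 0.0015), c(0.0064, 0.0015))
#' @export
barcoding_gap <- function(max_intra, min_inter) {
  if (length(max_intra) != length(min_inter))
    stop("'max_intra' and 'min_inter' must have equal length")
  gap <- min_inter - max_intra
  data.frame(gap = gap, has_gap = ifelse(is.na(gap), NA, gap > 0))
}

#' Per-species barcoding-gap summary
#'
#' For each species: the maximum p-distance among conspecific pairs, the
#' minimum p-distance to any congeneric sample (interspecific comparisons
#' are restricted to congeners, by the metadata genus column), and the
#' resulting barcoding gap. Singleton species have undefined `max_intra`;
#' species whose genus contains no second sampled species have undefined
#' `min_inter`; either propagates to an undefined gap.
#'
#' @param dist a [p_distance_matrix()] result.
#' @param records sample metadata covering all samples in `dist`.
#' @return data.frame with columns `species`, `n_samples`, `max_intra`,
#'   `min_inter`, `gap`, `has_gap` (`NA` marks "n.d.").
#' @export
species_distance_summary <- function(dist, records) {
  idx <- match(dist$samples, records$sample_id)
  if (anyNA(idx))
    stop("sample(s) without metadata record: ",
         paste(dist$samples[is.na(idx)], collapse = ", "))
  sp <- records$species[idx]
  gn <- records$genus[idx]
  species <- unique(sp)
  rows <- lapply(species, function(s) {
    mine <- which(sp == s)
    genus <- gn[mine[1L]]
    congener <- which(gn == genus & sp != s)
    max_intra <- if (length(mine) >= 2L)
      max(dist$d[mine, mine][upper.tri(diag(length(mine)))]) else NA_real_
    min_inter <- if (length(congener) >= 1L)
      min(dist$d[mine, congener, drop = FALSE]) else NA_real_
    data.frame(species = s, n_samples = length(mine),
               max_intra = max_intra, min_inter = min_inter,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(out, barcoding_gap(out$max_intra, out$min_inter))
  out[order(out$species), , drop = FALSE]
}

#' Format a gap summary for reporting
#'
#' Rounds distances and gaps to 4 decimals (full precision is kept in the
#' summary itself) and keeps `NA` for the "n.d." sentinel written by
#' [write_report()].
#'
#' @param summary output of [species_distance_summary()].
#' @return data.frame with rounded numeric columns.
#' @export
format_gap_summary <- function(summary) {
  for (col in c("max_intra", "min_inter", "gap"))
    summary[[col]] <- round(summary[[col]], 4)
  summary
}
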