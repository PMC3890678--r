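#' Build a reference library for best-match identification
#'
#' A reference library is a set of aligned sequences with species labels.
#' It plays the role of a public sequence database, made local and
#' deterministic; a species may have zero entries, which models database
#' incompleteness.
#'
#' @param marker marker name; queries must come from the same marker.
#' @param seqs named character vector of aligned sequences (entry ids).
#' @param species character vector of species labels, parallel to `seqs`.
#' @return object of class `reference_library`.
#' @export
reference_library <- function(marker, seqs, species) {
  if (length(seqs) != length(species))
    stop("'seqs' and 'species' must have equal length")
  if (length(seqs) == 0L)
    return(structure(list(marker = marker, seqs = character(0),
                          species = character(0), length = NA_integer_),
                     class = "reference_library"))
  aln <- marker_alignment(marker, seqs)
  structure(list(marker = marker, seqs = aln$seqs,
                 species = as.character(species), length = aln$length),
            class = "reference_library")
}

#' Reference library from an alignment plus metadata
#'
#' @param alignment a [marker_alignment()].
#' @param records sample metadata.
#' @param mask_species species to omit entirely (models absence from a
#'   public database). Default none.
#' @return a [reference_library()].
#' @export
library_from_alignment <- function(alignment, records,
                                   mask_species = character(0)) {
  check_alignment_records(alignment, records)
  sp <- records$species[match(alignment$samples, records$sample_id)]
  keep <- !(sp %in% mask_species)
  reference_library(alignment$marker, alignment$seqs[keep], sp[keep])
}

#' Alignment-based match score between two aligned rows
#'
#' A local, deterministic surrogate for a database similarity score: the
#' number of positions where both rows carry the same unambiguous base
#' (gaps, `N` and ambiguity codes never match). Higher is better; the score
#' is monotone in identity for near-full-length queries. Returns `NA` (no
#' hit) when the two rows share no mutually unambiguous column.
#'
#' @param query_row,reference_row equal-length aligned sequences.
#' @return integer match count, or `NA_integer_`.
#' @examples
#' score_pair("ACGT", "ACGA")  # 3
#' @export
score_pair <- function(query_row, reference_row) {
  if (nchar(query_row) != nchar(reference_row))
    stop("query and reference rows must have equal aligned length")
  a <- strsplit(toupper(query_row), "")[[1L]]
  b <- strsplit(toupper(reference_row), "")[[1L]]
  cmp <- a %in% BV_BASES & b %in% BV_BASES
  if (!any(cmp)) return(NA_integer_)
  sum(a[cmp] == b[cmp])
}

#' Identify one query against a reference library
#'
#' Scores the query against every entry and takes the species attaining the
#' top score. Ties are NEVER broken: when more than one species attains the
#' top score the result is `ambiguous`, a failure. Status is one of:
#' `correct` (top species set is exactly the true species), `ambiguous`
#' (several top species including the true one), `wrong` (true species
#' represented but not top), `unrepresented` (true species has no library
#' entry; evaluable only at genus level). `genus_correct` is `TRUE` when
#' all top species share the true genus.
#'
#' @param query_seq aligned query sequence (same columns as the library).
#' @param true_species the query's true species label.
#' @param library a [reference_library()] for the same marker.
#' @param query_id identifier recorded in the result. Default `"query"`.
#' @param marker marker of the query; checked against the library when
#'   given.
#' @return one-row data.frame: `sample_id`, `true_species`, `top_score`,
#'   `top_species` (comma-separated, sorted), `status`, `genus_correct`.
#' @export
identify_query <- function(query_seq, true_species, library,
                           query_id = "query", marker = NULL) {
  if (!inherits(library, "reference_library"))
    stop("'library' must be a reference_library")
  if (!is.null(marker) && !identical(marker, library$marker))
    stop("marker mismatch: query is '", marker, "', library is '",
         library$marker, "'")
  if (length(library$seqs) == 0L)
    stop("reference library is empty")
  scores <- vapply(library$seqs, score_pair, integer(1),
                   query_row = query_seq)
  represented <- true_species %in% library$species
  if (all(is.na(scores))) {
    top_score <- NA_integer_
    top_species <- character(0)
  } else {
    top_score <- max(scores, na.rm = TRUE)
    top_species <- sort(unique(library$species[!is.na(scores) &
                                                 scores == top_score]))
  }
  status <- if (!represented) "unrepresented"
  else if (identical(top_species, true_species)) "correct"
  else if (true_species %in% top_species) "ambiguous"
  else "wrong"
  true_genus <- strsplit(true_species, "[ _]")[[1L]][1L]
  top_genera <- unique(vapply(strsplit(top_species, "[ _]"), `[[`,
                              character(1), 1L))
  genus_correct <- length(top_genera) > 0L &&
    identical(top_genera, true_genus)
  data.frame(sample_id = query_id, true_species = true_species,
             top_score = top_score,
             top_species = paste(top_species, collapse = ","),
             status = status, genus_correct = genus_correct,
             stringsAsFactors = FALSE)
}

#' Leave-one-out identification over a dataset
#'
#' Queries every sample against the library of all remaining samples,
#' emulating an identification scenario with the dataset itself as the
#' reference database. Singleton species necessarily come out
#' `unrepresented`. With `leave_species_out = TRUE` all conspecific entries
#' are removed as well, modelling total database absence of the species.
#'
#' @param alignment a [marker_alignment()].
#' @param records sample metadata.
#' @param leave_species_out drop conspecifics from each query's library.
#'   Default `FALSE`.
#' @return data.frame of [identify_query()] rows, one per sample.
#' @export
leave_one_out <- function(alignment, records, leave_species_out = FALSE) {
  check_alignment_records(alignment, records)
  if (length(alignment$samples) < 2L)
    stop("leave-one-out needs at least 2 samples")
  sp <- records$species[match(alignment$samples, records$sample_id)]
  rows <- lapply(seq_along(alignment$samples), function(i) {
    drop <- if (leave_species_out) sp == sp[i]
    else seq_along(alignment$samples) == i
    lib <- reference_library(alignment$marker, alignment$seqs[!drop],
                             sp[!drop])
    identify_query(alignment$seqs[[i]], sp[i], lib,
                   query_id = alignment$samples[i],
                   marker = alignment$marker)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-level and aggregate identification success
#'
#' A species is counted as correctly identified only when ALL of its
#' queries are `correct`. Two aggregate rates are reported: success over
#' species represented in the library (the headline figure of a database
#' identification scenario) and success over all species (unrepresented
#' species count as failures in the denominator only).
#'
#' @param results data.frame of [identify_query()] rows.
#' @param records sample metadata (defines the full species set).
#' @return list with `species` (data.frame: `species`, `n_queries`,
#'   `n_correct`, `represented`, `correct`, `genus_correct`),
#'   `n_represented`, `efficacy_represented_pct`, `efficacy_all_pct`
#'   (percentages rounded to 1 decimal).
#' @export
identification_summary <- function(results, records) {
  species <- unique(records$species)
  rows <- lapply(species, function(s) {
    r <- results[results$true_species == s, , drop = FALSE]
    represented <- nrow(r) > 0L && !any(r$status == "unrepresented")
    data.frame(species = s, n_queries = nrow(r),
               n_correct = sum(r$status == "correct"),
               represented = represented,
               correct = represented && nrow(r) > 0L &&
                 all(r$status == "correct"),
               genus_correct = nrow(r) > 0L && all(r$genus_correct),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$species), , drop = FALSE]
  n_rep <- sum(tab$represented)
  list(species = tab,
       n_represented = n_rep,
       efficacy_represented_pct = if (n_rep > 0)
         round(100 * sum(tab$correct) / n_rep, 1) else NA_real_,
       efficacy_all_pct = round(100 * sum(tab$correct) / nrow(tab), 1))
}
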