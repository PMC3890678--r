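#' Worked-example survey tables
#'
#' The package bundles summary tables from a barcode survey of 68
#' Mediterranean forest trees (24 species, 10 genera, 9 families) genotyped
#' at rbcL and trnH-psbA. They exercise the reporting side of every module
#' without any sequence download: sample counts per taxon, per-species
#' haplotype counts for each marker and the two-marker combination,
#' per-species distance extremes with barcoding gaps, and the per-method
#' identification outcomes (haplotype specificity, barcoding gap,
#' reference-database best match).
#'
#' `survey_samples()` returns one row per species (`family`, `species`,
#' `n_samples`). `survey_haplotypes()` returns unique/shared haplotype
#' counts per marker plus `shared_samples`, the number of individuals
#' carrying an inter-species shared haplotype (`NA` marks species with no
#' sampled congener, for which sharing is undefined). `survey_gaps()`
#' returns `max_intra`, `min_inter` and the printed `gap` (`NA` = not
#' determined). `survey_methods()` returns the three per-method outcomes
#' (`ref_ok` is `NA` for species absent from the reference database).
#'
#' @return a data.frame (see Details).
#' @name survey_tables
NULL

survey_file <- function(name) {
  system.file("extdata", name, package = "barcodeval", mustWork = TRUE)
}

read_survey_tsv <- function(name) {
  x <- read.delim(survey_file(name), sep = "\t", check.names = FALSE,
                  colClasses = "character")
  for (j in seq_along(x)) {
    v <- x[[j]]
    v[v == "n.d."] <- NA
    num <- suppressWarnings(as.numeric(v))
    x[[j]] <- if (all(is.na(num) == is.na(v))) num else {
      v2 <- v
      v2[!is.na(v)] <- v[!is.na(v)]
      v2
    }
  }
  x
}

#' @rdname survey_tables
#' @export
survey_samples <- function() read_survey_tsv("survey_samples.tsv")

#' @rdname survey_tables
#' @export
survey_haplotypes <- function() read_survey_tsv("survey_haplotypes.tsv")

#' @rdname survey_tables
#' @export
survey_gaps <- function() read_survey_tsv("survey_gaps.tsv")

#' @rdname survey_tables
#' @export
survey_methods <- function() {
  x <- read.delim(survey_file("survey_methods.tsv"), sep = "\t",
                  check.names = FALSE, colClasses = "character")
  yn <- function(v) ifelse(v %in% c("n.d.", "absent"), NA, v == "yes")
  x$hap_ok <- yn(x$hap_ok)
  x$gap_ok <- yn(x$gap_ok)
  x$ref_ok <- yn(x$ref_ok)
  x
}

#' Expand the per-species sample table to sample-level records
#'
#' Synthesizes one metadata record per individual (ids like
#' `Cedrus_atlantica_1`) from a per-species count table, for analyses that
#' need sample-level records but only species-level fixtures exist.
#'
#' @param samples data.frame with columns `family`, `species`, `n_samples`
#'   (default [survey_samples()]).
#' @return data.frame of sample records (see [validate_records()]).
#' @export
expand_records <- function(samples = survey_samples()) {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$species[i]
    data.frame(sample_id = paste0(gsub(" ", "_", s), "_",
                                  seq_len(samples$n_samples[i])),
               species = s,
               genus = strsplit(s, " ")[[1L]][1L],
               family = samples$family[i],
               stringsAsFactors = FALSE)
  })
  validate_records(do.call(rbind, rows))
}

#' Per-species haplotype status from a transcribed haplotype-count table
#'
#' Converts a [survey_haplotypes()]-shaped table into the
#' [species_haplotype_status()] layout for one marker, so transcribed
#' counts can feed [discrimination_rates()] and [method_comparison()]
#' exactly like computed ones. A species with undefined sharing (no
#' congener sampled, `NA` in the shared column) cannot share and is
#' discriminated.
#'
#' @param haplotypes data.frame (default [survey_haplotypes()]).
#' @param marker one of `"rbcL"`, `"trnH"`, `"combined"`.
#' @return data.frame in the [species_haplotype_status()] layout.
#' @export
hap_status_from_counts <- function(haplotypes = survey_haplotypes(),
                                   marker = c("combined", "rbcL", "trnH")) {
  marker <- match.arg(marker)
  uniq <- haplotypes[[paste0(marker, "_unique")]]
  shared <- haplotypes[[paste0(marker, "_shared")]]
  shared[is.na(shared)] <- 0
  data.frame(species = haplotypes$species,
             n_samples = as.integer(haplotypes$n_samples),
             n_unique_haplotypes = as.integer(uniq),
             n_shared_haplotypes = as.integer(shared),
             n_shared_samples = as.integer(haplotypes$shared_samples),
             discriminated = shared == 0,
             stringsAsFactors = FALSE)
}

#' Gap summary from a transcribed distance-extremes table
#'
#' Recomputes `gap`/`has_gap` from the `max_intra` and `min_inter` columns
#' via [barcoding_gap()] (the printed gap column is retained as
#' `gap_printed` for cross-checking).
#'
#' @param gaps data.frame (default [survey_gaps()]).
#' @return data.frame in the [species_distance_summary()] layout plus
#'   `gap_printed`.
#' @export
gap_summary_from_table <- function(gaps = survey_gaps()) {
  out <- data.frame(species = gaps$species,
                    n_samples = as.integer(gaps$n_samples),
                    max_intra = gaps$max_intra,
                    min_inter = gaps$min_inter,
                    stringsAsFactors = FALSE)
  out <- cbind(out, barcoding_gap(out$max_intra, out$min_inter))
  out$gap_printed <- gaps$gap
  out
}

#' Reference-identification status from a transcribed method table
#'
#' @param methods data.frame (default [survey_methods()]).
#' @return data.frame with columns `species`, `represented`, `correct`,
#'   matching [identification_summary()]`$species`.
#' @export
ref_status_from_table <- function(methods = survey_methods()) {
  data.frame(species = methods$species,
             represented = !is.na(methods$ref_ok),
             correct = !is.na(methods$ref_ok) & methods$ref_ok,
             stringsAsFactors = FALSE)
}
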