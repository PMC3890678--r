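#' Cross-method species identification summary
#'
#' Combines the three discrimination criteria — haplotype uniqueness,
#' barcoding gap, reference-library best match — into one per-species table
#' with a per-method efficacy line. An undefined gap (`NA`) or an
#' unrepresented species never counts as success or failure: it shrinks
#' that method's denominator.
#'
#' @param hap_statuses data.frame with columns `species`, `discriminated`
#'   (from [species_haplotype_status()] or a transcribed fixture).
#' @param gap_summaries data.frame with columns `species`, `has_gap`
#'   (logical, `NA` = not determined; from [species_distance_summary()]).
#' @param ref_statuses data.frame with columns `species`, `represented`,
#'   `correct` (from [identification_summary()]`$species` or a fixture).
#' @return list with `rows` (per species: `hap_ok`, `gap_ok`, `ref_ok`,
#'   `n_methods_ok`) and `efficacy` (named vector of percentages over each
#'   method's evaluable species, rounded to 1 decimal) plus the
#'   numerator/denominator bookkeeping in `counts`.
#' @export
method_comparison <- function(hap_statuses, gap_summaries, ref_statuses) {
  species <- sort(unique(hap_statuses$species))
  if (!setequal(species, gap_summaries$species) ||
      !setequal(species, ref_statuses$species))
    stop("the three inputs must cover the same species set")
  hap_ok <- hap_statuses$discriminated[match(species, hap_statuses$species)]
  gap_ok <- gap_summaries$has_gap[match(species, gap_summaries$species)]
  ref_i <- match(species, ref_statuses$species)
  ref_ok <- ifelse(ref_statuses$represented[ref_i],
                   ref_statuses$correct[ref_i], NA)
  ok <- cbind(hap_ok, gap_ok, ref_ok)
  rows <- data.frame(species = species, hap_ok = hap_ok, gap_ok = gap_ok,
                     ref_ok = ref_ok,
                     n_methods_ok = rowSums(ok, na.rm = TRUE),
                     stringsAsFactors = FALSE)
  num <- colSums(ok, na.rm = TRUE)
  den <- colSums(!is.na(ok))
  efficacy <- round(100 * num / den, 1)
  names(efficacy) <- names(num) <- names(den) <-
    c("haplotype", "gap", "reference")
  list(rows = rows, efficacy = efficacy,
       counts = data.frame(method = names(num), successes = unname(num),
                           evaluable = unname(den),
                           stringsAsFactors = FALSE))
}

#' Haplotype discrimination rates at three levels
#'
#' * `individual`: fraction of samples not carrying any inter-species
#'   shared haplotype.
#' * `species`: fraction of species discriminated (no shared haplotype).
#' * `species_in_multispecies_genera`: species rate after dropping species
#'   whose genus has only one sampled species (such species cannot share a
#'   congeneric haplotype, so keeping them inflates the rate).
#'
#' @param hap_statuses output of [species_haplotype_status()] (columns
#'   `species`, `n_samples`, `n_shared_samples`, `discriminated`).
#' @param records sample metadata (defines genus membership).
#' @param level one of `"individual"`, `"species"`,
#'   `"species_in_multispecies_genera"`.
#' @return percentage rounded to 1 decimal, with attributes `numerator`
#'   and `denominator`.
#' @export
discrimination_rates <- function(hap_statuses, records,
                                 level = c("individual", "species",
                                           "species_in_multispecies_genera")) {
  level <- match.arg(level)
  gn_of <- species_genus(records)
  if (level == "individual") {
    num <- sum(hap_statuses$n_samples) - sum(hap_statuses$n_shared_samples)
    den <- sum(hap_statuses$n_samples)
  } else {
    keep <- rep(TRUE, nrow(hap_statuses))
    if (level == "species_in_multispecies_genera") {
      genus <- gn_of[hap_statuses$species]
      keep <- genus %in% names(which(table(gn_of) >= 2L))
    }
    num <- sum(hap_statuses$discriminated[keep])
    den <- sum(keep)
  }
  structure(round(100 * num / den, 1), numerator = num, denominator = den)
}
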