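#' Cluster aligned sequences into exact-identity haplotypes
#'
#' Two samples share a haplotype if and only if their aligned sequences are
#' identical strings (after uppercase normalization). Gap characters and
#' ambiguity codes participate in identity: sequences differing only by a
#' gap are different haplotypes, and compatibility-based matching of
#' ambiguity codes is deliberately rejected because it would make identity
#' non-transitive and break the partition property. Cluster ids are assigned
#' by first-member input order, so they are deterministic for a given input
#' order while the partition itself is order-invariant.
#'
#' @param alignment a [marker_alignment()] or combined alignment.
#' @return object of class `haplotype_clusters`: a data.frame with columns
#'   `sample_id`, `cluster_id`, plus attributes `marker` and `n_clusters`.
#' @examples
#' aln <- marker_alignment("m", c(a = "ACGT", b = "ACGT", c = "ACGA"))
#' table(cluster_haplotypes(aln)$cluster_id)
#' @export
cluster_haplotypes <- function(alignment) {
  if (!inherits(alignment, "marker_alignment"))
    stop("'alignment' must be a marker_alignment")
  keys <- unname(alignment$seqs)
  cid <- match(keys, unique(keys))
  out <- data.frame(sample_id = alignment$samples,
                    cluster_id = as.integer(cid),
                    stringsAsFactors = FALSE)
  attr(out, "marker") <- alignment$marker
  attr(out, "n_clusters") <- length(unique(cid))
  class(out) <- c("haplotype_clusters", "data.frame")
  out
}

#' Tabulate haplotype clusters with species composition
#'
#' @param clusters output of [cluster_haplotypes()].
#' @param records sample metadata (see [validate_records()]).
#' @return data.frame with one row per cluster: `cluster_id`, `marker`,
#'   `n_members`, `member_ids`, `species_list`, `n_species`, `is_shared`
#'   (TRUE when the cluster contains more than one species).
#' @export
haplotype_table <- function(clusters, records) {
  sp <- records$species[match(clusters$sample_id, records$sample_id)]
  if (anyNA(sp))
    stop("sample(s) without metadata record: ",
         paste(clusters$sample_id[is.na(sp)], collapse = ", "))
  ids <- sort(unique(clusters$cluster_id))
  rows <- lapply(ids, function(k) {
    sel <- clusters$cluster_id == k
    spk <- sort(unique(sp[sel]))
    data.frame(cluster_id = k,
               marker = attr(clusters, "marker"),
               n_members = sum(sel),
               member_ids = paste(clusters$sample_id[sel], collapse = ","),
               species_list = paste(spk, collapse = ","),
               n_species = length(spk),
               is_shared = length(spk) > 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-species haplotype discrimination status
#'
#' Applies the shared-haplotype rule: a species is discriminated when none of
#' its haplotypes is shared with another species. `n_unique_haplotypes`
#' counts clusters containing only this species; `n_shared_haplotypes`
#' counts clusters containing this species and at least one other (a shared
#' cluster therefore appears in the count of every species involved).
#' `n_shared_samples` counts this species' individuals that carry a shared
#' haplotype, which feeds the individual-level discrimination rate.
#'
#' @param clusters output of [cluster_haplotypes()].
#' @param records sample metadata covering every clustered sample.
#' @return data.frame with columns `species`, `n_samples`,
#'   `n_unique_haplotypes`, `n_shared_haplotypes`, `n_shared_samples`,
#'   `discriminated`.
#' @export
species_haplotype_status <- function(clusters, records) {
  tab <- haplotype_table(clusters, records)
  sp <- records$species[match(clusters$sample_id, records$sample_id)]
  species <- unique(sp)
  member_species <- strsplit(tab$species_list, ",", fixed = TRUE)
  rows <- lapply(species, function(s) {
    in_cluster <- vapply(member_species, function(x) s %in% x, logical(1))
    uniq <- sum(in_cluster & !tab$is_shared)
    shared <- sum(in_cluster & tab$is_shared)
    shared_ids <- tab$cluster_id[in_cluster & tab$is_shared]
    n_shared_samples <- sum(sp == s & clusters$cluster_id %in% shared_ids)
    data.frame(species = s,
               n_samples = sum(sp == s),
               n_unique_haplotypes = uniq,
               n_shared_haplotypes = shared,
               n_shared_samples = n_shared_samples,
               discriminated = shared == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$species), , drop = FALSE]
}
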