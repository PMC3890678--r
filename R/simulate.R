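#' Configuration for a synthetic barcode community
#'
#' Describes a multi-genus community evolved on star phylogenies: one
#' ancestral sequence per genus and marker, species ancestors derived by
#' per-site substitution with probability `m_species`, individuals derived
#' from their species ancestor with probability `m_individual` (a
#' substituted site moves uniformly to one of the 3 other bases; at most
#' one hit per branch, adequate at barcode-scale divergences). Haplotype
#' sharing between congeneric species is modelled as exact identity:
#' `share_pairs` makes the second species copy the first species' ancestor.
#' `indels` injects species-fixed deletion runs. `mask_species` lists
#' species omitted from the reference library (database incompleteness).
#'
#' Defaults emulate a small temperate-tree barcode survey: a few genera
#' with 1-4 congeneric species and 1-5 individuals each, a slow coding
#' marker and a fast spacer, interspecific divergence well above
#' intraspecific (p-distances of order 0.01 vs 0.001).
#'
#' @param genera data.frame with columns `genus`, `n_species`,
#'   `n_individuals` (per species).
#' @param markers named integer vector of alignment lengths,
#'   `marker = columns`.
#' @param m_species,m_individual per-site substitution probabilities in
#'   `[0, 0.75]` on the species and individual branches.
#' @param share_pairs list of length-2 character vectors of congeneric
#'   species names forced to share their ancestor haplotype.
#' @param indels data.frame with columns `species`, `marker`, `start`,
#'   `end` (0-based, half-open): fixed deletions applied to every
#'   individual of the species.
#' @param mask_species species excluded from the reference library.
#' @param seed mandatory integer seed; the whole community is reproducible
#'   from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genera = data.frame(
                         genus = c("GenusA", "GenusB", "GenusC"),
                         n_species = c(3L, 2L, 1L),
                         n_individuals = c(3L, 3L, 4L)),
                       markers = c(rbcL = 688L, `trnH-psbA` = 500L),
                       m_species = 0.02, m_individual = 0.001,
                       share_pairs = list(),
                       indels = NULL,
                       mask_species = character(0),
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' is mandatory and must be a single integer")
  for (m in c(m_species, m_individual))
    if (m < 0 || m > 0.75)
      stop("substitution probabilities must lie in [0, 0.75]")
  if (is.null(names(markers)) || any(markers < 1L))
    stop("'markers' must be a named vector of positive lengths")
  stopifnot(all(c("genus", "n_species", "n_individuals") %in% names(genera)))
  species <- unlist(lapply(seq_len(nrow(genera)), function(i)
    paste0(genera$genus[i], "_sp", seq_len(genera$n_species[i]))))
  for (p in share_pairs) {
    if (length(p) != 2L || !all(p %in% species))
      stop("share_pairs entries must name two simulated species")
    if (!identical(sub("_sp\\d+$", "", p[1L]), sub("_sp\\d+$", "", p[2L])))
      stop("share_pairs must be congeneric: ", paste(p, collapse = ", "))
  }
  if (!is.null(indels)) {
    stopifnot(all(c("species", "marker", "start", "end") %in% names(indels)))
    for (i in seq_len(nrow(indels))) {
      L <- markers[[indels$marker[i]]]
      if (is.null(L) || is.na(L))
        stop("indel for unknown marker: ", indels$marker[i])
      if (indels$start[i] < 0L || indels$end[i] > L ||
          indels$start[i] >= indels$end[i])
        stop("invalid indel interval [", indels$start[i], ",",
             indels$end[i], ") for marker ", indels$marker[i])
      if (!indels$species[i] %in% species)
        stop("indel for unknown species: ", indels$species[i])
    }
  }
  structure(list(genera = genera, markers = markers,
                 m_species = m_species, m_individual = m_individual,
                 share_pairs = share_pairs, indels = indels,
                 mask_species = mask_species,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# mutate each site with probability m, uniformly to one of the 3 other bases
mutate_sites <- function(chars, m) {
  if (m == 0) return(chars)
  hit <- which(runif(length(chars)) < m)
  if (!length(hit)) return(chars)
  shift <- sample.int(3L, length(hit), replace = TRUE)
  idx <- match(chars[hit], BV_BASES)
  chars[hit] <- BV_BASES[((idx - 1L + shift) %% 4L) + 1L]
  chars
}

#' Simulate an aligned multi-genus barcode community
#'
#' Draws genus ancestors uniformly over `{A,C,G,T}`, evolves species and
#' individual sequences per [sim_config()], applies haplotype sharing and
#' fixed deletions, and assembles sample metadata, per-marker alignments
#' and a reference library per marker (all individuals minus
#' `mask_species`). Byte-identical outputs for identical configs; the
#' caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return list with `records` (data.frame), `alignments` (named list of
#'   [marker_alignment()]) and `libraries` (named list of
#'   [reference_library()]).
#' @examples
#' sim <- simulate_community(sim_config(seed = 1))
#' sim$alignments$rbcL
#' @export
simulate_community <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  g <- config$genera
  records <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    sp <- paste0(g$genus[i], "_sp", seq_len(g$n_species[i]))
    do.call(rbind, lapply(sp, function(s)
      data.frame(sample_id = paste0(s, "_", seq_len(g$n_individuals[i])),
                 species = s, genus = g$genus[i],
                 family = paste0(g$genus[i], "aceae"),
                 stringsAsFactors = FALSE)))
  }))

  alignments <- lapply(names(config$markers), function(mk) {
    L <- config$markers[[mk]]
    seqs <- character(0)
    for (i in seq_len(nrow(g))) {
      ancestor <- sample(BV_BASES, L, replace = TRUE)
      sp_names <- paste0(g$genus[i], "_sp", seq_len(g$n_species[i]))
      sp_anc <- lapply(sp_names, function(s)
        mutate_sites(ancestor, config$m_species))
      names(sp_anc) <- sp_names
      for (p in config$share_pairs)
        if (all(p %in% sp_names)) sp_anc[[p[2L]]] <- sp_anc[[p[1L]]]
      for (s in sp_names) {
        anc <- sp_anc[[s]]
        for (j in seq_len(g$n_individuals[i])) {
          ind <- mutate_sites(anc, config$m_individual)
          seqs[paste0(s, "_", j)] <- paste(ind, collapse = "")
        }
      }
    }
    if (!is.null(config$indels)) {
      iv <- config$indels[config$indels$marker == mk, , drop = FALSE]
      for (r in seq_len(nrow(iv))) {
        ids <- records$sample_id[records$species == iv$species[r]]
        for (id in ids) {
          s <- strsplit(seqs[[id]], "")[[1L]]
          s[(iv$start[r] + 1L):iv$end[r]] <- "-"
          seqs[id] <- paste(s, collapse = "")
        }
      }
    }
    marker_alignment(mk, seqs)
  })
  names(alignments) <- names(config$markers)

  libraries <- lapply(alignments, library_from_alignment,
                      records = records,
                      mask_species = config$mask_species)
  list(records = records, alignments = alignments, libraries = libraries)
}

#' Expected p-distance between two lineages from a common ancestor
#'
#' For two lineages independently substituting from a common ancestor with
#' per-site probabilities `m_a` and `m_b` (uniform over the 3 alternative
#' bases, single hit per branch), the probability that a site ends up
#' different between the lineages is
#' `1 - ((1 - m_a) (1 - m_b) + m_a m_b / 3)`: either neither lineage
#' changed, or both changed and collided on the same base (probability 1/3
#' given both changed).
#'
#' @param m_a,m_b per-site substitution probabilities in `[0, 0.75]`.
#' @return expected uncorrected p-distance.
#' @examples
#' expected_pairwise_distance(0.1, 0.1)  # 0.1866667
#' @export
expected_pairwise_distance <- function(m_a, m_b) {
  for (m in c(m_a, m_b))
    if (!is.numeric(m) || m < 0 || m > 0.75)
      stop("substitution probabilities must lie in [0, 0.75]")
  1 - ((1 - m_a) * (1 - m_b) + m_a * m_b / 3)
}
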