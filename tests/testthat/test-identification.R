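test_that("score_pair counts exact base matches over mutually unambiguous columns", {
  expect_equal(score_pair(strrep("ACGT", 25), strrep("ACGT", 25)), 100)
  expect_equal(score_pair("ACGT", "ACGA"), 3)
  expect_equal(score_pair("AC-T", "ACGT"), 3)  # gap column is skipped
  expect_equal(score_pair("ANGT", "ANGT"), 3)     # N never matches
  expect_true(is.na(score_pair("----", "ACGT")))  # no comparable column
  expect_error(score_pair("ACG", "ACGT"), "equal aligned length")
})

test_that("score is matches = compared - mismatches against the distances module", {
  set.seed(55)
  seqs <- random_rows(10, 60, gap_prob = 0.1)
  aln <- marker_alignment("m", seqs)
  d <- p_distance_matrix(aln, "pairwise_deletion")
  for (i in 1:9) for (j in (i + 1):10) {
    comp <- d$sites[i, j]
    expect_equal(score_pair(seqs[[i]], seqs[[j]]),
                 comp - round(d$d[i, j] * comp))
  }
})

ref_toy <- function() {
  reference_library("m",
    c(r1 = "ACGTACGTAC", r2 = "ACGTACGTAA", r3 = "TTTTACGTAC",
      r4 = "TTTTACGTAA"),
    c("Ga one", "Ga one", "Ga two", "Gb one"))
}

test_that("best-match identification statuses follow the tie-is-failure rule", {
  lib <- ref_toy()
  # unique top conspecific hit
  r <- identify_query("ACGTACGTAC", "Ga one", lib, "q1")
  expect_equal(r$status, "correct")
  expect_equal(r$top_species, "Ga one")
  expect_true(r$genus_correct)

  # equidistant from two species: ambiguous even though the true one is top
  r2 <- identify_query("TTTTACGTAG", "Ga two", lib, "q2")
  expect_equal(r2$status, "ambiguous")
  expect_equal(r2$top_species, "Ga two,Gb one")
  expect_false(r2$genus_correct)

  # true species represented but outscored
  r3 <- identify_query("TTTTACGTAC", "Ga one", lib, "q3")
  expect_equal(r3$status, "wrong")

  # true species absent from the library, congener top: genus-level rescue
  r4 <- identify_query("ACGTACGTAC", "Ga three", lib, "q4")
  expect_equal(r4$status, "unrepresented")
  expect_true(r4$genus_correct)

  expect_error(identify_query("ACGT", "x", lib, marker = "other"),
               "marker mismatch")
  expect_error(identify_query("ACGT", "x", reference_library("m",
    character(0), character(0))), "empty")
})

test_that("identification is deterministic under library entry permutation", {
  set.seed(88)
  seqs <- random_rows(20, 30)
  sp <- paste("Gen", rep(1:5, each = 4))
  q <- random_rows(1, 30)[[1]]
  base <- identify_query(q, "Gen 1", reference_library("m", seqs, sp))
  for (i in 1:10) {
    perm <- sample(20)
    r <- identify_query(q, "Gen 1",
                        reference_library("m", seqs[perm], sp[perm]))
    expect_equal(r[, c("top_score", "top_species", "status")],
                 base[, c("top_score", "top_species", "status")])
  }
})

test_that("leave-one-out: distinct fixed haplotypes identify perfectly, shared ones fail", {
  seqs <- c(A1 = "ACGTACGTAC", A2 = "ACGTACGTAC",
            B1 = "ACGTACGTTT", B2 = "ACGTACGTTT")
  rec <- data.frame(sample_id = names(seqs),
                    species = rep(c("G one", "G two"), each = 2),
                    genus = "G", family = "F")
  loo <- leave_one_out(marker_alignment("m", seqs), rec)
  expect_equal(loo$status, rep("correct", 4))

  # species pair sharing one haplotype: carriers ambiguous
  seqs2 <- seqs; seqs2["B1"] <- seqs2[["A1"]]
  loo2 <- leave_one_out(marker_alignment("m", seqs2), rec)
  expect_true(all(loo2$status[c(1, 2, 3)] %in% c("ambiguous", "wrong")))

  # singleton species is unrepresented once left out
  seqs3 <- c(seqs, C1 = "GGGGACGTAC")
  rec3 <- rbind(rec, data.frame(sample_id = "C1", species = "G three",
                                genus = "G", family = "F"))
  loo3 <- leave_one_out(marker_alignment("m", seqs3), rec3)
  expect_equal(loo3$status[loo3$sample_id == "C1"], "unrepresented")
})

test_that("summary counts a species correct only when all queries are correct", {
  res <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "c1"),
    true_species = c("S a", "S a", "S b", "S b", "S c"),
    top_score = 1,
    top_species = c("S a", "S b", "S b", "S b", "S x"),
    status = c("correct", "wrong", "correct", "correct", "unrepresented"),
    genus_correct = TRUE)
  rec <- data.frame(sample_id = res$sample_id, species = res$true_species,
                    genus = "S", family = "F")
  s <- identification_summary(res, rec)
  expect_equal(s$species$correct[s$species$species == "S a"], FALSE)
  expect_equal(s$species$correct[s$species$species == "S b"], TRUE)
  expect_equal(s$species$represented[s$species$species == "S c"], FALSE)
  expect_equal(s$n_represented, 2)
  expect_equal(s$efficacy_represented_pct, 50)
  expect_equal(s$efficacy_all_pct, round(100 / 3, 1))
})

test_that("masking k species changes only the all-species denominator rate", {
  for (seed in 1:5) {
    cfg <- sim_config(
      genera = data.frame(genus = "G", n_species = 4L, n_individuals = 3L),
      markers = c(m = 300L), m_species = 0.05, m_individual = 0.001,
      seed = seed)
    sim <- simulate_community(cfg)
    aln <- sim$alignments$m

    full <- identification_summary(leave_one_out(aln, sim$records),
                                   sim$records)
    # model library absence of one species: all its queries unrepresented
    masked_sp <- "G_sp2"
    res <- lapply(seq_along(aln$samples), function(i) {
      sp <- sim$records$species[match(aln$samples, sim$records$sample_id)]
      keep <- seq_along(aln$samples) != i & sp != masked_sp
      identify_query(aln$seqs[[i]], sp[i],
                     reference_library("m", aln$seqs[keep], sp[keep]),
                     query_id = aln$samples[i])
    })
    masked <- identification_summary(do.call(rbind, res), sim$records)
    # at this divergence every represented species is correct, so the
    # represented-species rate is unchanged while the all-species rate
    # drops by exactly one species in the numerator
    n_corr_mask <- sum(masked$species$correct)
    expect_equal(full$efficacy_represented_pct, 100)
    expect_equal(masked$efficacy_represented_pct, 100)
    expect_equal(masked$n_represented, full$n_represented - 1)
    expect_equal(n_corr_mask, sum(full$species$correct) - 1)
    expect_equal(masked$efficacy_all_pct, round(100 * n_corr_mask / 4, 1))
  }
})
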