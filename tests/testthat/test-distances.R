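test_that("p-distance basics: mismatch fraction, gap handling by policy", {
  expect_equal(p_distance_matrix(
    marker_alignment("m", c(a = "ACGT", b = "ACGA")))$d["a", "b"], 0.25)

  # complete deletion drops the gapped column for everyone
  d <- p_distance_matrix(marker_alignment("m", c(a = "AC-T", b = "ACGT")),
                         "complete_deletion")
  expect_equal(d$d["a", "b"], 0)
  expect_equal(d$sites["a", "b"], 3)

  # identical rows are at distance zero
  d0 <- p_distance_matrix(marker_alignment("m", c(a = "ACGT", b = "ACGT")))
  expect_equal(d0$d["a", "b"], 0)

  # a column gapped in a third row is still dropped for all pairs
  d3 <- p_distance_matrix(
    marker_alignment("m", c(a = "ACGT", b = "ACGA", c = "AC-T")),
    "complete_deletion")
  expect_equal(d3$sites["a", "b"], 3)
  expect_equal(d3$d["a", "b"], 1 / 3)
  # pairwise deletion keeps it for the a-b pair
  dp <- p_distance_matrix(
    marker_alignment("m", c(a = "ACGT", b = "ACGA", c = "AC-T")),
    "pairwise_deletion")
  expect_equal(dp$sites["a", "b"], 4)
  expect_equal(dp$d["a", "b"], 0.25)

  expect_error(p_distance_matrix(
    marker_alignment("m", c(a = "A-", b = "-C")), "complete_deletion"),
    "zero comparable")
  expect_error(p_distance_matrix(
    marker_alignment("m", c(a = "A-", b = "-C")), "pairwise_deletion"),
    "zero comparable sites between")
})

test_that("p-distance equals a brute-force mismatch counter on random data", {
  set.seed(77)
  seqs <- random_rows(12, 50, gap_prob = 0.08,
                      alphabet = c("A", "C", "G", "T", "N"))
  aln <- marker_alignment("m", seqs)
  for (policy in c("complete_deletion", "pairwise_deletion")) {
    got <- p_distance_matrix(aln, policy)
    rows <- if (policy == "complete_deletion") {
      m <- do.call(rbind, strsplit(seqs, ""))
      keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
      apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
    } else seqs
    for (i in 1:11) for (j in (i + 1):12) {
      o <- oracle_pair_p(rows[[i]], rows[[j]])
      expect_equal(got$d[i, j], o["mism"] / o["comp"], ignore_attr = TRUE)
      expect_equal(got$sites[i, j], unname(o["comp"]))
    }
  }
})

test_that("p-distance agrees with ape::dist.dna on gap-free data", {
  skip_if_not_installed("ape")
  set.seed(123)
  seqs <- random_rows(10, 200)
  aln <- marker_alignment("m", seqs)
  mine <- p_distance_matrix(aln)$d
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw"))
  expect_equal(unname(mine), unname(ref[rownames(mine), colnames(mine)]),
               tolerance = 1e-12)
})

test_that("p-distance is a semimetric on gap-free data", {
  set.seed(9)
  seqs <- random_rows(8, 30)
  d <- p_distance_matrix(marker_alignment("m", seqs))$d
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # identity of indiscernibles: zero distance iff identical rows
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(d[i, j] == 0, seqs[[i]] == seqs[[j]])
})

test_that("appending identical columns dilutes distance by exact arithmetic", {
  set.seed(31)
  seqs <- random_rows(4, 20)
  aln <- marker_alignment("m", seqs)
  base <- p_distance_matrix(aln)
  extra <- strrep("ACGTT", 2)  # same 10 columns appended to every row
  aug <- marker_alignment("m", vapply(seqs, paste0, character(1), extra))
  got <- p_distance_matrix(aug)
  expect_equal(got$d, base$d * 20 / 30)
})

test_that("barcoding gap: strict positivity, undefined propagation", {
  g <- barcoding_gap(c(0, 0.0015, 0.002898554, NA, 0),
                     c(0.0064, 0.0015, 0.000950571, 0.0142, NA))
  expect_equal(round(g$gap, 4), c(0.0064, 0, -0.0019, NA, NA))
  expect_equal(g$has_gap, c(TRUE, FALSE, FALSE, NA, NA))
  expect_error(barcoding_gap(1, c(1, 2)), "equal length")
})

test_that("species gap summary restricts min_inter to congeners and marks n.d.", {
  seqs <- c(A1 = "AAAAAAAAAA", A2 = "AAAAAAAAAC",  # intra 0.1
            B1 = "AAAAAAAAAA",                     # congener at 0
            C1 = "TTTTTAAAAA", C2 = "TTTTTAAAAA",  # other genus
            D1 = "TTTTCAAAAA")
  rec <- data.frame(
    sample_id = names(seqs),
    species = c("Ga one", "Ga one", "Ga two", "Gb one", "Gb one", "Gb two"),
    genus = c("Ga", "Ga", "Ga", "Gb", "Gb", "Gb"),
    family = "F")
  ss <- species_distance_summary(
    p_distance_matrix(marker_alignment("m", seqs)), rec)
  a <- ss[ss$species == "Ga one", ]
  expect_equal(a$max_intra, 0.1)
  expect_equal(a$min_inter, 0)       # to congener B1 only
  expect_false(a$has_gap)
  # singleton species: intra undefined
  b <- ss[ss$species == "Ga two", ]
  expect_true(is.na(b$max_intra) && is.na(b$gap))
  expect_equal(b$min_inter, 0)
  # genus singleton: drop genus Gb congeners -> test via genus-only species
  rec2 <- rec; rec2$genus[rec2$sample_id == "D1"] <- "Gc"
  rec2$species[rec2$sample_id == "D1"] <- "Gc one"
  ss2 <- species_distance_summary(
    p_distance_matrix(marker_alignment("m", seqs)), rec2)
  d <- ss2[ss2$species == "Gc one", ]
  expect_true(is.na(d$min_inter) && is.na(d$gap))
})

test_that("the survey gap table reproduces printed gaps and the 5 gap species", {
  g <- gap_summary_from_table()
  defined <- !is.na(g$gap_printed)
  expect_equal(round(g$gap[defined], 4), g$gap_printed[defined])
  expect_identical(is.na(g$gap), is.na(g$gap_printed))
  expect_setequal(g$species[which(g$has_gap)],
                  c("Cedrus deodara", "Cedrus libani", "Sorbus torminalis",
                    "Aesculus hippocastanus", "Aesculus indica"))
  expect_equal(sum(!is.na(g$has_gap)), 19)
})
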