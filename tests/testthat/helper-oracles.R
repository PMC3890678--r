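# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest possible route (character loops, all-pairs comparisons)
# so they share no code with the implementation they check.

# random aligned sequences, optionally gapped
random_rows <- function(n, len, gap_prob = 0, alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, len, replace = TRUE)
    if (gap_prob > 0) ch[runif(len) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(n))
  seqs
}

# equivalence classes by all-pairs string comparison (union-find)
oracle_partition <- function(seqs) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && seqs[[i]] == seqs[[j]]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(names(seqs), roots)
}

# per-pair mismatch/compared-site count by plain character loop
oracle_pair_p <- function(a, b, bases = c("A", "C", "G", "T")) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mism <- 0L; comp <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] %in% bases && cb[k] %in% bases) {
      comp <- comp + 1L
      if (ca[k] != cb[k]) mism <- mism + 1L
    }
  }
  c(mism = mism, comp = comp)
}

# maximal gap runs via regex scan
oracle_gap_runs <- function(seq) {
  m <- gregexpr("-+", seq)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# small two-genus toy community used by several modules
toy_dataset <- function() {
  seqs <- c(A1 = "ACGTACGTAC", A2 = "ACGTACGTAC", A3 = "ACGTACGAAC",
            B1 = "ACTTACGTAC", B2 = "ACTTACGTAC",
            C1 = "GGGTACGTAC")
  records <- data.frame(
    sample_id = names(seqs),
    species = c("Alpha one", "Alpha one", "Alpha one",
                "Alpha two", "Alpha two", "Beta one"),
    genus = c("Alpha", "Alpha", "Alpha", "Alpha", "Alpha", "Beta"),
    family = "Fam",
    stringsAsFactors = FALSE)
  list(alignment = marker_alignment("toy", seqs), records = records)
}
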