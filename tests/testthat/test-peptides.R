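test_that("query panel has the stated composition and is seed-stable", {
  q <- random_query_sequences(42)
  expect_length(q, 30)
  expect_equal(as.vector(table(nchar(q))), c(10, 10, 10))
  expect_equal(sort(unique(nchar(q))), c(10, 20, 30))
  expect_identical(q, random_query_sequences(42))
  expect_false(identical(q, random_query_sequences(43)))
  expect_true(all(strsplit(paste(q, collapse = ""), "")[[1]] %in%
                    PEPTIDE_ALPHABET))
})

test_that("residues are drawn uniformly", {
  # pooled residue frequencies across a large panel: chi-square GOF at 1%
  q <- random_query_sequences(99, n_per_length = 500, lengths = c(10, 20))
  res <- strsplit(paste(q, collapse = ""), "")[[1]]
  counts <- table(factor(res, levels = PEPTIDE_ALPHABET))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("peptide SMILES assembly follows condensation arithmetic", {
  # glycine, protonated: C2H6NO2+
  g <- smi_standardize(peptide_to_smiles("G"))
  expect_equal(g$n_atoms, 5)
  expect_equal(sum(g$elements == "C"), 2)
  expect_equal(sum(g$elements == "N"), 1)
  expect_equal(sum(g$elements == "O"), 2)
  expect_equal(sum(g$hcount), 6)
  expect_equal(sum(g$charge), 1)
  # di-glycine: 9 heavy atoms (one water lost)
  expect_equal(smi_standardize(peptide_to_smiles("GG"))$n_atoms, 9)
  # heavy atoms strictly increase with length for a fixed residue
  ha <- vapply(1:5, function(L) {
    smi_standardize(peptide_to_smiles(strrep("A", L)))$n_atoms
  }, integer(1))
  expect_true(all(diff(ha) > 0))
  expect_error(peptide_to_smiles("ACDEFGHIJ"), class = "mapfp_alphabet_error")
  expect_error(peptide_to_smiles(""), class = "mapfp_alphabet_error")
})

test_that("chain heavy atoms equal residue sums minus condensation waters", {
  heavy1 <- residue_heavy_atoms()
  withr::with_seed(4, {
    for (i in 1:5) {
      L <- sample(3:8, 1)
      seqn <- paste(sample(PEPTIDE_ALPHABET, L, replace = TRUE),
                    collapse = "")
      got <- smi_standardize(peptide_to_smiles(seqn))$n_atoms
      res <- strsplit(seqn, "")[[1]]
      # internal residues lose the N-terminal proton charge but no heavy
      # atoms; each bond loses one oxygen
      expect_equal(got, sum(heavy1[res]) - (L - 1), label = seqn)
    }
  })
  # proline participates correctly in chains
  expect_gt(smi_standardize(peptide_to_smiles("PGP"))$n_atoms, 10)
  # unprotonated variant is neutral
  m <- smi_standardize(peptide_to_smiles("KR", protonate = FALSE))
  expect_equal(sum(m$charge), 0)
})

test_that("scrambled sets are unique permutations excluding the query", {
  q <- "ACDEFGHIKL"
  set <- generate_scrambled_set(q, n = 500, seed = 7)
  expect_s3_class(set, "map_benchmark_set")
  m <- set$members$sequence
  expect_length(m, 500)
  expect_false(anyDuplicated(m) > 0)
  expect_false(q %in% m)
  sorted_q <- paste(sort(strsplit(q, "")[[1]]), collapse = "")
  resort <- vapply(strsplit(m, ""), function(x) {
    paste(sort(x), collapse = "")
  }, character(1))
  expect_true(all(resort == sorted_q))
  # reproducibility: (query, kind, seed) determines the member list
  expect_identical(m, generate_scrambled_set(q, n = 500, seed = 7)$members$sequence)
  expect_false(identical(m, generate_scrambled_set(q, n = 500, seed = 8)$members$sequence))
  expect_error(generate_scrambled_set("AAAAAAAAAA"),
               class = "mapfp_insufficient_diversity")
})

test_that("mutated sets follow the per-k ceiling rule and Hamming distances", {
  q <- "ACDEFGHIKL" # L = 10
  set <- generate_mutated_set(q, cap = 100, seed = 3)
  m <- set$members
  expect_equal(nrow(m), 100)
  expect_equal(as.vector(table(m$k)), rep(10, 10)) # ceiling(100/10) per k
  expect_false(anyDuplicated(m$sequence) > 0)
  qres <- strsplit(q, "")[[1]]
  hamming <- vapply(strsplit(m$sequence, ""), function(x) {
    sum(x != qres)
  }, integer(1))
  expect_equal(hamming, m$k)
  expect_identical(m, generate_mutated_set(q, cap = 100, seed = 3)$members)
  # truncation: L = 7 with cap 100 -> ceiling(100/7) = 15 per k, 105 -> 100
  set7 <- generate_mutated_set("ACDEFGH", cap = 100, seed = 3)
  expect_equal(nrow(set7$members), 100)
  expect_equal(sum(set7$members$k == 7), 100 - 6 * 15)
  # combinatorial ceiling: a 2-mer has only 2 * 19 = 38 single mutants
  set2 <- generate_mutated_set("AC", cap = 100, seed = 3)
  expect_equal(sum(set2$members$k == 1), 38)
  expect_equal(sum(set2$members$k == 2), 50)
  expect_false(anyDuplicated(set2$members$sequence) > 0)
})

test_that("identity stub labeller partitions members and is pluggable", {
  set <- generate_scrambled_set("ACDEFGHIKLMNPQRSTVWY", n = 300, seed = 1)
  lab <- identity_label(set, threshold = 0.25)
  expect_true(all(lab$members$label %in% c("active", "decoy")))
  expect_equal(sum(lab$members$label == "active") +
                 sum(lab$members$label == "decoy"), 300)
  # threshold 0 labels everything active; threshold 1 nothing
  expect_true(all(identity_label(set, 0)$members$label == "active"))
  expect_true(all(identity_label(set, 1)$members$label == "decoy"))
})

test_that("BLAST labelling marks near-identical members active", {
  skip_if(!nzchar(Sys.which("blastp")), "blastp not on PATH")
  q <- random_query_sequences(12)[["q20_01"]]
  set <- generate_mutated_set(q, cap = 200, seed = 5)
  lab <- blast_label(set)
  expect_true(all(lab$members$label %in% c("active", "decoy")))
  # single-point mutants of a 20-mer are unambiguous BLAST hits
  k1 <- lab$members$label[lab$members$k == 1]
  expect_true(mean(k1 == "active") > 0.9)
  # distant mutants are decoys
  kmax <- lab$members$label[lab$members$k >= 18]
  expect_true(mean(kmax == "decoy") > 0.9)
  expect_s3_class(attr(lab, "blast_report"), "data.frame")
})
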