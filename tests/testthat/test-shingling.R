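test_that("standardization canonicalizes, strips stereo, keeps largest fragment", {
  m <- smi_standardize("CCO")
  expect_s3_class(m, "map_mol")
  expect_equal(m$n_atoms, 3)
  expect_equal(m$canonical_smiles, "CCO")

  # methane: below the 2-heavy-atom filter
  expect_error(smi_standardize("C"), class = "mapfp_too_small")
  expect_error(smi_standardize("not a smiles"),
               class = "mapfp_invalid_structure")
  expect_error(smi_standardize(""), class = "mapfp_invalid_structure")

  # sodium acetate: acetate fragment (4 heavy atoms) survives
  m2 <- smi_standardize("[Na+].CC(=O)[O-]")
  expect_equal(m2$n_atoms, 4)
  expect_equal(sum(m2$charge), -1)

  # stereo descriptors removed: same canonical form as the flat molecule
  flat <- smi_standardize("CC(N)C(=O)O")$canonical_smiles
  expect_equal(smi_standardize("C[C@H](N)C(=O)O")$canonical_smiles, flat)
  expect_equal(smi_standardize("C[C@@H](N)C(=O)O")$canonical_smiles, flat)
  expect_equal(smi_standardize("F/C=C/F")$canonical_smiles,
               smi_standardize("FC=CF")$canonical_smiles)
})

test_that("stereo stripping agrees with the OpenBabel -xi oracle", {
  skip_if(!nzchar(Sys.which("obabel")), "obabel CLI not on PATH")
  cases <- c("C[C@H](N)C(=O)O", "F/C=C\\F", "O[C@@H]1CC[C@H](O)CC1")
  for (s in cases) {
    ours <- smi_standardize(s)$canonical_smiles
    ob <- system2("obabel", c(shQuote(paste0("-:", s)), "-ocan", "-xi"),
                  stdout = TRUE, stderr = FALSE)
    oracle <- smi_standardize(trimws(ob[1]), strip_stereo = FALSE)
    expect_equal(ours, oracle$canonical_smiles, label = s)
  }
})

test_that("topological distances are shortest-path bond counts", {
  d <- topological_distances("CCO")
  expect_equal(d, matrix(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L), 3))
  # cyclohexane: opposite atoms at distance 3 (shorter way round the ring)
  d6 <- topological_distances("C1CCCCC1")
  expect_true(all(diag(d6) == 0))
  expect_equal(d6, t(d6))
  expect_equal(max(d6), 3L)
  expect_equal(sort(unique(as.vector(d6))), 0:3)
})

test_that("environment SMILES are rooted, symmetric-equivalent, and saturate", {
  benz <- smi_standardize("c1ccccc1")
  for (r in 1:3) {
    envs <- vapply(1:6, function(i) {
      circular_environment_smiles(benz, i, r)
    }, character(1))
    expect_length(unique(envs), 1)
  }
  # radius ball covering the molecule: same string for all larger radii
  eth <- smi_standardize("CCO")
  full <- circular_environment_smiles(eth, 1, 2)
  expect_equal(circular_environment_smiles(eth, 1, 5), full)
  expect_equal(circular_environment_smiles(eth, 1, 10), full)
  # rooted: the string starts at the center atom (terminal C -> "CCO")
  expect_equal(full, "CCO")
  expect_equal(circular_environment_smiles(eth, 3, 5), "OCC")
  expect_error(circular_environment_smiles(eth, 7, 1), "out of range")
})

test_that("shingle sets follow the grammar and counting bound", {
  mols <- fixture_smiles(15)
  for (s in mols) {
    m <- smi_standardize(s)
    for (r in c(1, 2)) {
      sh <- shingle_set(m, r)
      expect_gt(length(sh), 0)
      expect_lte(length(sh), r * m$n_atoms * (m$n_atoms - 1) / 2)
      expect_false(anyDuplicated(sh) > 0)
      parts <- strsplit(sh, "|", fixed = TRUE)
      expect_true(all(lengths(parts) == 3))
      f1 <- vapply(parts, `[[`, character(1), 1)
      f2 <- vapply(parts, `[[`, character(1), 2)
      f3 <- vapply(parts, `[[`, character(1), 3)
      expect_true(all(f1 <= f3))
      expect_true(all(grepl("^[0-9]+$", f2)))
      expect_true(all(as.integer(f2) >= 1))
    }
  }
})

test_that("shingle sets match hand-enumerable cases", {
  # CCO at r = 2: 3 pairs x 2 radii, all distinct
  expect_length(shingle_set("CCO", 2), 6)
  # CCC at r = 1: the two terminal pairs give the same shingle
  sh <- shingle_set("CCC", 1)
  expect_length(sh, 2)
  # two runs are byte-identical
  expect_identical(shingle_set("CCC", 1), sh)
})

test_that("shingling is invariant to input atom ordering", {
  mols <- fixture_smiles(10, seed = 21)
  rends <- rdkit_random_renderings(unname(mols), n_each = 5)
  for (i in seq_along(mols)) {
    ref <- shingle_set(mols[[i]], 2)
    for (alt in rends[[i]]) {
      expect_identical(shingle_set(alt, 2), ref, label = alt)
    }
  }
})

test_that("corpus shingle statistics use set semantics", {
  # duplicate molecule adds nothing
  once <- corpus_unique_shingles("CCO", r = 2)
  twice <- corpus_unique_shingles(c("CCO", "CCO"), r = 2)
  expect_equal(once$n_unique, twice$n_unique)
  # union oracle
  u <- corpus_unique_shingles(c("CCO", "CCC"), r = 2)
  expect_equal(u$n_unique,
               length(union(shingle_set("CCO", 2), shingle_set("CCC", 2))))
  # empty corpus
  e <- corpus_unique_shingles(character(0), r = 2)
  expect_equal(e$n_unique, 0)
  # bad lines are skipped and counted
  suppressWarnings({
    b <- corpus_unique_shingles(c("CCO", "xxxx-no", "CCC"), r = 2)
  })
  expect_equal(b$n_skipped, 1)
  expect_equal(b$n_parsed, 2)
  expect_equal(b$n_unique, u$n_unique)
  # document frequency: each molecule counts a shingle once
  f <- corpus_unique_shingles(c("CCO", "CCO", "CCC"), r = 1,
                              frequency = TRUE)
  expect_true(all(f$frequency <= 3))
  shared <- intersect(shingle_set("CCO", 1), shingle_set("CCC", 1))
  expect_equal(sum(f$frequency == 3), length(shared))
})
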