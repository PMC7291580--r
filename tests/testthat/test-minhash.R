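test_that("SHA-1 truncation is pinned and collision-scarce", {
  # standard test vector: SHA-1("abc") starts 0xA9993E36
  expect_equal(hash_shingle("abc"), 2845392438)
  expect_equal(hash_shingle("abc"), hash_shingle("abc"))
  expect_error(hash_shingle(""), "empty")
  # birthday bound: a million random shingles stay almost all distinct
  x <- sprintf("shingle-%d", seq_len(1e6))
  h <- hash_shingle(x)
  expect_gte(length(unique(h)), 999800)
  expect_true(all(h >= 0 & h < 2^32))
})

test_that("MinHash components follow the universal-hash formula", {
  seeds <- structure(list(a = 3, b = 7, d = 1L, seed = 0L),
                     class = "map_seeds")
  f <- minhash_fingerprint(5, seeds)
  expect_equal(f$values, 22) # (3*5 + 7) mod p mod m
  # exactness at the top of the 32-bit range (products exceed 64 bits);
  # expected values computed with arbitrary-precision integer arithmetic
  big <- 2^32 - 1
  seeds2 <- structure(list(a = big, b = big, d = 1L, seed = 0L),
                      class = "map_seeds")
  expect_equal(minhash_fingerprint(big, seeds2)$values, 536870918)
  seeds3 <- structure(list(a = 1234567891, b = 987654321, d = 1L, seed = 0L),
                      class = "map_seeds")
  expect_equal(minhash_fingerprint(4019283471, seeds3)$values, 3945299200)
  expect_error(minhash_fingerprint(numeric(0), hash_seeds(8)),
               class = "mapfp_empty_fingerprint")
})

test_that("seed generation is reproducible and in range", {
  s1 <- hash_seeds(256, 42)
  s2 <- hash_seeds(256, 42)
  expect_identical(s1, s2)
  expect_false(identical(s1$a, hash_seeds(256, 43)$a))
  expect_true(all(s1$a >= 0 & s1$a < 2^32))
  expect_true(all(s1$b >= 0 & s1$b < 2^32))
})

test_that("superset minima never increase", {
  seeds <- hash_seeds(128, 1)
  withr::with_seed(11, {
    for (i in 1:20) {
      base <- sample(0:(2^32 - 1), 50)
      extra <- sample(0:(2^32 - 1), 10)
      f1 <- minhash_fingerprint(base, seeds)
      f2 <- minhash_fingerprint(c(base, extra), seeds)
      expect_true(all(f2$values <= f1$values))
    }
  })
})

test_that("the estimator tracks exact Jaccard within binomial error", {
  seeds <- hash_seeds(1024, 42)
  withr::with_seed(5, {
    ok <- 0L
    for (i in 1:100) {
      n_shared <- sample(20:150, 1)
      n1 <- sample(10:100, 1)
      n2 <- sample(10:100, 1)
      pool <- sample(0:(2^32 - 1), n_shared + n1 + n2)
      shared <- pool[seq_len(n_shared)]
      s1 <- c(shared, pool[n_shared + seq_len(n1)])
      s2 <- c(shared, pool[n_shared + n1 + seq_len(n2)])
      jtrue <- length(intersect(s1, s2)) / length(union(s1, s2))
      est <- jaccard_similarity_estimate(
        minhash_fingerprint(s1, seeds), minhash_fingerprint(s2, seeds)
      )
      sigma <- sqrt(jtrue * (1 - jtrue) / 1024)
      if (abs(est - jtrue) <= 3 * sigma) ok <- ok + 1L
    }
    expect_gte(ok, 95)
  })
})

test_that("the estimator is unbiased and near zero for disjoint sets", {
  withr::with_seed(17, {
    # disjoint sets at d = 1024: estimate stays at the binomial tail
    seeds <- hash_seeds(1024, 42)
    a <- minhash_fingerprint(sample(0:(2^32 - 1), 100), seeds)
    b <- minhash_fingerprint(sample(0:(2^32 - 1), 100), seeds)
    expect_lte(jaccard_similarity_estimate(a, b), 0.02)
    # exact J = 0.5 sets: mean over 200 seed draws within 0.02 of 0.5
    shared <- sample(0:(2^32 - 1), 100)
    only1 <- sample(0:(2^32 - 1), 50)
    only2 <- sample(0:(2^32 - 1), 50)
    s1 <- c(shared, only1)
    s2 <- c(shared, only2)
    ests <- vapply(1:200, function(seed) {
      sd <- hash_seeds(64, seed)
      jaccard_similarity_estimate(minhash_fingerprint(s1, sd),
                                  minhash_fingerprint(s2, sd))
    }, numeric(1))
    expect_lt(abs(mean(ests) - 0.5), 0.02)
  })
})

test_that("folded fingerprints fold by modulo and support Dice", {
  f0 <- folded_fingerprint(numeric(0), 2048)
  expect_length(f0$bits, 0)
  # collision: 3 and 3 + 2048 land on one bit
  f1 <- folded_fingerprint(c(3, 3 + 2048), 2048)
  expect_equal(f1$bits, 3L)
  h <- hash_shingle(sprintf("s%d", 1:40))
  expect_lte(length(folded_fingerprint(h, 2048)$bits), 40)
  # Dice identities
  a <- folded_fingerprint(c(0, 1, 2, 3), 64)
  b <- folded_fingerprint(c(1, 2, 3, 8, 9, 10), 64)
  expect_equal(dice_similarity(a, b), 0.6) # popcounts 4 and 6 sharing 3 bits
  expect_equal(dice_similarity(a, a), 1)
  expect_equal(dice_similarity(a, folded_fingerprint(c(10, 11), 64)), 0)
  expect_error(dice_similarity(folded_fingerprint(numeric(0), 64),
                               folded_fingerprint(numeric(0), 64)),
               class = "mapfp_undefined_similarity")
  expect_error(dice_similarity(a, folded_fingerprint(1, 128)),
               class = "mapfp_incompatible_fingerprint")
})

test_that("folded Dice approximates exact set Dice when collisions are rare", {
  withr::with_seed(23, {
    for (i in 1:20) {
      s1 <- sample(0:(2^32 - 1), 60)
      s2 <- c(sample(s1, 30), sample(0:(2^32 - 1), 30))
      exact <- 2 * length(intersect(s1, s2)) /
        (length(unique(s1)) + length(unique(s2)))
      folded <- dice_similarity(folded_fingerprint(s1, 2048),
                                folded_fingerprint(s2, 2048))
      expect_lt(abs(folded - exact), 0.05)
    }
  })
})

test_that("exact Jaccard oracle behaves on sets", {
  expect_equal(exact_jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(exact_jaccard(1:5, 1:5), 1)
  expect_equal(exact_jaccard(1:3, 4:6), 0)
})

test_that("incompatible fingerprints are rejected", {
  f1 <- map_fingerprint("CCO", d = 64, seed = 1)
  f2 <- map_fingerprint("CCO", d = 64, seed = 2)
  f3 <- map_fingerprint("CCO", d = 128, seed = 1)
  f4 <- map_fingerprint("CCO", r = 3, d = 64, seed = 1)
  expect_error(jaccard_similarity_estimate(f1, f2),
               class = "mapfp_incompatible_fingerprint")
  expect_error(jaccard_similarity_estimate(f1, f3),
               class = "mapfp_incompatible_fingerprint")
  expect_error(jaccard_similarity_estimate(f1, f4),
               class = "mapfp_incompatible_fingerprint")
})

test_that("all twelve benchmark variants are constructible", {
  vs <- fp_variants()
  expect_length(vs, 12)
  expect_setequal(
    names(vs),
    c(sprintf("MAP%d-1024", c(2, 4, 6, 8)),
      sprintf("MAP%d-2048", c(2, 4, 6, 8)),
      sprintf("foldedAP%d", c(2, 4, 6, 8)))
  )
  mol <- smi_standardize("CCOc1ccccc1")
  for (v in vs) {
    fp <- map_fingerprint(mol, r = v$r,
                          variant = v$type,
                          d = if (v$type == "minhash") v$d else 1024,
                          fold_length = if (v$type == "folded") v$fold_length else 2048)
    if (v$type == "minhash") {
      expect_s3_class(fp, "map_fp")
      expect_length(fp$values, v$d)
    } else {
      expect_s3_class(fp, "map_folded")
      expect_equal(fp$length, 2048)
    }
  }
})
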