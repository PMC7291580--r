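# MinHashing and folding of shingle hash sets, and the similarity measures
# used with each representation.
#
# Hash values are unsigned 32-bit integers carried in R doubles (exactly
# representable); all modular arithmetic happens in C++ with 128-bit
# intermediates, p = 2^61 - 1 (Mersenne prime) and m = 2^32 - 1.

#' Hash shingles to 32-bit integers
#'
#' Deterministic mapping of each shingle byte-string to the first 32-bit
#' word (big-endian) of its SHA-1 digest.
#'
#' @param shingles character vector of shingles.
#' @return numeric vector of unsigned 32-bit values.
#' @examples
#' hash_shingle("abc") # 2845392438 (0xA9993E36)
#' @export
hash_shingle <- function(shingles) {
  cpp_sha1_u32(as.character(shingles))
}

#' Universal-hash seed vectors
#'
#' Generates the `a`, `b` coefficient vectors of the d universal-hash
#' permutations used by MinHash. Values are drawn in \{0, ..., 2^32 - 1\}
#' by a counter-based construction (SHA-1 of "seed:role:index"), so the
#' same `seed` and `d` always regenerate identical seeds on any platform.
#'
#' @param d number of permutations (fingerprint dimension).
#' @param seed integer seed recorded inside every fingerprint built from
#'   these coefficients.
#' @return A `map_seeds` object.
#' @export
hash_seeds <- function(d = 1024, seed = 42) {
  d <- as.integer(d)
  if (is.na(d) || d < 1) stop("d must be a positive integer")
  i <- seq_len(d)
  structure(
    list(
      a = cpp_sha1_u32(sprintf("mapfp:%d:a:%d", as.integer(seed), i)),
      b = cpp_sha1_u32(sprintf("mapfp:%d:b:%d", as.integer(seed), i)),
      d = d, seed = as.integer(seed)
    ),
    class = "map_seeds"
  )
}

#' MinHashed fingerprint from a hash set
#'
#' Component i is `min over h of ((a_i * h + b_i) mod p) mod m` with
#' p = 2^61 - 1 and m = 2^32 - 1, evaluated in exact integer arithmetic.
#'
#' @param hashes numeric vector of unsigned 32-bit shingle hashes (a set).
#' @param seeds a `map_seeds` object (see [hash_seeds()]).
#' @param r optional shingle radius recorded as the variant tag.
#' @return A `map_fp` object with fields `values`, `d`, `seed`, `r`.
#' @export
minhash_fingerprint <- function(hashes, seeds = hash_seeds(), r = NA_integer_) {
  if (!inherits(seeds, "map_seeds")) stop("seeds must come from hash_seeds()")
  if (!length(hashes)) {
    map_abort("mapfp_empty_fingerprint",
              "cannot MinHash an empty shingle set")
  }
  structure(
    list(values = cpp_minhash(unique(as.numeric(hashes)), seeds$a, seeds$b),
         d = seeds$d, seed = seeds$seed, r = as.integer(r)),
    class = "map_fp"
  )
}

#' Folded (modulo) fingerprint from a hash set
#'
#' Sets bit `h mod length` for every hash; the binary alternative to
#' MinHashing (the foldedAP variants).
#'
#' @param hashes numeric vector of unsigned 32-bit shingle hashes.
#' @param length bit-vector length (default 2048).
#' @param r optional shingle radius recorded as the variant tag.
#' @return A `map_folded` object with `bits` (sorted 0-based positions of
#'   set bits) and `length`.
#' @export
folded_fingerprint <- function(hashes, length = 2048, r = NA_integer_) {
  length <- as.integer(length)
  if (is.na(length) || length < 1) stop("length must be >= 1")
  structure(
    list(bits = sort(unique(as.integer(as.numeric(hashes) %% length))),
         length = length, r = as.integer(r)),
    class = "map_folded"
  )
}

#' @export
print.map_fp <- function(x, ...) {
  cat("<map_fp> MinHashed atom-pair fingerprint, d = ", x$d,
      ", seed = ", x$seed,
      if (!is.na(x$r)) paste0(", r = ", x$r), "\n", sep = "")
  invisible(x)
}

#' @export
print.map_folded <- function(x, ...) {
  cat("<map_folded> folded atom-pair fingerprint, length = ", x$length,
      ", popcount = ", length(x$bits),
      if (!is.na(x$r)) paste0(", r = ", x$r), "\n", sep = "")
  invisible(x)
}

check_compatible <- function(f1, f2) {
  if (f1$d != f2$d || f1$seed != f2$seed ||
      (!is.na(f1$r) && !is.na(f2$r) && f1$r != f2$r)) {
    map_abort("mapfp_incompatible_fingerprint",
              "fingerprints differ in dimension, seed, or radius")
  }
  invisible(TRUE)
}

#' Estimated Jaccard similarity between MinHashed fingerprints
#'
#' Fraction of matching components; an unbiased estimator of the Jaccard
#' similarity of the underlying shingle sets. The Jaccard distance used
#' throughout the package is `1 - jaccard_similarity_estimate(...)`.
#'
#' @param f1,f2 `map_fp` objects sharing dimension and seed.
#' @return similarity in \[0, 1\].
#' @export
jaccard_similarity_estimate <- function(f1, f2) {
  stopifnot(inherits(f1, "map_fp"), inherits(f2, "map_fp"))
  check_compatible(f1, f2)
  mean(f1$values == f2$values)
}

#' Exact Jaccard similarity of two sets
#'
#' Brute-force |intersection| / |union| on shingle (or hash) sets; the
#' oracle against which the MinHash estimator is validated.
#'
#' @param s1,s2 vectors treated as sets.
#' @return similarity in \[0, 1\].
#' @export
exact_jaccard <- function(s1, s2) {
  s1 <- unique(s1)
  s2 <- unique(s2)
  u <- length(union(s1, s2))
  if (u == 0) stop("both sets are empty")
  length(intersect(s1, s2)) / u
}

#' Dice similarity between folded fingerprints
#'
#' `2 |A & B| / (popcount(A) + popcount(B))`, the measure used for the
#' folded (binary) fingerprint variants.
#'
#' @param b1,b2 `map_folded` objects of equal length.
#' @return similarity in \[0, 1\].
#' @export
dice_similarity <- function(b1, b2) {
  stopifnot(inherits(b1, "map_folded"), inherits(b2, "map_folded"))
  if (b1$length != b2$length) {
    map_abort("mapfp_incompatible_fingerprint",
              "folded fingerprints differ in length")
  }
  denom <- length(b1$bits) + length(b2$bits)
  if (denom == 0) {
    map_abort("mapfp_undefined_similarity",
              "Dice similarity undefined for two empty bit vectors")
  }
  2 * length(intersect(b1$bits, b2$bits)) / denom
}

#' One-call fingerprint computation
#'
#' Standardizes a molecule (if given as SMILES), shingles it at radius `r`,
#' hashes, and produces either the MinHashed or the folded fingerprint.
#'
#' @param x SMILES string or `map_mol`.
#' @param r maximal shingle radius (2 = MAP4).
#' @param variant `"minhash"` (MAPx) or `"folded"` (foldedAPx).
#' @param d MinHash dimension (ignored for folded).
#' @param seed MinHash seed (ignored for folded).
#' @param fold_length folded bit-vector length (ignored for minhash).
#' @param include_distance `FALSE` gives the distance-stripped
#'   substructure-only control fingerprint.
#' @param seeds optional precomputed `map_seeds` (overrides `d`/`seed`).
#' @return `map_fp` or `map_folded`.
#' @examples
#' \donttest{
#' fp <- map_fingerprint("CCO", r = 2, d = 1024)
#' }
#' @export
map_fingerprint <- function(x, r = 2, variant = c("minhash", "folded"),
                            d = 1024, seed = 42, fold_length = 2048,
                            include_distance = TRUE, seeds = NULL) {
  variant <- match.arg(variant)
  sh <- shingle_set(x, r = r, include_distance = include_distance)
  h <- hash_shingle(sh)
  if (variant == "minhash") {
    if (is.null(seeds)) seeds <- hash_seeds(d = d, seed = seed)
    minhash_fingerprint(h, seeds, r = r)
  } else {
    folded_fingerprint(h, length = fold_length, r = r)
  }
}

#' The twelve benchmark fingerprint variants
#'
#' MAP2/4/6/8 (radii 1-4) in 1024 and 2048 dimensions plus foldedAP2/4/6/8
#' at 2048 bits.
#'
#' @param seed MinHash seed shared by the MinHashed variants.
#' @return named list of variant descriptors consumed by [run_benchmark()].
#' @export
fp_variants <- function(seed = 42) {
  vs <- list()
  for (r in 1:4) {
    for (d in c(1024, 2048)) {
      nm <- sprintf("MAP%d-%d", 2 * r, d)
      vs[[nm]] <- list(name = nm, type = "minhash", r = r, d = d,
                       seed = seed, include_distance = TRUE)
    }
    nm <- sprintf("foldedAP%d", 2 * r)
    vs[[nm]] <- list(name = nm, type = "folded", r = r, fold_length = 2048,
                     include_distance = TRUE)
  }
  vs
}

#' Distance-stripped control variant
#'
#' Identical to a MinHashed atom-pair variant except that the topological
#' distance token is deleted from every shingle, leaving a bag of circular
#' substructure pairs. Used to demonstrate the contribution of the
#' atom-pair distance term.
#'
#' @param r shingle radius.
#' @param d MinHash dimension.
#' @param seed MinHash seed.
#' @return a variant descriptor for [run_benchmark()].
#' @export
control_variant <- function(r = 2, d = 1024, seed = 42) {
  nm <- sprintf("substructure-control-r%d-%d", r, d)
  list(name = nm, type = "minhash", r = r, d = d, seed = seed,
       include_distance = FALSE)
}
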