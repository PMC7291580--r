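# LSH forest over MinHashed fingerprints: 32 prefix trees, each ordering a
# seeded permutation of the fingerprint components. Queries descend to the
# longest matching prefix, over-fetch candidates across trees, and re-rank
# them by the estimated Jaccard distance.

# per-tree component selection: deterministic permutation derived from the
# fingerprint seed and tree number through the counter-based hash
.tree_components <- function(d, seed, tree, depth) {
  key <- cpp_sha1_u32(sprintf("mapfp:lsh:%d:%d:%d", seed, tree, seq_len(d)))
  order(key)[seq_len(depth)]
}

.hex_keys <- function(values_mat, comps) {
  # components are unsigned 32-bit values carried in doubles; format via
  # 16-bit halves (sprintf %x cannot take values above .Machine$integer.max)
  v <- values_mat[, comps, drop = FALSE]
  hx <- matrix(paste0(sprintf("%04x", as.integer(v %/% 65536)),
                      sprintf("%04x", as.integer(v %% 65536))),
               nrow = nrow(v))
  do.call(paste0, as.data.frame(hx, stringsAsFactors = FALSE))
}

# first index in sorted `keys` with key >= x (1-based; length(keys)+1 if none)
.lower_bound <- function(keys, x) {
  lo <- 1L
  hi <- length(keys) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (keys[mid] < x) lo <- mid + 1L else hi <- mid
  }
  lo
}

#' Build an LSH forest over MinHashed fingerprints
#'
#' Indexes the fingerprints in `n_trees` prefix trees for approximate
#' k-nearest-neighbor search. All fingerprints must share dimension, seed,
#' and radius; ids must be unique.
#'
#' @param fps list of `map_fp`.
#' @param ids character identifiers, one per fingerprint.
#' @param n_trees number of prefix trees (default 32).
#' @param depth prefix length in components per tree (default 16).
#' @return a `map_lsh_forest`.
#' @export
build_forest <- function(fps, ids, n_trees = 32, depth = 16) {
  if (!length(fps) || length(fps) != length(ids)) {
    stop("need one id per fingerprint and at least one fingerprint")
  }
  if (anyDuplicated(ids)) {
    map_abort("mapfp_duplicate_id", "ids must be unique")
  }
  if (!all(vapply(fps, inherits, logical(1), "map_fp"))) {
    map_abort("mapfp_incompatible_fingerprint",
              "an LSH forest indexes MinHashed fingerprints only")
  }
  f1 <- fps[[1]]
  for (f in fps) check_compatible(f1, f)
  depth <- min(depth, f1$d)
  mat <- do.call(rbind, lapply(fps, `[[`, "values"))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    comps <- .tree_components(f1$d, f1$seed, t, depth)
    keys <- .hex_keys(mat, comps)
    ord <- order(keys, method = "radix")
    trees[[t]] <- list(comps = comps, keys = keys[ord], idx = ord)
  }
  structure(
    list(trees = trees, ids = as.character(ids), mat = mat,
         d = f1$d, seed = f1$seed, r = f1$r, n_trees = n_trees,
         depth = depth),
    class = "map_lsh_forest"
  )
}

#' @export
print.map_lsh_forest <- function(x, ...) {
  cat("<map_lsh_forest> ", length(x$ids), " fingerprints, ", x$n_trees,
      " trees, d = ", x$d, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Approximate k-nearest-neighbor query
#'
#' Descends every tree to the longest prefix matching the query, relaxing
#' the prefix until at least `max(4k, 64)` candidates are gathered (the
#' fixed floor keeps results for different small k nested), then re-ranks
#' candidates by estimated Jaccard distance with ties broken by id.
#'
#' @param forest a `map_lsh_forest`.
#' @param q a compatible `map_fp` query.
#' @param k number of neighbors.
#' @return data frame `(id, distance)` in ascending distance (at most `k`
#'   rows).
#' @export
query_knn <- function(forest, q, k) {
  stopifnot(inherits(forest, "map_lsh_forest"), inherits(q, "map_fp"))
  if (k < 1) stop("k must be >= 1")
  check_compatible(list(d = forest$d, seed = forest$seed, r = forest$r), q)
  want <- max(4 * k, 64)
  qmat <- matrix(q$values, nrow = 1)
  cand <- integer(0)
  for (p in seq(forest$depth, 0)) {
    if (p == 0) { # degenerate: full scan
      cand <- seq_along(forest$ids)
      break
    }
    cand <- integer(0)
    for (t in seq_len(forest$n_trees)) {
      tr <- forest$trees[[t]]
      qkey <- .hex_keys(qmat, tr$comps[seq_len(p)])
      lo <- .lower_bound(tr$keys, qkey)
      hi <- .lower_bound(tr$keys, paste0(qkey, "g")) # 'g' > any hex digit
      if (hi > lo) cand <- c(cand, tr$idx[lo:(hi - 1L)])
    }
    cand <- unique(cand)
    if (length(cand) >= min(want, length(forest$ids))) break
  }
  rerank_candidates(forest, q, cand, k)
}

rerank_candidates <- function(forest, q, cand, k) {
  matches <- cpp_match_counts(forest$mat[cand, , drop = FALSE], q$values)
  dist <- 1 - matches / forest$d
  ids <- forest$ids[cand]
  ord <- order(dist, ids)
  take <- head(ord, k)
  data.frame(id = ids[take], distance = dist[take],
             stringsAsFactors = FALSE)
}

#' Exact k-nearest-neighbor search
#'
#' Exhaustive counterpart of [query_knn()] under the same estimator and tie
#' rule; the oracle for recall measurements.
#'
#' @param fps list of `map_fp` (the database).
#' @param ids identifiers, one per fingerprint.
#' @param q query `map_fp`.
#' @param k number of neighbors.
#' @return data frame `(id, distance)` in ascending distance.
#' @export
exact_knn <- function(fps, ids, q, k) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(length(fps) == length(ids))
  f1 <- fps[[1]]
  check_compatible(f1, q)
  mat <- do.call(rbind, lapply(fps, `[[`, "values"))
  matches <- cpp_match_counts(mat, q$values)
  dist <- 1 - matches / q$d
  ord <- order(dist, as.character(ids))
  take <- head(ord, k)
  data.frame(id = as.character(ids)[take], distance = dist[take],
             stringsAsFactors = FALSE)
}

#' Persist / restore an LSH forest
#'
#' Versioned binary serialization of the index (including the indexed
#' fingerprint matrix).
#'
#' @param forest a `map_lsh_forest`.
#' @param path file path.
#' @return `lsh_load` returns the forest; `lsh_save` its path, invisibly.
#' @export
lsh_save <- function(forest, path) {
  stopifnot(inherits(forest, "map_lsh_forest"))
  saveRDS(list(format = "mapfp-lsh", version = 1L, forest = forest), path)
  invisible(path)
}

#' @rdname lsh_save
#' @export
lsh_load <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "mapfp-lsh") ||
      !identical(obj$version, 1L)) {
    map_abort("mapfp_format_error", "not a mapfp LSH index file: %s", path)
  }
  obj$forest
}
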