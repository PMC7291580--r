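# Exhaustive nearest-neighbor analysis: per-molecule NN distances,
# indistinguishable-pair counting (estimated Jaccard distance exactly 0),
# hydroxyl-count stratification, and fingerprint-bin occupancy.

fp_matrix <- function(fps) {
  stopifnot(length(fps) >= 1,
            all(vapply(fps, inherits, logical(1), "map_fp")))
  f1 <- fps[[1]]
  for (f in fps) check_compatible(f1, f)
  do.call(rbind, lapply(fps, `[[`, "values"))
}

#' All nearest-neighbor distances
#'
#' For every molecule, the minimum estimated Jaccard distance to any other
#' molecule in the set (self excluded), computed exhaustively.
#'
#' @param fps list of compatible `map_fp`.
#' @param ids optional identifiers (defaults to `fp_<i>`).
#' @return data frame `(id, nn_id, nn_distance)`; ties between equally
#'   close neighbors resolve to the earliest input position.
#' @export
all_nn_distances <- function(fps, ids = NULL) {
  if (length(fps) < 2) stop("need at least 2 molecules")
  if (is.null(ids)) ids <- sprintf("fp_%d", seq_along(fps))
  stopifnot(length(ids) == length(fps))
  mat <- fp_matrix(fps)
  best <- cpp_nn_best(mat)
  data.frame(
    id = as.character(ids),
    nn_id = as.character(ids)[best[, 1]],
    nn_distance = 1 - best[, 2] / ncol(mat),
    stringsAsFactors = FALSE
  )
}

#' Count molecules with an indistinguishable nearest neighbor
#'
#' Number of molecules whose nearest neighbor is at estimated Jaccard
#' distance exactly 0, i.e. all fingerprint components equal. The test is
#' defined on the fingerprint; [exact_jaccard()] on raw shingle sets serves
#' as the oracle when ground truth is needed.
#'
#' @param nn_results output of [all_nn_distances()].
#' @return integer count.
#' @export
count_indistinguishable <- function(nn_results) {
  sum(nn_results$nn_distance == 0)
}

#' Hydroxyl group count
#'
#' Counts oxygens with exactly one attached hydrogen and two connections in
#' total (one heavy neighbor + the hydrogen). This includes alcohol and
#' carboxylic-acid OH, matching the stratification that separates lipids
#' (OH = 0, 1) from carbohydrate derivatives (OH > 4).
#'
#' @param mol a `map_mol` (or SMILES string).
#' @return integer count.
#' @export
hydroxyl_count <- function(mol) {
  mol <- as_map_mol(mol)
  deg <- rep(0L, mol$n_atoms)
  if (nrow(mol$bonds)) {
    t1 <- table(factor(mol$bonds[, 1], levels = seq_len(mol$n_atoms)))
    t2 <- table(factor(mol$bonds[, 2], levels = seq_len(mol$n_atoms)))
    deg <- as.integer(t1 + t2)
  }
  sum(mol$elements == "O" & mol$hcount == 1L & deg == 1L)
}

#' Fingerprint bin occupancy
#'
#' Groups molecules by identical full fingerprint and returns group sizes
#' in descending order — the "compounds per fingerprint bin" view that
#' exposes fingerprints unable to separate related structures.
#'
#' @param fps list of compatible `map_fp`.
#' @param ids optional identifiers.
#' @return data frame `(pattern, count, ids)` sorted by descending count;
#'   `pattern` is the comma-joined component vector, `ids` the member ids
#'   (semicolon-joined).
#' @export
bin_occupancy <- function(fps, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("fp_%d", seq_along(fps))
  stopifnot(length(ids) == length(fps))
  mat <- fp_matrix(fps)
  key <- apply(mat, 1, paste, collapse = ",")
  grp <- split(as.character(ids), key)
  out <- data.frame(
    pattern = names(grp),
    count = vapply(grp, length, integer(1)),
    ids = vapply(grp, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$count, out$pattern), , drop = FALSE]
}
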