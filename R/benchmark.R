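# The virtual-screening benchmark driver: fingerprint several variants on
# labelled datasets, screen with max-fusion query sets, collect the metric
# table, and aggregate per-metric average ranks across datasets.

#' Labelled screening dataset
#'
#' The unit of the benchmark: SMILES with active/decoy labels. Peptide
#' benchmark sets convert via [as_screening_dataset()].
#'
#' @param smiles character vector of member SMILES.
#' @param labels `"active"`/`"decoy"` per member.
#' @param id dataset identifier.
#' @return object of class `map_screening_dataset`.
#' @export
screening_dataset <- function(smiles, labels, id = "dataset") {
  stopifnot(length(smiles) == length(labels))
  act <- as_active(labels)
  structure(
    list(id = id, smiles = as.character(smiles),
         labels = ifelse(act, "active", "decoy")),
    class = "map_screening_dataset"
  )
}

#' Convert a labelled peptide benchmark set for screening
#'
#' Builds member SMILES with [peptide_to_smiles()] and carries the labels
#' over.
#'
#' @param set a labelled `map_benchmark_set`.
#' @param protonate passed to [peptide_to_smiles()].
#' @return a `map_screening_dataset`.
#' @export
as_screening_dataset <- function(set, protonate = TRUE) {
  stopifnot(inherits(set, "map_benchmark_set"))
  if (anyNA(set$members$label)) {
    stop("benchmark set is unlabelled; run blast_label() or identity_label()")
  }
  screening_dataset(
    vapply(set$members$sequence, peptide_to_smiles, character(1),
           protonate = protonate, USE.NAMES = FALSE),
    set$members$label,
    id = paste0(set$kind, ":", set$query)
  )
}

# shingle hash sets per dataset member for each radius a variant needs;
# computed once and shared across variants/repetitions
.dataset_hash_sets <- function(smiles, radii, include_distance_levels) {
  mols <- lapply(smiles, smi_standardize)
  out <- list()
  for (incl in include_distance_levels) {
    for (r in radii) {
      key <- paste0(r, ":", incl)
      out[[key]] <- lapply(mols, function(m) {
        hash_shingle(shingle_set(m, r = r, include_distance = incl))
      })
    }
  }
  out
}

.variant_fps <- function(hash_sets, variant) {
  key <- paste0(variant$r, ":", isTRUE(variant$include_distance))
  hs <- hash_sets[[key]]
  if (variant$type == "minhash") {
    seeds <- hash_seeds(d = variant$d, seed = variant$seed)
    lapply(hs, minhash_fingerprint, seeds = seeds, r = variant$r)
  } else {
    lapply(hs, folded_fingerprint, length = variant$fold_length,
           r = variant$r)
  }
}

.metric_row <- function(scores, labels) {
  data.frame(
    auc = auc(scores, labels),
    ef1 = enrichment_factor(scores, labels, 0.01),
    ef5 = enrichment_factor(scores, labels, 0.05),
    bedroc20 = bedroc(scores, labels, 20),
    bedroc100 = bedroc(scores, labels, 100),
    rie20 = rie(scores, labels, 20),
    rie100 = rie(scores, labels, 100)
  )
}

#' Run the fingerprint screening benchmark
#'
#' For each dataset and repetition, a query set of `n_queries` actives is
#' drawn, the remaining members are scored by max-fusion similarity under
#' every fingerprint variant, and the retrieval metrics (AUC, EF1, EF5,
#' BEDROC20/100, RIE20/100) are recorded. Datasets with fewer actives than
#' `n_queries + 1` are skipped with a warning.
#'
#' @param datasets list of `map_screening_dataset` (or labelled
#'   `map_benchmark_set`, converted automatically).
#' @param variants list of variant descriptors ([fp_variants()],
#'   [control_variant()], or hand-built).
#' @param repetitions screening repetitions per dataset.
#' @param n_queries actives per query set.
#' @param seed RNG seed for query sampling.
#' @return list with `metrics` (one row per dataset x variant x repetition)
#'   and `average_ranks` (see [average_variant_ranks()]).
#' @export
run_benchmark <- function(datasets, variants = fp_variants(),
                          repetitions = 5, n_queries = 5, seed = 42) {
  datasets <- lapply(datasets, function(d) {
    if (inherits(d, "map_benchmark_set")) as_screening_dataset(d) else d
  })
  stopifnot(all(vapply(datasets, inherits, logical(1),
                       "map_screening_dataset")))
  if (is.null(names(variants)) || any(!nzchar(names(variants)))) {
    names(variants) <- vapply(variants, `[[`, character(1), "name")
  }
  rows <- list()
  for (ds in datasets) {
    act_idx <- which(ds$labels == "active")
    if (length(act_idx) < n_queries + 1) {
      warning("dataset '", ds$id, "' skipped: needs > ", n_queries,
              " actives, has ", length(act_idx))
      next
    }
    radii <- unique(vapply(variants, `[[`, numeric(1), "r"))
    incls <- unique(vapply(variants, function(v) {
      isTRUE(v$include_distance)
    }, logical(1)))
    hash_sets <- .dataset_hash_sets(ds$smiles, radii, incls)
    for (v in variants) {
      fps <- .variant_fps(hash_sets, v)
      for (rep_i in seq_len(repetitions)) {
        q_idx <- withr::with_seed(as.integer(seed) + rep_i, {
          sample(act_idx, n_queries)
        })
        eval_idx <- setdiff(seq_along(fps), q_idx)
        scores <- score_by_max_fusion(fps[q_idx], fps[eval_idx])
        m <- .metric_row(scores, ds$labels[eval_idx])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(dataset = ds$id, variant = v$name, repetition = rep_i,
                     stringsAsFactors = FALSE),
          m
        )
      }
    }
  }
  metrics <- do.call(rbind, rows)
  list(metrics = metrics,
       average_ranks = if (!is.null(metrics)) average_variant_ranks(metrics))
}

#' Average fingerprint rank per metric
#'
#' Within every (dataset, repetition) cell the variants are ranked by each
#' metric (rank 1 = best; ties share the mean rank), and ranks are averaged
#' across cells — the aggregation used to compare fingerprint variants
#' across heterogeneous datasets.
#'
#' @param metrics the `metrics` data frame from [run_benchmark()].
#' @return data frame: variant x metric average ranks plus the overall mean.
#' @export
average_variant_ranks <- function(metrics) {
  metric_cols <- c("auc", "ef1", "ef5", "bedroc20", "bedroc100",
                   "rie20", "rie100")
  metric_cols <- intersect(metric_cols, names(metrics))
  cell <- interaction(metrics$dataset, metrics$repetition, drop = TRUE)
  variants <- sort(unique(metrics$variant))
  out <- data.frame(variant = variants, stringsAsFactors = FALSE)
  for (mc in metric_cols) {
    rk <- stats::ave(-metrics[[mc]], cell, FUN = rank)
    agg <- tapply(rk, metrics$variant, mean)
    out[[mc]] <- as.numeric(agg[variants])
  }
  out$mean_rank <- rowMeans(out[metric_cols])
  out[order(out$mean_rank), , drop = FALSE]
}
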