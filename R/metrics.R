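# Virtual-screening retrieval metrics: AUC, enrichment factors, RIE and
# BEDROC. Ranking ties are always resolved pessimistically for actives
# (decoys placed first inside a tie block), so reported enrichment never
# benefits from tied scores.

as_active <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("active", "decoy"))
    if (length(bad)) stop("labels must be 'active'/'decoy' or logical")
    return(labels == "active")
  }
  stop("labels must be 'active'/'decoy' or logical")
}

check_two_classes <- function(act) {
  if (length(act) < 2 || !any(act) || all(act)) {
    map_abort("mapfp_degenerate_labels",
              "metrics need at least one active and one decoy")
  }
}

# 1-based ranks after sorting by decreasing score, decoys first within ties
pessimistic_ranks <- function(scores, act) {
  ord <- order(-scores, act) # FALSE (decoy) sorts before TRUE within a tie
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  r
}

#' Ranking AUC (Mann-Whitney statistic)
#'
#' `P(score_active > score_decoy) + 0.5 P(tie)` over all active/decoy
#' pairs; 1 when every active outscores every decoy, 0.5 for exchangeable
#' scores.
#'
#' @param scores numeric similarity scores, larger = ranked earlier.
#' @param labels `"active"`/`"decoy"` (or logical, `TRUE` = active).
#' @return value in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  act <- as_active(labels)
  check_two_classes(act)
  r <- rank(scores) # average ranks handle ties as 0.5
  n1 <- sum(act)
  n0 <- sum(!act)
  (sum(r[act]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Enrichment factor at a fraction of the ranked list
#'
#' Ratio of the active rate in the top `ceiling(x N)` ranked members to the
#' overall active rate; EF1 and EF5 correspond to `x` = 0.01 and 0.05.
#'
#' @inheritParams auc
#' @param x top fraction in (0, 1).
#' @return value >= 0 (1 expected under random ranking).
#' @export
enrichment_factor <- function(scores, labels, x) {
  act <- as_active(labels)
  check_two_classes(act)
  if (!is.numeric(x) || x <= 0 || x >= 1) stop("x must be in (0, 1)")
  n <- length(scores)
  top <- ceiling(x * n)
  r <- pessimistic_ranks(scores, act)
  hits <- sum(act & r <= top)
  (hits / top) / (sum(act) / n)
}

# mean of exp(-alpha * i / N) over i = 1..N (expectation under uniform ranks)
.mean_exp_uniform <- function(alpha, n_total) {
  mean(exp(-alpha * seq_len(n_total) / n_total))
}

#' Robust Initial Enhancement (RIE)
#'
#' Mean over actives of `exp(-alpha rank / N)`, normalized by its
#' expectation under uniform random ranks. `alpha` sets how sharply early
#' ranks are rewarded (20 and 100 in the benchmark).
#'
#' @inheritParams auc
#' @param alpha early-recognition exponent (> 0).
#' @return value >= 0 (1 expected under random ranking).
#' @export
rie <- function(scores, labels, alpha) {
  act <- as_active(labels)
  check_two_classes(act)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  n <- length(scores)
  r <- pessimistic_ranks(scores, act)
  mean(exp(-alpha * r[act] / n)) / .mean_exp_uniform(alpha, n)
}

#' BEDROC: RIE rescaled to \[0, 1\]
#'
#' Min-max rescaling of [rie()] between the worst possible value (all
#' actives ranked last) and the best possible value (all actives ranked
#' first) for the given N, number of actives, and `alpha`; a perfect
#' ranking scores exactly 1 and the worst exactly 0.
#'
#' @inheritParams rie
#' @return value in \[0, 1\].
#' @export
bedroc <- function(scores, labels, alpha) {
  act <- as_active(labels)
  check_two_classes(act)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  n <- length(scores)
  n_act <- sum(act)
  denom <- .mean_exp_uniform(alpha, n)
  r <- pessimistic_ranks(scores, act)
  v <- mean(exp(-alpha * r[act] / n)) / denom
  vmax <- mean(exp(-alpha * seq_len(n_act) / n)) / denom
  vmin <- mean(exp(-alpha * seq.int(n - n_act + 1, n) / n)) / denom
  (v - vmin) / (vmax - vmin)
}

#' Max-fusion similarity scoring
#'
#' Scores every dataset member by its maximum similarity over a set of
#' query fingerprints — the data-fusion rule used when screening with
#' several known actives as the query.
#'
#' @param query_fps list of fingerprints (all `map_fp` or all `map_folded`).
#' @param dataset_fps list of member fingerprints of the same class.
#' @param similarity similarity function; defaults to
#'   [jaccard_similarity_estimate()] for MinHashed and [dice_similarity()]
#'   for folded fingerprints.
#' @return numeric score vector aligned with `dataset_fps`.
#' @export
score_by_max_fusion <- function(query_fps, dataset_fps, similarity = NULL) {
  if (!length(query_fps)) stop("need at least one query fingerprint")
  if (is.null(similarity)) {
    similarity <- if (inherits(query_fps[[1]], "map_folded")) {
      dice_similarity
    } else {
      jaccard_similarity_estimate
    }
  }
  vapply(dataset_fps, function(f) {
    max(vapply(query_fps, function(q) similarity(q, f), numeric(1)))
  }, numeric(1))
}
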