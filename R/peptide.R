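# Peptide sequence handling: sequence -> SMILES assembly and the scrambled /
# point-mutated benchmark dataset generators.

#' @rdname peptide_to_smiles
#' @format NULL
#' @export
PEPTIDE_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(sequence)) {
    map_abort("mapfp_alphabet_error", "peptide sequence must be a non-empty string")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, PEPTIDE_ALPHABET)
  if (length(bad)) {
    map_abort("mapfp_alphabet_error",
              "non-proteogenic residue(s): %s", paste(unique(bad), collapse = ", "))
  }
  res
}

# side-chain SMILES fragments attached to the alpha carbon, with basic side
# chains protonated; proline is handled separately (ring to the backbone N)
.side_chains_protonated <- list(
  A = "C", R = "CCCNC(=[NH2+])N", N = "CC(N)=O", D = "CC(=O)O", C = "CS",
  E = "CCC(=O)O", Q = "CCC(N)=O", G = "", H = "Cc1c[nH]cn1", I = "C(C)CC",
  L = "CC(C)C", K = "CCCC[NH3+]", M = "CCSC", F = "Cc1ccccc1",
  S = "CO", T = "C(C)O", W = "Cc1c[nH]c2ccccc12", Y = "Cc1ccc(O)cc1",
  V = "C(C)C"
)
.side_chains_neutral <- local({
  x <- .side_chains_protonated
  x$R <- "CCCNC(=N)N"
  x$K <- "CCCCN"
  x
})

#' Linear peptide SMILES from a sequence
#'
#' Assembles the SMILES of a linear peptide by amide condensation of residue
#' templates: backbone N-Calpha-C(=O) units joined N-to-C, free acid at the
#' C-terminus. With `protonate = TRUE` (the convention used for all peptide
#' benchmark structures) the N-terminal amine and the Lys/Arg side chains are
#' protonated; carboxylic acids and His stay neutral. The heavy-atom count of
#' the product equals the sum over residues minus one water-loss oxygen per
#' peptide bond.
#'
#' @param sequence peptide as one-letter codes over the 20 proteogenic amino
#'   acids.
#' @param protonate apply the protonation convention above.
#' @return A SMILES string (unstandardized; feed to [smi_standardize()] or
#'   [map_fingerprint()] as needed).
#' @examples
#' peptide_to_smiles("G")   # protonated glycine, C2H6NO2+
#' peptide_to_smiles("GG")  # 9 heavy atoms
#' @export
peptide_to_smiles <- function(sequence, protonate = TRUE) {
  res <- check_peptide(sequence)
  side <- if (protonate) .side_chains_protonated else .side_chains_neutral
  parts <- character(length(res))
  for (i in seq_along(res)) {
    aa <- res[i]
    first <- i == 1
    if (aa == "P") {
      n_tok <- if (first && protonate) "[NH2+]1" else "N1"
      parts[i] <- paste0(n_tok, "CCCC1C(=O)")
    } else {
      n_tok <- if (first && protonate) "[NH3+]" else "N"
      sc <- side[[aa]]
      ca <- if (nzchar(sc)) paste0("C(", sc, ")") else "C"
      parts[i] <- paste0(n_tok, ca, "C(=O)")
    }
  }
  paste0(paste(parts, collapse = ""), "O")
}

#' Random benchmark query peptides
#'
#' Generates the benchmark query panel: ten 10-mers, ten 20-mers, and ten
#' 30-mers with every residue drawn independently and uniformly from the 20
#' proteogenic amino acids.
#'
#' @param seed RNG seed; the same seed always returns the same panel.
#' @param n_per_length how many sequences of each length.
#' @param lengths sequence lengths.
#' @return character vector (named `q<length>_<index>`).
#' @export
random_query_sequences <- function(seed = 42, n_per_length = 10,
                                   lengths = c(10, 20, 30)) {
  withr::with_seed(as.integer(seed), {
    out <- character(0)
    for (L in lengths) {
      for (i in seq_len(n_per_length)) {
        s <- paste(sample(PEPTIDE_ALPHABET, L, replace = TRUE), collapse = "")
        out[sprintf("q%d_%02d", L, i)] <- s
      }
    }
    out
  })
}

# log count of distinct residue permutations (multinomial coefficient)
log_distinct_permutations <- function(sequence) {
  res <- check_peptide(sequence)
  counts <- table(res)
  lfactorial(length(res)) - sum(lfactorial(counts))
}

new_benchmark_set <- function(query, kind, members, seed) {
  structure(
    list(query = query, kind = kind, members = members, seed = seed),
    class = "map_benchmark_set"
  )
}

#' @export
print.map_benchmark_set <- function(x, ...) {
  nlab <- sum(!is.na(x$members$label))
  cat("<map_benchmark_set> ", x$kind, " set for query ", x$query, "\n",
      "  members: ", nrow(x$members),
      if (nlab) paste0(" (", sum(x$members$label == "active", na.rm = TRUE),
                       " active / ", sum(x$members$label == "decoy",
                                         na.rm = TRUE), " decoy)")
      else " (unlabelled)", "\n", sep = "")
  invisible(x)
}

#' Scrambled peptide benchmark set
#'
#' Unique random permutations of the query's residues (the query itself is
#' excluded). Used as the scrambled decoy background in the peptide
#' virtual-screening benchmark.
#'
#' @param query parent sequence.
#' @param n number of scrambled analogs (default 10,000).
#' @param seed RNG seed; (query, kind, seed) fully determines the output.
#' @return an unlabelled `map_benchmark_set`.
#' @section Errors: `mapfp_insufficient_diversity` if the residue multiset
#'   of the query admits fewer than `n + 1` distinct permutations.
#' @export
generate_scrambled_set <- function(query, n = 10000, seed = 42) {
  res <- check_peptide(query)
  if (log_distinct_permutations(query) < log(n + 1)) {
    map_abort("mapfp_insufficient_diversity",
              "query admits fewer than %d distinct permutations", n + 1)
  }
  withr::with_seed(as.integer(seed), {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- character(n)
    got <- 0L
    tries <- 0L
    max_tries <- 200L * n
    while (got < n && tries < max_tries) {
      tries <- tries + 1L
      s <- paste(sample(res), collapse = "")
      if (s == query || !is.null(seen[[s]])) next
      got <- got + 1L
      out[got] <- s
      seen[[s]] <- TRUE
    }
    if (got < n) {
      map_abort("mapfp_generation_error",
                "retry bound exhausted after %d draws (%d/%d unique)",
                tries, got, n)
    }
    new_benchmark_set(query, "scrambled",
                      data.frame(sequence = out, k = NA_integer_,
                                 label = NA_character_,
                                 stringsAsFactors = FALSE),
                      as.integer(seed))
  })
}

#' Point-mutated peptide benchmark set
#'
#' For a query of length L, generates `ceiling(cap / L)` unique sequences at
#' Hamming distance exactly k from the query for every k in 1..L (each
#' mutated position receives a uniformly chosen different residue),
#' concatenates the blocks in ascending k, and truncates to the first `cap`
#' sequences. With the default cap of 10,000 this is the benchmark rule:
#' L = 30 gives 334 x 30 = 10,020, truncated to 10,000.
#'
#' A k-block can never exceed the `choose(L, k) * 19^k` distinct sequences
#' that exist at that Hamming distance, so the per-k count is capped there:
#' a 10-mer has only 190 distinct single-point mutants, and its k = 1 block
#' holds all 190 of them rather than the nominal 1000.
#'
#' @param query parent sequence.
#' @param cap maximum total number of mutated analogs (default 10,000).
#' @param seed RNG seed.
#' @return an unlabelled `map_benchmark_set`; column `k` records the exact
#'   Hamming distance of each member from the query.
#' @export
generate_mutated_set <- function(query, cap = 10000, seed = 42) {
  res <- check_peptide(query)
  L <- length(res)
  n_nominal <- as.integer(ceiling(cap / L))
  withr::with_seed(as.integer(seed), {
    seqs <- character(0)
    ks <- integer(0)
    for (k in seq_len(L)) {
      # cap at the number of distinct sequences at Hamming distance k
      log_avail <- lchoose(L, k) + k * log(19)
      n_per_k <- if (log_avail < log(n_nominal)) {
        as.integer(round(exp(log_avail)))
      } else {
        n_nominal
      }
      seen <- new.env(hash = TRUE, parent = emptyenv())
      got <- 0L
      tries <- 0L
      max_tries <- 1000L * n_per_k
      block <- character(n_per_k)
      while (got < n_per_k && tries < max_tries) {
        tries <- tries + 1L
        pos <- sample.int(L, k)
        mut <- res
        for (p in pos) {
          mut[p] <- sample(setdiff(PEPTIDE_ALPHABET, res[p]), 1)
        }
        s <- paste(mut, collapse = "")
        if (!is.null(seen[[s]])) next
        got <- got + 1L
        block[got] <- s
        seen[[s]] <- TRUE
      }
      if (got < n_per_k) {
        map_abort("mapfp_generation_error",
                  "retry bound exhausted at k = %d (%d/%d unique)",
                  k, got, n_per_k)
      }
      seqs <- c(seqs, block)
      ks <- c(ks, rep.int(k, n_per_k))
    }
    keep <- seq_len(min(cap, length(seqs)))
    new_benchmark_set(query, "mutated",
                      data.frame(sequence = seqs[keep], k = ks[keep],
                                 label = NA_character_,
                                 stringsAsFactors = FALSE),
                      as.integer(seed))
  })
}

#' Identity-fraction stub labeller
#'
#' Offline alternative to BLAST labelling: a member is active when the
#' fraction of positions identical to the query (sequences of equal length)
#' meets `threshold`. Intended for tests and desk-scale screens where an
#' external aligner is unwanted; the labelling stage is pluggable, so
#' [blast_label()] can be swapped in without touching generation.
#'
#' @param set an unlabelled `map_benchmark_set`.
#' @param threshold minimal identity fraction for the active label.
#' @return the set with `label` filled in.
#' @export
identity_label <- function(set, threshold = 0.3) {
  stopifnot(inherits(set, "map_benchmark_set"))
  q <- strsplit(set$query, "")[[1]]
  idf <- vapply(strsplit(set$members$sequence, ""), function(s) {
    L <- max(length(s), length(q))
    sum(head(s, min(length(s), length(q))) ==
          head(q, min(length(s), length(q)))) / L
  }, numeric(1))
  set$members$label <- ifelse(idf >= threshold, "active", "decoy")
  attr(set, "labeller") <- sprintf("identity>=%.2f", threshold)
  set
}
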