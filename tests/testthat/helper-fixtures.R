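# Shared helpers: small fixture corpora built in code, brute-force oracles,
# and an RDKit bridge (via the python interpreter) used only as an
# independent oracle for randomized SMILES renderings.

fixture_smiles <- function(n = 20, seed = 7) {
  random_drug_smiles(n, seed)
}

# randomized-atom-order SMILES renderings of each input molecule, produced
# by RDKit through the system python; returns a list of character vectors
rdkit_random_renderings <- function(smiles, n_each = 10) {
  py <- Sys.which("python")
  if (!nzchar(py)) skip("python not available for the RDKit oracle")
  inp <- tempfile(); out <- tempfile()
  writeLines(smiles, inp)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "n = int(sys.argv[3])",
    "with open(sys.argv[1]) as fh, open(sys.argv[2], 'w') as oh:",
    "    for line in fh:",
    "        m = Chem.MolFromSmiles(line.strip())",
    "        alts = [Chem.MolToSmiles(m, canonical=False, doRandom=True)",
    "                for _ in range(n)]",
    "        oh.write('\\t'.join(alts) + '\\n')"
  ), script)
  status <- system2(py, c(script, inp, out, n_each), stdout = FALSE,
                    stderr = FALSE)
  if (!identical(status, 0L)) skip("RDKit oracle run failed")
  strsplit(readLines(out), "\t", fixed = TRUE)
}

# naive double-loop nearest-neighbor oracle over MinHashed fingerprints
naive_nn <- function(fps) {
  n <- length(fps)
  out <- data.frame(nn = integer(n), dist = numeric(n))
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(n)) {
      if (i == j) next
      d <- 1 - jaccard_similarity_estimate(fps[[i]], fps[[j]])
      if (d < best) { best <- d; bj <- j }
    }
    out$nn[i] <- bj; out$dist[i] <- best
  }
  out
}

# direct-summation RIE oracle (no shared code with the implementation)
oracle_rie <- function(active_ranks, n_total, alpha) {
  num <- mean(exp(-alpha * active_ranks / n_total))
  den <- sum(exp(-alpha * seq_len(n_total) / n_total)) / n_total
  num / den
}

oracle_bedroc <- function(active_ranks, n_total, alpha) {
  n <- length(active_ranks)
  v <- oracle_rie(active_ranks, n_total, alpha)
  vmax <- oracle_rie(seq_len(n), n_total, alpha)
  vmin <- oracle_rie(seq.int(n_total - n + 1, n_total), n_total, alpha)
  (v - vmin) / (vmax - vmin)
}

# pairwise-counting AUC oracle
oracle_auc <- function(scores, active) {
  a <- scores[active]; d <- scores[!active]
  tot <- 0
  for (x in a) for (y in d) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(d))
}

# free-amino-acid heavy atom counts derived from single-residue molecules
residue_heavy_atoms <- function(protonate = TRUE) {
  vapply(PEPTIDE_ALPHABET, function(aa) {
    smi_standardize(peptide_to_smiles(aa, protonate = protonate))$n_atoms
  }, integer(1))
}
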