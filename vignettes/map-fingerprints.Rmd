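---
title: "MinHashed atom-pair fingerprints: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MinHashed atom-pair fingerprints: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapfp)
```

## The fingerprint model

Substructure fingerprints (ECFP-style circular environments) describe local
chemistry well but are blind to global size and shape: two scrambled
peptides, or two lipids differing only in chain arrangement, contain the
same bag of small substructures. Atom-pair fingerprints encode shape through
topological distances but describe each atom too coarsely for small-molecule
screening. The MinHashed atom-pair (MAP) family combines both ideas.

For a standardized molecule and a radius parameter $r$, every unordered
heavy-atom pair $(j, k)$ contributes one *shingle* per radius value
$1 \dots r$:

$$\min(CS_{rad}(j), CS_{rad}(k)) \;|\; TP_{j,k} \;|\; \max(CS_{rad}(j), CS_{rad}(k))$$

where $CS_{rad}(j)$ is the canonical SMILES of the circular substructure of
radius $rad$ bonds around atom $j$, rooted at $j$, the min/max order is
lexicographic, and $TP_{j,k}$ is the shortest-path bond count between the
two centers. The shingle *set* (duplicates collapse) is hashed to 32-bit
integers by truncated SHA-1 and then either

* **MinHashed** (MAP2/4/6/8 for $r = 1..4$): component $i$ of the sketch is
  $\min_h ((a_i h + b_i) \bmod p) \bmod m$ with $p = 2^{61}-1$,
  $m = 2^{32}-1$, and $a_i, b_i \in \{0,\dots,2^{32}-1\}$ drawn once per
  seed. The fraction of equal components between two sketches is an
  unbiased estimator of the Jaccard similarity of the underlying shingle
  sets, with binomial standard error $\sqrt{J(1-J)/d}$; or
* **folded** (foldedAP2..8): bit $h \bmod 2048$ is set for every hash, and
  bit vectors compare by Dice similarity. Folding introduces collisions,
  which is why the folded variants trail the MinHashed ones in screening
  performance as $r$ grows.

`map_fingerprint()` is the one-call entry point; `fp_variants()` enumerates
the twelve standard variants (MAP{2,4,6,8} at 1024 and 2048 dimensions,
foldedAP{2,4,6,8} at 2048 bits).

```{r example}
fp1 <- map_fingerprint("CCOc1ccccc1", r = 2, d = 1024)
fp2 <- map_fingerprint("CCOc1ccccc1C", r = 2, d = 1024)
jaccard_similarity_estimate(fp1, fp2)
```

## Parameters that matter

* `r` (unitless, bonds): maximal environment radius. `r = 2` (MAP4) is the
  default compromise — detailed enough for small-molecule screening without
  the shingle explosion of larger radii.
* `d`: sketch dimension; estimator noise scales as $1/\sqrt{d}$. 1024 is
  the benchmarking default, 512 the search-index default (cheaper, still
  ~0.022 standard error at $J = 0.5$).
* `seed`: drives the $a, b$ coefficient vectors through a counter-based
  construction (SHA-1 of `"mapfp:<seed>:a|b:<i>"`), so fingerprints are
  reproducible across platforms. The seed and dimension are recorded inside
  every fingerprint and checked on comparison: sketches from different
  seeds are incomparable, and that mistake is caught rather than silently
  producing nonsense.
* `include_distance = FALSE` deletes the $TP$ token, producing a
  deliberately crippled substructure-only control. It exists to make the
  contribution of the distance term measurable: the control cannot
  distinguish scrambled heptapeptides (KLLKKLL vs KLKKLLL) or long-chain
  homolog alkanols, while the full fingerprint separates all of them.

## Standardization and numerical choices

* Input SMILES are canonicalized with OpenBabel; stereo descriptors are
  removed first (the fingerprint is defined on non-isomeric SMILES), and
  that stripping is oracle-checked against `obabel -ocan -xi` in the test
  suite. Multi-fragment inputs keep the largest fragment by heavy-atom
  count, ties resolved toward the lexicographically smallest canonical
  SMILES. Molecules with fewer than 2 heavy atoms are rejected
  (`mapfp_too_small`), mirroring standard database preprocessing.
* Molecules are kept kekulized (as OpenBabel's SDF emits them), and
  environment SMILES are written kekulized. Because every input passes
  through whole-molecule canonicalization first, the pipeline is
  deterministic and invariant to input atom ordering; the byte-level
  shingle strings are a documented convention of this implementation, not
  an interchange format.
* The canonical rooted environment writer refines atom ranks by iterated
  neighborhood invariants (Weisfeiler–Lehman style over written atom
  tokens and bond orders) and resolves residual symmetry cells by bounded
  branching, keeping the lexicographically smallest completed SMILES.
  Symmetry-equivalent centers therefore produce identical strings (all six
  benzene carbons at any radius). If the branch budget (96 completions) is
  ever exhausted, remaining ties fall back to the canonicalized atom
  order, which is still deterministic.
* Implicit hydrogens come from a standard valence model (B, C, N, O, F,
  Si, P, S, halogens, with multi-valence S/P/N and charge adjustment).
  Charges outside ±3 are not representable in the SDF charge column the
  parser reads and are out of scope.
* MinHash arithmetic is exact 128-bit integer arithmetic in C++; no
  floating point touches the hash path. Hash values travel through R as
  doubles, which represent all values below $2^{53}$ exactly.

## The peptide benchmark

`random_query_sequences()` generates the 30-query panel (ten each of
length 10, 20, 30; residues i.i.d. uniform over the 20 proteogenic amino
acids). Per query, two datasets:

* `generate_scrambled_set()`: 10,000 unique residue permutations
  (excluding the parent). Queries whose residue multiset admits too few
  permutations are rejected analytically before any sampling.
* `generate_mutated_set()`: for each Hamming distance $k = 1..L$,
  `ceiling(10000/L)` unique sequences with exactly $k$ substituted
  positions, concatenated in ascending $k$ and truncated to the first
  10,000. The truncation order (ascending $k$, generation order within
  $k$) is pinned: with $L = 30$, the $k = 30$ block keeps only
  $10000 - 29 \times 334 = 314$ of its 334 members. A $k$-block can never
  exceed the $\binom{L}{k} 19^k$ distinct sequences that exist, so short
  queries saturate their small-$k$ blocks: a 10-mer has only 190 distinct
  single-point mutants and its $k = 1$ block contains all of them — the
  nominal $1000 \times 10$ count is unattainable and the set holds 9190
  members, all unique.

Labels are a separable stage. `blast_label()` runs blastp (subject-mode,
gap open 11, extend 1, E-cutoff 10, word size 3, BLOSUM62, SEG) and labels
reported hits with $E < 10$ active. blastp's standard 500-hit report cap is
kept deliberately: it is what bounds the active fraction of a mutated
10,000-member set at roughly 5%, the composition the benchmark expects.
`identity_label()` is the offline stub: active when the positional identity
to the query reaches a threshold (default 0.3 — for scrambled 10-mers the
number of fixed points of a random permutation is approximately Poisson(1),
so ~8% of members become actives, a realistic composition).

Peptide structures come from `peptide_to_smiles()`: residue templates
joined by amide condensation, free-acid C-terminus. "Protonated SMILES" is
realised as: N-terminal amine and Lys/Arg side chains protonated,
carboxylic acids and His neutral. This convention is a documented choice
(exposed via `protonate`); heavy-atom arithmetic
($\sum_\text{residues} - (L-1)$ condensation oxygens) is verified in the
tests against per-residue reference molecules.

`run_benchmark()` repeats each screen (default 5 times) with a fresh query
set of 5 actives, scores the remaining members by max-fusion similarity
(Jaccard estimate for MinHashed, Dice for folded), and reports AUC, EF1,
EF5, BEDROC20/100, RIE20/100 plus cross-dataset average ranks (rank 1 =
best, ties share the mean). Two protocol readings are possible — stored
query-set lists versus fresh per-repetition query sets; the driver
implements the per-repetition reading and both counts are configurable
(`repetitions`, `n_queries`).

### Metric conventions

Ties in a ranked list are resolved decoys-first, so enrichment never
profits from ties. AUC is the Mann–Whitney statistic (ties count half).
RIE is the mean of $e^{-\alpha \cdot rank/N}$ over actives normalized by
its expectation under uniform ranks, evaluated by direct summation rather
than the closed-form approximation. BEDROC is the exact min–max rescaling
of RIE between the worst- and best-possible rankings for the given $N$,
$n$, $\alpha$ — so a perfect ranking scores exactly 1 and the worst exactly
0, and as $\alpha \to 0$ BEDROC converges to AUC (checked numerically at
$\alpha = 0.001$).

## Similarity search

`build_forest()` indexes MinHashed fingerprints in an LSH forest of 32
prefix trees. Each tree orders a seeded pseudo-random permutation of the
sketch components (first 16 of them as the key); queries descend to the
longest matching prefix and relax depth until at least `max(4k, 64)`
candidates are gathered, which are then re-ranked exactly by the Jaccard
estimator with ties broken by id. The fixed 64-candidate floor makes
results for all $k \le 16$ draw from the same candidate pool, so growing
$k$ extends rather than reshuffles the neighbor list. On small databases
the relaxation may reach depth 0 and degrade gracefully to an exact scan —
the standard behavior of forest-style LSH when prefixes are underfilled.
Recall@10 against the exhaustive oracle exceeds 0.8 on the package's
1000-molecule synthetic corpus.

## What the synthetic corpora do and do not show

`make_fixtures()` builds everything the tests consume: a template-
randomized drug-like SMILES corpus (scaffold + two substituents from fixed
fragment lists), the 30-query peptide panel with full-size scrambled and
mutated sets, and the C2–C20 alkan-1-ol homolog series. These corpora
reproduce the *structural regimes* the fingerprint is designed for —
repetitive biopolymers, homolog series, small drug-like rings — and every
count and invariant of the generators is enforced at full scale. They do
not reproduce the property distributions of curated databases (ChEMBL,
HMDB, SwissProt): absolute screening metrics and shingle counts on the
synthetic corpora are not comparable to values measured on those
databases, which require the external data themselves. Desk-scale problem
sizes used by the tests and the acceptance script (150-member screens,
1000-molecule search corpus, 50 sampled queries) were chosen as the
smallest sizes at which the qualitative orderings are stable.

## Known limitations

* Shingle byte-strings (kekulized, this package's bracket conventions)
  differ from any other implementation's, so raw hash values are not
  interchangeable across toolkits even though all set-level and
  similarity-level behavior matches.
* No stereochemistry-aware variant: stereoisomers are deliberately
  indistinguishable.
* Cyclic or branched peptides are out of scope for the sequence-to-SMILES
  builder (linear chains only).
* The WL-refinement canonicalization is not a proven canonical labeling
  for all graphs; for the molecular subgraphs that occur in practice the
  bounded branching resolves every case, and determinism is guaranteed
  regardless by upstream canonicalization.
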