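# Molecule standardization and atom-pair shingling.
#
# SMILES parsing and whole-molecule canonicalization are delegated to
# OpenBabel (through ChemmineOB/ChemmineR); the package keeps molecules as a
# light heavy-atom graph (element, charge, implicit H count, kekulized bond
# table) which is what the shingling core consumes.

# stereo descriptors: tetrahedral marks inside brackets and bond direction
strip_stereo_smiles <- function(smiles) {
  gsub("[/\\\\]", "", gsub("@", "", smiles, fixed = TRUE))
}

# canonical SMILES of one molecule via OpenBabel; "" on failure
ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  if (!length(out) || is.na(out) || !nzchar(out)) return("")
  line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  strsplit(line, "\t", fixed = TRUE)[[1]][1]
}

# SDF legacy charge codes -> formal charge
.charge_from_code <- function(code) {
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  code[is.na(code) | code < 0 | code > 7] <- 0L
  map[code + 1L]
}

.allowed_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

# implicit hydrogen count from a standard valence model
.implicit_h <- function(elem, charge, bondsum) {
  av <- .allowed_valences[[elem]]
  if (is.null(av)) return(0L)
  target <- av[av >= bondsum][1]
  if (is.na(target)) return(0L)
  if (charge > 0 && elem %in% c("N", "O", "P", "S")) {
    target <- target + charge
  } else if (charge != 0) {
    target <- target - abs(charge)
  }
  as.integer(max(0, target - bondsum))
}

# parse already-canonical SMILES (one connected fragment each) into graph
# parts; input is trusted to be OpenBabel-canonical
parse_canonical <- function(canonical_smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canonical_smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_\\d+$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) {
    .charge_from_code(as.integer(ab[, "C6"]))
  } else {
    rep(0L, nrow(ab))
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    matrix(integer(0), ncol = 3)
  } else {
    matrix(as.integer(bb[, 1:3]), ncol = 3)
  }
  # fold any explicit hydrogens into their heavy neighbor's H count
  extra_h <- rep(0L, length(elements))
  if (any(elements == "H")) {
    hs <- which(elements == "H")
    for (h in hs) {
      nb <- c(bonds[bonds[, 1] == h, 2], bonds[bonds[, 2] == h, 1])
      extra_h[nb] <- extra_h[nb] + 1L
    }
    keep <- setdiff(seq_along(elements), hs)
    remap <- match(seq_along(elements), keep)
    bonds <- bonds[!(bonds[, 1] %in% hs | bonds[, 2] %in% hs), , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
    elements <- elements[keep]
    charge <- charge[keep]
    extra_h <- extra_h[keep]
  }
  n <- length(elements)
  bondsum <- rep(0, n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds[, 3] == 4L, 1.5, bonds[, 3])
    for (e in seq_len(nrow(bonds))) {
      bondsum[bonds[e, 1]] <- bondsum[bonds[e, 1]] + ord[e]
      bondsum[bonds[e, 2]] <- bondsum[bonds[e, 2]] + ord[e]
    }
  }
  hcount <- vapply(seq_len(n), function(i) {
    .implicit_h(elements[i], charge[i], ceiling(bondsum[i]))
  }, integer(1)) + extra_h
  list(elements = elements, charge = charge, hcount = hcount,
       bonds = bonds, n_atoms = n)
}

# heavy-atom count of a canonical single-fragment SMILES by token counting
# (cheap, avoids a full parse for largest-fragment selection; single-atom
# fragments would not even round-trip through the SDF path)
.fragment_heavy_atoms <- function(canonical_smiles) {
  brackets <- regmatches(canonical_smiles,
                         gregexpr("\\[[^][]*\\]", canonical_smiles))[[1]]
  n_br <- sum(!grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", brackets))
  rest <- gsub("\\[[^][]*\\]", "", canonical_smiles)
  n_two <- length(gregexpr("Cl|Br", rest)[[1]])
  if (n_two == 1 && gregexpr("Cl|Br", rest)[[1]][1] == -1) n_two <- 0
  rest <- gsub("Cl|Br", "", rest)
  n_one <- nchar(gsub("[^BCNOPSFIbcnops]", "", rest))
  as.integer(n_br + n_two + n_one)
}

#' Parse and standardize a SMILES string
#'
#' Canonicalizes the input with OpenBabel, removes stereochemistry
#' descriptors (by default), keeps the largest fragment of multi-fragment
#' inputs, and builds the heavy-atom graph used for shingling. Mirrors the
#' database preprocessing used throughout the MAP fingerprint workflow:
#' canonical, non-isomeric, single-fragment structures with at least two
#' heavy atoms.
#'
#' @param smiles a single SMILES string.
#' @param id optional molecule identifier carried through downstream results.
#' @param strip_stereo remove tetrahedral and double-bond stereo descriptors
#'   before canonicalization (default `TRUE`; the fingerprint is defined on
#'   non-isomeric SMILES).
#' @return A `map_mol` object: heavy-atom elements, formal charges, implicit
#'   hydrogen counts, the kekulized bond table, and the canonical SMILES.
#' @section Errors:
#'   `mapfp_invalid_structure` if the SMILES cannot be parsed;
#'   `mapfp_too_small` if fewer than 2 heavy atoms remain after
#'   standardization (such inputs are discarded from fingerprint corpora).
#' @examples
#' \donttest{
#' mol <- smi_standardize("CCO")
#' mol$n_atoms   # 3
#' }
#' @export
smi_standardize <- function(smiles, id = NULL, strip_stereo = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    map_abort("mapfp_invalid_structure", "input is not a SMILES string")
  }
  src <- trimws(smiles)
  s <- if (strip_stereo) strip_stereo_smiles(src) else src
  canon <- ob_canonical(s)
  if (!nzchar(canon)) {
    map_abort("mapfp_invalid_structure", "could not parse SMILES '%s'", src)
  }
  # multi-fragment: keep the largest fragment (ties: lexicographically
  # smallest canonical SMILES), then re-canonicalize it on its own
  if (grepl(".", canon, fixed = TRUE)) {
    frags <- strsplit(canon, ".", fixed = TRUE)[[1]]
    frags <- vapply(frags, ob_canonical, character(1), USE.NAMES = FALSE)
    frags <- frags[nzchar(frags)]
    if (!length(frags)) {
      map_abort("mapfp_invalid_structure", "could not parse SMILES '%s'", src)
    }
    sizes <- vapply(frags, .fragment_heavy_atoms, integer(1), USE.NAMES = FALSE)
    best <- which(sizes == max(sizes))
    canon <- sort(frags[best])[1]
  }
  if (.fragment_heavy_atoms(canon) < 2) {
    map_abort("mapfp_too_small",
              "molecule '%s' has fewer than 2 heavy atoms", src)
  }
  parts <- parse_canonical(canon)
  structure(
    c(parts, list(canonical_smiles = canon, source_smiles = src,
                  id = if (is.null(id)) NA_character_ else as.character(id))),
    class = "map_mol"
  )
}

#' @export
print.map_mol <- function(x, ...) {
  cat("<map_mol> ", x$canonical_smiles, "\n", sep = "")
  cat("  heavy atoms: ", x$n_atoms, ", bonds: ", nrow(x$bonds),
      if (!is.na(x$id)) paste0(", id: ", x$id), "\n", sep = "")
  invisible(x)
}

as_map_mol <- function(x) {
  if (inherits(x, "map_mol")) return(x)
  smi_standardize(x)
}

#' Topological distance matrix
#'
#' Shortest-path bond counts between all heavy-atom pairs of a standardized
#' molecule (the TP term of the atom-pair shingle).
#'
#' @param mol a `map_mol` (or a SMILES string, standardized on the fly).
#' @return Symmetric integer matrix with zero diagonal.
#' @export
topological_distances <- function(mol) {
  mol <- as_map_mol(mol)
  cpp_topo_dist(mol$n_atoms, mol$bonds)
}

#' Canonical rooted SMILES of a circular atom environment
#'
#' Writes the subgraph induced by all atoms within `radius` bonds of
#' `atom_index` as a canonical SMILES rooted at (starting with) the center
#' atom. Output is deterministic and independent of input atom numbering;
#' symmetry-equivalent atoms yield identical strings.
#'
#' @param mol a `map_mol` (or SMILES string).
#' @param atom_index 1-based heavy-atom index of the center.
#' @param radius environment radius in bonds (>= 1).
#' @return A SMILES string.
#' @export
circular_environment_smiles <- function(mol, atom_index, radius) {
  mol <- as_map_mol(mol)
  if (atom_index < 1 || atom_index > mol$n_atoms) {
    stop("atom_index out of range [1, ", mol$n_atoms, "]")
  }
  as.character(cpp_env_smiles(mol$elements, mol$charge, mol$hcount,
                              mol$bonds, as.integer(atom_index),
                              as.integer(radius)))
}

#' Atom-pair shingle set
#'
#' For every unordered heavy-atom pair (j, k) and every radius 1..r, emits
#' one shingle `min(CS, CS')|TP|max(CS, CS')` where CS are the canonical
#' rooted SMILES of the two circular environments and TP the shortest-path
#' bond distance. The result is a deduplicated set (returned sorted so two
#' runs are byte-identical).
#'
#' @param mol a `map_mol` (or SMILES string).
#' @param r maximal environment radius; r = 2 corresponds to the default
#'   MAP4 fingerprint.
#' @param include_distance set to `FALSE` for the distance-stripped
#'   substructure-only control shingles `CS|CS'` (used to demonstrate what
#'   the atom-pair distance term adds).
#' @return Character vector of shingles (a set: unique, sorted).
#' @export
shingle_set <- function(mol, r = 2, include_distance = TRUE) {
  mol <- as_map_mol(mol)
  cpp_shingles(mol$elements, mol$charge, mol$hcount, mol$bonds,
               as.integer(r), isTRUE(include_distance))
}

#' Unique shingles across a corpus
#'
#' Streams a corpus of SMILES, standardizes each molecule, and counts the
#' distinct atom-pair shingles over the corpus (per-molecule sets are
#' unioned, so a shingle repeated inside one molecule counts once).
#' Unparseable or too-small inputs are skipped and counted.
#'
#' @param smiles character vector of SMILES.
#' @param r maximal shingle radius.
#' @param frequency also return the per-shingle document frequency (number
#'   of molecules containing the shingle).
#' @return list with `n_unique`, `frequency` (named integer vector or
#'   `NULL`), `n_parsed`, `n_skipped`.
#' @export
corpus_unique_shingles <- function(smiles, r = 2, frequency = FALSE) {
  sets <- vector("list", length(smiles))
  skipped <- 0L
  for (i in seq_along(smiles)) {
    mol <- tryCatch(smi_standardize(smiles[[i]]),
                    mapfp_error = function(e) NULL)
    if (is.null(mol)) {
      skipped <- skipped + 1L
      next
    }
    sets[[i]] <- shingle_set(mol, r = r)
  }
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (!length(sets)) {
    return(list(n_unique = 0L, frequency = if (frequency) integer(0),
                n_parsed = 0L, n_skipped = skipped))
  }
  all <- unlist(sets, use.names = FALSE)
  freq <- table(all)
  out <- list(
    n_unique = length(freq),
    frequency = if (frequency) {
      f <- as.integer(freq)
      names(f) <- names(freq)
      sort(f, decreasing = TRUE)
    },
    n_parsed = length(sets),
    n_skipped = skipped
  )
  out
}
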