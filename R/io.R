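# File formats and fixture generation: SMILES line files, FASTA peptide
# sets, the binary fingerprint store, benchmark manifests, and the
# deterministic synthetic corpora used for tests and examples.

#' Read a SMILES line file
#'
#' Format: one molecule per line, `<smiles>[<whitespace><id>]`; lines
#' starting with `#` and blank lines are ignored. With `validate = TRUE`
#' records that OpenBabel cannot parse are skipped and counted.
#'
#' @param path file path.
#' @param validate drop unparseable SMILES (default `TRUE`).
#' @return data frame `(smiles, id)` with attribute `n_skipped`.
#' @export
read_smiles_file <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- trimws(lines[keep])
  toks <- strsplit(lines, "\\s+")
  smiles <- vapply(toks, `[[`, character(1), 1)
  ids <- vapply(seq_along(toks), function(i) {
    if (length(toks[[i]]) > 1) toks[[i]][2] else sprintf("mol_%d", i)
  }, character(1))
  n_skipped <- 0L
  if (validate && length(smiles)) {
    ok <- vapply(smiles, function(s) nzchar(ob_canonical(s)), logical(1),
                 USE.NAMES = FALSE)
    n_skipped <- sum(!ok)
    if (n_skipped) {
      warning(n_skipped, " unparseable SMILES record(s) skipped")
    }
    smiles <- smiles[ok]
    ids <- ids[ok]
  }
  structure(
    data.frame(smiles = smiles, id = ids, stringsAsFactors = FALSE),
    n_skipped = n_skipped
  )
}

#' @rdname read_smiles_file
#' @param records data frame with columns `smiles` and `id`.
#' @export
write_smiles_file <- function(records, path) {
  writeLines(paste(records$smiles, records$id, sep = "\t"), path)
  invisible(path)
}

#' Read / write peptide FASTA
#'
#' FASTA I/O for peptide sequence sets (via Biostrings); sequences are
#' checked against the 20-letter proteogenic alphabet.
#'
#' @param path file path.
#' @return `read_fasta_peptides`: data frame `(id, sequence)`.
#' @export
read_fasta_peptides <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  for (s in seqs) check_peptide(s)
  data.frame(id = names(ss), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' @rdname read_fasta_peptides
#' @param sequences character vector of peptide sequences.
#' @param ids sequence identifiers.
#' @export
write_fasta_peptides <- function(sequences, ids, path) {
  stopifnot(length(sequences) == length(ids))
  ss <- Biostrings::AAStringSet(setNames(sequences, ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- binary fingerprint store -------------------------------------------
# header: magic "MAPF", version, variant code (1 minhash / 2 folded), r,
# d or bit length, seed, record count; then records as 32-bit words
# (written as two little-endian uint16 halves) or packed bits. Molecule ids
# go to a sidecar text file "<path>.ids".

.write_u32 <- function(con, x) {
  x <- as.numeric(x)
  lo <- as.integer(x %% 65536)
  hi <- as.integer(x %/% 65536)
  v <- as.integer(rbind(lo, hi))
  writeBin(v, con, size = 2, endian = "little")
}

.read_u32 <- function(con, n) {
  v <- readBin(con, "integer", n = 2 * n, size = 2, signed = FALSE,
               endian = "little")
  if (length(v) != 2 * n) {
    map_abort("mapfp_format_error", "truncated fingerprint store")
  }
  v[seq(1, 2 * n, 2)] + 65536 * v[seq(2, 2 * n, 2)]
}

#' Fingerprint store
#'
#' Bit-exact binary round trip for a homogeneous collection of fingerprints
#' including the variant metadata (type, radius, dimension/length, seed).
#' Identifiers are written to a plain-text sidecar `<path>.ids`.
#'
#' @param path store path.
#' @param fps list of `map_fp` or list of `map_folded` (not mixed).
#' @param ids identifiers, one per fingerprint.
#' @return `read_fingerprints` returns `list(fps, ids)`.
#' @export
write_fingerprints <- function(path, fps, ids = NULL) {
  stopifnot(length(fps) >= 1)
  if (is.null(ids)) ids <- sprintf("fp_%d", seq_along(fps))
  stopifnot(length(ids) == length(fps))
  minhash <- vapply(fps, inherits, logical(1), "map_fp")
  folded <- vapply(fps, inherits, logical(1), "map_folded")
  if (!(all(minhash) || all(folded))) {
    map_abort("mapfp_format_error",
              "cannot mix MinHashed and folded fingerprints in one store")
  }
  f1 <- fps[[1]]
  if (all(minhash)) for (f in fps) check_compatible(f1, f)
  if (all(folded) && !all(vapply(fps, `[[`, integer(1), "length") ==
                            f1$length)) {
    map_abort("mapfp_format_error", "folded fingerprints differ in length")
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("MAPF"), con)
  .write_u32(con, 1) # format version
  if (all(minhash)) {
    .write_u32(con, c(1, if (is.na(f1$r)) 0 else f1$r, f1$d, f1$seed,
                      length(fps)))
    for (f in fps) .write_u32(con, f$values)
  } else {
    .write_u32(con, c(2, if (is.na(f1$r)) 0 else f1$r, f1$length, 0,
                      length(fps)))
    for (f in fps) {
      bits <- logical(f1$length)
      bits[f$bits + 1] <- TRUE
      writeBin(packBits(c(bits, rep(FALSE, (-f1$length) %% 8))), con)
    }
  }
  writeLines(as.character(ids), paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "MAPF")) {
    map_abort("mapfp_format_error", "not a mapfp fingerprint store: %s", path)
  }
  version <- .read_u32(con, 1)
  if (version != 1) {
    map_abort("mapfp_format_error", "unsupported store version %d", version)
  }
  hdr <- .read_u32(con, 5)
  code <- hdr[1]; r <- if (hdr[2] == 0) NA_integer_ else as.integer(hdr[2])
  dim <- hdr[3]; seed <- hdr[4]; count <- hdr[5]
  fps <- vector("list", count)
  if (code == 1) {
    for (i in seq_len(count)) {
      fps[[i]] <- structure(
        list(values = .read_u32(con, dim), d = as.integer(dim),
             seed = as.integer(seed), r = r),
        class = "map_fp"
      )
    }
  } else if (code == 2) {
    nbytes <- ceiling(dim / 8)
    for (i in seq_len(count)) {
      raw <- readBin(con, "raw", nbytes)
      if (length(raw) != nbytes) {
        map_abort("mapfp_format_error", "truncated fingerprint store")
      }
      bits <- which(as.logical(rawToBits(raw)[seq_len(dim)])) - 1L
      fps[[i]] <- structure(
        list(bits = bits, length = as.integer(dim), r = r),
        class = "map_folded"
      )
    }
  } else {
    map_abort("mapfp_format_error", "unknown variant code %d", code)
  }
  extra <- readBin(con, "raw", 1)
  if (length(extra)) {
    map_abort("mapfp_format_error", "trailing bytes in fingerprint store")
  }
  idf <- paste0(path, ".ids")
  ids <- if (file.exists(idf)) readLines(idf) else sprintf("fp_%d", seq_len(count))
  if (length(ids) != count) {
    map_abort("mapfp_format_error", "id sidecar does not match record count")
  }
  list(fps = fps, ids = ids)
}

# ---- benchmark manifests -------------------------------------------------

#' Benchmark set manifest (TSV)
#'
#' Plain-text round trip of a benchmark set: columns
#' `sequence`, `label`, `kind`, `k`; the query and seed ride in `#` header
#' comments.
#'
#' @param set a `map_benchmark_set`.
#' @param path file path.
#' @return `read_benchmark_manifest` returns the `map_benchmark_set`.
#' @export
write_benchmark_manifest <- function(set, path) {
  stopifnot(inherits(set, "map_benchmark_set"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(paste0("# query=", set$query),
               paste0("# kind=", set$kind),
               paste0("# seed=", set$seed),
               "sequence\tlabel\tkind\tk"), con)
  df <- set$members
  writeLines(paste(df$sequence,
                   ifelse(is.na(df$label), "NA", df$label),
                   set$kind,
                   ifelse(is.na(df$k), "NA", df$k), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_benchmark_manifest
#' @export
read_benchmark_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "",
                           grep(paste0("^# ", key, "="), hdr, value = TRUE))
  body <- read.delim(text = lines[!grepl("^#", lines)],
                     stringsAsFactors = FALSE, na.strings = "NA")
  new_benchmark_set(
    query = get("query"), kind = get("kind"),
    members = data.frame(sequence = body$sequence,
                         k = as.integer(body$k),
                         label = as.character(body$label),
                         stringsAsFactors = FALSE),
    seed = as.integer(get("seed"))
  )
}

# ---- synthetic corpora ---------------------------------------------------

#' Homolog alkanol series
#'
#' Linear alkan-1-ols CnH(2n+1)OH — a synthetic homolog series whose
#' members differ only in chain length, the regime where atom-pair distance
#' encoding separates molecules that substructure sets cannot.
#'
#' @param n_carbons chain lengths.
#' @return named character vector of SMILES.
#' @export
alkanol_series <- function(n_carbons = 2:20) {
  setNames(paste0(strrep("C", n_carbons), "O"),
           sprintf("alkanol_C%d", n_carbons))
}

.fixture_cores <- c(
  "%sc1ccc(%s)cc1",        # para-disubstituted benzene
  "%sc1ccc(%s)nc1",        # pyridine
  "%sC1CCN(%s)CC1",        # piperidine
  "%sC(=O)Nc1ccc(%s)cc1",  # anilide
  "%sNC(=O)%s",            # amide link
  "%sOC(=O)%s",            # ester link
  "%sc1ccc2ccccc2c1O%s",   # naphthalene ether
  "%sC1CCC(%s)CC1",        # cyclohexane
  "%sc1cccc(%s)c1O",       # ortho-phenol
  "%sCC(%s)C"              # branched aliphatic
)

# substituents must stay chemically valid whether attached through their
# first atom (branch position) or their last atom (textual prefix)
.fixture_subs <- c("C", "CC", "CCC", "CCCC", "O", "OC", "N", "NC", "F",
                   "Cl", "Br", "C(=O)O", "C(=O)N", "OCC", "CO", "CN",
                   "C(C)C", "CCO", "SC", "CCN")

#' Deterministic drug-like SMILES corpus
#'
#' Template-randomized small molecules: a scaffold with two substituents
#' drawn from a fixed fragment list. Every emitted SMILES parses and
#' standardizes; the corpus is reproducible from the seed.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return named character vector of SMILES (unique).
#' @export
random_drug_smiles <- function(n = 200, seed = 42) {
  withr::with_seed(as.integer(seed), {
    out <- character(0)
    while (length(out) < n) {
      core <- sample(.fixture_cores, 1)
      s <- sprintf(core, sample(.fixture_subs, 1), sample(.fixture_subs, 1))
      out <- unique(c(out, s))
    }
    setNames(out[seq_len(n)], sprintf("fix_%03d", seq_len(n)))
  })
}

#' Packaged synthetic fixtures
#'
#' One deterministic bundle of everything the examples and tests consume:
#' a drug-like SMILES corpus, the 30 benchmark query peptides, one
#' scrambled and one mutated benchmark set per query (identity-stub
#' labelled), and the alkanol homolog series. When `dir` is given the
#' corpora are also written out (SMILES file, FASTA, TSV manifests).
#'
#' @param seed seed driving every random choice.
#' @param dir optional output directory.
#' @param n_molecules size of the drug-like corpus.
#' @param n_scrambled scrambled analogs per query.
#' @param mutated_cap cap of each mutated set.
#' @param queries query peptides (defaults to the standard 30-query panel).
#' @param label_threshold identity threshold for the stub labeller.
#' @return list with `drug_smiles`, `query_peptides`, `scrambled`,
#'   `mutated`, `alkanols`.
#' @export
make_fixtures <- function(seed = 42, dir = NULL, n_molecules = 200,
                          n_scrambled = 10000, mutated_cap = 10000,
                          queries = random_query_sequences(seed),
                          label_threshold = 0.3) {
  fixtures <- list(
    drug_smiles = random_drug_smiles(n_molecules, seed),
    query_peptides = queries,
    scrambled = lapply(queries, function(q) {
      identity_label(generate_scrambled_set(q, n = n_scrambled, seed = seed),
                     threshold = label_threshold)
    }),
    mutated = lapply(queries, function(q) {
      identity_label(generate_mutated_set(q, cap = mutated_cap, seed = seed),
                     threshold = label_threshold)
    }),
    alkanols = alkanol_series()
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_smiles_file(
      data.frame(smiles = unname(fixtures$drug_smiles),
                 id = names(fixtures$drug_smiles)),
      file.path(dir, "drug_like.smi")
    )
    write_fasta_peptides(unname(queries), names(queries),
                         file.path(dir, "queries.fasta"))
    for (nm in names(queries)) {
      write_benchmark_manifest(
        fixtures$scrambled[[nm]],
        file.path(dir, paste0("scrambled_", nm, ".tsv"))
      )
      write_benchmark_manifest(
        fixtures$mutated[[nm]],
        file.path(dir, paste0("mutated_", nm, ".tsv"))
      )
    }
    write_smiles_file(
      data.frame(smiles = unname(fixtures$alkanols),
                 id = names(fixtures$alkanols)),
      file.path(dir, "alkanols.smi")
    )
  }
  fixtures
}
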