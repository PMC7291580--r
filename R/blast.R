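# BLAST labelling of benchmark sets. blastp is invoked as an external
# process in -subject mode (no database build needed); members reported
# with an expectation value below the cutoff become actives.

#' blastp labelling configuration
#'
#' Defaults mirror the benchmark's alignment settings: gap opening 11, gap
#' extension 1, expectation cutoff 10.0, word size 3, BLOSUM62, SEG query
#' filter. `max_hits` keeps blastp's standard 500-hit report cap, which is
#' what bounds the active count of a 10,000-member set at roughly 5%.
#'
#' @param gapopen,gapextend gap penalties.
#' @param evalue expectation-value cutoff for the active label.
#' @param word_size blastp word size.
#' @param matrix substitution matrix name.
#' @param seg `"yes"` or `"no"`, SEG low-complexity query filtering.
#' @param max_hits maximum number of reported subject sequences.
#' @param blastp path to the blastp executable.
#' @return list of class `map_blast_config`.
#' @export
blast_config <- function(gapopen = 11, gapextend = 1, evalue = 10.0,
                         word_size = 3, matrix = "BLOSUM62", seg = "yes",
                         max_hits = 500, blastp = "blastp") {
  structure(
    list(gapopen = gapopen, gapextend = gapextend, evalue = evalue,
         word_size = word_size, matrix = matrix, seg = seg,
         max_hits = max_hits, blastp = blastp),
    class = "map_blast_config"
  )
}

#' Label a benchmark set with BLAST
#'
#' Searches the set's members with blastp using the parent sequence as the
#' query; members hit with expectation value below the cutoff are labelled
#' active, the rest decoy. The raw tabular report is kept as an attribute
#' for audit.
#'
#' @param set an unlabelled `map_benchmark_set`.
#' @param config a [blast_config()].
#' @return the set with `label` filled in and attribute `blast_report`.
#' @section Errors: `mapfp_external_dependency` when blastp is not on the
#'   PATH; `mapfp_format_error` when its report cannot be parsed.
#' @export
blast_label <- function(set, config = blast_config()) {
  stopifnot(inherits(set, "map_benchmark_set"))
  if (!nzchar(Sys.which(config$blastp))) {
    map_abort("mapfp_external_dependency",
              "external tool '%s' (NCBI BLAST+) is required for BLAST labelling",
              config$blastp)
  }
  qf <- tempfile(fileext = ".fa")
  sf <- tempfile(fileext = ".fa")
  rf <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(qf, sf, rf)), add = TRUE)
  writeLines(c(">query", set$query), qf)
  ids <- sprintf("m%06d", seq_len(nrow(set$members)))
  writeLines(rbind(paste0(">", ids), set$members$sequence), sf)
  args <- c("-query", qf, "-subject", sf, "-out", rf,
            "-outfmt", shQuote("6 sseqid evalue"),
            "-evalue", format(config$evalue),
            "-gapopen", config$gapopen, "-gapextend", config$gapextend,
            "-word_size", config$word_size, "-matrix", config$matrix,
            "-seg", config$seg, "-max_target_seqs", config$max_hits)
  status <- system2(config$blastp, as.character(args),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(rf)) {
    map_abort("mapfp_external_dependency", "blastp run failed (status %s)",
              as.character(status))
  }
  rep <- if (file.size(rf) == 0) {
    data.frame(sseqid = character(0), evalue = numeric(0))
  } else {
    tryCatch(
      read.delim(rf, header = FALSE, col.names = c("sseqid", "evalue"),
                 stringsAsFactors = FALSE),
      error = function(e) NULL
    )
  }
  if (is.null(rep)) {
    map_abort("mapfp_format_error", "could not parse blastp report")
  }
  hit <- unique(rep$sseqid[rep$evalue < config$evalue])
  set$members$label <- ifelse(ids %in% hit, "active", "decoy")
  attr(set, "labeller") <- "blastp"
  attr(set, "blast_report") <- rep
  set
}
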