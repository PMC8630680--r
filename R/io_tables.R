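#' Read domain hits from an hmmscan per-domain table
#'
#' Parses the whitespace-delimited per-domain tabular output dialect of
#' `hmmscan --domtblout` (23 columns; the trailing description may contain
#' spaces). Envelope coordinates are converted from 1-based inclusive residue
#' positions to the internal 0-based half-open convention, and the
#' per-domain independent E-value is kept as the filtering statistic.
#'
#' @param path Path to a domtblout-style file. `#` comment lines are skipped.
#' @return A data frame of domain hits with columns `protein_id`,
#'   `domain_accession`, `domain_name`, `env_start`, `env_end` (0-based
#'   half-open) and `i_evalue`.
#' @export
read_domtbl <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(empty_domain_hits())
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22L)) {
    stop("domtblout parse error: row with fewer than 22 columns (row ",
         which(nf < 22L)[1L], ")")
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  env_from <- as.integer(get(20L))
  env_to <- as.integer(get(21L))
  ieval <- as.numeric(get(13L))
  if (anyNA(env_from) || anyNA(env_to) || anyNA(ieval)) {
    stop("domtblout parse error: non-numeric envelope coordinates or i-E-value")
  }
  out <- data.frame(
    protein_id = get(4L),
    domain_accession = get(2L),
    domain_name = get(1L),
    env_start = env_from - 1L,
    env_end = env_to,
    i_evalue = ieval,
    stringsAsFactors = FALSE
  )
  bad <- out$env_start >= out$env_end | out$i_evalue < 0
  if (any(bad)) {
    stop("domtblout parse error: invalid envelope or negative E-value (row ",
         which(bad)[1L], ")")
  }
  out
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(), domain_accession = character(),
             domain_name = character(), env_start = integer(),
             env_end = integer(), i_evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Write domain hits in the hmmscan per-domain tabular dialect
#'
#' Inverse of [read_domtbl()]; columns not represented in the in-memory model
#' are written as placeholders. Used mainly by the synthetic-data generator.
#'
#' @param hits Domain-hit data frame (see [read_domtbl()]).
#' @param path Output path.
#' @param qlen Optional named vector of protein lengths.
#' @return `path`, invisibly.
#' @export
write_domtbl <- function(hits, path, qlen = NULL) {
  ql <- if (is.null(qlen)) rep(0L, nrow(hits)) else unname(qlen[hits$protein_id])
  ql[is.na(ql)] <- 0L
  lines <- sprintf(
    paste0("%s %s %d %s - %d %.2g 0.0 0.0 1 1 %.2g %.2g 0.0 0.0 ",
           "%d %d %d %d %d %d 0.90 -"),
    hits$domain_name, hits$domain_accession,
    hits$env_end - hits$env_start, hits$protein_id, ql,
    hits$i_evalue, hits$i_evalue, hits$i_evalue,
    hits$env_start + 1L, hits$env_end,
    hits$env_start + 1L, hits$env_end,
    hits$env_start + 1L, hits$env_end
  )
  header <- paste("#", "target name accession tlen query name accession qlen",
                  "E-value score bias ...")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read all-vs-all protein homology hits in BLAST tabular format
#'
#' Parses the 12-column tab-separated `-outfmt 6` dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Self-hits are retained; downstream stages filter them.
#'
#' @param path Path to a BLAST outfmt-6 file.
#' @return A data frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `evalue` and `bitscore`.
#' @export
read_blast_tab <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(empty_homology_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("BLAST tabular parse error: expected 12 tab-separated columns (row ",
         which(nf != 12L)[1L], ")")
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  out <- data.frame(
    query_id = get(1L),
    subject_id = get(2L),
    pct_identity = as.numeric(get(3L)),
    evalue = as.numeric(get(11L)),
    bitscore = as.numeric(get(12L)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$evalue)) || any(out$evalue < 0) ||
      any(!nzchar(out$query_id)) || any(!nzchar(out$subject_id))) {
    stop("BLAST tabular parse error: invalid E-value or empty sequence id")
  }
  out
}

empty_homology_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

#' Write homology hits in BLAST outfmt-6 format
#'
#' @param hits Homology-hit data frame (see [read_blast_tab()]).
#' @param path Output path.
#' @param aln_length Alignment length written in column 4 (placeholder).
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path, aln_length = 100L) {
  lines <- sprintf("%s\t%s\t%.1f\t%d\t0\t0\t1\t%d\t1\t%d\t%.3g\t%.1f",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   aln_length, aln_length, aln_length,
                   hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}
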