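#' Read gene models from a GFF3 annotation file
#'
#' Parses the 9-column GFF3 dialect, keeps features of one type (genes by
#' default) and converts the 1-based inclusive GFF coordinates to the 0-based
#' half-open convention used everywhere inside the package. Chromosome labels
#' outside the expected set are normalised to `"chrUn"` so that unplaced
#' scaffolds are tallied separately downstream.
#'
#' @param path Path to a GFF3 file. Comment lines (`#`) and blank lines are
#'   skipped.
#' @param feature_type Feature type (column 3) to extract; default `"gene"`.
#'   Some genome releases anchor gene locations at the mRNA level instead.
#' @param chromosomes Character vector of recognised chromosome labels; any
#'   other sequence name becomes `"chrUn"`. `NULL` keeps labels verbatim.
#' @param protein_suffix Suffix appended to the gene ID to form the protein ID
#'   (releases differ; e.g. `".1"`). Default `""`: protein ID equals gene ID.
#' @return A data frame of gene models with columns `gene_id`, `chromosome`,
#'   `start`, `end` (0-based half-open), `strand` and `protein_id`.
#' @export
read_gff3 <- function(path, feature_type = "gene",
                      chromosomes = paste0("chr", 1:7),
                      protein_suffix = "") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_gene_models())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9L)) {
    bad <- idx[which(nfield != 9L)[1L]]
    stop("GFF3 parse error at line ", bad, ": expected 9 tab-separated columns")
  }
  m <- do.call(rbind, fields)
  sel <- m[, 3L] == feature_type
  if (!any(sel)) {
    return(empty_gene_models())
  }
  m <- m[sel, , drop = FALSE]
  idx <- idx[sel]
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start1) | is.na(end1) | start1 > end1)
  if (length(bad) > 0L) {
    stop("GFF3 parse error at line ", idx[bad[1L]],
         ": non-integer coordinates or start > end")
  }
  ids <- gff3_attribute(m[, 9L], "ID")
  if (anyNA(ids)) {
    stop("GFF3 parse error at line ", idx[which(is.na(ids))[1L]],
         ": missing ID attribute")
  }
  chrom <- m[, 1L]
  if (!is.null(chromosomes)) {
    chrom[!(chrom %in% chromosomes)] <- "chrUn"
  }
  strand <- m[, 7L]
  strand[!(strand %in% c("+", "-"))] <- "unknown"
  out <- data.frame(
    gene_id = ids,
    chromosome = chrom,
    start = start1 - 1L,   # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = strand,
    protein_id = paste0(ids, protein_suffix),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    stop("GFF3 parse error: duplicated gene_id '",
         out$gene_id[anyDuplicated(out$gene_id)], "'")
  }
  out
}

empty_gene_models <- function() {
  data.frame(gene_id = character(), chromosome = character(),
             start = integer(), end = integer(), strand = character(),
             protein_id = character(), stringsAsFactors = FALSE)
}

gff3_attribute <- function(attr, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]+)")
  m <- regmatches(attr, regexec(pat, attr))
  vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_, "")
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to the 1-based inclusive GFF convention.
#'
#' @param genes Gene-model data frame (see [read_gff3()]).
#' @param path Output path.
#' @param source Value for GFF column 2.
#' @param feature_type Feature type written in column 3.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "nlrome", feature_type = "gene") {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chromosome, source, feature_type,
                   genes$start + 1L, genes$end, strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
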