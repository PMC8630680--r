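#' Tally genes per chromosome
#'
#' @param genes Gene-model data frame.
#' @return Named integer vector of per-chromosome counts; unplaced genes
#'   (`chrUn`) are reported under `"unplaced"`.
#' @export
tally_by_chromosome <- function(genes) {
  if (nrow(genes) == 0L) {
    return(stats::setNames(integer(), character()))
  }
  chrom <- ifelse(genes$chromosome == "chrUn", "unplaced", genes$chromosome)
  tab <- table(chrom)
  out <- as.integer(tab)
  names(out) <- names(tab)
  placed <- sort(setdiff(names(out), "unplaced"))
  out[c(placed, intersect("unplaced", names(out)))]
}

#' Group NLR genes into singleton and cluster loci
#'
#' Per chromosome, genes are sorted by start coordinate and successive genes
#' whose start-to-start distance is at most `window_bp` are chained
#' (transitively) into one locus, following the 250-kb sliding-window
#' convention for NLR clusters. The boundary is inclusive; chains may span
#' more than `window_bp` end to end. Strand is ignored. Unplaced (`chrUn`)
#' genes are excluded from clustering and reported via the `n_unplaced`
#' attribute.
#'
#' @param genes Gene-model data frame (the NLR subset).
#' @param window_bp Maximum start-to-start distance (bp) between successive
#'   clustered genes; default 250000.
#' @return Data frame of loci with columns `locus_id`, `chromosome`,
#'   `n_genes`, `span_start`, `span_end` and a list column `gene_ids`
#'   (members ordered by start). Attribute `n_unplaced` carries the count of
#'   excluded unplaced genes.
#' @export
cluster_loci <- function(genes, window_bp = 250000) {
  stopifnot(window_bp > 0)
  placed <- genes[genes$chromosome != "chrUn", , drop = FALSE]
  n_unplaced <- nrow(genes) - nrow(placed)
  if (nrow(placed) == 0L) {
    out <- data.frame(locus_id = character(), chromosome = character(),
                      n_genes = integer(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE)
    out$gene_ids <- list()
    attr(out, "n_unplaced") <- n_unplaced
    return(out)
  }
  placed <- placed[order(placed$chromosome, placed$start, placed$gene_id), ,
                   drop = FALSE]
  rows <- list()
  for (chr in unique(placed$chromosome)) {
    g <- placed[placed$chromosome == chr, , drop = FALSE]
    new_locus <- c(TRUE, diff(g$start) > window_bp)
    locus <- cumsum(new_locus)
    for (l in unique(locus)) {
      m <- g[locus == l, , drop = FALSE]
      rows[[length(rows) + 1L]] <- list(
        chromosome = chr, n_genes = nrow(m),
        span_start = min(m$start), span_end = max(m$end),
        gene_ids = m$gene_id
      )
    }
  }
  out <- data.frame(
    locus_id = sprintf("locus%04d", seq_along(rows)),
    chromosome = vapply(rows, `[[`, "", "chromosome"),
    n_genes = vapply(rows, `[[`, 1L, "n_genes"),
    span_start = vapply(rows, function(r) as.integer(r$span_start), 1L),
    span_end = vapply(rows, function(r) as.integer(r$span_end), 1L),
    stringsAsFactors = FALSE
  )
  out$gene_ids <- lapply(rows, `[[`, "gene_ids")
  attr(out, "n_unplaced") <- n_unplaced
  out
}

#' Summarise the chromosomal layout of NLR loci
#'
#' @param loci Locus data frame from [cluster_loci()].
#' @param n_unplaced Number of unplaced genes (defaults to the attribute set
#'   by [cluster_loci()]).
#' @return A list: `n_genes` (anchored), `n_unplaced`, `n_loci`,
#'   `n_singletons`, `n_clusters`, `n_clustered_genes`, `pct_clustered`
#'   (rounded half-up to integer) and `pct_clustered_raw`,
#'   `mean_genes_per_cluster`, and `cluster_size_histogram` (named integer
#'   vector over cluster sizes >= 2).
#' @export
summarize_layout <- function(loci, n_unplaced = NULL) {
  if (is.null(n_unplaced)) {
    n_unplaced <- attr(loci, "n_unplaced")
    if (is.null(n_unplaced)) n_unplaced <- 0L
  }
  sizes <- loci$n_genes
  n_genes <- sum(sizes)
  singleton <- sizes == 1L
  n_clustered <- sum(sizes[!singleton])
  hist <- table(sizes[!singleton])
  hist_out <- as.integer(hist)
  names(hist_out) <- names(hist)
  pct_raw <- if (n_genes > 0) 100 * n_clustered / n_genes else 0
  list(
    n_genes = n_genes,
    n_unplaced = n_unplaced,
    n_loci = nrow(loci),
    n_singletons = sum(singleton),
    n_clusters = sum(!singleton),
    n_clustered_genes = n_clustered,
    pct_clustered = round_half_up(pct_raw),
    pct_clustered_raw = pct_raw,
    mean_genes_per_cluster = if (any(!singleton)) mean(sizes[!singleton])
                             else NA_real_,
    cluster_size_histogram = hist_out
  )
}

#' Round half away from zero (reporting convention)
#'
#' Base R's `round()` rounds halves to even; summary percentages in reports
#' use the conventional half-up rule instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits; default 0.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
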