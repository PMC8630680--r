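#' Run the NLR analysis pipeline end to end
#'
#' Orchestrates the stages in dependency order — identification, chromosomal
#' layout, intra-genome synteny and duplication typing, and gene-tree /
#' species-tree reconciliation — from a configuration naming the input files
#' per stage, and assembles a consolidated report with the summary tables of
#' a genome-wide NLR study: subclass counts, architecture groups with
#' percentages, the motif histogram, per-chromosome counts, the locus
#' summary, duplication-type proportions, syntenic pair counts and the
#' ancestral-lineage accounting. Percentages are reported rounded half-up to
#' integers alongside the raw ratios.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   `inputs` (paths: `gff`, `fasta`, `domtbl`, `refhits`, `blast_intra`,
#'   `blast_inter`, `gff_b`, `genetrees`, `leafmap`, `speciestree`),
#'   `stages` (subset of `c("identify","layout","dupclass","synteny",
#'   "reconcile")`; defaults to whatever the inputs allow), and optional
#'   `params` overriding defaults (`evalue_cutoff`, `window_bp`, and the
#'   [synteny_params()] entries).
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus TSV tables.
#' @return The report as a nested list, with a `manifest` recording the
#'   configuration, input digests, package version and parameters.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  inputs <- config$inputs
  params <- config$params
  if (is.null(params)) params <- list()
  evalue_cutoff <- params$evalue_cutoff %||% 1e-4
  window_bp <- params$window_bp %||% 250000
  sp <- synteny_params()
  for (nm in intersect(names(params), names(sp))) sp[[nm]] <- params[[nm]]

  stages <- config$stages
  if (is.null(stages)) {
    stages <- c("identify",
                if (!is.null(inputs$gff)) "layout",
                if (!is.null(inputs$blast_intra)) "dupclass",
                if (!is.null(inputs$blast_inter)) "synteny",
                if (!is.null(inputs$genetrees)) "reconcile")
  }
  need <- function(stage, ...) {
    miss <- c(...)[!vapply(c(...), function(k) !is.null(inputs[[k]]),
                           logical(1L))]
    if (length(miss) > 0L) {
      stop("stage '", stage, "' is missing input(s): ",
           paste(miss, collapse = ", "))
    }
  }

  report <- list()
  report$manifest <- list(
    tool = "nlrome",
    version = as.character(utils::packageVersion("nlrome")),
    config = config,
    params = c(list(evalue_cutoff = evalue_cutoff, window_bp = window_bp), sp),
    input_digests = lapply(inputs, function(p)
      if (is.character(p) && file.exists(p)) unname(tools::md5sum(p))
      else NA_character_)
  )

  annotations <- NULL
  genes <- NULL
  nlr_genes <- NULL

  if ("identify" %in% stages) {
    need("identify", "gff", "domtbl")
    genes <- read_gff3(inputs$gff)
    hits <- read_domtbl(inputs$domtbl)
    proteins <- if (!is.null(inputs$fasta)) read_protein_fasta(inputs$fasta)
                else NULL
    refhits <- if (!is.null(inputs$refhits)) {
      utils::read.delim(inputs$refhits, stringsAsFactors = FALSE)
    } else NULL
    annotations <- nlr_annotate(hits, proteins, refhits,
                                evalue_cutoff = evalue_cutoff)
    nlr_genes <- genes[genes$protein_id %in% annotations$protein_id, ,
                       drop = FALSE]
    motif_cols <- default_motif_patterns()$name
    mm <- as.matrix(annotations[, motif_cols, drop = FALSE])
    hist <- count_motif_loss_categories(mm)
    arch_tab <- table(annotations$architecture)
    n <- nrow(annotations)
    report$identify <- list(
      n_nlr = n,
      subclass_counts = as.list(table(annotations$subclass)),
      architecture_counts = as.list(arch_tab),
      architecture_pct = as.list(round_half_up(100 * arch_tab / n)),
      n_with_integrated_domain =
        sum(nzchar(annotations$integrated_domains)),
      pct_with_integrated_domain = round_half_up(
        100 * sum(nzchar(annotations$integrated_domains)) / n),
      n_all_five_motifs = sum(annotations$n_motifs == 5L),
      pct_all_five_motifs = round_half_up(
        100 * sum(annotations$n_motifs == 5L) / n),
      motif_loss_histogram = as.list(hist),
      motif_histogram_consistent = sum(hist) == n
    )
  }

  if ("layout" %in% stages) {
    if (is.null(nlr_genes)) stop("stage 'layout' requires stage 'identify'")
    loci <- cluster_loci(nlr_genes, window_bp)
    lay <- summarize_layout(loci)
    report$layout <- c(list(per_chromosome =
                              as.list(tally_by_chromosome(nlr_genes))),
                       lay[c("n_genes", "n_unplaced", "n_loci",
                             "n_singletons", "n_clusters",
                             "n_clustered_genes", "pct_clustered",
                             "mean_genes_per_cluster")],
                       list(cluster_size_histogram =
                              as.list(lay$cluster_size_histogram)))
    report$tables$loci <- loci
  }

  if ("dupclass" %in% stages) {
    need("dupclass", "blast_intra")
    if (is.null(nlr_genes)) stop("stage 'dupclass' requires stage 'identify'")
    hits <- read_blast_tab(inputs$blast_intra)
    index <- build_rank_index(genes)
    blocks <- chain_anchors(hits, index, index, sp)
    dup <- classify_duplication(nlr_genes$gene_id, hits, index, blocks, sp)
    tab <- table(factor(dup$dup_type,
                        levels = c("singleton", "dispersed", "proximal",
                                   "tandem", "segmental")))
    report$duplication <- list(
      counts = as.list(tab),
      pct = as.list(round_half_up(100 * tab / sum(tab))),
      n_blocks = nrow(blocks)
    )
    report$tables$duplication <- dup
  }

  if ("synteny" %in% stages) {
    need("synteny", "blast_inter", "gff_b", "nlr_b")
    hits <- read_blast_tab(inputs$blast_inter)
    genes_b <- read_gff3(inputs$gff_b)
    nlr_b <- readLines(inputs$nlr_b, warn = FALSE)
    index_a <- build_rank_index(genes)
    index_b <- build_rank_index(genes_b)
    blocks <- chain_anchors(hits, index_a, index_b, sp)
    syn <- syntenic_nlr_pairs(blocks, nlr_genes$gene_id, nlr_b)
    report$synteny <- list(
      n_blocks = nrow(blocks),
      n_nlr_pairs = nrow(syn$pairs),
      pairs_per_chromosome_pair = syn$counts
    )
    report$tables$syntenic_pairs <- syn$pairs
  }

  if ("reconcile" %in% stages) {
    need("reconcile", "genetrees", "leafmap")
    species_tree <- if (!is.null(inputs$speciestree)) {
      read_newick(inputs$speciestree)
    } else triticeae_species_tree()
    lm <- utils::read.delim(inputs$leafmap, header = FALSE,
                            stringsAsFactors = FALSE)
    leaf_map <- stats::setNames(lm[[2L]], lm[[1L]])
    fams <- readLines(inputs$genetrees, warn = FALSE)
    fams <- fams[nzchar(trimws(fams))]
    names(fams) <- sprintf("family%04d", seq_along(fams))
    forest <- reconcile_forest(fams, leaf_map, species_tree)
    venn <- venn_partition(forest$lineages,
                           species = species_tree$tip.label)
    acct <- branch_accounting(forest$lineages, species_tree)
    events <- if (length(forest$reconciliations) > 0L) {
      branch_event_summary(forest$reconciliations)
    } else NULL
    per_species <- vapply(species_tree$tip.label, function(s) {
      sum(venn[grepl(paste0("(^|\\+)", s, "($|\\+)"), names(venn))])
    }, 1L)
    report$reconciliation <- list(
      n_lineages = nrow(forest$lineages),
      venn = as.list(venn),
      inherited_per_species = as.list(per_species),
      branch_accounting = acct,
      branch_duplications = if (is.null(events)) NULL
                            else as.list(events$duplications),
      branch_losses = if (is.null(events)) NULL
                      else as.list(events$losses)
    )
    report$tables$lineages <- forest$lineages[, c("lineage_id", "family",
                                                  "n_members", "presence")]
  }

  if (!is.null(annotations)) report$tables$annotations <- annotations

  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report bundle
#'
#' @param report Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- report$tables
  report$tables <- NULL
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    listcols <- vapply(tb, is.list, logical(1L))
    for (lc in names(tb)[listcols]) {
      tb[[lc]] <- vapply(tb[[lc]], paste, "", collapse = ";")
    }
    utils::write.table(tb, file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
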