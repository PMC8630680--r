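#' Simulation configuration for synthetic NLR genomes
#'
#' Defaults describe a desk-scale rye-like genome: seven chromosomes with a
#' background of ordinary genes, NLR loci planted as singletons and physical
#' clusters (intra-cluster start-to-start spacing well under the 250-kb
#' clustering window, inter-locus spacing well over it), tandem arrays,
#' proximal and dispersed homolog pairs, three intra-genome collinear blocks
#' whose NLR anchors form three segmental pairs, a handful of unplaced
#' genes, one reference-annotated RNL, integrated-domain fusions, and
#' per-motif knockout rates tuned so roughly two thirds of NLR proteins keep
#' all five NBS motifs.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_chromosomes Number of chromosomes (default 7).
#' @param background_per_chromosome Ordinary (non-NLR) genes per chromosome.
#' @param cluster_sizes Sizes of planted NLR clusters (assigned round-robin
#'   to chromosomes); sizes of 15 mirror large resistance-gene clusters.
#' @param n_tandem_clusters How many of the clusters (taken from the front
#'   of `cluster_sizes`) are tandem arrays, i.e. also carry homology hits
#'   between adjacent members.
#' @param n_proximal_pairs,n_dispersed_pairs Planted homolog pairs within 10
#'   ranks on one chromosome / across chromosomes.
#' @param n_segmental_blocks Planted intra-genome collinear blocks; each
#'   contributes one NLR anchor pair (two segmental genes).
#' @param block_len Anchors per planted block (>= 5 to be detectable).
#' @param n_singletons Plain singleton NLR loci (no homologs).
#' @param n_unplaced NLR genes on unplaced scaffolds (`chrUn`).
#' @param architecture_mix Proportions of base architectures; must sum to 1.
#' @param id_rate Probability that a CNL gene carries an integrated domain.
#' @param n_rnl Number of RNL genes (classified via the reference best-hit
#'   table; their proteins lack a detectable RPW8 domain).
#' @param motif_knockout_rate Per-motif knockout probability (length 5 or 1).
#' @param intra_cluster_bp Start-to-start spacing within clusters (bp).
#' @param inter_locus_bp Minimum spacing flanking every NLR locus (bp).
#' @param bg_gap_bp Start-to-start spacing of background genes (bp).
#' @param decoy_n Decoy NB-ARC domain rows at `decoy_evalue` planted on
#'   background proteins (removed by the E-value filter).
#' @param decoy_evalue Independent E-value of decoy rows.
#' @param noise_hits Random homology rows at `noise_evalue` (above the
#'   chaining cutoff, so they change nothing).
#' @param noise_evalue E-value of noise homology rows.
#' @param genome_tag Prefix distinguishing genomes (for two-genome setups).
#' @return A validated configuration list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 7L,
                       background_per_chromosome = 40L,
                       cluster_sizes = c(2L, 2L, 3L, 3L, 4L, 15L),
                       n_tandem_clusters = 3L,
                       n_proximal_pairs = 3L,
                       n_dispersed_pairs = 4L,
                       n_segmental_blocks = 3L,
                       block_len = 6L,
                       n_singletons = 14L,
                       n_unplaced = 3L,
                       architecture_mix = c(CNL = 0.35, CN = 0.24,
                                            NL = 0.11, N = 0.25,
                                            other = 0.05),
                       id_rate = 0.08,
                       n_rnl = 1L,
                       motif_knockout_rate = 0.07,
                       intra_cluster_bp = 50000L,
                       inter_locus_bp = 400000L,
                       bg_gap_bp = 35000L,
                       decoy_n = 10L,
                       decoy_evalue = 0.5,
                       noise_hits = 20L,
                       noise_evalue = 1e-3,
                       genome_tag = "A") {
  stopifnot(abs(sum(architecture_mix) - 1) < 1e-9,
            intra_cluster_bp < 250000L, inter_locus_bp > 250000L,
            block_len >= 5L, n_tandem_clusters <= length(cluster_sizes))
  if (length(motif_knockout_rate) == 1L) {
    motif_knockout_rate <- rep(motif_knockout_rate, 5L)
  }
  stopifnot(length(motif_knockout_rate) == 5L)
  as.list(environment())
}

# ---- sequence cassettes ----------------------------------------------------
# All filler/linker alphabets avoid residues that could complete any default
# motif pattern (no G+K/T runs, no DD, no R, no P, no F), so motif truth is
# exactly what was planted.
safe_filler <- function(n) {
  paste(rep_len(strsplit("NQCA", "")[[1L]], n), collapse = "")
}

motif_sequences <- function() {
  c("P-loop" = "GMGGLGKTT", "Kinase-2" = "LLVLDDVW", "RNBS-B" = "QTTRQ",
    "GLPL" = "GLPL", "RNBS-D" = "FLHIQ")
}

cc_cassette <- function() paste(rep("LQQLLQQ", 6L), collapse = "")
lrr_cassette <- function() paste(rep("LGSLGLSSN", 6L), collapse = "")

nbarc_cassette <- function(motifs_present) {
  mot <- motif_sequences()
  parts <- character(0)
  offs <- list()
  pos <- 0L
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add(safe_filler(8L))
  for (i in seq_along(mot)) {
    m <- if (motifs_present[i]) mot[[i]] else safe_filler(nchar(mot[[i]]))
    add(m)
    add(safe_filler(10L))
  }
  paste(parts, collapse = "")
}

id_accessions <- function() {
  c(WRKY = "PF03106", Jacalin = "PF01419", ZnF_BED = "PF02892")
}

# Assemble one protein from cassettes; returns sequence plus domain rows
# (0-based half-open envelopes) ready for the domtblout writer.
build_protein <- function(base_arch, motifs_present, id_wrap = "",
                          id_domain = NA_character_) {
  seqs <- character(0)
  doms <- list()
  pos <- 0L
  add <- function(s, accession = NULL, name = NULL, evalue = 1e-10) {
    if (!is.null(accession)) {
      doms[[length(doms) + 1L]] <<- list(accession = accession, name = name,
                                         env_start = pos,
                                         env_end = pos + nchar(s),
                                         i_evalue = evalue)
    }
    seqs[[length(seqs) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  idacc <- id_accessions()
  if (id_wrap %in% c("ID-CNL", "ID-CNL-ID")) {
    add(safe_filler(60L), idacc[[id_domain]], id_domain)
    add(safe_filler(10L))
  }
  if (base_arch %in% c("CNL", "CN")) {
    add(cc_cassette(), "CDD:CC", "CC")
    add(safe_filler(12L))
  } else {
    add(safe_filler(30L))
  }
  add(nbarc_cassette(motifs_present), "PF00931", "NB-ARC", 1e-20)
  if (base_arch == "other") {
    add(safe_filler(60L))
    add(nbarc_cassette(rep(TRUE, 5L)), "PF00931", "NB-ARC", 1e-18)
  }
  if (base_arch %in% c("CNL", "NL")) {
    add(safe_filler(12L))
    add(lrr_cassette(), "PF13855", "LRR_8")
  }
  if (id_wrap %in% c("CNL-ID", "ID-CNL-ID")) {
    add(safe_filler(10L))
    add(safe_filler(60L), idacc[[id_domain]], id_domain)
  }
  add(safe_filler(20L))
  dom_df <- do.call(rbind, lapply(doms, function(d) {
    data.frame(domain_accession = d$accession, domain_name = d$name,
               env_start = d$env_start, env_end = d$env_end,
               i_evalue = d$i_evalue, stringsAsFactors = FALSE)
  }))
  list(seq = paste(seqs, collapse = ""), domains = dom_df)
}

#' Generate a synthetic genome with planted NLR structure
#'
#' Builds gene models on `n_chromosomes` chromosomes plus unplaced scaffolds,
#' assembles protein sequences from domain cassettes (so domain-hit tables
#' can be emitted without any external search tool), and plants clusters,
#' tandem arrays, proximal/dispersed pairs and intra-genome collinear blocks
#' with exact machine-readable ground truth. Deterministic for a fixed seed.
#'
#' @param config Configuration from [sim_config()].
#' @return A list with `genes` (gene-model data frame), `proteins` (named
#'   character vector), `domain_truth` (planted domain envelope rows),
#'   `relations` (planted homolog pairs with their duplication class),
#'   `blocks` (planted collinear block anchor tables), `reference_hits`
#'   (reference best-hit rows for RNL genes) and `truth` (per-gene truth
#'   table plus layout summary truth).
#' @export
gen_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  tag <- config$genome_tag
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  # ---- NLR roster -----------------------------------------------------------
  nlr_specs <- list()
  new_nlr <- function(kind, cluster = NA_character_, dup = NA_character_) {
    nlr_specs[[length(nlr_specs) + 1L]] <<-
      list(kind = kind, cluster = cluster, dup = dup)
    length(nlr_specs)
  }

  # chromosome plans: ordered unit lists
  plans <- stats::setNames(vector("list", length(chroms)), chroms)
  add_unit <- function(chr, unit) {
    plans[[chr]][[length(plans[[chr]]) + 1L]] <<- unit
  }

  # clusters (first n_tandem_clusters are tandem arrays)
  for (i in seq_along(config$cluster_sizes)) {
    chr <- chroms[((i - 1L) %% length(chroms)) + 1L]
    size <- config$cluster_sizes[i]
    tandem <- i <= config$n_tandem_clusters
    tagc <- sprintf("cluster%02d", i)
    ids <- vapply(seq_len(size), function(j) {
      new_nlr("cluster", tagc, if (tandem) "tandem" else "singleton")
    }, 1L)
    add_unit(chr, list(type = "cluster", nlr = ids, tandem = tandem))
  }
  # proximal pairs
  for (i in seq_len(config$n_proximal_pairs)) {
    chr <- chroms[((i - 1L) %% length(chroms)) + 1L]
    a <- new_nlr("proximal", dup = "proximal")
    b <- new_nlr("proximal", dup = "proximal")
    add_unit(chr, list(type = "proximal", nlr = c(a, b), n_between = 9L))
  }
  # dispersed pairs (two chromosomes each)
  dispersed_pairs <- list()
  for (i in seq_len(config$n_dispersed_pairs)) {
    c1 <- chroms[((2L * i - 2L) %% length(chroms)) + 1L]
    c2 <- chroms[((2L * i - 1L) %% length(chroms)) + 1L]
    a <- new_nlr("dispersed", dup = "dispersed")
    b <- new_nlr("dispersed", dup = "dispersed")
    add_unit(c1, list(type = "single", nlr = a))
    add_unit(c2, list(type = "single", nlr = b))
    dispersed_pairs[[i]] <- c(a, b)
  }
  # segmental blocks: two 6-gene segments, one NLR anchor each
  seg_blocks <- list()
  for (i in seq_len(config$n_segmental_blocks)) {
    cA <- chroms[((i - 1L) %% length(chroms)) + 1L]
    cB <- chroms[((i + 1L) %% length(chroms)) + 1L]
    if (i > 1L) cB <- cA  # later blocks are intra-chromosomal, as in rye
    a <- new_nlr("segmental", dup = "segmental")
    b <- new_nlr("segmental", dup = "segmental")
    add_unit(cA, list(type = "segment", nlr = a, block = i, side = "a",
                      len = config$block_len, nlr_at = 3L))
    add_unit(cB, list(type = "segment", nlr = b, block = i, side = "b",
                      len = config$block_len, nlr_at = 3L))
    seg_blocks[[i]] <- c(a, b)
  }
  # plain singletons
  for (i in seq_len(config$n_singletons)) {
    chr <- chroms[((i - 1L) %% length(chroms)) + 1L]
    add_unit(chr, list(type = "single",
                       nlr = new_nlr("singleton", dup = "singleton")))
  }

  n_placed_nlr <- length(nlr_specs)
  for (i in seq_len(config$n_unplaced)) {
    new_nlr("unplaced", dup = "singleton")
  }
  n_nlr <- length(nlr_specs)

  # ---- architectures, subclasses, motifs ------------------------------------
  mix <- config$architecture_mix
  base_arch <- sample(names(mix), n_nlr, replace = TRUE, prob = mix)
  id_wrap <- rep("", n_nlr)
  cnl_idx <- which(base_arch == "CNL")
  n_id <- stats::rbinom(1L, length(cnl_idx), config$id_rate)
  if (n_id > 0L) {
    pick <- cnl_idx[sample.int(length(cnl_idx), n_id)]
    id_wrap[pick] <- sample(c("CNL-ID", "ID-CNL", "ID-CNL-ID"), n_id,
                            replace = TRUE, prob = c(23, 25, 1))
  }
  id_domain <- rep(NA_character_, n_nlr)
  id_domain[id_wrap != ""] <- sample(names(id_accessions()),
                                     sum(id_wrap != ""), replace = TRUE)
  subclass <- rep("CNL", n_nlr)
  if (config$n_rnl > 0L) {
    pool <- which(base_arch %in% c("NL", "N") & id_wrap == "")
    rnl_idx <- pool[sample.int(length(pool), min(config$n_rnl, length(pool)))]
    subclass[rnl_idx] <- "RNL"
    base_arch[rnl_idx] <- "NL"  # NBS and LRR, no detectable RPW8
  }
  motifs <- matrix(TRUE, n_nlr, 5L)
  for (k in 1:5) {
    motifs[, k] <- stats::runif(n_nlr) >= config$motif_knockout_rate[k]
  }

  # ---- assemble chromosomes -------------------------------------------------
  gene_rows <- list()
  dom_rows <- list()
  prot <- character(0)
  gene_counter <- 0L
  nlr_gene_id <- character(n_nlr)
  block_anchor_acc <- lapply(seq_len(config$n_segmental_blocks),
                             function(i) list(a = character(), b = character()))

  emit_gene <- function(chr, start, nlr_id = NA_integer_) {
    gene_counter <<- gene_counter + 1L
    gid <- sprintf("%s%s.g%03d", tag, chr, gene_counter)
    if (is.na(nlr_id)) {
      seq <- safe_filler(200L)
      dom <- NULL
      is_nlr <- FALSE
    } else {
      bp <- build_protein(base_arch[nlr_id], motifs[nlr_id, ],
                          id_wrap[nlr_id], id_domain[nlr_id])
      seq <- bp$seq
      dom <- bp$domains
      dom$protein_id <- gid
      is_nlr <- TRUE
      nlr_gene_id[nlr_id] <<- gid
    }
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      gene_id = gid, chromosome = chr, start = start,
      end = start + 3000L, strand = if (gene_counter %% 2L) "+" else "-",
      protein_id = gid, is_nlr = is_nlr,
      nlr_id = if (is.na(nlr_id)) NA_integer_ else nlr_id,
      stringsAsFactors = FALSE)
    if (!is.null(dom)) dom_rows[[length(dom_rows) + 1L]] <<- dom
    prot[gid] <<- seq
    gid
  }

  for (chr in chroms) {
    units <- plans[[chr]]
    if (is.null(units)) units <- list()
    if (length(units) > 1L) {
      units <- units[sample.int(length(units))]  # shuffle along chromosome
    }
    n_bg <- config$background_per_chromosome
    bg_chunks <- if (length(units) > 0L) {
      sizes <- rep(n_bg %/% (length(units) + 1L), length(units) + 1L)
      sizes[1L] <- sizes[1L] + n_bg %% (length(units) + 1L)
      sizes
    } else n_bg
    cursor <- 1000000L
    place_bg <- function(k) {
      for (j in seq_len(k)) {
        emit_gene(chr, cursor)
        cursor <<- cursor + config$bg_gap_bp
      }
    }
    for (u in seq_along(units)) {
      place_bg(bg_chunks[u])
      unit <- units[[u]]
      cursor <- cursor + config$inter_locus_bp
      if (unit$type == "cluster") {
        for (nid in unit$nlr) {
          emit_gene(chr, cursor, nid)
          cursor <- cursor + config$intra_cluster_bp
        }
        cursor <- cursor - config$intra_cluster_bp
      } else if (unit$type == "single") {
        emit_gene(chr, cursor, unit$nlr)
      } else if (unit$type == "proximal") {
        emit_gene(chr, cursor, unit$nlr[1L])
        for (j in seq_len(unit$n_between)) {
          cursor <- cursor + config$bg_gap_bp
          emit_gene(chr, cursor)
        }
        cursor <- cursor + config$bg_gap_bp
        emit_gene(chr, cursor, unit$nlr[2L])
      } else if (unit$type == "segment") {
        ids <- character(unit$len)
        for (j in seq_len(unit$len)) {
          ids[j] <- emit_gene(chr, cursor,
                              if (j == unit$nlr_at) unit$nlr else NA_integer_)
          if (j < unit$len) cursor <- cursor + config$bg_gap_bp
        }
        block_anchor_acc[[unit$block]][[unit$side]] <- ids
      }
      cursor <- cursor + config$inter_locus_bp
    }
    place_bg(bg_chunks[length(bg_chunks)])
  }
  # unplaced NLRs
  for (nid in which(vapply(nlr_specs, `[[`, "", "kind") == "unplaced")) {
    emit_gene("chrUn", 5000L + 10000L * nid, nid)
  }

  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  domain_truth <- do.call(rbind, dom_rows)
  domain_truth <- domain_truth[, c("protein_id", "domain_accession",
                                   "domain_name", "env_start", "env_end",
                                   "i_evalue")]
  rownames(domain_truth) <- NULL

  # ---- planted relations ----------------------------------------------------
  rel <- list()
  add_rel <- function(a, b, class) {
    rel[[length(rel) + 1L]] <<- data.frame(
      gene_a = a, gene_b = b, class = class, stringsAsFactors = FALSE)
  }
  for (i in seq_along(config$cluster_sizes)) {
    if (i > config$n_tandem_clusters) next
    ids <- which(vapply(nlr_specs, function(s)
      identical(s$cluster, sprintf("cluster%02d", i)), TRUE))
    gids <- nlr_gene_id[ids]
    for (a in seq_along(gids)) {
      for (b in seq_along(gids)) {
        if (a < b) add_rel(gids[a], gids[b], "tandem")
      }
    }
  }
  prox_ids <- which(vapply(nlr_specs, `[[`, "", "kind") == "proximal")
  for (i in seq_len(length(prox_ids) %/% 2L)) {
    add_rel(nlr_gene_id[prox_ids[2L * i - 1L]],
            nlr_gene_id[prox_ids[2L * i]], "proximal")
  }
  for (p in dispersed_pairs) {
    add_rel(nlr_gene_id[p[1L]], nlr_gene_id[p[2L]], "dispersed")
  }
  relations <- if (length(rel) > 0L) do.call(rbind, rel) else
    data.frame(gene_a = character(), gene_b = character(),
               class = character(), stringsAsFactors = FALSE)

  blocks <- lapply(seq_len(config$n_segmental_blocks), function(i) {
    data.frame(gene_a = block_anchor_acc[[i]]$a,
               gene_b = block_anchor_acc[[i]]$b,
               block = i, stringsAsFactors = FALSE)
  })

  # ---- reference hits (RNL) -------------------------------------------------
  rnl_genes <- nlr_gene_id[subclass == "RNL"]
  reference_hits <- data.frame(protein_id = rnl_genes,
                               besthit = rep("ADR1", length(rnl_genes)),
                               stringsAsFactors = FALSE)

  # ---- per-gene truth -------------------------------------------------------
  arch_label <- ifelse(id_wrap != "", id_wrap, base_arch)
  truth_genes <- data.frame(
    gene_id = nlr_gene_id,
    kind = vapply(nlr_specs, `[[`, "", "kind"),
    cluster = vapply(nlr_specs, function(s)
      if (is.na(s$cluster)) NA_character_ else s$cluster, ""),
    dup_type = vapply(nlr_specs, `[[`, "", "dup"),
    subclass = subclass,
    base_architecture = base_arch,
    architecture = arch_label,
    integrated_domain = id_domain,
    stringsAsFactors = FALSE
  )
  for (k in 1:5) truth_genes[[paste0("motif", k)]] <- motifs[, k]

  list(genes = genes[, c("gene_id", "chromosome", "start", "end", "strand",
                         "protein_id")],
       gene_flags = genes[, c("gene_id", "is_nlr")],
       proteins = prot,
       domain_truth = domain_truth,
       relations = relations,
       blocks = blocks,
       reference_hits = reference_hits,
       truth = list(genes = truth_genes,
                    n_nlr = n_nlr,
                    n_placed_nlr = n_placed_nlr,
                    n_unplaced = config$n_unplaced),
       config = config)
}

#' Emit a domain-hit table consistent with the planted architectures
#'
#' Returns the planted domain envelopes plus configurable decoy NB-ARC rows
#' at a high E-value on background proteins (removed by the identification
#' filter) and kinase-domain rows on other background proteins.
#'
#' @param sim Result of [gen_genome()].
#' @return A domain-hit data frame (see [read_domtbl()] for the schema).
#' @export
gen_domtbl <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  hits <- sim$domain_truth
  bg <- sim$gene_flags$gene_id[!sim$gene_flags$is_nlr]
  if (cfg$decoy_n > 0L && length(bg) > 0L) {
    pick <- sample(bg, min(cfg$decoy_n, length(bg)))
    half <- length(pick) %/% 2L
    decoy <- data.frame(
      protein_id = pick,
      domain_accession = c(rep("PF00931", half),
                           rep("PF00069", length(pick) - half)),
      domain_name = c(rep("NB-ARC", half),
                      rep("Pkinase", length(pick) - half)),
      env_start = 10L, env_end = 90L,
      i_evalue = cfg$decoy_evalue,
      stringsAsFactors = FALSE)
    hits <- rbind(hits, decoy)
  }
  rownames(hits) <- NULL
  hits
}

#' Emit an intra-genome homology table with planted duplication structure
#'
#' Symmetric high-confidence hits for planted tandem arrays, proximal and
#' dispersed pairs, anchor-to-anchor hits for every planted collinear block,
#' and random noise rows above the chaining E-value cutoff.
#'
#' @param sim Result of [gen_genome()].
#' @return A homology-hit data frame (see [read_blast_tab()]).
#' @export
gen_homology <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 2L)
  rows <- list()
  add <- function(a, b, evalue = 1e-50, ident = 92, bits = 500) {
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = c(a, b), subject_id = c(b, a),
      pct_identity = ident, evalue = evalue, bitscore = bits,
      stringsAsFactors = FALSE)
  }
  if (nrow(sim$relations) > 0L) {
    for (i in seq_len(nrow(sim$relations))) {
      add(sim$relations$gene_a[i], sim$relations$gene_b[i])
    }
  }
  for (bl in sim$blocks) {
    for (i in seq_len(nrow(bl))) add(bl$gene_a[i], bl$gene_b[i])
  }
  all_ids <- sim$genes$gene_id
  if (cfg$noise_hits > 0L && length(all_ids) >= 2L) {
    qa <- sample(all_ids, cfg$noise_hits, replace = TRUE)
    qb <- sample(all_ids, cfg$noise_hits, replace = TRUE)
    keep <- qa != qb
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qa[keep], subject_id = qb[keep],
        pct_identity = 35, evalue = cfg$noise_evalue, bitscore = 60,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plant inter-genome collinear blocks between two synthetic genomes
#'
#' Picks runs of consecutive genes on matching chromosomes of two genomes
#' and emits anchor-to-anchor homology hits, optionally reversing one side
#' (an inverted block). Runs are chosen so some anchors are NLR genes in
#' both genomes, providing ground truth for syntenic NLR pair counting.
#'
#' @param genes_a,genes_b Gene-model data frames of the two genomes.
#' @param n_blocks Number of planted blocks.
#' @param block_len Anchors per block.
#' @param invert Logical vector (recycled): invert each block?
#' @param seed Integer seed.
#' @return A list with `hits` (homology data frame) and `truth` (data frame
#'   of planted anchors: `gene_a`, `gene_b`, `block`, `inverted`).
#' @export
gen_interspecies_homology <- function(genes_a, genes_b, n_blocks = 4L,
                                      block_len = 8L, invert = FALSE,
                                      seed = 1L) {
  set.seed(seed)
  invert <- rep_len(invert, n_blocks)
  ia <- build_rank_index(genes_a)
  ib <- build_rank_index(genes_b)
  chroms <- intersect(unique(ia$chromosome), unique(ib$chromosome))
  rows <- list(); truth <- list()
  for (k in seq_len(n_blocks)) {
    chr <- chroms[((k - 1L) %% length(chroms)) + 1L]
    ga <- ia$gene_id[ia$chromosome == chr]
    gb <- ib$gene_id[ib$chromosome == chr]
    len <- min(block_len, length(ga), length(gb))
    sa <- sample(seq_len(length(ga) - len + 1L), 1L)
    runa <- ga[sa:(sa + len - 1L)]
    runb <- gb[sa:(sa + len - 1L)]
    if (invert[k]) runb <- rev(runb)
    for (i in seq_len(len)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = runa[i], subject_id = runb[i], pct_identity = 88,
        evalue = 1e-60, bitscore = 480, stringsAsFactors = FALSE)
    }
    truth[[k]] <- data.frame(gene_a = runa, gene_b = runb, block = k,
                             inverted = invert[k], stringsAsFactors = FALSE)
  }
  list(hits = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Write a simulated genome to standard files
#'
#' Emits GFF3, protein FASTA, an hmmscan-dialect domain table, a BLAST
#' outfmt-6 homology table and TSV truth tables into a directory.
#'
#' @param sim Result of [gen_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  write_protein_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  qlen <- stats::setNames(nchar(sim$proteins), names(sim$proteins))
  write_domtbl(gen_domtbl(sim), file.path(dir, "domains.domtbl"), qlen)
  write_blast_tab(gen_homology(sim), file.path(dir, "homology.blast6"))
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$reference_hits, file.path(dir, "reference_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
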