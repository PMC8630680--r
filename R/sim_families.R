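#' Simulate gene families by birth-death along the species tree
#'
#' Each family starts as a single gene copy on a stem branch above the
#' species root and evolves by a constant-rate birth-death process
#' (duplication rate `lambda`, loss rate `mu`) along every branch. At each
#' species-tree node surviving copies speciate into both daughter branches;
#' copies reaching a tip become extant genes. Extinct copies are pruned from
#' the reported gene trees.
#'
#' Ground truth is recorded at the level of *observable* events, i.e. the
#' events that remain inferable after pruning: a duplication is recorded iff
#' both daughter copies left extant descendants, placed at the species node
#' spanning their joint extant species; a loss is recorded for the dead
#' daughter of a surviving speciation passage iff it falls at or below the
#' species image of the nearest retained ancestor node (below when that
#' ancestor is a speciation, at-or-below when it is a duplication). Root
#' ancestral lineages are obtained by cutting each pruned tree at retained
#' duplications spanning the species root.
#'
#' @param species_tree Rooted binary `phylo` with branch lengths; default
#'   [triticeae_species_tree()].
#' @param lambda,mu Nonnegative duplication and loss rates per copy per unit
#'   branch length.
#' @param n_families Number of independent families.
#' @param seed Optional integer seed.
#' @param stem_length Length of the stem branch above the root; default 1.
#' @return A list: `newick` (named character vector, one rooted tree per
#'   surviving family; single-gene families are bare `label;` strings),
#'   `leaf_map` (named character vector leaf -> species label), `families`
#'   (data frame `family`, `n_extant`, `n_lineages`, `extinct`), `lineages`
#'   (data frame `family`, `presence`), `truth_duplications` and
#'   `truth_losses` (named integer vectors per species node/branch label).
#' @export
sim_gene_families <- function(species_tree = triticeae_species_tree(),
                              lambda, mu, n_families, seed = NULL,
                              stem_length = 1) {
  stopifnot(lambda >= 0, mu >= 0, n_families >= 0)
  if (!is.null(seed)) set.seed(seed)
  sp <- index_species_tree(species_tree)
  blen <- stats::setNames(rep(NA_real_, sp$n_node), NULL)
  blen[species_tree$edge[, 2L]] <- species_tree$edge.length
  children_of <- function(v) species_tree$edge[species_tree$edge[, 1L] == v, 2L]

  sim_copy <- function(node, t_remaining) {
    rate <- lambda + mu
    w <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (w < t_remaining) {
      if (stats::runif(1L) < lambda / rate) {
        list(kind = "dup", node = node,
             children = list(sim_copy(node, t_remaining - w),
                             sim_copy(node, t_remaining - w)))
      } else {
        list(kind = "dead")
      }
    } else if (node <= sp$n_tip) {
      list(kind = "leaf", node = node)
    } else {
      kids <- children_of(node)
      list(kind = "spec", node = node,
           children = lapply(kids, function(k) sim_copy(k, blen[k])))
    }
  }

  extant_species <- function(x) {
    switch(x$kind,
           leaf = x$node,
           dead = integer(),
           sort(unique(unlist(lapply(x$children, extant_species)))))
  }
  lca_of_set <- function(nodes) Reduce(function(a, b) species_lca(sp, a, b),
                                       nodes)

  dup_truth <- stats::setNames(integer(sp$n_node), sp$labels)
  loss_truth <- stats::setNames(integer(sp$n_node), sp$labels)
  fam_rows <- list(); lin_rows <- list()
  newick <- character(); leaf_map <- character()

  for (f in seq_len(n_families)) {
    fam <- sprintf("fam%04d", f)
    root_copy <- sim_copy(sp$root, stem_length)
    ext <- extant_species(root_copy)
    extinct <- length(ext) == 0L

    # --- observable event accounting -------------------------------------
    # Truth is the parsimony-observable history on the pruned structure:
    # hidden events (a duplication whose copies are later re-partitioned by
    # complementary losses, losses below unobservable duplications) are not
    # inferable by any method and are not recorded. Retained nodes are those
    # with >= 2 surviving children; each maps to the species LCA of its
    # extant descendants; a retained node is a duplication iff it maps where
    # one of its retained children maps, and losses are the species-path
    # gaps between the images of consecutive retained nodes.
    live_of <- function(x) {
      vapply(x$children, function(c) length(extant_species(c)) > 0L,
             logical(1L))
    }
    next_kept <- function(x) {
      if (x$kind == "leaf") return(x)
      live <- which(live_of(x))
      if (length(live) >= 2L) x else next_kept(x$children[[live]])
    }
    count_losses <- function(m_child, m_parent, rec_dup) {
      steps <- sp$depth[m_child] - sp$depth[m_parent] - 1L
      if (rec_dup && m_child != m_parent) steps <- steps + 1L
      x <- m_child
      while (steps > 0L) {
        par <- sp$parent[x]
        sib <- setdiff(children_of(par), x)
        loss_truth[sp$labels[sib]] <<- loss_truth[sp$labels[sib]] + 1L
        x <- par
        steps <- steps - 1L
      }
    }
    traverse <- function(v) { # v: retained node or leaf
      if (v$kind == "leaf") return(invisible())
      kept_children <- lapply(v$children[live_of(v)], next_kept)
      m_v <- lca_of_set(extant_species(v))
      m_ch <- vapply(kept_children,
                     function(b) lca_of_set(extant_species(b)), 1L)
      rec_dup <- any(m_ch == m_v)
      if (rec_dup) {
        dup_truth[sp$labels[m_v]] <<- dup_truth[sp$labels[m_v]] + 1L
      }
      for (i in seq_along(kept_children)) {
        count_losses(m_ch[i], m_v, rec_dup)
        traverse(kept_children[[i]])
      }
    }
    if (!extinct) traverse(next_kept(root_copy))

    # --- ancestral lineage truth -----------------------------------------
    # cut the pruned structure at retained duplications mapping to the root
    lineages_of <- function(v) {
      if (v$kind != "leaf") {
        kept_children <- lapply(v$children[live_of(v)], next_kept)
        m_v <- lca_of_set(extant_species(v))
        m_ch <- vapply(kept_children,
                       function(b) lca_of_set(extant_species(b)), 1L)
        if (any(m_ch == m_v) && m_v == sp$root) {
          return(do.call(c, lapply(kept_children, lineages_of)))
        }
      }
      list(extant_species(v))
    }
    n_lin <- 0L
    if (!extinct) {
      lins <- lineages_of(next_kept(root_copy))
      n_lin <- length(lins)
      for (l in lins) {
        lin_rows[[length(lin_rows) + 1L]] <- list(
          family = fam,
          presence = paste(sort(sp$labels[unlist(l)]), collapse = "+"))
      }
    }

    # --- pruned gene tree --------------------------------------------------
    counter <- stats::setNames(rep(0L, sp$n_tip), species_tree$tip.label)
    build <- function(x) {
      if (x$kind == "dead") return(NULL)
      if (x$kind == "leaf") {
        spn <- species_tree$tip.label[x$node]
        counter[spn] <<- counter[spn] + 1L
        lab <- sprintf("%s_%s_%d", fam, spn, counter[spn])
        leaf_map[lab] <<- spn
        return(lab)
      }
      parts <- Filter(Negate(is.null), lapply(x$children, build))
      if (length(parts) == 0L) return(NULL)
      if (length(parts) == 1L) return(parts[[1L]])
      paste0("(", paste(parts, collapse = ","), ")")
    }
    if (!extinct) {
      newick[fam] <- paste0(build(root_copy), ";")
    }
    fam_rows[[f]] <- list(family = fam, n_extant = 0L, n_lineages = n_lin,
                          extinct = extinct)
    if (!extinct) fam_rows[[f]]$n_extant <- sum(counter)
  }

  families <- data.frame(
    family = vapply(fam_rows, `[[`, "", "family"),
    n_extant = vapply(fam_rows, `[[`, 1L, "n_extant"),
    n_lineages = vapply(fam_rows, `[[`, 1L, "n_lineages"),
    extinct = vapply(fam_rows, `[[`, TRUE, "extinct"),
    stringsAsFactors = FALSE
  )
  lineages <- data.frame(
    family = vapply(lin_rows, `[[`, "", "family"),
    presence = vapply(lin_rows, `[[`, "", "presence"),
    stringsAsFactors = FALSE
  )
  list(newick = newick, leaf_map = leaf_map, families = families,
       lineages = lineages, truth_duplications = dup_truth,
       truth_losses = loss_truth, species_tree = species_tree)
}

#' Reconcile a forest of family trees against one species tree
#'
#' Convenience wrapper: parses each family's Newick string, reconciles it
#' with [lca_map()] and decomposes ancestral lineages. Single-gene families
#' (bare `label;` strings, which are not binary trees) contribute one
#' lineage with a singleton presence set directly.
#'
#' @param newick Named character vector of Newick strings (one per family).
#' @param leaf_species_map Named character vector leaf -> species label.
#' @param species_tree Rooted binary species tree.
#' @return A list with `reconciliations` (named list of [lca_map()] results
#'   for multi-gene families) and `lineages` (data frame over all families).
#' @export
reconcile_forest <- function(newick, leaf_species_map,
                             species_tree = triticeae_species_tree()) {
  recs <- list()
  singleton_rows <- list()
  for (fam in names(newick)) {
    txt <- newick[[fam]]
    if (!grepl("(", txt, fixed = TRUE)) {
      leaf <- sub(";.*$", "", trimws(txt))
      singleton_rows[[length(singleton_rows) + 1L]] <- list(
        family = fam, members = leaf,
        presence = unname(leaf_species_map[leaf]))
      next
    }
    gt <- read_newick(txt)
    recs[[fam]] <- lca_map(gt, species_tree, leaf_species_map)
  }
  lineages <- decompose_lineages(recs)
  if (length(singleton_rows) > 0L) {
    extra <- data.frame(
      lineage_id = sprintf("lineageS%04d", seq_along(singleton_rows)),
      family = vapply(singleton_rows, `[[`, "", "family"),
      n_members = 1L,
      presence = vapply(singleton_rows, `[[`, "", "presence"),
      stringsAsFactors = FALSE
    )
    extra$members <- lapply(singleton_rows, `[[`, "members")
    lineages <- rbind(lineages, extra)
  }
  list(reconciliations = recs, lineages = lineages)
}
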