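#' The default Triticeae species tree
#'
#' Rooted binary species tree over rye (*Secale cereale*, `Sc`), diploid
#' wheat (*Triticum urartu*, `Tu`) and barley (*Hordeum vulgare*, `Hv`):
#' `((Sc,Tu),Hv)`. Branch lengths are in arbitrary time units used by the
#' birth-death simulator.
#'
#' @return A `phylo` object with node labels `ScTu` and `root`.
#' @export
triticeae_species_tree <- function() {
  read_newick("((Sc:1,Tu:1)ScTu:1,Hv:2)root;")
}

# Flat indexed view of a rooted tree: per-node parent, depth, label, and the
# tip set below each node. Node ids follow ape numbering (tips first).
index_species_tree <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  depth <- rep(NA_integer_, n_node)
  depth[root] <- 0L
  # simple repeated relaxation (trees are small)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
      if (!is.na(depth[p]) && is.na(depth[c])) {
        depth[c] <- depth[p] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels <- character(n_node)
  labels[seq_len(n_tip)] <- tree$tip.label
  if (!is.null(tree$node.label)) {
    labels[(n_tip + 1L):n_node] <- tree$node.label
  }
  need <- which(!nzchar(labels))
  tips_below <- vector("list", n_node)
  for (v in seq_len(n_node)) {
    tips_below[[v]] <- tree$tip.label[tips_under(tree, v)]
  }
  for (v in need) {
    labels[v] <- paste0("anc(", paste(sort(tips_below[[v]]), collapse = ","),
                        ")")
  }
  list(tree = tree, n_tip = n_tip, n_node = n_node, parent = parent,
       root = root, depth = depth, labels = labels, tips_below = tips_below)
}

tips_under <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(v)
  out <- integer()
  stack <- v
  while (length(stack) > 0L) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x <= n_tip) {
      out <- c(out, x)
    } else {
      stack <- c(stack, tree$edge[tree$edge[, 1L] == x, 2L])
    }
  }
  out
}

species_lca <- function(sp_index, a, b) {
  while (a != b) {
    if (sp_index$depth[a] < sp_index$depth[b]) b <- sp_index$parent[b]
    else if (sp_index$depth[a] > sp_index$depth[b]) a <- sp_index$parent[a]
    else { a <- sp_index$parent[a]; b <- sp_index$parent[b] }
  }
  a
}

# Deterministic resolution of polytomies: children sorted by smallest tip
# label, combined left to right.
resolve_polytomies_sorted <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  tree <- ape::makeNodeLabel(tree, method = "number", prefix = "n")
  mm <- ape::multi2di(tree, random = FALSE)
  mm
}

#' Reconcile a rooted gene tree with the species tree by LCA mapping
#'
#' Standard duplication-loss reconciliation: each gene-tree leaf maps to the
#' species of its gene; each internal node maps to the species-tree LCA of
#' its children's images. A node is a duplication when it maps to the same
#' species node as one of its children, otherwise a speciation. Losses are
#' counted along each gene-tree edge as `depth(M(child)) - depth(M(parent))
#' - 1`, plus one when the parent is a duplication whose child maps below it,
#' and each loss is attributed to the species-tree branch it falls on.
#'
#' @param gene_tree Rooted binary `phylo` gene tree (polytomies are an error
#'   unless `resolve_polytomies = TRUE`, which resolves them
#'   deterministically).
#' @param species_tree Rooted binary `phylo` species tree.
#' @param leaf_species_map Named character vector mapping every gene-tree
#'   leaf label to a species-tree tip label.
#' @param resolve_polytomies Logical; default `FALSE`.
#' @return A list with `nodes` (data frame: `node`, `event` in
#'   `{leaf, speciation, duplication}`, `species_node`, `species_label`),
#'   `losses` (named integer vector per species branch, named by the child
#'   node label of the branch), `n_duplications`, `n_losses`,
#'   `root_species_label`, plus the trees and the species index used.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_species_map,
                    resolve_polytomies = FALSE) {
  # a rooted binary tree has exactly Ntip - 1 internal nodes; anything less
  # (including a trifurcating root, which Newick cannot distinguish from an
  # unrooted tree) is treated as polytomous
  if (gene_tree$Nnode != length(gene_tree$tip.label) - 1L) {
    if (!resolve_polytomies) {
      stop("gene tree contains polytomies (or is unrooted); ",
           "set resolve_polytomies = TRUE")
    }
    gene_tree <- resolve_polytomies_sorted(gene_tree)
  }
  sp <- index_species_tree(species_tree)
  sp_tip <- stats::setNames(seq_len(sp$n_tip), species_tree$tip.label)
  n_tip <- length(gene_tree$tip.label)
  n_node <- n_tip + gene_tree$Nnode
  species_of_leaf <- leaf_species_map[gene_tree$tip.label]
  if (anyNA(species_of_leaf) || !all(species_of_leaf %in%
                                       species_tree$tip.label)) {
    bad <- gene_tree$tip.label[is.na(species_of_leaf) |
                                 !(species_of_leaf %in%
                                     species_tree$tip.label)][1L]
    stop("gene leaf '", bad, "' is not mapped to a species")
  }
  M <- rep(NA_integer_, n_node)
  M[seq_len(n_tip)] <- sp_tip[species_of_leaf]
  children <- split(gene_tree$edge[, 2L], gene_tree$edge[, 1L])
  # relaxation until all internal nodes are mapped (trees are small)
  internal <- as.integer(names(children))
  repeat {
    progressed <- FALSE
    for (v in internal) {
      if (is.na(M[v]) && all(!is.na(M[children[[as.character(v)]]]))) {
        ch <- children[[as.character(v)]]
        M[v] <- Reduce(function(a, b) species_lca(sp, a, b), M[ch])
        progressed <- TRUE
      }
    }
    if (all(!is.na(M[internal])) || !progressed) break
  }
  event <- rep("leaf", n_node)
  for (v in internal) {
    ch <- children[[as.character(v)]]
    event[v] <- if (any(M[ch] == M[v])) "duplication" else "speciation"
  }
  # loss attribution per species branch (named by child-end node label)
  losses <- stats::setNames(integer(sp$n_node), sp$labels)
  n_loss <- 0L
  for (e in seq_len(nrow(gene_tree$edge))) {
    p <- gene_tree$edge[e, 1L]; c <- gene_tree$edge[e, 2L]
    k <- sp$depth[M[c]] - sp$depth[M[p]]
    # walk from M(c) up; sibling branches off the path are losses
    x <- M[c]
    steps <- if (event[p] == "duplication" && M[c] != M[p]) k else k - 1L
    while (steps > 0L) {
      par <- sp$parent[x]
      sib <- setdiff(sp$tree$edge[sp$tree$edge[, 1L] == par, 2L], x)
      losses[sp$labels[sib]] <- losses[sp$labels[sib]] + 1L
      n_loss <- n_loss + 1L
      x <- par
      steps <- steps - 1L
    }
  }
  gene_root <- setdiff(gene_tree$edge[, 1L], gene_tree$edge[, 2L])[1L]
  nodes <- data.frame(
    node = seq_len(n_node), event = event, species_node = M,
    species_label = sp$labels[M], stringsAsFactors = FALSE
  )
  list(nodes = nodes, losses = losses,
       n_duplications = sum(event == "duplication"),
       n_losses = n_loss,
       root_node = gene_root,
       root_species = M[gene_root],
       root_species_label = sp$labels[M[gene_root]],
       gene_tree = gene_tree, species_index = sp,
       leaf_species = stats::setNames(as.character(species_of_leaf),
                                      gene_tree$tip.label))
}

#' Decompose reconciled gene families into ancestral lineages
#'
#' Within each reconciled family tree, the tree is cut at every duplication
#' node mapped to the species root; each resulting maximal subtree is one
#' ancestral lineage (a gene copy inferred present in the species' common
#' ancestor). A family whose root maps below the species root contributes
#' exactly one lineage, so each family yields one lineage more than its
#' count of root-mapped duplications. Each lineage carries its
#' species-presence set.
#'
#' @param reconciliations List of results from [lca_map()] against the same
#'   species tree.
#' @return Data frame with `lineage_id`, `family`, `n_members`, `presence`
#'   (sorted `+`-joined species labels) and a list column `members`.
#' @export
decompose_lineages <- function(reconciliations) {
  rows <- list()
  fam_names <- names(reconciliations)
  if (is.null(fam_names)) {
    fam_names <- sprintf("family%04d", seq_along(reconciliations))
  }
  for (fi in seq_along(reconciliations)) {
    rec <- reconciliations[[fi]]
    gt <- rec$gene_tree
    sp_root <- rec$species_index$root
    n_tip <- length(gt$tip.label)
    children <- split(gt$edge[, 2L], gt$edge[, 1L])
    collect <- function(v) {
      if (v > n_tip && rec$nodes$event[v] == "duplication" &&
          rec$nodes$species_node[v] == sp_root) {
        do.call(c, lapply(children[[as.character(v)]], collect))
      } else {
        tips <- if (v <= n_tip) v else tips_under(gt, v)
        list(gt$tip.label[tips])
      }
    }
    res <- collect(rec$root_node)
    for (mem in res) {
      pres <- sort(unique(rec$leaf_species[mem]))
      rows[[length(rows) + 1L]] <- list(
        family = fam_names[fi], members = mem,
        presence = paste(pres, collapse = "+")
      )
    }
  }
  out <- data.frame(
    lineage_id = sprintf("lineage%05d", seq_along(rows)),
    family = vapply(rows, `[[`, "", "family"),
    n_members = vapply(rows, function(r) length(r$members), 1L),
    presence = vapply(rows, `[[`, "", "presence"),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(rows, `[[`, "members")
  out
}

#' Venn partition of ancestral lineages by species presence
#'
#' Counts ancestral lineages in each nonempty cell of the species-presence
#' Venn diagram (7 cells for three species).
#'
#' @param lineages Data frame from [decompose_lineages()].
#' @param species Character vector of species labels; defaults to the tips
#'   of [triticeae_species_tree()].
#' @return Named integer vector over all nonempty subsets (`+`-joined,
#'   sorted labels), summing to the number of lineages.
#' @export
venn_partition <- function(lineages, species = c("Hv", "Sc", "Tu")) {
  species <- sort(species)
  subsets <- unlist(lapply(seq_along(species), function(k) {
    apply(utils::combn(species, k), 2L, paste, collapse = "+")
  }))
  out <- stats::setNames(integer(length(subsets)), subsets)
  if (nrow(lineages) > 0L) {
    tab <- table(lineages$presence)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Per-branch inheritance and loss accounting for ancestral lineages
#'
#' For each branch of the species tree, counts the ancestral lineages
#' preserved into the clade below the branch (presence set intersects the
#' clade's species) and those lost on the branch (present somewhere in the
#' parent's clade but absent from this clade). At the root all lineages are
#' present, so preserved + lost on a branch equals the count preserved at the
#' parent.
#'
#' @param lineages Data frame from [decompose_lineages()].
#' @param species_tree Rooted species tree; default
#'   [triticeae_species_tree()].
#' @return Data frame with `branch` (label of the node below the branch, the
#'   root row describing the root itself), `preserved` and `lost`.
#' @export
branch_accounting <- function(lineages, species_tree = triticeae_species_tree()) {
  sp <- index_species_tree(species_tree)
  pres_sets <- strsplit(lineages$presence, "+", fixed = TRUE)
  present_in_clade <- function(v) {
    clade <- sp$tips_below[[v]]
    vapply(pres_sets, function(s) any(s %in% clade), logical(1L))
  }
  preserved <- integer(sp$n_node)
  for (v in seq_len(sp$n_node)) {
    preserved[v] <- sum(present_in_clade(v))
  }
  lost <- integer(sp$n_node)
  for (v in seq_len(sp$n_node)) {
    if (v == sp$root) next
    p <- sp$parent[v]
    lost[v] <- sum(present_in_clade(p) & !present_in_clade(v))
  }
  ord <- order(sp$depth, sp$labels)
  data.frame(branch = sp$labels[ord], preserved = preserved[ord],
             lost = lost[ord], stringsAsFactors = FALSE)
}

#' Aggregate duplication and loss counts per species-tree branch
#'
#' Sums, over a list of reconciled families, the duplication events mapped to
#' each species node and the losses attributed to each species branch.
#'
#' @param reconciliations List of results from [lca_map()] against the same
#'   species tree.
#' @return A list with `duplications` and `losses`, both named integer
#'   vectors over species-node labels.
#' @export
branch_event_summary <- function(reconciliations) {
  stopifnot(length(reconciliations) > 0L)
  sp <- reconciliations[[1L]]$species_index
  dups <- stats::setNames(integer(sp$n_node), sp$labels)
  losses <- stats::setNames(integer(sp$n_node), sp$labels)
  for (rec in reconciliations) {
    dn <- rec$nodes[rec$nodes$event == "duplication", , drop = FALSE]
    if (nrow(dn) > 0L) {
      tab <- table(dn$species_label)
      dups[names(tab)] <- dups[names(tab)] + as.integer(tab)
    }
    losses[names(rec$losses)] <- losses[names(rec$losses)] + rec$losses
  }
  list(duplications = dups, losses = losses)
}
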