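# Independent brute-force oracles. These deliberately avoid the package's
# algorithmic code paths: clustering is checked against connected components
# of the all-pairs linkage graph, chaining against exhaustive chain
# enumeration, and reconciliation against exhaustive mapping enumeration.

# --- clustering oracle ------------------------------------------------------
# connected components of the all-pairs linkage graph (any two genes within
# the window are linked), via union-find.
oracle_cluster_sizes <- function(starts, window_bp) {
  n <- length(starts)
  if (n == 0L) return(integer())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(starts[i] - starts[j]) <= window_bp) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(sort(as.integer(table(roots))))
}

# --- chaining oracle --------------------------------------------------------
# exhaustive DFS over all valid chains (both orientations), returning the
# best score and the maximum chain length achieving it.
oracle_best_chain <- function(anchors, params) {
  n <- nrow(anchors)
  if (n == 0L) return(list(score = -Inf, length = 0L))
  a <- anchors[order(anchors$rank_a, anchors$rank_b), , drop = FALSE]
  best <- list(score = -Inf, length = 0L)
  consider <- function(score, len) {
    if (score > best$score ||
        (score == best$score && len > best$length)) {
      best <<- list(score = score, length = len)
    }
  }
  extend <- function(i, score, len, orient) {
    consider(score, len)
    for (j in seq_len(n)) {
      da <- a$rank_a[j] - a$rank_a[i]
      db <- if (orient == "same") a$rank_b[j] - a$rank_b[i]
            else a$rank_b[i] - a$rank_b[j]
      if (da >= 1L && db >= 1L && da <= params$max_gap_ranks &&
          db <= params$max_gap_ranks) {
        extend(j, score + params$match_score +
                 params$gap_penalty * ((da - 1L) + (db - 1L)), len + 1L,
               orient)
      }
    }
  }
  for (orient in c("same", "inverted")) {
    for (i in seq_len(n)) extend(i, params$match_score, 1L, orient)
  }
  best
}

# --- reconciliation oracle --------------------------------------------------
# enumerate every valid mapping of gene-tree internal nodes to species-tree
# nodes (image of a node must be an ancestor-or-self of its children's
# images); cost = duplications + losses with the standard arithmetic.
oracle_min_mappings <- function(gene_tree, species_tree, leaf_species_map) {
  sp_n_tip <- length(species_tree$tip.label)
  sp_n <- sp_n_tip + species_tree$Nnode
  sp_parent <- rep(NA_integer_, sp_n)
  sp_parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  sp_root <- setdiff(species_tree$edge[, 1L], species_tree$edge[, 2L])[1L]
  sp_depth <- rep(NA_integer_, sp_n)
  sp_depth[sp_root] <- 0L
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(species_tree$edge))) {
      p <- species_tree$edge[e, 1L]; c <- species_tree$edge[e, 2L]
      if (!is.na(sp_depth[p]) && is.na(sp_depth[c])) {
        sp_depth[c] <- sp_depth[p] + 1L; done <- FALSE
      }
    }
    if (done) break
  }
  is_anc <- function(a, d) { # a ancestor-or-equal of d
    while (!is.na(d)) {
      if (d == a) return(TRUE)
      d <- sp_parent[d]
    }
    FALSE
  }
  n_tip <- length(gene_tree$tip.label)
  n_node <- n_tip + gene_tree$Nnode
  internal <- (n_tip + 1L):n_node
  children <- split(gene_tree$edge[, 2L], gene_tree$edge[, 1L])
  leaf_img <- match(leaf_species_map[gene_tree$tip.label],
                    species_tree$tip.label)
  sp_children <- split(species_tree$edge[, 2L], species_tree$edge[, 1L])
  route_via <- function(s, d) {
    # which child of s the descendant d lies under (NA if d == s)
    if (d == s) return(NA_integer_)
    for (k in sp_children[[as.character(s)]]) {
      if (is_anc(k, d)) return(k)
    }
    NA_integer_
  }
  cost_of <- function(M) {
    dup <- logical(n_node)
    for (v in internal) {
      ch <- children[[as.character(v)]]
      if (!all(vapply(ch, function(c) is_anc(M[v], M[c]), TRUE))) {
        return(NULL)
      }
      # speciation only when the children descend through distinct
      # daughters of the image; anything else is a duplication
      via <- vapply(ch, function(c) route_via(M[v], M[c]), 1L)
      dup[v] <- any(M[ch] == M[v]) || anyNA(via) ||
        length(unique(via)) < length(via)
    }
    losses <- 0L
    for (e in seq_len(nrow(gene_tree$edge))) {
      p <- gene_tree$edge[e, 1L]; ch <- gene_tree$edge[e, 2L]
      l <- sp_depth[M[ch]] - sp_depth[M[p]] - 1L
      if (dup[p]) l <- l + 1L
      losses <- losses + max(0L, l)
    }
    c(ndup = sum(dup), nloss = losses)
  }
  grid <- rep(list(seq_len(sp_n)), length(internal))
  combos <- do.call(expand.grid, grid)
  best_cost <- Inf
  best <- list()
  min_dup <- Inf
  for (r in seq_len(nrow(combos))) {
    M <- rep(NA_integer_, n_node)
    M[seq_len(n_tip)] <- leaf_img
    M[internal] <- as.integer(combos[r, ])
    res <- cost_of(M)
    if (is.null(res)) next
    min_dup <- min(min_dup, res[["ndup"]])
    tot <- res[["ndup"]] + res[["nloss"]]
    if (tot < best_cost) {
      best_cost <- tot
      best <- list(list(M = M, ndup = res[["ndup"]], nloss = res[["nloss"]]))
    } else if (tot == best_cost) {
      best[[length(best) + 1L]] <- list(M = M, ndup = res[["ndup"]],
                                        nloss = res[["nloss"]])
    }
  }
  list(best = best, best_cost = best_cost, min_dup = min_dup)
}

# random rooted binary gene tree over species labels, as newick
random_gene_tree <- function(n_leaves, species = c("Sc", "Tu", "Hv")) {
  labs <- sprintf("g%d", seq_len(n_leaves))
  map <- stats::setNames(sample(species, n_leaves, replace = TRUE), labs)
  nodes <- as.list(labs)
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    merged <- paste0("(", nodes[[i[1L]]], ",", nodes[[i[2L]]], ")")
    nodes <- c(nodes[-i], merged)
  }
  list(newick = paste0(nodes[[1L]], ";"), map = map)
}

# all rooted binary topologies on n labelled leaves (as nested index lists)
all_rooted_topologies <- function(leaves) {
  if (length(leaves) == 1L) return(list(leaves[[1L]]))
  out <- list()
  n <- length(leaves)
  first <- leaves[[1L]]
  rest <- leaves[-1L]
  # split rest into left (containing subsets) and right
  for (mask in 0:(2^(n - 1L) - 1L)) {
    left_sel <- as.logical(bitwAnd(mask, 2^(seq_len(n - 1L) - 1L)))
    left <- c(list(first), rest[left_sel])
    right <- rest[!left_sel]
    if (length(right) == 0L) next
    for (lt in all_rooted_topologies(left)) {
      for (rt in all_rooted_topologies(right)) {
        out[[length(out) + 1L]] <- paste0("(", lt, ",", rt, ")")
      }
    }
  }
  out
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
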