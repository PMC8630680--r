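#' Build a per-chromosome gene rank index
#'
#' Genes are ordered along each chromosome by start coordinate (ties broken
#' lexicographically by gene ID) and given consecutive integer ranks from 0.
#' Ranks, not base pairs, are the substrate for collinearity chaining and
#' duplicate-gene classification.
#'
#' @param genes Gene-model data frame.
#' @return Data frame with columns `gene_id`, `chromosome`, `rank`; unplaced
#'   (`chrUn`) genes are excluded.
#' @export
build_rank_index <- function(genes) {
  placed <- genes[genes$chromosome != "chrUn", , drop = FALSE]
  placed <- placed[order(placed$chromosome, placed$start, placed$gene_id), ,
                   drop = FALSE]
  rank <- integer(nrow(placed))
  for (chr in unique(placed$chromosome)) {
    sel <- placed$chromosome == chr
    rank[sel] <- seq_len(sum(sel)) - 1L
  }
  data.frame(gene_id = placed$gene_id, chromosome = placed$chromosome,
             rank = rank, stringsAsFactors = FALSE)
}

#' Default chaining and classification parameters
#'
#' Mirrors the documented MCScanX defaults: blocks need at least five
#' anchors, rank gaps are capped at 25, matches score +1 and each skipped
#' rank costs the gap penalty.
#'
#' @return Named list of parameters.
#' @export
synteny_params <- function() {
  list(min_block_size = 5L, max_gap_ranks = 25L, gap_penalty = -1,
       match_score = 1, evalue_cutoff = 1e-5, top_hits = 5L,
       proximal_max_rank = 10L)
}

# Filter homology hits and map both ends onto chromosome ranks.
prepare_anchors <- function(hits, index_a, index_b, params,
                            intra = identical(index_a, index_b)) {
  hits <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) > 0L && params$top_hits > 0L) {
    hits <- hits[order(hits$query_id, hits$evalue, -hits$bitscore,
                       hits$subject_id), , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id),
                          function(i) i[seq_len(min(length(i),
                                                    params$top_hits))]))
    hits <- hits[sort(keep), , drop = FALSE]
  }
  ia <- stats::setNames(seq_len(nrow(index_a)), index_a$gene_id)
  ib <- stats::setNames(seq_len(nrow(index_b)), index_b$gene_id)
  qa <- ia[hits$query_id]; sb <- ib[hits$subject_id]
  ok <- !is.na(qa) & !is.na(sb)
  hits <- hits[ok, , drop = FALSE]; qa <- qa[ok]; sb <- sb[ok]
  anch <- data.frame(
    gene_a = hits$query_id, gene_b = hits$subject_id,
    chr_a = index_a$chromosome[qa], rank_a = index_a$rank[qa],
    chr_b = index_b$chromosome[sb], rank_b = index_b$rank[sb],
    stringsAsFactors = FALSE
  )
  if (intra && nrow(anch) > 0L) {
    # canonical orientation + dedupe of symmetric duplicates
    flip <- anch$chr_a > anch$chr_b |
      (anch$chr_a == anch$chr_b & anch$rank_a > anch$rank_b)
    anch[flip, c("gene_a", "gene_b", "chr_a", "rank_a", "chr_b", "rank_b")] <-
      anch[flip, c("gene_b", "gene_a", "chr_b", "rank_b", "chr_a", "rank_a")]
    anch <- anch[!duplicated(anch[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  unique(anch)
}

#' Detect collinear blocks by dynamic-programming anchor chaining
#'
#' Homology hits are filtered (E-value cutoff, best `top_hits` per query,
#' self-pairs removed), mapped onto chromosome ranks, and chained on the
#' rank-rank dot plot per chromosome pair. A chain extends an anchor when
#' both rank gaps are within `max_gap_ranks` and ranks stay strictly monotone
#' in genome A and monotone (increasing or decreasing, fixing the block
#' orientation) in genome B. Chain score is the number of anchors times
#' `match_score` plus skipped ranks times `gap_penalty`. Maximal
#' non-overlapping chains with at least `min_block_size` anchors are reported
#' greedily by score with a deterministic lexicographic tie-break.
#'
#' @param hits Homology-hit data frame (see [read_blast_tab()]).
#' @param index_a,index_b Rank indexes from [build_rank_index()] for the two
#'   genomes (identical for intra-species mode).
#' @param params Parameter list; see [synteny_params()].
#' @return Data frame of blocks (`block_id`, `chr_a`, `chr_b`, `orientation`,
#'   `score`, `n_anchors`) with a list column `anchors`, each element a data
#'   frame of the chained anchor pairs in order.
#' @export
chain_anchors <- function(hits, index_a, index_b, params = synteny_params()) {
  anch <- prepare_anchors(hits, index_a, index_b, params)
  blocks <- list()
  if (nrow(anch) > 0L) {
    key <- paste(anch$chr_a, anch$chr_b, sep = "\r")
    for (k in sort(unique(key))) {
      a <- anch[key == k, , drop = FALSE]
      blocks <- c(blocks, chain_one_pair(a, params))
    }
  }
  out <- data.frame(
    block_id = sprintf("block%03d", seq_along(blocks)),
    chr_a = vapply(blocks, function(b) b$anchors$chr_a[1L], ""),
    chr_b = vapply(blocks, function(b) b$anchors$chr_b[1L], ""),
    orientation = vapply(blocks, `[[`, "", "orientation"),
    score = vapply(blocks, `[[`, 1, "score"),
    n_anchors = vapply(blocks, function(b) nrow(b$anchors), 1L),
    stringsAsFactors = FALSE
  )
  out$anchors <- lapply(blocks, `[[`, "anchors")
  out
}

# Greedy extraction of non-overlapping chains on one chromosome pair.
chain_one_pair <- function(anchors, params) {
  out <- list()
  avail <- anchors[order(anchors$rank_a, anchors$rank_b, anchors$gene_a,
                         anchors$gene_b), , drop = FALSE]
  repeat {
    if (nrow(avail) < params$min_block_size) break
    best <- NULL
    for (orient in c("same", "inverted")) {
      cand <- best_chain_dp(avail, params, orient)
      if (is.null(cand)) next
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score &&
             (length(cand$idx) > length(best$idx) ||
                (length(cand$idx) == length(best$idx) &&
                   chain_before(cand, best))))) {
        best <- cand
      }
    }
    if (is.null(best) || length(best$idx) < params$min_block_size) break
    out[[length(out) + 1L]] <- list(
      anchors = avail[best$idx, , drop = FALSE],
      score = best$score, orientation = best$orientation
    )
    avail <- avail[-best$idx, , drop = FALSE]
  }
  if (length(out) > 1L) {
    ord <- order(-vapply(out, `[[`, 1, "score"),
                 vapply(out, function(b) b$anchors$rank_a[1L], 1L),
                 vapply(out, function(b) b$anchors$rank_b[1L], 1L))
    out <- out[ord]
  }
  out
}

# Deterministic tie-break: earlier first anchor in (rank_a, rank_b) order.
chain_before <- function(x, y) {
  x$idx[1L] < y$idx[1L]
}

# DP over anchors sorted by (rank_a, rank_b): best-scoring chain.
best_chain_dp <- function(a, params, orientation = c("same", "inverted")) {
  orientation <- match.arg(orientation)
  n <- nrow(a)
  if (n == 0L) return(NULL)
  dp <- rep(params$match_score, n)
  pred <- rep(NA_integer_, n)
  len <- rep(1L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- a$rank_a[j] - a$rank_a[i]
      db <- if (orientation == "same") a$rank_b[j] - a$rank_b[i]
            else a$rank_b[i] - a$rank_b[j]
      if (da >= 1L && db >= 1L &&
          da <= params$max_gap_ranks && db <= params$max_gap_ranks) {
        sc <- dp[i] + params$match_score +
          params$gap_penalty * ((da - 1L) + (db - 1L))
        better <- sc > dp[j] ||
          (sc == dp[j] && (len[i] + 1L > len[j] ||
                             (len[i] + 1L == len[j] && !is.na(pred[j]) &&
                                i < pred[j])))
        if (better) {
          dp[j] <- sc; pred[j] <- i; len[j] <- len[i] + 1L
        }
      }
    }
  }
  j <- which(dp == max(dp))
  j <- j[order(-len[j], a$rank_a[j], a$rank_b[j])][1L]
  idx <- integer()
  k <- j
  while (!is.na(k)) {
    idx <- c(k, idx)
    k <- pred[k]
  }
  list(idx = idx, score = dp[j], orientation = orientation)
}

#' Extract syntenic NLR gene pairs from collinear blocks
#'
#' Keeps the anchor pairs whose genes are NLRs at both ends and counts them
#' per chromosome pair.
#'
#' @param blocks Block data frame from [chain_anchors()].
#' @param nlr_ids_a,nlr_ids_b NLR gene IDs in genomes A and B.
#' @return A list with `pairs` (data frame `gene_a`, `gene_b`, `chr_a`,
#'   `chr_b`, `block_id`) and `counts` (data frame per chromosome pair).
#' @export
syntenic_nlr_pairs <- function(blocks, nlr_ids_a, nlr_ids_b) {
  if (nrow(blocks) == 0L) {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        chr_a = character(), chr_b = character(),
                        block_id = character(), stringsAsFactors = FALSE)
  } else {
    pairs <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
      a <- blocks$anchors[[i]]
      a$block_id <- blocks$block_id[i]
      a
    }))
    pairs <- pairs[pairs$gene_a %in% nlr_ids_a &
                     pairs$gene_b %in% nlr_ids_b,
                   c("gene_a", "gene_b", "chr_a", "chr_b", "block_id"),
                   drop = FALSE]
    rownames(pairs) <- NULL
  }
  counts <- if (nrow(pairs) == 0L) {
    data.frame(chr_a = character(), chr_b = character(), n_pairs = integer(),
               stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(n_pairs = pairs$gene_a),
                            by = list(chr_a = pairs$chr_a,
                                      chr_b = pairs$chr_b), FUN = length)
    agg[order(agg$chr_a, agg$chr_b), , drop = FALSE]
  }
  list(pairs = pairs, counts = counts)
}

#' Classify genes by duplication type
#'
#' MCScanX-style partition of a genome's genes into singleton, dispersed,
#' proximal, tandem and segmental duplicates, from intra-species homology
#' hits and collinear blocks. Priority: a gene with no non-self homolog at or
#' below the E-value cutoff is a singleton; an anchor gene of any
#' intra-species block is segmental; a gene with a homolog at the adjacent
#' rank on the same chromosome is tandem; within `proximal_max_rank` ranks,
#' proximal; otherwise dispersed. Unplaced genes can only be singleton or
#' dispersed (no rank neighbourhood) and are flagged.
#'
#' @param gene_ids Genes to classify.
#' @param hits Intra-species homology hits.
#' @param index Rank index from [build_rank_index()].
#' @param blocks Intra-species blocks from [chain_anchors()].
#' @param params Parameter list; see [synteny_params()].
#' @return Data frame `gene_id`, `dup_type`, `flagged` (logical, unplaced).
#' @export
classify_duplication <- function(gene_ids, hits, index, blocks,
                                 params = synteny_params()) {
  hits <- hits[hits$evalue <= params$evalue_cutoff &
                 hits$query_id != hits$subject_id, , drop = FALSE]
  partners <- function(g) {
    unique(c(hits$subject_id[hits$query_id == g],
             hits$query_id[hits$subject_id == g]))
  }
  anchor_genes <- if (nrow(blocks) == 0L) character() else {
    unique(unlist(lapply(blocks$anchors,
                         function(a) c(a$gene_a, a$gene_b))))
  }
  pos <- stats::setNames(seq_len(nrow(index)), index$gene_id)
  dup <- character(length(gene_ids))
  flagged <- logical(length(gene_ids))
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    hom <- partners(g)
    placed <- !is.na(pos[g])
    if (length(hom) == 0L) {
      dup[i] <- "singleton"
      flagged[i] <- !placed
      next
    }
    if (g %in% anchor_genes) {
      dup[i] <- "segmental"
      next
    }
    if (!placed) {
      dup[i] <- "dispersed"
      flagged[i] <- TRUE
      next
    }
    chr <- index$chromosome[pos[g]]
    rk <- index$rank[pos[g]]
    hp <- pos[hom]
    hp <- hp[!is.na(hp)]
    same_chr <- hp[index$chromosome[hp] == chr]
    drank <- abs(index$rank[same_chr] - rk)
    if (any(drank == 1L)) {
      dup[i] <- "tandem"
    } else if (any(drank >= 1L & drank <= params$proximal_max_rank)) {
      dup[i] <- "proximal"
    } else {
      dup[i] <- "dispersed"
    }
  }
  data.frame(gene_id = gene_ids, dup_type = dup, flagged = flagged,
             stringsAsFactors = FALSE)
}
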