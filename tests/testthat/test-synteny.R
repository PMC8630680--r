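mk_index_genes <- function(n, chrom = "chr1", gap = 50000L) {
  ids <- sprintf("%s_g%03d", chrom, seq_len(n))
  data.frame(gene_id = ids, chromosome = chrom,
             start = seq(0L, by = gap, length.out = n),
             end = seq(0L, by = gap, length.out = n) + 3000L,
             strand = "+", protein_id = ids, stringsAsFactors = FALSE)
}

mk_hits <- function(qa, sb, evalue = 1e-50, bits = 500) {
  data.frame(query_id = qa, subject_id = sb,
             pct_identity = rep_len(90, length(qa)),
             evalue = rep_len(evalue, length(qa)),
             bitscore = rep_len(bits, length(qa)), stringsAsFactors = FALSE)
}

test_that("rank index orders genes by start with deterministic ties", {
  g <- mk_index_genes(3)
  idx <- build_rank_index(g)
  expect_equal(idx$rank, 0:2)
  tie <- g
  tie$start <- 0L
  tie$gene_id <- c("b", "a", "c")
  idx2 <- build_rank_index(tie)
  expect_equal(idx2$gene_id, c("a", "b", "c"))
  # permutation invariance
  set.seed(5)
  g3 <- mk_index_genes(30)
  expect_equal(build_rank_index(g3[sample.int(30), ]), build_rank_index(g3))
})

test_that("a planted collinear run is chained into one block", {
  ga <- mk_index_genes(20, "chr1")
  gb <- mk_index_genes(20, "chr2")
  ia <- build_rank_index(ga)
  ib <- build_rank_index(gb)
  # 10-anchor run with two interleaved non-anchor genes
  apos <- c(1:5, 7:11)
  hits <- mk_hits(ga$gene_id[apos], gb$gene_id[apos])
  blocks <- chain_anchors(hits, ia, ib)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$n_anchors, 10L)
  expect_equal(blocks$orientation, "same")
  # below min_block_size nothing is reported
  b4 <- chain_anchors(mk_hits(ga$gene_id[1:4], gb$gene_id[1:4]), ia, ib)
  expect_equal(nrow(b4), 0L)
  expect_equal(nrow(chain_anchors(mk_hits(character(), character()), ia, ib)),
               0L)
})

test_that("inverted blocks are recovered with the same anchor count", {
  ga <- mk_index_genes(15, "chr1")
  gb <- mk_index_genes(15, "chr2")
  hits_f <- mk_hits(ga$gene_id[3:10], gb$gene_id[3:10])
  hits_r <- mk_hits(ga$gene_id[3:10], gb$gene_id[10:3])
  bf <- chain_anchors(hits_f, build_rank_index(ga), build_rank_index(gb))
  br <- chain_anchors(hits_r, build_rank_index(ga), build_rank_index(gb))
  expect_equal(bf$n_anchors, br$n_anchors)
  expect_equal(bf$orientation, "same")
  expect_equal(br$orientation, "inverted")
  expect_equal(bf$score, br$score)
})

test_that("DP chain score equals exhaustive enumeration on random instances", {
  set.seed(31)
  params <- synteny_params()
  params$min_block_size <- 2L
  for (rep in 1:15) {
    n <- sample(6:14, 1)
    anchors <- data.frame(
      gene_a = sprintf("a%02d", seq_len(n)),
      gene_b = sprintf("b%02d", seq_len(n)),
      chr_a = "chr1", chr_b = "chr2",
      rank_a = sample.int(30, n),
      rank_b = sample.int(30, n),
      stringsAsFactors = FALSE
    )
    anchors <- anchors[!duplicated(anchors[, c("rank_a", "rank_b")]), ]
    oracle <- oracle_best_chain(anchors, params)
    got <- nlrome:::chain_one_pair(anchors, params)
    if (oracle$length >= params$min_block_size) {
      expect_gt(length(got), 0)
      expect_equal(got[[1]]$score, oracle$score)
    } else if (length(got) > 0) {
      expect_equal(got[[1]]$score, oracle$score)
    }
  }
})

test_that("syntenic NLR pairs require NLRs at both anchor ends", {
  ga <- mk_index_genes(12, "chr1")
  gb <- mk_index_genes(12, "chr2")
  hits <- mk_hits(ga$gene_id[2:9], gb$gene_id[2:9])
  blocks <- chain_anchors(hits, build_rank_index(ga), build_rank_index(gb))
  nlr_a <- ga$gene_id[c(3, 5, 7)]
  nlr_b <- gb$gene_id[c(3, 7, 9)]
  syn <- syntenic_nlr_pairs(blocks, nlr_a, nlr_b)
  expect_equal(nrow(syn$pairs), 2L)  # anchors 3 and 7; 5 and 9 are one-sided
  expect_equal(syn$counts$n_pairs, 2L)
  expect_equal(nrow(syntenic_nlr_pairs(blocks, character(), nlr_b)$pairs), 0L)
})

test_that("syntenic pair extraction is symmetric between genomes", {
  sim_a <- gen_genome(sim_config(seed = 61, genome_tag = "A"))
  sim_b <- gen_genome(sim_config(seed = 61, genome_tag = "B"))
  inter <- gen_interspecies_homology(sim_a$genes, sim_b$genes, n_blocks = 4,
                                     block_len = 8, invert = c(FALSE, TRUE),
                                     seed = 3)
  ia <- build_rank_index(sim_a$genes)
  ib <- build_rank_index(sim_b$genes)
  fwd <- chain_anchors(inter$hits, ia, ib)
  rev_hits <- inter$hits
  names(rev_hits)[1:2] <- c("subject_id", "query_id")
  bwd <- chain_anchors(rev_hits, ib, ia)
  nlr_a <- sim_a$truth$genes$gene_id
  nlr_b <- sim_b$truth$genes$gene_id
  pf <- syntenic_nlr_pairs(fwd, nlr_a, nlr_b)$pairs
  pb <- syntenic_nlr_pairs(bwd, nlr_b, nlr_a)$pairs
  expect_equal(nrow(pf), nrow(pb))
  expect_setequal(paste(pf$gene_a, pf$gene_b),
                  paste(pb$gene_b, pb$gene_a))
  # planted NLR anchor pairs are recovered exactly
  truth_pairs <- inter$truth[inter$truth$gene_a %in% nlr_a &
                               inter$truth$gene_b %in% nlr_b, ]
  expect_setequal(paste(pf$gene_a, pf$gene_b),
                  paste(truth_pairs$gene_a, truth_pairs$gene_b))
})

test_that("duplication classes respect the stated priority", {
  g <- mk_index_genes(30, "chr1")
  idx <- build_rank_index(g)
  no_blocks <- chain_anchors(mk_hits(character(), character()), idx, idx)
  gid <- g$gene_id
  # threshold sweep: 4 ranks away is proximal, 11 is dispersed
  hits <- rbind(mk_hits(gid[1], gid[5]), mk_hits(gid[15], gid[26]))
  cl <- classify_duplication(c(gid[1], gid[15], gid[20]), hits, idx,
                             no_blocks)
  expect_equal(cl$dup_type, c("proximal", "dispersed", "singleton"))
  # adjacent rank beats proximal
  hits2 <- rbind(mk_hits(gid[8], gid[9]), mk_hits(gid[8], gid[12]))
  expect_equal(classify_duplication(gid[8], hits2, idx, no_blocks)$dup_type,
               "tandem")
  # block anchorship beats tandem
  ga <- mk_index_genes(20, "chr2")
  both <- rbind(g, ga)
  idx2 <- build_rank_index(both)
  anchor_hits <- mk_hits(gid[1:6], ga$gene_id[1:6])
  blocks <- chain_anchors(anchor_hits, idx2, idx2)
  expect_equal(nrow(blocks), 1L)
  hits3 <- rbind(anchor_hits, mk_hits(gid[1], gid[2]))
  expect_equal(classify_duplication(gid[1], hits3, idx2, blocks)$dup_type,
               "segmental")
  # hits above the cutoff leave a singleton
  weak <- mk_hits(gid[3], gid[4], evalue = 1e-3)
  expect_equal(classify_duplication(gid[3], weak, idx, no_blocks)$dup_type,
               "singleton")
})

test_that("planted duplication classes are recovered exactly", {
  sim <- gen_genome(sim_config(seed = 77))
  hom <- gen_homology(sim)
  idx <- build_rank_index(sim$genes)
  blocks <- chain_anchors(hom, idx, idx)
  expect_equal(nrow(blocks), sim$config$n_segmental_blocks)
  truth <- sim$truth$genes
  cl <- classify_duplication(truth$gene_id, hom, idx, blocks)
  m <- merge(cl, truth[, c("gene_id", "dup_type")], by = "gene_id")
  expect_true(all(m$dup_type.x == m$dup_type.y))
  # the six planted segmental genes form three anchor pairs
  seg <- truth$gene_id[truth$dup_type == "segmental"]
  expect_equal(length(seg), 6L)
  seg_pairs <- lapply(blocks$anchors, function(a)
    a[a$gene_a %in% seg & a$gene_b %in% seg, ])
  expect_equal(sum(vapply(seg_pairs, nrow, 1L)), 3L)
  # classification is a total function over its input
  expect_equal(nrow(cl), nrow(truth))
  expect_true(all(cl$dup_type %in% c("singleton", "dispersed", "proximal",
                                     "tandem", "segmental")))
})
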