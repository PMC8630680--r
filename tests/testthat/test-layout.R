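mk_genes <- function(chrom, starts, ids = NULL) {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(n))
  data.frame(gene_id = ids, chromosome = rep_len(chrom, n),
             start = as.integer(starts), end = as.integer(starts) + 3000L,
             strand = "+", protein_id = ids, stringsAsFactors = FALSE)
}

test_that("per-chromosome tallies partition the input", {
  g <- rbind(mk_genes("chr1", c(1, 2, 3) * 1e5, sprintf("a%d", 1:3)),
             mk_genes("chrUn", 5e4, "u1"))
  expect_equal(tally_by_chromosome(g), c(chr1 = 3L, unplaced = 1L))
  expect_equal(length(tally_by_chromosome(g[0, ])), 0L)
})

test_that("transitive chaining clusters successive genes within the window", {
  g <- mk_genes("chr1", c(0, 200000, 400000))
  loci <- cluster_loci(g)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_genes, 3L)
  # above-threshold neighbours stay separate singletons
  g2 <- mk_genes("chr1", c(0, 300001))
  expect_equal(nrow(cluster_loci(g2)), 2L)
  # the 250 kb boundary is inclusive
  g3 <- mk_genes("chr1", c(0, 250000))
  expect_equal(nrow(cluster_loci(g3)), 1L)
  g4 <- mk_genes("chr1", c(0, 250001))
  expect_equal(nrow(cluster_loci(g4)), 2L)
})

test_that("clustering equals all-pairs linkage components on random instances", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(2:100, 1)
    starts <- sort(sample.int(5e6, n))
    g <- mk_genes("chr1", starts)
    sizes <- sort(cluster_loci(g)$n_genes)
    expect_equal(sizes, oracle_cluster_sizes(starts, 250000))
  }
})

test_that("clustering is invariant to input order and monotone in window", {
  set.seed(23)
  starts <- sample.int(3e6, 60)
  g <- mk_genes(sample(paste0("chr", 1:3), 60, replace = TRUE), starts)
  a <- cluster_loci(g)
  b <- cluster_loci(g[sample.int(60), ])
  expect_equal(a[order(a$chromosome, a$span_start), -1],
               b[order(b$chromosome, b$span_start), -1],
               ignore_attr = TRUE)
  windows <- c(50e3, 150e3, 250e3, 500e3, 2e6)
  n_loci <- vapply(windows, function(w) nrow(cluster_loci(g, w)), 1L)
  expect_true(all(diff(n_loci) <= 0))
})

test_that("unplaced genes are excluded from clustering but counted", {
  g <- rbind(mk_genes("chr1", c(0, 100000), c("a", "b")),
             mk_genes("chrUn", c(0, 1000), c("u1", "u2")))
  loci <- cluster_loci(g)
  expect_equal(attr(loci, "n_unplaced"), 2L)
  expect_equal(sum(loci$n_genes), 2L)
})

test_that("layout summary reproduces the rye-scale worked example", {
  # 312 singleton loci plus 86 clusters holding 246 of 558 anchored genes
  sizes <- c(rep(1L, 312), rep(2L, 12), rep(3L, 74))
  loci <- data.frame(locus_id = sprintf("l%03d", seq_along(sizes)),
                     chromosome = "chr1", n_genes = sizes,
                     span_start = 0L, span_end = 1L,
                     stringsAsFactors = FALSE)
  s <- summarize_layout(loci, n_unplaced = 24L)
  expect_equal(s$n_genes, 558L)
  expect_equal(s$n_loci, 398L)
  expect_equal(s$n_singletons, 312L)
  expect_equal(s$n_clusters, 86L)
  expect_equal(s$n_clustered_genes, 246L)
  expect_equal(s$pct_clustered, 44)
  expect_equal(round_half_up(s$mean_genes_per_cluster), 3)
  expect_equal(s$n_singletons + s$n_clustered_genes, s$n_genes)
  expect_equal(sum(s$cluster_size_histogram), s$n_clusters)
})

test_that("all-singleton layouts report zero clustering", {
  loci <- cluster_loci(mk_genes("chr1", c(0, 1e6, 2e6)))
  s <- summarize_layout(loci)
  expect_equal(s$pct_clustered, 0)
  expect_equal(length(s$cluster_size_histogram), 0L)
})

test_that("planted cluster sizes come back as the truth histogram", {
  g <- rbind(
    mk_genes("chr1", seq(0, by = 50000, length.out = 2),
             sprintf("c1_%d", 1:2)),
    mk_genes("chr2", 1e6 + seq(0, by = 50000, length.out = 2),
             sprintf("c2_%d", 1:2)),
    mk_genes("chr3", 5e6 + seq(0, by = 50000, length.out = 15),
             sprintf("c3_%d", 1:15))
  )
  s <- summarize_layout(cluster_loci(g))
  expect_equal(s$cluster_size_histogram, c("2" = 2L, "15" = 1L))
})
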