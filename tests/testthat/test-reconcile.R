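st <- triticeae_species_tree()

test_that("LCA mapping reproduces textbook duplication-loss cases", {
  # two copies in each of two species: one duplication at their ancestor
  r <- lca_map(read_newick("((a1,b1),(a2,b2));"), st,
               c(a1 = "Sc", b1 = "Tu", a2 = "Sc", b2 = "Tu"))
  expect_equal(r$n_duplications, 1L)
  expect_equal(r$n_losses, 0L)
  expect_equal(r$root_species_label, "ScTu")

  # one duplication with a loss of the second copy in Tu
  r2 <- lca_map(read_newick("(a1,(a2,b1));"), st,
                c(a1 = "Sc", a2 = "Sc", b1 = "Tu"))
  expect_equal(r2$n_duplications, 1L)
  expect_equal(r2$n_losses, 1L)
  expect_equal(unname(r2$losses["Tu"]), 1L)

  # a species-congruent gene tree needs no events
  r3 <- lca_map(read_newick("((s1,t1),h1);"), st,
                c(s1 = "Sc", t1 = "Tu", h1 = "Hv"))
  expect_equal(r3$n_duplications, 0L)
  expect_equal(r3$n_losses, 0L)
})

test_that("unmapped leaves and polytomies are rejected", {
  gt <- read_newick("((a,b),c);")
  expect_error(lca_map(gt, st, c(a = "Sc", b = "Tu")), "not mapped")
  poly <- read_newick("(a,b,c);")
  map <- c(a = "Sc", b = "Tu", c = "Hv")
  expect_error(lca_map(poly, st, map), "polytom")
  r <- lca_map(poly, st, map, resolve_polytomies = TRUE)
  expect_true(r$n_duplications >= 0L)
})

test_that("LCA mapping is the unique minimum-cost mapping on small trees", {
  # exhaustive over all labelled rooted binary topologies with 2-4 leaves
  set.seed(41)
  n_checked <- 0L
  for (n in 2:4) {
    labs <- sprintf("g%d", seq_len(n))
    topos <- all_rooted_topologies(as.list(labs))
    assignments <- expand.grid(rep(list(c("Sc", "Tu", "Hv")), n),
                               stringsAsFactors = FALSE)
    keep <- sample.int(nrow(assignments),
                       min(nrow(assignments), if (n < 4) 27 else 20))
    for (topo in topos) {
      gt <- read_newick(paste0(topo, ";"))
      for (k in keep) {
        map <- stats::setNames(as.character(assignments[k, ]), labs)
        r <- lca_map(gt, st, map)
        o <- oracle_min_mappings(gt, st, map)
        expect_equal(r$n_duplications + r$n_losses, o$best_cost)
        expect_equal(r$n_duplications, o$min_dup)
        expect_equal(length(o$best), 1L)  # unique minimiser
        expect_equal(r$nodes$species_node, o$best[[1]]$M)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 300L)
})

test_that("ancestral lineages count one more than root-mapped duplications", {
  # root duplication with two species-congruent subtrees: two lineages
  gt <- read_newick("(((s1,t1),h1),((s2,t2),h2));")
  map <- c(s1 = "Sc", t1 = "Tu", h1 = "Hv", s2 = "Sc", t2 = "Tu", h2 = "Hv")
  r <- lca_map(gt, st, map)
  lin <- decompose_lineages(list(fam1 = r))
  expect_equal(nrow(lin), 2L)
  expect_equal(lin$presence, rep("Hv+Sc+Tu", 2))

  # five independent single-copy families: five lineages
  recs <- lapply(1:5, function(i)
    lca_map(read_newick("((s1,t1),h1);"), st,
            c(s1 = "Sc", t1 = "Tu", h1 = "Hv")))
  names(recs) <- sprintf("fam%d", 1:5)
  expect_equal(nrow(decompose_lineages(recs)), 5L)

  # a one-species family maps below the root: one singleton-presence lineage
  r1 <- lca_map(read_newick("(s1,s2);"), st, c(s1 = "Sc", s2 = "Sc"))
  lin1 <- decompose_lineages(list(f = r1))
  expect_equal(nrow(lin1), 1L)
  expect_equal(lin1$presence, "Sc")

  # invariant on simulated families
  s <- sim_gene_families(lambda = 0.4, mu = 0.3, n_families = 50, seed = 13)
  fr <- reconcile_forest(s$newick, s$leaf_map, st)
  for (fam in names(fr$reconciliations)) {
    rec <- fr$reconciliations[[fam]]
    root_dups <- sum(rec$nodes$event == "duplication" &
                       rec$nodes$species_node == rec$species_index$root)
    expect_equal(sum(fr$lineages$family == fam), root_dups + 1L)
  }
})

test_that("venn partition cells sum to the lineage count", {
  lin <- data.frame(presence = c("Sc", "Sc+Tu", "Hv+Sc+Tu"))
  v <- venn_partition(lin)
  expect_equal(sum(v), 3L)
  expect_equal(unname(v[c("Sc", "Sc+Tu", "Hv+Sc+Tu")]), c(1L, 1L, 1L))
  sc_total <- sum(v[grepl("(^|\\+)Sc($|\\+)", names(v))])
  expect_equal(sc_total, 3L)
  expect_equal(sum(venn_partition(lin[0, , drop = FALSE])), 0L)
  # simulated cell counts match simulator truth
  s <- sim_gene_families(lambda = 0.3, mu = 0.6, n_families = 120, seed = 29)
  fr <- reconcile_forest(s$newick, s$leaf_map, st)
  expect_equal(venn_partition(fr$lineages), venn_partition(s$lineages))
})

test_that("branch accounting follows presence-set logic", {
  lin <- data.frame(presence = c("Hv", "Hv+Sc", "Hv+Sc+Tu", "Sc+Tu"))
  acct <- branch_accounting(lin, st)
  row <- function(br) acct[acct$branch == br, ]
  expect_equal(row("root")$preserved, 4L)
  # the Hv-only lineage dies on the branch to the Sc/Tu ancestor
  expect_equal(row("ScTu")$lost, 1L)
  expect_equal(row("ScTu")$preserved, 3L)
  # {Hv,Sc} survives to the Sc/Tu ancestor but dies on the Tu terminal
  expect_equal(row("Tu")$lost, 1L)
  expect_equal(row("Tu")$preserved, 2L)
  expect_equal(row("Hv")$lost, 1L)
  # preserved(parent) = preserved(child) + lost(child) on every branch
  expect_equal(row("ScTu")$preserved,
               row("Sc")$preserved + row("Sc")$lost)
  all3 <- data.frame(presence = rep("Hv+Sc+Tu", 7))
  a3 <- branch_accounting(all3, st)
  expect_true(all(a3$lost == 0L))
  expect_true(all(a3$preserved == 7L))
})

test_that("neutral birth-death gives every lineage to all three species", {
  s <- sim_gene_families(lambda = 0, mu = 0, n_families = 30, seed = 3)
  expect_equal(nrow(s$lineages), 30L)
  expect_true(all(s$lineages$presence == "Hv+Sc+Tu"))
  fr <- reconcile_forest(s$newick, s$leaf_map, st)
  v <- venn_partition(fr$lineages)
  expect_equal(unname(v["Hv+Sc+Tu"]), 30L)
  expect_equal(sum(v), 30L)
})

test_that("inferred per-branch event counts equal simulator truth", {
  s <- sim_gene_families(lambda = 0.4, mu = 0.7, n_families = 150, seed = 91)
  fr <- reconcile_forest(s$newick, s$leaf_map, st)
  ev <- branch_event_summary(fr$reconciliations)
  expect_equal(ev$duplications, s$truth_duplications)
  expect_equal(ev$losses, s$truth_losses)
  expect_equal(sort(fr$lineages$presence), sort(s$lineages$presence))
})
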