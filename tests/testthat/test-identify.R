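mk_hit <- function(prot, acc, name, from, to, ie = 1e-10) {
  data.frame(protein_id = prot, domain_accession = acc, domain_name = name,
             env_start = from, env_end = to, i_evalue = ie,
             stringsAsFactors = FALSE)
}

test_that("candidate filtering requires a conserved NB-ARC domain", {
  hits <- rbind(
    mk_hit("keep", "PF00931", "NB-ARC", 10, 100, 1e-12),
    mk_hit("lrr_only", "PF13855", "LRR_8", 10, 100, 1e-30),
    mk_hit("weak", "PF00931", "NB-ARC", 10, 100, 5e-4)
  )
  expect_equal(filter_candidates(hits), "keep")
  expect_equal(filter_candidates(hits, 1e-3), c("keep", "weak"))
  expect_equal(filter_candidates(empty_domain_hits()), character())
})

test_that("relaxing the E-value cutoff never shrinks the candidate set", {
  set.seed(11)
  hits <- mk_hit(sprintf("p%02d", 1:40), "PF00931", "NB-ARC", 10, 100,
                 10^runif(40, -30, 1))
  cuts <- 10^seq(-12, 0, by = 1)
  sets <- lapply(cuts, function(ct) filter_candidates(hits, ct))
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("subclass follows TIR > RPW8 > reference > CNL precedence", {
  nb <- mk_hit("p", "PF00931", "NB-ARC", 50, 150)
  expect_equal(assign_subclass(rbind(nb, mk_hit("p", "PF01582", "TIR", 1, 40))),
               "TNL")
  expect_equal(assign_subclass(rbind(nb, mk_hit("p", "PF05659", "RPW8", 1, 40))),
               "RNL")
  # ADR1-lineage RNL lacking a detectable RPW8 domain
  expect_equal(assign_subclass(rbind(nb, mk_hit("p", "PF13855", "LRR_8",
                                                200, 300)),
                               reference_besthit = "ADR1"), "RNL")
  expect_equal(assign_subclass(nb), "CNL")
  expect_warning(
    out <- assign_subclass(rbind(nb, mk_hit("p", "PF01582", "TIR", 1, 40),
                                 mk_hit("p", "PF05659", "RPW8", 160, 200))),
    "TIR")
  expect_equal(out, "TNL")
})

test_that("architecture labels follow domain order around the NB-ARC", {
  cc <- mk_hit("p", "CDD:CC", "CC", 1, 42)
  nb <- mk_hit("p", "PF00931", "NB-ARC", 60, 160)
  lrr <- mk_hit("p", "PF13855", "LRR_8", 180, 280)
  wrky <- mk_hit("p", "PF03106", "WRKY", 300, 360)

  expect_equal(build_architecture(rbind(cc, nb, lrr))$architecture, "CNL")
  expect_equal(build_architecture(nb)$architecture, "N")
  expect_equal(build_architecture(rbind(cc, nb))$architecture, "CN")
  expect_equal(build_architecture(rbind(nb, lrr))$architecture, "NL")

  a <- build_architecture(rbind(cc, nb, lrr, wrky))
  expect_equal(a$architecture, "CNL-ID")
  expect_equal(a$integrated_domains, "PF03106")

  pre <- mk_hit("p", "PF01419", "Jacalin", 1, 50)
  cc2 <- mk_hit("p", "CDD:CC", "CC", 60, 100)
  nb2 <- mk_hit("p", "PF00931", "NB-ARC", 120, 220)
  lrr2 <- mk_hit("p", "PF13855", "LRR_8", 240, 340)
  expect_equal(build_architecture(rbind(pre, cc2, nb2, lrr2))$architecture,
               "ID-CNL")
  wrky_c <- mk_hit("p", "PF03106", "WRKY", 360, 420)
  b <- build_architecture(rbind(pre, cc2, nb2, lrr2, wrky_c))
  expect_equal(b$architecture, "ID-CNL-ID")
  expect_setequal(b$integrated_domains, c("PF01419", "PF03106"))
})

test_that("multiple NB-ARC copies and disordered domains give 'other'", {
  nb1 <- mk_hit("p", "PF00931", "NB-ARC", 50, 150)
  nb2 <- mk_hit("p", "PF00931", "NB-ARC", 300, 400)
  expect_equal(build_architecture(rbind(nb1, nb2))$architecture, "other")
  # heavily overlapping envelopes merge into one copy instead
  nb3 <- mk_hit("p", "PF00931", "NB-ARC", 60, 160)
  merged <- build_architecture(rbind(nb1, nb3))
  expect_equal(merged$architecture, "N")
  expect_equal(merged$nbs_interval, c(50, 160))
  # LRR before the NB-ARC is out of canonical order
  lrr_first <- mk_hit("p", "PF13855", "LRR_8", 1, 40)
  expect_equal(build_architecture(rbind(lrr_first, nb1))$architecture,
               "other")
  expect_error(build_architecture(lrr_first), "NB-ARC")
})

test_that("motif scanning finds planted motifs and their knockouts", {
  filler <- function(n) paste(rep_len(strsplit("NQCA", "")[[1]], n),
                              collapse = "")
  nbs <- paste0(filler(8), "GMGGLGKTT", filler(10), "LLVLDDVW", filler(10),
                "QTTRQ", filler(10), "GLPL", filler(10), "FLHIQ", filler(8))
  seq <- paste0(filler(30), nbs, filler(30))
  iv <- c(30L, 30L + nchar(nbs))
  v <- scan_motifs(seq, iv)
  expect_true(all(v))
  expect_named(v, c("P-loop", "Kinase-2", "RNBS-B", "GLPL", "RNBS-D"))

  knocked <- sub("GLPL", "AAAA", seq)
  expect_equal(unname(scan_motifs(knocked, iv)), c(TRUE, TRUE, TRUE, FALSE,
                                                   TRUE))
  # the CNL-characteristic Kinase-2 signature ends in W
  expect_true(grepl(default_motif_patterns()$pattern[2], "LLVLDDVW"))
  expect_false(grepl(default_motif_patterns()$pattern[2], "LLVLDDVQ"))

  expect_error(scan_motifs("", c(0L, 5L)), "empty")
  expect_error(scan_motifs("MGGK", c(0L, 10L)), "bounds")
})

test_that("motif-loss histogram partitions proteins by motifs lost", {
  all_true <- matrix(TRUE, 4, 5)
  h <- count_motif_loss_categories(all_true)
  expect_equal(h[["0"]], 4L)
  mixed <- rbind(rep(TRUE, 5), c(TRUE, TRUE, TRUE, FALSE, TRUE),
                 c(FALSE, FALSE, TRUE, TRUE, TRUE),
                 c(TRUE, TRUE, TRUE, FALSE, TRUE))
  h2 <- count_motif_loss_categories(mixed)
  expect_equal(unname(h2[c("0", "1", "2")]), c(1L, 2L, 1L))
  expect_equal(sum(h2), 4L)
  expect_equal(length(count_motif_loss_categories(matrix(TRUE, 0, 5))), 0L)
})

test_that("heptad scoring detects coiled coils and rejects non-coils", {
  polyA <- paste(rep("A", 60), collapse = "")
  expect_false(cc_heptad_score(polyA)$call)
  zipper <- paste(rep("LQQLLQQ", 8), collapse = "")
  expect_true(cc_heptad_score(zipper)$call)
  expect_false(cc_heptad_score(zipper, threshold = Inf)$call)
  expect_false(cc_heptad_score("LQQL")$call)
  expect_equal(length(cc_heptad_score("LQQL")$scores), 0L)
})

test_that("planted architectures, subclasses and motifs are recovered exactly", {
  sim <- gen_genome(sim_config(seed = 101))
  ann <- nlr_annotate(gen_domtbl(sim), sim$proteins, sim$reference_hits)
  truth <- sim$truth$genes
  expect_setequal(ann$protein_id, truth$gene_id)
  m <- merge(ann, truth, by.x = "protein_id", by.y = "gene_id")
  expect_equal(nrow(m), sim$truth$n_nlr)
  expect_true(all(m$architecture.x == m$architecture.y))
  expect_true(all(m$subclass.x == m$subclass.y))
  found <- as.matrix(m[, default_motif_patterns()$name])
  planted <- as.matrix(m[, paste0("motif", 1:5)])
  expect_true(all(found == planted))
})

test_that("every candidate gets exactly one subclass and one architecture", {
  sim <- gen_genome(sim_config(seed = 55))
  ann <- nlr_annotate(gen_domtbl(sim), sim$proteins, sim$reference_hits)
  expect_false(anyDuplicated(ann$protein_id) > 0)
  expect_true(all(ann$subclass %in% c("CNL", "TNL", "RNL")))
  expect_equal(sum(table(ann$architecture)), nrow(ann))
  expect_equal(sum(table(ann$subclass)), nrow(ann))
})
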