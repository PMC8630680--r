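#!/usr/bin/env Rscript
# Intra-genome collinear blocks and duplication typing of the NLR genes,
# plus cross-genome synteny against a second synthetic genome and the
# syntenic NLR pair counts per chromosome pair.

library(nlrome)

dir <- "results/simdata"
genes <- read_gff3(file.path(dir, "genes.gff3"))
ann <- read.delim("results/annotations.tsv", check.names = FALSE)
nlr_ids <- genes$gene_id[genes$protein_id %in% ann$protein_id]
hom <- read_blast_tab(file.path(dir, "homology.blast6"))

idx <- build_rank_index(genes)
blocks <- chain_anchors(hom, idx, idx)
cat(sprintf("intra-genome collinear blocks: %d (anchors: %s)\n",
            nrow(blocks), paste(blocks$n_anchors, collapse = ", ")))

dup <- classify_duplication(nlr_ids, hom, idx, blocks)
write.table(dup, "results/duplication_types.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tab <- table(dup$dup_type)
cat("duplication types:\n"); print(tab)
cat("proportions (%):\n")
print(round_half_up(100 * tab / sum(tab)))
seg <- dup$gene_id[dup$dup_type == "segmental"]
seg_pairs <- do.call(rbind, lapply(blocks$anchors, function(a)
  a[a$gene_a %in% seg & a$gene_b %in% seg, c("gene_a", "gene_b")]))
cat(sprintf("the %d segmental NLR genes form %d gene pairs\n",
            length(seg), nrow(seg_pairs)))

# cross-genome synteny against an independently simulated genome "B"
sim_b <- gen_genome(sim_config(seed = 42L, genome_tag = "B"))
inter <- gen_interspecies_homology(genes, sim_b$genes, n_blocks = 6,
                                   block_len = 10, invert = c(FALSE, TRUE),
                                   seed = 43L)
idx_b <- build_rank_index(sim_b$genes)
bl_ab <- chain_anchors(inter$hits, idx, idx_b)
syn <- syntenic_nlr_pairs(bl_ab, nlr_ids, sim_b$truth$genes$gene_id)
write.table(syn$counts, "results/syntenic_pair_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("cross-genome blocks: %d; syntenic NLR pairs: %d\n",
            nrow(bl_ab), nrow(syn$pairs)))
if (nrow(syn$counts) > 0) print(syn$counts)
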