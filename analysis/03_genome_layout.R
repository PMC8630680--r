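#!/usr/bin/env Rscript
# Chromosomal distribution of the identified NLR genes and 250-kb physical
# clustering into singleton and cluster loci.

library(nlrome)

dir <- "results/simdata"
genes <- read_gff3(file.path(dir, "genes.gff3"))
ann <- read.delim("results/annotations.tsv", check.names = FALSE)
nlr <- genes[genes$protein_id %in% ann$protein_id, ]

cat("NLR genes per chromosome:\n")
print(tally_by_chromosome(nlr))

loci <- cluster_loci(nlr, window_bp = 250000)
lay <- summarize_layout(loci)
out <- loci
out$gene_ids <- vapply(out$gene_ids, paste, "", collapse = ";")
write.table(out, "results/loci.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("\n%d anchored NLR genes fall into %d loci: %d singletons + %d clusters\n",
            lay$n_genes, lay$n_loci, lay$n_singletons, lay$n_clusters))
cat(sprintf("%d genes (%d%%) are clustered; mean cluster size %.1f\n",
            lay$n_clustered_genes, lay$pct_clustered,
            lay$mean_genes_per_cluster))
cat("cluster-size histogram:\n"); print(lay$cluster_size_histogram)
cat(sprintf("%d NLR genes are on unplaced scaffolds\n", lay$n_unplaced))
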