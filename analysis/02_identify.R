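#!/usr/bin/env Rscript
# Identify NLR genes from the domain-hit table, assign subclasses and
# domain architectures, and profile the five conserved NBS motifs.

library(nlrome)

dir <- "results/simdata"
hits <- read_domtbl(file.path(dir, "domains.domtbl"))
proteins <- read_protein_fasta(file.path(dir, "proteins.fasta"))
refhits <- read.delim(file.path(dir, "reference_hits.tsv"))

ann <- nlr_annotate(hits, proteins, refhits)
dir.create("results", showWarnings = FALSE)
write.table(ann, "results/annotations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d NLR genes identified (E-value cutoff 1e-4)\n", nrow(ann)))
cat("subclasses:\n"); print(table(ann$subclass))
cat("architecture groups:\n"); print(table(ann$architecture))
hist <- count_motif_loss_categories(
  as.matrix(ann[, default_motif_patterns()$name]))
cat("motifs lost per protein:\n"); print(hist)
cat(sprintf("%d/%d proteins (%d%%) keep all five NBS motifs\n",
            sum(ann$n_motifs == 5), nrow(ann),
            round_half_up(100 * sum(ann$n_motifs == 5) / nrow(ann))))

# verify against planted truth
truth <- read.delim(file.path(dir, "truth_genes.tsv"))
m <- merge(ann, truth, by.x = "protein_id", by.y = "gene_id")
cat(sprintf("planted-truth recovery: architecture %.0f%%, subclass %.0f%%\n",
            100 * mean(m$architecture.x == m$architecture.y),
            100 * mean(m$subclass.x == m$subclass.y)))
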