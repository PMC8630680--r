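---
title: "Methods: genome-wide NLR gene family analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide NLR gene family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrome)
```

## The problem

Plant NBS-LRR (NLR) genes are the largest family of disease-resistance
genes. A genome-wide NLR study proceeds in four stages, all implemented
here: (1) identify NLR genes from domain evidence and classify them into
subclasses and domain architectures; (2) describe their chromosomal layout,
in particular physical clustering; (3) classify how they were duplicated,
using collinear (syntenic) blocks; (4) reconcile NLR gene trees with the
species tree to count ancestral lineages, duplications and losses. The
package targets Triticeae genomes — rye (*Secale cereale*, `Sc`), diploid
wheat (*Triticum urartu*, `Tu`) and barley (*Hordeum vulgare*, `Hv`) — with
the fixed species tree `((Sc,Tu),Hv)`, but every function is generic.

Profile-HMM and BLAST searches, multiple alignment and ML tree inference
are deliberately out of scope: the pipeline consumes their standard output
formats (hmmscan `--domtblout`, BLAST `-outfmt 6`, Newick) as inputs.
Internally, all genomic and residue coordinates are 0-based half-open;
conversion happens only at file boundaries, which makes the coordinate
conversion an involution that the tests exercise directly.

## Identification and classification

A protein is an NLR candidate iff it has at least one NB-ARC (Pfam PF00931)
domain hit with independent E-value at or below the cutoff
(default `1e-4`). Subclass assignment follows N-terminal domain evidence
with precedence TIR > RPW8 > reference best hit > CNL:

* TIR (PF01582) present → TNL (never expected in Triticeae, whose TNLs were
  lost ancestrally — the generator plants none, and the tests assert none
  are called);
* RPW8 (PF05659) present, **or** the protein's best hit against a curated
  reference NLR set is labelled ADR1/NRG1/RNL → RNL. The reference route
  matters because ADR1-lineage RNLs can lack a detectable RPW8 domain;
* otherwise CNL.

Architecture labels order domain envelopes by midpoint: coiled-coil (CC)
evidence before the NB-ARC contributes a "C", LRR evidence after it an "L",
giving `CNL`, `CN`, `NL` or `N`. Two rules the source data leave open are
fixed here and exposed as code: more than one NB-ARC copy (after merging
envelopes that overlap by more than half of the shorter) or canonical
domains out of order yield `other`; a non-canonical ("integrated") domain
before the first or after the last canonical domain wraps the label as
`ID-CNL`, `CNL-ID` or `ID-CNL-ID`. LRR evidence is any hit in a
configurable accession list (LRRs span many Pfam families) or whose name
begins with "LRR".

CC domains have no Pfam HMM in the standard tables, so explicit CC rows in
the input (e.g. imported from a CDD scan) take precedence, and a
sliding-window heptad scorer (`cc_heptad_score()`) is the fallback: over
28-residue windows and all seven registers, the score is the mean
hydrophobic propensity at the heptad `a`/`d` positions, with a fixed
in-package propensity table; a window at or above 0.7 triggers a CC call.
The threshold separates an ideal leucine-zipper repeat (score 1.0) from
both random sequence and leucine-rich repeats (at most ~0.63 under any
register, because LRR leucines recur with period 9, incommensurate with the
heptad).

### Motif profiling

De novo motif discovery (MEME-style) is dataset-dependent and not
reproducible at desk scale, so the five conserved NBS motifs are detected
by degenerate consensus patterns, shipped as configuration data
(`default_motif_patterns()`): P-loop `G....G[GK][TS][TS]`, Kinase-2
`[LIVMF][LIVMF].[LIVMF]DD[LIV][WDE]` (ending in W for the CNL-typical
"DDVW"), RNBS-B `[ST][ST]R` (the CNL "TTR" core), GLPL `G[LIM]PL`, RNBS-D
`FL[HY][IV]`. Each is searched within the NB-ARC envelope extended by a
40-residue margin. Published motif-loss breakdowns are not always
internally consistent (a well-known example reports 77+37+29+21 = 164
proteins in its loss categories against a stated 182, and per-chromosome
counts summing to 552 against a stated 558); the toolkit therefore always
reports its own histogram, which provably partitions the input, and the
report carries an explicit consistency flag.

## Chromosomal layout

Two successive NLR genes on a chromosome within 250 kb are clustered, and
clustering is the transitive closure of that pairwise rule, so clusters may
span more than 250 kb end to end. The convention left open by the sliding
window description is fixed as: distance is start-to-start of successive
genes sorted by start, and the boundary is inclusive (exactly 250,000 bp
clusters). Both choices are parameters. Strand is ignored; unplaced
(`chrUn`) genes are excluded from clustering and counted separately.
The suite checks clustering against an independent union-find oracle
(connected components of the all-pairs linkage graph) on 200 random
instances of up to 100 genes, and reported percentages use half-up
rounding (`round_half_up()`), matching the integer-percent reporting style
of genome papers.

## Collinearity and duplication typing

Collinear blocks are re-implemented MCScanX-style rather than wrapped:
homology hits are filtered (E ≤ 1e-5, best 5 hits per query, self-pairs
removed), mapped to per-chromosome gene ranks, and chained by dynamic
programming on the rank-rank dot plot. A chain extends an anchor when both
rank gaps are at most 25 and ranks stay strictly monotone in genome A and
monotone (either direction — the block orientation) in genome B; the score
is +1 per anchor and −1 per skipped rank; blocks need at least 5 anchors.
Non-overlapping chains are taken greedily by score with deterministic
tie-breaks (longer chain, then lexicographically earliest first anchor).
The exact scoring of the original tool is not published; these defaults
mirror its documented parameters and are all exposed in
`synteny_params()`. The DP is validated against exhaustive chain
enumeration on random ≤30×30 rank instances.

Duplication typing is a total function with fixed priority: no non-self
homolog at the cutoff → `singleton`; block anchor → `segmental`; homolog at
adjacent rank on the same chromosome → `tandem`; within 10 ranks →
`proximal`; otherwise `dispersed`. Segmental outranks tandem (the
convention of the reference implementation) so that the partition is
unique. Unplaced genes can only be singleton or dispersed and are flagged.

## Reconciliation and ancestral lineages

`lca_map()` implements standard duplication–loss reconciliation: leaves map
to their species, internal nodes to the LCA of their children's images; a
node is a duplication iff it maps where one of its children maps. Losses on
the edge to a child are `depth(M(child)) − depth(M(parent)) − 1`, plus one
when the parent is a duplication mapping above the child, and each loss is
attributed to the species branch it falls on. The suite verifies, by
exhaustive enumeration of all valid mappings on small trees, that the LCA
mapping is the unique minimiser of duplications + losses and attains the
minimum duplication count (enumeration covers *all* labelled rooted binary
gene trees with up to 4 leaves over the three species, plus a seeded sample
of 5–8-leaf trees; full enumeration at 8 leaves would be ~10^7 trees for no
additional structural coverage).

Ancestral lineages are obtained by cutting each reconciled family tree at
every duplication node mapped to the species root; each family therefore
yields one more lineage than its count of root-mapped duplications.
Lineages carry species-presence sets, tabulated as a 7-cell Venn partition,
and `branch_accounting()` counts per branch the lineages preserved into the
clade below versus lost on the branch, so that preserved(parent) =
preserved(child) + lost(child) on every branch — totals always balance,
and duplication gains are reported separately (`branch_event_summary()`)
rather than netted against losses.

Reconciliation is defined on rooted binary trees. A Newick trifurcating
root cannot be distinguished from an unrooted tree, so any tree with fewer
than `Ntip − 1` internal nodes is treated as polytomous: an error by
default, or a deterministic resolution (via `ape::multi2di`, non-random)
behind `resolve_polytomies = TRUE`. Single-gene families, which are not
binary trees at all, contribute one lineage directly in
`reconcile_forest()`.

## The synthetic-data generator

`gen_genome()` builds a desk-scale rye-like genome: 7 chromosomes with ~40
background genes each, 66 NLR genes planted as 6 clusters (sizes 2, 2, 3,
3, 4 and 15 — the largest mirroring the biggest observed rye cluster), 14
plain singletons, 3 tandem arrays (the 2- and 3-gene clusters), 3 proximal
and 4 dispersed homolog pairs, 3 intra-genome collinear blocks whose NLR
anchors form 3 segmental pairs (one inter-chromosomal, two
intra-chromosomal, as in rye), 3 unplaced genes and exactly one
reference-annotated RNL whose protein lacks RPW8. Spacings are fixed by
construction: 50 kb start-to-start within clusters (safely below the
250-kb window), 400 kb flanking every NLR locus (safely above it), 35 kb
between background genes, so a proximal pair separated by nine background
genes is within 10 ranks but **not** physically clustered. Architecture
proportions (35/24/11/25/5% for CNL/CN/NL/N/other, 8% integrated-domain
fusions) and a 7% per-motif knockout rate reproduce the reported group
structure of the rye NLR complement, under which ~69% of proteins retain
all five motifs.

Proteins are assembled from sequence cassettes so that the domain-hit table
can be emitted without running any search tool while the motif scanner and
CC scorer still operate on real strings. All linker and filler alphabets
avoid every residue that could complete a motif pattern (no G/K/T runs, no
DD, R, P or F), so the planted motif vector is exactly what the scanner can
find; this is also why planted-truth recovery is asserted at 100% rather
than with a tolerance. Decoy NB-ARC rows at E = 0.5 and noise homology rows
at E = 1e-3 are planted above the respective cutoffs to exercise the
filters without changing any truth.

`sim_gene_families()` evolves each family as a birth–death process
(duplication rate λ, loss rate μ per copy per unit branch length) along the
species tree, starting from a single copy on a stem branch above the root
(so root-mapped duplications, hence multi-lineage families, can arise).
The recorded truth is the *parsimony-observable* history of the pruned
tree: a duplication whose sibling copy leaves no extant descendants, or
losses below it, are not inferable by any method, and the truth counts are
computed by set logic on the simulator's own event tree (retained nodes,
extant-species LCAs, species-path gaps) — structurally independent of the
reconciliation code it validates. The default study condition for the
analysis scripts is λ = 0.3, μ = 0.5 over 200 families, which yields a
realistic excess of one- and two-species lineages over three-species ones.

### What the generator does not emulate

Sequence evolution is not simulated: proteins are cassette concatenations,
homology hits are planted rather than computed, and gene trees are the true
simulated topologies. Passing tests therefore demonstrate the correctness
of the *rules and algorithms* on inputs with the assumed statistical
structure — not robustness to alignment error, fragmented gene models,
mis-specified domain boundaries or tree-inference uncertainty, all of which
affect real genome scans. Genome-scale headline counts of any particular
species likewise require that species' real inputs.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; generation is
byte-identical for a fixed seed. The test suite uses 200 random clustering
instances (≤100 genes), 50 random chaining instances (≤30×30 ranks,
exhaustive oracle), four planted genomes giving ≥50 genes per duplication
class, exhaustive reconciliation oracles on all ≤4-leaf labelled trees, and
200-family birth–death simulations — sizes at which every oracle is exact
and the suite completes in a few minutes on one CPU.
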