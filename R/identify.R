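#' Domain category configuration for NLR classification
#'
#' NLR proteins are recognised and classified from domain-hit evidence.
#' The canonical domains are the central NB-ARC (Pfam PF00931), the
#' N-terminal TIR (PF01582), RPW8 (PF05659) and coiled-coil (CC) domains, and
#' C-terminal leucine-rich repeats (LRRs, which span many Pfam families).
#' Everything else counts as a potential integrated domain (ID).
#'
#' @param lrr_accessions Pfam accessions treated as LRR evidence, in addition
#'   to any hit whose domain name starts with "LRR".
#' @param cc_names Domain names treated as explicit coiled-coil evidence
#'   (e.g. rows imported from a CDD scan).
#' @return A list of category definitions consumed by the classifiers.
#' @export
domain_categories <- function(lrr_accessions = c("PF00560", "PF07725",
                                                 "PF12799", "PF13306",
                                                 "PF13504", "PF13516",
                                                 "PF13855", "PF08263"),
                              cc_names = c("CC", "Coil", "coiled_coil")) {
  list(
    nbarc = "PF00931",
    tir = "PF01582",
    rpw8 = "PF05659",
    lrr_accessions = lrr_accessions,
    cc_names = cc_names
  )
}

strip_pfam_version <- function(acc) sub("\\..*$", "", acc)

#' Categorise domain hits into canonical NLR domain classes
#'
#' @param hits Domain-hit data frame.
#' @param categories Output of [domain_categories()].
#' @return `hits` with an added `category` column in
#'   `{nbarc, tir, rpw8, cc, lrr, other}`.
#' @keywords internal
categorise_hits <- function(hits, categories = domain_categories()) {
  acc <- strip_pfam_version(hits$domain_accession)
  cat <- rep("other", nrow(hits))
  cat[acc %in% categories$lrr_accessions |
        grepl("^LRR", hits$domain_name, ignore.case = TRUE)] <- "lrr"
  cat[hits$domain_name %in% categories$cc_names] <- "cc"
  cat[acc == categories$rpw8] <- "rpw8"
  cat[acc == categories$tir] <- "tir"
  cat[acc == categories$nbarc] <- "nbarc"
  hits$category <- cat
  hits
}

#' Filter candidate proteins by presence of a conserved NB-ARC domain
#'
#' A protein is kept if and only if it carries at least one NB-ARC (PF00931)
#' hit whose independent E-value is at or below the cutoff. Proteins without
#' a conserved NBS domain are removed from the candidate set.
#'
#' @param domain_hits Domain-hit data frame (see [read_domtbl()]).
#' @param evalue_cutoff Positive E-value cutoff; default `1e-4`.
#' @param categories Output of [domain_categories()].
#' @return Character vector of retained protein IDs (sorted, unique).
#' @export
filter_candidates <- function(domain_hits, evalue_cutoff = 1e-4,
                              categories = domain_categories()) {
  stopifnot(evalue_cutoff > 0)
  if (nrow(domain_hits) == 0L) {
    return(character())
  }
  hits <- categorise_hits(domain_hits, categories)
  keep <- hits$category == "nbarc" & hits$i_evalue <= evalue_cutoff
  sort(unique(hits$protein_id[keep]))
}

#' Assign an NLR subclass from domain evidence
#'
#' Subclasses follow the N-terminal domain: TIR present gives TNL; otherwise
#' RPW8 present, or a reference best hit annotated as RNL/ADR1/NRG1, gives
#' RNL; otherwise CNL (the default for monocot NLRs, whose TNLs were lost
#' ancestrally). Precedence is TIR > RPW8 > reference > CNL; the RNL route via
#' the reference table covers ADR1-lineage genes that lack a detectable RPW8
#' domain.
#'
#' @param hits_for_protein Domain hits for a single protein.
#' @param reference_besthit Optional label of the protein's best hit against a
#'   curated reference NLR set (e.g. `"ADR1"`); `NA`/`NULL` if absent.
#' @param categories Output of [domain_categories()].
#' @return One of `"TNL"`, `"RNL"`, `"CNL"`.
#' @export
assign_subclass <- function(hits_for_protein, reference_besthit = NULL,
                            categories = domain_categories()) {
  hits <- categorise_hits(hits_for_protein, categories)
  has_tir <- any(hits$category == "tir")
  has_rpw8 <- any(hits$category == "rpw8")
  if (has_tir && has_rpw8) {
    warning("protein carries both TIR and RPW8 evidence; classified TNL")
  }
  if (has_tir) {
    return("TNL")
  }
  ref_rnl <- !is.null(reference_besthit) && !is.na(reference_besthit) &&
    grepl("RNL|ADR1|NRG1", reference_besthit, ignore.case = TRUE)
  if (has_rpw8 || ref_rnl) {
    return("RNL")
  }
  "CNL"
}

#' Build the domain-architecture label of an NLR protein
#'
#' Domain envelopes are ordered by midpoint. Coiled-coil evidence before the
#' NB-ARC contributes the "C" prefix, any LRR evidence after it the "L"
#' suffix, giving a base label in `{CNL, CN, NL, N}`. More than one NB-ARC
#' copy (after merging envelopes that overlap by more than half) or canonical
#' domains out of order yield `"other"`. Non-canonical domains are recorded as
#' integrated domains (IDs); an ID before the first canonical domain wraps the
#' label with an `ID-` prefix, one after the last canonical domain with an
#' `-ID` suffix (e.g. `CNL-ID`, `ID-CNL`, `ID-CNL-ID`).
#'
#' @param hits_for_protein Domain hits for a single protein (must include at
#'   least one NB-ARC hit).
#' @param protein_length Optional protein length (residues); unused by the
#'   rules but validated against envelopes when given.
#' @param cc_call Logical fallback coiled-coil call from [cc_heptad_score()],
#'   used only when no explicit CC domain row is present.
#' @param categories Output of [domain_categories()].
#' @return A list with `architecture` (possibly ID-wrapped label),
#'   `base_architecture`, `integrated_domains` (character vector of
#'   accessions) and `nbs_interval` (0-based half-open residue interval).
#' @export
build_architecture <- function(hits_for_protein, protein_length = NULL,
                               cc_call = FALSE,
                               categories = domain_categories()) {
  hits <- categorise_hits(hits_for_protein, categories)
  nb <- hits[hits$category == "nbarc", , drop = FALSE]
  if (nrow(nb) == 0L) {
    stop("build_architecture requires at least one NB-ARC hit")
  }
  if (!is.null(protein_length) && any(hits$env_end > protein_length)) {
    stop("domain envelope extends beyond protein length")
  }
  nb_merged <- merge_envelopes(nb$env_start, nb$env_end, min_frac = 0.5)
  multiple_nbarc <- nrow(nb_merged) > 1L
  nbs_interval <- c(nb_merged$start[1L], nb_merged$end[1L])
  nb_mid <- mean(nbs_interval)

  mid <- (hits$env_start + hits$env_end) / 2
  cc_hits <- hits$category == "cc"
  lrr_hits <- hits$category == "lrr"
  has_c <- any(cc_hits & mid < nb_mid) || (!any(cc_hits) && isTRUE(cc_call))
  has_l <- any(lrr_hits & mid > nb_mid)
  out_of_order <- any(cc_hits & mid > nb_mid) || any(lrr_hits & mid < nb_mid)

  base <- if (multiple_nbarc || out_of_order) {
    "other"
  } else {
    paste0(if (has_c) "C" else "", "N", if (has_l) "L" else "")
  }

  canonical <- hits$category != "other"
  ids <- character()
  id_prefix <- FALSE
  id_suffix <- FALSE
  if (any(!canonical)) {
    first_can <- min(hits$env_start[canonical])
    last_can <- max(hits$env_end[canonical])
    idh <- hits[!canonical, , drop = FALSE]
    idm <- (idh$env_start + idh$env_end) / 2
    ids <- unique(strip_pfam_version(idh$domain_accession))
    id_prefix <- any(idm < first_can)
    id_suffix <- any(idm > last_can)
  }
  label <- base
  if (id_prefix) label <- paste0("ID-", label)
  if (id_suffix) label <- paste0(label, "-ID")

  list(architecture = label, base_architecture = base,
       integrated_domains = ids, nbs_interval = nbs_interval)
}

# Merge intervals whose reciprocal overlap exceeds min_frac of the shorter.
merge_envelopes <- function(start, end, min_frac = 0.5) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1L]) {
    ov <- min(me, end[i]) - max(ms, start[i])
    shorter <- min(me - ms, end[i] - start[i])
    if (ov > min_frac * shorter) {
      ms <- min(ms, start[i]); me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Default consensus patterns for the five conserved NB-ARC motifs
#'
#' Degenerate amino-acid patterns (POSIX character classes) for the P-loop,
#' Kinase-2, RNBS-B, GLPL and RNBS-D motifs of the NBS domain. The Kinase-2
#' pattern ends in `[WDE]`, accommodating the "DDVW" signature characteristic
#' of CNL proteins, and RNBS-B carries the CNL-typical "TTR" core. All
#' patterns are configuration data and can be overridden.
#'
#' @return A data frame with columns `name` and `pattern`.
#' @export
default_motif_patterns <- function() {
  data.frame(
    name = c("P-loop", "Kinase-2", "RNBS-B", "GLPL", "RNBS-D"),
    pattern = c(
      "G....G[GK][TS][TS]",
      "[LIVMF][LIVMF].[LIVMF]DD[LIV][WDE]",
      "[ST][ST]R",
      "G[LIM]PL",
      "FL[HY][IV]"
    ),
    stringsAsFactors = FALSE
  )
}

#' Scan the NBS domain of a protein for the five conserved motifs
#'
#' Each consensus pattern is searched within the NB-ARC envelope extended by
#' a margin on both sides; presence means at least one match. The result is
#' an ordered logical 5-vector (P-loop, Kinase-2, RNBS-B, GLPL, RNBS-D).
#'
#' @param protein_seq Amino-acid sequence (single string).
#' @param nbs_interval 0-based half-open residue interval of the NB-ARC
#'   envelope.
#' @param patterns Motif pattern table; see [default_motif_patterns()].
#' @param margin Residues added on both sides of the envelope; default 40.
#' @return Named logical vector of length 5.
#' @export
scan_motifs <- function(protein_seq, nbs_interval,
                        patterns = default_motif_patterns(), margin = 40L) {
  if (!nzchar(protein_seq)) {
    stop("scan_motifs: empty protein sequence")
  }
  n <- nchar(protein_seq)
  if (nbs_interval[1L] < 0 || nbs_interval[2L] > n ||
      nbs_interval[1L] >= nbs_interval[2L]) {
    stop("scan_motifs: NBS interval outside sequence bounds")
  }
  from <- max(0L, nbs_interval[1L] - margin)
  to <- min(n, nbs_interval[2L] + margin)
  zone <- substr(protein_seq, from + 1L, to)
  out <- vapply(patterns$pattern, function(p) grepl(p, zone), logical(1L))
  names(out) <- patterns$name
  out
}

#' Histogram of motif-loss categories across proteins
#'
#' Counts, over a set of annotated proteins, how many lost 0, 1, ..., 5 of
#' the five conserved NBS motifs.
#'
#' @param motif_matrix Logical matrix (proteins x 5 motifs) or a list of
#'   5-vectors as returned by [scan_motifs()].
#' @return Integer vector named "0".."5"; entries sum to the protein count.
#' @export
count_motif_loss_categories <- function(motif_matrix) {
  if (is.list(motif_matrix)) {
    motif_matrix <- do.call(rbind, motif_matrix)
  }
  if (is.null(motif_matrix) || nrow(motif_matrix) == 0L) {
    return(stats::setNames(integer(6L), as.character(0:5))[0])
  }
  stopifnot(ncol(motif_matrix) == 5L)
  lost <- 5L - rowSums(motif_matrix)
  tab <- table(factor(lost, levels = 0:5))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0 | as.integer(names(out)) <= max(lost)]
}

#' Annotate a set of candidate NLR proteins
#'
#' End-to-end per-protein annotation: NB-ARC filtering, subclass assignment,
#' architecture and integrated-domain calling, and motif profiling. The
#' coiled-coil fallback scorer is applied only to proteins without explicit
#' CC evidence when sequences are available.
#'
#' @param domain_hits Domain-hit data frame covering all proteins.
#' @param proteins Optional named character vector of protein sequences
#'   (required for motif scanning and the CC fallback).
#' @param reference_hits Optional data frame with columns `protein_id` and
#'   `besthit` from a reference NLR BLAST (labels like "ADR1" mark RNLs).
#' @param evalue_cutoff NB-ARC E-value cutoff; default `1e-4`.
#' @param patterns Motif patterns; see [default_motif_patterns()].
#' @param margin Motif search margin (residues) around the NB-ARC envelope.
#' @param cc_threshold Threshold for the heptad coiled-coil fallback call.
#' @param categories Output of [domain_categories()].
#' @return Data frame with one row per retained protein: `protein_id`,
#'   `subclass`, `architecture`, `base_architecture`, `integrated_domains`
#'   (comma-joined), `nbs_start`, `nbs_end`, `n_motifs` and five logical
#'   motif columns.
#' @export
nlr_annotate <- function(domain_hits, proteins = NULL, reference_hits = NULL,
                         evalue_cutoff = 1e-4,
                         patterns = default_motif_patterns(), margin = 40L,
                         cc_threshold = 0.7,
                         categories = domain_categories()) {
  kept <- filter_candidates(domain_hits, evalue_cutoff, categories)
  if (length(kept) == 0L) {
    return(empty_annotation(patterns))
  }
  ref <- NULL
  if (!is.null(reference_hits) && nrow(reference_hits) > 0L) {
    ref <- stats::setNames(reference_hits$besthit, reference_hits$protein_id)
  }
  rows <- lapply(kept, function(pid) {
    hits <- domain_hits[domain_hits$protein_id == pid, , drop = FALSE]
    seq <- if (!is.null(proteins)) proteins[[pid]] else NULL
    cc_call <- FALSE
    cat_hits <- categorise_hits(hits, categories)
    if (!any(cat_hits$category == "cc") && !is.null(seq)) {
      cc_call <- cc_heptad_score(seq, threshold = cc_threshold)$call
    }
    arch <- build_architecture(hits, protein_length =
                                 if (is.null(seq)) NULL else nchar(seq),
                               cc_call = cc_call, categories = categories)
    subclass <- assign_subclass(hits, if (is.null(ref)) NULL else ref[pid],
                                categories)
    motifs <- if (is.null(seq)) {
      stats::setNames(rep(NA, nrow(patterns)), patterns$name)
    } else {
      scan_motifs(seq, arch$nbs_interval, patterns, margin)
    }
    cbind(
      data.frame(protein_id = pid, subclass = subclass,
                 architecture = arch$architecture,
                 base_architecture = arch$base_architecture,
                 integrated_domains = paste(arch$integrated_domains,
                                            collapse = ","),
                 nbs_start = arch$nbs_interval[1L],
                 nbs_end = arch$nbs_interval[2L],
                 n_motifs = sum(motifs), stringsAsFactors = FALSE),
      as.data.frame(as.list(motifs), check.names = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_annotation <- function(patterns = default_motif_patterns()) {
  base <- data.frame(protein_id = character(), subclass = character(),
                     architecture = character(),
                     base_architecture = character(),
                     integrated_domains = character(), nbs_start = integer(),
                     nbs_end = integer(), n_motifs = integer(),
                     stringsAsFactors = FALSE)
  for (nm in patterns$name) base[[nm]] <- logical()
  base
}
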