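#' Read and write trees in Newick format
#'
#' Thin wrappers over \pkg{ape} with the validity checks the pipeline relies
#' on: a terminating semicolon, balanced parentheses, unique leaf labels.
#' Polytomies are preserved on parse; reconciliation later insists on binary
#' trees (or resolves polytomies deterministically when asked).
#'
#' @param text A Newick string, or a path to a file containing one tree per
#'   line (a forest) when `text` names an existing file.
#' @return For `read_newick`, a single `phylo` object (or a `multiPhylo` list
#'   when the input holds several trees). For `write_newick`, the Newick
#'   string, invisibly returned and optionally written to `path`.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl(";", text) && file.exists(text)) {
    txt <- paste(readLines(text, warn = FALSE), collapse = "\n")
  } else {
    txt <- paste(text, collapse = "\n")
  }
  if (!grepl(";", txt)) {
    stop("Newick parse error: missing terminating semicolon")
  }
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close) {
    stop("Newick parse error: unbalanced parentheses")
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) {
    stop("Newick parse error: could not parse tree")
  }
  check <- function(t) {
    if (anyDuplicated(t$tip.label)) {
      stop("Newick parse error: duplicated leaf labels")
    }
    t
  }
  if (inherits(tr, "multiPhylo")) {
    for (t in tr) check(t)
    tr
  } else {
    check(tr)
  }
}

#' @param tree A `phylo` (or `multiPhylo`) object.
#' @param path Optional path; when given, the Newick text is written there.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
  }
  invisible(txt)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return A named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
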