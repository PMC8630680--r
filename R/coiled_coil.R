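#' Sliding-window heptad coiled-coil propensity
#'
#' Fallback detector for N-terminal coiled-coil (CC) domains when no explicit
#' CC evidence is present in the domain-hit input. Coiled coils follow a
#' heptad repeat (abcdefg) with hydrophobic residues at the `a` and `d`
#' positions; for each window the score is the mean hydrophobic propensity at
#' the `a`/`d` positions, maximised over the seven possible registers. The
#' propensity table is fixed package data in the style of published
#' coiled-coil predictors.
#'
#' @param protein_seq Amino-acid sequence (single string).
#' @param window Window length in residues (must span at least one heptad);
#'   default 28 (four heptads).
#' @param threshold Score at or above which a window triggers a positive CC
#'   call; default 0.7. `Inf` disables the call.
#' @return A list with `scores` (one per window start) and `call` (logical:
#'   any window at or above threshold). Sequences shorter than the window
#'   give an empty score vector and a `FALSE` call.
#' @export
cc_heptad_score <- function(protein_seq, window = 28L, threshold = 0.7) {
  stopifnot(window >= 7L)
  n <- nchar(protein_seq)
  if (n < window) {
    return(list(scores = numeric(), call = FALSE))
  }
  prop <- cc_propensity_table()
  res <- strsplit(protein_seq, "", fixed = TRUE)[[1L]]
  p <- prop[res]
  p[is.na(p)] <- 0
  starts <- seq_len(n - window + 1L)
  scores <- vapply(starts, function(s) {
    win <- p[s:(s + window - 1L)]
    best <- 0
    for (off in 0:6) {
      # heptad positions a and d relative to this register
      pos <- seq_len(window) - 1L
      ad <- ((pos + off) %% 7L) %in% c(0L, 3L)
      sc <- mean(win[ad])
      if (sc > best) best <- sc
    }
    best
  }, numeric(1L))
  list(scores = scores, call = any(scores >= threshold))
}

# Hydrophobic propensities at core heptad positions; leucine-rich cores score
# highest, alanine is a weak core residue, polar/charged residues score zero.
cc_propensity_table <- function() {
  c(L = 1.0, I = 0.9, M = 0.85, V = 0.8, F = 0.7, A = 0.3, Y = 0.3,
    W = 0.3, C = 0.2, T = 0.1, S = 0.05, G = 0.0, P = 0.0, N = 0.0,
    Q = 0.1, D = 0.0, E = 0.1, K = 0.1, R = 0.1, H = 0.1)
}
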