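# RNA secondary-structure energies.
#
# Two backends behind one interface:
#  * "vienna": the production nearest-neighbor thermodynamic model at 37 C,
#    delegated to the RNAfold executable (ViennaRNA) when it is on the PATH.
#    Required only for reproducing published kcal/mol values.
#  * "basepair": a self-contained dynamic program that minimizes a simple
#    additive energy (per-pair terms GC -3, AU -2, GU -1, a -1 stacking
#    bonus for helix continuation, minimum hairpin loop of 3 unpaired
#    bases). Not thermodynamically calibrated, but exactly checkable
#    against exhaustive enumeration, which is what the tests rely on.

PAIR_ENERGY <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
STACK_BONUS <- -1
MIN_HAIRPIN <- 3L

pair_energy <- function(b1, b2) {
  e <- PAIR_ENERGY[paste0(b1, b2)]
  ifelse(is.na(e), NA_real_, unname(e))
}

#' Minimum free energy of an RNA sequence
#'
#' @param seq Nucleotide string (T and U both accepted; case-insensitive).
#' @param backend `"basepair"` (self-contained dynamic program; default) or
#'   `"vienna"` (RNAfold at 37 C with default parameters; requires the
#'   ViennaRNA executable on the PATH).
#' @return Minimum free energy dG (<= 0). A sequence admitting no base
#'   pairs returns 0.
#' @export
mfe_fold <- function(seq, backend = c("basepair", "vienna")) {
  backend <- match.arg(backend)
  check_nt(seq, "seq")
  seq <- rna_norm(seq)
  if (nchar(seq) < 1L) stop_param("`seq` must have length >= 1")
  switch(backend,
         basepair = mfe_basepair(seq),
         vienna = mfe_vienna(seq))
}

# O(n^2)-memory Zuker-style DP on the simple additive model. V[i,j] is the
# best energy of i..j given (i,j) paired; W[i,j] the best energy of i..j
# unconstrained. The stacking bonus applies when (i+1, j-1) is also paired.
mfe_basepair <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < MIN_HAIRPIN + 2L) return(0)
  V <- matrix(Inf, n, n)
  W <- matrix(0, n, n)
  for (span in (MIN_HAIRPIN + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      e <- pair_energy(chars[i], chars[j])
      if (!is.na(e)) {
        inner <- W[i + 1L, j - 1L]
        stacked <- V[i + 1L, j - 1L] + STACK_BONUS
        V[i, j] <- e + min(inner, stacked)
      }
      w <- min(W[i + 1L, j], W[i, j - 1L], V[i, j])
      if (span >= 2L) {
        ks <- i:(j - 1L)
        w <- min(w, min(W[cbind(i, ks)] + W[cbind(ks + 1L, j)]))
      }
      W[i, j] <- w
    }
  }
  min(0, W[1L, n])
}

mfe_vienna <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop_param("the 'vienna' backend needs the RNAfold executable on the ",
               "PATH")
  }
  out <- system2(exe, args = "--noPS", input = seq, stdout = TRUE)
  line <- out[length(out)]
  m <- regmatches(line, regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", line))
  if (!length(m)) stop_param("could not parse RNAfold output: ", line)
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

#' Length-normalized folding strength
#'
#' -dG divided by sequence length; higher values mean a more folded
#' region, lower values a less structured one.
#'
#' @param dg Minimum free energy (kcal/mol, <= 0).
#' @param length Sequence length in nt (> 0).
#' @return -dG / length (kcal/mol/nt, >= 0).
#' @export
neg_dg_per_nt <- function(dg, length) {
  if (any(length <= 0)) stop_param("`length` must be positive")
  -dg / length
}

#' GC fraction of a sequence
#'
#' @param seq Nucleotide string (case-insensitive; T and U equivalent).
#' @return (#G + #C) / length, in [0, 1].
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    check_nt(s, "seq")
    chars <- strsplit(toupper(s), "")[[1]]
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}
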