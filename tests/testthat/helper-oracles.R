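# Independent oracles used across the suite. Each one recomputes the
# quantity under test by a different route (numeric quadrature, exhaustive
# enumeration, brute-force permutation) so agreement is evidence, not
# tautology.

# Bayes factor by numeric quadrature of the binomial-likelihood integrals:
# M1 integrates het and homo likelihoods against their own Beta priors,
# M0 integrates the product likelihood against the shared error prior.
bf_oracle <- function(k1, n1, k2, n2,
                      prior_error = c(1, 1), prior_mobile = c(1, 1)) {
  # The posterior integrands are sharply peaked around k/n for large n, so
  # integrate on a fine fixed grid (Simpson) over [0, 1]; 2e5 panels give
  # ~1e-8 relative accuracy for the count ranges used in tests.
  simpson <- function(f, n_panels = 2e5) {
    x <- seq(0, 1, length.out = 2L * n_panels + 1L)
    y <- f(x)
    h <- x[2] - x[1]
    idx <- seq(2L, length(x) - 1L, by = 2L)
    (h / 3) * (y[1] + y[length(y)] + 4 * sum(y[idx]) +
                 2 * sum(y[seq(3L, length(x) - 2L, by = 2L)]))
  }
  m_het <- simpson(function(t) {
    stats::dbinom(k1, n1, t) *
      stats::dbeta(t, prior_mobile[1], prior_mobile[2])
  })
  m_homo <- simpson(function(t) {
    stats::dbinom(k2, n2, t) *
      stats::dbeta(t, prior_error[1], prior_error[2])
  })
  m_shared <- simpson(function(t) {
    stats::dbinom(k1, n1, t) * stats::dbinom(k2, n2, t) *
      stats::dbeta(t, prior_error[1], prior_error[2])
  })
  log10(m_het * m_homo / m_shared)
}

# --- Exhaustive-enumeration MFE oracle -------------------------------------
# Enumerates every non-crossing set of base pairs with hairpin loops >= 3
# and scores it with the same simple model the basepair backend minimizes
# (GC -3, AU -2, GU -1, stacking bonus -1). Feasible for n <= ~20.

oracle_pair_energy <- c(GC = -3, CG = -3, AU = -2, UA = -2,
                        GU = -1, UG = -1)

enum_structures <- function(chars, i, j, memo = new.env(parent = emptyenv())) {
  key <- paste(i, j)
  if (!is.null(memo[[key]])) return(memo[[key]])
  if (j - i < 4L) {
    res <- list(matrix(integer(), ncol = 2))
  } else {
    res <- lapply(enum_structures(chars, i + 1L, j, memo), identity)
    for (k in seq.int(i + 4L, j)) {
      if (is.na(oracle_pair_energy[paste0(chars[i], chars[k])])) next
      inner <- enum_structures(chars, i + 1L, k - 1L, memo)
      right <- if (k + 1L <= j) enum_structures(chars, k + 1L, j, memo) else
        list(matrix(integer(), ncol = 2))
      for (si in inner) for (sr in right) {
        res[[length(res) + 1L]] <- rbind(c(i, k), si, sr)
      }
    }
  }
  memo[[key]] <- res
  res
}

score_structure <- function(chars, pairs) {
  if (!nrow(pairs)) return(0)
  e <- sum(oracle_pair_energy[paste0(chars[pairs[, 1]], chars[pairs[, 2]])])
  key <- paste(pairs[, 1], pairs[, 2])
  stacks <- sum(paste(pairs[, 1] + 1L, pairs[, 2] - 1L) %in% key)
  e + stacks * -1
}

enum_mfe <- function(seq) {
  chars <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(chars)
  if (n < 5L) return(0)
  structs <- enum_structures(chars, 1L, n)
  min(0, min(vapply(structs, function(p) score_structure(chars, p),
                    numeric(1))))
}

# Random RNA sequence for property loops.
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# --- Exhaustive permutation KS ---------------------------------------------
# Two-sample KS: D for every assignment of the pooled values to groups of
# the original sizes; the exact p is the fraction of assignments with
# D >= D_obs.
ks_D <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pooled) - stats::ecdf(b)(pooled)))
}

ks_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  d_obs <- ks_D(a, b)
  assignments <- utils::combn(length(pooled), n_a)
  d_all <- apply(assignments, 2L, function(idx) {
    ks_D(pooled[idx], pooled[-idx])
  })
  mean(d_all >= d_obs - 1e-12)
}
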