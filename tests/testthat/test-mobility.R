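test_that("site allele counting maps pileups onto the diagnostic pair", {
  ref <- data.frame(contig = "Chr1", pos = 500L, allele_a = "G",
                    allele_b = "T", stringsAsFactors = FALSE)
  obs_row <- function(n_A = 0L, n_C = 0L, n_G = 0L, n_T = 0L) {
    data.frame(sample_id = "s1", tissue = "root", self_genotype = "A",
               contig = "Chr1", pos = 500L, transcript_id = "TX1",
               n_A = n_A, n_C = n_C, n_G = n_G, n_T = n_T,
               stringsAsFactors = FALSE)
  }
  # rootstock genotype A (allele G): 48 G + 2 T -> 2 foreign of 50
  out <- site_allele_counts(obs_row(n_G = 48L, n_T = 2L), ref)
  expect_identical(out$n_foreign, 2L)
  expect_identical(out$n_total, 50L)
  expect_identical(out$n_local, 48L)
  # all-local pileup
  out <- site_allele_counts(obs_row(n_G = 50L), ref)
  expect_identical(out$n_foreign, 0L)
  # bases matching neither allele go to n_other, never n_foreign
  out <- site_allele_counts(obs_row(n_G = 48L, n_C = 2L), ref)
  expect_identical(out$n_foreign, 0L)
  expect_identical(out$n_other, 2L)
  # sites absent from the reference are skipped with a warning
  stray <- obs_row(n_G = 10L)
  stray$pos <- 999L
  expect_warning(out <- site_allele_counts(rbind(obs_row(n_G = 5L), stray),
                                           ref),
                 "skipped")
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "n_skipped"), 1L)
})

test_that("closed-form Bayes factor matches the quadrature oracle", {
  cases <- rbind(
    c(0, 50, 0, 200), c(20, 50, 1, 1000), c(1, 200, 1, 200),
    c(5, 100, 2, 400), c(0, 10, 3, 50), c(50, 50, 0, 500),
    c(2, 30, 2, 30)
  )
  for (i in seq_len(nrow(cases))) {
    k1 <- cases[i, 1]; n1 <- cases[i, 2]
    k2 <- cases[i, 3]; n2 <- cases[i, 4]
    expect_equal(log10_bayes_factor(k1, n1, k2, n2),
                 bf_oracle(k1, n1, k2, n2), tolerance = 1e-6,
                 label = paste("case", i))
  }
  # non-uniform priors too
  expect_equal(
    log10_bayes_factor(8, 40, 1, 400, prior_error = c(1, 99),
                       prior_mobile = c(2, 18)),
    bf_oracle(8, 40, 1, 400, prior_error = c(1, 99),
              prior_mobile = c(2, 18)),
    tolerance = 1e-6)
})

test_that("Bayes factor orders the spec scenarios correctly", {
  # nothing foreign anywhere: evidence against mobility
  expect_lt(log10_bayes_factor(0, 50, 0, 200), 0)
  # strong foreign excess over a clean homograft: decisive
  expect_gt(log10_bayes_factor(20, 50, 1, 1000), 1)
  # het indistinguishable from homograft error: no support for mobility.
  # (Under uniform priors the shared-rate model is actively favoured,
  # log10 BF ~ -1.7, as the quadrature oracle confirms.)
  bf_eq <- log10_bayes_factor(1, 200, 1, 200)
  expect_lt(bf_eq, 0)
  expect_equal(bf_eq, bf_oracle(1, 200, 1, 200), tolerance = 1e-6)
  # undefined at zero heterograft depth
  expect_true(is.na(log10_bayes_factor(0, 0, 1, 100)))
})

test_that("Bayes factor is monotone in the heterograft foreign count", {
  bf <- log10_bayes_factor(0:40, 40, 2, 400)
  expect_true(all(diff(bf) > 0))
})

test_that("informative-site selection uses a strict threshold", {
  bf <- data.frame(contig = "Chr1", pos = 1:3,
                   log10_bf = c(1.0, 1.01, NA))
  kept <- informative_sites(bf)
  expect_identical(kept$pos, 2L)
  expect_identical(informative_sites(numeric(0)), numeric(0))
  expect_identical(informative_sites(c(1.0, 1.2, 0.5)), 1.2)
})

test_that("mobile detection needs >3 reads in >=2 replicates", {
  expect_true(call_mobile(c(4, 5, 0)))
  expect_false(call_mobile(c(4, 0, 0)))
  expect_false(call_mobile(c(3, 3, 3)))
  expect_true(call_mobile(c(10, 10), min_reads = 3, min_replicates = 2))
  expect_error(call_mobile(numeric(0)), "replicate")
})

test_that("mobile abundance is per-million and scale invariant", {
  expect_identical(mobile_abundance(5, 1e6), 5)
  expect_identical(mobile_abundance(0, 1e6), 0)
  expect_equal(mobile_abundance(c(4, 6), c(2e6, 2e6)),
               mobile_abundance(c(8, 12), c(4e6, 4e6)))
  expect_error(mobile_abundance(1, 0), "positive")
})

test_that("mobile index is the recipient/donor abundance ratio", {
  expect_identical(mobile_index(1, 4), 0.25)
  expect_identical(mobile_index(0, 4), 0)
  expect_warning(mi <- mobile_index(1, 0), "undefined")
  expect_true(is.na(mi))
})

test_that("condition-specificity categories partition all detection sets", {
  expect_identical(classify_condition_specificity(c("NP3D", "NP7D")),
                   "PSI-specific")
  expect_identical(classify_condition_specificity(c("FP7D", "NP7DRP2D")),
                   "PSD-specific")
  expect_identical(
    classify_condition_specificity(c("FP7D", "NP3D", "NP7D", "NP7DRP2D")),
    "common")
  expect_identical(classify_condition_specificity(character(0)), "other")
  expect_error(classify_condition_specificity("XX"), "unknown")
  # every subset of the four conditions lands in exactly one category
  conds <- pi_conditions()
  cats <- vapply(0:15, function(mask) {
    classify_condition_specificity(conds[as.logical(bitwAnd(mask, 2^(0:3)))])
  }, character(1))
  expect_true(all(cats %in% c("PSI-specific", "PSD-specific", "common",
                              "other")))
  expect_identical(sum(cats == "other"), 1L)  # only the empty set
})

test_that("PHR dependence splits wild-type calls against the mutant", {
  res <- phr_dependence(c("a", "b", "c", "d"), "a")
  expect_identical(res$dependent, c("b", "c", "d"))
  expect_identical(res$retained_fraction, 0.25)
  res2 <- phr_dependence(c("a", "b"), c("a", "b"))
  expect_identical(res2$dependent, character(0))
  expect_identical(res2$retained_fraction, 1)
  expect_error(phr_dependence(character(0), "a"), "empty")
})

test_that("hypergeometric overlap matches the combinatorial oracle", {
  u <- letters[1:20]
  res <- hypergeometric_overlap(letters[1:5], letters[1:5], u)
  expect_identical(res$overlap, 5L)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap of small sets in a large universe: p ~ 1
  u2 <- as.character(1:1000)
  res2 <- hypergeometric_overlap(as.character(1:3), as.character(501:503),
                                 u2)
  expect_gt(res2$p_value, 0.95)
  expect_error(hypergeometric_overlap("zzz", "a", u), "subsets")
})
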