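# Site-level evidence for mobility: allele counting over reference SNPs and
# the Bayes-factor gate separating genuine foreign-allele reads from
# sequencing error.

#' Count local/foreign alleles at reference SNP sites
#'
#' Maps per-site base counts onto the accession-diagnostic allele pair: for
#' each observation row the *local* allele is the one belonging to the
#' tissue's self genotype and the *foreign* allele is the one diagnostic of
#' the other graft partner. Bases matching neither allele are counted as
#' `n_other` and never contribute to `n_foreign`.
#'
#' @param obs Observation table with sample metadata columns (`tissue`,
#'   `self_genotype`, ...), site keys `contig`/`pos` and base counts
#'   `n_A`, `n_C`, `n_G`, `n_T` (see [generate_graft_experiment()]).
#' @param ref_snps A `reference_snp_set`, or a data.frame with columns
#'   contig, pos, allele_a, allele_b.
#' @param accessions Length-2 character vector mapping `allele_a` to the
#'   first accession and `allele_b` to the second.
#' @param genotype_map Optional named vector sample_id -> self genotype,
#'   overriding the `self_genotype` column.
#' @return The observation table restricted to reference sites, with
#'   `n_local`, `n_foreign`, `n_other`, `n_total` appended. Sites absent
#'   from the reference set are dropped; their number is reported via a
#'   warning and the `n_skipped` attribute.
#' @export
site_allele_counts <- function(obs, ref_snps, accessions = c("A", "B"),
                               genotype_map = NULL) {
  entries <- if (inherits(ref_snps, "reference_snp_set")) {
    ref_snps$entries
  } else ref_snps
  stopifnot(all(c("contig", "pos", "allele_a", "allele_b") %in%
                  names(entries)))
  self <- if (!is.null(genotype_map)) {
    unname(genotype_map[obs$sample_id])
  } else obs$self_genotype
  if (any(is.na(self)) || !all(self %in% accessions)) {
    stop_param("every observation needs a self genotype from `accessions`")
  }

  key_obs <- paste(obs$contig, obs$pos)
  key_ref <- paste(entries$contig, entries$pos)
  hit <- match(key_obs, key_ref)
  n_skipped <- sum(is.na(hit))
  if (n_skipped > 0L) {
    warning(n_skipped,
            " observation row(s) at sites absent from the reference set",
            " were skipped", call. = FALSE)
  }
  keep <- !is.na(hit)
  obs <- obs[keep, , drop = FALSE]
  hit <- hit[keep]
  self <- self[keep]

  allele_a <- entries$allele_a[hit]
  allele_b <- entries$allele_b[hit]
  self_is_a <- self == accessions[1]
  local_allele <- ifelse(self_is_a, allele_a, allele_b)
  foreign_allele <- ifelse(self_is_a, allele_b, allele_a)

  counts <- as.matrix(obs[, paste0("n_", DNA_BASES)])
  idx <- seq_len(nrow(obs))
  obs$n_local <- counts[cbind(idx, match(local_allele, DNA_BASES))]
  obs$n_foreign <- counts[cbind(idx, match(foreign_allele, DNA_BASES))]
  obs$n_total <- as.integer(rowSums(counts))
  obs$n_other <- obs$n_total - obs$n_local - obs$n_foreign
  obs$foreign_genotype <- ifelse(self_is_a, accessions[2], accessions[1])
  rownames(obs) <- NULL
  attr(obs, "n_skipped") <- n_skipped
  obs
}

#' Beta-binomial Bayes factor for foreign reads beyond sequencing error
#'
#' Compares two models for the foreign-allele counts at one site. M0 (error
#' only): the heterograft and matched homograft counts share one error rate
#' theta ~ Beta(a0, b0). M1 (mobility): the homograft keeps its error rate
#' theta_err ~ Beta(a0, b0) while the heterograft has an independent rate
#' theta_mob ~ Beta(a1, b1). Both marginal likelihoods are beta-binomial
#' and available in closed form, so the log10 Bayes factor is
#'
#' log10 BF = log10 [ BetaBin(k_het | n_het; a1, b1)
#'                    * BetaBin(k_homo | n_homo; a0, b0) ]
#'          - log10 [ BetaBin(k_het + k_homo | n_het + n_homo; a0, b0) ]
#'
#' (binomial coefficients cancel). Homograft counts come from the matched
#' homografted sample at the same site, which is what rules out sequencing
#' or PCR errors masquerading as foreign alleles.
#'
#' @param het_foreign,het_total Foreign and total read counts at the site in
#'   the heterograft (vectorized).
#' @param homo_foreign,homo_total The same counts in the matched homograft.
#' @param prior_error Beta prior (length-2, shape1/shape2) on the error
#'   rate; default Beta(1, 1).
#' @param prior_mobile Beta prior on the heterograft foreign-read rate under
#'   M1; default Beta(1, 1).
#' @return Numeric vector of log10 Bayes factors; `NA` where
#'   `het_total == 0` (non-informative site).
#' @export
log10_bayes_factor <- function(het_foreign, het_total, homo_foreign,
                               homo_total, prior_error = c(1, 1),
                               prior_mobile = c(1, 1)) {
  stopifnot(length(prior_error) == 2L, all(prior_error > 0),
            length(prior_mobile) == 2L, all(prior_mobile > 0))
  k1 <- as.numeric(het_foreign); n1 <- as.numeric(het_total)
  k2 <- as.numeric(homo_foreign); n2 <- as.numeric(homo_total)
  if (any(k1 > n1, na.rm = TRUE) || any(k2 > n2, na.rm = TRUE) ||
      any(c(k1, k2, n1, n2) < 0, na.rm = TRUE)) {
    stop_param("counts must satisfy 0 <= k <= n")
  }
  a0 <- prior_error[1]; b0 <- prior_error[2]
  a1 <- prior_mobile[1]; b1 <- prior_mobile[2]
  lm1 <- lbeta(a1 + k1, b1 + n1 - k1) - lbeta(a1, b1) +
    lbeta(a0 + k2, b0 + n2 - k2) - lbeta(a0, b0)
  lm0 <- lbeta(a0 + k1 + k2, b0 + n1 + n2 - k1 - k2) - lbeta(a0, b0)
  out <- (lm1 - lm0) / log(10)
  out[n1 == 0] <- NA_real_
  out
}

#' Select informative SNP sites by Bayes factor
#'
#' Sites pass only with log10 BF strictly greater than `threshold`
#' (default 1); everything else is removed from all downstream counting.
#'
#' @param bf Data.frame with a `log10_bf` column plus site keys, or a bare
#'   numeric vector of log10 Bayes factors.
#' @param threshold Strict lower bound (default 1.0).
#' @return Same shape as the input, restricted to passing sites (rows or
#'   elements); `NA` Bayes factors never pass.
#' @export
informative_sites <- function(bf, threshold = 1.0) {
  if (is.data.frame(bf)) {
    stopifnot("log10_bf" %in% names(bf))
    keep <- !is.na(bf$log10_bf) & bf$log10_bf > threshold
    out <- bf[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  bf[!is.na(bf) & bf > threshold]
}
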