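# Transcript-level mobile calling, abundance, condition classification and
# the set-level comparisons (PHR dependence, overlap tests).

#' Mobile-transcript detection rule
#'
#' A transcript is detected (in one condition and direction) when strictly
#' more than `min_reads` foreign SNP reads are seen in at least
#' `min_replicates` biological replicates. With the defaults that is
#' "> 3 reads in >= 2 replicates".
#'
#' @param replicate_counts Numeric vector of per-replicate foreign-SNP-read
#'   counts over the transcript's informative sites.
#' @param min_reads Strict lower bound on reads per replicate (default 3).
#' @param min_replicates Minimum number of qualifying replicates (default 2).
#' @return Logical scalar.
#' @export
call_mobile <- function(replicate_counts, min_reads = 3L,
                        min_replicates = 2L) {
  if (length(replicate_counts) < 1L) {
    stop_param("at least one replicate count is required")
  }
  if (any(is.na(replicate_counts)) || any(replicate_counts < 0)) {
    stop_param("replicate counts must be non-negative")
  }
  sum(replicate_counts > min_reads) >= min_replicates
}

#' Library-normalized mobile abundance
#'
#' Foreign SNP-read counts scaled per million SNP-covering reads of the same
#' sample, averaged over replicates.
#'
#' @param counts Per-replicate foreign-read counts.
#' @param library_sizes Per-replicate totals of SNP-covering reads
#'   (recycled if scalar).
#' @return Mean normalized abundance (reads per million SNP-covering reads).
#' @export
mobile_abundance <- function(counts, library_sizes) {
  if (any(library_sizes <= 0)) stop_param("library sizes must be positive")
  mean(counts / library_sizes * 1e6)
}

#' Mobile index
#'
#' Ratio of the mean mobile abundance in the recipient tissue to the mean
#' local abundance of the same transcript in the donor tissue; a
#' dimensionless transfer efficiency.
#'
#' @param recipient_mobile Mean normalized mobile abundance (recipient).
#' @param donor_local Mean normalized local abundance (donor); must be > 0.
#' @return The ratio, or `NA` (with a warning) when the donor mean is zero.
#' @export
mobile_index <- function(recipient_mobile, donor_local) {
  out <- recipient_mobile / donor_local
  bad <- donor_local == 0
  if (any(bad)) {
    warning("mobile index undefined where donor abundance is zero",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Classify a transcript's condition specificity
#'
#' Partition by the set of conditions a transcript was detected in:
#' `PSI-specific` (detected only under Pi starvation: >= 1 of NP3D/NP7D,
#' none of FP7D/NP7DRP2D), `PSD-specific` (the converse), `common`
#' (>= 1 condition in each group), otherwise `other`.
#'
#' @param detected_conditions Character vector (subset of
#'   [pi_conditions()]).
#' @return One of "PSI-specific", "PSD-specific", "common", "other".
#' @export
classify_condition_specificity <- function(detected_conditions) {
  bad <- setdiff(detected_conditions, PI_CONDITIONS)
  if (length(bad)) {
    stop_param("unknown condition(s): ", paste(bad, collapse = ", "))
  }
  minus <- any(detected_conditions %in% MINUS_PI)
  plus <- any(detected_conditions %in% PLUS_PI)
  if (minus && !plus) return("PSI-specific")
  if (plus && !minus) return("PSD-specific")
  if (plus && minus) return("common")
  "other"
}

#' PHR dependence of mobile transcripts
#'
#' Compares mobile calls between a wild-type heterograft and the
#' PSR-signaling mutant heterograft: transcripts mobile in the wild type
#' but not the mutant are PHR-dependent.
#'
#' @param wildtype_calls,mutant_calls Character vectors of transcript ids.
#' @return List: `dependent` (wild type minus mutant), `retained_fraction`
#'   (|intersection| / |wild type|).
#' @export
phr_dependence <- function(wildtype_calls, mutant_calls) {
  wildtype_calls <- unique(wildtype_calls)
  mutant_calls <- unique(mutant_calls)
  if (!length(wildtype_calls)) {
    stop_param("retained fraction undefined for an empty wild-type set")
  }
  list(
    dependent = sort(setdiff(wildtype_calls, mutant_calls)),
    retained_fraction =
      length(intersect(wildtype_calls, mutant_calls)) /
      length(wildtype_calls)
  )
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= observed overlap) when |B| draws are taken without replacement
#' from a universe containing |A| "successes".
#'
#' @param set_a,set_b Character vectors of ids; must be subsets of
#'   `universe`.
#' @param universe Character vector of all ids.
#' @return List: `overlap`, `p_value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop_param("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1L, length(set_a),
                     length(universe) - length(set_a), length(set_b),
                     lower.tail = FALSE)
  list(overlap = k, p_value = p)
}

# Pool replicate counts of a site table by a grouping key.
pool_counts <- function(tab, by) {
  agg <- stats::aggregate(tab[, c("n_foreign", "n_total")],
                          by = tab[, by, drop = FALSE], FUN = sum)
  agg
}

#' Run the full mobile-transcript identification pipeline
#'
#' From heterograft and homograft allele counts over reference SNPs to a
#' per-transcript, per-direction mobile-call table:
#'
#' 1. Pool heterograft replicates per condition x tissue x site and pool
#'    the matched homograft (same self genotype, condition, tissue).
#' 2. Gate sites with the beta-binomial Bayes factor (strictly
#'    `> bf_threshold`) against the homograft error evidence.
#' 3. Count per-replicate foreign reads per transcript over informative
#'    sites and apply the "> `min_reads` reads in >= `min_replicates`
#'    replicates" rule.
#' 4. Compute mobile abundance (per million SNP-covering reads) and the
#'    mobile index against the donor tissue's local abundance, then
#'    classify condition specificity.
#'
#' @param het_counts,homo_counts Outputs of [site_allele_counts()] for the
#'   heterograft and homograft samples.
#' @param bf_threshold Bayes-factor gate (log10 scale, strict; default 1).
#' @param min_reads,min_replicates Detection rule (see [call_mobile()]).
#' @param prior_error,prior_mobile Beta priors for the Bayes factor.
#' @return List of class `mobile_call_set`: `calls` (transcript_id,
#'   direction, detected_conditions, category, mean MI), `per_condition`
#'   (long table with per-condition detection, mobile abundance and MI),
#'   `evidence` (per-replicate foreign counts), `bf_sites` (site-level
#'   Bayes factors) and `n_informative_sites`.
#' @export
identify_mobile_transcripts <- function(het_counts, homo_counts,
                                        bf_threshold = 1.0,
                                        min_reads = 3L, min_replicates = 2L,
                                        prior_error = c(1, 1),
                                        prior_mobile = c(1, 1)) {
  if (!nrow(het_counts)) stop_param("no heterograft observations")
  if (!nrow(homo_counts)) stop_param("no homograft observations")

  het_pool <- pool_counts(het_counts,
                          c("condition", "tissue", "self_genotype",
                            "contig", "pos", "transcript_id"))
  homo_pool <- pool_counts(homo_counts,
                           c("condition", "tissue", "self_genotype",
                             "contig", "pos"))

  key <- function(d) paste(d$condition, d$tissue, d$self_genotype,
                           d$contig, d$pos)
  hit <- match(key(het_pool), key(homo_pool))
  het_pool$homo_foreign <- homo_pool$n_foreign[hit]
  het_pool$homo_total <- homo_pool$n_total[hit]
  # Sites without a matched homograft observation carry no error evidence;
  # treat as 0/0 (the gate then relies on the prior alone).
  het_pool$homo_foreign[is.na(het_pool$homo_foreign)] <- 0
  het_pool$homo_total[is.na(het_pool$homo_total)] <- 0

  het_pool$log10_bf <- log10_bayes_factor(
    het_pool$n_foreign, het_pool$n_total,
    het_pool$homo_foreign, het_pool$homo_total,
    prior_error = prior_error, prior_mobile = prior_mobile
  )
  informative <- informative_sites(het_pool, threshold = bf_threshold)

  # Per-sample library size: total SNP-covering reads over all reference
  # sites in that sample replicate.
  lib <- stats::aggregate(
    n_total ~ sample_id, data = het_counts, FUN = sum)
  lib_size <- stats::setNames(lib$n_total, lib$sample_id)

  info_key <- paste(informative$condition, informative$tissue,
                    informative$contig, informative$pos)
  het_inf <- het_counts[paste(het_counts$condition, het_counts$tissue,
                              het_counts$contig, het_counts$pos) %in%
                          info_key, , drop = FALSE]

  empty_calls <- data.frame(
    transcript_id = character(), direction = character(),
    detected_conditions = character(), category = character(),
    mean_mobile_index = numeric(), stringsAsFactors = FALSE
  )
  if (!nrow(het_inf)) {
    return(structure(list(calls = empty_calls,
                          per_condition = NULL,
                          evidence = NULL, bf_sites = het_pool,
                          n_informative_sites = 0L),
                     class = "mobile_call_set"))
  }

  # Per-replicate foreign counts per transcript x condition x tissue.
  evidence <- stats::aggregate(
    cbind(n_foreign, n_local, n_total) ~
      transcript_id + condition + tissue + sample_id + replicate,
    data = het_inf, FUN = sum)
  evidence$direction <- ifelse(evidence$tissue == "root",
                               "shoot_to_root", "root_to_shoot")
  evidence$library_size <- lib_size[evidence$sample_id]

  # Donor-side local abundance, restricted to the *recipient* tissue's
  # informative sites so numerator and denominator of the mobile index
  # count the same site set. The donor of a shoot_to_root call is the
  # shoot sample of the same condition.
  donor_abundance <- function(tx, cond, recipient_tissue) {
    donor_tissue <- if (recipient_tissue == "root") "shoot" else "root"
    sites <- informative[informative$condition == cond &
                           informative$tissue == recipient_tissue, ]
    rows <- het_counts[het_counts$condition == cond &
                         het_counts$tissue == donor_tissue &
                         het_counts$transcript_id == tx &
                         paste(het_counts$contig, het_counts$pos) %in%
                           paste(sites$contig, sites$pos), , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    by_rep <- tapply(rows$n_local, rows$sample_id, sum)
    mean(by_rep / lib_size[names(by_rep)] * 1e6)
  }

  split_key <- paste(evidence$transcript_id, evidence$condition,
                     evidence$direction)
  groups <- split(evidence, split_key)
  per_condition <- do.call(rbind, lapply(groups, function(g) {
    detected <- call_mobile(g$n_foreign, min_reads = min_reads,
                            min_replicates = min_replicates)
    abundance <- mobile_abundance(g$n_foreign, g$library_size)
    dl <- donor_abundance(g$transcript_id[1], g$condition[1], g$tissue[1])
    mi <- if (length(dl) == 1L && !is.na(dl) && dl > 0) {
      abundance / dl
    } else NA_real_
    data.frame(transcript_id = g$transcript_id[1],
               condition = g$condition[1], direction = g$direction[1],
               detected = detected, mobile_abundance = abundance,
               mobile_index = mi, stringsAsFactors = FALSE)
  }))
  rownames(per_condition) <- NULL

  det <- per_condition[per_condition$detected, , drop = FALSE]
  calls <- if (nrow(det)) {
    do.call(rbind, lapply(
      split(det, paste(det$transcript_id, det$direction)),
      function(g) {
        conds <- sort(unique(g$condition))
        data.frame(
          transcript_id = g$transcript_id[1], direction = g$direction[1],
          detected_conditions = paste(conds, collapse = ","),
          category = classify_condition_specificity(conds),
          mean_mobile_index = mean(g$mobile_index, na.rm = TRUE),
          stringsAsFactors = FALSE
        )
      }))
  } else empty_calls
  rownames(calls) <- NULL
  calls <- calls[order(calls$direction, calls$transcript_id), ,
                 drop = FALSE]

  structure(list(calls = calls, per_condition = per_condition,
                 evidence = evidence, bf_sites = het_pool,
                 n_informative_sites = nrow(informative)),
            class = "mobile_call_set")
}

#' @export
print.mobile_call_set <- function(x, ...) {
  cat("<mobile_call_set>\n")
  cat("  informative sites:", x$n_informative_sites, "\n")
  cat("  mobile transcript x direction calls:", nrow(x$calls), "\n")
  if (nrow(x$calls)) {
    print(table(direction = x$calls$direction,
                category = x$calls$category))
  }
  invisible(x)
}
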