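# Simulated sequencing experiments over a synthetic_truth object.
# Observations are emitted as per-site base-count tables (not FASTQ):
# every downstream rule consumes SNP-covering read counts, so per-site
# counts are loss-free for the analysis.

#' Standard graft design for an accession pair
#'
#' One heterograft (rootstock = first accession, scion = second) and the two
#' matching homografts, each sampled in both tissues under all four Pi
#' conditions. This mirrors a reciprocal hypocotyl-grafting layout with
#' homograft controls.
#'
#' @param accessions Length-2 character vector of accession names.
#' @param conditions Conditions to include (default all four).
#' @param heterograft_only If TRUE, omit homograft rows.
#' @return data.frame with columns scion, rootstock, condition, tissue.
#' @export
standard_graft_design <- function(accessions = c("A", "B"),
                                  conditions = pi_conditions(),
                                  heterograft_only = FALSE) {
  stopifnot(length(accessions) == 2L)
  check_flag(heterograft_only, "heterograft_only")
  pairs <- data.frame(
    scion = c(accessions[2], accessions[1], accessions[2]),
    rootstock = c(accessions[1], accessions[1], accessions[2]),
    stringsAsFactors = FALSE
  )
  if (heterograft_only) pairs <- pairs[1, , drop = FALSE]
  design <- merge(
    merge(pairs, data.frame(condition = conditions)),
    data.frame(tissue = c("shoot", "root"))
  )
  design[order(design$scion != design$rootstock, decreasing = TRUE), ,
         drop = FALSE]
}

#' Simulate per-site allele observations for grafted samples
#'
#' For every SNP in the truth object and every design row x replicate, draws
#' a read pileup as base counts (`n_A` .. `n_T`). The tissue's self genotype
#' is the rootstock accession for root samples and the scion accession for
#' shoot samples. In a heterograft, a transcript labelled mobile in the
#' sampled condition and with a direction pointing into the sampled tissue
#' contributes foreign-allele reads at its truth rate; all remaining reads
#' start as the self allele and acquire sequencing errors independently at
#' `error_rate`, substituting uniformly among the three non-self bases (so a
#' third of errors mimic the foreign allele). Homografts receive error reads
#' only.
#'
#' @param truth A `synthetic_truth` object.
#' @param design data.frame with columns scion, rootstock, condition, tissue
#'   (see [standard_graft_design()]).
#' @param depth Mean reads per SNP site (Poisson, scaled by the transcript's
#'   expression multiplier).
#' @param error_rate Per-base sequencing error probability (< 0.05).
#' @param replicates Biological replicates per design row (>= 1).
#' @param seed Integer seed.
#' @return data.frame of class `graft_observations`: one row per
#'   sample x replicate x SNP site with sample metadata, `self_genotype`,
#'   and base counts `n_A`, `n_C`, `n_G`, `n_T`.
#' @export
generate_graft_experiment <- function(truth, design, depth = 50,
                                      error_rate = 0.002, replicates = 3L,
                                      seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.05) {
    stop_param("`error_rate` must be in [0, 0.05)")
  }
  replicates <- check_count(replicates, "replicates", min = 1L)
  req <- c("scion", "rootstock", "condition", "tissue")
  if (!all(req %in% names(design))) {
    stop_param("`design` needs columns ", paste(req, collapse = ", "))
  }
  bad_cond <- setdiff(design$condition, PI_CONDITIONS)
  if (length(bad_cond)) {
    stop_param("unknown condition(s) in design: ",
               paste(bad_cond, collapse = ", "))
  }
  bad_acc <- setdiff(c(design$scion, design$rootstock), truth$accessions)
  if (length(bad_acc)) {
    stop_param("unknown accession(s) in design: ",
               paste(bad_acc, collapse = ", "))
  }

  snp <- truth$snp_table
  if (!nrow(snp)) {
    stop_param("truth object has no SNPs; nothing to observe")
  }
  expr_key <- with(truth$expression_truth,
                   paste(transcript_id, tissue, condition))
  mob_key <- with(truth$mobile_truth, paste(transcript_id, direction,
                                            condition))
  # The two bases that are neither allele at each site (error sinks);
  # independent of which accession is "self".
  other_bases <- t(mapply(function(a, b) setdiff(DNA_BASES, c(a, b)),
                          snp$allele_a, snp$allele_b))

  with_seed(seed, {
    out <- vector("list", nrow(design) * replicates)
    k <- 0L
    for (d in seq_len(nrow(design))) {
      row <- design[d, ]
      self <- if (row$tissue == "root") row$rootstock else row$scion
      donor <- if (row$tissue == "root") row$scion else row$rootstock
      hetero <- row$scion != row$rootstock
      direction <- if (row$tissue == "root") "shoot_to_root" else
        "root_to_shoot"
      self_is_a <- self == truth$accessions[1]
      local_allele <- if (self_is_a) snp$allele_a else snp$allele_b
      foreign_allele <- if (self_is_a) snp$allele_b else snp$allele_a

      expr <- truth$expression_truth$mean_expr[
        match(paste(snp$transcript_id, row$tissue, row$condition), expr_key)]
      expr[is.na(expr)] <- 1
      rate <- truth$mobile_truth$foreign_rate[
        match(paste(snp$transcript_id, direction, row$condition), mob_key)]
      rate[is.na(rate) | !hetero] <- 0

      for (r in seq_len(replicates)) {
        n_total <- stats::rpois(nrow(snp), depth * expr)
        n_foreign_true <- stats::rbinom(nrow(snp), n_total, rate)
        n_self <- n_total - n_foreign_true
        n_err <- stats::rbinom(nrow(snp), n_self, error_rate)
        n_err_foreign <- stats::rbinom(nrow(snp), n_err, 1 / 3)
        n_err_rest <- n_err - n_err_foreign
        # Split remaining errors between the two bases that are neither
        # allele of this site.
        n_err_b1 <- stats::rbinom(nrow(snp), n_err_rest, 0.5)
        n_err_b2 <- n_err_rest - n_err_b1

        counts <- matrix(0L, nrow(snp), 4L,
                         dimnames = list(NULL, DNA_BASES))
        idx <- seq_len(nrow(snp))
        other <- other_bases
        counts[cbind(idx, match(local_allele, DNA_BASES))] <-
          n_self - n_err
        counts[cbind(idx, match(foreign_allele, DNA_BASES))] <-
          n_foreign_true + n_err_foreign
        counts[cbind(idx, match(other[, 1], DNA_BASES))] <-
          counts[cbind(idx, match(other[, 1], DNA_BASES))] + n_err_b1
        counts[cbind(idx, match(other[, 2], DNA_BASES))] <-
          counts[cbind(idx, match(other[, 2], DNA_BASES))] + n_err_b2

        k <- k + 1L
        out[[k]] <- data.frame(
          sample_id = sprintf("r%s_s%s.%s.%s.rep%d", row$rootstock,
                              row$scion, row$condition, row$tissue, r),
          scion = row$scion, rootstock = row$rootstock,
          condition = row$condition, tissue = row$tissue,
          replicate = r, self_genotype = self, donor_genotype = donor,
          heterograft = hetero,
          contig = snp$contig, pos = snp$pos,
          transcript_id = snp$transcript_id,
          n_A = counts[, "A"], n_C = counts[, "C"],
          n_G = counts[, "G"], n_T = counts[, "T"],
          stringsAsFactors = FALSE
        )
      }
    }
    obs <- do.call(rbind, out)
    rownames(obs) <- NULL
    class(obs) <- c("graft_observations", class(obs))
    obs
  })
}

#' Simulate a TRAP-seq experiment by thinning input observations
#'
#' Models ribosome affinity purification as binomial thinning of an input
#' (total RNA) observation table at `capture_efficiency`. Foreign-allele
#' reads of mobile transcripts whose truth label says they are *not*
#' translated in the recipient tissue are removed entirely from the IP
#' (they never co-purify with ribosomes); all other reads are thinned
#' independently.
#'
#' @param truth A `synthetic_truth` object.
#' @param input_obs A `graft_observations` table (the TRAP input fraction).
#' @param capture_efficiency IP capture probability in (0, 1].
#' @param seed Integer seed.
#' @return A `graft_observations` table of IP counts, same shape as
#'   `input_obs`.
#' @export
generate_trap_experiment <- function(truth, input_obs,
                                     capture_efficiency = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_prob(capture_efficiency, "capture_efficiency",
             lower = 0, lower_open = TRUE, upper = 1)

  snp_key <- with(truth$snp_table, paste(contig, pos))
  allele_a <- truth$snp_table$allele_a[match(
    paste(input_obs$contig, input_obs$pos), snp_key)]
  allele_b <- truth$snp_table$allele_b[match(
    paste(input_obs$contig, input_obs$pos), snp_key)]
  self_is_a <- input_obs$self_genotype == truth$accessions[1]
  foreign_allele <- ifelse(self_is_a, allele_b, allele_a)

  untranslated <- truth$translated_truth$transcript_id[
    !truth$translated_truth$translated]

  with_seed(seed, {
    ip <- input_obs
    for (base in DNA_BASES) {
      col <- paste0("n_", base)
      thin <- if (capture_efficiency == 1) ip[[col]] else
        stats::rbinom(nrow(ip), ip[[col]], capture_efficiency)
      # Foreign reads of untranslated mobile transcripts are not
      # ribosome-bound in the recipient tissue: zero them in the IP.
      drop <- ip$heterograft & foreign_allele == base &
        ip$transcript_id %in% untranslated
      thin[drop] <- 0L
      ip[[col]] <- thin
    }
    class(ip) <- class(input_obs)
    ip
  })
}

#' Simulate targeted DMS-MaPseq mismatch counts
#'
#' Dimethyl sulfate methylates unpaired adenosines and cytosines; during
#' reverse transcription these sites read out as mismatches. Given a known
#' secondary structure (dot-bracket) the generator draws per-position
#' mismatch counts Binomial(depth, rate), where the rate is `rate_unpaired`
#' at unpaired A/C, `rate_paired` at paired A/C, and `background_rate` at
#' G/U positions (reverse-transcription noise).
#'
#' @param structure Dot-bracket string, same length as `sequence`.
#' @param sequence Nucleotide string (T and U both accepted).
#' @param depth Reads per position.
#' @param rate_unpaired,rate_paired Mismatch probabilities at unpaired vs
#'   paired A/C; `rate_unpaired` must exceed `rate_paired`.
#' @param background_rate Mismatch probability at G/U positions.
#' @param seed Integer seed.
#' @return data.frame: position, base, paired, depth, mismatch.
#' @export
generate_dms_experiment <- function(structure, sequence, depth = 2000L,
                                    rate_unpaired = 0.05,
                                    rate_paired = 0.005,
                                    background_rate = 5e-4, seed = 1L) {
  if (nchar(structure) != nchar(sequence)) {
    stop_param("`structure` and `sequence` must have equal length")
  }
  if (!(rate_unpaired > rate_paired)) {
    stop_param("`rate_unpaired` must exceed `rate_paired`")
  }
  check_prob(rate_unpaired, "rate_unpaired")
  check_prob(rate_paired, "rate_paired")
  depth <- check_count(depth, "depth", min = 1L)
  seq_chars <- strsplit(rna_norm(sequence), "")[[1]]
  struct_chars <- strsplit(structure, "")[[1]]
  bad <- setdiff(unique(struct_chars), c("(", ")", "."))
  if (length(bad)) stop_param("invalid dot-bracket characters: ",
                              paste(bad, collapse = ""))
  paired <- struct_chars != "."
  is_ac <- seq_chars %in% c("A", "C")
  rate <- ifelse(is_ac, ifelse(paired, rate_paired, rate_unpaired),
                 background_rate)
  with_seed(seed, data.frame(
    position = seq_along(seq_chars),
    base = seq_chars,
    paired = paired,
    depth = depth,
    mismatch = stats::rbinom(length(seq_chars), depth, rate)
  ))
}

#' Synthesize annotated variant records from a truth object
#'
#' Emits one candidate SNP record per truth SNP with clean quality
#' annotations, consistent per-dataset genotype alleles and ample DNA/RNA
#' depths, so the reference-SNP builder can recover the truth set exactly.
#' With `decoys = TRUE` it appends records that each violate exactly one
#' filter (bad QD, shallow RNA depth, inconsistent genotype, organelle
#' contig), for audit-log testing.
#'
#' @param truth A `synthetic_truth` object.
#' @param seed Integer seed.
#' @param decoys Add known-bad records?
#' @param depth Depth used for the clean records.
#' @return data.frame of candidate SNP records (see
#'   [build_reference_snps()] for the required columns).
#' @export
simulate_variant_calls <- function(truth, seed = 1L, decoys = FALSE,
                                   depth = 30L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_flag(decoys, "decoys")
  snp <- truth$snp_table
  with_seed(seed, {
    clean <- data.frame(
      contig = snp$contig, pos = snp$pos,
      ref_allele = snp$allele_a, alt_allele = snp$allele_b,
      transcript_id = snp$transcript_id,
      QD = stats::runif(nrow(snp), 15, 35),
      MQ = stats::runif(nrow(snp), 55, 60),
      FS = stats::runif(nrow(snp), 0, 5),
      SOR = stats::runif(nrow(snp), 0.3, 1.5),
      DP = stats::rpois(nrow(snp), depth) + 10L,
      allele_a_dna = snp$allele_a, allele_a_rna = snp$allele_a,
      allele_b_dna = snp$allele_b, allele_b_rna = snp$allele_b,
      dna_depth_a = stats::rpois(nrow(snp), depth) + 10L,
      rna_depth_a = stats::rpois(nrow(snp), depth) + 10L,
      dna_depth_b = stats::rpois(nrow(snp), depth) + 10L,
      rna_depth_b = stats::rpois(nrow(snp), depth) + 10L,
      stringsAsFactors = FALSE
    )
    if (!decoys || !nrow(clean)) return(clean)

    decoy_at <- function(pos_offset, mutate) {
      rec <- clean[1, ]
      rec$pos <- max(clean$pos) + pos_offset
      mutate(rec)
    }
    bad <- rbind(
      decoy_at(101L, function(r) { r$QD <- 1.0; r }),
      decoy_at(102L, function(r) { r$rna_depth_b <- 4L; r }),
      decoy_at(103L, function(r) { r$allele_a_rna <- r$alt_allele; r }),
      decoy_at(104L, function(r) { r$contig <- "ChrM"; r })
    )
    bad$transcript_id <- NA_character_
    rbind(clean, bad)
  })
}
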