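# Targeted DMS-MaPseq reactivity profiling. DMS methylates unpaired A and C
# bases; mismatches introduced during reverse transcription read out the
# modification, so reactivity = mismatch / depth at A/C positions. The
# module follows the processing order: per-replicate profiles -> QC ->
# averaging -> normalization (median of the top 5%) -> winsorization at 1.0.

#' Per-position mismatch/depth profile from aligned reads
#'
#' Reads are given as alignments to the amplicon: a 1-based start plus an
#' aligned sequence in which `-` marks a deleted reference base (an indel).
#' Depth counts every read covering a position (deletions included);
#' mismatches within `indel_mask_nt` nucleotides of any indel in the same
#' read are discarded (their depth still counts), since
#' reverse-transcription artifacts cluster around indels.
#'
#' @param reads data.frame with columns `start` (1-based) and `seq`
#'   (aligned bases over A/C/G/T/-, same length as the covered reference
#'   window).
#' @param amplicon_ref Reference sequence of the amplicon.
#' @param indel_mask_nt Mask half-width around indels (default 3).
#' @return data.frame of class `dms_profile`: position, base (reference),
#'   depth, mismatch.
#' @export
mutation_profile <- function(reads, amplicon_ref, indel_mask_nt = 3L) {
  indel_mask_nt <- check_count(indel_mask_nt, "indel_mask_nt")
  check_nt(amplicon_ref, "amplicon_ref")
  ref <- strsplit(dna_norm(amplicon_ref), "")[[1]]
  n <- length(ref)
  depth <- integer(n)
  mismatch <- integer(n)
  for (i in seq_len(nrow(reads))) {
    start <- reads$start[i]
    bases <- strsplit(toupper(reads$seq[i]), "")[[1]]
    bases[bases == "U"] <- "T"
    end <- start + length(bases) - 1L
    if (start < 1L || end > n) {
      stop_param("read ", i, " extends beyond the amplicon")
    }
    pos <- seq.int(start, end)
    depth[pos] <- depth[pos] + 1L
    indel_pos <- pos[bases == "-"]
    mm <- pos[bases != "-" & bases != ref[pos]]
    if (length(indel_pos) && length(mm)) {
      near <- vapply(mm, function(p) any(abs(p - indel_pos) <=
                                           indel_mask_nt), logical(1))
      mm <- mm[!near]
    }
    mismatch[mm] <- mismatch[mm] + 1L
  }
  structure(data.frame(position = seq_len(n), base = ref,
                       depth = depth, mismatch = mismatch,
                       stringsAsFactors = FALSE),
            class = c("dms_profile", "data.frame"))
}

#' Raw DMS reactivity
#'
#' mismatch / depth at A and C positions; other bases and positions below
#' `min_depth` get `NA` (no data).
#'
#' @param profile data.frame with position, base, depth, mismatch (see
#'   [mutation_profile()] or [generate_dms_experiment()]).
#' @param min_depth Minimum per-position depth (default 500, appropriate
#'   for targeted amplicons).
#' @return Numeric vector of raw rates, one per position, `NA` where
#'   undefined.
#' @export
raw_reactivity <- function(profile, min_depth = 500L) {
  stopifnot(all(c("base", "depth", "mismatch") %in% names(profile)))
  if (any(profile$mismatch > profile$depth)) {
    stop_param("mismatch counts exceed depth")
  }
  rate <- ifelse(toupper(profile$base) %in% c("A", "C") &
                   profile$depth >= min_depth,
                 profile$mismatch / profile$depth, NA_real_)
  rate
}

#' Replicate quality control
#'
#' Flags the PCR-bias pathology where a few A/C positions show dramatically
#' high mutation rates while almost all others are essentially silent
#' (< `low_rate`): a replicate fails when the fraction of A/C rates below
#' `low_rate` exceeds `low_frac` *and* the maximum rate reaches
#' `high_rate`. An all-zero profile fails as degenerate.
#'
#' @param rates Raw reactivities (output of [raw_reactivity()]); `NA`s are
#'   ignored.
#' @param low_rate Rate below which a position counts as silent (default
#'   0.005).
#' @param low_frac Silent-fraction threshold (default 0.90).
#' @param high_rate Spike threshold (default 0.05).
#' @return TRUE (pass) or FALSE (fail).
#' @export
replicate_qc <- function(rates, low_rate = 0.005, low_frac = 0.90,
                         high_rate = 0.05) {
  rates <- rates[!is.na(rates)]
  if (!length(rates) || all(rates == 0)) return(FALSE)
  frac_low <- mean(rates < low_rate)
  !(frac_low > low_frac && max(rates) >= high_rate)
}

#' Average reactivity profiles across passing replicates
#'
#' Position-wise arithmetic mean of raw reactivities; positions with data
#' in only some replicates use the available replicates (the count is
#' returned alongside).
#'
#' @param profiles List of equal-length raw-reactivity vectors.
#' @return List: `mean` (vector), `n_obs` (replicates contributing per
#'   position).
#' @export
average_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  lens <- vapply(profiles, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop_param("replicate profiles must have equal length")
  }
  m <- do.call(cbind, profiles)
  n_obs <- rowSums(!is.na(m))
  mean_rate <- rowMeans(m, na.rm = TRUE)
  mean_rate[n_obs == 0L] <- NA_real_
  list(mean = mean_rate, n_obs = n_obs)
}

#' Normalize DMS reactivities
#'
#' Divides all raw reactivities by the median of the highest 5% of rates
#' (ceiling(0.05 n) positions; the median of an even subset is the midpoint
#' mean) and winsorizes values above 1.0 down to 1.0.
#'
#' @param raw_rates Raw (or replicate-averaged) reactivities; `NA`s pass
#'   through.
#' @return Normalized reactivities in [0, 1].
#' @export
normalize_reactivity <- function(raw_rates) {
  obs <- raw_rates[!is.na(raw_rates)]
  if (!length(obs) || all(obs == 0)) {
    stop_param("cannot normalize: no positive reactivity (normalizer 0)")
  }
  k <- ceiling(0.05 * length(obs))
  top <- sort(obs, decreasing = TRUE)[seq_len(k)]
  normalizer <- stats::median(top)
  pmin(raw_rates / normalizer, 1.0)
}

#' Export SHAPE-style folding constraints
#'
#' Two columns (position, reactivity), with -999 at non-A/C positions and
#' positions without data, the convention structure-modelling tools expect.
#'
#' @param normalized Normalized reactivities (one per position).
#' @param bases Reference base per position.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
export_constraints <- function(normalized, bases, path) {
  stopifnot(length(normalized) == length(bases))
  value <- ifelse(toupper(bases) %in% c("A", "C") & !is.na(normalized),
                  normalized, -999)
  utils::write.table(
    data.frame(position = seq_along(value), reactivity = value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SHAPE-style constraint file
#'
#' @param path File written by [export_constraints()].
#' @return data.frame: position, reactivity.
#' @export
read_constraints <- function(path) {
  utils::read.table(path, sep = "\t",
                    col.names = c("position", "reactivity"))
}

#' Agreement between reactivity and a reference structure (AUC)
#'
#' Area under the ROC curve for normalized reactivity separating unpaired
#' from paired A/C positions of a reference structure; 1.0 means perfect
#' separation, 0.5 chance.
#'
#' @param normalized Normalized reactivities (one per position).
#' @param structure Reference dot-bracket string.
#' @param bases Reference base per position.
#' @return AUC in [0, 1].
#' @export
structure_agreement <- function(normalized, structure, bases) {
  if (nchar(structure) != length(normalized) ||
      length(bases) != length(normalized)) {
    stop_param("profile, structure and bases must have equal length")
  }
  paired <- strsplit(structure, "")[[1]] != "."
  use <- toupper(bases) %in% c("A", "C") & !is.na(normalized)
  x <- normalized[use & !paired]  # unpaired = positives
  y <- normalized[use & paired]
  if (!length(x) || !length(y)) {
    stop_param("need both paired and unpaired A/C positions with data")
  }
  # Mann-Whitney AUC with tie correction.
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}
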