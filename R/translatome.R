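# TRAP-seq translatome analysis of mobile transcripts: which mobile mRNAs
# co-purify with tagged ribosomes in the recipient tissue, and how
# efficiently they are translated.

#' Partition mobile transcripts into translated and untranslated
#'
#' A mobile transcript counts as translated in the recipient tissue when it
#' is also detected in the TRAP-seq (IP) data processed with the same
#' informative-site and detection thresholds as the RNA-seq; otherwise it is
#' untranslated. `trap_detected` may be a precomputed id set or a
#' `mobile_call_set` from running [identify_mobile_transcripts()] on TRAP
#' counts.
#'
#' @param mobile_ids Character vector of mobile transcript ids (RNA-seq).
#' @param trap_detected Character vector of TRAP-detected ids, or a
#'   `mobile_call_set`.
#' @return List: `translated`, `untranslated` (a disjoint, exhaustive
#'   partition of `mobile_ids`).
#' @export
call_translated_mobile <- function(mobile_ids, trap_detected) {
  if (inherits(trap_detected, "mobile_call_set")) {
    trap_detected <- trap_detected$calls$transcript_id
  }
  mobile_ids <- unique(mobile_ids)
  list(
    translated = sort(intersect(mobile_ids, trap_detected)),
    untranslated = sort(setdiff(mobile_ids, trap_detected))
  )
}

#' Translational efficiency
#'
#' TE = normalized TRAP-seq abundance / normalized RNA-seq abundance, on
#' identically normalized (per-million) scales.
#'
#' @param trap_abundance,rna_abundance Numeric vectors.
#' @return TE; `NA` (with a warning) where `rna_abundance` is zero.
#' @export
translational_efficiency <- function(trap_abundance, rna_abundance) {
  if (any(trap_abundance < 0) || any(rna_abundance < 0)) {
    stop_param("abundances must be non-negative")
  }
  out <- trap_abundance / rna_abundance
  bad <- rna_abundance == 0
  if (any(bad)) {
    warning("TE undefined where RNA abundance is zero", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Log2 contrast of translational efficiencies
#'
#' Positive values mean a higher TE under the treatment.
#'
#' @param te_treatment,te_control Numeric vectors of TEs.
#' @return log2(te_treatment / te_control); `NA` where the control TE is 0.
#' @export
te_contrast <- function(te_treatment, te_control) {
  out <- log2(te_treatment / te_control)
  bad <- te_control == 0
  if (any(bad, na.rm = TRUE)) {
    warning("TE contrast undefined where the control TE is zero",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}
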