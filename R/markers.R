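# In-silico CAPS/dCAPS genotyping: virtual PCR from primer pairs, virtual
# restriction digestion, and matching the fragment pattern against the
# expected per-genotype patterns. Used to verify which accession a grafted
# tissue sample belongs to.

# Built-in enzymes as (recognition sequence, cut offset) pairs: the cut
# falls after `cut_offset` bases of the recognition site, on both strands
# for palindromic sites.
RESTRICTION_ENZYMES <- list(
  RsaI = list(recognition = "GTAC", cut_offset = 2L),
  BamHI = list(recognition = "GGATCC", cut_offset = 1L)
)

#' Built-in restriction enzymes
#'
#' @return Named list of (recognition, cut_offset) pairs; `RsaI` (GT^AC)
#'   and `BamHI` (G^GATCC) are shipped.
#' @export
restriction_enzymes <- function() RESTRICTION_ENZYMES

# All start positions where `pattern` matches `subject` with at most
# `max_mismatch` mismatches. Returns a data.frame(start, mismatches).
approx_matches <- function(subject, pattern, max_mismatch,
                           require_3prime = TRUE) {
  sub_chars <- strsplit(subject, "")[[1]]
  pat_chars <- strsplit(pattern, "")[[1]]
  m <- length(pat_chars)
  n <- length(sub_chars)
  if (m > n) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  starts <- seq_len(n - m + 1L)
  mm <- vapply(starts, function(s) {
    sum(sub_chars[s:(s + m - 1L)] != pat_chars)
  }, integer(1))
  ok <- mm <= max_mismatch
  if (require_3prime) {
    # A primer whose 3'-terminal base mismatches does not prime.
    ok <- ok & vapply(starts, function(s) {
      sub_chars[s + m - 1L] == pat_chars[m]
    }, logical(1))
  }
  data.frame(start = starts[ok], mismatches = mm[ok])
}

#' In-silico PCR
#'
#' Finds the unique amplicon delimited by the forward primer on the plus
#' strand and the reverse complement of the reverse primer downstream of
#' it. Primers anneal with at most `max_mismatch` mismatches, but a
#' 3'-terminal mismatch abolishes priming (the standard dCAPS convention).
#' Ambiguity (no hit, or several equally good amplicons) is an error that
#' lists the candidates.
#'
#' @param template Template sequence (DNA).
#' @param fwd,rev Primer sequences, 5' to 3', each >= 15 nt.
#' @param max_mismatch Mismatch tolerance per primer (default 1).
#' @return List of class `amplicon`: `sequence`, `start`, `end` (1-based
#'   closed, template coordinates), `length`.
#' @export
insilico_pcr <- function(template, fwd, rev, max_mismatch = 1L) {
  max_mismatch <- check_count(max_mismatch, "max_mismatch")
  template <- dna_norm(template)
  fwd <- dna_norm(fwd)
  rev <- dna_norm(rev)
  check_nt(template, "template", alphabet = DNA_BASES)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    stop_param("primers must be at least 15 nt")
  }

  fwd_hits <- approx_matches(template, fwd, max_mismatch)
  rev_rc <- revcomp(rev)
  rev_hits <- approx_matches_revcomp(template, rev_rc, max_mismatch)

  if (!nrow(fwd_hits) || !nrow(rev_hits)) {
    stop_param("no amplicon: ", nrow(fwd_hits), " forward and ",
               nrow(rev_hits), " reverse primer site(s) found")
  }
  # Candidate amplicons: every fwd site paired with every rev site that
  # ends downstream of it.
  cand <- merge(fwd_hits, rev_hits, by = NULL,
                suffixes = c("_fwd", "_rev"))
  cand <- cand[cand$start_rev > cand$start_fwd + nchar(fwd) - 1L, ,
               drop = FALSE]
  if (!nrow(cand)) {
    stop_param("no amplicon: reverse primer site lies upstream of the ",
               "forward primer site")
  }
  cand$total_mm <- cand$mismatches_fwd + cand$mismatches_rev
  best <- cand[cand$total_mm == min(cand$total_mm), , drop = FALSE]
  if (nrow(best) > 1L) {
    stop_param("ambiguous PCR: ", nrow(best),
               " equally good amplicons (starts ",
               paste(best$start_fwd, collapse = ", "), ")")
  }
  start <- best$start_fwd
  end <- best$start_rev + nchar(rev) - 1L
  structure(list(sequence = substring(template, start, end),
                 start = start, end = end, length = end - start + 1L),
            class = "amplicon")
}

# Reverse-primer matching: the primer binds the minus strand, so its
# reverse complement must match the plus strand, and the primer's 3' end
# corresponds to the *first* base of that plus-strand match.
approx_matches_revcomp <- function(subject, pattern_rc, max_mismatch) {
  sub_chars <- strsplit(subject, "")[[1]]
  pat_chars <- strsplit(pattern_rc, "")[[1]]
  m <- length(pat_chars)
  n <- length(sub_chars)
  if (m > n) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  starts <- seq_len(n - m + 1L)
  mm <- vapply(starts, function(s) {
    sum(sub_chars[s:(s + m - 1L)] != pat_chars)
  }, integer(1))
  ok <- mm <= max_mismatch &
    vapply(starts, function(s) sub_chars[s] == pat_chars[1L], logical(1))
  data.frame(start = starts[ok], mismatches = mm[ok])
}

#' Virtual restriction digest
#'
#' Cuts after `cut_offset` bases of every occurrence of the recognition
#' site and returns the ordered fragment lengths. For palindromic sites a
#' plus-strand scan finds both strands' sites. Fragments always sum to the
#' input length.
#'
#' @param seq Sequence to digest.
#' @param recognition Recognition site (e.g. "GTAC"), or the name of a
#'   built-in enzyme (see [restriction_enzymes()]).
#' @param cut_offset Bases 5' of the cut within the site; ignored when
#'   `recognition` names a built-in enzyme.
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @export
restriction_digest <- function(seq, recognition, cut_offset = NULL) {
  seq <- dna_norm(seq)
  check_nt(seq, "seq", alphabet = DNA_BASES)
  if (recognition %in% names(RESTRICTION_ENZYMES)) {
    enz <- RESTRICTION_ENZYMES[[recognition]]
    recognition <- enz$recognition
    cut_offset <- enz$cut_offset
  }
  recognition <- dna_norm(recognition)
  if (is.null(cut_offset)) stop_param("`cut_offset` required")
  cut_offset <- check_count(cut_offset, "cut_offset")
  if (cut_offset > nchar(recognition)) {
    stop_param("`cut_offset` exceeds the recognition site length")
  }
  n <- nchar(seq)
  hits <- gregexpr(recognition, seq, fixed = TRUE)[[1]]
  cuts <- integer()
  if (hits[1] != -1L) cuts <- as.integer(hits) + cut_offset - 1L
  # Non-palindromic sites also occur on the minus strand; the plus-strand
  # image of such a site is its reverse complement, cut symmetrically.
  rc <- revcomp(recognition)
  if (rc != recognition) {
    hits_rc <- gregexpr(rc, seq, fixed = TRUE)[[1]]
    if (hits_rc[1] != -1L) {
      cuts <- c(cuts,
                as.integer(hits_rc) + (nchar(recognition) - cut_offset) - 1L)
    }
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  diff(c(0L, cuts, n))
}

#' Call a genotype from a digest fragment pattern
#'
#' Matches the observed fragment-length multiset against expected
#' per-genotype patterns, allowing `tolerance` bp per fragment. Returns the
#' single matching genotype label, or `"ambiguous"` when zero or several
#' patterns match.
#'
#' @param fragments Observed fragment lengths.
#' @param expected_patterns Named list: genotype -> expected fragment
#'   lengths.
#' @param tolerance Per-fragment length tolerance in bp (default 2).
#' @return Genotype label or `"ambiguous"`.
#' @export
genotype_call <- function(fragments, expected_patterns, tolerance = 2L) {
  tolerance <- check_count(tolerance, "tolerance")
  matches <- vapply(expected_patterns, function(expected) {
    if (length(expected) != length(fragments)) return(FALSE)
    all(abs(sort(fragments) - sort(expected)) <= tolerance)
  }, logical(1))
  if (sum(matches) == 1L) names(expected_patterns)[matches] else "ambiguous"
}
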