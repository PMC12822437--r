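# Region extraction and the distribution-level structure comparisons:
# -dG/nt, GC and length per 5'UTR/CDS/3'UTR, Kolmogorov-Smirnov and
# rank-sum group tests, and the quartile enrichment layout.

#' Extract 5'UTR/CDS/3'UTR sequences in transcript orientation
#'
#' Fetches each annotated region from its contig and reverse-complements
#' minus-strand regions, so all returned sequences read 5' to 3' in the
#' transcript's own orientation.
#'
#' @param annotation data.frame with columns transcript_id, contig, strand,
#'   region (one of `five_prime_utr`, `cds`, `three_prime_utr`), start, end
#'   (1-based closed).
#' @param sequences Named character vector of contig sequences.
#' @param as_rna Return RNA alphabet (T -> U)? Default TRUE.
#' @return Named list (by transcript id) of lists with the available
#'   region sequences; transcripts lacking a region simply omit it.
#' @export
extract_regions <- function(annotation, sequences, as_rna = TRUE) {
  check_flag(as_rna, "as_rna")
  req <- c("transcript_id", "contig", "strand", "region", "start", "end")
  stopifnot(all(req %in% names(annotation)))
  bad <- !(annotation$contig %in% names(sequences))
  if (any(bad)) {
    stop_param("contig(s) absent from `sequences`: ",
               paste(unique(annotation$contig[bad]), collapse = ", "))
  }
  too_far <- annotation$end > nchar(sequences[annotation$contig]) |
    annotation$start < 1L
  if (any(too_far)) stop_param("region outside contig bounds")

  out <- lapply(split(annotation, annotation$transcript_id), function(ann) {
    regs <- lapply(seq_len(nrow(ann)), function(i) {
      s <- substring(sequences[[ann$contig[i]]], ann$start[i], ann$end[i])
      if (ann$strand[i] == "-") s <- revcomp(s)
      if (as_rna) rna_norm(s) else s
    })
    stats::setNames(regs, ann$region)
  })
  out[unique(annotation$transcript_id)]
}

#' Per-region structure statistics
#'
#' Computes dG, -dG/nt, GC fraction and length for each region of each
#' transcript.
#'
#' @param regions Output of [extract_regions()].
#' @param backend Folding backend passed to [mfe_fold()].
#' @return data.frame: transcript_id, region, length, gc, dg,
#'   neg_dg_per_nt.
#' @export
region_structure_stats <- function(regions, backend = "basepair") {
  rows <- lapply(names(regions), function(tx) {
    regs <- regions[[tx]]
    do.call(rbind, lapply(names(regs), function(r) {
      s <- regs[[r]]
      dg <- mfe_fold(s, backend = backend)
      data.frame(transcript_id = tx, region = r, length = nchar(s),
                 gc = gc_content(s), dg = dg,
                 neg_dg_per_nt = neg_dg_per_nt(dg, nchar(s)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two groups of values (KS + rank-sum)
#'
#' Two-sample Kolmogorov-Smirnov statistic D (maximal ECDF separation) with
#' its P-value (exact where feasible) and a two-sided Wilcoxon rank-sum
#' P-value, plus ECDF tables for cumulative-distribution plots.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List of class `group_comparison`: `D`, `ks_p`, `wilcoxon_p`,
#'   `n_a`, `n_b`, `ecdf_a`, `ecdf_b` (data.frames of x and cumulative
#'   fraction).
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop_param("both groups must be non-empty")
  }
  ks <- suppressWarnings(stats::ks.test(values_a, values_b))
  wx <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  ecdf_tab <- function(v) {
    x <- sort(unique(v))
    data.frame(x = x, cum_fraction = stats::ecdf(v)(x))
  }
  structure(list(D = unname(ks$statistic), ks_p = ks$p.value,
                 wilcoxon_p = wx$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 ecdf_a = ecdf_tab(values_a), ecdf_b = ecdf_tab(values_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> n = %d vs %d\n", x$n_a, x$n_b))
  cat(sprintf("  KS D = %.4f, P = %.3g; Wilcoxon P = %.3g\n",
              x$D, x$ks_p, x$wilcoxon_p))
  invisible(x)
}

#' Quartile partition with enrichment of a query set
#'
#' Ranks values ascending (ties broken by id order, so labels are
#' deterministic) and labels the lowest ceiling(n/4) as `bottom25`, the
#' highest ceiling(n/4) as `top25` and the rest as `middle50`. For each
#' stratum an upper-tail hypergeometric enrichment P-value of the query
#' set is reported.
#'
#' @param values Named numeric vector (ids -> value, e.g. -dG/nt of the
#'   5'UTR); needs >= 4 values.
#' @param query_set Character vector of ids to test for enrichment.
#' @return List: `labels` (named character), `enrichment` (data.frame:
#'   stratum, size, n_query, p_value).
#' @export
quartile_partition <- function(values, query_set = character()) {
  n <- length(values)
  if (n < 4L) stop_param("need at least 4 values")
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop_param("`values` must have unique names")
  }
  extra <- setdiff(query_set, names(values))
  if (length(extra)) {
    stop_param("query ids absent from `values`: ",
               paste(utils::head(extra, 5L), collapse = ", "))
  }
  k <- ceiling(n / 4)
  ord <- names(values)[order(values, names(values))]
  labels <- stats::setNames(rep("middle50", n), ord)
  labels[ord[seq_len(k)]] <- "bottom25"
  labels[ord[seq.int(n - k + 1L, n)]] <- "top25"
  labels <- labels[names(values)]

  strata <- c("bottom25", "middle50", "top25")
  enrichment <- do.call(rbind, lapply(strata, function(s) {
    ids <- names(labels)[labels == s]
    hit <- length(intersect(ids, query_set))
    p <- stats::phyper(hit - 1L, length(query_set),
                       n - length(query_set), length(ids),
                       lower.tail = FALSE)
    data.frame(stratum = s, size = length(ids), n_query = hit,
               p_value = p, stringsAsFactors = FALSE)
  }))
  list(labels = labels, enrichment = enrichment)
}
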