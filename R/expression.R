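# Count normalization and the paper-style differential-expression decision
# rule. This is a deliberately simple, self-contained stand-in for a full
# negative-binomial DE framework: median-of-ratios size factors, a Welch
# test on log-scale normalized counts, and the |log2FC| > 1 & P < 0.05
# cutoff. It is adequate for the cutoff semantics this pipeline needs and
# nothing more.

#' Median-of-ratios normalization
#'
#' Size factor per sample = median, over genes with all-positive counts, of
#' the ratio of the sample's count to the gene's geometric mean across
#' samples; normalized counts = counts / size factor.
#'
#' @param counts Non-negative integer matrix, genes x samples (>= 2
#'   samples).
#' @return List: `normalized` (matrix), `size_factors` (named numeric).
#' @export
normalize_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop_param("need at least two samples")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_param("counts must be non-negative integers")
  }
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop_param("no gene has positive counts in every sample; ",
               "size factors are undefined")
  }
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  size_factors <- apply(counts[all_pos, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  list(normalized = sweep(counts, 2L, size_factors, "/"),
       size_factors = size_factors)
}

#' Differential expression with the fold-change/P cutoff rule
#'
#' Per gene: log2 fold-change = log2((mean_B + eps) / (mean_A + eps)) on
#' normalized counts with pseudocount `eps`, and a two-sided Welch test on
#' log2(normalized + 1). Status is `Up` when log2FC > 1 and P < 0.05,
#' `Down` when log2FC < -1 and P < 0.05, else `NS`.
#'
#' @param group_a,group_b Normalized count matrices (genes x replicates)
#'   with matching row order; A is the reference/control group.
#' @param pseudocount Fold-change stabilizer (default 1).
#' @param adjust Apply Benjamini-Hochberg to the P-values before the status
#'   rule? Default FALSE (the cutoff is applied to raw P-values).
#' @return data.frame: gene, log2fc, p_value, status.
#' @export
differential_expression <- function(group_a, group_b, pseudocount = 1,
                                    adjust = FALSE) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) != nrow(group_b)) {
    stop_param("groups must have the same genes")
  }
  check_flag(adjust, "adjust")
  genes <- rownames(group_a) %||% as.character(seq_len(nrow(group_a)))

  mean_a <- rowMeans(group_a); mean_b <- rowMeans(group_b)
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))

  small <- ncol(group_a) < 2L || ncol(group_b) < 2L
  if (small) {
    warning("fewer than two replicates in a group; P-values undefined, ",
            "all genes reported NS", call. = FALSE)
    p <- rep(NA_real_, nrow(group_a))
  } else {
    la <- log2(group_a + 1); lb <- log2(group_b + 1)
    p <- vapply(seq_len(nrow(group_a)), function(i) {
      x <- la[i, ]; y <- lb[i, ]
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      }
      stats::t.test(y, x, var.equal = FALSE)$p.value
    }, numeric(1))
  }
  p_used <- if (adjust) stats::p.adjust(p, "BH") else p

  status <- rep("NS", length(p))
  status[!is.na(p_used) & log2fc > 1 & p_used < 0.05] <- "Up"
  status[!is.na(p_used) & log2fc < -1 & p_used < 0.05] <- "Down"
  data.frame(gene = genes, log2fc = log2fc, p_value = p, status = status,
             stringsAsFactors = FALSE)
}
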