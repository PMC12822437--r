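# Accession-specific reference SNP construction.
#
# Candidate variant records are screened through a fixed ladder:
#   1. hard filter on the caller's annotations (QD, MQ, FS, SOR, DP),
#   2. support filter (>= 10 reads in both DNA- and RNA-seq, both accessions),
#   3. genotype consistency (accession-diagnostic alleles across datasets),
#   4. organelle exclusion (mitochondrial/plastid contigs are editing-prone).
# Each failing record is attributed to its first failing stage so the audit
# log is reproducible.

HARD_FILTER_KEYS <- c("QD", "MQ", "FS", "SOR", "DP")

#' Hard-filter a candidate variant on caller annotations
#'
#' A record fails if any clause holds: QD < 2.0, MQ < 40.0, FS > 60.0,
#' SOR > 3.0, or DP < 10. Missing or non-finite annotations are an error,
#' never a silent pass.
#'
#' @param v A one-row data.frame (or named list) with numeric fields
#'   `QD`, `MQ`, `FS`, `SOR`, `DP`. Vectorized over rows of a data.frame.
#' @return Logical: TRUE when the record passes all clauses.
#' @export
hard_filter_variant <- function(v) {
  miss <- setdiff(HARD_FILTER_KEYS, names(v))
  if (length(miss)) {
    stop_param("missing annotation(s): ", paste(miss, collapse = ", "))
  }
  vals <- lapply(HARD_FILTER_KEYS, function(k) as.numeric(v[[k]]))
  names(vals) <- HARD_FILTER_KEYS
  if (any(!vapply(vals, function(x) all(is.finite(x)), logical(1)))) {
    stop_param("non-finite annotation value(s); refusing to filter silently")
  }
  !(vals$QD < 2.0 | vals$MQ < 40.0 | vals$FS > 60.0 | vals$SOR > 3.0 |
      vals$DP < 10)
}

#' Depth-support filter
#'
#' Requires the site to be covered by at least `min_depth` reads in both the
#' genomic and the RNA-seq data of both accessions.
#'
#' @param v Record(s) with integer fields `dna_depth_a`, `rna_depth_a`,
#'   `dna_depth_b`, `rna_depth_b`.
#' @param min_depth Minimum depth (default 10).
#' @return Logical vector.
#' @export
support_filter <- function(v, min_depth = 10L) {
  min_depth <- check_count(min_depth, "min_depth")
  cols <- c("dna_depth_a", "rna_depth_a", "dna_depth_b", "rna_depth_b")
  miss <- setdiff(cols, names(v))
  if (length(miss)) {
    stop_param("missing depth field(s): ", paste(miss, collapse = ", "))
  }
  d <- vapply(cols, function(k) as.numeric(v[[k]]), numeric(length(v[[cols[1]]])))
  d <- matrix(d, ncol = length(cols))
  if (any(d < 0)) stop_param("negative depth")
  apply(d >= min_depth, 1L, all)
}

#' Genotype-consistency filter
#'
#' Passes only when every dataset of accession A reports the same allele,
#' every dataset of accession B reports the same allele, and the two
#' accession alleles differ (accession-diagnostic site). Heterozygous calls
#' (encoded e.g. "A/G") and IUPAC ambiguity codes fail.
#'
#' @param v Record(s) with fields `allele_a_dna`, `allele_a_rna`,
#'   `allele_b_dna`, `allele_b_rna`.
#' @return Logical vector.
#' @export
genotype_consistency <- function(v) {
  cols <- c("allele_a_dna", "allele_a_rna", "allele_b_dna", "allele_b_rna")
  miss <- setdiff(cols, names(v))
  if (length(miss)) {
    stop_param("missing genotype field(s): ", paste(miss, collapse = ", "))
  }
  a1 <- toupper(as.character(v[["allele_a_dna"]]))
  a2 <- toupper(as.character(v[["allele_a_rna"]]))
  b1 <- toupper(as.character(v[["allele_b_dna"]]))
  b2 <- toupper(as.character(v[["allele_b_rna"]]))
  valid <- function(x) x %in% DNA_BASES
  valid(a1) & valid(a2) & valid(b1) & valid(b2) &
    a1 == a2 & b1 == b2 & a1 != b1
}

#' Build the accession-specific reference SNP set
#'
#' Applies the filter ladder (hard filter, depth support, genotype
#' consistency, organelle exclusion, biallelic check) to a table of
#' candidate SNP records and returns the surviving accession-diagnostic
#' sites together with per-stage removal counts.
#'
#' @param candidates data.frame of candidate records; required columns:
#'   contig, pos, ref_allele, alt_allele, the hard-filter annotations
#'   (QD, MQ, FS, SOR, DP), per-accession depths (`dna_depth_a`,
#'   `rna_depth_a`, `dna_depth_b`, `rna_depth_b`) and per-dataset alleles
#'   (`allele_a_dna`, `allele_a_rna`, `allele_b_dna`, `allele_b_rna`).
#'   An optional `transcript_id` column is carried through.
#' @param organelle_contigs Contig names to exclude (default
#'   `c("ChrM", "ChrC")`).
#' @param min_depth Support-filter threshold.
#' @return List of class `reference_snp_set`: `entries` (contig, pos,
#'   allele_a, allele_b, transcript_id), `stage_counts` (named removals per
#'   stage, first-failing-stage attribution) and `n_input`.
#' @export
build_reference_snps <- function(candidates,
                                 organelle_contigs = c("ChrM", "ChrC"),
                                 min_depth = 10L) {
  stages <- c("hard_filter", "support", "consistency", "organelle",
              "biallelic")
  empty <- data.frame(contig = character(), pos = integer(),
                      allele_a = character(), allele_b = character(),
                      transcript_id = character(), stringsAsFactors = FALSE)
  if (is.null(candidates) || !nrow(candidates)) {
    return(structure(list(entries = empty,
                          stage_counts = stats::setNames(
                            integer(length(stages)), stages),
                          n_input = 0L),
                     class = "reference_snp_set"))
  }

  n <- nrow(candidates)
  pass_hard <- hard_filter_variant(candidates)
  pass_support <- support_filter(candidates, min_depth = min_depth)
  pass_consistent <- genotype_consistency(candidates)
  nuclear <- !(candidates$contig %in% organelle_contigs)
  # Biallelic: exactly one alternative allele, both single nucleotides.
  biallelic <- nchar(as.character(candidates$ref_allele)) == 1L &
    nchar(as.character(candidates$alt_allele)) == 1L &
    toupper(candidates$ref_allele) %in% DNA_BASES &
    toupper(candidates$alt_allele) %in% DNA_BASES &
    toupper(candidates$ref_allele) != toupper(candidates$alt_allele)

  first_fail <- rep(NA_character_, n)
  first_fail[!pass_hard] <- "hard_filter"
  first_fail[is.na(first_fail) & !pass_support] <- "support"
  first_fail[is.na(first_fail) & !pass_consistent] <- "consistency"
  first_fail[is.na(first_fail) & !nuclear] <- "organelle"
  first_fail[is.na(first_fail) & !biallelic] <- "biallelic"
  keep <- is.na(first_fail)

  stage_counts <- vapply(stages, function(s) sum(first_fail == s,
                                                 na.rm = TRUE), integer(1))

  kept <- candidates[keep, , drop = FALSE]
  entries <- data.frame(
    contig = kept$contig, pos = as.integer(kept$pos),
    allele_a = toupper(kept$allele_a_dna),
    allele_b = toupper(kept$allele_b_dna),
    transcript_id = if ("transcript_id" %in% names(kept)) {
      kept$transcript_id
    } else rep(NA_character_, nrow(kept)),
    stringsAsFactors = FALSE
  )
  key <- paste(entries$contig, entries$pos)
  if (anyDuplicated(key)) {
    dup <- entries[key %in% key[duplicated(key)], ]
    confl <- any(tapply(paste(dup$allele_a, dup$allele_b),
                        paste(dup$contig, dup$pos),
                        function(x) length(unique(x)) > 1L))
    if (confl) {
      stop_param("duplicate (contig, pos) with conflicting alleles")
    }
    entries <- entries[!duplicated(key), , drop = FALSE]
  }
  entries <- entries[order(entries$contig, entries$pos), , drop = FALSE]
  rownames(entries) <- NULL

  structure(list(entries = entries, stage_counts = stage_counts,
                 n_input = n),
            class = "reference_snp_set")
}

#' @export
print.reference_snp_set <- function(x, ...) {
  cat("<reference_snp_set>\n")
  cat("  input candidates:", x$n_input, "\n")
  cat("  retained SNPs:", nrow(x$entries), "\n")
  removed <- x$stage_counts
  for (s in names(removed)) {
    cat(sprintf("  removed at %-12s %d\n", paste0(s, ":"), removed[[s]]))
  }
  invisible(x)
}

#' Read candidate SNP records from a VCF file
#'
#' Thin wrapper over \pkg{vcfR}: extracts biallelic SNP rows and the INFO
#' annotations the hard filter needs. Depth/genotype evidence columns are
#' not present in a single VCF and must be merged on separately.
#'
#' @param path Path to a VCF file.
#' @return data.frame with contig, pos, ref_allele, alt_allele and the
#'   QD/MQ/FS/SOR/DP annotations.
#' @export
read_candidate_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_param("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    stringsAsFactors = FALSE
  )
  for (k in HARD_FILTER_KEYS) {
    out[[k]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = k)))
  }
  out
}

#' Write a reference SNP set as TSV
#'
#' @param ref A `reference_snp_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference_snps <- function(ref, path) {
  stopifnot(inherits(ref, "reference_snp_set"))
  utils::write.table(ref$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
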