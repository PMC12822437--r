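# Synthetic ground truth: a pair of accessions ("A" and "B") differing at
# biallelic SNPs inside annotated transcripts, with labelled mobile
# transcripts, their translation status and per-tissue expression levels.
# This emulates the heterograft design between two polymorphic accessions:
# every downstream rule consumes SNP-covering allele counts, so the truth
# object carries exactly the information those rules assume.

#' Generate a synthetic accession pair with diagnostic SNPs
#'
#' Builds two accession genomes that differ at biallelic nuclear (and,
#' for negative-control purposes, organellar) SNPs, an annotation with
#' 5'UTR/CDS/3'UTR intervals per transcript, and ground-truth labels for
#' mobile transcripts (which phosphate conditions and graft direction they
#' move under, and at what foreign-read rate), their translation status in
#' recipient tissue, and per-transcript expression multipliers.
#'
#' Transcripts are tiled along five nuclear contigs (plus `ChrM`/`ChrC`
#' organelle contigs when `organelle_fraction > 0`) with intergenic gaps;
#' each transcript is a contiguous 5'UTR + CDS + 3'UTR block on a random
#' strand. SNP counts per transcript are Binomial(length, `snp_density`),
#' with the alternative allele drawn uniformly from the three non-reference
#' bases. Mobile transcripts are drawn only from nuclear transcripts
#' carrying at least one SNP, so every truth label is recoverable in
#' principle.
#'
#' @param seed Integer seed; the whole object is deterministic given it.
#' @param n_transcripts Number of transcripts (>= 1).
#' @param snp_density Per-nucleotide SNP probability, in (0, 0.2).
#' @param organelle_fraction Fraction of transcripts placed on organelle
#'   contigs (these must be excluded by the reference-SNP builder).
#' @param mean_length Approximate mean transcript length in nt.
#' @param mobile_fraction Fraction of eligible nuclear transcripts labelled
#'   mobile.
#' @param mobile_rate Expected fraction of reads at a recipient-tissue SNP
#'   site that carry the foreign allele, for a mobile transcript in a
#'   condition where it moves.
#' @param translated_fraction Fraction of mobile transcripts that remain
#'   ribosome-associated (translated) in the recipient tissue.
#' @param accessions Length-2 character vector naming the two accessions.
#'
#' @return A list of class `synthetic_truth` with elements `genomes`
#'   (list `A`,`B` of named contig sequence vectors), `annotation`
#'   (data.frame: transcript_id, contig, strand, region, start, end),
#'   `transcripts` (one row per transcript with span and organelle flag),
#'   `snp_table` (contig, pos, allele_a, allele_b, transcript_id),
#'   `organelle_contigs`, `mobile_truth` (transcript_id, direction,
#'   condition, foreign_rate), `translated_truth`, `expression_truth`
#'   and `accessions`.
#' @export
generate_accession_pair <- function(seed,
                                    n_transcripts = 200L,
                                    snp_density = 0.01,
                                    organelle_fraction = 0.05,
                                    mean_length = 1000L,
                                    mobile_fraction = 0.15,
                                    mobile_rate = 0.1,
                                    translated_fraction = 0.5,
                                    accessions = c("A", "B")) {
  n_transcripts <- check_count(n_transcripts, "n_transcripts", min = 1L)
  if (!is.numeric(snp_density) || length(snp_density) != 1L ||
      snp_density < 0 || snp_density >= 0.2) {
    stop_param("`snp_density` must be in [0, 0.2)")
  }
  check_prob(organelle_fraction, "organelle_fraction")
  check_prob(mobile_fraction, "mobile_fraction")
  check_prob(mobile_rate, "mobile_rate", lower_open = TRUE, upper = 1)
  check_prob(translated_fraction, "translated_fraction")
  stopifnot(length(accessions) == 2L, accessions[1] != accessions[2])

  with_seed(seed, {
    nuclear_contigs <- paste0("Chr", seq_len(5L))
    organelle_contigs <- c("ChrM", "ChrC")

    n_org <- round(organelle_fraction * n_transcripts)
    is_org <- c(rep(TRUE, n_org), rep(FALSE, n_transcripts - n_org))

    # Region lengths: short UTRs around a protein-coding CDS.
    len5 <- pmax(30L, stats::rpois(n_transcripts, 0.15 * mean_length))
    len_cds <- pmax(90L, stats::rpois(n_transcripts, 0.65 * mean_length))
    len_cds <- len_cds - (len_cds %% 3L)
    len3 <- pmax(30L, stats::rpois(n_transcripts, 0.20 * mean_length))
    total <- len5 + len_cds + len3
    strand <- sample(c("+", "-"), n_transcripts, replace = TRUE)

    contig <- character(n_transcripts)
    contig[is_org] <- rep_len(organelle_contigs, sum(is_org))
    contig[!is_org] <- rep_len(nuclear_contigs, sum(!is_org))

    # Tile transcripts along each contig with fixed intergenic gaps.
    start <- integer(n_transcripts)
    gap <- 200L
    for (ctg in unique(contig)) {
      idx <- which(contig == ctg)
      start[idx] <- cumsum(c(1L, utils::head(total[idx] + gap, -1L)))
    }
    end <- start + total - 1L

    tx_id <- sprintf("TX%04d", seq_len(n_transcripts))
    transcripts <- data.frame(
      transcript_id = tx_id, contig = contig, strand = strand,
      start = start, end = end, length = total,
      organelle = is_org, stringsAsFactors = FALSE
    )

    # Region intervals in genomic coordinates; on the minus strand the
    # 5'UTR occupies the interval with the largest coordinates.
    region_rows <- lapply(seq_len(n_transcripts), function(i) {
      lens <- c(five_prime_utr = len5[i], cds = len_cds[i],
                three_prime_utr = len3[i])
      if (strand[i] == "-") lens <- rev(lens)
      ends <- start[i] + cumsum(lens) - 1L
      starts <- ends - lens + 1L
      data.frame(
        transcript_id = tx_id[i], contig = contig[i], strand = strand[i],
        region = names(lens), start = starts, end = ends,
        stringsAsFactors = FALSE
      )
    })
    annotation <- do.call(rbind, region_rows)
    rownames(annotation) <- NULL

    # Genome A: uniform random bases per contig (covering all transcripts
    # plus trailing gap); genome B: substitute the alternative allele at
    # each SNP.
    contig_len <- vapply(split(end, contig), max, integer(1)) + gap
    genome_a <- vapply(contig_len, function(n) {
      paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
    }, character(1))

    snp_rows <- lapply(seq_len(n_transcripts), function(i) {
      n_snp <- stats::rbinom(1L, total[i], snp_density)
      if (n_snp == 0L) return(NULL)
      pos <- sort(sample(seq.int(start[i], end[i]), n_snp))
      data.frame(contig = contig[i], pos = pos, transcript_id = tx_id[i],
                 stringsAsFactors = FALSE)
    })
    snp_table <- do.call(rbind, snp_rows)
    if (is.null(snp_table)) {
      snp_table <- data.frame(contig = character(), pos = integer(),
                              transcript_id = character(),
                              allele_a = character(), allele_b = character(),
                              stringsAsFactors = FALSE)
    } else {
      snp_table$allele_a <- substring(genome_a[snp_table$contig],
                                      snp_table$pos, snp_table$pos)
      snp_table$allele_b <- vapply(snp_table$allele_a, function(a) {
        sample(setdiff(DNA_BASES, a), 1L)
      }, character(1), USE.NAMES = FALSE)
    }

    genome_b <- genome_a
    if (nrow(snp_table)) {
      for (ctg in unique(snp_table$contig)) {
        s <- snp_table[snp_table$contig == ctg, ]
        chars <- strsplit(genome_b[[ctg]], "")[[1]]
        chars[s$pos] <- s$allele_b
        genome_b[[ctg]] <- paste(chars, collapse = "")
      }
    }

    # Mobile truth: direction, condition set and foreign-read rate per
    # mobile transcript. Only nuclear transcripts with >= 1 SNP are
    # eligible, so mobility is always observable.
    eligible <- intersect(tx_id[!is_org], unique(snp_table$transcript_id))
    n_mobile <- min(length(eligible), round(mobile_fraction * n_transcripts))
    mobile_ids <- sort(sample(eligible, n_mobile))

    mobile_rows <- lapply(mobile_ids, function(id) {
      direction <- sample(c("shoot_to_root", "root_to_shoot", "both"),
                          1L, prob = c(0.55, 0.35, 0.10))
      dirs <- if (direction == "both") {
        c("shoot_to_root", "root_to_shoot")
      } else direction
      kind <- sample(c("PSI", "PSD", "common"), 1L, prob = c(0.35, 0.35, 0.3))
      conds <- switch(kind,
        PSI = sample(MINUS_PI, sample(1:2, 1L)),
        PSD = sample(PLUS_PI, sample(1:2, 1L)),
        common = c(sample(MINUS_PI, sample(1:2, 1L)),
                   sample(PLUS_PI, sample(1:2, 1L)))
      )
      expand.grid(transcript_id = id, direction = dirs,
                  condition = sort(conds), foreign_rate = mobile_rate,
                  stringsAsFactors = FALSE)
    })
    mobile_truth <- do.call(rbind, mobile_rows) %||% data.frame(
      transcript_id = character(), direction = character(),
      condition = character(), foreign_rate = numeric(),
      stringsAsFactors = FALSE
    )

    translated_truth <- data.frame(
      transcript_id = mobile_ids,
      translated = stats::runif(length(mobile_ids)) < translated_fraction,
      stringsAsFactors = FALSE
    )

    # Per-transcript expression multiplier (log-normal, shared across
    # tissues/conditions with mild condition jitter); scales read depth.
    base_expr <- stats::rlnorm(n_transcripts, meanlog = 0, sdlog = 0.4)
    expression_truth <- expand.grid(
      transcript_id = tx_id, tissue = c("shoot", "root"),
      condition = PI_CONDITIONS, stringsAsFactors = FALSE
    )
    expression_truth$mean_expr <- base_expr[
      match(expression_truth$transcript_id, tx_id)] *
      stats::rlnorm(nrow(expression_truth), 0, 0.05)

    structure(
      list(
        genomes = list(A = genome_a, B = genome_b),
        annotation = annotation,
        transcripts = transcripts,
        snp_table = snp_table[, c("contig", "pos", "allele_a", "allele_b",
                                  "transcript_id")],
        organelle_contigs = organelle_contigs,
        mobile_truth = mobile_truth,
        translated_truth = translated_truth,
        expression_truth = expression_truth,
        accessions = accessions
      ),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat("  accessions:", paste(x$accessions, collapse = " / "), "\n")
  cat("  transcripts:", nrow(x$transcripts),
      sprintf("(%d organellar)", sum(x$transcripts$organelle)), "\n")
  cat("  SNPs:", nrow(x$snp_table), "\n")
  cat("  mobile transcripts:", length(unique(x$mobile_truth$transcript_id)),
      "\n")
  invisible(x)
}

#' Write the two accession genomes as FASTA
#'
#' @param truth A `synthetic_truth` object.
#' @param dir Output directory.
#' @return Invisibly, the two file paths written.
#' @export
write_truth_fasta <- function(truth, dir = ".") {
  stopifnot(inherits(truth, "synthetic_truth"))
  paths <- vapply(names(truth$genomes), function(acc) {
    path <- file.path(dir, paste0(
      "accession_", truth$accessions[match(acc, c("A", "B"))], ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(truth$genomes[[acc]]), path)
    path
  }, character(1))
  invisible(paths)
}

#' Write the transcript annotation as GFF3
#'
#' One feature row per annotated region (5'UTR, CDS, 3'UTR) in genomic
#' coordinates, 1-based closed intervals.
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_truth_gff3 <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ann <- truth$annotation
  type <- c(five_prime_utr = "five_prime_UTR", cds = "CDS",
            three_prime_utr = "three_prime_UTR")[ann$region]
  lines <- c("##gff-version 3",
             sprintf("%s\tgraftmobile\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                     ann$contig, type, ann$start, ann$end, ann$strand,
                     ann$transcript_id))
  writeLines(lines, path)
  invisible(path)
}
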