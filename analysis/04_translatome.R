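#!/usr/bin/env Rscript
# Step 4: translatome analysis of mobile transcripts.
#
# Runs the TRAP-seq (IP) observations through the identical
# informative-site and detection thresholds as the RNA-seq, partitions
# mobile transcripts into translated (TRAP-detected) and untranslated,
# compares the partition with the simulated ribosome-binding truth, and
# computes translational efficiencies with their -Pi vs +Pi contrasts.
#
# Reads:  results/allele_observations.tsv.gz,
#         results/trap_observations.tsv.gz, results/reference_snps.tsv,
#         results/mobile_calls.tsv, results/truth.rds
# Writes: results/translatome.tsv, results/te_contrasts.tsv

suppressPackageStartupMessages(library(graftmobile))

truth <- readRDS("results/truth.rds")
ref_entries <- utils::read.table("results/reference_snps.tsv",
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
calls <- utils::read.table("results/mobile_calls.tsv", header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
trap <- utils::read.table(gzfile("results/trap_observations.tsv.gz"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
rna <- utils::read.table(gzfile("results/allele_observations.tsv.gz"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)

cx <- function(obs) {
  counts <- suppressWarnings(
    site_allele_counts(obs, ref_entries, accessions = truth$accessions))
  list(het = counts[counts$heterograft, ],
       homo = counts[!counts$heterograft, ])
}
trap_cx <- cx(trap)
trap_calls <- identify_mobile_transcripts(trap_cx$het, trap_cx$homo)
part <- call_translated_mobile(calls$transcript_id, trap_calls)
message(sprintf("mobile transcripts: %d translated, %d untranslated (%.1f%% untranslated)",
                length(part$translated), length(part$untranslated),
                100 * length(part$untranslated) /
                  (length(part$translated) + length(part$untranslated))))

# agreement with the simulated ribosome-binding truth
tt <- truth$translated_truth
acc <- mean(c(part$translated %in% tt$transcript_id[tt$translated],
              part$untranslated %in% tt$transcript_id[!tt$translated]))
message(sprintf("classification agreement with truth: %.3f", acc))

out <- data.frame(
  transcript_id = c(part$translated, part$untranslated),
  translated = rep(c(TRUE, FALSE),
                   c(length(part$translated), length(part$untranslated))))
utils::write.table(out, "results/translatome.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# Translational efficiency per transcript x condition x tissue on
# per-million foreign+local abundances over reference sites, contrasting
# each -Pi condition against the Pi-sufficient control.
abund <- function(counts_het) {
  lib <- stats::aggregate(n_total ~ sample_id, counts_het, sum)
  lib_size <- stats::setNames(lib$n_total, lib$sample_id)
  a <- stats::aggregate(n_local ~ transcript_id + condition + tissue +
                          sample_id, counts_het, sum)
  a$abundance <- a$n_local / lib_size[a$sample_id] * 1e6
  stats::aggregate(abundance ~ transcript_id + condition + tissue, a, mean)
}
rna_ab <- abund(cx(rna)$het)
trap_ab <- abund(trap_cx$het)
te <- merge(rna_ab, trap_ab,
            by = c("transcript_id", "condition", "tissue"),
            suffixes = c("_rna", "_trap"))
te <- te[te$abundance_rna > 0, ]
te$TE <- translational_efficiency(te$abundance_trap, te$abundance_rna)

ctrl <- te[te$condition == "FP7D", c("transcript_id", "tissue", "TE")]
names(ctrl)[3] <- "TE_control"
contrasts <- merge(te[te$condition != "FP7D", ], ctrl)
contrasts <- contrasts[contrasts$TE_control > 0, ]
contrasts$log2_te_ratio <- te_contrast(contrasts$TE, contrasts$TE_control)
utils::write.table(
  contrasts[, c("transcript_id", "condition", "tissue", "TE",
                "TE_control", "log2_te_ratio")],
  "results/te_contrasts.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "TE contrasts: %d transcript x condition x tissue rows; %.1f%% shifted >1.5-fold",
  nrow(contrasts), 100 * mean(abs(contrasts$log2_te_ratio) > log2(1.5))))
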