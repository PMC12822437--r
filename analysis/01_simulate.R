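#!/usr/bin/env Rscript
# Step 1: simulate the study design.
#
# Two polymorphic accessions ("A" = the rootstock accession, "B" = the
# scion accession) differing at biallelic SNPs; one heterograft plus both
# homograft controls; shoot and root tissues; four Pi regimes
# (FP7D, NP3D, NP7D, NP7DRP2D) x 3 biological replicates. 15% of nuclear
# SNP-bearing transcripts are mobile at a 10% foreign-read rate; half of
# the mobile ones stay ribosome-bound in the recipient tissue.
#
# Writes: results/truth_*.tsv, results/allele_observations.tsv.gz,
#         results/trap_observations.tsv.gz, genomes/annotation files.

suppressPackageStartupMessages(library(graftmobile))
dir.create("results", showWarnings = FALSE)

seed <- 20260925L

truth <- generate_accession_pair(seed = seed, n_transcripts = 200,
                                 snp_density = 0.01,
                                 mobile_fraction = 0.15, mobile_rate = 0.1,
                                 translated_fraction = 0.5)
print(truth)

design <- standard_graft_design()
obs <- generate_graft_experiment(truth, design, depth = 50,
                                 error_rate = 0.002, replicates = 3,
                                 seed = seed + 1L)
trap <- generate_trap_experiment(truth, obs, capture_efficiency = 0.8,
                                 seed = seed + 2L)
cands <- simulate_variant_calls(truth, seed = seed + 3L, decoys = TRUE)

write_tsv <- function(x, name) {
  path <- file.path("results", name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path, " (", nrow(x), " rows)")
}
write_tsv(truth$snp_table, "truth_snps.tsv")
write_tsv(truth$mobile_truth, "truth_mobile.tsv")
write_tsv(truth$translated_truth, "truth_translated.tsv")
write_tsv(cands, "variant_candidates.tsv")

con <- gzfile("results/allele_observations.tsv.gz", "w")
utils::write.table(obs, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
con <- gzfile("results/trap_observations.tsv.gz", "w")
utils::write.table(trap, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
message("wrote per-site observations for ", nrow(design),
        " sample groups x 3 replicates")

write_truth_fasta(truth, "results")
write_truth_gff3(truth, "results/annotation.gff3")
saveRDS(truth, "results/truth.rds")  # convenience for later steps
message("done: simulated ", nrow(truth$snp_table), " SNPs across ",
        nrow(truth$transcripts), " transcripts; ",
        length(unique(truth$mobile_truth$transcript_id)),
        " truly mobile")
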