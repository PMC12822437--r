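#!/usr/bin/env Rscript
# Step 6: targeted DMS-MaPseq reactivity profiling.
#
# Simulates two DMS replicates over one 5'UTR amplicon with a known
# secondary structure (folded from the simulated genome), then runs the
# full reactivity pipeline: raw rates -> replicate QC -> averaging ->
# top-5% normalization with winsorization -> SHAPE-style constraint
# export -> AUC agreement with the generating structure.
#
# Reads:  results/truth.rds
# Writes: results/dms_profile.tsv, results/dms_constraints.shape

suppressPackageStartupMessages(library(graftmobile))

truth <- readRDS("results/truth.rds")
seed <- 20260930L

# take a 5'UTR from the simulated annotation as the amplicon
ann <- truth$annotation
utr <- ann[ann$region == "five_prime_utr" & ann$end - ann$start >= 79, ][1, ]
amplicon <- substring(truth$genomes$A[[utr$contig]], utr$start,
                      utr$start + 119)
if (utr$strand == "-") {
  amplicon <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amplicon)))
}

# reference structure: RNAfold's MFE structure when available, otherwise a
# synthetic alternating pattern
structure <- if (nzchar(Sys.which("RNAfold"))) {
  out <- system2("RNAfold", args = "--noPS", input = amplicon,
                 stdout = TRUE)
  sub(" .*$", "", out[2])
} else {
  paste(rep(c("(", "."), length.out = nchar(amplicon)), collapse = "")
}

profs <- lapply(1:2, function(r) {
  generate_dms_experiment(structure, amplicon, depth = 2000,
                          rate_unpaired = 0.05, rate_paired = 0.005,
                          seed = seed + r)
})
rates <- lapply(profs, raw_reactivity, min_depth = 500)
qc <- vapply(rates, replicate_qc, logical(1))
message("replicate QC: ", paste(ifelse(qc, "pass", "fail"), collapse = ", "))
avg <- average_replicates(rates[qc])
norm <- normalize_reactivity(avg$mean)

out <- data.frame(position = profs[[1]]$position, base = profs[[1]]$base,
                  depth = profs[[1]]$depth,
                  raw = round(avg$mean, 5), normalized = round(norm, 4))
utils::write.table(out, "results/dms_profile.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
export_constraints(norm, profs[[1]]$base, "results/dms_constraints.shape")

auc <- structure_agreement(norm, structure, profs[[1]]$base)
message(sprintf(
  "DMS profile over %d nt: %d A/C positions with data, AUC vs reference structure %.3f",
  nchar(amplicon), sum(!is.na(norm)), auc))
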