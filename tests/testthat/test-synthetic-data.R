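test_that("accession-pair generation is deterministic given the seed", {
  t1 <- generate_accession_pair(seed = 1, n_transcripts = 50,
                                snp_density = 0.01)
  t2 <- generate_accession_pair(seed = 1, n_transcripts = 50,
                                snp_density = 0.01)
  expect_identical(t1, t2)
  t3 <- generate_accession_pair(seed = 2, n_transcripts = 50,
                                snp_density = 0.01)
  expect_false(identical(t1$snp_table, t3$snp_table))
})

test_that("SNP count follows the binomial expectation", {
  truth <- generate_accession_pair(seed = 1, n_transcripts = 200,
                                   snp_density = 0.01, mean_length = 1000)
  total_len <- sum(truth$transcripts$length)
  expected <- total_len * 0.01
  sigma <- sqrt(total_len * 0.01 * 0.99)
  expect_lt(abs(nrow(truth$snp_table) - expected), 3 * sigma)
})

test_that("truth object invariants hold", {
  truth <- generate_accession_pair(seed = 7, n_transcripts = 80,
                                   snp_density = 0.02)
  expect_true(all(truth$snp_table$allele_a != truth$snp_table$allele_b))
  # SNPs lie inside their transcript's span
  tx <- truth$transcripts[match(truth$snp_table$transcript_id,
                                truth$transcripts$transcript_id), ]
  expect_true(all(truth$snp_table$pos >= tx$start &
                    truth$snp_table$pos <= tx$end))
  # every mobile transcript has >= 1 nuclear SNP
  mob <- unique(truth$mobile_truth$transcript_id)
  expect_true(all(mob %in% truth$snp_table$transcript_id))
  expect_false(any(mob %in%
                     truth$transcripts$transcript_id[truth$transcripts$organelle]))
  # regions are non-overlapping and ordered 5'UTR < CDS < 3'UTR in
  # transcript orientation
  for (id in utils::head(truth$transcripts$transcript_id, 10)) {
    ann <- truth$annotation[truth$annotation$transcript_id == id, ]
    ann <- ann[order(ann$start), ]
    expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))
    expected_order <- if (ann$strand[1] == "+") {
      c("five_prime_utr", "cds", "three_prime_utr")
    } else {
      c("three_prime_utr", "cds", "five_prime_utr")
    }
    expect_identical(ann$region, expected_order)
  }
  # genomes differ exactly at SNP positions
  for (ctg in unique(truth$snp_table$contig)[1:2]) {
    a <- strsplit(truth$genomes$A[[ctg]], "")[[1]]
    b <- strsplit(truth$genomes$B[[ctg]], "")[[1]]
    expect_identical(sort(which(a != b)),
                     sort(truth$snp_table$pos[truth$snp_table$contig == ctg]))
  }
})

test_that("zero SNP density gives an empty downstream reference set", {
  truth <- generate_accession_pair(seed = 1, n_transcripts = 20,
                                   snp_density = 0)
  expect_identical(nrow(truth$snp_table), 0L)
  ref <- build_reference_snps(simulate_variant_calls(truth, seed = 1))
  expect_identical(nrow(ref$entries), 0L)
})

test_that("invalid generator parameters error", {
  expect_error(generate_accession_pair(seed = 1, n_transcripts = 0),
               "n_transcripts")
  expect_error(generate_accession_pair(seed = 1, n_transcripts = 10,
                                       snp_density = 0.5), "snp_density")
})

test_that("graft observations conserve depth and honour the error model", {
  truth <- generate_accession_pair(seed = 3, n_transcripts = 60,
                                   snp_density = 0.01,
                                   mobile_fraction = 0)
  design <- standard_graft_design(heterograft_only = TRUE)
  obs <- generate_graft_experiment(truth, design, depth = 100,
                                   error_rate = 0.005, replicates = 1,
                                   seed = 4)
  counts <- suppressWarnings(
    site_allele_counts(obs, truth$snp_table, accessions = truth$accessions))
  expect_true(all(counts$n_local + counts$n_foreign + counts$n_other ==
                    counts$n_total))
  # with no mobility, foreign reads come only from errors hitting one
  # specific base: rate error_rate / 3
  n_reads <- sum(counts$n_total)
  expected <- n_reads * 0.005 / 3
  sigma <- sqrt(n_reads * (0.005 / 3))
  expect_lt(abs(sum(counts$n_foreign) - expected), 3 * sigma)
})

test_that("error-free, mobility-free grafts have zero foreign reads", {
  truth <- generate_accession_pair(seed = 5, n_transcripts = 30,
                                   snp_density = 0.01, mobile_fraction = 0)
  obs <- generate_graft_experiment(truth, standard_graft_design(),
                                   depth = 50, error_rate = 0,
                                   replicates = 2, seed = 6)
  counts <- site_allele_counts(obs, truth$snp_table,
                               accessions = truth$accessions)
  expect_identical(sum(counts$n_foreign), 0L)
  expect_identical(sum(counts$n_other), 0L)
})

test_that("graft generator is reproducible and validates its design", {
  truth <- generate_accession_pair(seed = 1, n_transcripts = 10,
                                   snp_density = 0.02)
  design <- standard_graft_design(heterograft_only = TRUE)
  o1 <- generate_graft_experiment(truth, design, seed = 9)
  o2 <- generate_graft_experiment(truth, design, seed = 9)
  expect_identical(o1, o2)
  bad <- design
  bad$condition <- "NOPE"
  expect_error(generate_graft_experiment(truth, bad, seed = 1),
               "unknown condition")
})

test_that("mobile transcripts draw foreign reads only where the truth says",
{
  truth <- generate_accession_pair(seed = 11, n_transcripts = 50,
                                   snp_density = 0.01,
                                   mobile_fraction = 0.3, mobile_rate = 0.2)
  obs <- generate_graft_experiment(truth, standard_graft_design(),
                                   depth = 80, error_rate = 0,
                                   replicates = 2, seed = 12)
  counts <- site_allele_counts(obs, truth$snp_table,
                               accessions = truth$accessions)
  foreign <- counts[counts$n_foreign > 0, ]
  expect_true(all(foreign$heterograft))
  key_obs <- with(foreign, paste(
    transcript_id,
    ifelse(tissue == "root", "shoot_to_root", "root_to_shoot"), condition))
  key_truth <- with(truth$mobile_truth,
                    paste(transcript_id, direction, condition))
  expect_true(all(key_obs %in% key_truth))
})

test_that("TRAP thinning behaves as binomial sampling with a hard zero for
          untranslated foreign reads", {
  truth <- generate_accession_pair(seed = 21, n_transcripts = 40,
                                   snp_density = 0.01,
                                   mobile_fraction = 0.25,
                                   mobile_rate = 0.2,
                                   translated_fraction = 0)
  input <- generate_graft_experiment(truth,
                                     standard_graft_design(heterograft_only = TRUE),
                                     depth = 100, error_rate = 0,
                                     replicates = 2, seed = 22)
  # capture_efficiency = 1: identical except zeroed untranslated foreign
  ip <- generate_trap_experiment(truth, input, capture_efficiency = 1,
                                 seed = 23)
  ip_counts <- site_allele_counts(ip, truth$snp_table,
                                  accessions = truth$accessions)
  expect_identical(sum(ip_counts$n_foreign), 0L)
  in_counts <- site_allele_counts(input, truth$snp_table,
                                  accessions = truth$accessions)
  expect_identical(ip_counts$n_local, in_counts$n_local)

  # thinning at 0.5 halves the local counts on average
  ip5 <- generate_trap_experiment(truth, input, capture_efficiency = 0.5,
                                  seed = 24)
  ip5_counts <- site_allele_counts(ip5, truth$snp_table,
                                   accessions = truth$accessions)
  n <- sum(in_counts$n_local)
  expect_lt(abs(sum(ip5_counts$n_local) - 0.5 * n),
            3 * sqrt(n * 0.25))
  expect_error(generate_trap_experiment(truth, input,
                                        capture_efficiency = 0),
               "capture_efficiency")
})

test_that("DMS generator follows the pairing-state rate model", {
  # fully paired A/C at rate 0: only background mismatches at G/U
  prof <- generate_dms_experiment("((((....))))", "AACCGGGGGGUU",
                                  depth = 1000, rate_unpaired = 0.05,
                                  rate_paired = 0, background_rate = 0,
                                  seed = 1)
  expect_identical(sum(prof$mismatch), 0L)

  # unpaired A at rate 0.05, depth 10000: empirical rate within 3 sigma
  n <- 40L
  prof2 <- generate_dms_experiment(strrep(".", n), strrep("A", n),
                                   depth = 10000, rate_unpaired = 0.05,
                                   rate_paired = 0.005, seed = 2)
  total <- n * 10000
  expect_lt(abs(sum(prof2$mismatch) - total * 0.05),
            3 * sqrt(total * 0.05 * 0.95))

  expect_identical(
    generate_dms_experiment("....", "ACGU", seed = 3),
    generate_dms_experiment("....", "ACGU", seed = 3))
  expect_error(generate_dms_experiment("...", "ACGU", seed = 1), "length")
  expect_error(generate_dms_experiment("....", "ACGU", rate_unpaired = 0.01,
                                       rate_paired = 0.05, seed = 1),
               "exceed")
})

test_that("truth FASTA/GFF3 writers round-trip through standard readers", {
  truth <- generate_accession_pair(seed = 31, n_transcripts = 10,
                                   snp_density = 0.01)
  dir <- withr::local_tempdir()
  paths <- write_truth_fasta(truth, dir)
  seqs <- Biostrings::readDNAStringSet(paths[[1]])
  expect_identical(as.character(seqs[["Chr1"]]), truth$genomes$A[["Chr1"]])
  gff <- file.path(dir, "ann.gff3")
  write_truth_gff3(truth, gff)
  reread <- utils::read.table(gff, sep = "\t", skip = 1)
  expect_identical(nrow(reread), nrow(truth$annotation))
  expect_true(all(reread$V4 == truth$annotation$start))
})
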