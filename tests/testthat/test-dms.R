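test_that("mutation profile counts depth and masks mismatches near indels",
{
  ref <- strrep("ACGT", 10)  # 40 nt
  perfect <- data.frame(start = rep(1L, 10), seq = rep(ref, 10))
  prof <- mutation_profile(perfect, ref)
  expect_identical(prof$depth[5], 10L)
  expect_identical(prof$mismatch[5], 0L)

  # read with a deletion at 20 and a mismatch at 22: |22 - 20| <= 3 masks it
  read <- strsplit(ref, "")[[1]]
  read[20] <- "-"
  read[22] <- "A"  # ref at 22 is C
  r <- data.frame(start = 1L, seq = paste(read, collapse = ""))
  prof2 <- mutation_profile(r, ref)
  expect_identical(prof2$mismatch[22], 0L)
  expect_identical(prof2$depth[22], 1L)   # depth still counted

  # mismatch at 24 with the indel at 20 is outside the mask and counted
  read2 <- strsplit(ref, "")[[1]]
  read2[20] <- "-"
  read2[24] <- "A"  # ref at 24 is T
  prof3 <- mutation_profile(data.frame(start = 1L,
                                       seq = paste(read2, collapse = "")),
                            ref)
  expect_identical(prof3$mismatch[24], 1L)

  expect_error(mutation_profile(data.frame(start = 30L, seq = ref), ref),
               "beyond")
})

test_that("widening the indel mask never increases mismatch counts", {
  set.seed(91)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  reads <- do.call(rbind, lapply(1:30, function(i) {
    chars <- strsplit(ref, "")[[1]]
    chars[sample(60, 3)] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    if (i %% 3 == 0) chars[sample(60, 1)] <- "-"
    data.frame(start = 1L, seq = paste(chars, collapse = ""))
  }))
  mm <- sapply(0:6, function(w) {
    sum(mutation_profile(reads, ref, indel_mask_nt = w)$mismatch)
  })
  expect_true(all(diff(mm) <= 0))
})

test_that("raw reactivity is defined only at covered A/C positions", {
  prof <- data.frame(position = 1:4, base = c("A", "G", "C", "A"),
                     depth = c(100L, 1000L, 1000L, 0L),
                     mismatch = c(5L, 10L, 30L, 0L))
  rates <- raw_reactivity(prof, min_depth = 100)
  expect_identical(rates[1], 0.05)
  expect_true(is.na(rates[2]))   # G: never defined
  expect_identical(rates[3], 0.03)
  expect_true(is.na(rates[4]))   # zero depth: no data
  bad <- prof; bad$mismatch[1] <- 200L
  expect_error(raw_reactivity(bad), "exceed")
})

test_that("replicate QC flags the spiky-silent pathology", {
  spiky <- c(rep(0.001, 95), 0.2, 0.2, rep(0.001, 3))
  expect_false(replicate_qc(spiky))
  expect_true(replicate_qc(rep(0.03, 50)))
  expect_false(replicate_qc(rep(0, 50)))
  # mostly silent but no spike: passes (no PCR-jackpot signature)
  expect_true(replicate_qc(c(rep(0.001, 95), rep(0.02, 5))))
})

test_that("replicate averaging is positionwise with NA tolerance", {
  avg <- average_replicates(list(c(0.02, NA, 0.1), c(0.04, 0.05, NA)))
  expect_equal(avg$mean, c(0.03, 0.05, 0.1))
  expect_identical(avg$n_obs, c(2, 1, 1))
  one <- average_replicates(list(c(0.1, 0.2)))
  expect_identical(one$mean, c(0.1, 0.2))
  expect_error(average_replicates(list(1:2, 1:3)), "equal length")
})

test_that("normalization divides by the median of the top 5% and
          winsorizes at 1", {
  # 40 rates whose top two are 0.20 and 0.18: normalizer 0.19
  rates <- c(rep(0.01, 38), 0.20, 0.18)
  norm <- normalize_reactivity(rates)
  expect_equal(norm[1], 0.01 / 0.19, tolerance = 1e-12)
  expect_equal(norm[40], 0.18 / 0.19, tolerance = 1e-12)
  expect_equal(norm[39], 1.0)               # 0.20 -> 1.0526 -> winsorized

  # explicit winsorization arithmetic: 80 rates whose top four are
  # {0.25, 0.20, 0.18, 0.18} give normalizer 0.19 (midpoint median), so
  # the raw 0.25 maps to 1.3158 and is winsorized to exactly 1.0
  rates2 <- c(rep(0.01, 76), 0.25, 0.20, 0.18, 0.18)
  expect_equal(rates2[77] / 0.19, 1.3158, tolerance = 1e-4)
  norm2 <- normalize_reactivity(rates2)
  expect_identical(norm2[77], 1.0)
  expect_equal(norm2[80], 0.18 / 0.19, tolerance = 1e-12)

  # 20 positions: top 5% is one position, the max, which maps to 1
  rates3 <- seq(0.01, 0.2, length.out = 20)
  norm3 <- normalize_reactivity(rates3)
  expect_identical(max(norm3), 1.0)
  expect_identical(norm3[20], 1.0)

  expect_true(all(normalize_reactivity(runif(50, 0, 0.3)) <= 1))
  expect_error(normalize_reactivity(rep(0, 10)), "normalizer 0")
})

test_that("average-then-normalize differs from normalize-then-average", {
  # the processing order matters: normalizers differ per replicate
  r1 <- c(0.02, 0.04, 0.40, 0.01)
  r2 <- c(0.02, 0.04, 0.04, 0.01)
  paper_order <- normalize_reactivity(average_replicates(list(r1, r2))$mean)
  wrong_order <- average_replicates(list(normalize_reactivity(r1),
                                         normalize_reactivity(r2)))$mean
  expect_false(isTRUE(all.equal(paper_order, wrong_order)))
})

test_that("constraint export writes -999 at non-A/C and round-trips", {
  norm <- c(0.7, NA, 0.2, 1.0)
  bases <- c("A", "G", "C", "A")
  path <- withr::local_tempfile(fileext = ".shape")
  export_constraints(norm, bases, path)
  back <- read_constraints(path)
  expect_identical(back$reactivity, c(0.7, -999, 0.2, 1.0))
  expect_identical(back$position, 1:4)
})

test_that("structure agreement AUC separates clean profiles and matches an
          independent ROC implementation", {
  struct <- "((((....))))"
  bases <- strsplit("AACCAACCAACC", "")[[1]]
  perfect <- ifelse(strsplit(struct, "")[[1]] == ".", 1, 0)
  expect_identical(structure_agreement(perfect, struct, bases), 1)

  set.seed(92)
  n <- 60
  struct2 <- paste(sample(c("(", "."), n, replace = TRUE), collapse = "")
  bases2 <- sample(c("A", "C"), n, replace = TRUE)
  vals <- runif(n)
  auc <- structure_agreement(vals, struct2, bases2)
  if (requireNamespace("pROC", quietly = TRUE)) {
    paired <- strsplit(struct2, "")[[1]] != "."
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = !paired, predictor = vals, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(auc, ref, tolerance = 1e-12)
  }
  # shuffled reactivities carry no structural signal
  set.seed(93)
  aucs <- replicate(50, structure_agreement(sample(vals), struct2, bases2))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("simulated DMS profile recovers the generating structure", {
  set.seed(94)
  n <- 80
  struct <- paste(sample(c("(", "."), n, replace = TRUE, prob = c(0.5, 0.5)),
                  collapse = "")
  seqs <- paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
  prof <- generate_dms_experiment(struct, seqs, depth = 2000,
                                  rate_unpaired = 0.05, rate_paired = 0.005,
                                  seed = 95)
  rates <- raw_reactivity(prof, min_depth = 500)
  norm <- normalize_reactivity(rates)
  expect_true(all(norm >= 0 & norm <= 1, na.rm = TRUE))
  expect_gt(structure_agreement(norm, struct, prof$base), 0.8)
})
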