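test_that("reference generation places disjoint features and is deterministic", {
  cfg <- sim_config(seed = 1, n_mirna = 100, genome_length = 100000)
  b1 <- generate_reference(cfg)
  b2 <- generate_reference(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$annotation, b2$annotation)
  expect_identical(b1$truth, b2$truth)

  mir <- b1$annotation[b1$annotation$class == "miRNA", ]
  expect_equal(nrow(mir), 100)
  w <- mir$end - mir$start
  expect_true(all(w >= 18 & w <= 24))
  o <- order(b1$annotation$start)
  ann <- b1$annotation[o, ]
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))

  # byte-identical artifacts on re-run
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(b1$genome, f1); write_genome_fasta(b2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  b1_bed <- tempfile(fileext = ".bed"); b2_bed <- tempfile(fileext = ".bed")
  write_bed(b1$annotation, b1_bed); write_bed(b2$annotation, b2_bed)
  expect_identical(readLines(b1_bed), readLines(b2_bed))
})

test_that("the designated repeat is an exact two-copy duplication", {
  b <- tiny_bundle()
  rr <- b$repeat_region
  s1 <- substring(b$genome[rr$contig[1]], rr$start[1] + 1, rr$end[1])
  s2 <- substring(b$genome[rr$contig[2]], rr$start[2] + 1, rr$end[2])
  expect_identical(s1, s2)
  expect_gte(nchar(s1), 30)
  # the repeat does not overlap any annotated feature
  for (i in 1:2) {
    ov <- b$annotation$start < rr$end[i] & b$annotation$end > rr$start[i]
    expect_false(any(ov))
  }
})

test_that("impossible feature density raises a capacity error", {
  expect_error(
    generate_reference(sim_config(seed = 1, n_mirna = 50, genome_length = 900)),
    "too small"
  )
})

test_that("down/up fractions are assigned exactly, not sampled", {
  b <- generate_reference(sim_config(seed = 9, n_mirna = 60, frac_down = 0.4,
                                     frac_up = 0.05))
  lfc <- b$truth$true_log2FC[b$truth$class == "miRNA"]
  expect_equal(sum(lfc < 0), round(0.4 * 60))
  expect_equal(sum(lfc > 0), round(0.05 * 60))
  expect_true(all(-lfc[lfc < 0] >= 1 & -lfc[lfc < 0] <= 2))  # 2-4x in log2
})

test_that("drawn counts match the NB/Poisson moments", {
  n <- 10000
  # Poisson limit: mean 50, variance/mean ~ 1
  b <- truth_only_bundle(n, base_mean = 50, dispersion = 0)
  x <- draw_counts(b, "control", seed = 42)
  expect_lt(abs(mean(x) - 50), 3 * sqrt(50 / n))
  expect_lt(abs(var(x) / mean(x) - 1), 3 * sqrt(2 / n))

  # NB: variance = mu + phi mu^2
  b2 <- truth_only_bundle(n, base_mean = 50, dispersion = 0.5)
  y <- draw_counts(b2, "control", seed = 43)
  v_expect <- 50 + 0.5 * 50^2
  # SE of the sample variance from the exact NB fourth central moment
  k <- 0:100000
  pmf <- dnbinom(k, size = 2, mu = 50)
  mu4 <- sum((k - 50)^4 * pmf)
  se_var <- sqrt((mu4 - v_expect^2) / n)
  expect_lt(abs(var(y) - v_expect), 3 * se_var)

  # a true log2FC of -1 halves the knockdown mean
  b3 <- truth_only_bundle(n, base_mean = 50, log2fc = -1, dispersion = 0)
  ctrl <- draw_counts(b3, "control", seed = 44)
  kd <- draw_counts(b3, "knockdown", seed = 45)
  expect_lt(abs(mean(kd) / mean(ctrl) - 0.5), 0.03)

  # determinism given seed
  expect_identical(draw_counts(b, "control", seed = 42), x)
})

test_that("synthesized reads carry the adaptor/barcode template and exact inserts at zero error", {
  b <- tiny_bundle()
  cfg <- b$config
  cfg$error_profile_truth <- rep(0, cfg$read_length)
  b0 <- b; b0$config <- cfg
  counts <- list(control = draw_counts(b0, "control"),
                 knockdown = draw_counts(b0, "knockdown"))
  reads <- synthesize_fastq(b0, counts)
  # 5' adaptor with the sample barcode at position 0
  ctrl <- reads[reads$sample == "control", ]
  expect_true(all(startsWith(ctrl$seq, "ACAGGTTCAGAGTTCTACAGACGTA")))
  kd <- reads[reads$sample == "knockdown", ]
  expect_true(all(startsWith(kd$seq, "ACAGGTTCAGAGTTCTACAGGTCAA")))
  # insert is an exact substring of its (strand-aware) feature sequence
  fseq <- feature_sequences(b0)
  idx <- sample.int(nrow(reads), 200)
  hit <- mapply(function(ins, fid) grepl(ins, fseq[fid], fixed = TRUE),
                reads$insert[idx], reads$feature_id[idx])
  expect_true(all(hit))
  # read = template truncated to the read length
  expect_true(all(nchar(reads$seq) <= cfg$read_length))
  expect_true(all(nchar(reads$seq) == nchar(reads$qual)))
})

test_that("injected errors match the per-cycle truth profile", {
  b <- tiny_bundle()
  e <- rep(0, 36); e[5] <- 0.1
  r0 <- sample_genome_reads(b$genome, 10000, 36, error = 0, seed = 77)
  r1 <- sample_genome_reads(b$genome, 10000, 36, error = e, seed = 77)
  # same seed -> same origins; mismatches are purely injected errors
  expect_identical(r0$start, r1$start)
  mm_rate <- vapply(1:36, function(j) {
    mean(substr(r1$seq, j, j) != substr(r0$seq, j, j))
  }, numeric(1))
  expect_lt(abs(mm_rate[5] - 0.1), 0.01)
  expect_true(all(mm_rate[-5] == 0))
})

test_that("synthesis is deterministic given the seed", {
  b <- tiny_bundle()
  counts <- list(control = draw_counts(b, "control"))
  r1 <- synthesize_fastq(b, counts, seed = 5)
  r2 <- synthesize_fastq(b, counts, seed = 5)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
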