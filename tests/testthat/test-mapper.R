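test_that("the seed index enumerates k-mer positions exhaustively", {
  idx <- build_seed_index(c(chr = "ACGTACGT"), k = 4)
  hits <- query_kmer(idx, "ACGT")
  expect_equal(hits$pos, c(0, 4))
  expect_equal(hits$contig, c("chr", "chr"))
  expect_equal(nrow(query_kmer(idx, "GGGG")), 0)
  expect_error(build_seed_index(c(chr = "ACGT"), k = 12), "length of every contig")
})

test_that("candidate windows anchor on unique hits, repeats and reject all-N reads", {
  b <- tiny_bundle()
  idx <- build_seed_index(b$genome, 12)
  # unique error-free read -> one window containing the true origin
  rd <- sample_genome_reads(b$genome, 30, 30, error = 0, seed = 5)
  for (i in 1:10) {
    cand <- candidate_locations(rd$seq[i], idx)
    expect_equal(nrow(cand), 1)
    expect_lte(cand$wstart, rd$start[i])
    expect_gte(cand$wend, rd$end[i])
    expect_equal(cand$strand, rd$strand[i])
  }
  # a read from inside the two-copy repeat -> two candidate windows
  rr <- b$repeat_region
  rep_read <- substring(b$genome[rr$contig[1]], rr$start[1] + 1, rr$start[1] + 30)
  cand2 <- candidate_locations(rep_read, idx)
  expect_equal(nrow(cand2), 2)
  # all-N read -> unmapped (no candidates)
  expect_equal(nrow(candidate_locations(strrep("N", 30), idx)), 0)
  aln <- map_reads(strrep("N", 30), idx, error_profile(rep(0.01, 30)))
  expect_false(aln$mapped)
})

test_that("forward likelihood handles the degenerate and closed-form cases", {
  pr0 <- error_profile(rep(0, 12), gap_open = 0, gap_extend = 0)
  expect_equal(phmm_forward("ACGTACGTACGT", "ACGTACGTACGT", pr0), 0)
  e <- c(0.02, 0.01, 0.05, 0.01, 0.03, 0.02, 0.01, 0.04)
  pr <- error_profile(e, gap_open = 0, gap_extend = 0)
  read <- "ACGTACGT"
  win <- "ACTTACGT"  # mismatch at cycle 3
  expect_equal(phmm_forward(read, win, pr),
               sum(log(1 - e[-3])) + log(e[3] / 3), tolerance = 1e-12)
  expect_error(phmm_forward("ACGTACGTAC", "ACGTACGTAC", pr), "shorter")
})

test_that("forward likelihood equals the exhaustive alignment-sum oracle", {
  # validate the memoised oracle against literal path enumeration first
  set.seed(11)
  for (i in 1:5) {
    r <- random_seq(sample(2:4, 1)); w <- random_seq(sample(3:6, 1))
    e <- runif(nchar(r), 0.01, 0.2)
    expect_equal(oracle_forward(r, w, e, 0.05, 0.3),
                 oracle_forward_paths(r, w, e, 0.05, 0.3), tolerance = 1e-12)
  }
  # then the implementation against the oracle on larger random cases
  for (i in 1:40) {
    m <- sample(2:8, 1); n <- sample(m:20, 1)
    r <- random_seq(m); w <- random_seq(n)
    e <- runif(m, 0.005, 0.2)
    g <- runif(1, 0, 0.1); gx <- runif(1, 0.05, 0.5)
    pr <- error_profile(e, gap_open = g, gap_extend = gx)
    expect_equal(phmm_forward(r, w, pr), oracle_forward(r, w, e, g, gx),
                 tolerance = 1e-9)
  }
})

test_that("mapping quality encodes the posterior of the best location", {
  # posterior 0.90 <-> the MAPQ 10 discard boundary
  res <- compute_mapq(log(c(0.9, 0.1)))
  expect_equal(res$mapq, 10L)
  expect_false(res$is_discarded)
  expect_equal(res$posterior, 0.9, tolerance = 1e-12)
  # two identical candidates: posterior 1/2 -> MAPQ 3, discarded
  res2 <- compute_mapq(c(-5.3, -5.3))
  expect_equal(res2$mapq, 3L)
  expect_true(res2$is_discarded)
  expect_equal(res2$best, 1L)  # tie -> earliest (lowest coordinate)
  # single candidate: posterior 1 -> capped
  res3 <- compute_mapq(-2.5)
  expect_equal(res3$mapq, 60L)
  expect_error(compute_mapq(c(-Inf, -Inf)), "zero")
})

test_that("an extra competing candidate never increases the best posterior", {
  set.seed(21)
  for (i in 1:50) {
    ll <- sort(rnorm(sample(2:8, 1), sd = 4), decreasing = TRUE)
    extra <- c(ll, max(ll) - abs(rnorm(1, sd = 4)))  # competitor, not a new best
    expect_lte(compute_mapq(extra)$posterior, compute_mapq(ll)$posterior + 1e-12)
    expect_lte(compute_mapq(extra)$mapq, compute_mapq(ll)$mapq)
  }
})

test_that("error-free unique reads map to their exact origin at the MAPQ cap", {
  b <- tiny_bundle()
  idx <- build_seed_index(b$genome, 12)
  rd <- sample_genome_reads(b$genome, 400, 32, error = 0, seed = 8)
  pr <- error_profile(rep(0.01, 32))
  aln <- map_reads(rd$seq, idx, pr)
  away_from_repeat <- !(rd$start < max(b$repeat_region$end) + 32 &
                          rd$end > min(b$repeat_region$start) - 32)
  ok <- aln$mapped & aln$start == rd$start & aln$end == rd$end &
    aln$strand == rd$strand & aln$contig == rd$contig
  expect_true(all(ok[away_from_repeat]))
  expect_true(all(aln$mapq[away_from_repeat & aln$n_candidates == 1] == 60L))
  expect_true(all(aln$cigar[ok] == "32M"))
})

test_that("repeat-derived reads are ambiguous and discarded at threshold 10", {
  b <- tiny_bundle()
  idx <- build_seed_index(b$genome, 12)
  rr <- b$repeat_region
  rd <- sample_genome_reads(
    b$genome, 40, 30, error = 0, seed = 13,
    intervals = data.frame(contig = rr$contig[1], start = rr$start[1],
                           end = rr$end[1])
  )
  aln <- map_reads(rd$seq, idx, error_profile(rep(0.01, 30)))
  expect_true(all(aln$mapped))
  expect_true(all(aln$mapq == 3L))
  expect_true(all(aln$is_discarded))
  # the best location tie broke to the lower coordinate (copy 1)
  expect_true(all(aln$start >= rr$start[1] & aln$end <= rr$end[1]))
})

test_that("mapping the reverse complement recovers the same locus on the other strand", {
  b <- tiny_bundle()
  idx <- build_seed_index(b$genome, 12)
  rd <- sample_genome_reads(b$genome, 50, 30, error = 0, seed = 17,
                            stranded = FALSE)
  pr <- error_profile(rep(0.02, 30))
  fwd <- map_reads(rd$seq, idx, pr)
  rc <- vapply(rd$seq, srnascreen:::cpp_revcomp, character(1), USE.NAMES = FALSE)
  rev <- map_reads(rc, idx, pr)
  expect_equal(rev$start, fwd$start)
  expect_equal(rev$end, fwd$end)
  expect_true(all(rev$strand != fwd$strand))
})

test_that("SAM output is valid, reconcilable and round-trips", {
  b <- tiny_bundle()
  idx <- build_seed_index(b$genome, 12)
  rd <- sample_genome_reads(b$genome, 30, 30, error = 0, seed = 23)
  rr <- b$repeat_region
  amb <- sample_genome_reads(b$genome, 5, 30, error = 0, seed = 3,
                             intervals = data.frame(contig = rr$contig[1],
                                                    start = rr$start[1],
                                                    end = rr$end[1]))
  reads <- data.frame(read_id = c(rd$read_id, paste0("amb", 1:5)),
                      seq = c(rd$seq, amb$seq), stringsAsFactors = FALSE)
  aln <- map_reads(reads, idx, error_profile(rep(0.01, 30)))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, b$genome, sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ")))
  expect_equal(sum(!startsWith(lines, "@")), nrow(reads))  # nothing silently dropped
  back <- read_sam(sam)
  expect_equal(back$read_id, aln$read_id)
  keep <- aln$mapped & !aln$is_discarded
  expect_equal(back$mapped, keep)
  expect_equal(back$start[keep], aln$start[keep])
  expect_equal(back$end[keep], aln$end[keep])
  expect_equal(back$mapq[keep], aln$mapq[keep])
  expect_true(all(back$is_discarded[aln$mapped & aln$is_discarded]))
  # empty input: valid header, zero records
  sam0 <- tempfile(fileext = ".sam")
  write_sam(map_reads(character(0), idx, error_profile(rep(0.01, 30))),
            b$genome, sam0)
  l0 <- readLines(sam0)
  expect_true(all(startsWith(l0, "@")))
})
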