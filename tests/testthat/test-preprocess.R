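mk_reads <- function(seqs) {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

manifest1 <- data.frame(
  sample = c("S1", "S2"), tag = c("ACGT", "GTCA"),
  condition = c("control", "knockdown"), library = c("lib1", "lib1"),
  stringsAsFactors = FALSE
)

test_that("demultiplexing assigns by exact barcode behind the 5' adaptor", {
  insert <- "TACCCTGTAGATCCGAA"
  reads <- mk_reads(c(
    paste0("ACAGGTTCAGAGTTCTACAG", "ACGT", "A", insert),   # S1
    paste0("ACAGGTTCAGAGTTCTACAG", "TTTT", "A", insert),   # unknown tag
    paste0("ACTGGTTCAGAGTTCTACAG", "GTCA", "A", insert),   # 1 prefix mismatch -> ok
    paste0("ACTGGTACAGAGTTCTACAG", "ACGT", "A", insert)    # 2 mismatches -> no
  ))
  out <- demultiplex(reads, manifest1)
  expect_equal(out$sample, c("S1", "UNASSIGNED", "S2", "UNASSIGNED"))
  expect_equal(out$seq[1], insert)                  # adaptor+tag+A removed
  expect_equal(out$seq[2], reads$seq[2])            # untouched
  expect_equal(nchar(out$qual[1]), nchar(insert))   # quality trimmed alongside
  # conservation: every read lands in exactly one stream
  expect_equal(sum(out$sample != "UNASSIGNED") + sum(out$sample == "UNASSIGNED"),
               nrow(reads))
})

test_that("demultiplexing rejects bad manifests", {
  r <- mk_reads("ACAGGTTCAGAGTTCTACAGACGTATTT")
  expect_error(demultiplex(r, manifest1[0, ]), "empty")
  m_dup <- manifest1; m_dup$tag <- c("ACGT", "ACGT")
  expect_error(demultiplex(r, m_dup), "duplicate")
})

test_that("demultiplexing of zero-error simulated reads is perfect", {
  b <- tiny_bundle()
  cfg <- b$config
  cfg$error_profile_truth <- rep(0, cfg$read_length)
  b0 <- b; b0$config <- cfg
  reads <- synthesize_fastq(b0, list(control = draw_counts(b0, "control"),
                                     knockdown = draw_counts(b0, "knockdown")))
  manifest <- data.frame(sample = names(cfg$barcode_map),
                         tag = unname(cfg$barcode_map),
                         condition = names(cfg$barcode_map),
                         library = "lib1", stringsAsFactors = FALSE)
  out <- demultiplex(reads[, c("read_id", "seq", "qual")], manifest, cfg$adapter5)
  expect_identical(out$sample, reads$sample)
})

test_that("3' adaptor trimming finds the leftmost adaptor prefix", {
  a3 <- "TCGTATGCCGTCTTCTGCTTG"
  insert <- "TGAGGTAGTAGGTTGTATAGTT"
  r <- mk_reads(c(
    paste0(insert, a3),                      # full adaptor
    paste0(insert, substr(a3, 1, 7)),        # partial adaptor at the end
    insert,                                  # no adaptor occurrence
    a3                                       # adaptor only -> empty insert
  ))
  out <- trim_adapter3(r, a3)
  expect_equal(out$seq[1], insert)
  expect_equal(out$seq[2], insert)
  expect_equal(out$seq[3], insert)
  expect_false(any(out$rejected[1:3]))
  expect_true(out$rejected[4])
  expect_equal(out$reject_reason[4], "empty")
})

test_that("trimming tolerates mismatches within the rate and rejects captured siRNA", {
  a3 <- "TCGTATGCCGTCTTCTGCTTG"
  insert <- "TGAGGTAGTAGGTTGTATAGTT"
  bad_a3 <- a3
  substr(bad_a3, 3, 3) <- "A"  # 1 mismatch in 21 bases: rate 0.048 <= 0.1
  out <- trim_adapter3(mk_reads(paste0(insert, bad_a3)), a3)
  expect_equal(out$seq[1], insert)
  # the transfected TERT siRNA sense strand (DNA form) is an artifact
  sirna <- "GAGCAAGTTGCAAAGCATTTT"
  out2 <- trim_adapter3(mk_reads(paste0(sirna, a3)), a3, blocklist = sirna)
  expect_true(out2$rejected[1])
  expect_equal(out2$reject_reason[1], "artifact")
})

test_that("the low-abundance filter keeps sequences with total >= 10 across libraries", {
  seqs <- c(rep("AAAACCCCGGGGTTT", 3),  # A: 3 in lib1
            rep("AAAATTTTGGGGCCC", 4))  # B: 4 in lib1
  lib1 <- data.frame(seq = seqs, library = "lib1", stringsAsFactors = FALSE)
  lib2 <- data.frame(seq = rep("AAAACCCCGGGGTTT", 7), library = "lib2",
                     stringsAsFactors = FALSE)
  joint <- rbind(lib1, lib2)
  out <- filter_low_abundance(joint, 10)
  expect_setequal(unique(out$seq), "AAAACCCCGGGGTTT")     # A kept at 10, B dropped at 4
  expect_equal(sum(out$library == "lib1"), 3)             # per-library counts unchanged
  expect_equal(sum(out$library == "lib2"), 7)
  # boundary: exactly 10 kept, 9 removed
  nine <- data.frame(seq = rep("ACACACACACACACA", 9), library = "lib1")
  expect_equal(nrow(filter_low_abundance(nine, 10)), 0)
  # idempotent and order-independent
  out2 <- filter_low_abundance(out, 10)
  expect_equal(nrow(out2), nrow(out))
  shuf <- joint[rev(seq_len(nrow(joint))), ]
  expect_equal(sort(rownames(filter_low_abundance(shuf, 10))),
               sort(rownames(out)))
})

test_that("the length window is inclusive on both ends", {
  r <- mk_reads(c(strrep("A", 14), strrep("C", 15), strrep("G", 30),
                  strrep("T", 31), strrep("A", 50), strrep("C", 51)))
  expect_equal(nchar(select_length(r, 15, 30)$seq), c(15, 30))
  expect_equal(nchar(select_length(r, 15, 50)$seq), c(15, 30, 31, 50))
  expect_error(select_length(r, 30, 15), "min_nt")
})
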