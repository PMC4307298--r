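# Demultiplexing, adaptor trimming, and the screen's abundance and length
# filters.

#' Demultiplex pooled reads by their 4-nt barcode
#'
#' A read is assigned to a sample iff the 4-mer in the barcode slot of the
#' 5' adaptor equals that sample's tag exactly, after verifying that the
#' constant adaptor prefix matches with at most one mismatch. Barcodes are
#' only four nucleotides, so no tag tolerance is allowed. Assigned reads
#' have the adaptor, barcode and trailing constant base removed; unassigned
#' reads are kept untouched under sample `"UNASSIGNED"` so that input and
#' output read counts always reconcile.
#'
#' @param reads data.frame with at least `read_id`, `seq` (and optionally
#'   `qual`, trimmed alongside the sequence).
#' @param manifest data.frame(sample, tag, condition, library); tags must be
#'   unique 4-mers.
#' @param adapter5 the 5' adaptor template containing the literal "XXXX"
#'   barcode slot.
#' @param max_prefix_mismatch allowed mismatches in the constant prefix
#'   (default 1).
#' @return The input data.frame with a `sample` column and trimmed
#'   `seq`/`qual` for assigned reads.
#' @export
demultiplex <- function(reads, manifest, adapter5 = "ACAGGTTCAGAGTTCTACAGXXXXA",
                        max_prefix_mismatch = 1L) {
  if (!nrow(manifest)) stop("empty barcode manifest")
  if (anyDuplicated(manifest$tag)) stop("duplicate barcode tags in manifest")
  if (any(nchar(manifest$tag) != 4L)) stop("barcode tags must be 4 nt")
  slot <- as.integer(regexpr("XXXX", adapter5, fixed = TRUE))
  if (slot < 0) stop("adapter5 must contain the literal XXXX barcode slot")
  pre <- substr(adapter5, 1L, slot - 1L)
  post_len <- nchar(adapter5) - (slot + 3L)  # trailing constant bases
  npre <- nchar(pre)
  trim_len <- npre + 4L + post_len

  seqs <- reads$seq
  prefix_mm <- integer(length(seqs))
  if (npre > 0) {
    pre_ch <- strsplit(pre, "")[[1]]
    for (j in seq_len(npre)) {
      prefix_mm <- prefix_mm + (substr(seqs, j, j) != pre_ch[j])
    }
  }
  tag_obs <- substr(seqs, npre + 1L, npre + 4L)
  sample <- manifest$sample[match(tag_obs, manifest$tag)]
  ok <- !is.na(sample) & prefix_mm <= max_prefix_mismatch &
    nchar(seqs) >= trim_len
  sample[!ok] <- NA_character_

  out <- reads
  out$sample <- ifelse(ok, sample, "UNASSIGNED")
  out$seq <- ifelse(ok, substring(seqs, trim_len + 1L), seqs)
  if ("qual" %in% names(out)) {
    out$qual <- ifelse(ok, substring(reads$qual, trim_len + 1L), reads$qual)
  }
  out
}

#' Trim the 3' adaptor and reject artifact reads
#'
#' Removes the leftmost suffix of each read that matches a prefix of the 3'
#' adaptor with at least `min_overlap` bases and a mismatch rate at most
#' `max_mismatch_rate`. A read whose remaining insert is empty, or whose
#' insert equals an entry of the artifact `blocklist` (e.g. the transfected
#' siRNA strands, in DNA form), is rejected. Reads without any adaptor
#' occurrence are returned unchanged — rejection is a result, not an error.
#'
#' @param reads data.frame with `seq` (and optionally `qual`).
#' @param adapter3 DNA portion of the 3' adaptor.
#' @param min_overlap minimum adaptor overlap (default 5).
#' @param max_mismatch_rate maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @param blocklist character vector of exact artifact insert sequences to
#'   reject.
#' @return The input data.frame with trimmed `seq`, plus logical `rejected`
#'   and character `reject_reason` (`"empty"`, `"artifact"` or NA).
#' @export
trim_adapter3 <- function(reads, adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                          min_overlap = 5L, max_mismatch_rate = 0.1,
                          blocklist = character(0)) {
  useq <- unique(reads$seq)
  cut <- cpp_trim3(useq, adapter3, as.integer(min_overlap), max_mismatch_rate)
  cut_all <- cut[match(reads$seq, useq)]
  keep_len <- ifelse(cut_all < 0, nchar(reads$seq), cut_all)
  out <- reads
  out$seq <- substr(reads$seq, 1L, keep_len)
  if ("qual" %in% names(out)) out$qual <- substr(reads$qual, 1L, keep_len)
  out$rejected <- keep_len == 0L
  out$reject_reason <- ifelse(keep_len == 0L, "empty", NA_character_)
  if (length(blocklist)) {
    art <- out$seq %in% blocklist & !out$rejected
    out$rejected <- out$rejected | art
    out$reject_reason[art] <- "artifact"
  }
  out
}

#' Remove inserts seen fewer than `min_total` times across all libraries
#'
#' A distinct insert sequence is retained iff its summed occurrence count
#' across every library/sample is at least `min_total` (default 10, i.e.
#' sequences found less than 10 times in all experiments jointly are
#' dropped; a total of exactly 10 is kept). Operates on the exact insert
#' string; per-library counts of retained sequences are unchanged, making
#' the filter idempotent and order-independent.
#'
#' @param reads data.frame with `seq` (one row per read, any number of
#'   libraries/samples mixed).
#' @param min_total minimum total occurrence count (default 10).
#' @return The subset of `reads` whose sequences pass the filter.
#' @export
filter_low_abundance <- function(reads, min_total = 10L) {
  tot <- table(reads$seq)
  keep <- names(tot)[as.vector(tot) >= min_total]
  reads[reads$seq %in% keep, , drop = FALSE]
}

#' Keep inserts within an inclusive length window
#'
#' @param reads data.frame with `seq`.
#' @param min_nt,max_nt inclusive bounds on insert length (e.g. 15-50 for a
#'   broad small-RNA screen, 15-30 when targeting the miRNA fraction).
#' @return The subset of `reads` with `min_nt <= nchar(seq) <= max_nt`.
#' @export
select_length <- function(reads, min_nt = 15L, max_nt = 50L) {
  if (min_nt > max_nt) stop("min_nt must not exceed max_nt")
  len <- nchar(reads$seq)
  reads[len >= min_nt & len <= max_nt, , drop = FALSE]
}
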