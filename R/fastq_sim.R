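# Read synthesis: inserts sampled from features, wrapped in the 5' barcoded
# adaptor and the 3' adaptor, truncated to the read length, with per-cycle
# substitution errors injected according to the configured truth profile.

# Inject substitution errors: at cycle j each base mutates with probability
# e[j] to one of the three other bases. Vectorised over reads; only affected
# reads are rebuilt.
inject_errors <- function(seqs, e) {
  lens <- nchar(seqs)
  if (!length(seqs) || max(lens) == 0) return(seqs)
  maxlen <- max(lens)
  if (length(e) < maxlen) e <- c(e, rep(e[length(e)], maxlen - length(e)))
  hit_read <- integer(0)
  hit_cycle <- integer(0)
  for (j in seq_len(maxlen)) {
    if (e[j] <= 0) next
    alive <- which(lens >= j)
    hits <- alive[runif(length(alive)) < e[j]]
    hit_read <- c(hit_read, hits)
    hit_cycle <- c(hit_cycle, rep.int(j, length(hits)))
  }
  if (!length(hit_read)) return(seqs)
  bases <- c("A", "C", "G", "T")
  ord <- order(hit_read, hit_cycle)
  hit_read <- hit_read[ord]; hit_cycle <- hit_cycle[ord]
  for (r in unique(hit_read)) {
    cyc <- hit_cycle[hit_read == r]
    ch <- strsplit(seqs[r], "")[[1]]
    for (j in cyc) {
      others <- bases[bases != ch[j]]
      if (length(others) < 3) others <- bases  # N or unexpected char
      ch[j] <- others[sample.int(length(others), 1L)]
    }
    seqs[r] <- paste(ch, collapse = "")
  }
  seqs
}

phred33_string <- function(e, len) {
  q <- pmin(40L, as.integer(round(-10 * log10(pmax(e, 1e-4)))))
  full <- intToUtf8(q + 33L, multiple = FALSE)
  substring(full, 1L, len)
}

#' Synthesize barcoded FASTQ reads for a set of per-sample count vectors
#'
#' Each counted read is an insert taken from its feature (the full mature
#' sequence for miRNA loci; a random subfragment within
#' `insert_length_range` for the longer contaminant loci), prefixed by the
#' 5' adaptor with the XXXX slot replaced by the sample barcode and suffixed
#' by the DNA portion of the 3' adaptor, truncated to the configured read
#' length. Substitution errors are injected per cycle according to
#' `error_profile_truth`, and the quality string encodes the true per-cycle
#' error rate in Phred+33 (the mapper is expected to estimate its own
#' profile rather than trust these values).
#'
#' @param bundle a `reference_bundle`.
#' @param counts named list: sample -> named count vector over features
#'   (as from [draw_counts()]); sample names must match the config's
#'   `barcode_map`.
#' @param path optional FASTQ output path; the pooled library is written
#'   with [write_fastq()].
#' @param seed integer seed (default: config seed + 1).
#' @return Invisibly, a data.frame with one row per read: `read_id`, `seq`,
#'   `qual` plus the simulation truth (`sample`, `feature_id`, `insert`,
#'   `origin_start`, `origin_end`, `strand`).
#' @export
synthesize_fastq <- function(bundle, counts, path = NULL, seed = NULL) {
  cfg <- bundle$config
  if (!all(names(counts) %in% names(cfg$barcode_map))) {
    stop("count list names must be samples present in barcode_map")
  }
  if (is.null(seed)) seed <- cfg$seed + 1L
  slot <- as.integer(regexpr("XXXX", cfg$adapter5, fixed = TRUE))
  pre <- substr(cfg$adapter5, 1L, slot - 1L)
  post <- substr(cfg$adapter5, slot + 4L, nchar(cfg$adapter5))
  fseq <- feature_sequences(bundle)
  ann <- bundle$annotation
  rownames(ann) <- ann$feature_id

  withr::with_seed(as.integer(seed), {
    per_sample <- lapply(names(counts), function(smp) {
      cnt <- counts[[smp]]
      cnt <- cnt[cnt > 0]
      if (!length(cnt)) {
        return(data.frame(sample = character(0), feature_id = character(0),
                          insert = character(0), origin_start = integer(0),
                          origin_end = integer(0), strand = character(0),
                          stringsAsFactors = FALSE))
      }
      fid <- rep(names(cnt), cnt)
      width <- ann[fid, "end"] - ann[fid, "start"]
      cls <- ann[fid, "class"]
      full <- fseq[fid]
      # insert: the full mature sequence for miRNAs; one of the locus's
      # discrete processed-fragment species (weight-sampled) otherwise
      ilen <- width
      off <- integer(length(fid))
      frag <- which(cls != "miRNA")
      if (length(frag)) {
        sp <- bundle$fragment_species
        for (f in unique(fid[frag])) {
          rows <- which(sp$feature_id == f)
          here <- frag[fid[frag] == f]
          pick <- rows[sample.int(length(rows), length(here), replace = TRUE,
                                  prob = sp$weight[rows])]
          ilen[here] <- sp$length[pick]
          off[here] <- sp$offset[pick]
        }
      }
      insert <- substring(full, off + 1L, off + ilen)
      # origin in genome coordinates (0-based half-open, forward strand)
      strand <- ann[fid, "strand"]
      ostart <- ifelse(strand == "+", ann[fid, "start"] + off,
                       ann[fid, "end"] - off - ilen)
      data.frame(sample = smp, feature_id = fid, insert = insert,
                 origin_start = as.integer(ostart),
                 origin_end = as.integer(ostart + ilen),
                 strand = strand, stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, per_sample)
    if (!nrow(reads)) stop("no reads to synthesize (all counts zero)")
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]  # shuffle the pool
    tag <- cfg$barcode_map[reads$sample]
    template <- paste0(pre, tag, post, reads$insert, cfg$adapter3)
    seq <- substr(template, 1L, cfg$read_length)
    seq <- inject_errors(seq, cfg$error_profile_truth)
    reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))
    reads$seq <- seq
    reads$qual <- phred33_string(cfg$error_profile_truth, nchar(seq))
    rownames(reads) <- NULL
    reads <- reads[, c("read_id", "seq", "qual", "sample", "feature_id",
                       "insert", "origin_start", "origin_end", "strand")]
    if (!is.null(path)) write_fastq(reads, path)
    invisible(reads)
  })
}

#' Sample raw reads directly from genome intervals
#'
#' A lower-level generator used to exercise the mapper in isolation: reads
#' of fixed length are drawn uniformly from the given intervals (fully
#' contained), on a random strand, with per-cycle substitution errors. No
#' adaptors or barcodes are attached.
#'
#' @param genome named character vector of contig sequences.
#' @param n number of reads.
#' @param read_length read length (nt); intervals narrower than this are
#'   skipped.
#' @param error per-cycle substitution probabilities (recycled last value if
#'   shorter than `read_length`), or a single number for a flat profile.
#' @param intervals data.frame(contig, start, end) in 0-based half-open
#'   coordinates; default: the whole of every contig.
#' @param stranded if TRUE (default) each read picks a random strand and
#'   minus-strand reads are reverse-complemented.
#' @param seed integer seed.
#' @return data.frame: read_id, seq, contig, start, end, strand (truth).
#' @export
sample_genome_reads <- function(genome, n, read_length, error = 0,
                                intervals = NULL, stranded = TRUE, seed = 1L) {
  if (is.null(intervals)) {
    intervals <- data.frame(contig = names(genome), start = 0L,
                            end = nchar(genome), stringsAsFactors = FALSE)
  }
  iv <- intervals[intervals$end - intervals$start >= read_length, , drop = FALSE]
  if (!nrow(iv)) stop("no interval can hold a read of the requested length")
  if (length(error) == 1L) error <- rep(error, read_length)
  withr::with_seed(as.integer(seed), {
    room <- iv$end - iv$start - read_length + 1L
    pick <- sample.int(nrow(iv), n, replace = TRUE, prob = room)
    start <- iv$start[pick] + floor(runif(n) * room[pick])
    contig <- iv$contig[pick]
    seq <- substring(genome[contig], start + 1L, start + read_length)
    strand <- if (stranded) sample(c("+", "-"), n, replace = TRUE) else rep("+", n)
    minus <- strand == "-"
    seq[minus] <- vapply(seq[minus], cpp_revcomp, character(1), USE.NAMES = FALSE)
    seq <- inject_errors(seq, error)
    data.frame(read_id = sprintf("g%07d", seq_len(n)), seq = seq,
               contig = contig, start = as.integer(start),
               end = as.integer(start + read_length), strand = strand,
               stringsAsFactors = FALSE)
  })
}
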