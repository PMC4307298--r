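# Standard-format I/O. FASTA/FASTQ go through Biostrings, BED6 through
# rtracklayer; SAM records (with the mapper's custom tags) are serialized by
# a small writer/reader of our own since the alignment table is in-memory.

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `seq` and optionally `qual`
#'   (missing qualities are written as maximum, "I").
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(qual)
  qs <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ file (Phred+33).
#' @return data.frame: read_id, seq, qual.
#' @export
read_fastq <- function(path) {
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    # Biostrings warns while internally shuffling the qualities out of the
    # metadata columns; nothing of ours is dropped
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  data.frame(read_id = names(qs), seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the toy genome as FASTA
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write the feature annotation as BED6
#'
#' Coordinates are 0-based half-open; the feature class is encoded in the
#' name field as `feature_id|class`.
#' @param annotation annotation data.frame (contig, start, end, strand,
#'   class, feature_id).
#' @param path output file.
#' @export
write_bed <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(start = annotation$start + 1L, end = annotation$end),
    strand = annotation$strand
  )
  gr$name <- paste0(annotation$feature_id, "|", annotation$class)
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 annotation written by [write_bed()]
#' @param path BED file with `feature_id|class` name fields.
#' @return annotation data.frame in 0-based half-open coordinates.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  parts <- strsplit(nm, "|", fixed = TRUE)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = vapply(parts, function(p) if (length(p) > 1) p[2] else "other",
                   character(1)),
    feature_id = vapply(parts, `[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
}

#' Read / write the sample manifest (sample, tag, condition, library)
#' @param manifest data.frame with columns sample, tag, condition, library.
#' @param path TSV file.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Write alignments as SAM
#'
#' Retained alignments become mapped records (1-based POS, MAPQ as
#' computed); discarded reads (MAPQ below the threshold) are written as
#' unmapped records carrying an `XD:i:1` tag rather than silently dropped,
#' as are reads with no candidate location (`XD:i:0`). Custom tags: `XP:f:`
#' posterior probability of the reported location, `XE:Z:` per-cycle edit
#' string (=/X/I in read orientation).
#'
#' @param aln alignment data.frame from [map_reads()].
#' @param genome named character vector (for `@SQ` header lines).
#' @param path output SAM path.
#' @export
write_sam <- function(aln, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(genome[[nm]])), con)
  }
  writeLines(sprintf("@PG\tID:srnascreen\tPN:srnascreen\tVN:%s",
                     as.character(utils::packageVersion("srnascreen"))), con)
  if (!nrow(aln)) return(invisible(path))
  keep <- aln$mapped & !aln$is_discarded
  flag <- ifelse(!keep, 4L, ifelse(aln$strand == "-", 16L, 0L))
  seq_out <- aln$seq
  minus <- keep & aln$strand == "-"
  seq_out[minus] <- vapply(seq_out[minus], cpp_revcomp, character(1),
                           USE.NAMES = FALSE)
  cig <- aln$cigar
  cig[minus] <- vapply(cig[minus], rev_cigar, character(1), USE.NAMES = FALSE)
  rec <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
    aln$read_id, flag,
    ifelse(keep, aln$contig, "*"),
    ifelse(keep, aln$start + 1L, 0L),
    ifelse(keep, aln$mapq, 0L),
    ifelse(keep, cig, "*"),
    seq_out
  )
  tags <- ifelse(aln$mapped,
                 sprintf("XP:f:%.6g\tXE:Z:%s%s", aln$posterior, aln$edit,
                         ifelse(aln$is_discarded, "\tXD:i:1", "")),
                 "XD:i:0")
  writeLines(paste(rec, tags, sep = "\t"), con)
  invisible(path)
}

rev_cigar <- function(cig) {
  ops <- regmatches(cig, gregexpr("[0-9]+[MID]", cig))[[1]]
  paste(rev(ops), collapse = "")
}

#' Read a SAM file written by [write_sam()]
#' @param path SAM file.
#' @return data.frame with read_id, mapped, contig, start (0-based), end,
#'   strand, mapq, cigar, is_discarded.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), mapped = logical(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mapq = integer(0), cigar = character(0),
                      is_discarded = logical(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  cigar <- vapply(f, `[`, character(1), 6L)
  reflen <- vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MID]", cg))[[1]]
    sum(as.integer(sub("[MID]", "", ops[grepl("[MD]$", ops)])))
  }, integer(1), USE.NAMES = FALSE)
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  data.frame(
    read_id = vapply(f, `[`, character(1), 1L),
    mapped = bitwAnd(flag, 4L) == 0L,
    contig = vapply(f, `[`, character(1), 3L),
    start = start,
    end = start + reflen,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
    cigar = cigar,
    is_discarded = vapply(f, function(x) any(x == "XD:i:1"), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a counts table (features x libraries) as TSV
#' @param cm a `count_matrix` (see [count_features()]).
#' @param path output TSV.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an estimated error profile as TSV (cycle, e)
#' @param profile an `error_profile`.
#' @param path output TSV.
#' @export
write_error_profile <- function(profile, path) {
  write.table(data.frame(cycle = seq_along(profile$sub), e = profile$sub),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
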