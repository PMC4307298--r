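# Assignment of retained alignments to annotated features and per-library
# counting / class composition.

#' Assign retained alignments to annotated features
#'
#' A read is assigned to a feature iff its genomic interval overlaps the
#' feature's interval by at least one base on the same strand (strand
#' awareness can be toggled). When several features overlap a read the one
#' with the largest overlap wins, ties going to the lowest feature start;
#' reads overlapping nothing are labelled class `"other"`. Interval overlap
#' is computed with `GenomicRanges::findOverlaps`.
#'
#' @param alignments data.frame of retained alignments (mapq at or above
#'   the discard threshold) with `contig`, `start`, `end` (0-based
#'   half-open), `strand`, and any bookkeeping columns (e.g. `read_id`,
#'   `library`).
#' @param annotation annotation data.frame (0-based half-open `start`,
#'   `end`, `strand`, `class`, `feature_id`), validated against
#'   `genome_lengths` when given.
#' @param stranded require same-strand overlap (default TRUE).
#' @param genome_lengths optional named vector of contig lengths for
#'   annotation validation.
#' @return `alignments` with `feature_id` (NA when unassigned) and `class`
#'   (`"other"` when unassigned) columns appended.
#' @export
intersect_features <- function(alignments, annotation, stranded = TRUE,
                               genome_lengths = NULL) {
  if (!is.null(genome_lengths)) {
    glen <- genome_lengths[annotation$contig]
    if (any(is.na(glen)) || any(annotation$start < 0) ||
        any(annotation$end > glen)) {
      stop("annotation intervals fall outside the genome")
    }
  }
  out <- alignments
  out$feature_id <- NA_character_
  out$class <- "other"
  if (!nrow(alignments)) return(out)
  qry <- GenomicRanges::GRanges(
    seqnames = alignments$contig,
    ranges = IRanges::IRanges(start = alignments$start + 1L,
                              end = alignments$end),
    strand = alignments$strand
  )
  sbj <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand
  )
  ov <- GenomicRanges::findOverlaps(qry, sbj, minoverlap = 1L,
                                    ignore.strand = !stranded)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(qry)[qh],
                                            IRanges::ranges(sbj)[sh]))
    # largest overlap wins; ties -> lowest feature start
    o <- order(qh, -w, annotation$start[sh])
    first <- !duplicated(qh[o])
    out$feature_id[qh[o][first]] <- annotation$feature_id[sh[o][first]]
    out$class[qh[o][first]] <- annotation$class[sh[o][first]]
  }
  out
}

#' Build the features x libraries count matrix
#'
#' `counts[i, l]` is the number of reads of library `l` assigned to feature
#' `i`; column marginals reconcile with the retained totals through the
#' unassigned ("other") reads: `colSums(counts) + other = lib_sizes`.
#'
#' @param assignments output of [intersect_features()] with a `library`
#'   column (duplicate read ids in different libraries are counted
#'   independently).
#' @param feature_ids row order of the matrix (default: features observed).
#' @param libraries column order (default: libraries observed).
#' @param conditions optional named vector library -> condition label.
#' @return An object of class `count_matrix`: list(counts, lib_sizes,
#'   other, conditions).
#' @export
count_features <- function(assignments, feature_ids = NULL, libraries = NULL,
                           conditions = NULL) {
  if (is.null(libraries)) libraries <- sort(unique(assignments$library))
  if (is.null(feature_ids)) {
    feature_ids <- sort(unique(assignments$feature_id[!is.na(assignments$feature_id)]))
  }
  counts <- matrix(0L, nrow = length(feature_ids), ncol = length(libraries),
                   dimnames = list(feature_ids, libraries))
  assigned <- assignments[!is.na(assignments$feature_id) &
                            assignments$feature_id %in% feature_ids, , drop = FALSE]
  if (nrow(assigned)) {
    tab <- table(factor(assigned$feature_id, levels = feature_ids),
                 factor(assigned$library, levels = libraries))
    counts[] <- as.integer(tab)
  }
  lib_sizes <- vapply(libraries, function(l) sum(assignments$library == l),
                      numeric(1))
  other <- lib_sizes - colSums(counts)
  structure(list(counts = counts, lib_sizes = lib_sizes, other = other,
                 conditions = conditions),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d features x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  library sizes:", paste(sprintf("%s=%d", names(x$lib_sizes),
                                        as.integer(x$lib_sizes)),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Per-library class composition of retained reads
#'
#' @param assignments output of [intersect_features()] with a `library`
#'   column.
#' @param classes class order (default miRNA, tRNA, rRNA, other).
#' @return data.frame: library, class, n, fraction; fractions sum to one
#'   per library.
#' @export
class_summary <- function(assignments,
                          classes = c("miRNA", "tRNA", "rRNA", "other")) {
  cls <- assignments$class
  cls[!cls %in% classes] <- "other"
  tab <- table(factor(assignments$library),
               factor(cls, levels = classes))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("library", "class", "n")
  tot <- ave(df$n, df$library, FUN = sum)
  df$fraction <- ifelse(tot > 0, df$n / tot, 0)
  df[order(df$library, match(df$class, classes)), , drop = FALSE]
}
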