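# Pair-HMM mapper: seed index, forward likelihood, Phred-scaled mapping
# quality, iterative error-profile estimation, and batch read placement.

#' Build an exhaustive k-mer seed index of the genome
#'
#' Indexes every k-mer of the forward strand of every contig; reverse-strand
#' candidates are obtained at query time from the read's reverse complement.
#'
#' @param genome named character vector of contig sequences.
#' @param k seed length (default 12, <= 31). Values below ~8 are only
#'   useful for toy demonstrations: candidate generation loses specificity.
#' @return An object of class `seed_index`.
#' @export
build_seed_index <- function(genome, k = 12L) {
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  ptr <- cpp_build_index(genome, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), contigs = names(genome),
                 contig_lengths = setNames(nchar(genome), names(genome)),
                 genome = genome),
            class = "seed_index")
}

#' Look up the genome positions of one k-mer
#' @param index a `seed_index`.
#' @param kmer a string of length `k`.
#' @return data.frame(contig, pos) with 0-based forward-strand positions.
#' @export
query_kmer <- function(index, kmer) {
  hits <- cpp_query_kmer(index$ptr, kmer)
  hits$contig <- index$contigs[hits$contig]
  hits
}

#' Candidate alignment windows for one read
#'
#' Every exact k-mer hit of the read (forward strand) or of its reverse
#' complement (minus strand) anchors an implied alignment start; windows of
#' read span +/- `band` are merged per contig and strand when they overlap,
#' ranked by supporting hit count (ties broken by lowest contig, coordinate,
#' then '+' strand) and capped at `max_candidates`. An empty result means
#' the read is unmapped.
#'
#' @param read read sequence (length >= k).
#' @param index a `seed_index`.
#' @param max_candidates cap on returned windows (default 50).
#' @param band extra genome bases on each side of the implied span
#'   (default 3).
#' @return data.frame(contig, wstart, wend, strand, hits), 0-based
#'   half-open windows.
#' @export
candidate_locations <- function(read, index, max_candidates = 50L, band = 3L) {
  if (nchar(read) < index$k) {
    return(data.frame(contig = character(0), wstart = integer(0),
                      wend = integer(0), strand = character(0),
                      hits = integer(0), stringsAsFactors = FALSE))
  }
  cpp_candidates(index$ptr, read, as.integer(band), as.integer(max_candidates))
}

#' Construct a per-cycle error profile
#'
#' @param sub per-cycle substitution probabilities e_j (one per read cycle).
#' @param gap_open probability of opening an insertion or deletion
#'   (transition M->X and M->Y each).
#' @param gap_extend gap extension probability (X->X, Y->Y).
#' @param iteration estimation iteration counter (0 for a prior profile).
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(sub, gap_open = 1e-3, gap_extend = 0.1,
                          iteration = 0L) {
  if (any(sub < 0) || any(sub > 0.75)) {
    stop("per-cycle substitution probabilities must lie in [0, 0.75]")
  }
  if (gap_open < 0 || gap_open > 0.25 || gap_extend < 0 || gap_extend >= 1) {
    stop("invalid gap probabilities")
  }
  structure(list(sub = as.numeric(sub), gap_open = gap_open,
                 gap_extend = gap_extend, iteration = as.integer(iteration)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("Per-cycle error profile: %d cycles, mean e = %.4g (iteration %d)\n",
              length(x$sub), mean(x$sub), x$iteration))
  invisible(x)
}

pad_profile <- function(profile, len) {
  e <- profile$sub
  if (length(e) < len) e <- c(e, rep(e[length(e)], len - length(e)))
  e
}

#' Forward-algorithm likelihood of a read given a genome window
#'
#' Sums the probability of the read over all alignments to the window under
#' a three-state pair HMM (match/mismatch M, read-insertion X, genome-
#' deletion Y). Emission at M for read cycle j is `1 - e_j` on base equality
#' and `e_j/3` otherwise (N counts as a mismatch); X emits 1/4; transitions
#' are `M->X = M->Y = gap_open`, `X->X = Y->Y = gap_extend`, with no X<->Y
#' moves. Alignment is global in the read and local in the window (free,
#' unscored flanks; start offsets are not renormalised). Computation is in
#' linear space, which cannot underflow for reads up to ~100 nt.
#'
#' @param read read sequence.
#' @param window genome window sequence (already reverse-complemented by the
#'   caller for minus-strand hypotheses).
#' @param profile an [error_profile()] covering every read cycle.
#' @return Natural-log likelihood `log P(read | window, profile)`.
#' @export
phmm_forward <- function(read, window, profile) {
  if (length(profile$sub) < nchar(read)) {
    stop("error profile shorter than the read")
  }
  cpp_forward(read, window, profile$sub, profile$gap_open, profile$gap_extend)
}

round_half_up <- function(x) floor(x + 0.5)

#' Phred-scaled mapping quality from candidate likelihoods
#'
#' With a uniform prior over candidate locations, the posterior of the best
#' location is `L_best / sum(L_i)`; the mapping quality is
#' `round(-10*log10(1 - posterior))`, capped. A read whose quality is below
#' `threshold` (default 10, i.e. less than a 90% chance of being placed
#' correctly) is flagged for discarding. Likelihood ties are broken in
#' favour of the earliest candidate, so callers should order candidates by
#' (contig, coordinate).
#'
#' @param loglik numeric vector of natural-log candidate likelihoods,
#'   ordered by (contig, coordinate).
#' @param mapq_cap maximum reported quality (default 60).
#' @param threshold discard threshold on the integer quality (default 10).
#' @return list(best, posterior, mapq, is_discarded).
#' @export
compute_mapq <- function(loglik, mapq_cap = 60L, threshold = 10L) {
  ok <- is.finite(loglik)
  if (!length(loglik) || !any(ok)) stop("all candidate likelihoods are zero")
  best <- which(loglik >= max(loglik[ok]) - 1e-9)[1]
  others <- loglik[-best]
  others <- others[is.finite(others)]
  ll_others <- if (length(others)) logsumexp(others) else -Inf
  ll_total <- logsumexp(c(loglik[best], ll_others))
  mapq <- mapq_from_ll(loglik[best], ll_others, mapq_cap)
  list(best = best,
       posterior = exp(loglik[best] - ll_total),
       mapq = mapq,
       is_discarded = mapq < threshold)
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Vectorised MAPQ from best-candidate and rest-of-candidates log likelihoods.
mapq_from_ll <- function(ll_best, ll_others, mapq_cap = 60L) {
  # log(1 - posterior) = ll_others - logsumexp(ll_best, ll_others)
  m <- pmax(ll_best, ll_others)
  ll_total <- m + log(exp(ll_best - m) + exp(ll_others - m))
  log_pmiss <- ll_others - ll_total
  mapq <- round_half_up(-10 * log_pmiss / log(10))
  mapq[!is.finite(ll_others)] <- Inf
  as.integer(pmin(mapq, mapq_cap))
}

#' Map reads to the genome with the pair HMM
#'
#' For each read, candidate windows are generated from exact k-mer seeds,
#' each window is scored with the forward algorithm, the best location is
#' reported (likelihood ties resolve to the lowest contig/coordinate) with
#' its posterior probability and Phred-scaled mapping quality, and reads
#' with quality below `mapq_threshold` are flagged as discarded rather than
#' dropped. Identical sequences are mapped once and the result reused.
#'
#' @param reads character vector of read sequences (optionally named by read
#'   id) or a data.frame with `read_id` and `seq`.
#' @param index a `seed_index`.
#' @param profile an [error_profile()].
#' @param mapq_threshold discard threshold (default 10).
#' @param band,max_candidates candidate generation parameters.
#' @param mapq_cap maximum mapping quality (default 60).
#' @return data.frame: read_id, seq, mapped, contig, start, end (0-based
#'   half-open), strand, n_candidates, ll_best, posterior, mapq,
#'   is_discarded, cigar, edit.
#' @export
map_reads <- function(reads, index, profile, mapq_threshold = 10L,
                      band = 3L, max_candidates = 50L, mapq_cap = 60L) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- reads$seq
  } else {
    seqs <- unname(reads)
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%07d", seq_along(reads))
  }
  if (!length(seqs)) {
    return(data.frame(read_id = character(0), seq = character(0),
                      mapped = logical(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_candidates = integer(0),
                      ll_best = numeric(0), posterior = numeric(0),
                      mapq = integer(0), is_discarded = logical(0),
                      cigar = character(0), edit = character(0),
                      stringsAsFactors = FALSE))
  }
  useq <- unique(seqs)
  e <- pad_profile(profile, max(nchar(useq)))
  res <- cpp_map_batch(index$ptr, useq, e, profile$gap_open,
                       profile$gap_extend, as.integer(band),
                       as.integer(max_candidates))
  i <- match(seqs, useq)
  mapped <- res$mapped[i]
  ll_best <- res$ll_best[i]
  ll_others <- res$ll_others[i]
  mapq <- rep(NA_integer_, length(seqs))
  post <- rep(NA_real_, length(seqs))
  if (any(mapped)) {
    mapq[mapped] <- mapq_from_ll(ll_best[mapped], ll_others[mapped], mapq_cap)
    m <- pmax(ll_best[mapped], ll_others[mapped])
    post[mapped] <- exp(ll_best[mapped] - (m + log(exp(ll_best[mapped] - m) +
                                                   exp(ll_others[mapped] - m))))
  }
  data.frame(
    read_id = ids, seq = seqs, mapped = mapped,
    contig = res$contig[i], start = res$start[i], end = res$end[i],
    strand = res$strand[i], n_candidates = res$n_candidates[i],
    ll_best = ll_best, posterior = post, mapq = mapq,
    is_discarded = ifelse(mapped, mapq < mapq_threshold, NA),
    cigar = res$cigar[i], edit = res$edit[i],
    stringsAsFactors = FALSE
  )
}

#' Iteratively estimate the per-cycle error profile
#'
#' Alternates (1) mapping all reads with the current profile and (2)
#' re-estimating each cycle's substitution probability from the confidently
#' placed, gapless best alignments:
#' `e_j <- (mismatches at cycle j + alpha) / (aligned bases at cycle j +
#' 4*alpha)` with pseudocount `alpha = 1`. Stops when no cycle moves by more
#' than `tol` or after `max_iter` iterations. When no read maps confidently
#' the initial profile is returned with `no_confident_reads = TRUE`.
#'
#' @param reads character vector (or data.frame with `seq`) of preprocessed
#'   read sequences.
#' @param index a `seed_index`.
#' @param init initial [error_profile()]; default: flat 0.02 over the
#'   longest read.
#' @param max_iter maximum iterations (default 5).
#' @param tol convergence tolerance on `max_j |delta e_j|` (default 1e-4).
#' @param confident_mapq minimum mapping quality for a read to contribute to
#'   the estimate (default 20).
#' @param alpha pseudocount (default 1).
#' @param ... passed to [map_reads()].
#' @return An `error_profile` with fields `iteration` (iterations run),
#'   `converged`, `loglik_trace` (summed best-alignment log likelihood per
#'   iteration) and `no_confident_reads`.
#' @export
estimate_error_profile <- function(reads, index, init = NULL, max_iter = 5L,
                                   tol = 1e-4, confident_mapq = 20L,
                                   alpha = 1, ...) {
  seqs <- if (is.data.frame(reads)) reads$seq else unname(reads)
  if (!length(seqs)) stop("no reads")
  lmax <- max(nchar(seqs))
  if (is.null(init)) init <- error_profile(rep(0.02, lmax))
  profile <- init
  profile$sub <- pad_profile(profile, lmax)
  # map unique sequences, weight tallies by multiplicity
  tab <- table(seqs)
  useq <- names(tab)
  w <- as.vector(tab)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    aln <- map_reads(useq, index, profile, ...)
    conf <- aln$mapped & aln$mapq >= confident_mapq &
      !grepl("[ID]", aln$cigar)
    trace <- c(trace, sum(aln$ll_best[aln$mapped] * w[aln$mapped]))
    if (!any(conf)) {
      out <- init
      out$iteration <- iter
      out$converged <- FALSE
      out$no_confident_reads <- TRUE
      out$loglik_trace <- trace
      warning("no confidently mapped reads; returning the initial profile")
      return(out)
    }
    mm <- numeric(lmax)
    nn <- numeric(lmax)
    edits <- strsplit(aln$edit[conf], "")
    wc <- w[conf]
    for (r in seq_along(edits)) {
      ed <- edits[[r]]
      jj <- seq_along(ed)
      nn[jj] <- nn[jj] + wc[r]
      x <- jj[ed == "X"]
      if (length(x)) mm[x] <- mm[x] + wc[r]
    }
    e_new <- (mm + alpha) / (nn + 4 * alpha)
    delta <- max(abs(e_new - profile$sub))
    profile$sub <- e_new
    profile$iteration <- iter
    if (delta < tol) { converged <- TRUE; break }
  }
  profile$converged <- converged
  profile$no_confident_reads <- FALSE
  profile$loglik_trace <- trace
  profile
}
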