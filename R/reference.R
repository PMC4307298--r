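#' Generate the toy reference genome, annotation and expression truth
#'
#' Builds a single random contig (i.i.d. uniform bases given the seed) with
#' one designated exact two-copy repeat, lays out non-overlapping miRNA,
#' tRNA-like and rRNA-like loci, and draws the per-feature expression truth:
#' lognormal base means and an exactly assigned down/up fold-change spectrum
#' for the knockdown condition. Contaminant loci receive no true fold change
#' and their base means are scaled so that the expected contaminant read
#' fraction matches `contaminant_fraction`.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `reference_bundle`: a list with `genome`
#'   (named character vector of contig sequences), `annotation` (data.frame
#'   with 0-based half-open `start`/`end`, `strand`, `class`, `feature_id`),
#'   `truth` (feature_id, class, base_mean, true_log2FC), `repeat_region`
#'   (two rows giving the repeat copies) and the `config`.
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n_mir <- config$n_mirna
    n_cont <- config$n_contaminant_loci
    n_trna <- round(0.7 * n_cont)
    n_rrna <- n_cont - n_trna
    widths <- c(
      sample(seq(config$mirna_length_range[1], config$mirna_length_range[2]),
             n_mir, replace = TRUE),
      sample(70:90, n_trna, replace = TRUE),
      sample(100:150, n_rrna, replace = TRUE)
    )
    classes <- c(rep("miRNA", n_mir), rep("tRNA", n_trna), rep("rRNA", n_rrna))
    feature_id <- c(sprintf("mir-%03d", seq_len(n_mir)),
                    if (n_trna) sprintf("trna-%03d", seq_len(n_trna)),
                    if (n_rrna) sprintf("rrna-%03d", seq_len(n_rrna)))
    # layout: features plus the two repeat copies, separated by random gaps
    unit_w <- c(widths, config$repeat_length, config$repeat_length)
    n_units <- length(unit_w)
    slack <- config$genome_length - sum(unit_w) - n_units  # >= 1 bp between units
    if (slack < 0) {
      stop("genome_length too small to place the requested features without overlap")
    }
    ord <- sample.int(n_units)
    gaps <- as.vector(rmultinom(1, slack, rep(1, n_units + 1))) + c(rep(1L, n_units), 0L)
    starts_ordered <- cumsum(gaps[seq_len(n_units)]) +
      cumsum(c(0L, unit_w[ord][-n_units]))
    start <- integer(n_units)
    start[ord] <- as.integer(starts_ordered)
    end <- start + unit_w

    genome_chars <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)
    # exact two-copy repeat: overwrite copy 2 with copy 1
    rep_idx <- c(n_units - 1L, n_units)
    r1 <- (start[rep_idx[1]] + 1L):end[rep_idx[1]]
    r2 <- (start[rep_idx[2]] + 1L):end[rep_idx[2]]
    genome_chars[r2] <- genome_chars[r1]
    genome <- c(chr_sim = paste(genome_chars, collapse = ""))

    keep <- seq_len(length(widths))
    annotation <- data.frame(
      contig = "chr_sim", start = start[keep], end = end[keep],
      strand = sample(c("+", "-"), length(keep), replace = TRUE),
      class = classes, feature_id = feature_id,
      stringsAsFactors = FALSE
    )

    base_mean <- rlnorm(n_mir, meanlog = log(config$mean_depth),
                        sdlog = config$base_mean_sdlog)
    lfc <- numeric(n_mir)
    n_down <- round(config$frac_down * n_mir)
    n_up <- round(config$frac_up * n_mir)
    de_idx <- sample.int(n_mir, n_down + n_up)
    if (n_down) {
      lfc[de_idx[seq_len(n_down)]] <-
        -log2(runif(n_down, config$fc_range_down[1], config$fc_range_down[2]))
    }
    if (n_up) {
      lfc[de_idx[n_down + seq_len(n_up)]] <-
        log2(runif(n_up, config$fc_range_up[1], config$fc_range_up[2]))
    }
    cont_mean <- numeric(0)
    if (n_cont > 0) {
      raw <- rlnorm(n_cont, meanlog = log(config$mean_depth),
                    sdlog = config$base_mean_sdlog)
      cf <- config$contaminant_fraction
      cont_mean <- raw * (cf / (1 - cf)) * sum(base_mean) / sum(raw)
    }
    truth <- data.frame(
      feature_id = feature_id, class = classes,
      base_mean = c(base_mean, cont_mean),
      true_log2FC = c(lfc, rep(0, n_cont)),
      stringsAsFactors = FALSE
    )
    repeat_region <- data.frame(
      contig = "chr_sim",
      start = start[rep_idx], end = end[rep_idx],
      copy = c(1L, 2L), stringsAsFactors = FALSE
    )
    # discrete processed-fragment species for the contaminant loci: tRNA and
    # rRNA degradation yields a few dominant fragments per locus, not a
    # uniform shred
    fragment_species <- NULL
    if (n_cont > 0) {
      nsp <- config$fragment_species_per_locus
      cont <- annotation[annotation$class != "miRNA", , drop = FALSE]
      fid <- rep(cont$feature_id, each = nsp)
      width <- rep(cont$end - cont$start, each = nsp)
      lo <- pmin(config$insert_length_range[1], width)
      hi <- pmin(config$insert_length_range[2], width)
      flen <- lo + floor(runif(length(fid)) * (hi - lo + 1))
      foff <- floor(runif(length(fid)) * (width - flen + 1))
      w <- stats::rexp(length(fid))
      fragment_species <- data.frame(
        feature_id = fid, offset = as.integer(foff), length = as.integer(flen),
        weight = w / ave(w, fid, FUN = sum), stringsAsFactors = FALSE
      )
    }
    bundle <- list(genome = genome, annotation = annotation, truth = truth,
                   repeat_region = repeat_region,
                   fragment_species = fragment_species, config = config)
    class(bundle) <- "reference_bundle"
    validate_reference(bundle)
    bundle
  })
}

validate_reference <- function(bundle) {
  ann <- bundle$annotation
  glen <- nchar(bundle$genome[ann$contig])
  if (any(ann$start < 0) || any(ann$end > glen) || any(ann$start >= ann$end)) {
    stop("annotation intervals must lie within contig bounds")
  }
  if (anyDuplicated(ann$feature_id)) stop("feature_ids must be unique")
  # non-overlap (all features, which subsumes the miRNA requirement)
  o <- order(ann$start)
  if (any(ann$start[o][-1] < ann$end[o][-nrow(ann)])) {
    stop("features must not overlap")
  }
  invisible(bundle)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("Reference bundle: %d contig(s), %d bp; %d features (%s)\n",
              length(x$genome), sum(nchar(x$genome)), nrow(x$annotation),
              paste(sprintf("%s=%d", names(table(x$annotation$class)),
                            as.integer(table(x$annotation$class))), collapse = ", ")))
  cat(sprintf("  exact repeat: %d bp at %d and %d\n", x$config$repeat_length,
              x$repeat_region$start[1], x$repeat_region$start[2]))
  invisible(x)
}

#' Extract feature sequences (strand-aware)
#'
#' @param bundle a `reference_bundle`.
#' @return Named character vector of feature sequences; minus-strand features
#'   are reverse-complemented so the returned sequence is the transcribed one.
#' @export
feature_sequences <- function(bundle) {
  ann <- bundle$annotation
  seqs <- substring(bundle$genome[ann$contig], ann$start + 1L, ann$end)
  minus <- ann$strand == "-"
  seqs[minus] <- vapply(seqs[minus], cpp_revcomp, character(1), USE.NAMES = FALSE)
  setNames(seqs, ann$feature_id)
}

#' Draw one library of per-feature counts
#'
#' Counts for feature i are negative-binomial with mean
#' `base_mean_i * 2^(true_log2FC_i)` in the knockdown condition (the base
#' mean in the control) and dispersion `phi` from the configuration;
#' `phi = 0` degenerates to Poisson.
#'
#' @param bundle a `reference_bundle`.
#' @param condition `"control"` or `"knockdown"`.
#' @param seed integer seed; defaults to the config seed offset by condition
#'   so the two libraries are independent but reproducible.
#' @return Named integer vector of counts over all features.
#' @export
draw_counts <- function(bundle, condition = c("control", "knockdown"), seed = NULL) {
  condition <- match.arg(condition)
  cfg <- bundle$config
  if (is.null(seed)) {
    seed <- cfg$seed + if (condition == "knockdown") 104729L else 7919L
  }
  truth <- bundle$truth
  mu <- truth$base_mean * 2^(truth$true_log2FC * (condition == "knockdown"))
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    counts <- if (cfg$dispersion == 0) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    }
    setNames(as.integer(counts), truth$feature_id)
  })
}
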