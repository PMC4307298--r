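#' Configuration for the synthetic knockdown screen
#'
#' Bundles every knob of the synthetic-data generator: the toy genome and
#' annotation, the negative-binomial expression truth, the adaptor/barcode
#' read layout and the per-cycle sequencing error truth. Defaults describe a
#' two-sample (control vs knockdown) screen pooled into a single barcoded
#' library: ~18-24 nt mature miRNA loci, a tRNA/rRNA contaminant fraction of
#' half the reads, a down-biased fold-change spectrum, and a mildly rising
#' Illumina-like error profile.
#'
#' @param seed integer seed controlling every random draw.
#' @param n_mirna number of mature miRNA loci.
#' @param n_contaminant_loci number of contaminant (tRNA/rRNA) loci; about
#'   70% are laid out as tRNA-sized (70-90 bp) and the rest rRNA-sized
#'   (100-150 bp) fragments.
#' @param genome_length toy genome size in bp (single contig).
#' @param mirna_length_range inclusive range of mature miRNA widths (nt).
#' @param frac_down,frac_up fractions of miRNA loci truly down-/upregulated
#'   in the knockdown; assigned exactly (rounded counts), not sampled.
#' @param fc_range_down fold-change interval for downregulated loci (a value
#'   f drawn uniformly gives true log2FC = -log2(f)).
#' @param fc_range_up fold-change interval for upregulated loci.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi*mu^2); 0 degenerates to Poisson. The default 0.01 reflects the
#'   near-technical variability of two libraries sequenced from one pooled
#'   lane.
#' @param mean_depth expected reads per feature per library (median of the
#'   lognormal base-mean distribution).
#' @param base_mean_sdlog lognormal sdlog of per-feature base means.
#' @param contaminant_fraction expected fraction of all reads drawn from
#'   contaminant loci (default 0.5, emulating the high tRNA content of
#'   broad-range small-RNA libraries).
#' @param error_profile_truth numeric vector of per-cycle substitution error
#'   probabilities (length >= read_length); default ramps 0.001 to 0.01.
#' @param read_length sequencer read length in cycles. Must fit the 25-nt
#'   5' adaptor+barcode prefix plus the smallest insert.
#' @param barcode_map named character vector sample -> 4-nt barcode.
#' @param conditions named character vector sample -> condition
#'   ("control"/"knockdown").
#' @param adapter5 5' adaptor template with a literal "XXXX" barcode slot.
#' @param adapter3 DNA portion of the 3' adaptor, searched during trimming.
#' @param insert_length_range length range for contaminant-locus subfragment
#'   inserts (miRNA inserts are the full mature sequence).
#' @param fragment_species_per_locus number of discrete processed-fragment
#'   species per contaminant locus (tRNA/rRNA degradation is dominated by a
#'   few specific fragments, not uniform shredding; this also lets
#'   contaminants survive the abundance filter the way real fragments do).
#' @param repeat_length length of the designated exact two-copy genomic
#'   repeat (>= 30 bp) used to exercise mapping-quality logic.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_mirna = 100L,
                       n_contaminant_loci = 20L,
                       genome_length = 100000L,
                       mirna_length_range = c(18L, 24L),
                       frac_down = 0.4,
                       fc_range_down = c(2, 4),
                       frac_up = 0.05,
                       fc_range_up = c(1.5, 2),
                       dispersion = 0.01,
                       mean_depth = 500,
                       base_mean_sdlog = 0.5,
                       contaminant_fraction = 0.5,
                       error_profile_truth = NULL,
                       read_length = 72L,
                       barcode_map = c(control = "ACGT", knockdown = "GTCA"),
                       conditions = c(control = "control", knockdown = "knockdown"),
                       adapter5 = "ACAGGTTCAGAGTTCTACAGXXXXA",
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       insert_length_range = c(15L, 30L),
                       fragment_species_per_locus = 3L,
                       repeat_length = 40L) {
  if (is.null(error_profile_truth)) {
    error_profile_truth <- seq(0.001, 0.01, length.out = read_length)
  }
  cfg <- list(
    seed = as.integer(seed), n_mirna = as.integer(n_mirna),
    n_contaminant_loci = as.integer(n_contaminant_loci),
    genome_length = as.integer(genome_length),
    mirna_length_range = as.integer(mirna_length_range),
    frac_down = frac_down, fc_range_down = fc_range_down,
    frac_up = frac_up, fc_range_up = fc_range_up,
    dispersion = dispersion, mean_depth = mean_depth,
    base_mean_sdlog = base_mean_sdlog,
    contaminant_fraction = contaminant_fraction,
    error_profile_truth = error_profile_truth,
    read_length = as.integer(read_length),
    barcode_map = barcode_map, conditions = conditions,
    adapter5 = adapter5, adapter3 = adapter3,
    insert_length_range = as.integer(insert_length_range),
    fragment_species_per_locus = as.integer(fragment_species_per_locus),
    repeat_length = as.integer(repeat_length)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, is.finite(cfg$seed),
    cfg$n_mirna >= 1L, cfg$n_contaminant_loci >= 0L, cfg$genome_length >= 100L,
    length(cfg$mirna_length_range) == 2L,
    cfg$mirna_length_range[1] <= cfg$mirna_length_range[2],
    cfg$mirna_length_range[1] >= 1L
  )
  if (cfg$frac_down < 0 || cfg$frac_up < 0 || cfg$frac_down + cfg$frac_up > 1) {
    stop("frac_down and frac_up must be non-negative with frac_down + frac_up <= 1")
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (any(cfg$error_profile_truth < 0) || any(cfg$error_profile_truth > 1)) {
    stop("error_profile_truth probabilities must lie in [0, 1]")
  }
  if (length(cfg$error_profile_truth) < cfg$read_length) {
    stop("error_profile_truth must cover every read cycle")
  }
  tags <- cfg$barcode_map
  if (length(tags) < 1L || any(nchar(tags) != 4L) || anyDuplicated(tags) ||
      is.null(names(tags)) || anyDuplicated(names(tags))) {
    stop("barcode_map must map uniquely named samples to distinct 4-nt tags")
  }
  if (!grepl("XXXX", cfg$adapter5, fixed = TRUE)) {
    stop("adapter5 must contain the literal XXXX barcode slot")
  }
  if (!setequal(names(cfg$conditions), names(cfg$barcode_map))) {
    stop("conditions must be named by the same samples as barcode_map")
  }
  slot <- regexpr("XXXX", cfg$adapter5, fixed = TRUE)
  prefix_len <- as.integer(slot) - 1L + 4L +
    (nchar(cfg$adapter5) - (as.integer(slot) + 3L))
  if (cfg$read_length < prefix_len + cfg$insert_length_range[1]) {
    stop("read_length is shorter than the 5' adaptor/barcode prefix plus the minimal insert")
  }
  if (cfg$repeat_length < 30L) stop("repeat_length must be >= 30 bp")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic small-RNA screen configuration\n")
  cat(sprintf("  seed %d | genome %d bp | %d miRNA loci | %d contaminant loci\n",
              x$seed, x$genome_length, x$n_mirna, x$n_contaminant_loci))
  cat(sprintf("  frac down/up %.2f/%.2f at %g-%gx | dispersion %.3g | mean depth %g\n",
              x$frac_down, x$frac_up, x$fc_range_down[1], x$fc_range_down[2],
              x$dispersion, x$mean_depth))
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s[%s]", names(x$barcode_map), x$barcode_map),
                    collapse = ", ")))
  invisible(x)
}
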