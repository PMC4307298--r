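# End-to-end orchestration: simulate -> preprocess -> map -> quantify ->
# test, with per-stage artifacts, a machine-readable ledger of read counts,
# and (on simulated data) confusion metrics against the truth.

#' Run the full screen pipeline on simulated (or provided) data
#'
#' Executes every stage in order, writing each stage's artifact in its
#' standard format plus a JSON run report. Stage read counts are ledgered so
#' inputs always equal outputs plus rejections. When the input is simulated
#' the report also contains mapping and differential-expression confusion
#' metrics against the generator's truth.
#'
#' @param config a [sim_config()] describing the simulated screen, or a list
#'   with `genome`, `annotation`, `manifest` and `reads` for pre-existing
#'   data (all in the package's standard data.frame forms).
#' @param outdir output directory (created); `NULL` keeps everything in
#'   memory.
#' @param min_total low-abundance threshold (default 10 across all
#'   libraries).
#' @param length_range inclusive insert length window (default c(15, 50),
#'   the broad initial screen; use c(15, 30) for the miRNA-targeted rerun).
#' @param mapq_threshold mapping-quality discard threshold (default 10).
#' @param fdr FDR threshold for DE calls (default 0.05).
#' @param k,band,max_candidates mapper parameters.
#' @param blocklist artifact sequences rejected during trimming.
#' @param test_class feature class carried into the exact test (default
#'   "miRNA", as the screen tests miRNAs only).
#' @return A list of class `screen_report`; see Details.
#' @details The report fields: `ledger` (per-stage read counts), `profile`
#'   (estimated error profile), `class_composition`, `counts`
#'   (`count_matrix`), `de` (`de_result`), `confusion` (simulated truth
#'   comparison: mapping accuracy, down/up recall and direction errors) and
#'   `paths` of written artifacts.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         min_total = 10L, length_range = c(15L, 50L),
                         mapq_threshold = 10L, fdr = 0.05, k = 12L,
                         band = 3L, max_candidates = 50L,
                         blocklist = character(0), test_class = "miRNA") {
  simulate <- inherits(config, "sim_config")
  paths <- list()
  ledger <- list()
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) {
    if (is.null(outdir)) return(NULL)
    p <- file.path(outdir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  # on stage failure: keep partial outputs, drop a FAILED marker, abort with
  # the stage name
  stage <- "setup"
  tryCatch({

  ## stage 1: simulate (or load)
  stage <- "simulate"
  if (simulate) {
    bundle <- generate_reference(config)
    counts_true <- list(
      control = draw_counts(bundle, "control"),
      knockdown = draw_counts(bundle, "knockdown")
    )
    reads <- synthesize_fastq(bundle, counts_true)
    manifest <- data.frame(
      sample = names(config$barcode_map),
      tag = unname(config$barcode_map),
      condition = unname(config$conditions[names(config$barcode_map)]),
      library = names(config$barcode_map),
      stringsAsFactors = FALSE
    )
    truth <- reads[, c("read_id", "sample", "feature_id", "origin_start",
                       "origin_end", "strand")]
    emit("genome.fasta", function(p) write_genome_fasta(bundle$genome, p))
    emit("annotation.bed", function(p) write_bed(bundle$annotation, p))
    emit("reads.fastq", function(p) write_fastq(reads, p))
    emit("manifest.tsv", function(p) write_manifest(manifest, p))
    emit("truth.tsv", function(p) write.table(
      merge(truth, bundle$truth, by = "feature_id"), p,
      sep = "\t", quote = FALSE, row.names = FALSE))
    genome <- bundle$genome
    annotation <- bundle$annotation
    adapter5 <- config$adapter5
    adapter3 <- config$adapter3
  } else {
    genome <- config$genome
    annotation <- config$annotation
    manifest <- config$manifest
    reads <- config$reads
    adapter5 <- if (!is.null(config$adapter5)) config$adapter5 else
      "ACAGGTTCAGAGTTCTACAGXXXXA"
    adapter3 <- if (!is.null(config$adapter3)) config$adapter3 else
      "TCGTATGCCGTCTTCTGCTTG"
    bundle <- NULL
    truth <- NULL
  }
  ledger$input_reads <- nrow(reads)

  ## stage 2: preprocess
  stage <- "preprocess"
  dm <- demultiplex(reads, manifest, adapter5)
  assigned <- dm[dm$sample != "UNASSIGNED", , drop = FALSE]
  ledger$demux_assigned <- nrow(assigned)
  ledger$demux_unassigned <- ledger$input_reads - nrow(assigned)
  tr <- trim_adapter3(assigned, adapter3, blocklist = blocklist)
  kept <- tr[!tr$rejected, , drop = FALSE]
  ledger$trim_rejected <- sum(tr$rejected)
  lensel <- select_length(kept, length_range[1], length_range[2])
  ledger$length_filtered <- nrow(kept) - nrow(lensel)
  filt <- filter_low_abundance(lensel, min_total)
  ledger$low_abundance_filtered <- nrow(lensel) - nrow(filt)
  ledger$preprocessed <- nrow(filt)
  if (!nrow(filt)) stop("preprocess: no reads survive the filters")
  filt$library <- filt$sample
  emit("preprocessed.fastq", function(p) write_fastq(filt, p))

  ## stage 3: error-profile estimation + mapping
  stage <- "map"
  index <- build_seed_index(genome, k)
  profile <- estimate_error_profile(filt$seq, index, band = band,
                                    max_candidates = max_candidates)
  emit("error_profile.tsv", function(p) write_error_profile(profile, p))
  aln <- map_reads(filt, index, profile, mapq_threshold = mapq_threshold,
                   band = band, max_candidates = max_candidates)
  aln$library <- filt$library
  aln$sample <- filt$sample
  ledger$mapped <- sum(aln$mapped)
  ledger$unmapped <- sum(!aln$mapped)
  ledger$mapq_discarded <- sum(aln$mapped & aln$is_discarded)
  ledger$retained_alignments <- sum(aln$mapped & !aln$is_discarded)
  emit("mapped.sam", function(p) write_sam(aln, genome, p))

  ## stage 4: quantify
  stage <- "quantify"
  retained <- aln[aln$mapped & !aln$is_discarded, , drop = FALSE]
  asg <- intersect_features(retained, annotation,
                            genome_lengths = nchar(genome))
  comp <- class_summary(asg)
  cm <- count_features(asg, feature_ids = annotation$feature_id,
                       libraries = manifest$library,
                       conditions = setNames(manifest$condition,
                                             manifest$library))
  emit("counts.tsv", function(p) write_counts(cm, p))
  emit("class_summary.tsv", function(p) write.table(
    comp, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## stage 5: exact NB test on the tested class
  stage <- "test"
  test_ids <- annotation$feature_id[annotation$class %in% test_class]
  ctrl_lib <- manifest$library[manifest$condition == "control"][1]
  test_lib <- manifest$library[manifest$condition == "knockdown"][1]
  sub <- cm$counts[test_ids, c(ctrl_lib, test_lib), drop = FALSE]
  de <- de_test(sub, lib_sizes = cm$lib_sizes[c(ctrl_lib, test_lib)],
                fdr = fdr)
  emit("de_results.tsv", function(p) write.table(
    as.data.frame(de), p, sep = "\t", quote = FALSE, row.names = FALSE))
  ledger$features_tested <- nrow(de)

  ## confusion metrics against simulation truth
  confusion <- NULL
  if (simulate) {
    tt <- bundle$truth
    truth_call <- ifelse(tt$true_log2FC < 0, "down",
                         ifelse(tt$true_log2FC > 0, "up", "null"))
    names(truth_call) <- tt$feature_id
    obs <- as.character(de$call)
    names(obs) <- de$feature_id
    tc <- truth_call[de$feature_id]
    n_true_down <- sum(truth_call[test_ids] == "down")
    n_true_up <- sum(truth_call[test_ids] == "up")
    confusion <- list(
      n_true_down = n_true_down,
      n_true_up = n_true_up,
      down_recall = if (n_true_down) sum(obs == "down" & tc == "down") / n_true_down else NA,
      up_recall = if (n_true_up) sum(obs == "up" & tc == "up") / n_true_up else NA,
      direction_errors = sum((obs == "down" & tc == "up") |
                               (obs == "up" & tc == "down")),
      false_calls_on_null = sum(obs != "ns" & tc == "null")
    )
  }

  s <- attr(de, "summary")
  report <- list(
    config = config, ledger = ledger, profile = profile,
    class_composition = comp, counts = cm, de = de,
    dispersion = attr(de, "dispersion"),
    n_down = unname(s["n_down"]), n_up = unname(s["n_up"]),
    n_ns = unname(s["n_ns"]),
    confusion = confusion, paths = paths,
    alignments = aln
  )
  class(report) <- "screen_report"
  if (!is.null(outdir)) {
    rep_json <- report[c("ledger", "n_down", "n_up", "n_ns")]
    rep_json$phi <- attr(de, "dispersion")$phi
    rep_json$class_composition <- comp
    rep_json$confusion <- confusion
    rep_json$seed <- if (simulate) config$seed else NA
    jsonlite::write_json(rep_json, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
  }, error = function(e) {
    if (!is.null(outdir)) {
      writeLines(c(stage, conditionMessage(e)), file.path(outdir, "FAILED"))
    }
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Small-RNA screen run report\n")
  cat("  ledger:\n")
  for (nm in names(x$ledger)) cat(sprintf("    %-24s %d\n", nm, x$ledger[[nm]]))
  cat(sprintf("  dispersion phi = %.4g; features tested = %d\n",
              x$dispersion$phi, nrow(x$de)))
  cat(sprintf("  at FDR < %g: %d down, %d up, %d ns\n",
              attr(x$de, "fdr"), x$n_down, x$n_up, x$n_ns))
  if (!is.null(x$confusion)) {
    cat(sprintf("  truth: %d down / %d up; down recall %.2f, direction errors %d\n",
                x$confusion$n_true_down, x$confusion$n_true_up,
                x$confusion$down_recall, x$confusion$direction_errors))
  }
  invisible(x)
}

#' Read a pipeline run configuration from YAML
#'
#' A thin front door for the command-line wrapper: the `simulate:` section
#' holds [sim_config()] fields, the `thresholds:` section the pipeline
#' filter settings.
#'
#' @param path YAML file.
#' @return list(config, thresholds).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulate
  cfg <- do.call(sim_config, sim[names(sim) %in% names(formals(sim_config))])
  thresholds <- y$thresholds
  list(config = cfg, thresholds = thresholds)
}
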