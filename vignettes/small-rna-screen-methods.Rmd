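---
title: "Methods: simulating and analysing a barcoded small-RNA knockdown screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a barcoded small-RNA knockdown screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design being modelled

`srnascreen` re-implements, at desk scale, the computational arm of a
small-RNA deep-sequencing knockdown screen: total small RNA from a control
and a knockdown sample is ligated to a 5' adaptor carrying a sample-specific
four-nucleotide barcode and to a common 3' adaptor, pooled into one
sequencing library, and sequenced on a single lane. Reads are demultiplexed,
adaptor-trimmed, filtered, mapped to the genome with a pair hidden Markov
model (pHMM) that learns its own per-cycle error rates, intersected with
miRNA annotation, and tested for differential expression with an exact
conditional negative-binomial (NB) test — with the dispersion estimated by
treating the two compared libraries as replicates of one group, because the
design has no biological replicates.

Every stage is an exported function; `run_pipeline()` chains them and
ledgers read counts so that input always equals output plus rejections.

# The synthetic-data generator

`sim_config()` + `generate_reference()` + `draw_counts()` +
`synthesize_fastq()` produce a complete, self-contained instance of the
screen. The generator is first-class, tested code: its statistical structure
is what every downstream stage is validated against.

**Genome and annotation.** A single random contig (i.i.d. uniform bases,
default 100 kb) carries non-overlapping mature-miRNA-sized loci (18–24 nt;
the screen counts reads over mature boundaries, not hairpins), tRNA-sized
(70–90 bp) and rRNA-sized (100–150 bp) contaminant loci, and one designated
exact two-copy repeat (default 40 bp) placed away from all features to
exercise the mapping-quality logic.

**Expression truth.** Per-miRNA base means are lognormal around
`mean_depth` (default 500 reads/feature/library, sdlog 0.5 — a deeply
sequenced pooled lane). An exactly assigned fraction of miRNAs (default
40%) is downregulated in the knockdown by a uniform 2–4× fold change, and
5% upregulated by 1.5–2×; contaminant loci never change. Counts are NB with
dispersion `phi` (variance `mu + phi*mu^2`); the default `phi = 0.01`
reflects near-technical variability of two libraries prepared from one
pooled lane, the situation in which treating them as pseudo-replicates is
least wrong. `phi = 0` degenerates to Poisson.

**Contaminant fragments.** Half of all reads (by expectation) come from
tRNA/rRNA loci, emulating the high tRNA content of broad-range small-RNA
libraries. Each contaminant locus expresses a small set of discrete
processed-fragment species (default 3, with random weights) rather than
uniform random subfragments: real tRNA/rRNA degradation is dominated by a
few specific fragments, and only discrete species behave correctly under
the screen's "seen at least 10 times" abundance filter.

**Read synthesis.** Each counted read is
`5'-adaptor(barcode)-insert-3'-adaptor-3'`, truncated to the read length,
with substitution errors injected per sequencing cycle from
`error_profile_truth` (default: a mild Illumina-like ramp from 0.001 to
0.01). The read length default is 72 nt: the 25-nt in-read adaptor/barcode
prefix plus a 15–30 nt insert plus enough 3' adaptor for trimming cannot
fit into a shorter early-Illumina read, and the pipeline's own length
filters (15–50 nt / 15–30 nt) require the insert to be fully recoverable.
Quality strings encode the *true* per-cycle error rate in Phred+33; the
mapper deliberately ignores them and estimates its own profile. Indels are
not simulated by default (the mapper still models them); this keeps the
placement truth exactly recoverable.

**What the generator does not emulate** — and hence what green tests do not
certify about real data: ligation/sequence bias, PCR duplicates, the
enzymatic pretreatments distinguishing 5'-cap/hydroxyl RNA classes,
isomiR ends, overlapping or clustered miRNA loci, and genome-scale
repetitiveness beyond the single designated repeat.

# Preprocessing rules

* **Demultiplexing** (`demultiplex()`): a read is assigned iff the 4-mer in
  the barcode slot matches a manifest tag *exactly* after the constant
  adaptor prefix matches with at most one mismatch. Four-nucleotide
  barcodes leave no room for tag tolerance. Assigned reads lose
  adaptor+barcode+trailing constant base; unassigned reads are kept
  untouched so counts reconcile.
* **3' adaptor trimming** (`trim_adapter3()`): the leftmost suffix matching
  a prefix of the adaptor with ≥ 5 nt overlap and ≤ 10% mismatches is
  removed. Empty inserts and exact artifact sequences (e.g. the transfected
  siRNA strands, supplied as a blocklist) are rejected — rejection is a
  result, not an error.
* **Abundance filter** (`filter_low_abundance()`): a distinct insert
  sequence is kept iff its total count across *all* libraries is ≥ 10
  ("found less than 10 times" read literally: exactly 10 is kept). The
  filter works on exact strings, before mapping, and is idempotent and
  order-independent.
* **Length windows** (`select_length()`): inclusive on both ends; 15–50 nt
  for a broad screen, 15–30 nt when targeting the miRNA fraction.

# The pair-HMM mapper

**Candidates.** An exhaustive k-mer index (default k = 12) of the genome's
forward strand anchors candidate windows from every exact k-mer hit of the
read or of its reverse complement; windows (read span ± 3 nt band) are
merged per contig/strand when they overlap, ranked by supporting hits and
capped (default 50). This is exact on the toy genome; no FM-index is
attempted, and genome-scale performance is out of scope.

**Model.** Three states: match/mismatch `M`, read-insertion `X`,
genome-deletion `Y`. At read cycle `j`, `M` emits the read base with
probability `1 - e_j` on equality and `e_j/3` otherwise (N counts as a
mismatch); `X` emits 1/4; `Y` is silent. Transitions:
`M->X = M->Y = gap_open` (default 1e-3), `X->X = Y->Y = gap_extend`
(default 0.1), no `X<->Y`. Alignments are global in the read, local in the
window: they start and end in `M` or `X`, flanking window bases are free
and start offsets are not renormalised (a perfect read therefore has
log-likelihood 0 regardless of window length). The forward algorithm runs
in linear probability space — products over ≤ ~100 cycles stay far above
double underflow — and the reported alignment comes from a Viterbi
traceback in the same model. Likelihood ties between candidate locations
(within 1e-9 log units) resolve to the lowest (contig, coordinate).

**Mapping quality.** With a uniform prior over the discovered candidates,
`posterior = L_best / sum(L_i)` and
`MAPQ = round(-10 log10(1 - posterior))`, rounded half-up, capped at 60; a
single candidate maps to the cap. Reads with integer MAPQ < 10 (posterior
< ~0.90) are flagged discarded but still written to the SAM output as
unmapped-with-tag, never silently dropped. The posterior is computed over
discovered candidates only — there is no explicit unmapped hypothesis; the
exhaustive index keeps missed-candidate risk negligible at toy scale. Two
exact repeat copies give posterior 1/2 and MAPQ 3, hence discard.

**Error-profile estimation** (`estimate_error_profile()`) is a hard EM:
map all reads with the current profile; over confidently placed (MAPQ ≥
20), gapless best alignments re-estimate
`e_j = (mismatches_j + 1) / (aligned_j + 4)` (pseudocount 1); stop when no
cycle moves by more than 1e-4 or after 5 iterations. The initial profile is
flat 0.02. Cycle positions are read cycles, not genome positions — the
standard choice for sequencer error. If nothing maps confidently the
initial profile is returned with a warning flag. Identical read sequences
are mapped once and re-weighted, which is what makes 50,000-read profile
estimation take seconds.

# Quantification

Retained alignments (MAPQ ≥ 10) are intersected with the annotation via
`GenomicRanges::findOverlaps`: ≥ 1 bp same-strand overlap assigns a read;
among several overlapping features the largest overlap wins, ties to the
lowest feature start; everything else is class "other". Strand awareness is
a flag (`stranded = FALSE` reproduces strand-blind intersection). Counts
are per feature × library with column marginals reconciling through the
"other" class; `class_summary()` reports the per-library miRNA/tRNA/rRNA/
other composition.

# The exact NB test without replicates

1. **Equalization** (`equalize_libraries()`): counts are scaled to the
   geometric-mean library size `N* = sqrt(N1*N2)` and rounded, so the exact
   test's conditioning on integer totals applies. This scale-and-round
   equalization deliberately replaces the original tool's quantile
   adjustment: it preserves the conditioning structure while remaining
   self-contained, and is a documented deviation.
2. **Dispersion** (`estimate_common_dispersion()`): the two libraries are
   treated as replicates of one group; conditioning each feature on its
   total removes the mean, and the summed conditional log-likelihood is
   maximised over `phi` in [0, 10] (golden-section via `optimize`,
   tolerance 1e-6; the zero boundary is checked explicitly). Features with
   total 0 are excluded.
3. **Exact test** (`exact_test()`): conditional on `s = a + b`, the split
   follows a mean-free law; the two-sided p-value sums the masses of all
   outcomes with mass ≤ the observed one (1e-12 slack on log masses makes
   floating-point ties deterministic). `phi = 0` reduces to
   Binomial(s, 1/2). For `phi > 1` the conditional law is U-shaped
   (beta-binomial shape `1/phi < 1`), so p is then *not* monotone in
   |a − b| — maximal imbalance is the mode and receives p = 1. This is a
   property of the small-mass convention, not a defect; the screen's
   estimated dispersions stay well below 1.
4. **Adjustment and calls**: Benjamini–Hochberg step-up (via
   `stats::p.adjust`), calls at FDR < 5% with the strict boundary (q
   exactly 0.05 is not called); `log2FC = log2((pseudo_b + 0.5) /
   (pseudo_a + 0.5))` with the 0.5 pseudo-count affecting reporting only.

# Power of the pseudo-replicate design — a deliberate caveat

Treating the two *compared* libraries as replicates makes every true fold
change look like biological noise. With 40% of features truly changed
2–4×, the pooled conditional-ML dispersion estimate lands around 0.2
regardless of the true dispersion (0.001–0.05) or the depth (200–20,000
reads/feature): in the conditional beta limit the proportion
`a/(a+b)` has variance `1/(4(2r+1))`, `r = 1/phi`, *independent of depth*,
so detecting a 2× change (proportion 1/3 vs 1/2) needs `phi` below ~0.06 —
far below what pseudo-replicate pooling returns when 40% of the features
carry real signal. The simulated default screen therefore calls few or no
features at FDR < 5% despite 40 truly-down miRNAs; the confusion metrics in
the run report quantify this. This conservatism is intrinsic to the
no-replicate design being modelled, not a numerical artifact: the same
behaviour is reproduced by the reference implementation of the exact test
when driven the same way. Any direction that *is* called, however, is
essentially always correct (the test never saw a direction error across the
acceptance simulations).

# Problem sizes and numerical settings

The shipped tests and the acceptance script use: a 100 kb genome with 100
miRNA and 20 contaminant loci; 2,000-feature count simulations for
dispersion recovery and type-I error; 50,000 reads for error-profile
recovery; 2,000 reads for placement accuracy; 200 random read/window pairs
(reads ≤ 8 nt, windows ≤ 20 nt) against an exhaustive alignment-sum oracle
at 1e-9 log tolerance; exact-test enumeration for all totals ≤ 50 at
`phi` in {0, 0.1, 0.5, 2} at 1e-10. These sizes were chosen so every
stochastic check sits well inside its Monte-Carlo tolerance while a full
run stays interactive on a laptop.

# Known limitations

* No base-quality-aware emissions: the pHMM trusts its estimated per-cycle
  profile, not the FASTQ qualities (by design — the simulator's qualities
  encode the truth the mapper must not peek at).
* No spliced or gapped-beyond-band alignment; no genome-scale index.
* Multi-mapping reads are resolved to a single best location or discarded;
  no fractional counting, no 5p/3p arm disambiguation, no isomiR analysis.
* The DE module is strictly two-group, single-library-per-group; tagwise or
  trended dispersion and GLM designs are out of scope.
* Equivalence to the original analysis is claimed at the level of the
  method class (conditional NB exact test with pooled common dispersion),
  not bit-level output of any particular tool version.
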