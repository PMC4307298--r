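# Exact conditional negative-binomial two-group test without replicates:
# library-size equalization, common dispersion by pseudo-replicate pooling,
# per-feature exact test, BH adjustment, FDR calls.

#' Equalize two libraries to their geometric mean size
#'
#' Scales each library's counts to the common size `N* = sqrt(N1*N2)` and
#' rounds to integers so the exact test's conditioning on integer totals
#' applies; original counts are kept for reporting.
#'
#' @param counts integer matrix with two columns (control, test) or a
#'   `count_matrix` restricted to two libraries.
#' @param lib_sizes per-library totals (defaults to column sums, or the
#'   `count_matrix` lib_sizes).
#' @return list(pseudo (integer matrix), counts, lib_sizes, n_star).
#' @export
equalize_libraries <- function(counts, lib_sizes = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(lib_sizes)) lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  if (ncol(counts) != 2L) stop("exactly two libraries (control, test) required")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  n_star <- sqrt(prod(lib_sizes))
  pseudo <- round(sweep(counts, 2L, n_star / lib_sizes, `*`))
  storage.mode(pseudo) <- "integer"
  list(pseudo = pseudo, counts = counts, lib_sizes = lib_sizes, n_star = n_star)
}

# Conditional log-likelihood of dispersion phi for one group of two
# equal-size replicate libraries: conditioning each feature on its total
# removes the mean parameter.
cond_loglik_phi <- function(phi, a, b) {
  s <- a + b
  if (phi < 1e-10) {
    return(sum(lchoose(s, a) - s * log(2)))
  }
  r <- 1 / phi
  sum(lgamma(a + r) + lgamma(b + r) + lgamma(2 * r) - 2 * lgamma(r) -
        lgamma(s + 2 * r) + lchoose(s, a))
}

#' Common dispersion by pseudo-replicate pooling
#'
#' In the absence of replicates the two compared libraries are treated as
#' replicates of a single group: the negative-binomial dispersion phi is the
#' maximizer of the summed per-feature conditional log-likelihood given each
#' feature's total (which removes the mean parameter), searched on [0, 10]
#' to a tolerance of 1e-6. Features with total zero carry no information and
#' are excluded. Note that any true fold change between the libraries
#' inflates this estimate — the price of having no replicates.
#'
#' @param pseudo two-column integer matrix of equalized counts (see
#'   [equalize_libraries()]).
#' @return An object of class `dispersion_estimate`: list(phi, method,
#'   n_features_used).
#' @export
estimate_common_dispersion <- function(pseudo) {
  a <- pseudo[, 1]
  b <- pseudo[, 2]
  keep <- (a + b) > 0
  if (!any(keep)) stop("all feature totals are zero")
  a <- a[keep]; b <- b[keep]
  opt <- optimize(function(phi) cond_loglik_phi(phi, a, b),
                  interval = c(0, 10), maximum = TRUE, tol = 1e-6)
  phi <- opt$maximum
  # the optimizer cannot land exactly on the boundary; snap when the
  # boundary is at least as good
  if (cond_loglik_phi(0, a, b) >= opt$objective) phi <- 0
  structure(list(phi = phi, method = "pseudo-replicate-pooled",
                 n_features_used = sum(keep)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Common NB dispersion (pseudo-replicate pooled): phi = %.4g over %d features\n",
              x$phi, x$n_features_used))
  invisible(x)
}

# log conditional mass of x successes given total s for two i.i.d. NB
# observations with dispersion phi (mean cancels); phi = 0 is Binomial(s, 1/2)
cond_log_mass <- function(s, phi) {
  x <- 0:s
  lw <- if (phi < 1e-10) {
    lchoose(s, x) - s * log(2)
  } else {
    r <- 1 / phi
    lgamma(x + r) + lgamma(s - x + r) - lgamma(x + 1) - lgamma(s - x + 1)
  }
  lw - logsumexp(lw)
}

#' Exact conditional negative-binomial test for two counts
#'
#' Conditional on the total `s = a + b`, two i.i.d. NB(mean, phi) counts
#' give a distribution over splits `(x, s - x)` that is free of the mean;
#' the two-sided p-value is the sum of the conditional masses of all
#' outcomes whose mass does not exceed the observed outcome's mass (with a
#' 1e-12 slack on log masses to make floating-point ties deterministic).
#' `phi = 0` reduces the conditional law to Binomial(s, 1/2). Vectorised
#' over features.
#'
#' @param a,b non-negative integer counts from the equalized libraries.
#' @param phi common NB dispersion (>= 0).
#' @return p-values in (0, 1]; a feature with `a + b = 0` returns 1.
#' @export
exact_test <- function(a, b, phi) {
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  if (phi < 0) stop("phi must be >= 0")
  mapply(function(ai, bi) {
    s <- ai + bi
    if (s == 0) return(1)
    lw <- cond_log_mass(s, phi)
    lobs <- lw[ai + 1]
    min(1, sum(exp(lw[lw <= lobs + 1e-12])))
  }, a, b)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} min(1, m * p_(j) / j)` in
#' sorted order, mapped back to the input order (delegated to
#' `stats::p.adjust`).
#'
#' @param pvals p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
adjust_bh <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  p.adjust(pvals, method = "BH")
}

#' Call differential expression at an FDR threshold
#'
#' `down` when `q < fdr` and log2FC < 0, `up` when `q < fdr` and
#' log2FC > 0, `ns` otherwise ("false discovery rate less than 5%" is
#' strict: q exactly at the threshold is not called).
#'
#' @param results data.frame with `q` and `log2FC`.
#' @param fdr threshold (default 0.05).
#' @return `results` with a `call` factor (down/up/ns) appended, sorted by
#'   q then feature_id.
#' @export
call_de <- function(results, fdr = 0.05) {
  call <- rep("ns", nrow(results))
  call[results$q < fdr & results$log2FC < 0] <- "down"
  call[results$q < fdr & results$log2FC > 0] <- "up"
  results$call <- factor(call, levels = c("down", "up", "ns"))
  o <- if ("feature_id" %in% names(results)) {
    order(results$q, results$feature_id)
  } else {
    order(results$q)
  }
  results[o, , drop = FALSE]
}

#' Exact NB differential expression between two libraries
#'
#' The full test pipeline of the screen: equalize library sizes to the
#' geometric mean, estimate the common dispersion by treating the two
#' libraries as pseudo-replicates, run the per-feature exact conditional
#' test, adjust with Benjamini-Hochberg, and call features at the FDR
#' threshold. Fold changes are `log2((pseudo_test + 0.5) /
#' (pseudo_control + 0.5))` — the pseudo-count only guards the zero case
#' and does not affect p-values. Zero-total features are excluded from
#' testing.
#'
#' @param counts two-column matrix (control, test) or `count_matrix`.
#' @param lib_sizes per-library totals (see [equalize_libraries()]).
#' @param fdr FDR threshold for calls (default 0.05).
#' @return A data.frame of class `de_result`: feature_id, count_control,
#'   count_test, pseudo_control, pseudo_test, log2FC, p, q, call; the
#'   dispersion estimate and the n down/up/ns summary are attached as
#'   attributes `dispersion` and `summary`.
#' @export
de_test <- function(counts, lib_sizes = NULL, fdr = 0.05) {
  eq <- equalize_libraries(counts, lib_sizes)
  keep <- rowSums(eq$pseudo) > 0
  disp <- estimate_common_dispersion(eq$pseudo[keep, , drop = FALSE])
  a <- eq$pseudo[keep, 1]
  b <- eq$pseudo[keep, 2]
  p <- exact_test(a, b, disp$phi)
  q <- adjust_bh(p)
  res <- data.frame(
    feature_id = rownames(eq$pseudo)[keep],
    count_control = eq$counts[keep, 1],
    count_test = eq$counts[keep, 2],
    pseudo_control = a, pseudo_test = b,
    log2FC = log2((b + 0.5) / (a + 0.5)),
    p = p, q = q, stringsAsFactors = FALSE, row.names = NULL
  )
  res <- call_de(res, fdr)
  attr(res, "dispersion") <- disp
  attr(res, "summary") <- c(n_down = sum(res$call == "down"),
                            n_up = sum(res$call == "up"),
                            n_ns = sum(res$call == "ns"))
  attr(res, "fdr") <- fdr
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  s <- attr(x, "summary")
  d <- attr(x, "dispersion")
  cat(sprintf("Exact NB test: %d features, phi = %.4g; at FDR < %g: %d down, %d up, %d ns\n",
              nrow(x), d$phi, attr(x, "fdr"), s["n_down"], s["n_up"], s["n_ns"]))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Bar plot of per-feature fold changes
#'
#' Features ordered by fold change; called features highlighted.
#' @param de a `de_result`.
#' @param main plot title.
#' @export
plot_fold_changes <- function(de, main = "Per-feature log2 fold change") {
  o <- order(de$log2FC)
  cols <- c(down = "steelblue", up = "firebrick", ns = "grey70")
  graphics::barplot(de$log2FC[o], col = cols[as.character(de$call[o])],
                    border = NA, main = main, ylab = "log2FC (test/control)")
  graphics::legend("topleft", legend = names(cols), fill = cols, bty = "n")
}
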