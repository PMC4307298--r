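test_that("library equalization scales to the geometric mean size", {
  m <- cbind(control = c(10L, 0L, 7L), test = c(40L, 0L, 7L))
  eq <- equalize_libraries(m, lib_sizes = c(1000, 4000))
  expect_equal(eq$n_star, 2000)
  expect_equal(unname(eq$pseudo[1, ]), c(20L, 20L))
  expect_equal(unname(eq$pseudo[2, ]), c(0L, 0L))   # all-zero stays zero
  # equal library sizes leave counts unchanged
  eq2 <- equalize_libraries(m, lib_sizes = c(3000, 3000))
  expect_equal(unname(eq2$pseudo), unname(m))
  expect_error(equalize_libraries(m, lib_sizes = c(0, 10)), "positive")
  expect_error(equalize_libraries(m[, 1, drop = FALSE]), "two libraries")
})

test_that("pseudo-replicate pooled dispersion recovers the truth on null data", {
  set.seed(61)
  n <- 2000
  mu <- rlnorm(n, log(150), 0.4)
  a <- rnbinom(n, mu = mu, size = 1 / 0.2)
  b <- rnbinom(n, mu = mu, size = 1 / 0.2)
  est <- estimate_common_dispersion(cbind(a, b))
  expect_lt(abs(est$phi - 0.2), 0.05)
  expect_equal(est$method, "pseudo-replicate-pooled")
  expect_equal(est$n_features_used, sum(a + b > 0))
  # Poisson data pushes the estimate to the zero boundary
  ap <- rpois(n, mu); bp <- rpois(n, mu)
  expect_lte(estimate_common_dispersion(cbind(ap, bp))$phi, 0.02)
  # degenerate single feature: no overdispersion evidence from (k, k)
  one <- estimate_common_dispersion(cbind(50L, 50L))
  expect_equal(one$n_features_used, 1L)
  expect_lte(one$phi, 0.02)
  expect_error(estimate_common_dispersion(cbind(0L, 0L)), "zero")
})

test_that("dispersion agrees with edgeR's common-dispersion estimate", {
  set.seed(67)
  n <- 1000
  mu <- rlnorm(n, log(200), 0.3)
  counts <- cbind(rnbinom(n, mu = mu, size = 1 / 0.15),
                  rnbinom(n, mu = mu, size = 1 / 0.15))
  est <- estimate_common_dispersion(counts)
  d <- edgeR::estimateCommonDisp(edgeR::DGEList(counts = counts, group = c(1, 1)))
  expect_lt(abs(est$phi - d$common.dispersion), 0.02)
})

test_that("exact test matches its closed-form and enumeration oracles", {
  # (5,5) at phi 0: the observed outcome is the mode, so every outcome counts
  expect_equal(exact_test(5, 5, 0), 1)
  # (0,10) at phi 0: only {0,10} have mass <= 1/1024
  expect_equal(exact_test(0, 10, 0), 2 / 1024, tolerance = 1e-12)
  # general case against the dnbinom-product oracle
  expect_equal(exact_test(2, 8, 0.5), oracle_exact_test(2, 8, 0.5),
               tolerance = 1e-10)
  set.seed(71)
  for (i in 1:30) {
    s <- sample(1:50, 1); a <- sample(0:s, 1)
    phi <- sample(c(0, 0.1, 0.5, 2), 1)
    expect_equal(exact_test(a, s - a, phi), oracle_exact_test(a, s - a, phi),
                 tolerance = 1e-10)
  }
  expect_error(exact_test(-1, 5, 0.1), "non-negative")
  expect_error(exact_test(1, 5, -0.1), "phi")
})

test_that("exact test is symmetric and monotone in imbalance", {
  for (phi in c(0, 0.1, 0.5, 2)) {
    for (s in c(6, 17, 30)) {
      p <- exact_test(0:s, s:0, phi)
      expect_equal(p, rev(p), tolerance = 1e-12)            # symmetry
      expect_true(all(p > 0 & p <= 1))
      # monotonicity in |a - b| holds only while the conditional law is
      # unimodal (1/phi >= 1); at phi = 2 it is U-shaped by design
      if (phi <= 1) {
        half <- p[seq_len(floor(s / 2) + 1)]
        expect_true(all(diff(half) >= -1e-12))
      }
    }
  }
})

test_that("exact test agrees with edgeR's small-p exact test", {
  set.seed(73)
  a <- rnbinom(50, mu = 60, size = 10)
  b <- rnbinom(50, mu = 60, size = 10)
  phi <- 0.1
  ours <- exact_test(a, b, phi)
  theirs <- edgeR::exactTestBySmallP(matrix(a, ncol = 1), matrix(b, ncol = 1),
                                     dispersion = phi)
  expect_equal(ours, as.vector(theirs), tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_identical(adjust_bh(numeric(0)), numeric(0))
  set.seed(79)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DE calls respect the strict FDR boundary and sort order", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2FC = c(-1.2, 0.8, -0.5, 0.4),
                    q = c(0.049, 0.01, 0.05, 0.2), stringsAsFactors = FALSE)
  out <- call_de(res, fdr = 0.05)
  expect_equal(as.character(out$call[match("a", out$feature_id)]), "down")
  expect_equal(as.character(out$call[match("b", out$feature_id)]), "up")
  expect_equal(as.character(out$call[match("c", out$feature_id)]), "ns")  # q = fdr exactly
  expect_equal(as.character(out$call[match("d", out$feature_id)]), "ns")
  expect_equal(out$feature_id, c("b", "a", "c", "d"))  # sorted by q then id
})

test_that("the full test wrapper reports fold changes, q-values and a summary", {
  set.seed(83)
  n <- 300
  mu <- rlnorm(n, log(120), 0.4)
  lfc <- rep(0, n); lfc[1:30] <- -2.5  # strong, detectable signal
  counts <- cbind(control = rnbinom(n, mu = mu, size = 100),
                  test = rnbinom(n, mu = mu * 2^lfc, size = 100))
  rownames(counts) <- sprintf("f%03d", 1:n)
  de <- de_test(counts)
  expect_s3_class(de, "de_result")
  s <- attr(de, "summary")
  expect_equal(unname(sum(s)), nrow(de))
  expect_gt(s["n_down"], 0)
  down_ids <- de$feature_id[de$call == "down"]
  expect_gte(mean(down_ids %in% sprintf("f%03d", 1:30)), 0.9)  # FDR-level purity
  # log2FC uses the 0.5 pseudo-count on equalized counts
  i <- match("f001", de$feature_id)
  expect_equal(de$log2FC[i],
               log2((de$pseudo_test[i] + 0.5) / (de$pseudo_control[i] + 0.5)))
})
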