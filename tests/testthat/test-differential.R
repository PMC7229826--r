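test_that("spike size factors are ratios to the geometric mean", {
  expect_equal(spike_size_factors(c(1000, 1000)), c(1, 1))
  expect_equal(spike_size_factors(c(1000, 2000)),
               c(0.70711, 1.41421), tolerance = 1e-5)
  expect_equal(sum(log(spike_size_factors(c(300, 1700, 900)))), 0,
               tolerance = 1e-12)
  # permutation equivariance
  s <- c(500, 2500, 1200)
  expect_equal(spike_size_factors(s)[c(2, 3, 1)],
               spike_size_factors(s[c(2, 3, 1)]))
  expect_error(spike_size_factors(c(0, 100)), "pseudo")
})

test_that("BH adjustment matches the hand step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # untested features excluded from m
  expect_equal(bh_adjust(c(0.025, NA)), c(0.025, NA))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification thresholds follow the FDR class definitions", {
  lfc <- c(1.2, 0.1, 0.5, -2, 0.3, NA)
  fdr <- c(0.05, 0.7, 0.3, 0.01, 0.5, NA)
  expect_equal(classify_features(lfc, fdr),
               c("up", "unchanged", "indeterminate", "down",
                 "indeterminate", "untested"))
})

test_that("exact null symmetry: identical groups give log2fc 0 and p 1", {
  k <- rbind(f1 = c(10, 10, 10, 10))
  fit <- nb_diff(k, c("C", "C", "T", "T"), contrast = c("T", "C"))
  expect_equal(fit$table$log2fc, 0)
  expect_equal(fit$table$wald_p, 1)
})

test_that("all-zero features are untested; non-integer counts are rejected", {
  k <- rbind(z = c(0, 0, 0, 0), a = c(5, 6, 9, 11))
  fit <- nb_diff(k, c("C", "C", "T", "T"), contrast = c("T", "C"))
  expect_equal(fit$table$class[1], "untested")
  expect_true(is.na(fit$table$wald_p[1]))
  expect_false(is.na(fit$table$wald_p[2]))
  expect_error(nb_diff(rbind(c(1.5, 2, 3, 4)), c("C", "C", "T", "T")),
               "integer")
})

test_that("Poisson limit matches the closed-form Poisson GLM oracle", {
  k <- rbind(f = c(4, 6, 18, 22))
  fit <- nb_diff(k, c("C", "C", "T", "T"), contrast = c("T", "C"),
                 dispersion = 0)
  expect_equal(fit$table$log2fc, 2, tolerance = 1e-12)
  # oracle: two-group Poisson GLM, Fisher information 1/sum(K) per group
  beta1 <- log(40 / 10)
  se <- sqrt(1 / 10 + 1 / 40)
  p_oracle <- 2 * pnorm(-beta1 / se)
  expect_equal(fit$table$wald_p, p_oracle, tolerance = 1e-9)
  expect_equal(fit$table$se, se / log(2), tolerance = 1e-9)
})

test_that("log2fc is exactly invariant to scaling one sample with its spike total", {
  set.seed(5)
  k <- matrix(rnbinom(400, mu = 50, size = 10), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  spikes <- c(900, 1100, 1000, 1050)
  cond <- c("C", "C", "T", "T")
  f0 <- nb_diff(k, cond, contrast = c("T", "C"), spike_totals = spikes)
  for (kscale in c(3, 10)) {
    k2 <- k; k2[, 2] <- k[, 2] * kscale
    sp2 <- spikes; sp2[2] <- spikes[2] * kscale
    f2 <- nb_diff(k2, cond, contrast = c("T", "C"), spike_totals = sp2)
    expect_equal(f2$table$log2fc, f0$table$log2fc, tolerance = 1e-6)
  }
})

test_that("spike normalization recovers a global shift that library size hides", {
  ch <- simulate_chip_peaks(gamma = 1, delta = 0,
                            depth_distortion = c(1, 1, 0.5, 0.5), seed = 8)
  fit_sp <- nb_diff(ch$counts, ch$samples$condition,
                    contrast = c("treated", "control"),
                    spike_totals = ch$samples$spike_total)
  fit_ls <- nb_diff(ch$counts, ch$samples$condition,
                    contrast = c("treated", "control"),
                    size_factors = library_size_factors(ch$samples$primary_total))
  expect_equal(median(fit_sp$table$log2fc), 1, tolerance = 0.15)
  expect_equal(median(fit_ls$table$log2fc), 0, tolerance = 0.15)
})

test_that("a group with no reads yields a large fold change, not a degenerate p", {
  k <- rbind(f = c(0, 0, 60, 80))
  fit <- nb_diff(k, c("C", "C", "T", "T"), contrast = c("T", "C"))
  expect_true(fit$table$log2fc > 5)
  expect_true(fit$table$wald_p < 0.05)
})

test_that("nb_diff agrees with DESeq2 on a shared design", {
  set.seed(6)
  mu <- rep(c(40, 200), each = 100)
  fc <- rep(c(1, 2.5), times = 100)
  k <- cbind(rnbinom(200, mu = mu, size = 20), rnbinom(200, mu = mu, size = 20),
             rnbinom(200, mu = mu * fc, size = 20),
             rnbinom(200, mu = mu * fc, size = 20))
  colnames(k) <- paste0("s", 1:4)
  cond <- c("C", "C", "T", "T")
  fit <- nb_diff(k, cond, contrast = c("T", "C"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      k, S4Vectors::DataFrame(condition = factor(cond, c("C", "T"))),
      ~condition)
    DESeq2::sizeFactors(dds) <- rep(1, 4)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("condition", "T", "C"))
  })
  ok <- !is.na(res$log2FoldChange) & !is.na(fit$table$log2fc)
  expect_gt(cor(fit$table$log2fc[ok], res$log2FoldChange[ok]), 0.98)
  expect_gt(cor(-log10(fit$table$wald_p[ok] + 1e-12),
                -log10(res$pvalue[ok] + 1e-12), method = "spearman"), 0.9)
})
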