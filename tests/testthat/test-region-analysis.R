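test_that("peak merging requires literal overlap, never book-ending", {
  a <- data.frame(chrom = "chr2L", start = 100, end = 200, name = "p1")
  b <- data.frame(chrom = "chr2L", start = 150, end = 250, name = "q1")
  m <- merge_overlapping_peaks(list(A = a, B = b))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100, 250))
  expect_equal(m$sources, "A:p1,B:q1")
  # book-ended: two regions
  b2 <- data.frame(chrom = "chr2L", start = 200, end = 300, name = "q1")
  m2 <- merge_overlapping_peaks(list(A = a, B = b2))
  expect_equal(nrow(m2), 2L)
  # chained overlaps collapse to one span
  ch <- data.frame(chrom = "chrX", start = c(0, 80, 160),
                   end = c(100, 180, 260), name = c("a", "b", "c"))
  m3 <- merge_overlapping_peaks(ch)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start, m3$end), c(0, 260))
  expect_equal(m3$n_sources, 3L)
})

test_that("peak merging agrees exactly with the brute-force closure oracle", {
  set.seed(30)
  for (i in 1:500) {
    n <- sample(1:12, 1)
    df <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                     start = sample(0:80, n, replace = TRUE))
    df$end <- df$start + sample(1:30, n, replace = TRUE)
    got <- merge_overlapping_peaks(df)[, c("chrom", "start", "end")]
    want <- oracle_merge(df)
    got <- got[order(got$chrom, got$start), ]
    want <- want[order(want$chrom, want$start), ]
    rownames(got) <- rownames(want) <- NULL
    got$chrom <- as.character(got$chrom)
    want$chrom <- as.character(want$chrom)
    expect_equal(got, want)
  }
})

test_that("blacklist filtering uses half-open >= 1 bp overlap", {
  bl <- data.frame(chrom = "chr2L", start = 40, end = 60)
  peaks <- data.frame(chrom = "chr2L", start = c(10, 10, 59),
                      end = c(50, 40, 80), name = c("in", "touch", "tail"))
  kept <- suppressMessages(filter_blacklist(peaks, bl))
  expect_setequal(kept$name, "touch")      # [10,40) vs [40,60): retained
  expect_identical(filter_blacklist(peaks, bl[0, ]), peaks)
})

test_that("peak-to-gene assignment keeps the largest absolute change per promoter", {
  g <- make_gene(tss = 5000)
  peaks <- data.frame(chrom = "chr2L", start = c(3900, 4500, 2000),
                      end = c(4100, 4700, 2500),
                      name = c("pA", "pB", "far"),
                      log2fc = c(0.5, 1.5, 3))
  got <- assign_peaks_to_genes(peaks, g, promoter_halfwidth = 1000)
  expect_equal(nrow(got), 1L)
  expect_equal(got$peak_name, "pB")        # 1.5 beats 0.5; 'far' not assigned
  expect_equal(got$log2fc, 1.5)
  # the negative direction also counts via |log2fc|
  peaks$log2fc <- c(-2.5, 1.5, 0)
  expect_equal(assign_peaks_to_genes(peaks, g)$peak_name, "pA")
  # window is half-open: peak starting at tss+hw does not overlap
  edge <- data.frame(chrom = "chr2L", start = 6000, end = 6100,
                     name = "edge", log2fc = 9)
  expect_equal(nrow(assign_peaks_to_genes(edge, g)), 0L)
})

test_that("z-scores standardize per feature and flag constant columns", {
  m <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  rownames(m) <- c("a", "b", "c")
  ez <- suppressMessages(enrichment_zscores(m))
  expect_equal(unname(ez$z[, "f1"]), c(-1, 0, 1))
  expect_equal(unname(ez$z[, "f2"]), c(0, 0, 0))
  expect_equal(ez$constant_features, "f2")
  expect_equal(unname(set_mean_z(ez, c("a", "b", "c"))), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(set_mean_z(ez, "c")["f1"]), 1)
})

test_that("state overlap fractions count promoters hitting each state", {
  gs <- do.call(rbind, lapply(1:4, function(i)
    make_gene(paste0("g", i), tss = i * 10000)))
  states <- data.frame(chrom = "chr2L",
                       start = c(9600, 19600, 0, 0),
                       end = c(10200, 20200, 1, 100000),
                       name = c("d5", "d5", "null", "all"))
  fr <- state_overlap_fraction(gs, states, promoter_halfwidth = 500)
  expect_equal(unname(fr["d5"]), 0.5)
  expect_equal(unname(fr["null"]), 0)
  expect_equal(unname(fr["all"]), 1)
  expect_error(state_overlap_fraction(gs[0, ], states), "empty")
})

test_that("enhancer classification thresholds summit-to-TSS distance at 100 bp", {
  g <- make_gene(tss = 5000)
  pk <- function(s) data.frame(chrom = "chr2L", start = s - 50, end = s + 50,
                               name = "p", summit = s)
  expect_equal(classify_enhancers(pk(5050), g)$class, "promoter_proximal")
  expect_equal(classify_enhancers(pk(5101), g)$class, "enhancer")
  expect_equal(classify_enhancers(pk(5000), g)$class, "promoter_proximal")
  expect_equal(classify_enhancers(pk(5100), g)$class, "promoter_proximal")
  expect_error(classify_enhancers(pk(5000), g[0, ]), "genes")
})

test_that("fold-change correlation handles exact and null relationships", {
  x <- c(-1, 0, 1, 2, 3)
  r <- fc_correlation(x, 2 * x)
  expect_equal(r$pearson, 1); expect_equal(r$spearman, 1)
  expect_equal(fc_correlation(x, -x)$pearson, -1)
  # non-finite pairs dropped and counted
  r2 <- fc_correlation(c(x, NA), c(2 * x, 5))
  expect_equal(r2$n, 5); expect_equal(r2$n_dropped, 1)
  expect_error(fc_correlation(c(1, 2, NA), c(1, 2, 3)), "3 finite")
  # independent draws stay near zero
  set.seed(31)
  hits <- sum(vapply(1:20, function(i)
    abs(fc_correlation(rnorm(1000), rnorm(1000))$pearson) < 0.1, logical(1)))
  expect_gte(hits, 19)
})

test_that("fold-gain thresholding is strict at log2(1.5)", {
  lfc <- c(gA = 0.6, gB = log2(1.5), gC = -1, gD = 2)
  expect_setequal(threshold_gain_set(lfc), c("gA", "gD"))
  expect_setequal(threshold_gain_set(lfc, fold = 1), c("gA", "gB", "gD"))
})

test_that("log2 IP-over-input is zero at equality and scale invariant", {
  ip <- make_track(pos = c(100, 101, 250), count = c(4, 4, 8))
  expect_true(all(log2_ip_over_input(ip, ip)$value == 0))
  # ip = 4x input in the pseudocount -> 0 limit
  inp <- make_track(pos = c(100, 101, 250), count = c(1, 1, 2))
  v <- log2_ip_over_input(ip, inp, pseudocount = 1e-9)
  expect_equal(v$value, rep(2, nrow(v)), tolerance = 1e-6)
  # doubling ip counts and its factor changes nothing
  ip2 <- make_track(pos = c(100, 101, 250), count = c(8, 8, 16))
  expect_equal(log2_ip_over_input(ip2, inp, ip_size_factor = 2),
               log2_ip_over_input(ip, inp, ip_size_factor = 1))
  expect_error(log2_ip_over_input(ip, inp, ip_size_factor = 0), "factor")
})

test_that("half-open windows never overlap at a shared boundary anywhere", {
  a <- data.frame(chrom = "c", start = 0, end = 10)
  b <- data.frame(chrom = "c", start = 10, end = 20)
  expect_equal(nrow(merge_overlapping_peaks(list(a, b))), 2L)
  expect_identical(filter_blacklist(a, b), a)
  g <- make_gene(tss = 10000)
  st <- data.frame(chrom = "chr2L", start = 10500, end = 10600, name = "s")
  expect_equal(unname(state_overlap_fraction(g, st, 500)), 0)
})

test_that("acetylation coupling recovers a shared target signal", {
  sim <- small_sim(seed = 55)
  cp <- acetylation_coupling(sim, seed = 56)
  expect_gt(cp$correlation$pearson, 0.3)   # small n; full check in acceptance
  expect_equal(nrow(cp$per_gene), 60)
  cp0 <- acetylation_coupling(sim, delta = 0, gamma = 0, seed = 57)
  tgt <- sim$truth$gene_id[sim$truth$is_target]
  g_ace <- with(cp0$per_gene, mean(acetylation_log2fc[gene_id %in% tgt]) -
                              mean(acetylation_log2fc[!gene_id %in% tgt]))
  expect_lt(abs(g_ace), 0.5)               # no acetylation signal when delta 0
})
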