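test_that("canonical transcript selection prefers longest CDS, then longest transcript, then smallest id", {
  ann <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC", "gC", "gD", "gD"),
    transcript_id = c("tA1", "tA2", "tB1", "tC2", "tC1", "tD1", "tD2"),
    chrom = "chr2L", strand = "+",
    txStart = c(0, 0, 100, 200, 200, 300, 300),
    txEnd = c(2000, 2500, 1600, 2200, 1700, 1300, 1300),
    cdsStart = c(0, 0, 100, 200, 200, 300, 300),
    cdsEnd = c(900, 300, 700, 800, 800, 900, 900))
  g <- suppressMessages(read_gene_annotation(write_annotation(ann)))
  # longest CDS wins (900 vs 300)
  expect_equal(g$transcript_id[g$gene_id == "gA"], "tA1")
  # single transcript: identity
  expect_equal(g$transcript_id[g$gene_id == "gB"], "tB1")
  # equal CDS 600: longer transcript (2000 vs 1500) wins
  expect_equal(g$transcript_id[g$gene_id == "gC"], "tC2")
  # equal CDS and length: lexicographically smallest id
  expect_equal(g$transcript_id[g$gene_id == "gD"], "tD1")
  expect_equal(nrow(g), 4L)
})

test_that("gene models are strand-aware and short genes are flagged but retained", {
  ann <- data.frame(gene_id = c("gP", "gM"), transcript_id = c("tP", "tM"),
                    chrom = "chr3R", strand = c("+", "-"),
                    txStart = c(1000, 5000), txEnd = c(4000, 5500),
                    cdsStart = c(1000, 5000), cdsEnd = c(4000, 5500))
  g <- suppressMessages(read_gene_annotation(write_annotation(ann)))
  gp <- g[g$gene_id == "gP", ]; gm <- g[g$gene_id == "gM", ]
  expect_equal(gp$tss, 1000); expect_equal(gp$tes, 3999)
  expect_equal(gm$tss, 5499); expect_equal(gm$tes, 5000)
  expect_false(gp$short); expect_true(gm$short)
  expect_equal(gm$length, 500)
})

test_that("annotation errors: duplicates and bad strand", {
  base <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c",
                     strand = "+", txStart = 0, txEnd = 100,
                     cdsStart = 0, cdsEnd = 100)
  expect_error(read_gene_annotation(write_annotation(rbind(base, base))),
               "duplicate")
  bad <- base; bad$strand <- "*"
  expect_error(read_gene_annotation(write_annotation(bad)), "strand")
})

test_that("read_end_counts separates spike reads and tallies duplicates", {
  p <- write_reads_bed(chrom = c("chr2L", "chr2L", "chr2L", "spike_chr1",
                                 "spike_chr1"),
                       start = c(100, 100, 250, 7, 9),
                       strand = c("+", "+", "-", "+", "+"))
  trk <- read_end_counts(p)
  expect_equal(trk$primary_total, 3L)
  expect_equal(trk$spike_total, 2L)
  expect_equal(trk$counts$count[trk$counts$pos == 100 &
                                trk$counts$strand == "+"], 2L)
  # idempotent
  expect_identical(read_end_counts(p)$counts, trk$counts)
})

test_that("read_end_counts validates record width and handles empty files", {
  empty <- tempfile(fileext = ".bed"); file.create(empty)
  trk <- read_end_counts(empty)
  expect_equal(trk$primary_total, 0L)
  expect_equal(trk$spike_total, 0L)
  wide <- tempfile(fileext = ".bed")
  writeLines("chr2L\t10\t20\t.\t0\t+", wide)
  expect_error(read_end_counts(wide), "line 1")
})

test_that("bedGraph writing merges equal-value runs and scales by the size factor", {
  trk <- make_track(pos = c(100, 101, 105), count = c(2, 2, 1))
  p <- tempfile(fileext = ".bedgraph")
  write_bedgraph(trk, p, size_factor = 1, strand = "+")
  bg <- read_bedgraph(p)
  expect_equal(bg$start, c(100, 105))
  expect_equal(bg$end, c(102, 106))
  expect_equal(bg$value, c(2, 1))
  write_bedgraph(trk, p, size_factor = 2, strand = "+")
  expect_equal(read_bedgraph(p)$value, c(1, 0.5))
  # empty strand -> header-only file
  write_bedgraph(trk, p, strand = "-")
  expect_equal(nrow(read_bedgraph(p)), 0L)
  expect_error(write_bedgraph(trk, p, size_factor = 0), "size_factor")
})

test_that("bedGraph round trip conserves the strand total / size_factor", {
  set.seed(1)
  for (i in 1:20) {
    pos <- sort(sample.int(500, 40))
    cnt <- sample.int(5, 40, replace = TRUE)
    sf <- runif(1, 0.5, 3)
    trk <- make_track(pos = pos, count = cnt)
    p <- tempfile(fileext = ".bedgraph")
    write_bedgraph(trk, p, size_factor = sf, strand = "+")
    bg <- read_bedgraph(p)
    expect_equal(sum(bg$value * (bg$end - bg$start)), sum(cnt) / sf,
                 tolerance = 1e-6)
  }
})

test_that("track round trip through BED6 reproduces the track exactly", {
  set.seed(2)
  pos <- sample.int(1000, 60, replace = TRUE)
  strand <- sample(c("+", "-"), 60, replace = TRUE)
  p <- write_reads_bed(chrom = "chrX", start = pos, strand = strand)
  trk <- read_end_counts(p)
  # re-emit every read and re-read
  reads <- trk$counts[rep(seq_len(nrow(trk$counts)), trk$counts$count), ]
  p2 <- write_reads_bed(reads$chrom, reads$pos, reads$strand)
  trk2 <- read_end_counts(p2)
  expect_identical(trk$counts, trk2$counts)
  expect_equal(trk$primary_total, trk2$primary_total)
})

test_that("relative coordinate mapping is 1-based, zero-free and strand mirrored", {
  expect_equal(rel_to_genomic(1000, "+", c(1, 2, -1)), c(1000, 1001, 999))
  expect_equal(rel_to_genomic(1000, "-", c(1, 50, -1)), c(1000, 951, 1001))
  expect_error(rel_to_genomic(1000, "+", 0), "0")
  expect_equal(rel_window_width(-50, 100), 150)
  expect_equal(rel_window_width(1, 70), 70)
  expect_equal(rel_window_width(-10, -1), 10)
})
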