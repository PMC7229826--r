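# Small in-code fixtures shared across test files.

# a track from explicit (chrom, strand, pos, count) rows
make_track <- function(pos, count = 1L, chrom = "chr2L", strand = "+",
                       spike_total = 0L, sample_id = "s") {
  n <- length(pos)
  end_count_track(data.frame(chrom = rep_len(chrom, n),
                             strand = rep_len(strand, n),
                             pos = as.integer(pos),
                             count = as.integer(rep_len(count, n))),
                  spike_total = spike_total, sample_id = sample_id)
}

# one-row gene model without going through a file
make_gene <- function(gene_id = "g1", chrom = "chr2L", strand = "+",
                      tss = 1000L, length = 4000L) {
  tes <- if (strand == "+") tss + length - 1L else tss - length + 1L
  data.frame(gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
             chrom = chrom, strand = strand, tss = tss, tes = tes,
             length = length, cds_length = length, short = length < 700L,
             stringsAsFactors = FALSE)
}

# annotation table on disk for read_gene_annotation
write_annotation <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# BED6 single-base read file
write_reads_bed <- function(chrom, start, strand, path = tempfile(fileext = ".bed")) {
  df <- data.frame(chrom = chrom, start = start, end = start + 1L,
                   name = ".", score = 0L, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# a small, fast simulation for unit tests (not the acceptance conditions)
small_sim <- function(seed = 42, ...) {
  args <- list(n_genes = 60L, n_targets = 10L, reads_per_sample = 6e4,
               spike_reads_base = 5e3, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_experiment(do.call(sim_config, args))
}

# brute-force window count: loop over every stored base
oracle_window_count <- function(track, gene, rel_start, rel_end) {
  rels <- setdiff(rel_start:rel_end, 0L)
  gpos <- rel_to_genomic(gene$tss, gene$strand, rels)
  cts <- track$counts
  total <- 0L
  for (i in seq_len(nrow(cts))) {
    if (cts$chrom[i] == gene$chrom && cts$strand[i] == gene$strand &&
        cts$pos[i] %in% gpos)
      total <- total + cts$count[i]
  }
  total
}

# brute-force O(n^2) overlap-closure merge of half-open intervals
oracle_merge <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(df[, c("chrom", "start", "end")])
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && df$chrom[i] == df$chrom[j] &&
          df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx)
    data.frame(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
               end = max(df$end[idx]))))
  out[order(out$chrom, out$start), , drop = FALSE]
}
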