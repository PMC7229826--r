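# BED half-open [start, end) <-> 1-based closed GRanges at the boundary
.bed_to_gr <- function(d) {
  GenomicRanges::GRanges(d$chrom,
                         IRanges::IRanges(start = d$start + 1L, end = d$end))
}

#' Merge peak sets into regions of literal overlap
#'
#' Union-merges intervals sharing at least one base across all input sets;
#' book-ended half-open intervals (`[a,b)` and `[b,c)`) are *not* merged.
#' Each merged region records which source peaks contributed.
#'
#' @param peak_sets a single peak data.frame (`chrom`, `start`, `end`,
#'   optional `name`) or a named list of them.
#' @return data.frame of merged regions: `chrom`, `start`, `end`, `name`
#'   (`merged_i`), `n_sources`, `sources` (comma-joined contributing peak
#'   labels).
#' @export
merge_overlapping_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peaks = peak_sets)
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("set", seq_along(peak_sets))
  all <- do.call(rbind, lapply(names(peak_sets), function(nm) {
    d <- peak_sets[[nm]]
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               label = paste0(nm, ":",
                              if ("name" %in% names(d)) d$name
                              else seq_len(nrow(d))),
               stringsAsFactors = FALSE)
  }))
  if (nrow(all) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      n_sources = integer(), sources = character()))
  gr <- .bed_to_gr(all)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE,
                               ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             name = paste0("merged_", seq_along(red)),
             n_sources = lengths(revmap),
             sources = vapply(revmap, function(i)
               paste(all$label[i], collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

#' Drop peaks overlapping a blacklist
#'
#' A peak overlapping any blacklist interval by at least one base is
#' removed; half-open arithmetic, so a peak ending where a blacklist
#' interval starts is retained.
#'
#' @param peaks,blacklist interval data.frames (`chrom`, `start`, `end`).
#' @return the retained rows of `peaks`.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0L || nrow(blacklist) == 0L) return(peaks)
  hit <- IRanges::overlapsAny(.bed_to_gr(peaks), .bed_to_gr(blacklist))
  if (any(hit)) .msg(sum(hit), " peak(s) removed by blacklist")
  peaks[!hit, , drop = FALSE]
}

#' Assign peaks to promoters and keep the largest change per gene
#'
#' A peak belongs to a gene when it overlaps the promoter window
#' `[tss - promoter_halfwidth, tss + promoter_halfwidth)`; per gene the
#' peak with maximal `|log2fc|` is kept (first on tie).  Genes without an
#' overlapping peak are omitted.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `name`, `log2fc`.
#' @param genes gene-model data.frame.
#' @param promoter_halfwidth half-width of the promoter window in bp.
#' @return data.frame: `gene_id`, `peak_name`, `log2fc`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, promoter_halfwidth = 1000L) {
  stopifnot("log2fc" %in% names(peaks))
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(genes$tss - promoter_halfwidth, 0L),
                     end = genes$tss + promoter_halfwidth)
  hits <- GenomicRanges::findOverlaps(.bed_to_gr(prom), .bed_to_gr(peaks))
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(), peak_name = character(),
                      log2fc = numeric()))
  d <- data.frame(gene = S4Vectors::queryHits(hits),
                  peak = S4Vectors::subjectHits(hits))
  d$alfc <- abs(peaks$log2fc[d$peak])
  d <- d[order(d$gene, -d$alfc, d$peak), ]
  d <- d[!duplicated(d$gene), ]
  data.frame(gene_id = genes$gene_id[d$gene],
             peak_name = peaks$name[d$peak],
             log2fc = peaks$log2fc[d$peak],
             stringsAsFactors = FALSE)
}

#' Standardize a genes-by-features enrichment matrix
#'
#' Per feature (column): `z = (x - mean) / sd` with the sample standard
#' deviation, so each feature becomes comparable regardless of assay
#' affinity.  Constant features yield all-zero z-scores and are flagged.
#'
#' @param raw numeric matrix or data.frame, genes x features, with
#'   rownames.
#' @return object of class `enrichment_z`: `raw`, `z`, and
#'   `constant_features` (character vector).
#' @export
enrichment_zscores <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) stop("need at least 2 genes")
  mu <- colMeans(raw)
  sdv <- apply(raw, 2L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  z <- sweep(sweep(raw, 2L, mu), 2L, sdv, "/")
  z[, const] <- 0
  if (any(const))
    .msg("constant feature(s) flagged: ",
         paste(colnames(raw)[const], collapse = ", "))
  structure(list(raw = raw, z = z,
                 constant_features = colnames(raw)[const]),
            class = "enrichment_z")
}

#' Mean z-score of a gene set per feature
#'
#' @param ez an [enrichment_zscores()] result.
#' @param gene_set character vector of gene ids (rownames of the matrix).
#' @return named numeric vector, one mean z per feature.
#' @export
set_mean_z <- function(ez, gene_set) {
  stopifnot(inherits(ez, "enrichment_z"))
  idx <- rownames(ez$z) %in% gene_set
  if (!any(idx)) stop("no genes of the set in the matrix")
  colMeans(ez$z[idx, , drop = FALSE])
}

#' Fraction of promoters overlapping each chromatin state
#'
#' @param genes gene-model data.frame (non-empty).
#' @param states interval data.frame with `chrom`, `start`, `end` and a
#'   state label column `name`.
#' @param promoter_halfwidth promoter half-width around the TSS (bp).
#' @return named numeric vector: per state, the fraction of genes whose
#'   promoter `[tss - hw, tss + hw)` overlaps at least one interval.
#' @export
state_overlap_fraction <- function(genes, states, promoter_halfwidth = 500L) {
  if (nrow(genes) == 0L) stop("empty gene set")
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(genes$tss - promoter_halfwidth, 0L),
                     end = genes$tss + promoter_halfwidth)
  gp <- .bed_to_gr(prom)
  vapply(split(seq_len(nrow(states)), states$name), function(i) {
    mean(IRanges::overlapsAny(gp, .bed_to_gr(states[i, , drop = FALSE])))
  }, numeric(1))
}

#' Classify peaks as enhancer or promoter-proximal by TSS distance
#'
#' A peak whose anchor lies more than `min_distance` bp from the nearest
#' TSS is called an enhancer.  The anchor is the peak summit by default
#' (the sharper signal position); `anchor = "edge"` uses the smallest
#' distance from either peak edge instead.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `name` and, for
#'   the summit anchor, `summit` (0-based position inside the peak).
#' @param genes gene-model data.frame (non-empty).
#' @param min_distance distance threshold in bp (strictly greater =>
#'   enhancer).
#' @param anchor `"summit"` or `"edge"`.
#' @return data.frame: `name`, `distance`, `class`
#'   (`"enhancer"`/`"promoter_proximal"`).
#' @export
classify_enhancers <- function(peaks, genes, min_distance = 100L,
                               anchor = c("summit", "edge")) {
  if (nrow(genes) == 0L) stop("no genes to measure distance against")
  anchor <- match.arg(anchor)
  dist_to_tss <- function(pos, chrom) {
    vapply(seq_along(pos), function(i) {
      same <- genes$chrom == chrom[i]
      if (!any(same)) return(Inf)
      min(abs(genes$tss[same] - pos[i]))
    }, numeric(1))
  }
  d <- if (anchor == "summit") {
    stopifnot("summit" %in% names(peaks))
    dist_to_tss(peaks$summit, peaks$chrom)
  } else {
    pmin(dist_to_tss(peaks$start, peaks$chrom),
         dist_to_tss(peaks$end - 1L, peaks$chrom))
  }
  data.frame(name = peaks$name, distance = d,
             class = ifelse(d > min_distance, "enhancer",
                            "promoter_proximal"),
             stringsAsFactors = FALSE)
}

#' Correlate acetylation and transcription fold changes
#'
#' @param x,y matched numeric vectors (e.g. promoter acetylation log2fc and
#'   gene-body transcription log2fc); non-finite pairs are dropped and
#'   counted.
#' @return list: `pearson`, `spearman`, `n`, `n_dropped`.
#' @export
fc_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("fewer than 3 finite pairs")
  list(pearson = stats::cor(x[ok], y[ok], method = "pearson"),
       spearman = stats::cor(x[ok], y[ok], method = "spearman"),
       n = sum(ok), n_dropped = sum(!ok))
}

#' Genes exceeding a fold-gain threshold
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param fold linear fold threshold; genes with
#'   `log2fc > log2(fold)` (strict) are returned.
#' @return character vector of gene ids.
#' @export
threshold_gain_set <- function(log2fc, fold = 1.5) {
  stopifnot(!is.null(names(log2fc)))
  names(log2fc)[!is.na(log2fc) & log2fc > log2(fold)]
}

#' Binned log2 IP-over-input signal
#'
#' Per genomic bin: `log2((ip/s_ip + pc) / (input/s_in + pc))` on
#' strand-combined counts.  Bins covered by neither track are omitted
#' (their value would be 0 by construction).
#'
#' @param ip,input [end_count_track()] objects.
#' @param ip_size_factor,input_size_factor positive scale divisors
#'   (spike-in factors).
#' @param pseudocount stabilizer added to both scaled signals.
#' @param bin_width bin width in bp.
#' @return data.frame: `chrom`, `start`, `end`, `value`.
#' @export
log2_ip_over_input <- function(ip, input, ip_size_factor = 1,
                               input_size_factor = 1, pseudocount = 1,
                               bin_width = 10L) {
  if (ip_size_factor <= 0 || input_size_factor <= 0)
    stop("size factors must be > 0")
  binit <- function(trk) {
    d <- trk$counts
    if (!nrow(d)) return(data.frame(chrom = character(), bin = integer(),
                                    count = numeric()))
    stats::aggregate(count ~ chrom + bin,
                     data = data.frame(chrom = d$chrom,
                                       bin = d$pos %/% bin_width,
                                       count = d$count),
                     FUN = sum)
  }
  a <- binit(ip); b <- binit(input)
  m <- merge(a, b, by = c("chrom", "bin"), all = TRUE,
             suffixes = c("_ip", "_in"))
  m$count_ip[is.na(m$count_ip)] <- 0
  m$count_in[is.na(m$count_in)] <- 0
  val <- log2((m$count_ip / ip_size_factor + pseudocount) /
              (m$count_in / input_size_factor + pseudocount))
  out <- data.frame(chrom = m$chrom, start = m$bin * bin_width,
                    end = (m$bin + 1L) * bin_width, value = val,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), ]
}

#' Acetylation-transcription coupling on a simulated experiment
#'
#' Simulates promoter acetylation ChIP peaks on the genes of a
#' [simulate_experiment()] result — one peak per promoter, a global
#' treatment gain `gamma` on every peak and an extra gain `delta` at the
#' experiment's target genes — then runs the spike-in normalized
#' differential test on both assays, keeps each gene's largest-change
#' promoter peak, and correlates promoter acetylation change with gene-body
#' transcription change.
#'
#' @param sim a [simulate_experiment()] result.
#' @param gamma global acetylation gain under treatment.
#' @param delta extra gain at target-gene promoters (0 decouples the
#'   assays).
#' @param promoter_halfwidth promoter window for peak-to-gene assignment.
#' @param seed seed of the ChIP simulation.
#' @return list: `correlation` (a [fc_correlation()] result), `per_gene`
#'   (gene_id, acetylation and transcription log2fc), `chip_fit`,
#'   `proseq_fit` (`nb_diff` objects).
#' @export
acetylation_coupling <- function(sim, gamma = 0.2, delta = 1.5,
                                 promoter_halfwidth = 1000L, seed = 1L) {
  stopifnot(inherits(sim, "sim_experiment"))
  g <- sim$genes
  pk <- data.frame(chrom = g$chrom, start = pmax(g$tss - 200L, 0L),
                   end = g$tss + 200L, name = paste0("pk_", g$gene_id),
                   stringsAsFactors = FALSE)
  is_t <- sim$truth$is_target[match(g$gene_id, sim$truth$gene_id)]
  chip <- simulate_chip_peaks(peaks = pk, is_target = is_t, gamma = gamma,
                              delta = delta,
                              nb_dispersion = sim$config$nb_dispersion,
                              replicates = sim$config$replicates,
                              seed = seed)
  chip_fit <- nb_diff(chip$counts, chip$samples$condition,
                      contrast = c("treated", "control"),
                      spike_totals = chip$samples$spike_total)
  cm <- count_matrix(sim$tracks, g, region = "body")
  keep <- !is.na(cm$counts[, 1L])
  proseq_fit <- nb_diff(cm$counts[keep, , drop = FALSE],
                        sim$samples$condition,
                        contrast = c("treated", "control"),
                        spike_totals = cm$spike_totals)
  pkfc <- cbind(pk, log2fc = chip_fit$table$log2fc)
  best <- assign_peaks_to_genes(pkfc, g, promoter_halfwidth)
  m <- match(best$gene_id, proseq_fit$table$feature_id)
  ok <- !is.na(m)
  per_gene <- data.frame(gene_id = best$gene_id[ok],
                         acetylation_log2fc = best$log2fc[ok],
                         body_log2fc = proseq_fit$table$log2fc[m[ok]],
                         stringsAsFactors = FALSE)
  list(correlation = fc_correlation(per_gene$acetylation_log2fc,
                                    per_gene$body_log2fc),
       per_gene = per_gene, chip_fit = chip_fit, proseq_fit = proseq_fit)
}
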