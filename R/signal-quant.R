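# fast strand-aware window sums over the sparse per-base counts of a track;
# vectorized over query windows via per-(chrom,strand) cumulative sums
.window_sums <- function(track, chrom, strand, start, end) {
  res <- numeric(length(chrom))
  cts <- track$counts
  if (!nrow(cts)) return(res)
  tkey <- paste0(cts$chrom, "\r", cts$strand)
  qkey <- paste0(chrom, "\r", strand)
  for (k in intersect(unique(qkey), unique(tkey))) {
    qi <- which(qkey == k)
    ti <- which(tkey == k)
    pos <- cts$pos[ti]                       # sorted (track invariant)
    cs <- c(0, cumsum(cts$count[ti]))
    hi <- findInterval(end[qi], pos)         # rightmost pos <= end
    lo <- findInterval(start[qi] - 1L, pos)  # rightmost pos <  start
    res[qi] <- cs[hi + 1L] - cs[lo + 1L]
  }
  res
}

#' Count 3' ends of a track inside a gene-relative window
#'
#' Sums the read 3' ends on the gene's own strand at genomic positions that
#' map into the inclusive relative window `[rel_start, rel_end]` (TSS = +1,
#' no position 0; minus-strand genes are mirror-mapped).  Windows reaching
#' below genomic position 0 are clipped; a window entirely off-chromosome
#' returns 0 with a warning.
#'
#' @param track an [end_count_track()].
#' @param gene one row of a gene-model data.frame
#'   (see [read_gene_annotation()]).
#' @param rel_start,rel_end relative window bounds, `rel_start <= rel_end`.
#' @return integer count.
#' @examples
#' trk <- end_count_track(data.frame(chrom = "chr2L", strand = "+",
#'                                   pos = c(990, 1049, 1199), count = c(2L, 3L, 1L)))
#' gene <- data.frame(gene_id = "g1", chrom = "chr2L", strand = "+",
#'                    tss = 1000, tes = 4999, length = 4000)
#' window_count(trk, gene, -50, 100)  # 5: reads at -10 and +50 are inside
#' @export
window_count <- function(track, gene, rel_start, rel_end) {
  stopifnot(nrow(gene) == 1L, rel_start <= rel_end)
  w <- .rel_window_genomic(gene$tss, gene$strand, rel_start, rel_end)
  if (w$end < 0) {
    warning("window entirely upstream of chromosome start for ", gene$gene_id)
    return(0L)
  }
  as.integer(.window_sums(track, gene$chrom, gene$strand,
                          max(w$start, 0L), w$end))
}

#' Promoter, body and full-gene window counts for a gene set
#'
#' The promoter window defaults to -50..+100 around the TSS and the body
#' window to +500..TES-100, the windows used for pausing-index and
#' differential gene-body statistics.  Genes flagged `short` (body window
#' empty) get `NA` body counts.
#'
#' @param track an [end_count_track()].
#' @param genes gene-model data.frame.
#' @param promoter_window length-2 integer vector, relative bounds.
#' @param body_start relative start of the gene-body window (bp from TSS).
#' @param tes_offset bases trimmed upstream of the TES; 0 extends the body
#'   window to the TES itself.
#' @return data.frame: `gene_id`, `promoter_count`, `body_count`,
#'   `full_count`, `promoter_length`, `body_length`.
#' @export
region_counts <- function(track, genes, promoter_window = c(-50L, 100L),
                          body_start = 500L, tes_offset = 100L) {
  stopifnot(nrow(genes) > 0)
  body_end <- genes$length - tes_offset            # relative position of body end
  ok <- body_end >= body_start
  pw <- .rel_window_genomic(genes$tss, genes$strand,
                            promoter_window[1], promoter_window[2])
  prom <- .window_sums(track, genes$chrom, genes$strand,
                       pmax(pw$start, 0L), pw$end)
  body <- rep(NA_real_, nrow(genes))
  if (any(ok)) {
    bw <- .rel_window_genomic(genes$tss[ok], genes$strand[ok],
                              body_start, body_end[ok])
    body[ok] <- .window_sums(track, genes$chrom[ok], genes$strand[ok],
                             pmax(bw$start, 0L), bw$end)
  }
  fw <- .rel_window_genomic(genes$tss, genes$strand, 1L, genes$length)
  full <- .window_sums(track, genes$chrom, genes$strand,
                       pmax(fw$start, 0L), fw$end)
  data.frame(gene_id = genes$gene_id,
             promoter_count = as.integer(prom),
             body_count = as.integer(body),
             full_count = as.integer(full),
             promoter_length = rel_window_width(promoter_window[1],
                                                promoter_window[2]),
             body_length = ifelse(ok, body_end - body_start + 1L, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Build a features-by-samples count matrix from tracks
#'
#' @param tracks named list of [end_count_track()] objects (one per sample).
#' @param genes gene-model data.frame.
#' @param region `"body"`, `"promoter"` or `"full"`.
#' @param ... passed to [region_counts()].
#' @return object of class `count_matrix`: list with `counts` (integer
#'   matrix, genes x samples), `spike_totals`, `primary_totals`,
#'   `lengths` (region lengths in bp).
#' @export
count_matrix <- function(tracks, genes, region = c("body", "promoter", "full"),
                         ...) {
  region <- match.arg(region)
  col <- paste0(ifelse(region == "full", "full", region), "_count")
  rc <- lapply(tracks, region_counts, genes = genes, ...)
  counts <- vapply(rc, function(r) r[[col]], numeric(nrow(genes)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(genes))
  dimnames(counts) <- list(genes$gene_id, names(tracks))
  lens <- switch(region,
                 promoter = rc[[1]]$promoter_length,
                 body = rc[[1]]$body_length,
                 full = genes$length)
  structure(list(counts = counts,
                 spike_totals = vapply(tracks, `[[`, numeric(1), "spike_total"),
                 primary_totals = vapply(tracks, `[[`, numeric(1), "primary_total"),
                 lengths = stats::setNames(lens, genes$gene_id),
                 region = region),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix (", x$region, "): ", nrow(x$counts), " features x ",
      ncol(x$counts), " samples; spike totals ",
      paste(x$spike_totals, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Region read density per kb per million primary-genome mapped reads
#'
#' The per-region "TPM" used throughout: read count divided by region length
#' in kb, divided by primary-genome mapped reads in millions.  Depth- and
#' length-invariant, which is what the pausing-index ratio requires.
#'
#' @param count region read count (vectorized).
#' @param region_length region length in bp (> 0).
#' @param primary_total primary-genome mapped reads of the sample (> 0).
#' @return numeric density.
#' @examples
#' region_tpm(5, 150, 1e6)  # 33.33
#' @export
region_tpm <- function(count, region_length, primary_total) {
  if (any(primary_total <= 0)) stop("primary_total must be > 0")
  stopifnot(all(region_length > 0, na.rm = TRUE))
  (count / (region_length / 1000)) / (primary_total / 1e6)
}

#' Expressed-gene filter on mean log2 body density
#'
#' A gene is expressed when its mean over samples of `log2(TPM + 1)` exceeds
#' `threshold_log2` (default 3, i.e. mean density above ~7 reads/kb/M).
#' The +1 pseudocount keeps all-zero genes finite (and excluded).
#'
#' @param tpm matrix or data.frame of body TPM, genes x samples, rownames =
#'   gene ids.
#' @param threshold_log2 threshold on the mean log2(TPM+1), strict.
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(tpm, threshold_log2 = 3) {
  tpm <- as.matrix(tpm)
  m <- rowMeans(log2(tpm + 1))
  rownames(tpm)[!is.na(m) & m > threshold_log2]
}

#' Pausing index per gene
#'
#' PI = promoter-window TPM (-50..+100) divided by gene-body TPM
#' (+500..TES-100).  Higher PI means proportionally more engaged polymerase
#' held at the pause site.  Genes flagged short (empty body window) are
#' omitted with a message; a zero body density yields an undefined PI
#' (`pi = NA`, `undefined = TRUE`).
#'
#' @param track an [end_count_track()].
#' @param genes gene-model data.frame.
#' @param promoter_window relative promoter window (default -50..+100).
#' @param body_start,body_tes_offset body window +`body_start`..TES-`body_tes_offset`;
#'   set `body_tes_offset = 0` for the body-to-TES variant.
#' @return data.frame: `gene_id`, `promoter_tpm`, `body_tpm`, `pi`,
#'   `undefined`.
#' @export
pausing_index <- function(track, genes, promoter_window = c(-50L, 100L),
                          body_start = 500L, body_tes_offset = 100L) {
  rc <- region_counts(track, genes, promoter_window = promoter_window,
                      body_start = body_start, tes_offset = body_tes_offset)
  keep <- !is.na(rc$body_count)
  if (any(!keep))
    .msg(sum(!keep), " gene(s) below minimum length omitted from pausing index")
  rc <- rc[keep, , drop = FALSE]
  ptpm <- region_tpm(rc$promoter_count, rc$promoter_length, track$primary_total)
  btpm <- region_tpm(rc$body_count, rc$body_length, track$primary_total)
  undef <- btpm == 0
  data.frame(gene_id = rc$gene_id,
             promoter_tpm = ptpm,
             body_tpm = btpm,
             pi = ifelse(undef, NA_real_, ptpm / btpm),
             undefined = undef,
             stringsAsFactors = FALSE)
}

#' Body TPM matrix across samples
#'
#' Convenience wrapper: body-window counts for every track converted to the
#' per-region density of [region_tpm()].
#'
#' @inheritParams count_matrix
#' @param body_start,tes_offset body window definition.
#' @return numeric matrix genes x samples (short genes `NA`).
#' @export
body_tpm_matrix <- function(tracks, genes, body_start = 500L, tes_offset = 100L) {
  cm <- count_matrix(tracks, genes, region = "body",
                     body_start = body_start, tes_offset = tes_offset)
  prim <- cm$primary_totals
  sweep_len <- cm$lengths
  t(t(cm$counts / (sweep_len / 1000)) / (prim / 1e6))
}
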