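#' TSS-anchored spike-scaled metagene matrix and average profile
#'
#' For every gene and relative offset (TSS = +1, no position 0), the
#' spike-scaled 3' end signal `count / size_factor` is averaged over the
#' replicates of each condition; minus-strand genes are mirror-mapped so
#' offsets always run in the direction of transcription.  Offsets beyond a
#' gene's 3' end (or off the chromosome start) are masked `NA` and excluded
#' from the per-offset means.
#'
#' @param tracks named list of [end_count_track()] objects.
#' @param genes gene-model data.frame (see [read_gene_annotation()]).
#' @param conditions per-track condition labels (same order as `tracks`).
#' @param offsets integer vector of relative positions, no zero; default
#'   -200..+1000.
#' @param size_factors per-track scale divisors (e.g.
#'   [spike_size_factors()] of the tracks' spike totals); default all 1.
#' @return object of class `metagene_matrix`: `offsets`, `gene_ids`,
#'   `conditions`, `values` (gene x offset x condition array), and
#'   `profile`, a data.frame of per-offset mean, SEM and n per condition.
#' @export
metagene_profile <- function(tracks, genes, conditions,
                             offsets = c(-200:-1, 1:1000),
                             size_factors = NULL) {
  if (nrow(genes) == 0L) stop("empty gene set")
  stopifnot(length(conditions) == length(tracks), all(offsets != 0))
  offsets <- sort(unique(as.integer(offsets)))
  if (is.null(size_factors)) size_factors <- rep(1, length(tracks))
  if (any(size_factors <= 0)) stop("size factors must be > 0")

  n_g <- nrow(genes); n_o <- length(offsets)
  # genomic position of every (gene, offset) pair, plus validity mask
  gpos <- outer(genes$tss, ifelse(offsets > 0, offsets - 1L, offsets),
                function(tss, off) tss + off)
  neg <- genes$strand == "-"
  if (any(neg))
    gpos[neg, ] <- outer(genes$tss[neg],
                         ifelse(offsets > 0, offsets - 1L, offsets),
                         function(tss, off) tss - off)
  valid <- outer(genes$length, offsets, function(L, o) o <= L) & gpos >= 0

  per_track <- lapply(seq_along(tracks), function(j) {
    trk <- tracks[[j]]
    cts <- trk$counts
    vals <- matrix(0, n_g, n_o)
    tkey <- paste0(cts$chrom, "\r", cts$strand)
    for (k in unique(paste0(genes$chrom, "\r", genes$strand))) {
      gi <- which(paste0(genes$chrom, "\r", genes$strand) == k)
      ti <- which(tkey == k)
      if (!length(ti)) next
      idx <- match(gpos[gi, , drop = FALSE], cts$pos[ti])
      hit <- !is.na(idx)
      v <- matrix(0, length(gi), n_o)
      v[hit] <- cts$count[ti][idx[hit]]
      vals[gi, ] <- v
    }
    vals[!valid] <- NA
    vals / size_factors[j]
  })

  conds <- unique(conditions)
  values <- array(NA_real_, dim = c(n_g, n_o, length(conds)),
                  dimnames = list(genes$gene_id, offsets, conds))
  for (cc in conds) {
    js <- which(conditions == cc)
    values[, , cc] <- Reduce(`+`, per_track[js]) / length(js)
  }
  prof <- do.call(rbind, lapply(conds, function(cc) {
    m <- values[, , cc, drop = FALSE][, , 1L]
    if (is.null(dim(m))) m <- matrix(m, nrow = n_g)
    n_ok <- colSums(!is.na(m))
    data.frame(condition = cc, offset = offsets,
               mean = colMeans(m, na.rm = TRUE),
               sem = apply(m, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1L)),
               n = n_ok)
  }))
  rownames(prof) <- NULL
  structure(list(offsets = offsets, gene_ids = genes$gene_id,
                 conditions = conds, values = values, profile = prof),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat("metagene_matrix: ", length(x$gene_ids), " genes x ",
      length(x$offsets), " offsets (", min(x$offsets), "..",
      max(x$offsets), "), conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot metagene average profiles
#' @param x a `metagene_matrix`.
#' @param ... passed to [plot()].
#' @importFrom graphics lines
#' @importFrom grDevices palette
#' @export
plot.metagene_matrix <- function(x, ...) {
  pr <- x$profile
  plot(range(pr$offset), range(pr$mean, na.rm = TRUE), type = "n",
       xlab = "position relative to TSS (bp)", ylab = "mean scaled signal",
       ...)
  for (i in seq_along(x$conditions))
    lines(pr$offset[pr$condition == x$conditions[i]],
          pr$mean[pr$condition == x$conditions[i]], col = i)
  legend("topright", bty = "n", lty = 1, col = seq_along(x$conditions),
         legend = x$conditions)
  invisible(x)
}

#' Paired window test between two conditions of a metagene matrix
#'
#' Per gene, signal is summed over the offsets falling in the inclusive
#' window and the paired difference `B - A` across genes is tested with a
#' two-sided paired t-test (the gene is the pairing unit; replicates were
#' already averaged into the matrix).  Genes with any masked position in
#' the window are dropped.
#'
#' @param mg a [metagene_profile()] result.
#' @param window length-2 vector of relative offsets, inclusive; a shared
#'   boundary offset belongs to both adjacent windows.
#' @param a,b condition labels (defaults: first two conditions, `b - a`).
#' @return list: `mean_diff`, `t`, `df`, `p`, `n`, `degenerate` (`TRUE`
#'   when all per-gene differences are equal, in which case `p` is `NaN`).
#' @export
window_paired_test <- function(mg, window, a = mg$conditions[1L],
                               b = mg$conditions[2L]) {
  stopifnot(inherits(mg, "metagene_matrix"), length(window) == 2L)
  sel <- mg$offsets >= window[1L] & mg$offsets <= window[2L]
  if (!any(sel)) stop("window contains no offsets of the matrix")
  sum_a <- rowSums(mg$values[, sel, a, drop = FALSE], dims = 1L)
  sum_b <- rowSums(mg$values[, sel, b, drop = FALSE], dims = 1L)
  ok <- !is.na(sum_a) & !is.na(sum_b)
  if (sum(ok) < 2L) stop("fewer than 2 genes with a fully defined window")
  res <- paired_t(sum_a[ok], sum_b[ok])
  c(list(mean_diff = mean(sum_b[ok] - sum_a[ok])), res)
}
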