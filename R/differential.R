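# ratio-to-geometric-mean factors shared by spike and library normalization
.ratio_factors <- function(x) x / .geomean(x)

#' Size factors from spike-in read totals
#'
#' One factor per sample: its spike-in read total divided by the geometric
#' mean of all spike totals, so the factors' logs sum to zero.  Because the
#' spike-in material has constant abundance per cell, these factors recover
#' the true cross-sample scale even when the primary signal shifts globally.
#'
#' @param spike_totals positive numeric vector of per-sample spike-in reads.
#' @return numeric vector of size factors (same names/order).
#' @examples
#' spike_size_factors(c(1000, 2000))  # 0.7071068 1.4142136
#' @export
spike_size_factors <- function(spike_totals) {
  if (any(spike_totals <= 0))
    stop("zero spike-in total: add a pseudo-count or exclude the sample")
  .ratio_factors(spike_totals)
}

#' Size factors from primary library sizes
#'
#' Same ratio-to-geometric-mean arithmetic as [spike_size_factors()] but on
#' primary-genome read totals.  Provided for comparison: under a global
#' signal shift these factors absorb the shift and bias fold changes toward
#' zero, which is exactly what spike-in normalization avoids.
#'
#' @param totals positive numeric vector of per-sample primary read totals.
#' @return numeric vector of size factors.
#' @export
library_size_factors <- function(totals) {
  if (any(totals <= 0)) stop("zero library total")
  .ratio_factors(totals)
}

#' Benjamini-Hochberg adjustment with untested features excluded
#'
#' Wraps `stats::p.adjust(method = "BH")`, computing the adjustment over the
#' tested (non-`NA`) p-values only so that untested features do not inflate
#' the multiple-testing burden.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA` marks untested.
#' @return vector of FDR values, `NA` where `p` was `NA`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify features by fold-change direction and FDR
#'
#' `up`/`down` at FDR below `up_down_fdr` (default 10%), `unchanged` at FDR
#' above `unchanged_fdr` (default 50%), `indeterminate` in between,
#' `untested` where no test was possible.
#'
#' @param log2fc,fdr numeric vectors.
#' @param up_down_fdr,unchanged_fdr class thresholds.
#' @return character vector of class labels.
#' @export
classify_features <- function(log2fc, fdr, up_down_fdr = 0.1,
                              unchanged_fdr = 0.5) {
  cls <- rep("indeterminate", length(fdr))
  cls[is.na(fdr)] <- "untested"
  cls[!is.na(fdr) & fdr < up_down_fdr & log2fc > 0] <- "up"
  cls[!is.na(fdr) & fdr < up_down_fdr & log2fc < 0] <- "down"
  cls[!is.na(fdr) & fdr > unchanged_fdr] <- "unchanged"
  cls
}

# method-of-moments dispersion on normalized counts, shrunk toward an
# a/mean + b trend on the log scale
.estimate_dispersion <- function(q, grp, s, shrink_weight = 0.5) {
  n <- ncol(q)
  mu <- rowMeans(q)
  ss <- 0
  for (g in unique(grp)) {
    qg <- q[, grp == g, drop = FALSE]
    ss <- ss + rowSums((qg - rowMeans(qg))^2)
  }
  v <- ss / max(n - length(unique(grp)), 1L)
  xi <- mean(1 / s)                      # Poisson part of Var(K/s)
  raw <- (v - mu * xi) / mu^2
  raw[!is.finite(raw)] <- NA_real_

  fit_ok <- sum(is.finite(raw) & mu > 0) >= 10
  if (fit_ok) {
    idx <- is.finite(raw) & mu > 0
    tf <- try(stats::lm(raw[idx] ~ I(1 / mu[idx])), silent = TRUE)
    if (inherits(tf, "try-error")) fit_ok <- FALSE
  }
  if (fit_ok) {
    b <- stats::coef(tf)[1]; a <- stats::coef(tf)[2]
    trend <- pmax(a / mu + b, 1e-8)
  } else {
    trend <- rep(max(mean(pmax(raw, 0), na.rm = TRUE), 1e-8), length(mu))
  }
  # raw MoM at few residual df is often negative by chance; flooring it at a
  # fixed tiny value before the log-blend collapses the blended dispersion
  # toward zero and inflates the Wald test, so shrinkage is one-sided: the
  # trend floors the raw estimate (1e-8 only protects the log).
  raw_fl <- pmax(raw, trend, 1e-8)
  raw_fl[is.na(raw_fl)] <- trend[is.na(raw_fl)]
  alpha <- exp(shrink_weight * log(trend) + (1 - shrink_weight) * log(raw_fl))
  list(mean = mu, raw = raw, trend = trend, alpha = pmax(alpha, 1e-8))
}

#' Spike-in normalized negative-binomial differential test
#'
#' Two-group Wald test of feature counts under the model
#' `K_ij ~ NB(mean = s_j * m_{g(j)}, variance = mu + alpha * mu^2)`.
#' Group means are estimated as the arithmetic mean of size-factor
#' normalized counts, the solution of the equal-weight NB estimating
#' equation; this makes every log2 fold change exactly invariant to
#' rescaling any sample's counts together with its spike total, and it
#' coincides with the NB/Poisson GLM solution whenever size factors are
#' equal within groups.  Per-feature dispersions are method-of-moments
#' estimates on normalized counts, shrunk on the log scale (weight
#' `shrink_weight`) toward an `a/mean + b` mean-dispersion trend.  P-values
#' are two-sided normal Wald; FDR is Benjamini-Hochberg over tested
#' features; classes follow [classify_features()].
#'
#' @param counts integer matrix (features x samples) or a [count_matrix()].
#' @param condition character/factor of per-sample condition labels.
#' @param contrast `c(treatment, control)`; defaults to the second versus
#'   the first factor level of `condition`.
#' @param size_factors explicit per-sample size factors; overrides
#'   `spike_totals`.
#' @param spike_totals per-sample spike-in totals, turned into factors via
#'   [spike_size_factors()].  If neither is given and `counts` is a
#'   [count_matrix()], its spike totals are used.
#' @param dispersion optional fixed dispersion (scalar or per feature);
#'   `0` gives a Poisson test.  Default `NULL` estimates it.
#' @param shrink_weight weight of the trend in the log-scale blend.
#' @param up_down_fdr,unchanged_fdr class thresholds
#'   (see [classify_features()]).
#' @return object of class `nb_diff`; its `$table` holds `feature_id`,
#'   `base_mean`, `log2fc`, `se`, `wald_p`, `fdr`, `class`.
#' @examples
#' k <- rbind(a = c(10, 10, 10, 10), b = c(4, 6, 18, 22))
#' fit <- nb_diff(k, c("C", "C", "T", "T"), dispersion = 0)
#' fit$table
#' @export
nb_diff <- function(counts, condition, contrast = NULL, size_factors = NULL,
                    spike_totals = NULL, dispersion = NULL,
                    shrink_weight = 0.5, up_down_fdr = 0.1,
                    unchanged_fdr = 0.5) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(size_factors) && is.null(spike_totals))
      spike_totals <- counts$spike_totals
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  keep_rows <- !apply(counts, 1L, function(r) any(is.na(r)))
  if (!all(keep_rows)) {
    .msg(sum(!keep_rows), " feature(s) with missing counts dropped")
    counts <- counts[keep_rows, , drop = FALSE]
  }
  if (any(counts < 0) || max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be non-negative integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature_", seq_len(nrow(counts)))
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("condition length must match the number of samples")
  if (is.null(contrast)) {
    lev <- unique(condition)
    contrast <- c(lev[2L], lev[1L])
  }
  if (!all(contrast %in% condition)) stop("contrast levels not in condition")
  use <- condition %in% contrast
  counts <- counts[, use, drop = FALSE]
  condition <- condition[use]
  n <- ncol(counts)
  if (is.null(size_factors)) {
    size_factors <- if (!is.null(spike_totals))
      spike_size_factors(spike_totals[use]) else rep(1, n)
  } else size_factors <- size_factors[use]
  if (any(size_factors <= 0)) stop("size factors must be > 0")

  x <- as.integer(condition == contrast[1L])          # 1 = treatment
  q <- sweep(counts, 2L, size_factors, "/")
  untested <- rowSums(counts) == 0
  grp_t <- x == 1L; grp_c <- x == 0L
  n_t <- sum(grp_t); n_c <- sum(grp_c)

  if (is.null(dispersion)) {
    disp <- .estimate_dispersion(q, x, size_factors, shrink_weight)
    alpha <- disp$alpha
  } else {
    alpha <- pmax(rep(dispersion, length.out = nrow(counts)), 0)
    disp <- list(mean = rowMeans(q), raw = alpha, trend = alpha, alpha = alpha)
  }

  m_t <- rowMeans(q[, grp_t, drop = FALSE])
  m_c <- rowMeans(q[, grp_c, drop = FALSE])
  # half-a-read floor so a group with no reads yields a large finite fold
  # change with an honest (large) standard error
  fl_t <- 0.5 / (n_t * mean(size_factors[grp_t]))
  fl_c <- 0.5 / (n_c * mean(size_factors[grp_c]))
  mh_t <- pmax(m_t, fl_t)
  mh_c <- pmax(m_c, fl_c)

  ln_fc <- log(mh_t) - log(mh_c)
  # Var(log mean q_g) ~ (1/m) * sum(1/s_j)/n^2 + alpha/n  (delta method)
  v_t <- (1 / mh_t) * sum(1 / size_factors[grp_t]) / n_t^2 + alpha / n_t
  v_c <- (1 / mh_c) * sum(1 / size_factors[grp_c]) / n_c^2 + alpha / n_c
  se_ln <- sqrt(v_t + v_c)
  z <- ln_fc / se_ln
  p <- 2 * stats::pnorm(-abs(z))

  log2fc <- ln_fc / log(2)
  se <- se_ln / log(2)
  base_mean <- rowMeans(q)
  log2fc[untested] <- NA; se[untested] <- NA; p[untested] <- NA
  fdr <- bh_adjust(p)
  cls <- classify_features(log2fc, fdr, up_down_fdr, unchanged_fdr)

  tab <- data.frame(feature_id = rownames(counts),
                    base_mean = base_mean,
                    log2fc = log2fc,
                    se = se,
                    wald_p = p,
                    fdr = fdr,
                    class = cls,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 size_factors = stats::setNames(size_factors,
                                                colnames(counts)),
                 condition = condition,
                 contrast = contrast,
                 dispersion = disp,
                 thresholds = c(up_down_fdr = up_down_fdr,
                                unchanged_fdr = unchanged_fdr),
                 call = match.call()),
            class = "nb_diff")
}

#' @export
print.nb_diff <- function(x, ...) {
  cat("nb_diff: ", nrow(x$table), " features, contrast ", x$contrast[1],
      " vs ", x$contrast[2], "\n", sep = "")
  print(table(factor(x$table$class,
                     levels = c("up", "down", "unchanged",
                                "indeterminate", "untested"))))
  invisible(x)
}

#' @export
summary.nb_diff <- function(object, ...) {
  tab <- object$table
  cat("Two-group NB Wald test, contrast ", object$contrast[1], " vs ",
      object$contrast[2], "\n", sep = "")
  cat("size factors: ",
      paste(sprintf("%.4f", object$size_factors), collapse = " "), "\n")
  cat("classes at FDR<", object$thresholds["up_down_fdr"], " / >",
      object$thresholds["unchanged_fdr"], ":\n", sep = "")
  print(table(tab$class))
  ok <- !is.na(tab$log2fc)
  cat("log2fc range: ",
      paste(sprintf("%.2f", range(tab$log2fc[ok])), collapse = " .. "), "\n")
  invisible(tab)
}

#' @export
coef.nb_diff <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$feature_id)
}

#' @export
as.data.frame.nb_diff <- function(x, ...) x$table

#' Volcano plot of an `nb_diff` fit
#'
#' @param x an `nb_diff` object.
#' @param ... passed to [plot()].
#' @importFrom graphics abline legend points
#' @export
plot.nb_diff <- function(x, ...) {
  tab <- x$table[!is.na(x$table$wald_p), ]
  col <- c(up = "firebrick", down = "steelblue", unchanged = "grey60",
           indeterminate = "grey30")[tab$class]
  plot(tab$log2fc, -log10(pmax(tab$wald_p, 1e-300)), col = col, pch = 16,
       cex = 0.5, xlab = "log2 fold change", ylab = "-log10 Wald p", ...)
  abline(v = 0, lty = 3)
  legend("topleft", bty = "n", pch = 16, cex = 0.8,
         col = c("firebrick", "steelblue", "grey60", "grey30"),
         legend = c("up", "down", "unchanged", "indeterminate"))
  invisible(x)
}
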