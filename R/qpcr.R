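#' Relative expression by the delta-delta Ct method
#'
#' Per sample, `dCt = Cq_target - Cq_reference`; per target and condition,
#' `ddCt = mean(dCt | condition) - mean(dCt | control)` and the fold change
#' is `2^(-ddCt)` (amplification efficiency fixed at 2).  Averaging is done
#' in Cq space across replicates.
#'
#' @param records data.frame with columns `condition`, `target_name`,
#'   `cq_target`, `cq_reference` (one row per replicate measurement).
#' @param control_condition the reference condition label.
#' @return data.frame: `target_name`, `condition`, `ddct`, `fold`.
#' @examples
#' rec <- data.frame(condition = c("ctrl", "tsa"), target_name = "Rpd3",
#'                   cq_target = c(25, 23), cq_reference = c(20, 20))
#' delta_delta_ct(rec, "ctrl")  # tsa fold = 4
#' @export
delta_delta_ct <- function(records, control_condition) {
  need <- c("condition", "target_name", "cq_target", "cq_reference")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (any(is.na(records$cq_reference)))
    stop("missing reference Cq value")
  if (!control_condition %in% records$condition)
    stop("control condition '", control_condition, "' absent from records")
  records$dct <- records$cq_target - records$cq_reference
  agg <- stats::aggregate(dct ~ target_name + condition, data = records,
                          FUN = mean)
  ctrl <- agg[agg$condition == control_condition,
              c("target_name", "dct")]
  names(ctrl)[2] <- "dct_control"
  out <- merge(agg, ctrl, by = "target_name")
  if (any(is.na(out$dct_control)))
    stop("control condition missing for some target")
  out$ddct <- out$dct - out$dct_control
  out$fold <- 2^(-out$ddct)
  out[order(out$target_name, out$condition),
      c("target_name", "condition", "ddct", "fold")]
}

#' Normalize ChIP-qPCR percent-input by background loci and histone H3
#'
#' Step 1 divides every locus's percent-input by the arithmetic mean of the
#' designated background loci (intergenic sites devoid of the modification).
#' Step 2, when an H3 percent-input table is supplied, divides by the H3
#' value at the same locus after H3 has been background-normalized the same
#' way — correcting enrichment for total nucleosome occupancy.
#'
#' @param percent_input named numeric vector of percent-input per locus.
#' @param background_loci names of at least one background locus present in
#'   `percent_input` (and in `h3_percent_input` if given).
#' @param h3_percent_input optional named numeric vector of H3
#'   percent-input at the same loci.
#' @return named numeric vector of normalized enrichment.
#' @examples
#' chip_qpcr_normalize(c(Rpd3 = 4, bg1 = 1, bg2 = 3), c("bg1", "bg2"),
#'                     h3_percent_input = c(Rpd3 = 2, bg1 = 1, bg2 = 1))
#' @export
chip_qpcr_normalize <- function(percent_input, background_loci,
                                h3_percent_input = NULL) {
  stopifnot(!is.null(names(percent_input)), length(background_loci) >= 1)
  if (!all(background_loci %in% names(percent_input)))
    stop("background loci absent from table")
  bg <- mean(percent_input[background_loci])
  if (bg == 0) stop("background mean is zero")
  out <- percent_input / bg
  if (!is.null(h3_percent_input)) {
    if (!all(background_loci %in% names(h3_percent_input)))
      stop("background loci absent from H3 table")
    h3bg <- mean(h3_percent_input[background_loci])
    if (h3bg == 0) stop("H3 background mean is zero")
    h3n <- h3_percent_input / h3bg
    common <- intersect(names(out), names(h3n))
    out[common] <- out[common] / h3n[common]
  }
  out
}

#' Two-sided paired t-test with explicit degenerate handling
#'
#' Standard paired t on `d = y - x` via `stats::t.test`; when all
#' differences are equal (zero variance) the statistic is undefined and the
#' result is flagged degenerate with `p = NaN`.
#'
#' @param x,y matched numeric vectors, `n >= 2`.
#' @return list: `t`, `df`, `p`, `n`, `degenerate`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 4, 3))  # t = sqrt(3), p ~ 0.2254
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- y - x
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p = NaN,
                n = length(d), degenerate = TRUE))
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(d), degenerate = FALSE)
}
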