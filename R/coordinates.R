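#' @import data.table
#' @importFrom stats rnbinom rpois rlnorm rbeta runif rnorm sd var cor
#'   pnorm pt qt p.adjust t.test lm coef complete.cases setNames
#' @importFrom utils packageVersion head
NULL

# Relative gene coordinates follow the 1-based biology convention with no
# position 0: the TSS is +1, the base immediately upstream is -1, and a
# window -50..+100 spans exactly 150 bases.  For minus-strand genes the axis
# runs against genomic coordinates (tss > tes genomically).

#' Map gene-relative positions to genomic positions
#'
#' Converts positions on the 1-based, zero-free gene axis (TSS = +1, first
#' upstream base = -1) to 0-based genomic coordinates, honouring strand.
#'
#' @param tss 0-based genomic position of the first transcribed base.
#' @param strand `"+"` or `"-"`.
#' @param rel integer vector of relative positions; 0 is not a valid position.
#' @return integer vector of 0-based genomic positions.
#' @examples
#' rel_to_genomic(1000, "+", c(-1, 1, 50))
#' rel_to_genomic(1000, "-", 50)  # genomic 951
#' @export
rel_to_genomic <- function(tss, strand, rel) {
  if (any(rel == 0)) stop("relative coordinate 0 does not exist (TSS is +1)")
  n <- max(length(tss), length(strand), length(rel))
  tss <- rep_len(tss, n)
  rel <- rep_len(rel, n)
  sgn <- rep_len(ifelse(strand == "+", 1L, -1L), n)
  off <- ifelse(rel > 0, rel - 1L, rel)
  tss + sgn * off
}

#' Number of bases spanned by a relative window
#'
#' @param rel_start,rel_end window bounds on the zero-free relative axis,
#'   `rel_start <= rel_end`, both inclusive.
#' @return integer width in bases.
#' @export
rel_window_width <- function(rel_start, rel_end) {
  stopifnot(rel_start <= rel_end, rel_start != 0, rel_end != 0)
  (rel_end - rel_start + 1L) - as.integer(rel_start < 0 & rel_end > 0)
}

# genomic [start, end] (0-based inclusive) covered by a relative window
.rel_window_genomic <- function(tss, strand, rel_start, rel_end) {
  g1 <- rel_to_genomic(tss, strand, rel_start)
  g2 <- rel_to_genomic(tss, strand, rel_end)
  list(start = pmin(g1, g2), end = pmax(g1, g2))
}

.geomean <- function(x) exp(mean(log(x)))

.msg <- function(...) message("[spikepause] ", ...)

# header comment written by all file writers
.writer_header <- function(what, ...) {
  params <- c(...)
  p <- if (length(params))
    paste(names(params), unname(params), sep = "=", collapse = " ") else ""
  sprintf("# spikepause %s %s %s",
          as.character(utils::packageVersion("spikepause")), what, p)
}
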