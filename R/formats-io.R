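#' Read a gene annotation table and pick one canonical transcript per gene
#'
#' The canonical transcript of a gene is the one with the longest CDS; ties
#' are broken by the longest transcript, then by the lexicographically
#' smallest transcript id.  Coordinates in the table are 0-based half-open
#' (`txStart`/`txEnd`, `cdsStart`/`cdsEnd`).  The returned gene models carry
#' strand-aware TSS and TES: for a minus-strand gene the TSS is `txEnd - 1`
#' and lies genomically downstream of the TES.
#'
#' @param path tab-separated file with header columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `txStart`, `txEnd`, `cdsStart`,
#'   `cdsEnd`.
#' @param min_length genes shorter than this are flagged (`short = TRUE`)
#'   and later excluded from pausing-index and body-window statistics; the
#'   default 700 bp keeps the +500..TES-100 body window at least 100 bp wide.
#' @return data.frame with one row per gene: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `tss`, `tes`, `length`, `cds_length`, `short`.
#' @export
read_gene_annotation <- function(path, min_length = 700L) {
  ann <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  need <- c("gene_id", "transcript_id", "chrom", "strand",
            "txStart", "txEnd", "cdsStart", "cdsEnd")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann[, c("gene_id", "transcript_id")]))
    stop("duplicate (gene_id, transcript_id) rows in annotation")
  if (!all(ann$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(ann$strand, c("+", "-"))), collapse = ", "))
  if (any(ann$txEnd <= ann$txStart)) stop("txEnd must exceed txStart")

  ann$cds_length <- ann$cdsEnd - ann$cdsStart
  ann$tx_length  <- ann$txEnd - ann$txStart
  # canonical pick: longest CDS, then longest transcript, then smallest id
  o <- order(ann$gene_id, -ann$cds_length, -ann$tx_length, ann$transcript_id)
  ann <- ann[o, ]
  ann <- ann[!duplicated(ann$gene_id), ]

  g <- data.frame(
    gene_id = ann$gene_id,
    transcript_id = ann$transcript_id,
    chrom = ann$chrom,
    strand = ann$strand,
    tss = ifelse(ann$strand == "+", ann$txStart, ann$txEnd - 1L),
    tes = ifelse(ann$strand == "+", ann$txEnd - 1L, ann$txStart),
    length = ann$tx_length,
    cds_length = ann$cds_length,
    stringsAsFactors = FALSE
  )
  g$short <- g$length < min_length
  if (any(g$short))
    .msg(sum(g$short), " gene(s) shorter than ", min_length,
         " bp flagged (retained, excluded from PI/body statistics)")
  rownames(g) <- NULL
  g[order(g$gene_id), ]
}

#' Read single-base 3' end reads from BED6 into an end-count track
#'
#' Every record must be exactly one base wide (`end == start + 1`): each
#' line is the 3' end of one nascent-RNA read, i.e. the position of one
#' engaged polymerase.  Reads on chromosomes whose name starts with
#' `spike_prefix` are spike-in material: they contribute only to the
#' track's spike total, never to its per-base counts or primary total.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @param spike_prefix chromosome-name prefix marking spike-in reads.
#' @param sample_id label stored on the track (defaults to the file name).
#' @return an object of class `end_count_track`; see [end_count_track()].
#' @export
read_end_counts <- function(path, spike_prefix = "spike_", sample_id = basename(path)) {
  empty <- function() end_count_track(
    data.frame(chrom = character(), strand = character(),
               pos = integer(), count = integer()),
    spike_total = 0L, sample_id = sample_id, spike_prefix = spike_prefix)
  if (file.size(path) == 0) return(empty())
  bed <- data.table::fread(path, sep = "\t", header = FALSE, data.table = TRUE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:6],
                           fill = TRUE)
  if (nrow(bed) == 0L) return(empty())
  bad <- which(bed$end != bed$start + 1L)
  if (length(bad))
    stop("read is not a single base (end != start + 1) at line ", bad[1L],
         " of ", path)
  if (any(is.na(bed$strand)) || !all(bed$strand %in% c("+", "-")))
    stop("missing or invalid strand in ", path)

  is_spike <- startsWith(bed$chrom, spike_prefix)
  spike_total <- sum(is_spike)
  prim <- bed[!is_spike, ]
  counts <- prim[, list(count = .N), by = list(chrom, start, strand)]
  data.table::setnames(counts, "start", "pos")
  end_count_track(as.data.frame(counts), spike_total = spike_total,
                  sample_id = sample_id, spike_prefix = spike_prefix)
}

#' Construct an end-count track
#'
#' Sparse per-(chromosome, strand) map of base position to 3' end read
#' count, plus the sample's primary-genome and spike-in read totals.
#'
#' @param counts data.frame with columns `chrom`, `strand`, `pos` (0-based
#'   base position), `count` (positive integer); one row per covered base.
#' @param spike_total number of spike-in reads observed for this sample.
#' @param sample_id sample label.
#' @param spike_prefix spike chromosome prefix used when the track was read.
#' @return classed list with elements `counts` (sorted), `primary_total`,
#'   `spike_total`, `sample_id`, `spike_prefix`.
#' @export
end_count_track <- function(counts, spike_total = 0L, sample_id = "sample",
                            spike_prefix = "spike_") {
  stopifnot(all(c("chrom", "strand", "pos", "count") %in% names(counts)),
            all(counts$count >= 0), spike_total >= 0)
  counts <- counts[counts$count > 0, c("chrom", "strand", "pos", "count"),
                   drop = FALSE]
  counts$pos <- as.integer(counts$pos)
  counts$count <- as.integer(counts$count)
  counts <- counts[order(counts$chrom, counts$strand, counts$pos), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts,
                 primary_total = as.integer(sum(counts$count)),
                 spike_total = as.integer(spike_total),
                 sample_id = sample_id,
                 spike_prefix = spike_prefix),
            class = "end_count_track")
}

#' @export
print.end_count_track <- function(x, ...) {
  cat("end_count_track '", x$sample_id, "': ", x$primary_total,
      " primary reads over ", nrow(x$counts), " bases (",
      length(unique(x$counts$chrom)), " chrom), ", x$spike_total,
      " spike-in reads\n", sep = "")
  invisible(x)
}

#' Write one strand of a track as spike-scaled bedGraph
#'
#' Each covered base is emitted at `count / size_factor`; runs of adjacent
#' bases with equal scaled value are merged into a single half-open record
#' and uncovered bases are omitted.
#'
#' @param track an [end_count_track()].
#' @param path output file.
#' @param size_factor positive scale divisor (e.g. a spike-in size factor).
#' @param strand which strand to emit, `"+"` or `"-"`.
#' @return invisibly, the number of records written.
#' @export
write_bedgraph <- function(track, path, size_factor = 1, strand = "+") {
  if (!is.numeric(size_factor) || size_factor <= 0)
    stop("size_factor must be > 0")
  stopifnot(strand %in% c("+", "-"))
  cts <- track$counts[track$counts$strand == strand, , drop = FALSE]
  hdr <- .writer_header("bedgraph", sample = track$sample_id,
                        size_factor = format(size_factor, digits = 15),
                        strand = strand)
  if (nrow(cts) == 0L) {
    writeLines(hdr, path)
    return(invisible(0L))
  }
  cts <- cts[order(cts$chrom, cts$pos), ]
  val <- cts$count / size_factor
  # merge runs: same chrom, consecutive pos, equal value
  new_run <- c(TRUE, !(cts$chrom[-1] == cts$chrom[-nrow(cts)] &
                       cts$pos[-1] == cts$pos[-nrow(cts)] + 1L &
                       val[-1] == val[-nrow(cts)]))
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = cts$chrom[new_run],
    start = cts$pos[new_run],
    end   = tapply(cts$pos, run, max) + 1L,
    value = format(val[new_run], digits = 9, scientific = FALSE, trim = TRUE)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(out))
}

#' Read a bedGraph file written by [write_bedgraph()]
#'
#' @param path bedGraph file; comment and `track` lines are skipped.
#' @return data.frame with `chrom`, `start`, `end` (half-open), `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  d <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"))
  as.data.frame(d)
}

#' Read a BED file of intervals (peaks, blacklist, chromatin states)
#'
#' @param path BED3+ file; columns beyond the sixth are ignored.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(d, nm[seq_len(min(ncol(d), 6L))])
  d <- as.data.frame(d)[, seq_len(min(ncol(d), 6L)), drop = FALSE]
  if (any(d$start >= d$end)) stop("invalid BED interval (start >= end)")
  d
}

#' Write intervals as BED
#'
#' @param intervals data.frame with at least `chrom`, `start`, `end`.
#' @param path output file.
#' @param what label recorded in the header comment.
#' @export
write_bed <- function(intervals, path, what = "intervals") {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.writer_header(what, n = nrow(intervals)), con)
  if (nrow(intervals))
    utils::write.table(intervals[, cols, drop = FALSE], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a plain TSV with a provenance header comment
#'
#' @param x data.frame.
#' @param path output file.
#' @param what label recorded in the header comment.
#' @export
write_tsv <- function(x, path, what = "table") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.writer_header(what, n = nrow(x)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  as.data.frame(data.table::fread(text = lines, sep = "\t", header = TRUE))
}
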