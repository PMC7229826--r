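#' Configuration for the paused-transcription simulator
#'
#' The generator emulates a two-condition (control vs treated), two-replicate
#' nascent-transcription experiment over a reduced gene complement.  Each
#' gene g has an initiation rate `I_g` and a pause-release probability
#' `r_g`; steady state puts paused-polymerase occupancy proportional to
#' `I_g / r_g` in the pause region and elongating occupancy proportional to
#' `I_g * L_g * r_g / (r_g + t)` over the body (termination weight `t`).
#' Treatment multiplies `r_g` by `release_multiplier` (capped at 1) at a
#' designated subset of highly paused target genes, moving signal out of
#' the pause window and into the body — the pause-release response the
#' pipeline is built to detect.  Window counts are negative binomial with
#' variance `mu + alpha * mu^2`; per-sample depth distortion `lambda_j`
#' scales primary and spike-in reads alike, while spike-in *abundance* is
#' condition-independent, so spike totals carry exactly the cross-sample
#' scale information that spike-in normalization assumes.
#'
#' Defaults are the recovery configuration exercised throughout the test
#' suite: 500 genes, 50 targets, release multiplier 3, 2 replicates,
#' dispersion 0.05, 1.5e6 reads per sample.
#'
#' @param n_genes,n_targets gene count and number of treatment-responsive
#'   target genes (`n_targets <= n_genes`).
#' @param replicates replicates per condition.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length (bp);
#'   lengths below `min_gene_length` are redrawn.
#' @param initiation_meanlog,initiation_sdlog log-normal initiation rate.
#' @param release_shape1,release_shape2 Beta parameters of `r_g` for
#'   non-targets.
#' @param target_release_shape1,target_release_shape2 Beta parameters of the
#'   low-release component targets are drawn from (more paused).
#' @param release_multiplier treatment multiplier `f >= 1` on target `r_g`.
#' @param termination_weight `t >= 0` in the body-occupancy denominator.
#' @param nb_dispersion NB dispersion `alpha >= 0` (0 = Poisson).
#' @param reads_per_sample expected primary reads per sample at `lambda = 1`.
#' @param depth_distortion per-sample `lambda_j` (recycled / named), or
#'   `NULL` to draw them log-normal(0, `depth_sdlog`).
#' @param depth_sdlog sd of drawn log depth distortions.
#' @param spike_reads_base expected spike-in reads at `lambda = 1`.
#' @param pause_window relative window (bases downstream of TSS) where
#'   paused-polymerase 3' ends are placed.
#' @param body_placement relative start of elongating-polymerase placement;
#'   reads fall uniformly from here to `TES - tes_margin`.
#' @param tes_margin bases before the TES left unoccupied.
#' @param min_gene_length minimum simulated gene length.
#' @param spike_prefix chromosome prefix for spike-in reads.
#' @param seed master seed; every random draw derives from it.
#' @return classed list of parameters (`sim_config`).
#' @export
sim_config <- function(n_genes = 500L, n_targets = 50L, replicates = 2L,
                       gene_length_meanlog = log(4000), gene_length_sdlog = 0.4,
                       initiation_meanlog = 0, initiation_sdlog = 0.5,
                       release_shape1 = 2, release_shape2 = 3,
                       target_release_shape1 = 1, target_release_shape2 = 15,
                       release_multiplier = 3,
                       termination_weight = 1,
                       nb_dispersion = 0.05,
                       reads_per_sample = 1.5e6,
                       depth_distortion = NULL,
                       depth_sdlog = 0.15,
                       spike_reads_base = 5e4,
                       pause_window = c(20L, 60L),
                       body_placement = 61L,
                       tes_margin = 100L,
                       min_gene_length = 700L,
                       spike_prefix = "spike_",
                       seed = 1L) {
  stopifnot(n_targets <= n_genes, release_multiplier >= 1,
            termination_weight >= 0, nb_dispersion >= 0,
            replicates >= 1, reads_per_sample > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_genes, " genes (", x$n_targets, " targets), ",
      x$replicates, " reps/condition, f=", x$release_multiplier,
      ", alpha=", x$nb_dispersion, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# NB draw that degrades to Poisson at alpha = 0
.rnb <- function(mu, alpha) {
  if (alpha == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
}

# lay genes head-to-tail with gaps over a handful of chromosomes
.layout_genes <- function(n, lengths, gap = 2000L) {
  chroms <- c("chr2L", "chr2R", "chr3L", "chr3R", "chrX")
  chrom <- chroms[(seq_len(n) - 1L) %% length(chroms) + 1L]
  strand <- rep(c("+", "-"), length.out = n)
  start <- integer(n)
  off <- stats::setNames(rep(1000L, length(chroms)), chroms)
  for (i in seq_len(n)) {
    start[i] <- off[chrom[i]]
    off[chrom[i]] <- off[chrom[i]] + lengths[i] + gap
  }
  data.frame(chrom = chrom, strand = strand, txStart = start,
             txEnd = start + lengths, stringsAsFactors = FALSE)
}

#' Simulate a spike-in normalized nascent-transcription experiment
#'
#' Draws the experiment described by [sim_config()]: an annotation, one
#' 3' end track per sample, and the ground truth needed to score any
#' downstream call.  Pause reads fall uniformly in the pause window
#' (default +20..+60), elongation reads uniformly from `body_placement`
#' (default +61) to `TES - tes_margin`, so the differential body window
#' (+500..TES-100) sees a pure elongation signal while the early gene body
#' carries the released polymerases.  Spike-in reads are drawn
#' `Poisson(spike_reads_base * lambda_j)`: constant expected abundance per
#' condition, scaled by the same per-sample depth distortion as the primary
#' reads, which is what makes spike totals informative about `lambda_j`.
#'
#' @param config a [sim_config()].
#' @param dir if non-`NULL`, the annotation (`annotation.tsv`), one BED6
#'   read file per sample (`reads_<sample>.bed`), the ground truth
#'   (`ground_truth.tsv`, `samples.tsv`) and the flat `config.txt` are
#'   written there.
#' @return classed list (`sim_experiment`) with `annotation` (table as read
#'   by [read_gene_annotation()]), `genes` (gene models), `tracks` (named
#'   list of [end_count_track()]), `samples` (per-sample condition,
#'   replicate, lambda, spike/primary totals), `truth` (per-gene
#'   `is_target`, `release_control`, `release_treated`,
#'   `true_log2fc_body`, `true_pi_control`, `true_pi_treated`), `config`.
#' @export
simulate_experiment <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  n <- cf$n_genes

  len <- as.integer(round(stats::rlnorm(n, cf$gene_length_meanlog, cf$gene_length_sdlog)))
  short <- len < cf$min_gene_length
  n_redraw <- 0L
  while (any(short)) {            # infeasible draws are redrawn, and logged
    n_redraw <- n_redraw + sum(short)
    len[short] <- as.integer(round(stats::rlnorm(sum(short), cf$gene_length_meanlog,
                                      cf$gene_length_sdlog)))
    short <- len < cf$min_gene_length
  }
  if (n_redraw > 0) .msg(n_redraw, " gene length draw(s) below ",
                         cf$min_gene_length, " bp redrawn")
  layout <- .layout_genes(n, len)
  gene_id <- sprintf("g%04d", seq_len(n))
  annotation <- data.frame(gene_id = gene_id,
                           transcript_id = paste0(gene_id, ".1"),
                           layout,
                           cdsStart = layout$txStart,
                           cdsEnd = layout$txEnd,
                           stringsAsFactors = FALSE)

  is_target <- seq_len(n) %in% sample.int(n, cf$n_targets)
  I <- stats::rlnorm(n, cf$initiation_meanlog, cf$initiation_sdlog)
  r <- ifelse(is_target,
              stats::rbeta(n, cf$target_release_shape1, cf$target_release_shape2),
              stats::rbeta(n, cf$release_shape1, cf$release_shape2))
  r <- pmin(pmax(r, 1e-4), 1)
  r_trt <- ifelse(is_target, pmin(cf$release_multiplier * r, 1), r)
  tw <- cf$termination_weight

  c_p <- 150; c_b <- 1   # promoter-vs-body weight giving field-typical PI
  occ <- function(rel) list(p = c_p * I / rel,
                            b = c_b * I * len * rel / (rel + tw))
  base <- occ(r)
  scale_c <- cf$reads_per_sample / sum(base$p + base$b)

  conditions <- rep(c("control", "treated"), each = cf$replicates)
  reps <- rep(seq_len(cf$replicates), 2L)
  sample_id <- paste0(conditions, "_rep", reps)
  lambda <- cf$depth_distortion
  if (is.null(lambda)) lambda <- stats::rlnorm(length(sample_id), 0, cf$depth_sdlog)
  lambda <- rep(lambda, length.out = length(sample_id))
  stopifnot(all(lambda > 0))

  tss <- ifelse(layout$strand == "+", layout$txStart, layout$txEnd - 1L)
  body_hi <- len - cf$tes_margin
  tracks <- vector("list", length(sample_id))
  names(tracks) <- sample_id
  spike_emitted <- integer(length(sample_id))
  for (j in seq_along(sample_id)) {
    u <- if (conditions[j] == "treated") occ(r_trt) else base
    mu_p <- lambda[j] * scale_c * u$p
    mu_b <- lambda[j] * scale_c * u$b
    k_p <- .rnb(mu_p, cf$nb_dispersion)
    k_b <- .rnb(mu_b, cf$nb_dispersion)
    gi <- c(rep.int(seq_len(n), k_p), rep.int(seq_len(n), k_b))
    lo <- c(rep.int(cf$pause_window[1], sum(k_p)),
            rep.int(cf$body_placement, sum(k_b)))
    hi <- c(rep.int(cf$pause_window[2], sum(k_p)), body_hi[gi[seq_len(sum(k_b)) + sum(k_p)]])
    rel <- lo + floor(stats::runif(length(gi)) * (hi - lo + 1))
    pos <- rel_to_genomic(tss[gi], layout$strand[gi], rel)
    dt <- data.table::data.table(chrom = layout$chrom[gi],
                                 strand = layout$strand[gi], pos = pos)
    agg <- dt[, list(count = .N), by = list(chrom, strand, pos)]
    spike_emitted[j] <- stats::rpois(1L, cf$spike_reads_base * lambda[j])
    tracks[[j]] <- end_count_track(as.data.frame(agg),
                                   spike_total = spike_emitted[j],
                                   sample_id = sample_id[j],
                                   spike_prefix = cf$spike_prefix)
  }

  # model-implied truth: body density is uniform over the placement span, so
  # the PI body window sees a constant fraction of the body occupancy
  frac_bw <- (len - cf$tes_margin - 500 + 1) / (body_hi - cf$body_placement + 1)
  pi_model <- function(u) (u$p / 150) / (u$b * frac_bw / (len - cf$tes_margin - 500 + 1))
  truth <- data.frame(gene_id = gene_id,
                      is_target = is_target,
                      initiation = I,
                      release_control = r,
                      release_treated = r_trt,
                      mu_promoter_control = scale_c * base$p,
                      mu_body_window_control = scale_c * base$b * frac_bw,
                      true_log2fc_body = log2((r_trt / (r_trt + tw)) /
                                              (r / (r + tw))),
                      true_pi_control = pi_model(base),
                      true_pi_treated = pi_model(occ(r_trt)),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, condition = conditions,
                        replicate = reps, lambda = lambda,
                        spike_total = spike_emitted,
                        primary_total = vapply(tracks, `[[`, numeric(1),
                                               "primary_total"),
                        stringsAsFactors = FALSE)
  genes <- local({
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    utils::write.table(annotation, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    suppressMessages(read_gene_annotation(tmp, min_length = cf$min_gene_length))
  })
  out <- structure(list(annotation = annotation, genes = genes,
                        tracks = tracks, samples = samples, truth = truth,
                        config = cf),
                   class = "sim_experiment")
  if (!is.null(dir)) .write_sim_experiment(out, dir)
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment: ", nrow(x$truth), " genes (",
      sum(x$truth$is_target), " targets), samples: ",
      paste(x$samples$sample_id, collapse = " "), "\n", sep = "")
  invisible(x)
}

.write_sim_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"), "ground_truth")
  write_tsv(sim$samples, file.path(dir, "samples.tsv"), "samples")
  cf <- sim$config
  keys <- names(cf)[vapply(cf, function(v) is.numeric(v) || is.character(v),
                           logical(1))]
  writeLines(vapply(keys, function(k)
    paste0(k, "=", paste(cf[[k]], collapse = ",")), character(1)),
    file.path(dir, "config.txt"))
  cf_seed_stream <- sum(utf8ToInt(paste(cf$seed, collapse = ""))) # stable
  for (j in seq_len(nrow(sim$samples))) {
    trk <- sim$tracks[[j]]
    reads <- trk$counts[rep(seq_len(nrow(trk$counts)), trk$counts$count), ]
    set.seed((cf$seed + cf_seed_stream + j) %% .Machine$integer.max)
    spike_pos <- sort(sample.int(1e6, trk$spike_total, replace = TRUE))
    bed <- data.frame(
      chrom = c(reads$chrom, rep(paste0(cf$spike_prefix, "chr1"),
                                 trk$spike_total)),
      start = c(reads$pos, spike_pos),
      name = ".", score = 0L,
      strand = c(reads$strand, rep("+", trk$spike_total)))
    bed$end <- bed$start + 1L
    bed <- bed[, c("chrom", "start", "end", "name", "score", "strand")]
    data.table::fwrite(bed, file.path(dir, paste0("reads_",
                                                  sim$samples$sample_id[j],
                                                  ".bed")),
                       sep = "\t", col.names = FALSE)
  }
  invisible(dir)
}

#' Simulate per-peak ChIP counts with a global gain and spike-ins
#'
#' Peak counts follow `NB(mean = baseline * lambda_j * (1 + gamma)^treated *
#' (1 + delta)^(treated & target))`: `gamma` is a global treatment gain on
#' every peak (the genome-wide acetylation increase an HDAC-inhibition
#' experiment produces) and `delta` an extra gain at target peaks.  Spike
#' totals are `Poisson(spike_reads_base * lambda_j)`, independent of
#' condition and of the gain — so library-size normalization absorbs a
#' global gain while spike-in normalization recovers it.
#'
#' @param n_peaks number of peaks (ignored when `peaks` is given).
#' @param peaks optional peak data.frame (`chrom`, `start`, `end`, `name`);
#'   default peaks are laid out 400 bp wide along chr2L.
#' @param is_target logical per peak; default: the first
#'   `round(0.1 * n_peaks)` peaks after shuffling.
#' @param gamma,delta global and target-extra treatment gains (>= 0).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline peak mean.
#' @param replicates replicates per condition.
#' @param nb_dispersion NB dispersion.
#' @param depth_distortion per-sample `lambda_j` or `NULL` to draw
#'   log-normal(0, `depth_sdlog`).
#' @param depth_sdlog sd of drawn log depth distortions.
#' @param spike_reads_base expected spike reads at `lambda = 1`.
#' @param seed master seed.
#' @return classed list (`sim_chip`): `peaks`, `counts` (peaks x samples),
#'   `samples`, `truth` (`is_target`, `true_log2fc`), parameters.
#' @export
simulate_chip_peaks <- function(n_peaks = 300L, peaks = NULL, is_target = NULL,
                                gamma = 1, delta = 0,
                                baseline_meanlog = log(200),
                                baseline_sdlog = 0.5,
                                replicates = 2L, nb_dispersion = 0.05,
                                depth_distortion = NULL, depth_sdlog = 0.15,
                                spike_reads_base = 5e4, seed = 1L) {
  stopifnot(gamma >= 0, delta >= 0)
  set.seed(seed)
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = "chr2L",
                        start = seq_len(n_peaks) * 2000L,
                        name = sprintf("peak%04d", seq_len(n_peaks)),
                        stringsAsFactors = FALSE)
    peaks$end <- peaks$start + 400L
    peaks$summit <- peaks$start + 200L
    peaks <- peaks[, c("chrom", "start", "end", "name", "summit")]
  }
  n_peaks <- nrow(peaks)
  if (is.null(is_target))
    is_target <- seq_len(n_peaks) %in% sample.int(n_peaks,
                                                  round(0.1 * n_peaks))
  baseline <- stats::rlnorm(n_peaks, baseline_meanlog, baseline_sdlog)
  conditions <- rep(c("control", "treated"), each = replicates)
  sample_id <- paste0(conditions, "_rep", rep(seq_len(replicates), 2L))
  lambda <- depth_distortion
  if (is.null(lambda)) lambda <- stats::rlnorm(length(sample_id), 0, depth_sdlog)
  lambda <- rep(lambda, length.out = length(sample_id))

  gain <- ifelse(is_target, (1 + gamma) * (1 + delta), 1 + gamma)
  counts <- matrix(0L, n_peaks, length(sample_id),
                   dimnames = list(peaks$name, sample_id))
  for (j in seq_along(sample_id)) {
    mu <- baseline * lambda[j] * (if (conditions[j] == "treated") gain else 1)
    counts[, j] <- .rnb(mu, nb_dispersion)
  }
  spike <- stats::rpois(length(sample_id), spike_reads_base * lambda)
  samples <- data.frame(sample_id = sample_id, condition = conditions,
                        replicate = rep(seq_len(replicates), 2L),
                        lambda = lambda, spike_total = spike,
                        primary_total = colSums(counts),
                        stringsAsFactors = FALSE)
  structure(list(peaks = peaks, counts = counts, samples = samples,
                 truth = data.frame(name = peaks$name, is_target = is_target,
                                    true_log2fc = log2(gain),
                                    stringsAsFactors = FALSE),
                 gamma = gamma, delta = delta, seed = seed),
            class = "sim_chip")
}

#' @export
print.sim_chip <- function(x, ...) {
  cat("sim_chip: ", nrow(x$counts), " peaks (", sum(x$truth$is_target),
      " targets), gamma=", x$gamma, " delta=", x$delta, "\n", sep = "")
  invisible(x)
}
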