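#' Pipeline configuration
#'
#' Bundles every threshold and window the end-to-end run applies, defaulted
#' to the study's printed values, plus either a simulator configuration or
#' paths to an annotation and per-sample BED6 read files.
#'
#' @param sim a [sim_config()] (used when no input paths are given).
#' @param annotation optional path to an annotation table; when given,
#'   `reads` must map sample ids to BED6 files and `conditions` give each
#'   sample's condition.
#' @param reads named character vector of BED6 paths (names = sample ids).
#' @param conditions named character vector of condition labels per sample.
#' @param contrast `c(treatment, control)` condition labels.
#' @param spike_prefix spike-in chromosome prefix.
#' @param promoter_window,body_start,tes_offset quantification windows.
#' @param expressed_log2_tpm expressed-gene threshold on mean log2(TPM+1).
#' @param up_down_fdr,unchanged_fdr differential class thresholds.
#' @param fold_gain acetylation gain threshold (linear fold).
#' @param metagene_offsets relative offsets of the metagene matrix.
#' @param pause_test_window,body_test_window windows of the paired
#'   pause-site and early-body tests.
#' @param seed master seed for the simulate stage.
#' @return classed list (`run_config`).
#' @export
run_config <- function(sim = sim_config(seed = seed),
                       annotation = NULL, reads = NULL, conditions = NULL,
                       contrast = c("treated", "control"),
                       spike_prefix = "spike_",
                       promoter_window = c(-50L, 100L),
                       body_start = 500L, tes_offset = 100L,
                       expressed_log2_tpm = 3,
                       up_down_fdr = 0.1, unchanged_fdr = 0.5,
                       fold_gain = 1.5,
                       metagene_offsets = c(-200:-1, 1:1000),
                       pause_test_window = c(1L, 70L),
                       body_test_window = c(70L, 200L),
                       seed = 1L) {
  stopifnot(up_down_fdr > 0, up_down_fdr < 1, unchanged_fdr > 0,
            unchanged_fdr < 1)
  if (!is.null(annotation)) {
    stopifnot(!is.null(reads), !is.null(conditions),
              all(names(reads) == names(conditions)))
    for (p in c(annotation, reads))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pausing pipeline
#'
#' Simulate (or load) the experiment, count gene-body windows, test them
#' with spike-in normalized NB Wald statistics, classify genes, filter
#' expressed genes, compute pausing indices per sample, build metagene
#' matrices for the up-regulated set with the paired pause-site and
#' early-body window tests, and write every table plus a run manifest
#' (parameters, package version, input checksums) under `outdir`.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory results: `genes`, `fit`
#'   (class `nb_diff`), `expressed`, `pi` (per-sample pausing tables),
#'   `metagene`, `pause_test`, `body_test`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    .msg(...)
  }
  inputs <- character()

  if (is.null(config$annotation)) {
    logf("simulate: seed=", config$sim$seed)
    sim <- simulate_experiment(config$sim)
    genes <- sim$genes
    tracks <- sim$tracks
    conditions <- sim$samples$condition
    write_tsv(sim$truth, file.path(outdir, "ground_truth.tsv"), "ground_truth")
    write_tsv(sim$samples, file.path(outdir, "samples.tsv"), "samples")
  } else {
    logf("load: ", config$annotation)
    genes <- read_gene_annotation(config$annotation)
    tracks <- lapply(config$reads, read_end_counts,
                     spike_prefix = config$spike_prefix)
    names(tracks) <- names(config$reads)
    conditions <- unname(config$conditions)
    inputs <- c(config$annotation, unname(config$reads))
  }

  logf("count: body windows +", config$body_start, "..TES-",
       config$tes_offset, " over ", nrow(genes), " genes")
  cm <- count_matrix(tracks, genes, region = "body",
                     body_start = config$body_start,
                     tes_offset = config$tes_offset)
  keep <- !is.na(cm$counts[, 1L])
  if (any(!keep)) logf("excluded ", sum(!keep), " short gene(s) from DE")

  fit <- nb_diff(cm$counts[keep, , drop = FALSE], conditions,
                 contrast = config$contrast,
                 spike_totals = cm$spike_totals,
                 up_down_fdr = config$up_down_fdr,
                 unchanged_fdr = config$unchanged_fdr)
  write_tsv(fit$table, file.path(outdir, "differential.tsv"), "differential")
  logf("diff: ", sum(fit$table$class == "up"), " up / ",
       sum(fit$table$class == "down"), " down / ",
       sum(fit$table$class == "unchanged"), " unchanged at FDR<",
       config$up_down_fdr, "/>", config$unchanged_fdr)

  tpm <- body_tpm_matrix(tracks, genes, body_start = config$body_start,
                         tes_offset = config$tes_offset)
  expressed <- filter_expressed(tpm[keep, , drop = FALSE],
                                config$expressed_log2_tpm)
  logf("expressed: ", length(expressed), " genes above mean log2(TPM+1) > ",
       config$expressed_log2_tpm)

  pi_tabs <- lapply(tracks, pausing_index, genes = genes,
                    promoter_window = config$promoter_window,
                    body_start = config$body_start,
                    body_tes_offset = config$tes_offset)
  pi_all <- do.call(rbind, lapply(names(pi_tabs), function(s)
    cbind(sample_id = s, pi_tabs[[s]])))
  write_tsv(pi_all, file.path(outdir, "pausing_index.tsv"), "pausing_index")

  up <- fit$table$feature_id[fit$table$class == "up"]
  mg_set <- if (length(up) >= 2L) up else genes$gene_id[keep]
  sf <- spike_size_factors(cm$spike_totals)
  mg <- metagene_profile(tracks, genes[genes$gene_id %in% mg_set, ],
                         conditions, offsets = config$metagene_offsets,
                         size_factors = sf)
  write_tsv(mg$profile, file.path(outdir, "metagene_profile.tsv"), "metagene")
  pause_test <- window_paired_test(mg, config$pause_test_window,
                                   a = config$contrast[2L],
                                   b = config$contrast[1L])
  body_test <- window_paired_test(mg, config$body_test_window,
                                  a = config$contrast[2L],
                                  b = config$contrast[1L])
  logf("paired tests on ", length(mg$gene_ids), " genes: pause window ",
       paste(config$pause_test_window, collapse = ".."), " t=",
       signif(pause_test$t, 4), ", body window ",
       paste(config$body_test_window, collapse = ".."), " t=",
       signif(body_test$t, 4))

  manifest <- list(
    package = "spikepause",
    version = as.character(utils::packageVersion("spikepause")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    parameters = config[!vapply(config, is.list, logical(1))],
    sim = if (is.null(config$annotation))
      config$sim[vapply(config$sim, is.numeric, logical(1))] else NULL,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    outputs = list.files(outdir)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done: ", length(manifest$outputs), " artifact(s) in ", outdir)
  invisible(list(genes = genes, fit = fit, expressed = expressed,
                 pi = pi_tabs, metagene = mg, pause_test = pause_test,
                 body_test = body_test, manifest = manifest))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key=value` (comments `#`, blanks ignored); values
#' that parse as numbers become numeric, comma-separated values become
#' vectors.  Recognized keys override [run_config()] defaults; `sim.*`
#' keys override [sim_config()] fields.
#'
#' @param path configuration file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: '", lines[which(bad)[1]], "'")
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- lapply(kv, function(p) {
    v <- strsplit(trimws(p[[2L]]), ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(vals) <- keys
  sim_keys <- grepl("^sim\\.", keys)
  sim_args <- stats::setNames(vals[sim_keys], sub("^sim\\.", "", keys[sim_keys]))
  run_args <- vals[!sim_keys]
  unknown <- setdiff(names(run_args), names(formals(run_config)))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  unknown_sim <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(unknown_sim)) stop("unknown config key: sim.", unknown_sim[1])
  if ("seed" %in% names(run_args) && !("seed" %in% names(sim_args)))
    sim_args$seed <- run_args$seed
  run_args$sim <- do.call(sim_config, sim_args)
  do.call(run_config, run_args)
}
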