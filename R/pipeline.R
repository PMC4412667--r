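#' Pipeline run configuration
#'
#' Bundles every threshold the calling chain uses, with validation. The
#' hard floor on panel size is 3 samples (below that a median baseline is
#' meaningless); panels smaller than 8 trigger a warning because the
#' median is not robust to a carrier at the same locus.
#'
#' @param p_cnv Probe/region CNV significance threshold (default 0.05).
#' @param p_seed2 Secondary seeding threshold (default 0.2).
#' @param p_loh LOH anchor threshold (default 0.01).
#' @param min_probes Minimum probes per CNV call (default 45).
#' @param min_cnv_size Minimum CNV size in bp (default 1e6).
#' @param min_loh_size Minimum reportable LOH size in bp (default 5e6).
#' @param max_gap Mergeable unmarked gap in probes (default 5).
#' @param window LOH window size in sites (default 25).
#' @param min_depth Minimum usable site depth (default 10).
#' @param min_samples Minimum panel size (default 8).
#' @param n_smooth Depth smoothing span (default 10).
#' @param loh_directional Directional gate on LOH windows (default TRUE).
#' @param seed Optional integer seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(p_cnv = 0.05, p_seed2 = 0.2, p_loh = 0.01,
                       min_probes = 45L, min_cnv_size = 1e6,
                       min_loh_size = 5e6, max_gap = 5L, window = 25L,
                       min_depth = 10L, min_samples = 8L, n_smooth = 10L,
                       loh_directional = TRUE, seed = NULL) {
  stopifnot(p_cnv > 0, p_cnv < 1, p_seed2 >= p_cnv, p_seed2 < 1,
            p_loh > 0, p_loh < 1, min_probes >= 4, min_cnv_size >= 0,
            min_loh_size >= 0, max_gap >= 0, window >= 4, min_depth >= 1,
            n_smooth >= 0)
  if (min_samples < 3L) {
    abort("min_samples below the hard floor of 3")
  }
  if (min_samples < 8L) {
    warn("min_samples below 8: the median baseline may not be robust")
  }
  structure(list(p_cnv = p_cnv, p_seed2 = p_seed2, p_loh = p_loh,
                 min_probes = as.integer(min_probes),
                 min_cnv_size = min_cnv_size, min_loh_size = min_loh_size,
                 max_gap = as.integer(max_gap), window = as.integer(window),
                 min_depth = as.integer(min_depth),
                 min_samples = as.integer(min_samples),
                 n_smooth = as.integer(n_smooth),
                 loh_directional = loh_directional, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key: ", unknown[1]))
  }
  do.call(run_config, vals)
}

#' Run the full calling pipeline over a panel
#'
#' Normalizes depths, then tests every sample against its leave-one-out
#' median baseline: CNV calling always, LOH calling and UPD
#' classification when allele counts are supplied, followed by the
#' CNV/LOH consistency cross-check. Each sample's own values are excluded
#' from the baseline medians so large events cannot suppress themselves.
#'
#' @param depths Long depth tibble `(sample_id, region_id, depth)`.
#' @param targets Target tibble.
#' @param allele_counts Optional long allele-count tibble.
#' @param sites Sites tibble (required with `allele_counts`).
#' @param config A [run_config()].
#' @param cytobands Optional cytoband tibble for karyotype strings.
#' @param test_samples Samples to test (default: every sample in the
#'   panel); the full panel always anchors the baselines.
#' @return A `sparsecnv_run`: list with `cnv_calls`, `loh_calls`,
#'   `consistency`, `karyotypes`, per-sample `cnv_scans` / `loh_scans`,
#'   and a `manifest`. `tidy()` returns the combined call table.
#' @export
run_pipeline <- function(depths, targets, allele_counts = NULL,
                         sites = NULL, config = run_config(),
                         cytobands = NULL, test_samples = NULL) {
  panel_samples <- sort(unique(depths$sample_id))
  samples <- if (is.null(test_samples)) panel_samples else {
    stopifnot(all(test_samples %in% panel_samples))
    sort(test_samples)
  }
  if (length(panel_samples) < config$min_samples) {
    abort(sprintf(paste0("panel has %d samples; the multi-sample median ",
                         "baseline needs at least %d (config min_samples)"),
                  length(panel_samples), config$min_samples))
  }
  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  ratios <- collect(normalize_depths(depths, targets,
                                     n_smooth = config$n_smooth))
  has_sex_chrom <- any(is_chrx(targets$chrom) | is_chry(targets$chrom))
  sexes <- if (has_sex_chrom) collect(infer_sex(ratios)) else NULL
  sex_vec <- if (!is.null(sexes)) setNames(sexes$sex, sexes$sample_id)

  tables <- NULL
  if (!is.null(allele_counts)) {
    if (is.null(sites)) abort("allele_counts given without a site table")
    tables <- collect(add_rhet(allele_counts, sites,
                               min_depth = config$min_depth))
  }

  cnv_scans <- list()
  loh_scans <- list()
  loh_calls <- list()
  consistency <- list()
  for (s in samples) {
    panel <- ratios[ratios$sample_id != s, ]
    n_panel <- length(panel_samples) - 1L
    baseline <- collect(build_baseline(
      panel, targets, min_samples = min(config$min_samples, n_panel),
      sex = sex_vec))
    test_rm <- normalize_by_baseline(ratios[ratios$sample_id == s, ],
                                     baseline)
    panel_rm <- normalize_by_baseline(panel, baseline)
    scan <- collect(call_cnvs(
      test_rm, panel_rm, targets,
      p_cnv = config$p_cnv, p_seed2 = config$p_seed2,
      min_probes = config$min_probes, min_size = config$min_cnv_size,
      max_gap = config$max_gap, n_smooth = config$n_smooth))
    cnv_scans[[s]] <- scan

    if (!is.null(tables)) {
      rbase <- collect(build_rhet_baseline(
        tables[tables$sample_id != s, ],
        min_samples = min(config$min_samples, n_panel)))
      lscan <- collect(call_loh(
        tables[tables$sample_id == s, ], rbase,
        window = config$window, p_loh = config$p_loh,
        directional = config$loh_directional))
      loh_scans[[s]] <- lscan
      classified <- classify_upd(tidy(lscan), tidy(scan),
                                 min_size = config$min_loh_size)
      loh_calls[[s]] <- classified
      consistency[[s]] <- collect(check_consistency(
        classified, tidy(scan), min_size = config$min_cnv_size))
    }
  }

  cnv_calls <- bind_rows(purrr::map(cnv_scans, tidy))
  loh_tbl <- if (length(loh_calls) > 0L) bind_rows(loh_calls) else NULL
  karyotypes <- NULL
  if (!is.null(sexes)) {
    karyotypes <- purrr::map_chr(samples, function(s) {
      format_karyotype(sexes[sexes$sample_id == s, ],
                       tidy(cnv_scans[[s]]), cytobands)
    })
    names(karyotypes) <- samples
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sparsecnv")),
    config = unclass(config),
    n_samples = length(panel_samples),
    n_targets = nrow(targets),
    n_sites = if (!is.null(sites)) nrow(sites) else 0L,
    per_sample = tibble(
      sample_id = samples,
      n_cnv_calls = vapply(samples, function(s)
        nrow(cnv_scans[[s]]$calls), integer(1)),
      probe_hit_rate = vapply(samples, function(s)
        glance(cnv_scans[[s]])$probe_hit_rate, numeric(1)),
      n_loh_calls = vapply(samples, function(s)
        if (is.null(loh_calls[[s]])) 0L else nrow(loh_calls[[s]]),
        integer(1))),
    warnings = warnings_seen)

  structure(list(cnv_calls = cnv_calls, loh_calls = loh_tbl,
                 consistency = if (length(consistency) > 0L)
                   bind_rows(consistency) else NULL,
                 karyotypes = karyotypes, cnv_scans = cnv_scans,
                 loh_scans = loh_scans, manifest = manifest,
                 config = config),
            class = "sparsecnv_run")
}

#' @export
print.sparsecnv_run <- function(x, ...) {
  cat(sprintf("<sparsecnv_run> %d samples, %d CNV call(s)%s\n",
              x$manifest$n_samples, nrow(x$cnv_calls),
              if (!is.null(x$loh_calls))
                sprintf(", %d LOH call(s)", nrow(x$loh_calls)) else ""))
  invisible(x)
}

#' @method tidy sparsecnv_run
#' @export
tidy.sparsecnv_run <- function(x, ...) {
  cnv <- x$cnv_calls
  if (nrow(cnv) > 0L) cnv$type <- "cnv"
  if (is.null(x$loh_calls) || nrow(x$loh_calls) == 0L) return(cnv)
  loh <- x$loh_calls
  loh$type <- "loh"
  bind_rows(cnv, loh)
}

#' @method glance sparsecnv_run
#' @export
glance.sparsecnv_run <- function(x, ...) {
  x$manifest$per_sample
}

#' Write a run manifest to YAML
#'
#' The manifest snapshots the configuration, input dimensions, per-stage
#' record counts and every warning raised during the run. It is written
#' atomically (temp file + rename).
#'
#' @param run A `sparsecnv_run`.
#' @param path Output YAML path.
#' @export
write_manifest <- function(run, path) {
  m <- run$manifest
  m$per_sample <- as.list(as.data.frame(m$per_sample))
  tmp <- paste0(path, ".tmp")
  yaml::write_yaml(m, tmp)
  file.rename(tmp, path)
  invisible(path)
}
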