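#' Per-target depth from aligned-base counts
#'
#' Converts per-target aligned-base counts into mean depth-of-coverage
#' (reads-per-base): TD_i = bases_i / length_i. Mean-depth input passes
#' through unchanged.
#'
#' @param counts Tibble `(sample_id, region_id, value)` where `value` is an
#'   aligned-base count (or a mean depth when `dialect = "mean_depth"`).
#' @param targets Target tibble.
#' @param dialect `"base_count"` (default here) or `"mean_depth"`.
#' @return Long tibble `(sample_id, region_id, depth)`.
#' @export
compute_region_depth <- function(counts, targets,
                                 dialect = c("base_count", "mean_depth")) {
  dialect <- match.arg(dialect)
  len <- setNames(targets$end - targets$start, targets$region_id)
  if (any(len <= 0)) abort("zero-length target region")
  out <- counts
  names(out)[names(out) == "value"] <- "depth"
  if (dialect == "base_count") {
    out$depth <- unname(out$depth / len[out$region_id])
  }
  out[c("sample_id", "region_id", "depth")]
}

# forward moving average over windows [i, i+n] truncated at the chromosome
# end; the divisor is the actual window size, and windows never cross
# chromosome boundaries.
smooth_vector <- function(x, n) {
  N <- length(x)
  if (N == 0L) return(numeric(0))
  w <- pmin(n + 1L, N - seq_len(N) + 1L)
  cs <- c(0, cumsum(x))
  (cs[pmin(seq_len(N) + n + 1L, N + 1L)] - cs[seq_len(N)]) / w
}

#' Smooth per-target depths along the genome
#'
#' Replaces each target's depth TD_i by the forward moving average TD_mi
#' over targets i..i+n on the same chromosome (n + 1 values; truncated near
#' the chromosome end). Smoothing stabilizes the ratio fluctuation between
#' adjacent targets before baseline normalization.
#'
#' @param depth Numeric vector of TD_i in genome order.
#' @param chrom Chromosome of each target (windows never cross a boundary).
#' @param n Number of downstream targets averaged in (default 10, i.e.
#'   11-target windows).
#' @return Numeric vector TD_mi of the same length.
#' @export
smooth_depth <- function(depth, chrom, n = 10L) {
  out <- numeric(length(depth))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2L) {
      warn(sprintf("chromosome %s has < 2 targets; smoothing is a no-op", ch))
      out[idx] <- depth[idx]
    } else {
      out[idx] <- smooth_vector(depth[idx], n)
    }
  }
  out
}

#' Pre-normalization ratio
#'
#' preR_i = TD_i / mean(TD) over all targets — the naive library-size
#' normalization before smoothing and baseline correction.
#'
#' @param depth Numeric TD_i vector.
#' @return Numeric preR_i vector.
#' @export
compute_pre_ratio <- function(depth) {
  m <- mean(depth)
  if (m == 0) abort("empty library: all target depths are zero")
  depth / m
}

#' Depth coefficient R_i
#'
#' R_i = TD_mi / (mean TD_mi over autosomal targets). The divisor excludes
#' sex chromosomes so that male samples do not deflate the genome-wide
#' scale; R_i is still defined for X/Y targets.
#'
#' @param td_m Smoothed depth vector TD_mi.
#' @param chrom Chromosome per target.
#' @return List with `r` (ratio vector) and `autosomal_mean` (the divisor).
#' @export
compute_ratio <- function(td_m, chrom) {
  auto <- is_autosome(chrom)
  if (!any(auto)) abort("no autosomal targets to normalize against")
  am <- mean(td_m[auto])
  if (am == 0) abort("autosomal mean depth is zero")
  list(r = td_m / am, autosomal_mean = am)
}

#' Full per-sample depth normalization
#'
#' Runs the per-sample half of the normalization chain for every sample in
#' a long depth table: TD_i -> preR_i (naive ratio), TD_mi (smoothed),
#' R_i (autosome-scaled depth coefficient), plus an unsmoothed autosome-
#' scaled ratio `r_raw` used for boundary refinement.
#'
#' @param depths Long tibble `(sample_id, region_id, depth)`.
#' @param targets Target tibble.
#' @param n_smooth Downstream targets in the smoothing window (default 10).
#' @return Tibble with one row per sample x target: sample_id, region_id,
#'   index, chrom, start, end, td, pre_r, td_m, r, r_raw, autosomal_mean.
#' @export
normalize_depths <- function(depths, targets, n_smooth = 10L) {
  joined <- left_join(depths, targets, by = "region_id")
  if (any(is.na(joined$index))) {
    abort(paste0("depth table region not in target set: ",
                 joined$region_id[is.na(joined$index)][1]))
  }
  joined <- joined[order(joined$sample_id, joined$index), ]
  out <- joined %>%
    group_by(.data$sample_id) %>%
    mutate(
      td = .data$depth,
      pre_r = compute_pre_ratio(.data$td),
      td_m = smooth_depth(.data$td, .data$chrom, n = n_smooth)
    ) %>%
    ungroup()
  per_sample <- split(seq_len(nrow(out)), out$sample_id)
  out$r <- NA_real_
  out$r_raw <- NA_real_
  out$autosomal_mean <- NA_real_
  for (ix in per_sample) {
    cr <- compute_ratio(out$td_m[ix], out$chrom[ix])
    out$r[ix] <- cr$r
    out$r_raw[ix] <- out$td[ix] / cr$autosomal_mean
    out$autosomal_mean[ix] <- cr$autosomal_mean
  }
  out[c("sample_id", "region_id", "index", "chrom", "start", "end",
        "td", "pre_r", "td_m", "r", "r_raw", "autosomal_mean")]
}

#' Build the multi-sample median baseline (panel of normals)
#'
#' The per-target median of R_i across the sample collection is the robust
#' baseline that replaces a matched control. Targets with zero depth in
#' more than half the panel, or with a zero median, are masked genome-wide.
#' When sample sex is supplied, X/Y baselines are computed within sex
#' groups (a mixed-sex median would sit between the female and male
#' levels); without it, X/Y medians use all samples and a warning is
#' emitted if the panel contains sex-chromosome targets.
#'
#' @param ratios Output of [normalize_depths()] for the whole panel.
#' @param targets Target tibble.
#' @param min_samples Minimum panel size (default 8; the method is
#'   unreliable below this).
#' @param sex Optional named vector mapping sample_id to "XX"/"XY".
#' @return Tibble `(region_id, index, chrom, median_r, n_samples, masked)`.
#' @export
build_baseline <- function(ratios, targets, min_samples = 8L, sex = NULL) {
  samples <- unique(ratios$sample_id)
  if (length(samples) < min_samples) {
    abort(sprintf(paste0("panel has %d samples but the median baseline ",
                         "requires at least %d for reliable calling"),
                  length(samples), min_samples))
  }
  rmat <- ratio_matrix(ratios, targets, "r")
  rawmat <- ratio_matrix(ratios, targets, "r_raw")
  tdmat <- ratio_matrix(ratios, targets, "td")
  med <- unname(apply(rmat, 1L, median))
  med_raw <- unname(apply(rawmat, 1L, median))
  sexchrom <- is_chrx(targets$chrom) | is_chry(targets$chrom)
  if (any(sexchrom)) {
    if (is.null(sex)) {
      warn("sex-chromosome targets present but sample sex unknown; X/Y baseline uses all samples")
    } else {
      for (grp in c("XX", "XY")) {
        cols <- colnames(rmat) %in% names(sex)[sex == grp]
        if (sum(cols) >= 2L) {
          grp_rows <- if (grp == "XX") is_chrx(targets$chrom) else sexchrom
          med[grp_rows & sexchrom] <- apply(rmat[grp_rows & sexchrom, cols,
                                                 drop = FALSE], 1L, median)
        }
      }
    }
  }
  zero_frac <- rowMeans(tdmat == 0)
  masked <- med <= 0 | zero_frac > 0.5
  tibble(region_id = rownames(rmat), index = targets$index,
         chrom = targets$chrom, median_r = med, median_r_raw = med_raw,
         n_samples = length(samples), masked = masked)
}

# targets x samples matrix of one ratio column, rows in index order
ratio_matrix <- function(ratios, targets, col) {
  wide <- tidyr::pivot_wider(ratios[c("sample_id", "region_id", col)],
                             names_from = "sample_id",
                             values_from = dplyr::all_of(col))
  wide <- wide[match(targets$region_id, wide$region_id), ]
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$region_id
  m
}

#' Normalize a sample's depth coefficients by the panel baseline
#'
#' R_mi = R_i / median_i(panel). Masked baseline targets propagate as NA
#' and are excluded downstream.
#'
#' @param ratios One sample's rows from [normalize_depths()].
#' @param baseline Baseline tibble from [build_baseline()].
#' @return `ratios` with `r_m` (and `r_m_raw`, the unsmoothed analogue)
#'   columns appended.
#' @export
normalize_by_baseline <- function(ratios, baseline) {
  med <- setNames(ifelse(baseline$masked, NA_real_, baseline$median_r),
                  baseline$region_id)
  med_raw <- setNames(ifelse(baseline$masked | baseline$median_r_raw <= 0,
                             NA_real_, baseline$median_r_raw),
                      baseline$region_id)
  out <- ratios
  out$r_m <- unname(out$r / med[out$region_id])
  out$r_m_raw <- unname(out$r_raw / med_raw[out$region_id])
  out
}
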