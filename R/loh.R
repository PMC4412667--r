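#' Heterozygosity coefficient R_Het
#'
#' R_Het = min(BAF/(1-BAF), (1-BAF)/BAF): 1 at perfect heterozygosity
#' (BAF 0.5), 0 at homozygosity (BAF 0 or 1), symmetric under
#' BAF <-> 1 - BAF.
#'
#' @param baf B-allele frequency in [0, 1] (vectorized).
#' @return R_Het in [0, 1].
#' @export
compute_rhet <- function(baf) {
  stopifnot(all(baf >= 0 & baf <= 1, na.rm = TRUE))
  out <- pmin(baf / (1 - baf), (1 - baf) / baf)
  out[baf == 0 | baf == 1] <- 0
  out
}

#' Per-site BAF and R_Het for one or more samples
#'
#' Joins raw allele counts with the site table and derives depth, BAF and
#' R_Het. Sites below `min_depth` reads are flagged unusable (their BAF is
#' too noisy to interpret) and are excluded from windows downstream rather
#' than zeroed.
#'
#' @param counts Long tibble `(sample_id, site_id, ref_count, alt_count)`.
#' @param sites Sites tibble.
#' @param min_depth Minimum total reads for a usable site (default 10).
#' @return Tibble with sample_id, site_id, chrom, pos, ref_count,
#'   alt_count, depth, baf, r_het, usable.
#' @export
add_rhet <- function(counts, sites, min_depth = 10L) {
  df <- left_join(counts, sites[c("site_id", "chrom", "pos")], by = "site_id")
  if (any(is.na(df$chrom))) {
    abort(paste0("allele counts at unknown site: ",
                 df$site_id[is.na(df$chrom)][1]))
  }
  df$depth <- df$ref_count + df$alt_count
  df$baf <- ifelse(df$depth > 0, df$alt_count / df$depth, NA_real_)
  df$r_het <- ifelse(is.na(df$baf), NA_real_, compute_rhet(df$baf))
  df$usable <- df$depth >= min_depth
  df[order(df$sample_id, chrom_rank(df$chrom), df$pos), ]
}

#' Per-site median R_Het baseline across the panel
#'
#' The per-site median R_Het over samples with usable depth stands in for
#' a matched control, exactly as the per-probe depth median does for CNV.
#' Sites usable in fewer than `min_samples` samples are masked.
#'
#' @param tables Output of [add_rhet()] across the panel.
#' @param min_samples Minimum usable samples per site (default 8).
#' @return Tibble `(site_id, chrom, pos, median_rhet, n_usable, masked)`.
#' @export
build_rhet_baseline <- function(tables, min_samples = 8L) {
  n_panel <- length(unique(tables$sample_id))
  if (n_panel < min_samples) {
    abort(sprintf("panel has %d samples but the R_Het baseline requires at least %d",
                  n_panel, min_samples))
  }
  tables %>%
    filter(.data$usable) %>%
    group_by(.data$site_id, .data$chrom, .data$pos) %>%
    summarise(median_rhet = median(.data$r_het),
              n_usable = dplyr::n(), .groups = "drop") %>%
    mutate(masked = .data$n_usable < min_samples) %>%
    arrange(chrom_rank(.data$chrom), .data$pos)
}

#' F test comparing one window's R_Het dispersion with the baseline's
#'
#' Sample variances (divisor n - 1) of the test window and the matching
#' baseline-median window are compared by the two-sided F construction:
#' F_upper = S2_max / S2_min, F_under its reciprocal (both with n - 1 and
#' n - 1 degrees of freedom), and p = p_upper + (1 - p_under) where each
#' p is the upper-tail F probability, clipped to 1. Equal variances give
#' p = 1. A zero minimum variance (total loss of dispersion) flags the
#' window and sets p to the smallest representable value.
#'
#' @param test_window Numeric R_Het values for the test sample.
#' @param baseline_window Matching baseline median R_Het values.
#' @return One-row tibble: s2_test, s2_mul, f_upper, f_under, p_value,
#'   flagged.
#' @export
window_f_test <- function(test_window, baseline_window) {
  n <- length(test_window)
  if (length(baseline_window) != n) {
    abort("test and baseline windows must have the same length")
  }
  s2_test <- var(test_window)
  s2_mul <- var(baseline_window)
  s2_max <- max(s2_test, s2_mul)
  s2_min <- min(s2_test, s2_mul)
  if (s2_min == 0) {
    if (s2_max == 0) {
      return(tibble(s2_test = s2_test, s2_mul = s2_mul, f_upper = NA_real_,
                    f_under = NA_real_, p_value = NA_real_, flagged = TRUE))
    }
    return(tibble(s2_test = s2_test, s2_mul = s2_mul, f_upper = Inf,
                  f_under = 0, p_value = .Machine$double.xmin,
                  flagged = TRUE))
  }
  f_upper <- s2_max / s2_min
  f_under <- s2_min / s2_max
  p_upper <- pf(f_upper, n - 1L, n - 1L, lower.tail = FALSE)
  p_under <- pf(f_under, n - 1L, n - 1L, lower.tail = FALSE)
  p <- min(1, p_upper + (1 - p_under))
  tibble(s2_test = s2_test, s2_mul = s2_mul, f_upper = f_upper,
         f_under = f_under, p_value = p, flagged = FALSE)
}

# rolling variance over windows of w consecutive values (divisor w - 1),
# via cumulative sums; returns length(x) - w + 1 values
roll_var <- function(x, w) {
  s <- roll_sum(x, w)
  ss <- roll_sum(x^2, w)
  pmax(0, (ss - s^2 / w) / (w - 1L))
}

#' Per-anchor sliding-window F tests for one sample
#'
#' Slides a window of `window` consecutive usable sites (step 1, never
#' crossing a chromosome) along the genome; each window is anchored at its
#' first site and tested with [window_f_test()]. With
#' `directional = TRUE` (default), an anchor can only go on to seed LOH
#' when the test window's mean R_Het is below the baseline window's mean —
#' dispersion can change without heterozygosity loss, but LOH always pulls
#' R_Het down; gated anchors report p = 1.
#'
#' @param test_table One sample's rows from [add_rhet()].
#' @param baseline Baseline tibble from [build_rhet_baseline()].
#' @param window Sites per window (default 25).
#' @param directional Apply the mean-decrease gate (default TRUE).
#' @return Anchor tibble: chrom, site_id, pos, window_end_pos, p_value,
#'   f_upper, flagged, gated.
#' @export
loh_windows <- function(test_table, baseline, window = 25L,
                        directional = TRUE) {
  df <- left_join(test_table,
                  baseline[c("site_id", "median_rhet", "masked")],
                  by = "site_id")
  df <- df[df$usable & !is.na(df$median_rhet) & !df$masked, ]
  df <- df[order(chrom_rank(df$chrom), df$pos), ]
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    n <- nrow(sub)
    if (n < window) next
    w <- window
    v_test <- roll_var(sub$r_het, w)
    v_mul <- roll_var(sub$median_rhet, w)
    v_max <- pmax(v_test, v_mul)
    v_min <- pmin(v_test, v_mul)
    flagged <- v_min == 0
    f_upper <- ifelse(flagged, Inf, v_max / v_min)
    f_under <- ifelse(flagged, 0, v_min / v_max)
    p <- ifelse(
      flagged,
      ifelse(v_max == 0, NA_real_, .Machine$double.xmin),
      pmin(1, pf(v_max / v_min, w - 1L, w - 1L, lower.tail = FALSE) +
             (1 - pf(v_min / pmax(v_max, .Machine$double.xmin), w - 1L,
                     w - 1L, lower.tail = FALSE))))
    gated <- rep(FALSE, length(p))
    if (directional) {
      m_test <- roll_sum(sub$r_het, w) / w
      m_mul <- roll_sum(sub$median_rhet, w) / w
      gated <- !is.na(p) & !(m_test < m_mul)
      p[gated] <- 1
    }
    out[[length(out) + 1L]] <- tibble(
      chrom = ch,
      site_id = sub$site_id[seq_along(p)],
      pos = sub$pos[seq_along(p)],
      window_end_pos = sub$pos[seq_along(p) + w - 1L],
      p_value = p, f_upper = f_upper, flagged = flagged, gated = gated)
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), site_id = character(),
                  pos = integer(), window_end_pos = integer(),
                  p_value = numeric(), f_upper = numeric(),
                  flagged = logical(), gated = logical()))
  }
  bind_rows(out)
}

#' Initiate LOH intervals from anchor p-values
#'
#' An interval is initiated wherever at least `init_run` consecutive
#' anchors have p below `p_loh`; each maximal such run is one raw
#' interval.
#'
#' @param p Numeric vector of anchor p-values (one chromosome, in order).
#' @param p_loh Significance threshold (default 0.01).
#' @param init_run Consecutive anchors required (default 3).
#' @return Tibble `(from, to)` of 1-based anchor positions.
#' @export
scan_loh <- function(p, p_loh = 0.01, init_run = 3L) {
  hot <- !is.na(p) & p < p_loh
  if (!any(hot)) return(tibble(from = integer(), to = integer()))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= init_run
  tibble(from = starts[keep], to = ends[keep])
}

#' Extend a raw LOH interval across its neighbors
#'
#' Greedily absorbs adjacent anchors with p below `p_loh` in both
#' directions. A single anchor at or above the threshold may be absorbed
#' per excursion, provided the running mean p of the extended interval
#' stays below `mean_p_cap`; two consecutive above-threshold anchors stop
#' the extension.
#'
#' @param p Anchor p-value vector (one chromosome).
#' @param from,to Raw interval bounds (1-based anchor positions).
#' @param p_loh Per-anchor threshold (default 0.01).
#' @param mean_p_cap Running-mean cap for tolerated excursions
#'   (default 0.1).
#' @return List with extended `from` and `to`.
#' @export
extend_loh <- function(p, from, to, p_loh = 0.01, mean_p_cap = 0.1) {
  grow <- function(lo, hi, step) {
    excursion <- FALSE
    repeat {
      nxt <- if (step > 0) hi + 1L else lo - 1L
      if (nxt < 1L || nxt > length(p) || is.na(p[nxt])) break
      if (p[nxt] < p_loh) {
        excursion <- FALSE
      } else {
        if (excursion) break
        new_mean <- mean(p[min(lo, nxt):max(hi, nxt)])
        if (new_mean >= mean_p_cap) break
        excursion <- TRUE
      }
      if (step > 0) hi <- nxt else lo <- nxt
    }
    c(lo, hi)
  }
  r <- grow(from, to, +1L)
  r <- grow(r[1], r[2], -1L)
  list(from = r[1], to = r[2])
}

#' Call LOH intervals for one sample
#'
#' Runs the windowed F-test scan, interval initiation and extension, and
#' converts anchor runs into genomic intervals (an interval spans its
#' first anchor through the last anchor's window end).
#'
#' @param test_table One sample's rows from [add_rhet()].
#' @param baseline Baseline from [build_rhet_baseline()].
#' @param window Sites per window (default 25).
#' @param p_loh Anchor significance threshold (default 0.01).
#' @param init_run Consecutive significant anchors to initiate (default 3).
#' @param mean_p_cap Running-mean cap during extension (default 0.1).
#' @param directional Mean-decrease gate (default TRUE).
#' @return A `loh_scan` object: list with `intervals` and `anchors`
#'   tibbles plus parameters. `tidy()` extracts the intervals.
#' @export
call_loh <- function(test_table, baseline, window = 25L, p_loh = 0.01,
                     init_run = 3L, mean_p_cap = 0.1, directional = TRUE) {
  anchors <- loh_windows(test_table, baseline, window = window,
                         directional = directional)
  sample_id <- test_table$sample_id[1]
  ivs <- list()
  for (ch in unique(anchors$chrom)) {
    sub <- anchors[anchors$chrom == ch, ]
    raw <- scan_loh(sub$p_value, p_loh = p_loh, init_run = init_run)
    if (nrow(raw) == 0L) next
    ext <- purrr::pmap_dfr(raw, function(from, to) {
      e <- extend_loh(sub$p_value, from, to, p_loh = p_loh,
                      mean_p_cap = mean_p_cap)
      tibble(from = e$from, to = e$to)
    })
    # extensions may overlap; merge into disjoint unions
    ext <- ext[order(ext$from), ]
    merged <- ext[1, ]
    if (nrow(ext) > 1L) for (k in 2:nrow(ext)) {
      if (ext$from[k] <= merged$to[nrow(merged)] + 1L) {
        merged$to[nrow(merged)] <- max(merged$to[nrow(merged)], ext$to[k])
      } else {
        merged <- rbind(merged, ext[k, ])
      }
    }
    ivs[[length(ivs) + 1L]] <- tibble(
      sample_id = sample_id, chrom = ch,
      start = sub$pos[merged$from],
      end = sub$window_end_pos[merged$to] + 1L,
      n_anchors = merged$to - merged$from + 1L,
      mean_p = vapply(seq_len(nrow(merged)), function(k)
        mean(sub$p_value[merged$from[k]:merged$to[k]]), numeric(1)))
  }
  intervals <- if (length(ivs) > 0L) bind_rows(ivs) else
    tibble(sample_id = character(), chrom = character(), start = integer(),
           end = integer(), n_anchors = integer(), mean_p = numeric())
  intervals$size_bp <- intervals$end - intervals$start
  structure(
    list(sample_id = sample_id, intervals = intervals, anchors = anchors,
         params = list(window = window, p_loh = p_loh, init_run = init_run,
                       mean_p_cap = mean_p_cap, directional = directional)),
    class = "loh_scan")
}

#' @export
print.loh_scan <- function(x, ...) {
  cat(sprintf("<loh_scan> sample %s: %d interval(s), %d anchors\n",
              x$sample_id, nrow(x$intervals), nrow(x$anchors)))
  if (nrow(x$intervals) > 0L) print(x$intervals)
  invisible(x)
}

#' @method tidy loh_scan
#' @export
tidy.loh_scan <- function(x, ...) x$intervals

#' @method glance loh_scan
#' @export
glance.loh_scan <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_anchors = nrow(x$anchors),
    anchor_hit_rate = mean(x$anchors$p_value < x$params$p_loh, na.rm = TRUE),
    n_intervals = nrow(x$intervals),
    total_bp = sum(x$intervals$size_bp)
  )
}

#' Plot an LOH scan
#'
#' Anchor -log10 p-values along the genome with called intervals shaded,
#' faceted by chromosome.
#'
#' @param object A `loh_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loh_scan
#' @export
autoplot.loh_scan <- function(object, ...) {
  an <- object$anchors[!is.na(object$anchors$p_value), ]
  p <- ggplot2::ggplot(an, ggplot2::aes(x = .data$pos,
                                        y = -log10(pmax(.data$p_value, 1e-300)))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5, colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(object$params$p_loh),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10]~p),
                  title = paste("LOH scan:", object$sample_id)) +
    ggplot2::theme_minimal()
  if (nrow(object$intervals) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE)
  }
  p
}

#' Classify LOH intervals as UPD or CNV-associated LOH
#'
#' Copy-neutral LOH is isodisomy (UPD): an interval whose majority-overlap
#' copy number is 2 is classed `"UPD"`, anything else `"LOH_nonUPD"` with
#' the overlapping CN recorded. Intervals below `min_size` are kept but
#' flagged not reportable.
#'
#' @param loh_intervals Tidied LOH interval tibble (one sample).
#' @param cnv_calls Tidied CNV call tibble for the same sample (may be
#'   empty).
#' @param min_size Minimum reportable size in bp (default 5e6).
#' @return `loh_intervals` with `cn_context`, `class` and `reportable`
#'   columns.
#' @export
classify_upd <- function(loh_intervals, cnv_calls, min_size = 5e6) {
  if (nrow(loh_intervals) == 0L) {
    return(mutate(loh_intervals, cn_context = integer(),
                  class = character(), reportable = logical()))
  }
  cn_ctx <- vapply(seq_len(nrow(loh_intervals)), function(k) {
    iv <- loh_intervals[k, ]
    if (is.null(cnv_calls) || nrow(cnv_calls) == 0L) return(2L)
    ov <- cnv_calls[cnv_calls$chrom == iv$chrom &
                    cnv_calls$start < iv$end & cnv_calls$end > iv$start, ]
    if (nrow(ov) == 0L) return(2L)
    ov$ov_len <- pmin(ov$end, iv$end) - pmax(ov$start, iv$start)
    best <- ov[which.max(ov$ov_len), ]
    if (best$ov_len > 0.5 * (iv$end - iv$start)) as.integer(best$cn) else 2L
  }, integer(1))
  loh_intervals %>%
    mutate(cn_context = cn_ctx,
           class = ifelse(cn_ctx == 2L, "UPD", "LOH_nonUPD"),
           reportable = .data$size_bp >= min_size)
}

#' Cross-check CNV and LOH calls
#'
#' Every reportable single-copy (CN = 1) CNV call should co-localize with
#' an LOH interval — a hemizygous deletion always loses heterozygosity.
#' Violations are listed as QC warnings.
#'
#' @param loh_intervals Tidied LOH interval tibble.
#' @param cnv_calls Tidied CNV call tibble.
#' @param min_size Minimum CNV size checked (default 1e6).
#' @return Tibble of inconsistent calls (empty when all consistent).
#' @export
check_consistency <- function(loh_intervals, cnv_calls, min_size = 1e6) {
  if (is.null(cnv_calls) || nrow(cnv_calls) == 0L) {
    return(tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), issue = character()))
  }
  dels <- cnv_calls[cnv_calls$cn == 1L &
                    (cnv_calls$end - cnv_calls$start) >= min_size, ]
  bad <- purrr::map_dfr(seq_len(nrow(dels)), function(k) {
    d <- dels[k, ]
    hit <- nrow(loh_intervals) > 0L &&
      any(loh_intervals$chrom == d$chrom &
          loh_intervals$start < d$end & loh_intervals$end > d$start)
    if (hit) return(NULL)
    tibble(sample_id = d$sample_id, chrom = d$chrom, start = d$start,
           end = d$end, issue = "CN=1 call without overlapping LOH")
  })
  if (nrow(bad) > 0L) {
    warn(sprintf("%d CN=1 call(s) lack a co-localizing LOH interval",
                 nrow(bad)))
  }
  if (nrow(bad) == 0L) {
    bad <- tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), issue = character())
  }
  bad
}
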