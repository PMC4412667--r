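#' Probe-level t test against the panel
#'
#' For each target, the test sample's normalized ratio R_mi is compared
#' with the panel's R_mi values by a one-vs-panel t test:
#' t = (R_test - mean_panel) / sqrt(S2_panel * (1 + 1/n)), with n - 1
#' degrees of freedom and a two-sided p-value. Probes with a degenerate
#' (zero-variance) panel are masked.
#'
#' @param r_m_test Numeric vector of the test sample's R_mi per target.
#' @param panel Numeric matrix of panel R_mi values, targets x samples.
#' @return Tibble with columns `z` (R_test - panel mean), `t_score`,
#'   `p_value`, `masked`.
#' @export
probe_level_ttest <- function(r_m_test, panel) {
  panel <- as.matrix(panel)
  n <- ncol(panel)
  if (n < 2L) abort("panel must contain at least 2 samples")
  mu <- rowMeans(panel)
  s2 <- rowSums((panel - mu)^2) / (n - 1L)
  z <- r_m_test - mu
  masked <- is.na(z) | is.na(s2) | s2 <= 0
  if (any(s2 <= 0 & !is.na(s2) & !is.na(z))) {
    warn(sprintf("%d probe(s) masked for zero panel variance",
                 sum(s2 <= 0 & !is.na(s2) & !is.na(z))))
  }
  t_score <- ifelse(masked, NA_real_, z / sqrt(s2 * (1 + 1 / n)))
  p_value <- ifelse(masked, NA_real_,
                    2 * pt(-abs(t_score), df = n - 1L))
  tibble(z = z, t_score = t_score, p_value = p_value, masked = masked)
}

# rolling sum over windows of `w` consecutive elements; length(x) - w + 1
roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]
}

#' Seed pseudo-signals from probe-level tests
#'
#' Every run of `window` (default 4) consecutive same-chromosome probes
#' whose t scores share a sign, with at least 3 p-values below `p1` and the
#' remaining p-value not exceeding `p2`, marks all probes in the window
#' with a "+" or "-" pseudo-signal. Windows slide by one probe and marks
#' accumulate, so overlapping qualifying windows extend the marked run.
#'
#' @param tests Tibble from [probe_level_ttest()].
#' @param chrom Chromosome per probe (windows never span chromosomes).
#' @param p1 Primary p threshold (default 0.05).
#' @param p2 Secondary threshold the remaining p-value must not exceed
#'   (default 0.2).
#' @param window Seeding window size (default 4).
#' @param r_m Optional per-probe normalized ratio. When supplied, a probe
#'   only qualifies if its own integer copy number differs from 2 in the
#'   window's direction (ratio below 0.75 for losses, at or above 1.25
#'   for gains) — a probe whose rounded CN is still 2 is not implicated
#'   in a copy-number change however small its p-value. This absolute
#'   gate is what keeps the autocorrelation introduced by depth smoothing
#'   from seeding spurious runs.
#' @return Character vector of marks per probe: "+", "-" or NA.
#' @export
seed_pseudo_signals <- function(tests, chrom, p1 = 0.05, p2 = 0.2,
                                window = 4L, r_m = NULL) {
  N <- nrow(tests)
  marks <- rep(NA_character_, N)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < window) next
    t <- tests$t_score[idx]
    p <- tests$p_value[idx]
    ok <- !is.na(t) & !is.na(p)
    pos <- ok & t > 0
    neg <- ok & t < 0
    if (!is.null(r_m)) {
      rm_ch <- r_m[idx]
      pos <- pos & !is.na(rm_ch) & rm_ch >= 1.25
      neg <- neg & !is.na(rm_ch) & rm_ch < 0.75
    }
    small <- ok & p < p1
    within2 <- ok & p <= p2
    same_sign <- roll_sum(pos, window) == window |
                 roll_sum(neg, window) == window
    qual <- same_sign & roll_sum(within2, window) == window &
            roll_sum(small, window) >= window - 1L
    marked <- logical(length(idx))
    for (off in 0:(window - 1L)) {
      marked[which(qual) + off] <- TRUE
    }
    marks[idx[marked & pos[seq_along(idx)]]] <- "+"
    marks[idx[marked & neg[seq_along(idx)]]] <- "-"
  }
  marks
}

#' Merge marked probe runs into candidate intervals
#'
#' Maximal runs of same-sign pseudo-signals become candidate intervals;
#' two same-sign runs separated by at most `max_gap` unmarked probes merge
#' (including the gap probes), iterated to a fixpoint. Runs of opposite
#' sign never merge.
#'
#' @param marks Character mark vector from [seed_pseudo_signals()].
#' @param chrom Chromosome per probe.
#' @param max_gap Largest bridgeable gap in probes (default 5).
#' @return Tibble `(chrom, from, to, sign)` of candidate intervals, `from`
#'   and `to` being 1-based row positions into the probe vector.
#' @export
merge_marked_runs <- function(marks, chrom, max_gap = 5L) {
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- marks[idx]
    r <- rle(ifelse(is.na(m), ".", m))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(from = starts, to = ends, sign = r$values,
                       stringsAsFactors = FALSE)
    runs <- runs[runs$sign %in% c("+", "-"), , drop = FALSE]
    if (nrow(runs) == 0L) next
    # single left-to-right pass reaches the fixpoint: merging only grows
    # the right edge of the accumulating run
    acc <- runs[1, ]
    res <- list()
    if (nrow(runs) > 1L) for (k in 2:nrow(runs)) {
      gap <- runs$from[k] - acc$to - 1L
      if (runs$sign[k] == acc$sign && gap <= max_gap) {
        acc$to <- runs$to[k]
      } else {
        res[[length(res) + 1L]] <- acc
        acc <- runs[k, ]
      }
    }
    res[[length(res) + 1L]] <- acc
    res <- do.call(rbind, res)
    res$chrom <- ch
    res$from <- idx[res$from]
    res$to <- idx[res$to]
    out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), from = integer(), to = integer(),
                  sign = character()))
  }
  as_tibble(do.call(rbind, out))[c("chrom", "from", "to", "sign")]
}

#' Region-level t test on a candidate interval
#'
#' One-sample t test of the per-probe deviations Z_i = R_mi_test -
#' mean(R_mi_panel) within the interval against zero, with m - 1 degrees
#' of freedom and a two-sided p-value.
#'
#' @param z Numeric vector of Z_i over the interval (NAs dropped).
#' @return List with `t`, `p` and `flagged` (TRUE when the Z dispersion is
#'   zero and p was set to the smallest representable value).
#' @export
region_level_ttest <- function(z) {
  z <- z[!is.na(z)]
  m <- length(z)
  if (m < 2L) return(list(t = NA_real_, p = NA_real_, flagged = TRUE))
  s <- sd(z)
  if (s == 0) {
    return(list(t = sign(mean(z)) * Inf, p = .Machine$double.xmin,
                flagged = TRUE))
  }
  t <- mean(z) * sqrt(m) / s
  list(t = t, p = 2 * pt(-abs(t), df = m - 1L), flagged = FALSE)
}

#' Integer copy number from a mean normalized ratio
#'
#' CN = nearest integer of mean(R_m) / 0.5, rounding half up (so a mean
#' ratio of 0.75 gives CN 2) and floored at zero. A continuous CN estimate
#' of 3.497 therefore rounds to 3.
#'
#' @param mean_r_m Mean normalized ratio over a region (vectorized).
#' @return Non-negative integer copy number(s).
#' @export
assign_copy_number <- function(mean_r_m) {
  pmax(0L, as.integer(round_half_up(mean_r_m / 0.5)))
}

#' Infer sample sex from depth ratios
#'
#' Uses the mean depth coefficient R over chrX probes: near 1 means two X
#' copies (XX), near 0.5 with chrY coverage means XY. Values in the
#' ambiguous band (0.65, 0.85) are flagged "other" for review.
#'
#' @param ratios Output of [normalize_depths()] (any number of samples).
#' @return Tibble `(sample_id, sex, chrx_mean_r, chry_mean_r)`.
#' @export
infer_sex <- function(ratios) {
  ratios %>%
    group_by(.data$sample_id) %>%
    summarise(
      chrx_mean_r = mean(.data$r[is_chrx(.data$chrom)]),
      chry_mean_r = if (any(is_chry(.data$chrom)))
        mean(.data$r[is_chry(.data$chrom)]) else 0,
      .groups = "drop"
    ) %>%
    mutate(sex = case_when(
      is.nan(.data$chrx_mean_r) ~ "other",
      .data$chrx_mean_r > 0.85 ~ "XX",
      .data$chrx_mean_r < 0.65 & .data$chry_mean_r > 0.25 ~ "XY",
      TRUE ~ "other"
    )) %>%
    select("sample_id", "sex", "chrx_mean_r", "chry_mean_r")
}

# Step-edge refinement on the unsmoothed normalized ratio. The forward
# moving average used for smoothing shifts a copy-number step's apparent
# edges upstream by up to the window length; the true edges are recovered
# by a least-squares two-segment fit of the raw ratio around each
# candidate edge.
refine_edge <- function(raw, cand, lo, hi, side) {
  best <- cand[1]
  best_sse <- Inf
  y <- raw[lo:hi]
  for (s in cand) {
    k <- s - lo + 1L
    if (side == "left") {
      seg1 <- y[seq_len(k - 1L)]
      seg2 <- y[k:length(y)]
    } else {
      seg1 <- y[seq_len(k)]
      seg2 <- if (k < length(y)) y[(k + 1L):length(y)] else numeric(0)
    }
    sse <- 0
    for (seg in list(seg1, seg2)) {
      seg <- seg[!is.na(seg)]
      if (length(seg) > 1L) sse <- sse + sum((seg - mean(seg))^2)
    }
    if (sse < best_sse) {
      best_sse <- sse
      best <- s
    }
  }
  best
}

#' Call CNVs for one sample against a panel
#'
#' Runs the full per-sample chain: probe-level t tests, pseudo-signal
#' seeding, run merging, region-level confirmation, size/probe filters,
#' boundary refinement on the unsmoothed ratio, integer CN assignment, and
#' whole-chromosome aneuploidy promotion.
#'
#' @param ratios_test One sample's rows from [normalize_by_baseline()]
#'   (needs `r_m` and `r_m_raw`).
#' @param panel_r_m Matrix (targets x panel samples) of panel R_mi values,
#'   rows aligned to `targets`, or a long tibble
#'   `(sample_id, region_id, r_m)`.
#' @param targets Target tibble.
#' @param p_cnv Probe/region significance threshold (default 0.05).
#' @param p_seed2 Secondary seeding threshold (default 0.2).
#' @param min_probes Minimum probes per reported call (default 45).
#' @param min_size Minimum call size in bp (default 1e6); combined with
#'   `min_probes` as an AND.
#' @param max_gap Largest bridgeable unmarked gap when merging runs
#'   (default 5).
#' @param seed_window Seeding window size (default 4).
#' @param refine Refine boundaries on the unsmoothed ratio (default TRUE).
#' @param n_smooth Smoothing span used upstream; bounds the refinement
#'   search (default 10).
#' @param aneuploidy_frac Fraction of a chromosome's probes that must sit
#'   in same-direction calls for promotion to an aneuploidy (default 0.9).
#' @return A `cnv_scan` object: list with `calls` and `probes` tibbles,
#'   `sample_id` and the parameters used. `tidy()` extracts the calls.
#' @export
call_cnvs <- function(ratios_test, panel_r_m, targets, p_cnv = 0.05,
                      p_seed2 = 0.2, min_probes = 45L, min_size = 1e6,
                      max_gap = 5L, seed_window = 4L, refine = TRUE,
                      n_smooth = 10L, aneuploidy_frac = 0.9) {
  if (is.data.frame(panel_r_m)) {
    panel_r_m <- ratio_matrix(panel_r_m, targets, "r_m")
  }
  rt <- ratios_test[match(targets$region_id, ratios_test$region_id), ]
  sample_id <- rt$sample_id[1]
  tests <- probe_level_ttest(rt$r_m, panel_r_m)
  marks <- seed_pseudo_signals(tests, targets$chrom, p1 = p_cnv,
                               p2 = p_seed2, window = seed_window,
                               r_m = rt$r_m)
  cand <- merge_marked_runs(marks, targets$chrom, max_gap = max_gap)
  probes <- dplyr::bind_cols(
    targets[c("chrom", "start", "end", "region_id", "index")],
    tests, tibble(r_m = rt$r_m, r_m_raw = rt$r_m_raw, mark = marks))

  calls <- purrr::pmap_dfr(cand, function(chrom, from, to, sign) {
    span <- from:to
    reg <- region_level_ttest(tests$z[span])
    if (is.na(reg$p) || reg$p >= p_cnv) return(NULL)
    if (refine) {
      ch_idx <- which(targets$chrom == chrom)
      lo_l <- max(min(ch_idx), from - 8L)
      hi_r <- min(max(ch_idx), to + n_smooth + 8L)
      cand_l <- max(min(ch_idx), from - 3L):min(to, from + n_smooth + 3L)
      cand_r <- max(from, to - 3L):min(max(ch_idx), to + n_smooth + 3L)
      # a step can only be fitted when probes exist outside the edge
      from2 <- if (from - min(ch_idx) >= 3L)
        refine_edge(rt$r_m_raw, cand_l, lo_l, hi_r, "left") else from
      to2 <- if (max(ch_idx) - to >= 3L)
        refine_edge(rt$r_m_raw, cand_r, lo_l, hi_r, "right") else to
      if (to2 >= from2) {
        from <- from2
        to <- to2
      }
      span <- from:to
    }
    # region-level test between the test sample and the panel: the test
    # sample's region mean against the panel samples' region means (the
    # panel means share the smoothing autocorrelation, so this re-test is
    # calibrated where the within-region t is not)
    test_mean <- mean(rt$r_m[span], na.rm = TRUE)
    pmeans <- colMeans(panel_r_m[span, , drop = FALSE], na.rm = TRUE)
    n <- length(pmeans)
    s2p <- var(pmeans)
    panel_p <- if (is.na(s2p) || s2p <= 0) NA_real_ else
      2 * pt(-abs((test_mean - mean(pmeans)) /
                    sqrt(s2p * (1 + 1 / n))), df = n - 1L)
    if (!is.na(panel_p) && panel_p >= p_cnv) return(NULL)
    # the assigned integer CN must be reliably different from 2: the
    # region mean has to clear the copy-neutral rounding boundary
    # (0.75 for losses, 1.25 for gains) by more than the panel's
    # region-mean dispersion allows by chance
    if (!is.na(s2p) && s2p > 0) {
      se <- sqrt(s2p * (1 + 1 / n))
      t_b <- if (sign == "-") (0.75 - test_mean) / se
             else (test_mean - 1.25) / se
      boundary_p <- pt(t_b, df = n - 1L, lower.tail = FALSE)
      if (boundary_p >= p_cnv) return(NULL)
    } else {
      boundary_p <- NA_real_
    }
    mean_raw <- mean(rt$r_m_raw[span], na.rm = TRUE)
    if (is.nan(mean_raw)) mean_raw <- mean(rt$r_m[span], na.rm = TRUE)
    n_used <- sum(!is.na(tests$z[from:to]))
    tibble(
      sample_id = sample_id, chrom = chrom,
      start = targets$start[from], end = targets$end[to],
      n_probes = to - from + 1L, n_tested = n_used,
      mean_ratio = mean_raw, stat = reg$t, p_value = reg$p,
      panel_p = panel_p,
      cn = assign_copy_number(mean_raw),
      direction = if (sign == "-") "loss" else "gain",
      flagged = reg$flagged
    )
  })
  if (nrow(calls) == 0L) {
    calls <- tibble(sample_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    n_probes = integer(), n_tested = integer(),
                    mean_ratio = numeric(), stat = numeric(),
                    p_value = numeric(), panel_p = numeric(),
                    cn = integer(),
                    direction = character(), flagged = logical())
  } else {
    calls <- calls[calls$n_probes >= min_probes &
                   (calls$end - calls$start) >= min_size, ]
  }
  calls$aneuploid <- logical(nrow(calls))
  # promote to aneuploidy when >= aneuploidy_frac of a chromosome's probes
  # sit inside same-direction calls
  if (nrow(calls) > 0L) {
    promoted <- list()
    keep <- rep(TRUE, nrow(calls))
    for (ch in unique(calls$chrom)) {
      n_chrom <- sum(targets$chrom == ch & !tests$masked)
      for (dir in c("loss", "gain")) {
        sel <- calls$chrom == ch & calls$direction == dir
        if (!any(sel)) next
        covered <- sum(calls$n_probes[sel])
        if (covered >= aneuploidy_frac * n_chrom) {
          ch_rows <- which(targets$chrom == ch)
          mean_raw <- mean(rt$r_m_raw[ch_rows], na.rm = TRUE)
          agg <- calls[sel, ][1, ]
          agg$start <- min(targets$start[ch_rows])
          agg$end <- max(targets$end[ch_rows])
          agg$n_probes <- length(ch_rows)
          agg$n_tested <- sum(!tests$masked[ch_rows])
          agg$mean_ratio <- mean_raw
          agg$cn <- assign_copy_number(mean_raw)
          agg$aneuploid <- TRUE
          keep[sel] <- FALSE
          promoted[[length(promoted) + 1L]] <- agg
        }
      }
    }
    calls <- bind_rows(calls[keep, ], promoted)
    calls <- calls[order(chrom_rank(calls$chrom), calls$start), ]
  }
  structure(
    list(sample_id = sample_id, calls = as_tibble(calls), probes = probes,
         params = list(p_cnv = p_cnv, p_seed2 = p_seed2,
                       min_probes = min_probes, min_size = min_size,
                       max_gap = max_gap, seed_window = seed_window)),
    class = "cnv_scan")
}

#' @export
print.cnv_scan <- function(x, ...) {
  cat(sprintf("<cnv_scan> sample %s: %d call(s) over %d probes\n",
              x$sample_id, nrow(x$calls), nrow(x$probes)))
  if (nrow(x$calls) > 0L) print(x$calls)
  invisible(x)
}

#' @method tidy cnv_scan
#' @export
tidy.cnv_scan <- function(x, ...) {
  if (nrow(x$calls) == 0L) return(x$calls)
  mutate(x$calls, size_bp = .data$end - .data$start,
         class = ifelse(.data$aneuploid, "aneuploidy", .data$direction))
}

#' @method glance cnv_scan
#' @export
glance.cnv_scan <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_probes = nrow(x$probes),
    n_masked = sum(x$probes$masked),
    n_marked = sum(!is.na(x$probes$mark)),
    n_calls = nrow(x$calls),
    n_loss = sum(x$calls$direction == "loss"),
    n_gain = sum(x$calls$direction == "gain"),
    probe_hit_rate = mean(x$probes$p_value < x$params$p_cnv, na.rm = TRUE)
  )
}

#' Plot a CNV scan
#'
#' Normalized ratio R_m along the genome with called intervals overlaid,
#' faceted by chromosome.
#'
#' @param object A `cnv_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_scan
#' @export
autoplot.cnv_scan <- function(object, ...) {
  pr <- object$probes[!is.na(object$probes$r_m), ]
  p <- ggplot2::ggplot(pr, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                        y = .data$r_m)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(0.5, 1, 1.5), linetype = "dotted") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(R[m]),
                  title = paste("CNV scan:", object$sample_id)) +
    ggplot2::theme_minimal()
  if (nrow(object$calls) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = object$calls,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$cn / 2, yend = .data$cn / 2),
      colour = "red", linewidth = 1.2, inherit.aes = FALSE)
  }
  p
}

#' Compose an ISCN-style karyotype string
#'
#' Builds strings such as `"46,XY"`, `"46,XY,del(5)(p14)"` or
#' `"48,XXX,+18"` from a sex assignment and a call set. Whole-chromosome
#' (aneuploid) calls adjust the modal number and contribute `+N`/`-N`
#' tokens (sex-chromosome aneuploidies adjust the X/Y counts instead);
#' segmental calls become del/dup tokens with cytoband coordinates.
#'
#' @param sex_row One row of [infer_sex()] output (or a list with `sex`).
#' @param calls Tidied CNV call tibble (needs chrom, start, end, cn,
#'   direction, aneuploid).
#' @param cytobands Cytoband tibble from [read_cytobands()], or NULL to
#'   omit band names.
#' @return A single karyotype string.
#' @export
format_karyotype <- function(sex_row, calls, cytobands = NULL) {
  base <- switch(sex_row$sex, XX = c(2L, 0L), XY = c(1L, 1L), c(1L, 0L))
  n_x <- base[1]
  n_y <- base[2]
  modal_delta <- 0L
  tokens <- character()
  if (!is.null(calls) && nrow(calls) > 0L) {
    calls <- calls[order(chrom_rank(calls$chrom), calls$start), ]
    for (k in seq_len(nrow(calls))) {
      cl <- calls[k, ]
      core <- sub("^chr", "", cl$chrom)
      if (isTRUE(cl$aneuploid)) {
        delta <- cl$cn - 2L
        if (is_chrx(cl$chrom)) {
          n_x <- max(0L, n_x + delta)
        } else if (is_chry(cl$chrom)) {
          n_y <- max(0L, n_y + delta)
        } else {
          modal_delta <- modal_delta + delta
          tok <- if (delta > 0) paste0("+", core) else paste0("-", core)
          tokens <- c(tokens, rep(tok, abs(delta)))
        }
      } else {
        type <- if (cl$direction == "loss") "del" else "dup"
        bands <- ""
        if (!is.null(cytobands)) {
          cb <- cytobands[cytobands$chrom == cl$chrom &
                          cytobands$start < cl$end &
                          cytobands$end > cl$start, ]
          if (nrow(cb) > 0L) {
            b1 <- cb$band[1]
            b2 <- cb$band[nrow(cb)]
            bands <- paste0("(", b1, if (b2 != b1) b2, ")")
          }
        }
        tokens <- c(tokens, sprintf("%s(%s)%s", type, core, bands))
      }
    }
  }
  modal <- 44L + n_x + n_y + modal_delta
  sex_tok <- paste0(strrep("X", n_x), strrep("Y", n_y))
  paste(c(modal, sex_tok, tokens), collapse = ",")
}
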