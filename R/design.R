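#' Filter candidate SNPs by population allele frequency
#'
#' Keeps sites whose population alternate-allele frequency lies in the
#' closed interval [af_min, af_max]; only common variants are informative
#' for heterozygosity detection.
#'
#' @param snps Sites tibble (needs `pop_af`).
#' @param af_min,af_max Closed retention bounds (defaults 0.10 and 0.90).
#' @return Filtered sites tibble.
#' @export
filter_by_af <- function(snps, af_min = 0.10, af_max = 0.90) {
  snps[snps$pop_af >= af_min & snps$pop_af <= af_max, ]
}

#' Drop clustered SNPs
#'
#' Scanning each chromosome in genome order, a site within `radius` bp of
#' the previously kept site is dropped (clustered SNPs destabilize capture
#' probes).
#'
#' @param snps Sites tibble in genome order.
#' @param radius Neighborhood in bp (default 100).
#' @return Thinned sites tibble.
#' @export
remove_clustered <- function(snps, radius = 100L) {
  keep <- logical(nrow(snps))
  last_chrom <- ""
  last_pos <- -Inf
  ord <- order(chrom_rank(snps$chrom), snps$pos)
  for (i in ord) {
    if (snps$chrom[i] != last_chrom || snps$pos[i] - last_pos > radius) {
      keep[i] <- TRUE
      last_chrom <- snps$chrom[i]
      last_pos <- snps$pos[i]
    }
  }
  snps[sort(which(keep)), ]
}

# genome helpers: genome is a named character vector of contig sequences
genome_lengths <- function(genome) vapply(genome, nchar, integer(1))

flank_seq <- function(genome, chrom, pos, up = 50L, down = 50L) {
  s <- genome[[chrom]]
  if (pos - up < 0L || pos + down >= nchar(s)) return(NA_character_)
  substr(s, pos - up + 1L, pos + down + 1L)
}

#' Flank-uniqueness filter
#'
#' A site passes when its 101-base flank (50 bp up, the site, 50 bp down)
#' occurs exactly once in the genome as a perfect match (either strand)
#' and no second locus matches it above `max_second_identity` identity.
#' Implemented with an exact/near-match string search (mismatch budget
#' floor((1 - max_second_identity) * k)) rather than an external aligner,
#' which makes the filter deterministic and self-contained. Sites whose
#' flank is truncated by a contig edge are dropped and counted.
#'
#' @param snps Sites tibble.
#' @param genome Named character vector of contig sequences.
#' @param k Flank length (default 101; must be odd).
#' @param max_second_identity Highest tolerated identity of a second
#'   locus (default 0.95).
#' @return Sites tibble with a `uniqueness_pass` column, filtered to
#'   passing sites.
#' @export
uniqueness_filter <- function(snps, genome, k = 101L,
                              max_second_identity = 0.95) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("uniqueness_filter requires the Biostrings package")
  }
  half <- (k - 1L) %/% 2L
  max_mm <- floor((1 - max_second_identity) * k)
  subject <- Biostrings::DNAStringSet(unlist(genome))
  names(subject) <- names(genome)
  n_edge <- 0L
  pass <- vapply(seq_len(nrow(snps)), function(i) {
    fl <- flank_seq(genome, snps$chrom[i], snps$pos[i], half, half)
    if (is.na(fl)) {
      n_edge <<- n_edge + 1L
      return(FALSE)
    }
    pat <- Biostrings::DNAString(fl)
    rc <- Biostrings::reverseComplement(pat)
    exact <- sum(Biostrings::vcountPattern(pat, subject)) +
             sum(Biostrings::vcountPattern(rc, subject))
    if (exact != 1L) return(FALSE)
    near <- sum(Biostrings::vcountPattern(pat, subject, max.mismatch = max_mm)) +
            sum(Biostrings::vcountPattern(rc, subject, max.mismatch = max_mm))
    near == 1L
  }, logical(1))
  if (n_edge > 0L) {
    inform(sprintf("dropped %d site(s) with contig-edge-truncated flanks",
                   n_edge))
  }
  out <- snps
  out$uniqueness_pass <- pass
  out[pass, ]
}

#' Thin SNPs to the target spacing grid
#'
#' Per chromosome, at most one SNP is kept per `spacing`-sized bin — the
#' one closest to the bin center (ties toward the lower position) — giving
#' a relatively even anchor scatter.
#'
#' @param snps Sites tibble.
#' @param spacing Bin width in bp (default 10 kb).
#' @return Anchor tibble `(chrom, anchor_pos, source = "snp")`.
#' @export
thin_to_grid <- function(snps, spacing = 1e4) {
  if (nrow(snps) == 0L) {
    return(tibble(chrom = character(), anchor_pos = integer(),
                  source = character()))
  }
  snps %>%
    mutate(bin = floor(.data$pos / spacing),
           center_dist = abs(.data$pos - (.data$bin + 0.5) * spacing)) %>%
    group_by(.data$chrom, .data$bin) %>%
    arrange(.data$center_dist, .data$pos, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    arrange(chrom_rank(.data$chrom), .data$pos) %>%
    dplyr::transmute(chrom = .data$chrom,
                     anchor_pos = as.integer(.data$pos), source = "snp")
}

# per-contig position classifiers for filler windows, O(1) per query via
# cumulative sums
window_index <- function(seqchar) {
  b <- strsplit(seqchar, "", fixed = TRUE)[[1]]
  gc <- cumsum(b %in% c("G", "C"))
  r <- rle(b)
  bad <- rep(r$lengths >= 10L, r$lengths)  # inside a homopolymer run >= 10
  badc <- cumsum(bad)
  list(gc = c(0L, gc), bad = c(0L, badc), len = length(b))
}

window_ok <- function(idx, start, end, gc_min, gc_max) {
  if (start < 0L || end > idx$len) return(FALSE)
  gc <- (idx$gc[end + 1L] - idx$gc[start + 1L]) / (end - start)
  nbad <- idx$bad[end + 1L] - idx$bad[start + 1L]
  gc >= gc_min && gc <= gc_max && nbad == 0L
}

#' Insert filler anchors into large gaps
#'
#' Inter-anchor gaps of at least 1.5x `spacing` receive
#' max(1, floor(gap / spacing) - 1) evenly spaced filler anchors (a 15 kb
#' gap takes one filler, a 35 kb gap two near its thirds); gaps only
#' marginally over the spacing are left alone, since bisecting them would
#' move the grid further from the target spacing than the gap itself. A
#' filler whose centered probe window contains a homopolymer run of 10+
#' bases or falls outside the GC window slides (up to spacing/2) to the
#' nearest compliant position, or is skipped with the gap logged.
#'
#' @param locations Anchor tibble from [thin_to_grid()].
#' @param genome Named character vector of contig sequences.
#' @param spacing Target spacing in bp (default 10 kb).
#' @param probe_len Probe window length (default 150).
#' @param gc_min,gc_max Allowed GC fraction of a filler window (defaults
#'   0.3 and 0.7).
#' @return Anchor tibble with `source` "snp" or "filler", sorted; skipped
#'   gaps are attached as the `skipped_gaps` attribute.
#' @export
fill_gaps <- function(locations, genome, spacing = 1e4, probe_len = 150L,
                      gc_min = 0.3, gc_max = 0.7) {
  half <- probe_len %/% 2L
  skipped <- list()
  fillers <- list()
  for (ch in unique(locations$chrom)) {
    pos <- sort(locations$anchor_pos[locations$chrom == ch])
    if (length(pos) < 2L) next
    idx <- window_index(genome[[ch]])
    for (g in seq_len(length(pos) - 1L)) {
      gap <- pos[g + 1L] - pos[g]
      if (gap < 1.5 * spacing) next
      n_fill <- max(1L, floor(gap / spacing) - 1L)
      anchors <- round(pos[g] + gap * seq_len(n_fill) / (n_fill + 1L))
      for (a in anchors) {
        placed <- NA_integer_
        for (d in 0:(spacing %/% 2L)) {  # slide outward, nearest first
          for (cand in unique(c(a - d, a + d))) {
            if (window_ok(idx, cand - half, cand - half + probe_len,
                          gc_min, gc_max)) {
              placed <- cand
              break
            }
          }
          if (!is.na(placed)) break
        }
        if (is.na(placed)) {
          skipped[[length(skipped) + 1L]] <-
            tibble(chrom = ch, gap_start = pos[g], gap_end = pos[g + 1L])
        } else {
          fillers[[length(fillers) + 1L]] <-
            tibble(chrom = ch, anchor_pos = as.integer(placed),
                   source = "filler")
        }
      }
    }
  }
  out <- bind_rows(locations, bind_rows(fillers))
  out <- out[order(chrom_rank(out$chrom), out$anchor_pos), ]
  attr(out, "skipped_gaps") <- bind_rows(skipped)
  out
}

#' Emit probe windows from anchor locations
#'
#' Each anchor becomes a `probe_len` window centered on it, clipped (by
#' shifting) at contig edges. Overlapping probes are resolved by keeping
#' the SNP-sourced one and dropping the filler; between two SNP probes,
#' the earlier wins.
#'
#' @param locations Anchor tibble.
#' @param genome Optional named contig sequences (enables right-edge
#'   clipping).
#' @param probe_len Probe length (default 150).
#' @return Target tibble (sorted, non-overlapping, indexed).
#' @export
emit_probes <- function(locations, genome = NULL, probe_len = 150L) {
  half <- probe_len %/% 2L
  lens <- if (!is.null(genome)) genome_lengths(genome) else NULL
  df <- locations
  df$start <- pmax(0L, df$anchor_pos - half)
  if (!is.null(lens)) {
    df$start <- pmin(df$start, pmax(0L, lens[df$chrom] - probe_len))
  }
  df$end <- df$start + probe_len
  df <- df[order(chrom_rank(df$chrom), df$start), ]
  keep <- rep(TRUE, nrow(df))
  last <- 0L
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (last > 0L && df$chrom[i] == df$chrom[last] &&
        df$start[i] < df$end[last]) {
      if (df$source[i] == "filler" || df$source[last] != "filler") {
        keep[i] <- FALSE
        next
      }
      keep[last] <- FALSE  # current is snp-sourced, previous was filler
    }
    last <- i
  }
  df <- df[keep, ]
  as_target_set(tibble(chrom = df$chrom, start = as.integer(df$start),
                       end = as.integer(df$end),
                       region_id = paste0(df$chrom, "_", df$start, "_",
                                          df$source)))
}

#' Summarize a designed probe set
#'
#' @param targets Target tibble.
#' @return List with `summary` (one row: probe count, total bp, mean and
#'   median center-to-center distance) and `per_chromosome` tibbles.
#' @export
design_report <- function(targets) {
  per_chrom <- targets %>%
    mutate(center = (.data$start + .data$end) / 2) %>%
    group_by(.data$chrom) %>%
    summarise(
      n_probes = dplyr::n(),
      total_bp = sum(.data$end - .data$start),
      mean_gap = mean(diff(.data$center)),
      median_gap = median(diff(.data$center)),
      .groups = "drop")
  gaps <- targets %>%
    mutate(center = (.data$start + .data$end) / 2) %>%
    group_by(.data$chrom) %>%
    summarise(g = list(diff(.data$center)), .groups = "drop")
  all_gaps <- unlist(gaps$g)
  list(
    summary = tibble(
      n_probes = nrow(targets),
      total_bp = sum(targets$end - targets$start),
      mean_gap = mean(all_gaps),
      median_gap = median(all_gaps)),
    per_chromosome = per_chrom)
}

#' Full probe-design pipeline
#'
#' AF filter, cluster removal, flank-uniqueness screen, grid thinning,
#' gap filling and probe emission in one call.
#'
#' @param snps Candidate sites tibble.
#' @param genome Named character vector of contig sequences.
#' @param spacing Target spacing (default 10 kb).
#' @param probe_len Probe length (default 150).
#' @param af_min,af_max AF retention window (defaults 0.10, 0.90).
#' @param cluster_radius SNP cluster radius (default 100).
#' @param ... Passed to [fill_gaps()].
#' @return Target tibble of designed probes.
#' @export
design_probes <- function(snps, genome, spacing = 1e4, probe_len = 150L,
                          af_min = 0.10, af_max = 0.90,
                          cluster_radius = 100L, ...) {
  snps %>%
    filter_by_af(af_min, af_max) %>%
    remove_clustered(cluster_radius) %>%
    uniqueness_filter(genome, k = 101L) %>%
    thin_to_grid(spacing) %>%
    fill_gaps(genome, spacing = spacing, probe_len = probe_len, ...) %>%
    emit_probes(genome, probe_len = probe_len)
}
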