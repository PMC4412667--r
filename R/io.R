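#' Read a target-region BED file
#'
#' Reads the probe grid (one row per capture target) from a 3+ column BED
#' file. Coordinates are BED-style: 0-based, half-open. Targets are sorted
#' into genome order and given stable 0-based indices; all per-probe vectors
#' elsewhere in the package align to these indices.
#'
#' @param path Path to a BED file with at least chrom, start, end columns.
#'   A fourth column, when present, supplies the region id; otherwise ids
#'   are generated as `chrom_start`.
#' @return A tibble with columns `chrom`, `start`, `end`, `region_id`,
#'   `index` (0-based, gap-free, in genome order).
#' @export
read_targets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    warn(paste0("empty target file: ", path))
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  region_id = character(), index = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  which(nf < 3L)[1]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  }
  df <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end,
    region_id = ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  )
  df$region_id <- ifelse(is.na(df$region_id) | df$region_id == "",
                         paste0(df$chrom, "_", df$start), df$region_id)
  as_target_set(df)
}

#' Validate and index a target-region table
#'
#' @param df Data frame with `chrom`, `start`, `end` and optionally
#'   `region_id` columns (0-based half-open coordinates).
#' @return The validated, sorted target tibble with 0-based `index`.
#' @export
as_target_set <- function(df) {
  df <- as_tibble(df)
  if (!"region_id" %in% names(df)) {
    df$region_id <- paste0(df$chrom, "_", df$start)
  }
  if (any(df$end <= df$start)) {
    abort("target regions must satisfy end > start")
  }
  if (anyDuplicated(df[c("chrom", "start", "end")]) > 0L) {
    abort("duplicate target intervals in BED input")
  }
  if (anyDuplicated(df$region_id) > 0L) {
    abort("duplicate region_id values in target set")
  }
  df <- sort_genomic(df)
  # overlap check within chromosome on the sorted order
  same_chrom <- df$chrom == dplyr::lag(df$chrom, default = "")
  prev_end <- dplyr::lag(df$end, default = -1L)
  if (any(same_chrom & df$start < prev_end)) {
    i <- which(same_chrom & df$start < prev_end)[1]
    abort(sprintf("overlapping targets on %s near position %d",
                  df$chrom[i], df$start[i]))
  }
  df$index <- seq_len(nrow(df)) - 1L
  df[c("chrom", "start", "end", "region_id", "index")]
}

#' Write a target set back to BED
#'
#' @param targets Target tibble from [read_targets()].
#' @param path Output BED path.
#' @export
write_targets <- function(targets, path) {
  readr::write_tsv(targets[c("chrom", "start", "end", "region_id")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a per-target depth matrix
#'
#' The on-disk layout is one row per target and one column per sample, with
#' a leading `region_id` column. Two dialects are supported: `"mean_depth"`
#' (values are already reads-per-base mean depths, TD_i) and `"base_count"`
#' (values are aligned-base counts, converted to depth by dividing by the
#' target length).
#'
#' @param path TSV path.
#' @param targets Target tibble the rows must align to.
#' @param dialect `"mean_depth"` (default) or `"base_count"`.
#' @return A long tibble `(sample_id, region_id, depth)` with exactly one
#'   row per sample x target.
#' @export
read_depth_table <- function(path, targets, dialect = c("mean_depth", "base_count")) {
  dialect <- match.arg(dialect)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(wide)[1] != "region_id") {
    abort("depth table must start with a 'region_id' column")
  }
  unknown <- setdiff(wide$region_id, targets$region_id)
  if (length(unknown) > 0L) {
    abort(paste0("depth table contains region absent from target set: ",
                 unknown[1]))
  }
  missing <- setdiff(targets$region_id, wide$region_id)
  if (length(missing) > 0L) {
    abort(paste0("depth table is missing target region: ", missing[1]))
  }
  long <- tidyr::pivot_longer(wide, -"region_id",
                              names_to = "sample_id", values_to = "depth")
  if (any(long$depth < 0)) {
    abort("negative depth values in depth table")
  }
  if (dialect == "base_count") {
    len <- setNames(targets$end - targets$start, targets$region_id)
    long$depth <- unname(long$depth / len[long$region_id])
  }
  long[c("sample_id", "region_id", "depth")]
}

#' Write a long depth table to the wide TSV dialect
#'
#' @param depths Long tibble `(sample_id, region_id, depth)`.
#' @param targets Target tibble fixing row order.
#' @param path Output TSV path.
#' @export
write_depth_table <- function(depths, targets, path) {
  wide <- tidyr::pivot_wider(depths, names_from = "sample_id",
                             values_from = "depth")
  wide <- wide[match(targets$region_id, wide$region_id), ]
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a SNP site table
#'
#' @param path TSV with columns chrom, pos (0-based), ref, alt, af.
#' @return Sites tibble `(chrom, pos, ref_allele, alt_allele, pop_af,
#'   site_id)` sorted in genome order.
#' @export
read_snp_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1:5] <- c("chrom", "pos", "ref_allele", "alt_allele", "pop_af")
  as_site_table(df)
}

#' Validate a SNP site table
#' @param df Data frame with chrom, pos, ref_allele, alt_allele, pop_af.
#' @return Sorted sites tibble with `site_id`.
#' @export
as_site_table <- function(df) {
  df <- as_tibble(df)
  if (any(df$pop_af < 0 | df$pop_af > 1)) {
    abort("pop_af must lie in [0, 1]")
  }
  if (!"site_id" %in% names(df)) {
    df$site_id <- paste0(df$chrom, "_", df$pos)
  }
  df <- sort_genomic(df, pos_col = "pos")
  df[unique(c("chrom", "pos", "ref_allele", "alt_allele", "pop_af", "site_id",
              setdiff(names(df), c("chrom", "pos", "ref_allele", "alt_allele",
                                   "pop_af", "site_id"))))]
}

#' Write a SNP site table
#' @param sites Sites tibble.
#' @param path Output TSV path.
#' @export
write_snp_table <- function(sites, path) {
  readr::write_tsv(sites[c("chrom", "pos", "ref_allele", "alt_allele",
                           "pop_af", "site_id")], path)
  invisible(path)
}

#' Attach each SNP site to its nearest target region
#'
#' Sites are assigned to the containing probe when one exists, otherwise to
#' the nearest probe on the same chromosome (ties broken toward the lower
#' index), so probe-indexed and site-indexed logic interoperate.
#'
#' @param sites Sites tibble.
#' @param targets Target tibble.
#' @return `sites` with a `region_index` column (NA when the chromosome has
#'   no probes).
#' @export
attach_sites <- function(sites, targets) {
  sites$region_index <- NA_integer_
  for (ch in unique(sites$chrom)) {
    tt <- targets[targets$chrom == ch, ]
    idx <- which(sites$chrom == ch)
    if (nrow(tt) == 0L) next
    mid <- (tt$start + tt$end) / 2
    pos <- sites$pos[idx]
    # distance to probe: 0 when inside, else gap to nearest edge
    assign <- vapply(pos, function(p) {
      d <- pmax(tt$start - p, 0) + pmax(p - (tt$end - 1L), 0)
      tt$index[which.min(d)]  # which.min takes the first (lowest index) tie
    }, integer(1))
    sites$region_index[idx] <- assign
  }
  sites
}

#' Read per-site allele counts (TSV or VCF dialect)
#'
#' The TSV dialect is long: columns `sample_id`, `site_id`, `ref_count`,
#' `alt_count`. The VCF dialect takes per-sample allelic depths from the AD
#' FORMAT field; multi-allelic records are skipped with a warning. In both
#' dialects, sites whose population allele frequency falls outside
#' `af_window` are dropped (heterozygosity detection only uses common
#' variants), with the dropped count reported.
#'
#' @param path Input path.
#' @param sites Sites tibble the records must belong to.
#' @param format `"tsv"` or `"vcf"`.
#' @param af_window Closed population-AF retention window, default
#'   `c(0.1, 0.9)`.
#' @return Long tibble `(sample_id, site_id, ref_count, alt_count)`.
#' @export
read_allele_counts <- function(path, sites, format = c("tsv", "vcf"),
                               af_window = c(0.1, 0.9)) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    df <- df[c("sample_id", "site_id", "ref_count", "alt_count")]
  } else {
    df <- read_allele_counts_vcf(path, sites)
  }
  unknown <- setdiff(df$site_id, sites$site_id)
  if (length(unknown) > 0L) {
    abort(paste0("allele-count record at site not in site list: ", unknown[1]))
  }
  if (any(df$ref_count != round(df$ref_count)) ||
      any(df$alt_count != round(df$alt_count))) {
    abort("allele counts must be integers")
  }
  if (any(df$ref_count < 0 | df$alt_count < 0)) {
    abort("allele counts must be non-negative")
  }
  keep_sites <- sites$site_id[sites$pop_af >= af_window[1] &
                              sites$pop_af <= af_window[2]]
  n_drop <- sum(!df$site_id %in% keep_sites)
  if (n_drop > 0L) {
    inform(sprintf("dropped %d allele-count records at sites outside AF window [%g, %g]",
                   n_drop, af_window[1], af_window[2]))
  }
  df <- df[df$site_id %in% keep_sites, ]
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  as_tibble(df)
}

# VCF dialect: AD field, biallelic records only; positions matched to sites
# by (chrom, 1-based VCF POS) -> 0-based pos
read_allele_counts_vcf <- function(path, sites) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF allele counts requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic VCF record(s)", sum(multi)))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  keep <- which(!multi)
  out <- purrr::map_dfr(keep, function(i) {
    counts <- strsplit(ad[i, ], ",", fixed = TRUE)
    tibble(
      sample_id = colnames(ad),
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]) - 1L,
      ref_count = as.integer(vapply(counts, `[[`, "", 1L)),
      alt_count = as.integer(vapply(counts, function(x) {
        if (length(x) >= 2L) x[[2L]] else "0"
      }, ""))
    )
  })
  out <- left_join(out, sites[c("chrom", "pos", "site_id")],
                   by = c("chrom", "pos"))
  if (any(is.na(out$site_id))) {
    bad <- out[is.na(out$site_id), ]
    abort(sprintf("allele-count record at site not in site list: %s_%d",
                  bad$chrom[1], bad$pos[1]))
  }
  out[c("sample_id", "site_id", "ref_count", "alt_count")]
}

#' Write allele counts in the long TSV dialect
#' @param counts Long allele-count tibble.
#' @param path Output TSV path.
#' @export
write_allele_counts <- function(counts, path) {
  readr::write_tsv(counts[c("sample_id", "site_id", "ref_count", "alt_count")],
                   path)
  invisible(path)
}

#' Read a UCSC-style cytoband table
#'
#' @param path TSV in UCSC cytoBand column order: chrom, start, end, band
#'   name (e.g. "p14"), Giemsa stain. 0-based half-open coordinates.
#' @return Cytoband tibble sorted in genome order.
#' @export
read_cytobands <- function(path) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "band", "stain"),
                        show_col_types = FALSE, comment = "#")
  sort_genomic(as_tibble(df))
}

#' Write CNV/LOH calls as a TSV + BED pair
#'
#' The TSV renders 1-based inclusive coordinates for human consumption; the
#' BED mirror keeps the internal 0-based half-open convention. Output is
#' bit-identical across reruns on the same input.
#'
#' @param calls Call tibble with columns sample_id, chrom, start, end,
#'   n_probes, mean_ratio, stat, p_value, cn, class.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.bed`.
#' @export
write_calls <- function(calls, prefix) {
  tsv <- tibble(
    sample = calls$sample_id,
    chrom = calls$chrom,
    start = calls$start + 1L,          # 1-based inclusive in the table
    end = calls$end,
    size_bp = calls$end - calls$start,
    n_probes = calls$n_probes,
    mean_ratio = calls$mean_ratio,
    t_or_F_stat = calls$stat,
    p_value = calls$p_value,
    CN = calls$cn,
    class = calls$class
  )
  tsv <- tsv[order(tsv$sample, chrom_rank(tsv$chrom), tsv$start), ]
  readr::write_tsv(tsv, paste0(prefix, ".tsv"))
  bed <- tibble(chrom = calls$chrom, start = calls$start, end = calls$end,
                name = paste(calls$sample_id, calls$class, calls$cn, sep = "|"))
  bed <- bed[order(chrom_rank(bed$chrom), bed$start), ]
  readr::write_tsv(bed, paste0(prefix, ".bed"), col_names = FALSE)
  invisible(prefix)
}

#' Export per-chromosome plotting tracks
#'
#' Writes bedGraph-style tracks (one file per chromosome and quantity) for
#' the normalized depth ratio, the per-site heterozygosity coefficient, and
#' per-anchor window p-values, suitable for external genome-track plotting.
#'
#' @param ratios Per-probe ratio tibble for one sample (needs chrom, start,
#'   end, r_m).
#' @param dir Output directory (created if needed).
#' @param sample_id Sample name used in file names.
#' @param rhet Optional per-site tibble (chrom, pos, r_het).
#' @param pvalues Optional per-anchor tibble (chrom, pos, p_value).
#' @return Invisibly, the vector of files written.
#' @export
export_tracks <- function(ratios, dir, sample_id, rhet = NULL, pvalues = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, cols, tag) {
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, cols]
      f <- file.path(dir, sprintf("%s_%s_%s.bedgraph", sample_id, tag, ch))
      readr::write_tsv(sub, f, col_names = FALSE)
      written <<- c(written, f)
    }
  }
  rr <- ratios[!is.na(ratios$r_m), ]
  emit(rr, c("chrom", "start", "end", "r_m"), "Rm")
  if (!is.null(rhet)) {
    rh <- rhet
    rh$start <- rh$pos
    rh$end <- rh$pos + 1L
    emit(rh, c("chrom", "start", "end", "r_het"), "RHet")
  }
  if (!is.null(pvalues)) {
    pv <- pvalues[!is.na(pvalues$p_value), ]
    pv$start <- pv$pos
    pv$end <- pv$pos + 1L
    emit(pv, c("chrom", "start", "end", "p_value"), "pval")
  }
  invisible(written)
}
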