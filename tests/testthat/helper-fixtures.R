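# shared fixture builders; everything is generated in code at test time

# a tiny target grid: n probes of 150 bp every 10 kb on each chromosome
toy_targets <- function(n = 10L, chroms = "chr1", spacing = 1e4) {
  df <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * spacing)
  }))
  df$end <- df$start + 150L
  as_target_set(df)
}

# long depth tibble from a probes x samples matrix
toy_depths <- function(mat, targets) {
  colnames(mat) <- colnames(mat) %||% sprintf("S%02d", seq_len(ncol(mat)))
  tibble::tibble(
    sample_id = rep(colnames(mat), each = nrow(mat)),
    region_id = rep(targets$region_id, ncol(mat)),
    depth = as.vector(mat))
}

# cytoband fixture: chr5 with p15..p11 / q11..q35 style bands
toy_cytobands <- function() {
  tibble::tibble(
    chrom = "chr5",
    start = c(0L, 20000000L, 40000000L, 60000000L, 90000000L),
    end = c(20000000L, 40000000L, 60000000L, 90000000L, 180000000L),
    band = c("p15", "p14", "p12", "q11", "q22"),
    stain = "gneg")
}

# small allele-count table for one sample over the given sites
toy_counts <- function(sites, sample_id = "S01", depth = 30L, baf = 0.5) {
  alt <- round(depth * baf)
  tibble::tibble(sample_id = sample_id, site_id = sites$site_id,
                 ref_count = depth - alt, alt_count = alt)
}
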