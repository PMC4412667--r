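#' Simulation configuration
#'
#' Parameters of the count-level simulator. Defaults mirror the benchmark
#' study conditions: two ~60 Mb chromosomes probed every 10 kb with ~150 bp
#' probes, 8 samples at ~30X mean depth, log-normal probe capture
#' efficiencies (sigma 0.4) shared across samples, and one common SNP per
#' probe.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param probe_spacing Distance between probe starts in bp.
#' @param probe_len Probe length in bp.
#' @param n_samples Panel size.
#' @param mean_depth Mean sequenced depth (reads per base) at efficiency 1.
#' @param capture_efficiency_sd Log-normal sigma of per-probe capture
#'   efficiency.
#' @param sites_per_probe Polymorphic sites placed inside each probe.
#' @param seed Mandatory integer seed; every generator is deterministic
#'   given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length_bp = 6e7,
                       probe_spacing = 1e4, probe_len = 150L,
                       n_samples = 8L, mean_depth = 30,
                       capture_efficiency_sd = 0.4, sites_per_probe = 1L,
                       seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_length_bp > 0, probe_spacing > 0,
            probe_len > 0, n_samples >= 1, mean_depth >= 0,
            capture_efficiency_sd >= 0, sites_per_probe >= 0,
            is.numeric(seed))
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length_bp = chrom_length_bp,
                 probe_spacing = probe_spacing,
                 probe_len = as.integer(probe_len),
                 n_samples = as.integer(n_samples),
                 mean_depth = mean_depth,
                 capture_efficiency_sd = capture_efficiency_sd,
                 sites_per_probe = as.integer(sites_per_probe),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate the probe grid and SNP sites
#'
#' Probes start every `probe_spacing` bp (floor(L / spacing) probes per
#' chromosome); each probe carries `sites_per_probe` sites at uniform
#' positions inside the probe window with population allele frequencies
#' drawn uniformly on [0.1, 0.9].
#'
#' @param config A [sim_config()].
#' @return List with `targets` and `sites` tibbles.
#' @export
make_grid <- function(config) {
  withr::with_seed(config$seed, {
    targets <- purrr::map_dfr(seq_len(config$n_chroms), function(c_ix) {
      n <- floor(config$chrom_length_bp / config$probe_spacing)
      start <- as.integer((seq_len(n) - 1L) * config$probe_spacing)
      tibble(chrom = paste0("chr", c_ix), start = start,
             end = start + config$probe_len)
    })
    targets <- as_target_set(targets)
    sites <- NULL
    if (config$sites_per_probe > 0L) {
      k <- config$sites_per_probe
      offs <- matrix(sample.int(config$probe_len, nrow(targets) * k,
                                replace = TRUE) - 1L,
                     ncol = k)
      sites <- purrr::map_dfr(seq_len(k), function(j) {
        tibble(chrom = targets$chrom, pos = targets$start + offs[, j],
               ref_allele = "A", alt_allele = "G",
               pop_af = runif(nrow(targets), 0.1, 0.9))
      })
      sites <- distinct(sites, .data$chrom, .data$pos, .keep_all = TRUE)
      sites <- as_site_table(sites)
      sites <- attach_sites(sites, targets)
    }
    list(targets = targets, sites = sites)
  })
}

# per-sample copy number per probe (or site) from the truth table
truth_cn <- function(chrom, pos, truth, sample_id) {
  cn <- rep(2L, length(pos))
  tr <- truth[truth$sample_id == sample_id & truth$kind %in% c("cnv", "upd"), ]
  if (nrow(tr) > 0L) for (k in seq_len(nrow(tr))) {
    hit <- chrom == tr$chrom[k] & pos >= tr$start[k] & pos < tr$end[k]
    cn[hit] <- tr$cn[k]
  }
  cn
}

#' Simulate per-probe depth tables
#'
#' Draws a shared per-probe capture efficiency e_i ~ log-normal(0, sigma),
#' then for each sample a Poisson depth with rate
#' mean_depth * e_i * CN/2, where CN comes from the truth table
#' (2 outside events).
#'
#' @param grid Output of [make_grid()].
#' @param truth Truth tibble `(sample_id, chrom, start, end, kind, cn)`;
#'   may be empty.
#' @param config A [sim_config()].
#' @return List with `depths` (long tibble) and `efficiency` (per-probe
#'   vector).
#' @export
simulate_depths <- function(grid, truth, config) {
  targets <- grid$targets
  withr::with_seed(config$seed + 1L, {
    eff <- rlnorm(nrow(targets), 0, config$capture_efficiency_sd)
    mid <- (targets$start + targets$end) / 2
    depths <- purrr::map_dfr(seq_len(config$n_samples), function(s) {
      sid <- sprintf("S%02d", s)
      cn <- truth_cn(targets$chrom, mid, truth, sid)
      lambda <- config$mean_depth * eff * cn / 2
      tibble(sample_id = sid, region_id = targets$region_id,
             depth = rpois(nrow(targets), lambda))
    })
    list(depths = depths, efficiency = eff)
  })
}

#' Simulate per-site allele counts
#'
#' Genotypes follow Hardy-Weinberg at each site's population allele
#' frequency. Implanted events modify the BAF target: LOH/UPD segments
#' force homozygosity (the retained allele drawn by allele frequency);
#' single-copy deletions leave a hemizygous allele (BAF 0 or 1); CN 3
#' segments shift heterozygous sites to BAF 1/3 or 2/3 (duplicated allele
#' chosen at random). A sequencing-error floor of 0.002 keeps homozygous
#' BAFs off the exact boundary. Site depth is Poisson at
#' mean_depth * e_probe * CN/2 and the alt count binomial at the BAF
#' target.
#'
#' @param grid Output of [make_grid()] (needs `sites` with
#'   `region_index`).
#' @param truth Truth tibble; `kind` in `cnv`, `loh`, `upd`.
#' @param config A [sim_config()].
#' @param efficiency Per-probe capture efficiencies from
#'   [simulate_depths()] (regenerated identically when omitted).
#' @param error_rate Sequencing-error BAF floor (default 0.002).
#' @return Long tibble `(sample_id, site_id, ref_count, alt_count)`.
#' @export
simulate_allele_counts <- function(grid, truth, config, efficiency = NULL,
                                   error_rate = 0.002) {
  sites <- grid$sites
  if (is.null(sites)) abort("grid has no sites (sites_per_probe = 0)")
  if (is.null(efficiency)) {
    efficiency <- withr::with_seed(config$seed + 1L,
      rlnorm(nrow(grid$targets), 0, config$capture_efficiency_sd))
  }
  eff <- efficiency[sites$region_index + 1L]
  withr::with_seed(config$seed + 2L, {
    purrr::map_dfr(seq_len(config$n_samples), function(s) {
      sid <- sprintf("S%02d", s)
      n <- nrow(sites)
      g <- rbinom(n, 2L, sites$pop_af)  # alt-allele dosage, HW at pop_af
      cn <- truth_cn(sites$chrom, sites$pos, truth, sid)
      in_loh <- rep(FALSE, n)
      tr <- truth[truth$sample_id == sid & truth$kind %in% c("loh", "upd"), ]
      if (nrow(tr) > 0L) for (k in seq_len(nrow(tr))) {
        in_loh <- in_loh | (sites$chrom == tr$chrom[k] &
                            sites$pos >= tr$start[k] &
                            sites$pos < tr$end[k])
      }
      baf <- g / 2
      # hemizygous deletion: one allele lost; het sites keep either allele
      del <- cn == 1L
      pick <- runif(n) < 0.5
      baf[del & g == 1L] <- ifelse(pick[del & g == 1L], 1, 0)
      baf[del & g == 2L] <- 1
      baf[del & g == 0L] <- 0
      # copy-neutral LOH / isodisomy: homozygous for one allele
      neutral_loh <- in_loh & cn == 2L
      baf[neutral_loh] <- ifelse(runif(n)[neutral_loh] < sites$pop_af[neutral_loh],
                                 1, 0)
      # three copies with a retained het genotype: 1/3 or 2/3
      tri_het <- cn == 3L & g == 1L & !in_loh
      baf[tri_het] <- ifelse(pick[tri_het], 2 / 3, 1 / 3)
      baf <- pmin(1 - error_rate, pmax(error_rate, baf))
      depth <- rpois(n, config$mean_depth * eff * cn / 2)
      alt <- rbinom(n, depth, baf)
      tibble(sample_id = sid, site_id = sites$site_id,
             ref_count = depth - alt, alt_count = alt)
    })
  })
}

# draw non-overlapping event intervals (whole probes) on a grid
place_events <- function(targets, n_events, size_range, chroms, spacing) {
  placed <- tibble(chrom = character(), start = integer(), end = integer())
  guard <- 0L
  while (nrow(placed) < n_events && guard < 10000L) {
    guard <- guard + 1L
    ch <- sample(chroms, 1L)
    tt <- targets[targets$chrom == ch, ]
    size <- runif(1, size_range[1], size_range[2])
    n_probes <- max(1L, round(size / spacing))
    if (n_probes + 2L >= nrow(tt)) next
    at <- sample.int(nrow(tt) - n_probes - 1L, 1L) + 1L
    start <- tt$start[at]
    end <- tt$end[at + n_probes - 1L]
    clash <- any(placed$chrom == ch & placed$start < end + 10 * spacing &
                 placed$end > start - 10 * spacing)
    if (clash) next
    placed <- bind_rows(placed, tibble(chrom = ch, start = start, end = end))
  }
  if (nrow(placed) < n_events) abort("could not place all events on the grid")
  placed
}

#' Simulate the CNV benchmark panel
#'
#' The benchmark preset: an 8-sample panel over two ~60 Mb chromosomes at
#' ~30X, with 9 CNV events (CN 1 or 3, sizes 450 kb to 3 Mb) implanted
#' across 3 carrier samples; the other 5 samples are normal and anchor the
#' median baseline.
#'
#' @param seed Integer seed.
#' @param config Optional [sim_config()] override (its seed is replaced by
#'   `seed`).
#' @param n_events Number of implanted CNV events (default 9).
#' @param n_carriers Carrier samples the events are spread over
#'   (default 3).
#' @param size_range Event size range in bp (default 450 kb to 3 Mb).
#' @param with_alleles Also simulate allele counts (default TRUE).
#' @return List with `grid`, `depths`, `allele_counts`, `truth`, `config`.
#' @export
simulate_benchmark <- function(seed, config = NULL, n_events = 9L,
                               n_carriers = 3L,
                               size_range = c(450e3, 3e6),
                               with_alleles = TRUE) {
  config <- config %||% sim_config()
  config$seed <- as.integer(seed)
  grid <- make_grid(config)
  truth <- withr::with_seed(config$seed + 3L, {
    ev <- place_events(grid$targets, n_events, size_range,
                       unique(grid$targets$chrom), config$probe_spacing)
    carriers <- sprintf("S%02d", seq_len(n_carriers))
    # every carrier gets at least one event; the rest are spread at random
    owner <- c(carriers[seq_len(min(n_carriers, n_events))],
               sample(carriers, max(0L, n_events - n_carriers),
                      replace = TRUE))
    ev$sample_id <- sample(owner)
    ev$kind <- "cnv"
    ev$cn <- sample(c(1L, 3L), n_events, replace = TRUE)
    ev[c("sample_id", "chrom", "start", "end", "kind", "cn")]
  })
  sim <- simulate_depths(grid, truth, config)
  counts <- if (with_alleles)
    simulate_allele_counts(grid, truth, config, sim$efficiency) else NULL
  list(grid = grid, depths = sim$depths, allele_counts = counts,
       truth = truth, config = config)
}

#' Simulate a null panel (no implanted events)
#'
#' @param seed Integer seed.
#' @param config Optional [sim_config()] override.
#' @param with_alleles Also simulate allele counts (default FALSE).
#' @return List with `grid`, `depths`, `allele_counts`, `truth` (empty),
#'   `config`.
#' @export
simulate_null <- function(seed, config = NULL, with_alleles = FALSE) {
  config <- config %||% sim_config()
  config$seed <- as.integer(seed)
  truth <- tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), kind = character(),
                  cn = integer())
  grid <- make_grid(config)
  sim <- simulate_depths(grid, truth, config)
  counts <- if (with_alleles)
    simulate_allele_counts(grid, truth, config, sim$efficiency) else NULL
  list(grid = grid, depths = sim$depths, allele_counts = counts,
       truth = truth, config = config)
}

#' Simulate an LOH/UPD benchmark panel
#'
#' Implants one copy-neutral UPD segment (CN 2, homozygous) and one
#' hemizygous deletion (CN 1, which both callers should flag) into the
#' first sample of an otherwise normal panel.
#'
#' @param seed Integer seed.
#' @param config Optional [sim_config()] override (default: one 30 Mb
#'   chromosome, 9 samples).
#' @param upd_size,del_size Implant sizes in bp (default 6 Mb each).
#' @return List with `grid`, `depths`, `allele_counts`, `truth`, `config`.
#' @export
simulate_loh_benchmark <- function(seed, config = NULL, upd_size = 6e6,
                                   del_size = 6e6) {
  config <- config %||% sim_config(n_chroms = 1L, chrom_length_bp = 3e7,
                                   n_samples = 9L)
  config$seed <- as.integer(seed)
  grid <- make_grid(config)
  L <- config$chrom_length_bp
  truth <- tibble(
    sample_id = "S01", chrom = grid$targets$chrom[1],
    start = as.integer(c(0.1 * L, 0.6 * L)),
    end = as.integer(c(0.1 * L + upd_size, 0.6 * L + del_size)),
    kind = c("upd", "cnv"), cn = c(2L, 1L))
  sim <- simulate_depths(grid, truth, config)
  counts <- simulate_allele_counts(grid, truth, config, sim$efficiency)
  list(grid = grid, depths = sim$depths, allele_counts = counts,
       truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the same BED/TSV dialects the readers consume, plus the truth
#' table; the written files and a fresh simulation from the same seed are
#' byte-identical.
#'
#' @param sim A simulation list (from [simulate_benchmark()] and friends).
#' @param dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    targets = file.path(dir, "targets.bed"),
    depths = file.path(dir, "depths.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_targets(sim$grid$targets, files[["targets"]])
  write_depth_table(sim$depths, sim$grid$targets, files[["depths"]])
  readr::write_tsv(sim$truth, files[["truth"]])
  if (!is.null(sim$grid$sites)) {
    files[["sites"]] <- file.path(dir, "sites.tsv")
    write_snp_table(sim$grid$sites, files[["sites"]])
  }
  if (!is.null(sim$allele_counts)) {
    files[["alleles"]] <- file.path(dir, "allele_counts.tsv")
    write_allele_counts(sim$allele_counts, files[["alleles"]])
  }
  invisible(files)
}

#' Synthetic genome fixture for probe design
#'
#' A random genome with planted features that exercise every design
#' filter: an exact duplicated segment (non-unique flanks), near-identical
#' decoys at ~99% and ~90% identity, a long homopolymer run, a GC-extreme
#' window, and a uniform scatter of labelled SNPs.
#'
#' @param seed Integer seed.
#' @param length_bp Genome length (default 1e6).
#' @param n_snps SNPs scattered over the genome (default 150).
#' @return List with `genome` (a named character vector of sequences),
#'   `snps` tibble, and `features` tibble describing the planted regions.
#' @export
make_design_fixture <- function(seed, length_bp = 1e6, n_snps = 150L) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seq <- sample(bases, length_bp, replace = TRUE)
    feat <- list()
    plant <- function(seq, at, what, label) {
      seq[at:(at + length(what) - 1L)] <- what
      feat[[length(feat) + 1L]] <<- tibble(
        feature = label, start = at - 1L, end = at - 1L + length(what))
      seq
    }
    # exact duplicate: copy a 600 bp segment to a distant locus
    src <- round(0.10 * length_bp)
    seg <- seq[src:(src + 599L)]
    seq <- plant(seq, round(0.80 * length_bp), seg, "exact_duplicate")
    feat[[length(feat) + 1L]] <- tibble(feature = "duplicate_source",
                                        start = src - 1L, end = src + 599L)
    # ~99% identical decoy of a segment at 20% (3 mismatches in 300 bp)
    src99 <- round(0.20 * length_bp)
    seg99 <- seq[src99:(src99 + 299L)]
    mut <- sample.int(300L, 3L)
    seg99[mut] <- vapply(seg99[mut], function(b) sample(setdiff(bases, b), 1L), "")
    seq <- plant(seq, round(0.70 * length_bp), seg99, "decoy_99")
    feat[[length(feat) + 1L]] <- tibble(feature = "decoy_99_source",
                                        start = src99 - 1L, end = src99 + 299L)
    # ~90% identical decoy of a segment at 30% (30 mismatches in 300 bp)
    src90 <- round(0.30 * length_bp)
    seg90 <- seq[src90:(src90 + 299L)]
    mut <- sample.int(300L, 30L)
    seg90[mut] <- vapply(seg90[mut], function(b) sample(setdiff(bases, b), 1L), "")
    seq <- plant(seq, round(0.60 * length_bp), seg90, "decoy_90")
    feat[[length(feat) + 1L]] <- tibble(feature = "decoy_90_source",
                                        start = src90 - 1L, end = src90 + 299L)
    # homopolymer and GC-extreme windows
    seq <- plant(seq, round(0.45 * length_bp), rep("A", 500L), "homopolymer")
    seq <- plant(seq, round(0.50 * length_bp),
                 sample(c("G", "C"), 1000L, replace = TRUE), "gc_extreme")
    genome <- setNames(paste(seq, collapse = ""), "ctg1")
    pos <- sort(sample.int(length_bp - 200L, n_snps) + 100L) - 1L
    snps <- tibble(chrom = "ctg1", pos = pos,
                   ref_allele = seq[pos + 1L],
                   alt_allele = vapply(seq[pos + 1L], function(b)
                     sample(setdiff(bases, b), 1L), ""),
                   pop_af = runif(n_snps, 0.02, 0.98))
    list(genome = genome, snps = as_site_table(snps),
         features = bind_rows(feat))
  })
}

#' Score CNV calls against a simulation truth table
#'
#' An implanted event counts as recovered when a call in the same sample
#' overlaps it; strict recovery additionally requires the call's integer
#' CN to equal the implanted one. Specificity is the fraction of emitted
#' calls that overlap some truth event of their sample.
#'
#' @param calls Tidied CNV call tibble.
#' @param truth Truth tibble from the simulator.
#' @return One-row tibble: n_events, n_recovered (correct CN), n_calls,
#'   n_true_calls, sensitivity_pct, specificity_pct.
#' @export
score_against_truth <- function(calls, truth) {
  overlaps <- function(a, b) {
    a$sample_id == b$sample_id & a$chrom == b$chrom &
      a$start < b$end & a$end > b$start
  }
  n_recovered <- sum(vapply(seq_len(nrow(truth)), function(k) {
    tr <- truth[k, ]
    any(overlaps(calls, tr) & calls$cn == tr$cn)
  }, logical(1)))
  n_true_calls <- sum(vapply(seq_len(nrow(calls)), function(k) {
    any(overlaps(truth, calls[k, ]))
  }, logical(1)))
  tibble(
    n_events = nrow(truth), n_recovered = n_recovered,
    n_calls = nrow(calls), n_true_calls = n_true_calls,
    sensitivity_pct = 100 * n_recovered / max(1L, nrow(truth)),
    specificity_pct = if (nrow(calls) == 0L) 100 else
      100 * n_true_calls / nrow(calls))
}
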