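test_that("R_Het identities and symmetry hold", {
  expect_equal(compute_rhet(0.5), 1)
  expect_equal(compute_rhet(0), 0)
  expect_equal(compute_rhet(1), 0)
  expect_equal(compute_rhet(0.2), 0.25)
  expect_equal(compute_rhet(0.8), 0.25)
  b <- seq(0, 1, by = 0.001)
  expect_equal(compute_rhet(b), compute_rhet(1 - b), tolerance = 1e-12)
  # maximal only at 0.5
  expect_true(all(compute_rhet(b[b != 0.5]) < 1))
  expect_true(all(compute_rhet(b) >= 0 & compute_rhet(b) <= 1))
})

test_that("add_rhet derives BAF and flags shallow sites unusable", {
  sites <- as_site_table(data.frame(
    chrom = "chr1", pos = c(100L, 200L), ref_allele = "A",
    alt_allele = "G", pop_af = 0.5))
  counts <- tibble::tibble(sample_id = "S01", site_id = sites$site_id,
                           ref_count = c(15L, 4L), alt_count = c(15L, 3L))
  tab <- add_rhet(counts, sites, min_depth = 10L)
  expect_equal(tab$baf, c(0.5, 3 / 7))
  expect_equal(tab$r_het[1], 1)
  expect_equal(tab$usable, c(TRUE, FALSE))
  expect_error(add_rhet(dplyr::mutate(counts, site_id = "nope"), sites),
               "unknown site")
})

test_that("the R_Het baseline is a per-site median over usable samples", {
  sites <- as_site_table(data.frame(
    chrom = "chr1", pos = c(100L, 200L), ref_allele = "A",
    alt_allele = "G", pop_af = 0.5))
  mk <- function(id, baf1, baf2, depth = 30L) tibble::tibble(
    sample_id = id, site_id = sites$site_id,
    ref_count = as.integer(round(depth * (1 - c(baf1, baf2)))),
    alt_count = as.integer(round(depth * c(baf1, baf2))))
  counts <- dplyr::bind_rows(mk("S01", 0.0, 0.5), mk("S02", 0.5, 0.5),
                             mk("S03", 0.5, 0.5))
  tab <- add_rhet(counts, sites)
  bl <- build_rhet_baseline(tab, min_samples = 3L)
  expect_equal(bl$median_rhet, c(1, 1))   # median of (0, 1, 1) is 1

  # a site shallow in most samples is masked
  counts2 <- counts
  counts2$ref_count[counts2$site_id == "chr1_100" &
                    counts2$sample_id != "S01"] <- 2L
  counts2$alt_count[counts2$site_id == "chr1_100" &
                    counts2$sample_id != "S01"] <- 2L
  bl2 <- build_rhet_baseline(add_rhet(counts2, sites), min_samples = 3L)
  expect_true(bl2$masked[bl2$site_id == "chr1_100"])
  expect_error(build_rhet_baseline(tab, min_samples = 8L), "at least 8")
})

test_that("the window F test follows the printed two-sided construction", {
  # equal variances: F = 1 and p = 1 exactly
  x <- c(0.1, 0.9, 0.4, 0.6, 0.2, 0.8)
  got <- window_f_test(x, x)
  expect_equal(got$f_upper, 1)
  expect_equal(got$p_value, 1)
  # a flat test window against a dispersed baseline collapses p to ~0
  flat <- window_f_test(rep(0, 6), x)
  expect_true(flat$flagged)
  expect_equal(flat$p_value, .Machine$double.xmin)
  # both windows flat: undefined, flagged
  und <- window_f_test(rep(0.5, 6), rep(0.5, 6))
  expect_true(und$flagged)
  expect_true(is.na(und$p_value))
})

test_that("F-test p matches an independent oracle over random fixtures", {
  withr::with_seed(5, {
    for (k in 1:250) {
      n <- sample(5:40, 1)
      a <- runif(n)
      b <- runif(n, 0, runif(1, 0.2, 2))
      got <- window_f_test(a, b)
      # oracle: explicit variance sums + F upper tails per the printed rule
      va <- sum((a - sum(a) / n)^2) / (n - 1)
      vb <- sum((b - sum(b) / n)^2) / (n - 1)
      fu <- max(va, vb) / min(va, vb)
      fd <- min(va, vb) / max(va, vb)
      pu <- stats::pf(fu, n - 1, n - 1, lower.tail = FALSE)
      pd <- stats::pf(fd, n - 1, n - 1, lower.tail = FALSE)
      expect_equal(got$p_value, min(1, pu + (1 - pd)), tolerance = 1e-10)
      expect_true(got$f_upper >= 1, info = "F_upper at least 1")
      expect_equal(got$f_upper * got$f_under, 1, tolerance = 1e-12)
    }
  })
})

test_that("LOH intervals initiate on 3 consecutive significant anchors", {
  expect_equal(nrow(scan_loh(c(0.001, 0.003, 0.002))), 1L)
  got <- scan_loh(c(0.5, 0.001, 0.003, 0.002, 0.5))
  expect_equal(c(got$from, got$to), c(2L, 4L))
  # a broken run does not initiate
  expect_equal(nrow(scan_loh(c(0.001, 0.02, 0.001, 0.001))), 0L)
  expect_equal(nrow(scan_loh(numeric(0))), 0L)
  # two separate runs give two intervals
  p <- c(rep(0.001, 3), 0.5, 0.5, rep(0.001, 4))
  expect_equal(nrow(scan_loh(p)), 2L)
})

test_that("extension absorbs small-p neighbors and tolerates one excursion", {
  # neighbor below threshold is absorbed
  p <- c(0.5, 0.005, 0.001, 0.001, 0.001, 0.5)
  got <- extend_loh(p, 3L, 5L)
  expect_equal(c(got$from, got$to), c(2L, 5L))
  # one above-threshold neighbor rides along while the mean stays low
  p2 <- c(0.001, 0.001, 0.001, 0.05, 0.001, 0.9)
  got2 <- extend_loh(p2, 1L, 3L)
  expect_equal(got2$to, 5L)
  # two consecutive excursions stop the extension before the second
  p3 <- c(0.001, 0.001, 0.001, 0.05, 0.06, 0.001)
  got3 <- extend_loh(p3, 1L, 3L)
  expect_equal(got3$to, 4L)
  # an excursion that would push the running mean past the cap is refused
  p4 <- c(0.001, 0.001, 0.001, 0.9)
  got4 <- extend_loh(p4, 1L, 3L)
  expect_equal(got4$to, 3L)
})

test_that("copy-neutral LOH classifies as UPD, deletion LOH as LOH_nonUPD", {
  loh <- tibble::tibble(
    sample_id = "S01", chrom = "chr1",
    start = c(0L, 20000000L, 40000000L),
    end = c(6000000L, 26000000L, 44000000L),
    n_anchors = 100L, mean_p = 0.001,
    size_bp = c(6000000L, 6000000L, 4000000L))
  cnv <- tibble::tibble(sample_id = "S01", chrom = "chr1",
                        start = 20000000L, end = 26000000L, cn = 1L)
  got <- classify_upd(loh, cnv, min_size = 5e6)
  expect_equal(got$class, c("UPD", "LOH_nonUPD", "UPD"))
  expect_equal(got$cn_context, c(2L, 1L, 2L))
  # the 4 Mb interval is retained but not reportable
  expect_equal(got$reportable, c(TRUE, TRUE, FALSE))
  # with no CNV calls everything is copy-neutral
  expect_equal(unique(classify_upd(loh, NULL)$class), "UPD")
})

test_that("consistency check flags CN=1 calls without co-localizing LOH", {
  cnv <- tibble::tibble(sample_id = "S01", chrom = "chr1",
                        start = c(0L, 30000000L),
                        end = c(6000000L, 36000000L), cn = c(1L, 1L))
  loh <- tibble::tibble(sample_id = "S01", chrom = "chr1",
                        start = 0L, end = 6000000L)
  expect_warning(bad <- check_consistency(loh, cnv), "lack a co-localizing")
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$start, 30000000L)
  # both covered: clean report
  loh2 <- dplyr::bind_rows(loh, tibble::tibble(
    sample_id = "S01", chrom = "chr1", start = 29000000L, end = 37000000L))
  expect_equal(nrow(check_consistency(loh2, cnv)), 0L)
  expect_equal(nrow(check_consistency(loh, cnv[0, ])), 0L)
})

test_that("call_loh finds an implanted homozygous stretch end to end", {
  cfg <- sim_config(n_chroms = 1L, chrom_length_bp = 1.2e7, n_samples = 9L,
                    seed = 19L)
  truth <- tibble::tibble(sample_id = "S01", chrom = "chr1",
                          start = 4000000L, end = 8000000L,
                          kind = "upd", cn = 2L)
  grid <- make_grid(cfg)
  counts <- simulate_allele_counts(grid, truth, cfg)
  tab <- add_rhet(counts, grid$sites)
  bl <- build_rhet_baseline(tab[tab$sample_id != "S01", ], min_samples = 8L)
  scan <- call_loh(tab[tab$sample_id == "S01", ], bl)
  expect_s3_class(scan, "loh_scan")
  ivs <- tidy(scan)
  expect_equal(nrow(ivs), 1L)
  expect_lt(abs(ivs$start - 4e6), 4e5)   # boundary fuzz under one window
  expect_lt(abs(ivs$end - 8e6), 4e5)
  # the normal panel member shows no intervals
  scan2 <- call_loh(tab[tab$sample_id == "S02", ],
                    build_rhet_baseline(tab[tab$sample_id != "S02", ],
                                        min_samples = 8L))
  expect_equal(nrow(tidy(scan2)), 0L)
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
  expect_equal(glance(scan)$n_intervals, 1L)
})

test_that("a balanced three-copy segment drives window R_Het toward 0.5", {
  cfg <- sim_config(n_chroms = 1L, chrom_length_bp = 8e6, n_samples = 2L,
                    mean_depth = 60, seed = 23L)
  truth <- tibble::tibble(sample_id = "S01", chrom = "chr1",
                          start = 2000000L, end = 6000000L,
                          kind = "cnv", cn = 3L)
  grid <- make_grid(cfg)
  counts <- simulate_allele_counts(grid, truth, cfg)
  tab <- add_rhet(counts, grid$sites)
  s1 <- tab[tab$sample_id == "S01", ]
  inside <- s1$pos >= 2e6 & s1$pos < 6e6
  het_in <- s1$r_het[inside & s1$r_het > 0.1]   # het sites inside the gain
  expect_gt(length(het_in), 50L)
  expect_lt(abs(median(het_in) - 0.5), 0.1)
})
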