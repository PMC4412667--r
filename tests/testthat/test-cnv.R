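test_that("probe-level t matches the closed form and is symmetric", {
  panel <- matrix(c(1.00, 1.01, 0.99, 1.02, 0.98, 1.00, 1.01, 0.99, 1.00,
                    1.00), nrow = 1)
  # equal to the panel mean: t = 0, p = 1
  res0 <- probe_level_ttest(mean(panel), panel)
  expect_equal(res0$t_score, 0)
  expect_equal(res0$p_value, 1)
  # hand-computed one-vs-panel t with the (1 + 1/n) inflation
  res <- probe_level_ttest(0.5, panel)
  n <- ncol(panel)
  t_hand <- (0.5 - mean(panel)) / sqrt(var(as.vector(panel)) * (1 + 1 / n))
  expect_equal(res$t_score, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), n - 1), tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  # reflecting the test value around the panel mean leaves p unchanged
  refl <- probe_level_ttest(2 * mean(panel) - 0.5, panel)
  expect_equal(refl$p_value, res$p_value, tolerance = 1e-12)
})

test_that("probe t agrees with a brute-force oracle over random fixtures", {
  withr::with_seed(42, {
    for (k in 1:250) {
      n <- sample(5:15, 1)
      vals <- rnorm(n, 1, runif(1, 0.02, 0.3))
      x <- rnorm(1, 1, 0.3)
      got <- probe_level_ttest(x, matrix(vals, nrow = 1))
      # oracle: explicit sums, no shared code path
      mu <- sum(vals) / n
      s2 <- sum((vals - mu)^2) / (n - 1)
      t_or <- (x - mu) / sqrt(s2 + s2 / n)
      p_or <- 2 * stats::pt(abs(t_or), n - 1, lower.tail = FALSE)
      expect_equal(got$t_score, t_or, tolerance = 1e-10)
      expect_equal(got$p_value, p_or, tolerance = 1e-10)
    }
  })
})

test_that("degenerate panels mask the probe with a warning", {
  panel <- matrix(rep(1, 8), nrow = 1)
  expect_warning(res <- probe_level_ttest(0.5, panel), "zero panel variance")
  expect_true(res$masked)
  expect_true(is.na(res$p_value))
})

test_that("probe-level p-values are uniform when the panel model holds", {
  withr::with_seed(7, {
    N <- 5000
    n <- 9
    panel <- matrix(rnorm(N * n, 1, 0.06), N, n)
    tests <- probe_level_ttest(rnorm(N, 1, 0.06), panel)
    expect_gt(stats::ks.test(tests$p_value, "punif")$p.value, 0.01)
  })
})

test_that("the 4-probe seeding rule marks qualifying windows only", {
  mk <- function(p, t = rep(-3, length(p))) {
    tibble::tibble(t_score = t, p_value = p, z = t, masked = FALSE)
  }
  ch <- rep("chr1", 4)
  # three p-values under 0.05, fourth within 0.2: all four marked
  expect_equal(seed_pseudo_signals(mk(c(0.01, 0.02, 0.03, 0.15)), ch),
               rep("-", 4))
  # fourth exceeds the secondary threshold: nothing marked
  expect_equal(seed_pseudo_signals(mk(c(0.01, 0.02, 0.03, 0.25)), ch),
               rep(NA_character_, 4))
  # mixed t-signs break the window
  expect_equal(seed_pseudo_signals(mk(c(0.01, 0.02, 0.03, 0.15),
                                      t = c(-3, -3, 3, -3)), ch),
               rep(NA_character_, 4))
  # gains are marked "+"
  expect_equal(seed_pseudo_signals(mk(c(0.01, 0.02, 0.03, 0.04),
                                      t = rep(3, 4)), ch), rep("+", 4))
  # overlapping windows accumulate marks over longer runs
  p7 <- c(0.01, 0.02, 0.03, 0.15, 0.01, 0.02, 0.03)
  expect_equal(seed_pseudo_signals(mk(p7), rep("chr1", 7)), rep("-", 7))
  # windows never span a chromosome boundary
  expect_equal(seed_pseudo_signals(mk(c(0.01, 0.02, 0.03, 0.01)),
                                   c("chr1", "chr1", "chr2", "chr2")),
               rep(NA_character_, 4))
})

test_that("the copy-number gate keeps near-neutral probes out of seeds", {
  tests <- tibble::tibble(t_score = rep(-3, 4),
                          p_value = c(0.01, 0.02, 0.03, 0.04),
                          z = -3, masked = FALSE)
  ch <- rep("chr1", 4)
  # all probes at ratio 0.5 round to CN 1: marked
  expect_equal(seed_pseudo_signals(tests, ch, r_m = rep(0.5, 4)),
               rep("-", 4))
  # one probe rounds back to CN 2 (0.8): window disqualified
  expect_equal(seed_pseudo_signals(tests, ch, r_m = c(0.5, 0.5, 0.8, 0.5)),
               rep(NA_character_, 4))
})

test_that("marked runs merge across small same-sign gaps only", {
  ch <- rep("chr1", 20)
  marks <- rep(NA_character_, 20)
  marks[1:4] <- "-"
  marks[8:11] <- "-"     # 3-probe gap
  got <- merge_marked_runs(marks, ch, max_gap = 5L)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$from, got$to), c(1L, 11L))

  marks2 <- rep(NA_character_, 20)
  marks2[1:4] <- "-"
  marks2[11:14] <- "-"   # 6-probe gap: stays split
  got2 <- merge_marked_runs(marks2, ch, max_gap = 5L)
  expect_equal(nrow(got2), 2L)

  marks3 <- rep(NA_character_, 20)
  marks3[1:4] <- "-"
  marks3[5:8] <- "+"     # adjacent opposite signs never merge
  got3 <- merge_marked_runs(marks3, ch, max_gap = 5L)
  expect_equal(got3$sign, c("-", "+"))
})

test_that("region-level t is a one-sample t on the deviations", {
  z <- c(-0.5, -0.5, -0.48, -0.52)
  got <- region_level_ttest(z)
  t_hand <- mean(z) * sqrt(length(z)) / sd(z)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_lt(got$p, 0.01)
  # symmetric deviations are not significant
  expect_gt(region_level_ttest(c(-0.1, 0.1, -0.12, 0.12))$p, 0.5)
  # zero dispersion flags and floors the p-value
  d <- region_level_ttest(rep(-0.5, 5))
  expect_true(d$flagged)
  expect_equal(d$p, .Machine$double.xmin)
})

test_that("region t agrees with a brute-force oracle over random fixtures", {
  withr::with_seed(11, {
    for (k in 1:250) {
      m <- sample(4:40, 1)
      z <- rnorm(m, runif(1, -0.5, 0.5), runif(1, 0.01, 0.2))
      got <- region_level_ttest(z)
      mu <- sum(z) / m
      s <- sqrt(sum((z - mu)^2) / (m - 1))
      t_or <- mu / (s / sqrt(m))
      expect_equal(got$t, t_or, tolerance = 1e-10)
      expect_equal(got$p, 2 * stats::pt(abs(t_or), m - 1,
                                        lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })
})

test_that("integer CN is the ratio over 0.5, rounded half up, floored at 0", {
  expect_identical(assign_copy_number(1.0), 2L)
  expect_identical(assign_copy_number(0.5), 1L)
  expect_identical(assign_copy_number(0.05), 0L)
  expect_identical(assign_copy_number(0), 0L)
  # a continuous CN estimate of 3.497 rounds down to 3
  expect_identical(assign_copy_number(3.497 * 0.5), 3L)
  # half-up tie-break: 0.75 -> CN 2, 1.25 -> CN 3
  expect_identical(assign_copy_number(0.75), 2L)
  expect_identical(assign_copy_number(1.25), 3L)
})

test_that("sex is inferred from chrX/chrY depth coefficients", {
  mk_ratios <- function(rx, ry, id = "S01") tibble::tibble(
    sample_id = id, chrom = c(rep("chr1", 4), rep("chrX", 4),
                              rep("chrY", 2)),
    r = c(rep(1, 4), rep(rx, 4), rep(ry, 2)))
  expect_equal(infer_sex(mk_ratios(1.0, 0.02))$sex, "XX")
  expect_equal(infer_sex(mk_ratios(0.5, 0.5))$sex, "XY")
  amb <- infer_sex(mk_ratios(0.8, 0.3))
  expect_equal(amb$sex, "other")
  expect_equal(amb$chrx_mean_r, 0.8)
})

test_that("call_cnvs recovers an implanted deletion with tight boundaries", {
  n <- 400L
  ts <- toy_targets(n)
  withr::with_seed(3, {
    mat <- matrix(rpois(n * 9L, 30), n, 9L)
    mat[101:200, 1] <- rpois(100L, 15)   # CN 1 over probes 101..200
  })
  ratios <- normalize_depths(toy_depths(mat, ts), ts)
  bl <- build_baseline(ratios[ratios$sample_id != "S01", ], ts,
                       min_samples = 8L)
  test_rm <- normalize_by_baseline(ratios[ratios$sample_id == "S01", ], bl)
  panel_rm <- normalize_by_baseline(ratios[ratios$sample_id != "S01", ], bl)
  scan <- call_cnvs(test_rm, panel_rm, ts, min_probes = 10L, min_size = 0)
  expect_s3_class(scan, "cnv_scan")
  calls <- tidy(scan)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$cn, 1L)
  expect_equal(calls$direction, "loss")
  # boundaries within 2 probes (20 kb) of the implant
  expect_lt(abs(calls$start - ts$start[101]), 2 * 1e4 + 1)
  expect_lt(abs(calls$end - ts$end[200]), 2 * 1e4 + 1)

  # a sample equal to the panel median yields no calls
  scan2 <- call_cnvs(normalize_by_baseline(
    ratios[ratios$sample_id == "S02", ], bl),
    panel_rm[panel_rm$sample_id != "S02", ], ts,
    min_probes = 10L, min_size = 0)
  expect_equal(nrow(scan2$calls), 0L)
  expect_equal(nrow(tidy(scan2)), 0L)
})

test_that("a whole-chromosome gain is promoted to an aneuploidy call", {
  # chr2 is small relative to the genome so its gain does not drag the
  # sample's own autosomal mean far from the panel's
  starts <- c((0:479) * 1e4, (0:59) * 1e4)
  ts <- as_target_set(data.frame(
    chrom = rep(c("chr1", "chr2"), c(480L, 60L)),
    start = as.integer(starts), end = as.integer(starts + 150L)))
  withr::with_seed(13, {
    mat <- matrix(rpois(540L * 9L, 30), 540L, 9L)
    mat[ts$chrom == "chr2", 1] <- rpois(60L, 45)   # CN 3 chromosome
  })
  ratios <- normalize_depths(toy_depths(mat, ts), ts)
  bl <- build_baseline(ratios[ratios$sample_id != "S01", ], ts,
                       min_samples = 8L)
  scan <- call_cnvs(
    normalize_by_baseline(ratios[ratios$sample_id == "S01", ], bl),
    normalize_by_baseline(ratios[ratios$sample_id != "S01", ], bl),
    ts, min_probes = 10L, min_size = 0)
  calls <- tidy(scan)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$aneuploid)
  expect_identical(calls$cn, 3L)
  expect_equal(calls$class, "aneuploidy")
  expect_equal(calls$n_probes, 60L)
})

test_that("glance and autoplot summarize a scan", {
  ts <- toy_targets(60L)
  withr::with_seed(2, mat <- matrix(rpois(60L * 9L, 30), 60L, 9L))
  ratios <- normalize_depths(toy_depths(mat, ts), ts)
  bl <- build_baseline(ratios[ratios$sample_id != "S01", ], ts,
                       min_samples = 8L)
  scan <- call_cnvs(
    normalize_by_baseline(ratios[ratios$sample_id == "S01", ], bl),
    normalize_by_baseline(ratios[ratios$sample_id != "S01", ], bl),
    ts, min_probes = 10L, min_size = 0)
  g <- glance(scan)
  expect_equal(g$n_probes, 60L)
  expect_equal(g$n_calls, 0L)
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})

test_that("karyotype strings follow ISCN conventions", {
  male <- list(sex = "XY")
  female <- list(sex = "XX")
  no_calls <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    cn = integer(), direction = character(), aneuploid = logical())
  expect_equal(format_karyotype(male, no_calls), "46,XY")

  cyto <- toy_cytobands()
  del5 <- tibble::tibble(chrom = "chr5", start = 21e6L, end = 39e6L,
                         cn = 1L, direction = "loss", aneuploid = FALSE)
  expect_equal(format_karyotype(male, del5, cyto), "46,XY,del(5)(p14)")
  # a deletion spanning two bands names both
  del5b <- tibble::tibble(chrom = "chr5", start = 21e6L, end = 45e6L,
                          cn = 1L, direction = "loss", aneuploid = FALSE)
  expect_equal(format_karyotype(male, del5b, cyto), "46,XY,del(5)(p14p12)")

  tri <- tibble::tibble(
    chrom = c("chrX", "chr18"), start = 0L, end = c(155e6L, 80e6L),
    cn = 3L, direction = "gain", aneuploid = TRUE)
  expect_equal(format_karyotype(female, tri), "48,XXX,+18")
})
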