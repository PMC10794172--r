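test_that("a linear Marey map gives a flat 1 cM/Mb track", {
  map <- data.frame(chrom = "c1", bp = seq(0, 50e6, length.out = 20),
                    cM = seq(0, 50, length.out = 20))
  tr <- smooth_marey(map)
  expect_true(all(abs(tr$rate - 1) < 1e-9))
  expect_equal(attr(tr, "n_clamped"), 0)
})

test_that("not-a-knot spline derivative is exact on a cubic toy", {
  # a cubic is reproduced exactly by a not-a-knot spline, so the recovered
  # rate must match the analytic derivative at interior grid points
  a <- 0.5; b <- 0.08; cc <- 0.004  # cM per Mb, Mb^2, Mb^3 terms
  xs_mb <- c(0, 7, 18, 26, 37, 50)
  g <- function(x) a * x + b * x^2 + cc * x^3
  gp <- function(x) a + 2 * b * x + 3 * cc * x^2
  map <- data.frame(chrom = "c1", bp = xs_mb * 1e6, cM = g(xs_mb))
  tr <- smooth_marey(map, grid_bp = 5e5)
  expected <- gp(tr$pos / 1e6)
  expect_lt(max(abs(tr$rate - expected) / expected), 1e-6)
})

test_that("spline interpolation preserves per-chromosome map length", {
  map <- simulate_marey_map(fx_hic_layout(), multiplier = 12,
                            n_markers = 150, seed = 21)
  tr <- smooth_marey(map)
  sp <- attr(tr, "splines")
  for (ch in unique(map$chrom)) {
    d <- map[map$chrom == ch, ]
    est <- frogsynt:::.spline_eval(sp[[ch]], max(d$bp)) -
      frogsynt:::.spline_eval(sp[[ch]], min(d$bp))
    expect_lt(abs(est - (max(d$cM) - min(d$cM))), 0.1)
  }
})

test_that("non-monotone maps are rejected with offending markers listed", {
  map <- data.frame(chrom = "c1", bp = c(0, 1e6, 2e6, 3e6, 4e6),
                    cM = c(0, 2, 1, 3, 4))
  expect_error(smooth_marey(map), "non-monotone")
})

test_that("simulated Marey maps are monotone with planted enrichment", {
  lay <- fx_hic_layout()
  map <- simulate_marey_map(lay, multiplier = 12, n_markers = 200, seed = 3)
  for (ch in unique(map$chrom)) {
    d <- map[map$chrom == ch, ]
    expect_true(all(diff(d$cM[order(d$bp)]) >= 0))
  }
  # multiplier 1: region medians statistically indistinguishable
  map1 <- simulate_marey_map(lay, multiplier = 1, n_markers = 300, seed = 4,
                             noise_sd = 0.05)
  cmp1 <- region_rate_comparison(smooth_marey(map1), lay)
  expect_lt(max(cmp1$medians) / min(cmp1$medians), 1.15)
})

test_that("pipeline closure: planted 12x subtelomeric enrichment recovered", {
  lay <- genome_layout(paste0("chr", 1:3), c(120e6, 100e6, 80e6),
                       c(50e6, 40e6, 35e6))
  map <- simulate_marey_map(lay, multiplier = 12, n_markers = 300, seed = 3)
  cmp <- region_rate_comparison(smooth_marey(map), lay)
  ratio <- cmp$medians["subtelomere"] / cmp$medians["arm"]
  expect_lt(abs(ratio - 12) / 12, 0.15)
  expect_lt(cmp$tests$p_adj[cmp$tests$class1 == "arm" &
                              cmp$tests$class2 == "subtelomere"], 1e-6)
  expect_equal(cmp$tests$p_adj,
               stats::p.adjust(cmp$tests$p, method = "hochberg"))
})

test_that("KS test of identical rate distributions is non-significant", {
  set.seed(6)
  r <- stats::rlnorm(400)
  kt <- suppressWarnings(stats::ks.test(r[1:200], r[201:400]))
  expect_gt(kt$p.value, 0.05)
})

test_that("recombination concentration: uniform and one-hot landscapes", {
  tr_u <- structure(data.frame(chrom = "c1", pos = 1:100 * 5e5,
                               rate = rep(1, 100)),
                    class = c("rate_track", "data.frame"))
  conc <- recombination_concentration(tr_u)
  expect_equal(unname(conc["q50"]), 0.5)
  tr_h <- tr_u
  tr_h$rate <- c(100, rep(0, 99))
  expect_equal(unname(recombination_concentration(tr_h)["q50"]), 0.01)
  # brute-force cumulative check on an enriched simulation
  lay <- genome_layout("c1", 120e6, 50e6)
  tr <- smooth_marey(simulate_marey_map(lay, multiplier = 12,
                                        n_markers = 200, seed = 8))
  got <- recombination_concentration(tr)
  r <- sort(tr$rate, decreasing = TRUE)
  brute <- which(cumsum(r) / sum(r) >= 0.5)[1] / length(r)
  expect_equal(unname(got["q50"]), brute)
  expect_lt(got["q50"], 0.5)
})

test_that("feature correlations hit the trivial anchors", {
  lay <- genome_layout("c1", 120e6, 50e6)
  tr <- smooth_marey(simulate_marey_map(lay, multiplier = 12,
                                        n_markers = 200, seed = 8))
  fc <- feature_correlation(tr, data.frame(self = tr$rate,
                                           anti = -tr$rate))
  expect_equal(fc$r[fc$feature == "self"], 1)
  expect_equal(fc$r[fc$feature == "anti"], -1)
  # noisy linear feature: r close to the attenuation-predicted value
  set.seed(9)
  sigma <- stats::sd(tr$rate)
  feat <- tr$rate + stats::rnorm(nrow(tr), 0, sigma)
  fc2 <- feature_correlation(tr, data.frame(noisy = feat))
  expect_lt(abs(fc2$r - 1 / sqrt(2)), 0.1)
})

test_that("variant filtering recovers planted pass labels exactly", {
  for (seed in 1:3) {
    v <- simulate_variant_sites(1500, seed = seed)
    f <- filter_variant_sites(v)
    expect_setequal(f$table$pos, v$pos[v$true_pass])
    expect_equal(unname(f$counts["multiallelic"]),
                 sum(v$n_alleles > 2))
  }
  # het site with out-of-window balance is removed
  v <- simulate_variant_sites(50, frac_depth_outlier = 0,
                              frac_bad_balance = 0, frac_multiallelic = 0,
                              seed = 4)
  v$dp <- 30L  # constant depth so only the balance filter can act
  v$gt_s1[1] <- "0/1"; v$ab_s1[1] <- 0.25
  f <- filter_variant_sites(v)
  expect_false(v$pos[1] %in% f$table$pos)
  expect_equal(unname(f$counts["balance"]), 1)
})

test_that("parental informativeness filter keeps fixed-different sites", {
  v <- simulate_variant_sites(200, samples = c("p1", "p2"),
                              frac_depth_outlier = 0, frac_multiallelic = 0,
                              frac_bad_balance = 0, seed = 5)
  v$dp <- 30L
  v$dp_p1 <- 30; v$dp_p2 <- 30
  v$dp_p1[1:10] <- 5  # low parental depth
  f <- filter_variant_sites(v, parents = c("p1", "p2"))
  keep <- v$gt_p1 %in% c("0/0", "1/1") & v$gt_p2 %in% c("0/0", "1/1") &
    v$gt_p1 != v$gt_p2 & v$dp_p1 >= 10
  expect_setequal(f$table$pos, v$pos[keep])
})

test_that("heterozygosity windows: counts, blocks and the map fraction", {
  lay <- genome_layout("c1", 10e6, 4e6)
  # window count per chromosome
  empty <- data.frame(chrom = "c1", pos = 1, gt_s1 = "0/0")
  hw0 <- heterozygosity_windows(empty, lay)
  expect_equal(nrow(hw0$windows), floor((10e6 - 5e5) / 5e4) + 1)
  expect_equal(nrow(hw0$blocks), 0)

  # planted blocks covering 125.12 cM of a 1070.16 cM map give 11.7%
  lay10 <- genome_layout(paste0("chr", 1:10), rep(100e6, 10), rep(40e6, 10))
  rate <- 107.016 / 100
  block_bp <- 12.512 / rate * 1e6
  sites <- do.call(rbind, lapply(lay10$chrom, function(ch)
    data.frame(chrom = ch, pos = seq(20e6, 20e6 + block_bp, by = 5e3),
               gt_s1 = "0/1", stringsAsFactors = FALSE)))
  map <- do.call(rbind, lapply(lay10$chrom, function(ch)
    data.frame(chrom = ch, bp = seq(0, 100e6, length.out = 50),
               cM = seq(0, 107.016, length.out = 50))))
  hw <- heterozygosity_windows(sites, lay10, map)
  expect_equal(hw$map_fraction, 125.12 / 1070.16, tolerance = 0.03)
  expect_equal(round(hw$map_fraction, 2), 0.12)
})

test_that("inbreeding expectation formula and limits", {
  expect_equal(inbreeding_expected_fraction(17), 1.17 * 0.809^17)
  expect_equal(round(inbreeding_expected_fraction(17), 3), 0.032)
  expect_equal(round(inbreeding_expected_fraction(13), 3), 0.074)
  expect_lt(inbreeding_expected_fraction(100), 1e-8)
  expect_warning(inbreeding_expected_fraction(3), "t < 5")
})
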