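random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("rotations of one monomer cluster together; unrelated ones apart", {
  m <- random_seq(205, 1)
  rot <- vapply(c(0, 50, 120, 199), function(k)
    frogsynt:::.rotate_seq(m, k), character(1))
  names(rot) <- paste0("r", seq_along(rot))
  db <- build_monomer_db(rot)
  expect_equal(length(unique(db$cluster)), 1)

  other <- random_seq(205, 2)
  db2 <- build_monomer_db(c(a = m, b = other))
  expect_equal(length(unique(db2$cluster)), 2)

  single <- build_monomer_db(c(solo = m))
  expect_equal(single$representative, "solo")
  expect_equal(single$rep_seq, m)
  expect_equal(nrow(build_monomer_db(character(0))), 0)
  expect_error(build_monomer_db(c(x = "ACGTACG")), "> 10 bp")
})

test_that("clustering is invariant to monomer rotation phase", {
  base <- c(f1 = random_seq(150, 3), f2 = random_seq(150, 4))
  for (seed in 1:8) {
    set.seed(seed)
    mono <- vapply(rep(names(base), each = 3), function(f)
      frogsynt:::.mutate_seq(
        frogsynt:::.rotate_seq(base[[f]], sample.int(150, 1) - 1L), 0.03),
      character(1))
    names(mono) <- sprintf("m%02d", seq_along(mono))
    db <- build_monomer_db(mono)
    truth <- rep(names(base), each = 3)
    tab <- table(truth, db$cluster[match(names(mono), db$monomer)])
    expect_equal(length(unique(db$cluster)), 2)
    expect_true(all(apply(tab > 0, 2, sum) == 1))
  }
})

test_that("divergent copies mutate at the requested rate (JC check)", {
  m <- random_seq(205, 5)
  expect_equal(simulate_copy_divergence(m, 0, 10, seed = 1),
               rep(0, 10))
  p <- 0.05
  mism <- simulate_copy_divergence(m, p, 400, seed = 2)
  jc <- jc_distance(mean(mism))
  expect_lt(abs(jc - (-0.75 * log(1 - 4 * p / 3))), 0.01)
})

test_that("JC distance: values, monotonicity, convexity and domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.05), 0.0517, tolerance = 1e-3)
  expect_equal(jc_distance(0.001), 0.001, tolerance = 1e-3)
  p <- seq(0.01, 0.74, by = 0.01)
  d <- jc_distance(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
  expect_error(jc_distance(0.75), "undefined")
  expect_error(jc_distance(-0.1), "undefined")
})

test_that("regional enrichment ranks a planted subtelomeric satellite first", {
  lay <- genome_layout(paste0("chr", 1:3), c(120e6, 100e6, 80e6),
                       c(50e6, 40e6, 35e6))
  sim <- simulate_tandem_annotations(
    lay, divergence = 0.03, n_arrays = 80, seed = 6,
    enrichment = list(fam01 = c(subtelomere = 60, arm = 1,
                                pericentromere = 1)))
  arrays <- sim$arrays
  arrays$cluster <- arrays$family
  reg <- layout_regions(lay)
  roi <- reg[reg$class == "subtelomere", ]
  fp <- cluster_footprints(arrays, roi)
  roi_len <- sum(roi$end - roi$start)
  enr <- region_enrichment(fp, roi_len, sum(lay$length) - roi_len)
  expect_equal(enr$cluster[1], "fam01")

  # scale invariance (up to the 1-bp pseudocount, so only clusters with a
  # nonzero rest-of-genome footprint are compared)
  fp2 <- fp
  fp2$roi_bp <- fp2$roi_bp * 2
  fp2$rest_bp <- fp2$rest_bp * 2
  enr2 <- region_enrichment(fp2, roi_len * 2, 2 * (sum(lay$length) - roi_len))
  nz <- enr$cluster[enr$rest_bp > 0]
  expect_equal(enr2$enrichment[match(nz, enr2$cluster)],
               enr$enrichment[match(nz, enr$cluster)], tolerance = 1e-3)

  # a cluster confined to the ROI is top-ranked by construction
  fp3 <- data.frame(cluster = c("only_roi", "uniform"),
                    roi_bp = c(5e4, 1e4), rest_bp = c(0, 1e4 * 9))
  enr3 <- region_enrichment(fp3, 1e7, 9e7)
  expect_equal(enr3$cluster[1], "only_roi")
})

test_that("tetramer enrichment: planted array, absent motif, strandedness", {
  set.seed(7)
  tandem <- paste(rep("TGGG", 50), collapse = "")
  background <- random_seq(5000, 8)
  te <- tetramer_enrichment(tandem, background)
  expect_gt(te$enrichment[te$motif == "TGGG"], 10)

  te2 <- tetramer_enrichment("AAAAAAAAAA", "TTTTTTTTTT",
                             motifs = "ACAG")
  expect_true(te2$absent)
  expect_true(is.na(te2$enrichment))

  # one forward + one reverse-complement occurrence: both strands double
  toy <- "ACAGTTTTTTTTCTGT"
  both <- tetramer_enrichment(toy, background, motifs = "ACAG")
  single <- tetramer_enrichment(toy, background, motifs = "ACAG",
                                both_strands = FALSE)
  expect_equal(both$tandem_per_kb, 2 * single$tandem_per_kb)
})

test_that("binned densities match brute-force overlap sums", {
  set.seed(9)
  iv <- data.frame(start = sort(sample.int(9e6, 10)))
  iv$end <- iv$start + sample.int(8e5, 10)
  bd <- binned_density(iv, chrom_length = 10e6, window = 1e6, step = 2e5)
  merged <- IRanges::reduce(IRanges::IRanges(iv$start + 1, iv$end))
  ms <- IRanges::start(merged) - 1; me <- IRanges::end(merged)
  brute <- vapply(seq_len(nrow(bd)), function(i)
    sum(pmax(0, pmin(me, bd$end[i]) - pmax(ms, bd$start[i]))), numeric(1))
  expect_equal(bd$value, brute)

  # full and half coverage anchors
  full <- binned_density(data.frame(start = 0, end = 10e6),
                         chrom_length = 10e6, window = 1e6, step = 1e6)
  expect_true(all(full$value == 1e6))
  half <- binned_density(data.frame(start = 0, end = 5e5),
                         chrom_length = 1e6, window = 1e6, step = 1e6)
  expect_equal(half$value, 5e5)

  # GC fraction of a sequence window
  gc <- binned_density(strrep("GCAT", 2500), window = 1e3, step = 1e3)
  expect_true(all(abs(gc$value - 0.5) < 1e-12))
})

test_that("density PCA recovers planted axes and correlates tracks", {
  set.seed(10)
  n <- 200
  f1 <- sin(seq(0, 6 * pi, length.out = n))
  f2 <- rep(c(1, -1), length.out = n)
  X <- cbind(outer(f1, c(3, 3, 3)) + matrix(stats::rnorm(3 * n, 0, 0.1), n),
             outer(f2, c(2, 2)) + matrix(stats::rnorm(2 * n, 0, 0.1), n))
  pc <- density_pca(X, compartment_track = f2)
  expect_gt(abs(stats::cor(pc$scores[, 1], f1)), 0.95)
  expect_gt(abs(stats::cor(pc$scores[, 2], f2)), 0.95)
  expect_gt(abs(pc$correlations[2]), 0.9)
  # correlation of a track with itself is 1
  pc2 <- density_pca(X, compartment_track = pc$scores[, 1])
  expect_equal(abs(unname(pc2$correlations[1])), 1, tolerance = 1e-6)
})

test_that("simulated tandem arrays respect copy-number and length bounds", {
  lay <- fx_hic_layout()
  sim <- simulate_tandem_annotations(lay, divergence = 0.05, n_arrays = 30,
                                     seed = 11)
  expect_true(all(sim$arrays$copies >= 5))
  expect_true(all(nchar(sim$monomers) > 10))
  expect_true(all(sim$arrays$end - sim$arrays$start ==
                    sim$arrays$copies * nchar(sim$monomers[sim$arrays$family])))
  expect_error(simulate_tandem_annotations(lay, copies_range = c(2, 5)),
               ">= 5")
})
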