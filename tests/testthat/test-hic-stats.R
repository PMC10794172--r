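test_that("planted centromeres are recovered within two bins", {
  for (seed in c(13, 14, 15)) {
    cm <- fx_hic(seed)
    calls <- infer_centromeres(cm)
    truth <- cm$truth$centromere_bins[calls$chrom]
    expect_true(all(abs(calls$bin - truth) <= 2))
  }
})

test_that("no Rabl wing gives low-confidence centromere calls", {
  cm <- fx_memo("hic_nowing", function() {
    balance_matrix(simulate_hic_matrix(
      fx_hic_layout(), hic_sim_params(w_r = 0, depth = 3e6),
      bin_size = 1e6, seed = 3), "KR")
  })
  calls <- infer_centromeres(cm)
  expect_true(all(!calls$confident))
  expect_true(all(grepl("low_confidence", calls$flag)))
})

test_that("near-edge acrocentric centromeres are called at the edge, flagged", {
  lay <- genome_layout(c("chrA", "chrB"), c(60e6, 50e6), c(1.5e6, 20e6))
  cm <- balance_matrix(simulate_hic_matrix(lay, hic_sim_params(depth = 2e6),
                                           bin_size = 1e6, seed = 4), "KR")
  calls <- infer_centromeres(cm)
  a <- calls[calls$chrom == "chrA", ]
  expect_lte(a$bin, 4)  # at the chromosome edge
  expect_match(a$flag, "acrocentric")
})

test_that("too-short chromosomes are flagged without a call", {
  lay <- genome_layout(c("chrA", "chrB"), c(60e6, 12e6), c(25e6, 5e6))
  cm <- balance_matrix(simulate_hic_matrix(lay, hic_sim_params(depth = 2e6),
                                           bin_size = 1e6, seed = 4), "KR")
  calls <- infer_centromeres(cm)
  b <- calls[calls$chrom == "chrB", ]
  expect_true(is.na(b$bin))
  expect_equal(b$flag, "too_short")
})

test_that("compartment calls recover planted labels across 20 simulations", {
  acc <- vapply(1:20, function(s) {
    cm <- balance_matrix(simulate_hic_matrix(
      fx_hic_layout(), hic_sim_params(depth = 4e6),
      bin_size = 1e6, seed = s), "KR")
    comp <- call_compartments(cm, cm$truth$gene_density)
    mean(comp$label == cm$truth$compartments, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(acc >= 0.95))
})

test_that("A bins are gene-richer than B bins on any oriented output", {
  cm <- fx_hic()
  comp <- call_compartments(cm, cm$truth$gene_density)
  gd <- cm$truth$gene_density
  expect_gt(mean(gd[which(comp$label == "A")]),
            mean(gd[which(comp$label == "B")]))
  # deterministic: repeated calls give identical labels
  comp2 <- call_compartments(cm, cm$truth$gene_density)
  expect_identical(comp$label, comp2$label)
})

test_that("compartment segment statistics: hand-checked means", {
  bins <- data.frame(chrom = "c1", start = seq(0, 5e6, 1e6),
                     end = seq(1e6, 6e6, 1e6), bin = 1:6)
  # single 4-Mb segment: both means equal the segment length
  tr <- data.frame(chrom = "c1", bin = 1:6,
                   label = c("A", "A", "A", "A", "B", "B"))
  st <- compartment_stats(tr, bins)
  a <- st$means[st$means$label == "A", ]
  expect_equal(a$arithmetic, 4e6)
  expect_equal(a$geometric, 4e6)
  # segment lengths {1, 4} Mb: arithmetic 2.5, geometric 2.0
  tr2 <- data.frame(chrom = "c1", bin = 1:6,
                    label = c("A", "B", "A", "A", "A", "A"))
  st2 <- compartment_stats(tr2, bins)
  a2 <- st2$means[st2$means$label == "A", ]
  expect_equal(a2$arithmetic, 2.5e6)
  expect_equal(a2$geometric, 2e6)
  # exponential-ish segment lengths: geometric < arithmetic
  cm <- fx_hic()
  comp <- call_compartments(cm, cm$truth$gene_density)
  st3 <- compartment_stats(comp, cm$bins)
  expect_true(all(st3$means$geometric < st3$means$arithmetic))
})

test_that("SSD vanishes for mirror-symmetric arm profiles", {
  # intra contacts depend only on separation (O/E = 1) and inter contacts
  # only on the relative arm coordinate u, so the i-th p and q bins have
  # exactly identical contact profiles
  lay <- genome_layout(c("c1", "c2"), c(21e6, 21e6), c(10.5e6, 10.5e6))
  bins <- make_bins(lay, 1e6)
  n <- nrow(bins)
  g <- exp(-bins$d_cen / 5e6) + 0.2
  counts <- matrix(0, n, n)
  intra <- outer(bins$chrom, bins$chrom, "==")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  counts[intra] <- (50 / (1 + d))[intra]
  counts[!intra] <- (10 * outer(g, g))[!intra]
  cm <- contact_matrix(bins[, c("chrom", "start", "end", "bin")],
                       counts, 1e6)
  cm$balanced <- cm$counts
  calls <- data.frame(chrom = c("c1", "c2"), bin = c(11, 32))
  ssd <- rabl_ssd(cm, calls)
  expect_lt(ssd$genome, 1e-12)
})

test_that("SSD decreases with planted Rabl strength", {
  grid <- vapply(c(0, 1.5, 3), function(wr) {
    cm <- balance_matrix(simulate_hic_matrix(
      fx_hic_layout(), hic_sim_params(w_r = wr, depth = 4e6),
      bin_size = 1e6, seed = 14), "KR")
    rabl_ssd(cm, fx_truth_calls(cm))$genome
  }, numeric(1))
  expect_true(all(diff(grid) < 0))
})

test_that("chromosomes lacking two sufficient arms are excluded from SSD", {
  cm <- fx_hic()
  ssd <- rabl_ssd(cm, fx_truth_calls(cm))
  per <- ssd$per_chrom
  expect_true(all(per$included[per$chrom != "chr3"]))
  expect_equal(ssd$genome, mean(per$ssd[per$included]))
})

test_that("CTP is exactly 1 on uniform inter-chromosomal contacts", {
  lay <- genome_layout(c("c1", "c2"), c(20e6, 20e6), c(10e6, 10e6))
  bins <- make_bins(lay, 1e6)
  counts <- matrix(10, nrow(bins), nrow(bins))
  cm <- contact_matrix(bins[, c("chrom", "start", "end", "bin")],
                       counts, 1e6)
  cm$balanced <- cm$counts
  calls <- data.frame(chrom = c("c1", "c2"), bin = c(10, 30))
  expect_equal(rabl_ctp(cm, calls)$genome, 1)
})

test_that("CTP exceeds 1.5 under strong polar organization", {
  cm <- balance_matrix(simulate_hic_matrix(
    fx_hic_layout(), hic_sim_params(w_pol = 4, depth = 4e6),
    bin_size = 1e6, seed = 12), "KR")
  expect_gt(rabl_ctp(cm, fx_truth_calls(cm))$genome, 1.5)
})

test_that("CTP increases with planted polar strength", {
  grid <- vapply(c(0, 1.5, 3), function(wp) {
    cm <- balance_matrix(simulate_hic_matrix(
      fx_hic_layout(), hic_sim_params(w_pol = wp, depth = 4e6),
      bin_size = 1e6, seed = 12), "KR")
    rabl_ctp(cm, fx_truth_calls(cm))$genome
  }, numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("statistics are invariant to chromosome relabeling order", {
  cm <- fx_hic()
  calls <- fx_truth_calls(cm)
  ctp <- rabl_ctp(cm, calls)$genome
  # permute chromosome blocks (chr order reversed)
  ord <- order(match(cm$bins$chrom, rev(unique(cm$bins$chrom))),
               cm$bins$start)
  cm2 <- cm
  cm2$counts <- cm$counts[ord, ord]
  cm2$balanced <- cm$balanced[ord, ord]
  cm2$weights <- cm$weights[ord]
  cm2$bins <- cm$bins[ord, ]
  cm2$bins$bin <- seq_len(nrow(cm2$bins))
  calls2 <- calls
  calls2$bin <- vapply(seq_len(nrow(calls)), function(i) {
    which(cm2$bins$chrom == calls$chrom[i])[
      match(calls$bin[i], which(cm$bins$chrom == calls$chrom[i]))]
  }, integer(1))
  expect_equal(rabl_ctp(cm2, calls2)$genome, ctp, tolerance = 1e-12)
  te1 <- territory_enrichment(cm)
  te2 <- territory_enrichment(cm2)
  expect_equal(te2$chisq, te1$chisq, tolerance = 1e-9)
})

test_that("permutation test: bounds, determinism and calibration", {
  cm <- fx_hic()
  calls <- fx_truth_calls(cm)
  stat <- function(m) rabl_ctp(m, calls)$genome
  p1 <- permutation_test(stat, cm, n = 49, seed = 5)
  p2 <- permutation_test(stat, cm, n = 49, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 50)
  # observed drawn from its own null: p roughly uniform over repeats
  set.seed(31)
  ps <- vapply(1:30, function(i) {
    perm <- seq_len(nrow(cm$bins))
    for (ch in unique(cm$bins$chrom)) {
      idx <- which(cm$bins$chrom == ch)
      s <- sample.int(length(idx), 1) - 1L
      perm[idx] <- idx[((seq_along(idx) + s - 1L) %% length(idx)) + 1L]
    }
    null_cm <- cm
    null_cm$counts <- cm$counts[perm, perm]
    null_cm$balanced <- cm$balanced[perm, perm]
    permutation_test(stat, null_cm, n = 49, seed = 100 + i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(min(ps), 0.3)
  expect_gt(max(ps), 0.7)
})

test_that("interarm enrichment: uniform, polar and hand-computed cases", {
  # uniform contacts: ratio 1, chi-square 0
  lay <- genome_layout(c("c1", "c2"), c(20e6, 20e6), c(10e6, 10e6))
  bins <- make_bins(lay, 1e6)
  cm <- contact_matrix(bins[, c("chrom", "start", "end", "bin")],
                       matrix(10, nrow(bins), nrow(bins)), 1e6)
  calls <- data.frame(chrom = c("c1", "c2"), bin = c(10, 30))
  ia <- interarm_enrichment(cm, calls)
  expect_equal(unname(ia$ratio), 1)
  expect_equal(ia$chisq, 0)

  # polar simulation enriches concordant (pp+qq) arm contacts
  cmp <- balance_matrix(simulate_hic_matrix(
    fx_hic_layout(), hic_sim_params(w_pol = 3, depth = 4e6),
    bin_size = 1e6, seed = 12), "KR")
  iap <- interarm_enrichment(cmp, fx_truth_calls(cmp))
  expect_gt(iap$ratio, 1)
  expect_lt(iap$p, 0.01)

  # hand-computed 2x2: 2 bins per arm, known counts
  lay2 <- genome_layout(c("x", "y"), c(5e6, 5e6), c(2.5e6, 2.5e6))
  bins2 <- make_bins(lay2, 1e6)
  cnt <- matrix(0, 10, 10)
  # arms: x p = bins 1:2, q = 4:5 (bin 3 holds the centromere); same for y
  cnt[1:2, 6:7] <- 3; cnt[4:5, 9:10] <- 3   # concordant 24
  cnt[1:2, 9:10] <- 1; cnt[4:5, 6:7] <- 1   # discordant 8
  cnt <- cnt + t(cnt)
  cm2 <- contact_matrix(bins2[, c("chrom", "start", "end", "bin")], cnt, 1e6)
  calls2 <- data.frame(chrom = c("x", "y"), bin = c(3, 8))
  ia2 <- interarm_enrichment(cm2, calls2)
  # totals 32; equal arm bin counts make both expectations 16
  expect_equal(unname(ia2$observed), c(24, 8))
  expect_equal(unname(ia2$expected), c(16, 16))
  expect_equal(ia2$ratio, 24 / 16, ignore_attr = TRUE)
  expect_equal(ia2$chisq, (24 - 16)^2 / 16 + (8 - 16)^2 / 16)
  expect_equal(ia2$df, 1)
})

test_that("territory enrichment: df, uniform case and planted factor", {
  # 10 chromosomes: chi-square df is 81
  lens <- round(seq(120e6, 40e6, length.out = 10))
  cens <- round(lens * 0.4)
  lay10 <- genome_layout(paste0("chr", 1:10), lens, cens)
  cm10 <- simulate_hic_matrix(lay10, hic_sim_params(depth = 2e6),
                              bin_size = 2e6, seed = 21)
  te <- territory_enrichment(cm10)
  expect_equal(te$df, 81)

  # independence: enrichment approximately 1 everywhere
  lay <- fx_hic_layout()
  cm <- simulate_hic_matrix(lay, hic_sim_params(
    w_r = 0, w_ab = 0, w_cen = 0, w_tel = 0, w_pol = 0, depth = 4e6),
    bin_size = 1e6, seed = 22)
  teu <- territory_enrichment(cm)
  expect_true(all(abs(teu$enrichment - 1) < 0.05, na.rm = TRUE))

  # planted territory factor: that pair ranks highest
  Tm <- matrix(1, 5, 5); Tm[1, 2] <- Tm[2, 1] <- 1.3
  cmt <- simulate_hic_matrix(lay, hic_sim_params(
    w_r = 0, w_ab = 0, w_cen = 0, w_tel = 0, w_pol = 0,
    territory = Tm, depth = 4e6), bin_size = 1e6, seed = 23)
  tet <- territory_enrichment(cmt)
  top <- tet$pairs[which.max(tet$pairs$enrichment), ]
  expect_setequal(c(top$chrom1, top$chrom2), c("chr1", "chr2"))
  expect_equal(tet$pairs$p_adj,
               stats::p.adjust(tet$pairs$p, method = "hochberg"))
})

test_that("centromere concordance against planted truth", {
  cm <- fx_hic()
  calls <- infer_centromeres(cm)
  truth <- data.frame(chrom = names(cm$truth$centromere_bins),
                      start = cm$bins$start[cm$truth$centromere_bins],
                      end = cm$bins$end[cm$truth$centromere_bins])
  conc <- centromere_concordance(calls, truth, tolerance_bp = 2e6)
  expect_gte(sum(conc$concordant), nrow(conc) - 1)
  # identical calls: all concordant; shifted beyond tolerance: none
  expect_true(all(centromere_concordance(truth, truth, 1)$concordant))
  shifted <- truth; shifted$start <- shifted$start + 5e6
  shifted$end <- shifted$end + 5e6
  expect_false(any(centromere_concordance(truth, shifted, 2e6)$concordant))
})
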