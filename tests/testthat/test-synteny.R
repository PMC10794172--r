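# small helper: ortholog table from per-species chromosome/position vectors
ortho_table <- function(genes, ...) {
  cols <- list(...)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  out
}

test_that("collinear runs: intact, inverted and shuffled chromosomes", {
  n <- 100
  tb <- ortho_table(sprintf("g%03d", 1:n),
                    s1.chrom = rep("c1", n), s1.pos = 1:n * 1e5,
                    s2.chrom = rep("k1", n), s2.pos = 1:n * 2e5)
  runs <- collinear_runs(tb, "s1", "s2")
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_genes, n)

  # one planted inversion splits the chromosome into two oriented runs
  inv <- c(1:50, 100:51)
  tb2 <- tb
  tb2$s2.pos <- order(inv) * 2e5
  runs2 <- collinear_runs(tb2, "s1", "s2", max_gap = 0)
  expect_equal(nrow(runs2), 2)
  expect_setequal(runs2$orientation, c(1, -1))

  # shuffled gene order leaves no long run
  set.seed(5)
  tb3 <- tb
  tb3$s2.pos <- sample(n) * 2e5
  runs3 <- collinear_runs(tb3, "s1", "s2", min_run = 5, max_gap = 0)
  expect_equal(nrow(runs3), 0)

  expect_error(collinear_runs(tb, "s1", "nope"), "absent")
})

test_that("stray ortholog filtering removes low-support signatures", {
  tb <- ortho_table(c(sprintf("g%02d", 1:8), "stray"),
                    s1.chrom = c(rep("c1", 8), "c1"),
                    s1.pos = 1:9,
                    s2.chrom = c(rep("k1", 8), "k9"),
                    s2.pos = 1:9)
  f <- filter_stray_orthologs(tb, m = 3)
  expect_equal(attr(f, "removed"), "stray")
  expect_equal(nrow(f), 8)
  # identity when nothing is below threshold
  f2 <- filter_stray_orthologs(tb[1:8, ], m = 3)
  expect_equal(nrow(f2), 8)
  # a planted 2-gene noise class is removed at m = 3
  tb3 <- tb
  tb3$s2.chrom[8:9] <- "k9"
  f3 <- filter_stray_orthologs(tb3, m = 3)
  expect_setequal(attr(f3, "removed"), c("g08", "stray"))
})

test_that("root-state parsimony on a 4-leaf toy merges and splits correctly", {
  tree <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1,s4:1):1);")
  # two ancestral chromosomes, fused only in s4: root state apart
  genes <- sprintf("g%02d", 1:20)
  grp <- rep(c("X", "Y"), each = 10)
  tb <- ortho_table(genes,
                    s1.chrom = ifelse(grp == "X", "a1", "a2"),
                    s1.pos = 1:20 * 1e5,
                    s2.chrom = ifelse(grp == "X", "b1", "b2"),
                    s2.pos = 1:20 * 1e5,
                    s3.chrom = ifelse(grp == "X", "c1", "c2"),
                    s3.pos = 1:20 * 1e5,
                    s4.chrom = rep("d1", 20),
                    s4.pos = 1:20 * 1e5)
  a <- infer_elements(tb, tree, ref_species = "s1")
  expect_equal(a$n_elements, 2)

  # fused everywhere except s1: root state together, one element
  tb2 <- tb
  tb2$s2.chrom <- "b1"
  tb2$s3.chrom <- "c1"
  a2 <- infer_elements(tb2, tree, ref_species = "s1")
  expect_equal(a2$n_elements, 1)
})

test_that("single species: each chromosome is its own element", {
  tb <- ortho_table(sprintf("g%02d", 1:9),
                    s1.chrom = rep(c("c1", "c2", "c3"), each = 3),
                    s1.pos = 1:9)
  a <- infer_elements(tb)
  expect_equal(a$n_elements, 3)
})

test_that("element recovery at the inferred rearrangement scale", {
  # planted 13-element count recovered in >= 95% of 100 replicates
  tree <- default_species_tree()
  res <- vapply(1:100, function(s) {
    h <- simulate_karyotype_history(tree, default_event_rates(),
                                    n_genes = 400, seed = 5000 + s)
    tb <- filter_stray_orthologs(h$orthologs)
    a <- infer_elements(tb, tree, ref_species = "sp1")
    c(a$n_elements, fx_element_agreement(a, tb))
  }, numeric(2))
  expect_gte(mean(res[1, ] == 13), 0.95)
  expect_gte(mean(res[2, ]), 0.99)
})

test_that("inference is deterministic given table and tree", {
  h <- fx_history()
  tb <- filter_stray_orthologs(h$orthologs)
  a1 <- infer_elements(tb, h$tree, ref_species = "sp1")
  a2 <- infer_elements(tb, h$tree, ref_species = "sp1")
  expect_identical(a1$elements, a2$elements)
})

test_that("conservation fraction: bounds, identity and relabeling invariance", {
  h <- fx_memo("hist_norearr", function()
    simulate_karyotype_history(default_species_tree(),
                               c(robertsonian_fusion = 0),
                               n_genes = 200, seed = 9))
  tb <- h$orthologs
  a <- infer_elements(tb, h$tree, ref_species = "sp1")
  expect_equal(conservation_fraction(a, tb), 1.0)

  h2 <- fx_history()
  tb2 <- filter_stray_orthologs(h2$orthologs)
  a2 <- infer_elements(tb2, h2$tree, ref_species = "sp1")
  f <- conservation_fraction(a2, tb2)
  expect_gte(f, 0)
  expect_lte(f, 1)
  # relabeling chromosomes of one species does not change the fraction
  tb3 <- tb2
  tb3$sp3.chrom <- paste0("renamed_", tb3$sp3.chrom)
  expect_equal(conservation_fraction(a2, tb3), f)
})

test_that("element proportions: scaling invariance and CV flags expansion", {
  h <- fx_memo("hist_norearr", function()
    simulate_karyotype_history(default_species_tree(),
                               c(robertsonian_fusion = 0),
                               n_genes = 200, seed = 9))
  tb <- h$orthologs
  a <- infer_elements(tb, h$tree, ref_species = "sp1")
  anc <- ancestral_frog_layout()
  cs1 <- data.frame(chrom = anc$chrom, bp = anc$length)
  cs2 <- data.frame(chrom = anc$chrom, bp = 2 * anc$length)
  pr <- element_proportions(a, tb, list(sp1 = cs1, sp2 = cs2))
  p1 <- pr[pr$species == "sp1", ]
  p2 <- pr[pr$species == "sp2", ]
  expect_equal(p1$frac_bp, p2$frac_bp)
  expect_lte(sum(p1$frac_bp), 1 + 1e-12)
  expect_lte(sum(p1$frac_genes), 1 + 1e-12)

  # planted expansion of one element in one species shows up in the bp CV
  cs3 <- cs1
  cs3$bp[cs3$chrom == "A"] <- cs3$bp[cs3$chrom == "A"] * 3
  pr2 <- element_proportions(a, tb, list(sp1 = cs1, sp2 = cs3))
  cv <- attr(pr2, "cv")
  expect_equal(cv$element[which.max(cv$cv_bp)], "A")
})
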