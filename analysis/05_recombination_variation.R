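#!/usr/bin/env Rscript
# Recombination landscape and genetic-variation analyses: Marey-map spline
# smoothing, concentration of recombination, regional rate comparisons,
# feature correlation, variant-site filtering, residual heterozygosity and
# the full-sib inbreeding expectation.

suppressMessages(library(frogsynt))
outdir <- "results/05_recombination"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

lens <- round(seq(190e6, 50e6, length.out = 10))
cens <- round(lens * 0.4)
cens[c(3, 8, 10)] <- 8e6
layout <- genome_layout(paste0("chr", 1:10), lens, cens)

# Marey maps with a planted 12x subtelomeric enrichment
map <- simulate_marey_map(layout, multiplier = 12, n_markers = 250,
                          seed = 505)
write_genetic_map(map, file.path(outdir, "genetic_map.tsv"))
track <- smooth_marey(map)
cat(sprintf("smoothed %d chromosomes on a 500-kb lattice (%d clamps)\n",
            length(unique(track$chrom)), attr(track, "n_clamped")))

conc <- recombination_concentration(track)
cat(sprintf("half of all recombination sits in %.1f%% of the genome; 90%% in %.1f%%\n",
            100 * conc["q50"], 100 * conc["q90"]))

cmp <- region_rate_comparison(track, layout)
cat(sprintf("median rates (cM/Mb): subtelomere %.2f, arm %.2f, pericentromere %.2f\n",
            cmp$medians["subtelomere"], cmp$medians["arm"],
            cmp$medians["pericentromere"]))
cat(sprintf("subtelomere vs arm KS: D = %.2f, Hochberg p = %.2g\n",
            cmp$tests$ks[cmp$tests$class1 == "arm" &
                           cmp$tests$class2 == "subtelomere"],
            cmp$tests$p_adj[cmp$tests$class1 == "arm" &
                              cmp$tests$class2 == "subtelomere"]))

# satellite density built to covary with recombination (plus noise)
set.seed(505)
sat <- track$rate + rnorm(nrow(track), 0, stats::sd(track$rate, na.rm = TRUE))
fc <- feature_correlation(track, data.frame(satellite = sat))
cat(sprintf("recombination vs satellite density: Pearson r = %.2f\n", fc$r))

# variant filtering on a planted table
v <- simulate_variant_sites(5000, seed = 505)
f <- filter_variant_sites(v)
cat(sprintf("variant filters: %d in, %d pass (%d multiallelic, %d depth, %d balance)\n",
            f$counts["input"], f$counts["pass"], f$counts["multiallelic"],
            f$counts["depth"], f$counts["balance"]))
stopifnot(setequal(f$table$pos, v$pos[v$true_pass]))

# residual heterozygosity: pedigree simulation vs the closed-form expectation
frac17 <- simulate_inbred_pedigree(17, rep(107.016, 10), n_rep = 500,
                                   seed = 505)
cat(sprintf("full-sib t=17: simulated %.2f%%, expected %.2f%%\n",
            100 * mean(frac17), 100 * inbreeding_expected_fraction(17)))
cat(sprintf("t=13 expectation: %.2f%%\n",
            100 * inbreeding_expected_fraction(13)))

write.table(track, file.path(outdir, "rate_track.bedgraph.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(f$table, file.path(outdir, "passing_variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(concentration = as.list(conc),
       medians = as.list(cmp$medians),
       satellite_r = fc$r,
       variant_counts = as.list(f$counts),
       het_fraction_t17_sim = mean(frac17),
       het_fraction_t17_expected = inbreeding_expected_fraction(17),
       het_fraction_t13_expected = inbreeding_expected_fraction(13)),
  file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
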