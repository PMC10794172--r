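# shared fixtures, built once per test run and memoized

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

# standard Hi-C test layout: 5 chromosomes, one acrocentric with a 5-bin
# short arm (centromeres below bin scale are an edge case, tested separately)
fx_hic_layout <- function() {
  genome_layout(paste0("chr", 1:5), c(60e6, 50e6, 45e6, 40e6, 35e6),
                c(25e6, 20e6, 5e6, 18e6, 15e6))
}

# default simulated + KR-balanced contact matrix
fx_hic <- function(seed = 13) {
  fx_memo(paste0("hic", seed), function() {
    cm <- simulate_hic_matrix(fx_hic_layout(), hic_sim_params(depth = 4e6),
                              bin_size = 1e6, seed = seed)
    balance_matrix(cm, "KR")
  })
}

fx_truth_calls <- function(cm) {
  data.frame(chrom = unique(cm$bins$chrom),
             bin = unname(cm$truth$centromere_bins),
             stringsAsFactors = FALSE)
}

# one default-condition karyotype history
fx_history <- function(seed = 42) {
  fx_memo(paste0("hist", seed), function() {
    simulate_karyotype_history(default_species_tree(), default_event_rates(),
                               n_genes = 400, seed = seed)
  })
}

# agreement between an inferred assignment and planted element labels:
# fraction of genes in the majority truth class of their inferred element
fx_element_agreement <- function(assignment, table) {
  m <- merge(assignment$elements, table[, c("gene", "element")], by = "gene")
  sum(apply(table(m$element.x, m$element.y), 1, max)) / nrow(m)
}
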