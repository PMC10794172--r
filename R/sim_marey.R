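#' Simulate a Marey map with subtelomere-concentrated recombination
#'
#' Draws a piecewise recombination-rate landscape on a 500-kb lattice with a
#' planted subtelomeric enrichment, integrates it into a monotone cM vs bp
#' (Marey) map, and samples marker positions along it. Rates are the base
#' rate on arm interiors, `multiplier` times the base in subtelomeres and
#' `peri_multiplier` times the base in the pericentromere, with small
#' lognormal interval noise.
#'
#' @param layout a [genome_layout()].
#' @param multiplier subtelomere/arm rate ratio (>= 1).
#' @param n_markers markers per chromosome.
#' @param base_rate arm-interior rate in cM/Mb.
#' @param peri_multiplier pericentromere rate multiplier (default 1).
#' @param noise_sd lognormal sd of per-interval rate noise.
#' @param interval_bp rate lattice spacing in bp.
#' @param subtel_bp,peri_bp region geometry, see [layout_regions()].
#' @param seed integer seed.
#' @return a `genetic_map`: data.frame `chrom`, `bp`, `cM` (markers, cM
#'   non-decreasing in bp per chromosome) with attribute `truth` (the
#'   planted per-interval rate table).
#' @export
simulate_marey_map <- function(layout, multiplier = 12, n_markers = 200,
                               base_rate = 0.4, peri_multiplier = 1,
                               noise_sd = 0.1, interval_bp = 5e5,
                               subtel_bp = 30e6, peri_bp = 5e6, seed = NULL) {
  if (multiplier < 1) stop("subtelomere multiplier must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  regions <- layout_regions(layout, subtel_bp = subtel_bp, peri_bp = peri_bp)
  maps <- list(); truths <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; L <- layout$length[i]
    starts <- seq(0, L - 1, by = interval_bp)
    ends <- pmin(starts + interval_bp, L)
    mid <- (starts + ends) / 2
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    cls <- reg$class[findInterval(mid, reg$start)]
    mult <- c(subtelomere = multiplier, arm = 1,
              pericentromere = peri_multiplier)[cls]
    rate <- base_rate * mult * stats::rlnorm(length(mid), -noise_sd^2 / 2,
                                             noise_sd)
    cm <- cumsum(rate * (ends - starts) / 1e6)
    bp <- sort(stats::runif(n_markers, 0, L))
    mk_cm <- stats::approx(c(0, ends), c(0, cm), xout = bp)$y
    maps[[ch]] <- data.frame(chrom = ch, bp = bp, cM = mk_cm,
                             stringsAsFactors = FALSE)
    truths[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                               class = cls, rate = rate,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truths)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Write / read a genetic map TSV
#'
#' @param map a genetic map data.frame (`chrom`, `bp`, `cM`).
#' @param path file path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("chrom", "bp", "cM")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  class(d) <- c("genetic_map", "data.frame")
  d
}
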