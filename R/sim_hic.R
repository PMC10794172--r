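#' Hi-C simulation parameters
#'
#' Parameters of the generative contact model. Intra-chromosomal expected
#' contacts decay as a power law of bin separation, modulated by an A/B
#' checkerboard factor, plus a Rabl "wing" term between opposite arms at
#' matched centromere distance (the transverse-to-diagonal stripe that
#' intersects the diagonal at the centromere). Inter-chromosomal
#' expectations are a background times a chromosome-territory factor, with
#' multiplicative enrichments for centromere clustering, telomere clustering
#' and centromere-to-telomere polarity (matched relative arm position).
#'
#' @param alpha power-law decay exponent (>0).
#' @param w_r Rabl wing weight (>= 0).
#' @param sigma wing / cluster width in bp.
#' @param w_ab compartment contrast (same-label pairs weighted `1 + w_ab`;
#'   default 1.2, a stark checkerboard).
#' @param block_scale mean A/B block length in bp (exponential).
#' @param b inter-chromosomal background level relative to the intra model.
#' @param w_cen,w_tel centromere-/telomere-cluster weights.
#' @param w_pol polar (matched nuclear height) weight: loci at similar
#'   absolute distance from their centromere cluster contact more.
#' @param sigma_pol polar width on the absolute centromere distance (bp).
#'   Because p arms are systematically shorter than q arms, large matched
#'   heights exist mostly on q arms, which yields the mild concordant
#'   (p-p + q-q) inter-arm contact excess seen in Rabl nuclei.
#' @param territory symmetric positive K x K matrix of per-chromosome-pair
#'   territory factors, or `NULL` for all 1.
#' @param depth total expected read count (> 0).
#' @return list of class `hic_sim_params`.
#' @export
hic_sim_params <- function(alpha = 1, w_r = 1.5, sigma = 4e6, w_ab = 1.2,
                           block_scale = 6e6, b = 0.02, w_cen = 3,
                           w_tel = 1.5, w_pol = 1.5, sigma_pol = 8e6,
                           territory = NULL, depth = 4e6) {
  weights <- c(w_r = w_r, w_ab = w_ab, b = b, w_cen = w_cen, w_tel = w_tel,
               w_pol = w_pol)
  if (any(weights < 0)) stop("all weights must be non-negative")
  if (depth <= 0) stop("total read count must be positive")
  if (alpha <= 0) stop("decay exponent must be positive")
  if (!is.null(territory)) {
    if (max(abs(territory - t(territory))) > 1e-12 || any(territory <= 0))
      stop("territory matrix must be symmetric positive")
  }
  structure(list(alpha = alpha, w_r = w_r, sigma = sigma, w_ab = w_ab,
                 block_scale = block_scale, b = b, w_cen = w_cen,
                 w_tel = w_tel, w_pol = w_pol, sigma_pol = sigma_pol,
                 territory = territory, depth = depth),
            class = "hic_sim_params")
}

# alternating A/B blocks with (truncated) exponential lengths; the cap at
# 3x the scale keeps single blocks from swallowing a whole arm, which would
# leave no checkerboard to recover
.sim_compartments <- function(bins, block_scale) {
  lab <- character(nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    L <- max(bins$end[idx])
    cur <- sample(c("A", "B"), 1)
    pos <- 0
    labs <- character(0); bounds <- numeric(0)
    while (pos < L) {
      len <- min(stats::rexp(1, 1 / block_scale), 3 * block_scale) +
        (bins$end[idx[1]] - bins$start[idx[1]])
      pos <- pos + len
      labs <- c(labs, cur); bounds <- c(bounds, pos)
      cur <- if (cur == "A") "B" else "A"
    }
    mid <- (bins$start[idx] + bins$end[idx]) / 2
    lab[idx] <- labs[findInterval(mid, c(0, bounds), rightmost.closed = TRUE)]
  }
  lab
}

#' Simulate a binned Hi-C contact matrix
#'
#' Builds the model expectation over all bin pairs (see [hic_sim_params()]),
#' scales it to the requested total read depth, and Poisson-samples
#' symmetric counts. The expectation matrix, planted compartment labels, a
#' matching gene-density track (gene-rich A, gene-poor B) and the true
#' centromere bins are returned alongside the counts.
#'
#' @param layout a [genome_layout()].
#' @param params a [hic_sim_params()].
#' @param bin_size bin size in bp.
#' @param seed integer seed.
#' @return a [contact_matrix()] with `expected` filled and extra fields
#'   `truth` (list: `compartments`, `gene_density`, `centromere_bins`) and
#'   `params`.
#' @export
simulate_hic_matrix <- function(layout, params = hic_sim_params(),
                                bin_size = 1e6, seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "hic_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  bins <- make_bins(layout, bin_size)
  comp <- .sim_compartments(bins, params$block_scale)
  E <- hic_expectation(bins, comp, params, bin_size)
  E <- E * (params$depth / sum(E[upper.tri(E, diag = TRUE)]))
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  ut <- upper.tri(counts, diag = TRUE)
  counts[ut] <- stats::rpois(sum(ut), E[ut])
  counts <- counts + t(counts) - diag(diag(counts))
  # gene density: gene-rich A vs gene-poor B (genes per bin)
  mb <- (bins$end - bins$start) / 1e6
  gd <- stats::rpois(n, ifelse(comp == "A", 20, 10) * mb)
  cen_bins <- vapply(unique(bins$chrom), function(ch) {
    idx <- which(bins$chrom == ch)
    idx[which.min(bins$d_cen[idx])]
  }, integer(1))
  cm <- contact_matrix(bins[, c("chrom", "start", "end", "bin")], counts,
                       bin_size, expected = E)
  cm$bin_geometry <- bins
  cm$truth <- list(compartments = comp, gene_density = gd,
                   centromere_bins = cen_bins)
  cm$params <- params
  cm
}

#' Model expectation over all bin pairs
#'
#' Evaluates the generative contact model (before depth scaling) on a bin
#' geometry table. Exported so the expectation can be checked against a
#' direct evaluation of the formula.
#'
#' @param bins bin geometry as from [make_bins()].
#' @param comp per-bin compartment label ("A"/"B").
#' @param params a [hic_sim_params()].
#' @param bin_size bin size in bp.
#' @return dense symmetric expectation matrix (unscaled).
#' @export
hic_expectation <- function(bins, comp, params, bin_size) {
  n <- nrow(bins)
  chrom <- bins$chrom
  chroms <- unique(chrom)
  k <- match(chrom, chroms)
  Tm <- params$territory
  if (is.null(Tm)) Tm <- matrix(1, length(chroms), length(chroms))
  # inter-chromosomal part, computed for all pairs then overwritten intra
  cenf <- exp(-(bins$d_cen^2) / (2 * params$sigma^2))
  telf <- exp(-(bins$d_tel^2) / (2 * params$sigma^2))
  E <- params$b * Tm[cbind(rep(k, n), rep(k, each = n))] *
    (1 + params$w_cen * outer(cenf, cenf) +
       params$w_tel * outer(telf, telf) +
       params$w_pol * exp(-outer(bins$d_cen, bins$d_cen, "-")^2 /
                            (2 * params$sigma_pol^2)))
  dim(E) <- c(n, n)
  # intra-chromosomal part
  for (ch in chroms) {
    idx <- which(chrom == ch)
    d <- abs(outer(idx, idx, "-"))
    d[d == 0] <- 1
    base <- d^(-params$alpha)
    same <- outer(comp[idx], comp[idx], "==")
    cfac <- 1 + params$w_ab * same
    opp <- outer(bins$arm[idx], bins$arm[idx], "!=")
    wing <- params$w_r * opp *
      exp(-outer(bins$d_cen[idx], bins$d_cen[idx], "-")^2 /
            (2 * params$sigma^2))
    E[idx, idx] <- base * (cfac + wing)
  }
  E
}
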