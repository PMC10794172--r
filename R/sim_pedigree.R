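#' Residual heterozygosity under repeated full-sib mating
#'
#' Forward simulation of strict brother-sister mating without selection.
#' Two unrelated founders carry four distinguishable haplotypes; each
#' generation two offspring are produced from the current pair and mated.
#' Crossovers are Poisson on the genetic map (one crossover expected per
#' 100 cM per meiosis) with no interference. For the individual sampled at
#' generation `t` the statistic is the fraction of the genetic map where its
#' two haplotypes are not identical by descent.
#'
#' The expected per-locus value follows the classical sib-mating recurrence
#' `H_t = H_{t-1}/2 + H_{t-2}/4` (H_0 = H_1 = 1), asymptotically
#' `1.17 x 0.809^t` (see [inbreeding_expected_fraction()]).
#'
#' @param t generations (>= 1); generation 1 are the founders' children.
#' @param map_lengths_cM numeric vector of per-chromosome map lengths (cM).
#' @param n_rep number of replicate pedigrees.
#' @param seed integer seed; replicate r uses stream `seed + r`.
#' @return numeric vector of length `n_rep`: per-replicate heterozygous map
#'   fraction.
#' @export
simulate_inbred_pedigree <- function(t, map_lengths_cM, n_rep = 500,
                                     seed = NULL) {
  if (t < 1) stop("t must be >= 1")
  if (any(map_lengths_cM <= 0) || !length(map_lengths_cM))
    stop("map lengths must be positive")
  vapply(seq_len(n_rep), function(r) {
    if (!is.null(seed)) set.seed(seed + r)
    .one_pedigree(t, map_lengths_cM)
  }, numeric(1))
}

# a haplotype along one chromosome: breakpoints bp (sorted, cM scale) and
# founder labels lab with length(lab) == length(bp) + 1; piece i covers
# [bp[i-1], bp[i])
.hap <- function(L, label) list(bp = numeric(0), lab = label)

.meiosis <- function(hap1, hap2, L) {
  nx <- stats::rpois(1, L / 100)
  if (nx == 0) return(if (stats::runif(1) < 0.5) hap1 else hap2)
  xs <- sort(stats::runif(nx, 0, L))
  cur <- if (stats::runif(1) < 0.5) 1L else 2L
  bp <- numeric(0); lab <- integer(0)
  pos <- 0
  for (x in c(xs, L)) {
    h <- if (cur == 1L) hap1 else hap2
    keep <- h$bp > pos & h$bp < x
    bp <- c(bp, h$bp[keep], x)
    piece_labs <- h$lab[c(findInterval(pos, h$bp) + 1L,
                          which(keep) + 1L)]
    lab <- c(lab, piece_labs)
    cur <- 3L - cur
    pos <- x
  }
  bp <- bp[-length(bp)]  # drop terminal L
  # merge adjacent identical labels
  if (length(bp)) {
    same <- lab[-1] == lab[-length(lab)]
    bp <- bp[!same]
    lab <- lab[c(TRUE, !same)]
  }
  list(bp = bp, lab = lab)
}

# fraction of [0, L) where two haplotypes carry different founder labels
.het_len <- function(h1, h2, L) {
  cuts <- sort(unique(c(0, h1$bp, h2$bp, L)))
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  l1 <- h1$lab[findInterval(mids, h1$bp) + 1L]
  l2 <- h2$lab[findInterval(mids, h2$bp) + 1L]
  sum((cuts[-1] - cuts[-length(cuts)])[l1 != l2])
}

.one_pedigree <- function(t, lens) {
  nchr <- length(lens)
  # founders: individual = list of chromosomes, each list(h1, h2)
  f1 <- lapply(lens, function(L) list(.hap(L, 1L), .hap(L, 2L)))
  f2 <- lapply(lens, function(L) list(.hap(L, 3L), .hap(L, 4L)))
  pair <- list(f1, f2)
  child <- function(pair) {
    lapply(seq_len(nchr), function(i) {
      list(.meiosis(pair[[1]][[i]][[1]], pair[[1]][[i]][[2]], lens[i]),
           .meiosis(pair[[2]][[i]][[1]], pair[[2]][[i]][[2]], lens[i]))
    })
  }
  for (g in seq_len(t)) pair <- list(child(pair), child(pair))
  ind <- pair[[1]]
  het <- sum(vapply(seq_len(nchr), function(i)
    .het_len(ind[[i]][[1]], ind[[i]][[2]], lens[i]), numeric(1)))
  het / sum(lens)
}

# one pedigree, returning per-chromosome IBD segment tracks of the sampled
# individual: data.frame(start, end, het) in cM coordinates
.one_pedigree_tracks <- function(t, lens) {
  nchr <- length(lens)
  f1 <- lapply(lens, function(L) list(.hap(L, 1L), .hap(L, 2L)))
  f2 <- lapply(lens, function(L) list(.hap(L, 3L), .hap(L, 4L)))
  pair <- list(f1, f2)
  child <- function(pair) {
    lapply(seq_len(nchr), function(i) {
      list(.meiosis(pair[[1]][[i]][[1]], pair[[1]][[i]][[2]], lens[i]),
           .meiosis(pair[[2]][[i]][[1]], pair[[2]][[i]][[2]], lens[i]))
    })
  }
  for (g in seq_len(t)) pair <- list(child(pair), child(pair))
  ind <- pair[[1]]
  lapply(seq_len(nchr), function(i) {
    h1 <- ind[[i]][[1]]; h2 <- ind[[i]][[2]]
    cuts <- sort(unique(c(0, h1$bp, h2$bp, lens[i])))
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    l1 <- h1$lab[findInterval(mids, h1$bp) + 1L]
    l2 <- h2$lab[findInterval(mids, h2$bp) + 1L]
    data.frame(start = cuts[-length(cuts)], end = cuts[-1], het = l1 != l2)
  })
}

#' Expected heterozygous map fraction under full-sib inbreeding
#'
#' Asymptotic expectation `min(1, 1.17 x 0.809^t)` for the fraction of the
#' genetic map remaining non-identical-by-descent after `t` generations of
#' full-sib mating (3.2% at t = 17, 7.4% at t = 13). The approximation holds
#' for t >= 5; below that a warning is issued.
#'
#' @param t generations.
#' @return expected fraction in `[0, 1]`.
#' @export
inbreeding_expected_fraction <- function(t) {
  if (any(t < 5))
    warning("asymptotic approximation is poor for t < 5")
  pmin(1, 1.17 * 0.809^t)
}
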