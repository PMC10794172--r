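#' Recombination landscapes from genetic maps
#'
#' Marey maps (cM vs bp) are smoothed with a not-a-knot cubic spline and the
#' local recombination rate is the spline derivative, evaluated on a 500-kb
#' lattice, in cM/Mb.
#'
#' @name recombination
NULL

# not-a-knot cubic spline: returns knots plus per-piece coefficients of
# S(x) = a + b t + c t^2 + d t^3, t = x - x_i
.notaknot_spline <- function(x, y) {
  n <- length(x)
  if (n < 4) stop("not-a-knot spline needs >= 4 points")
  h <- diff(x)
  dd <- diff(y) / h
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i] <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    rhs[i] <- dd[i] - dd[i - 1]
  }
  # third-derivative continuity at the second and second-to-last knots
  A[1, 1] <- h[2]; A[1, 2] <- -(h[1] + h[2]); A[1, 3] <- h[1]
  A[n, n - 2] <- h[n - 1]; A[n, n - 1] <- -(h[n - 2] + h[n - 1])
  A[n, n] <- h[n - 2]
  M <- solve(A, rhs)
  b <- dd - h * (2 * M[-n] + M[-1]) / 6
  list(x = x, y = y, b = b, M = M, h = h)
}

.spline_eval <- function(sp, xout, deriv = 0) {
  i <- pmin(pmax(findInterval(xout, sp$x), 1), length(sp$x) - 1)
  t <- xout - sp$x[i]
  c3 <- (sp$M[i + 1] - sp$M[i]) / (6 * sp$h[i])
  if (deriv == 0) {
    sp$y[i] + sp$b[i] * t + sp$M[i] / 2 * t^2 + c3 * t^3
  } else {
    sp$b[i] + sp$M[i] * t + 3 * c3 * t^2
  }
}

#' Smooth a Marey map into a recombination-rate track
#'
#' Fits a not-a-knot cubic spline to cM vs bp per chromosome and evaluates
#' its derivative on a `grid_bp` lattice, converting to cM/Mb. Negative
#' derivatives (spline overshoot) are clamped to zero and counted in the
#' `n_clamped` attribute. Grid points outside the marker span are `NA`.
#'
#' @param map genetic map data.frame (`chrom`, `bp`, `cM`).
#' @param grid_bp lattice spacing (default 500 kb).
#' @return `rate_track` data.frame: `chrom`, `pos`, `rate` (cM/Mb), with
#'   attributes `n_clamped` and `splines`.
#' @export
smooth_marey <- function(map, grid_bp = 5e5) {
  out <- list(); clamped <- 0; splines <- list()
  for (ch in unique(map$chrom)) {
    d <- map[map$chrom == ch, , drop = FALSE]
    d <- d[order(d$bp), , drop = FALSE]
    if (nrow(d) < 4) stop("chromosome ", ch, " has < 4 markers")
    if (any(diff(d$cM) < 0)) {
      bad <- d$bp[which(diff(d$cM) < 0) + 1]
      stop("non-monotone map on ", ch, " at bp ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    sp <- .notaknot_spline(d$bp, d$cM)
    grid <- seq(0, max(d$bp), by = grid_bp)
    grid <- grid[grid >= min(d$bp) & grid <= max(d$bp)]
    rate <- .spline_eval(sp, grid, deriv = 1) * 1e6
    clamped <- clamped + sum(rate < 0)
    rate[rate < 0] <- 0
    out[[ch]] <- data.frame(chrom = ch, pos = grid, rate = rate,
                            stringsAsFactors = FALSE)
    splines[[ch]] <- sp
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  attr(track, "n_clamped") <- clamped
  attr(track, "splines") <- splines
  class(track) <- c("rate_track", "data.frame")
  track
}

#' Concentration of recombination
#'
#' The smallest fraction of the genome (grid points, sorted by decreasing
#' rate) that accounts for 50% and 90% of the total map length.
#'
#' @param track a `rate_track` from [smooth_marey()].
#' @param quantiles cumulative-cM quantiles to report.
#' @return named numeric vector of genome fractions.
#' @export
recombination_concentration <- function(track, quantiles = c(0.5, 0.9)) {
  r <- sort(track$rate[!is.na(track$rate)], decreasing = TRUE)
  cum <- cumsum(r) / sum(r)
  f <- vapply(quantiles, function(q) which(cum >= q)[1] / length(r),
              numeric(1))
  names(f) <- paste0("q", quantiles * 100)
  f
}

#' Regional recombination-rate comparison
#'
#' Assigns each grid point a region class (subtelomere / arm /
#' pericentromere, see [layout_regions()]), reports the median rate per
#' class and all pairwise two-sample two-sided Kolmogorov-Smirnov tests with
#' Hochberg step-up correction.
#'
#' @param track a `rate_track`.
#' @param layout a [genome_layout()].
#' @param subtel_bp,peri_bp region geometry (defaults 30 Mb / 5 Mb).
#' @return list: `medians` (named vector), `tests` (data.frame `class1`,
#'   `class2`, `ks`, `p`, `p_adj`), `classes` (per grid point).
#' @export
region_rate_comparison <- function(track, layout, subtel_bp = 30e6,
                                   peri_bp = 5e6) {
  regions <- layout_regions(layout, subtel_bp = subtel_bp, peri_bp = peri_bp)
  cls <- rep(NA_character_, nrow(track))
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    reg <- reg[order(reg$start), , drop = FALSE]
    j <- findInterval(track$pos[idx], reg$start)
    j[j == 0] <- 1
    cls[idx] <- reg$class[j]
  }
  r <- track$rate
  med <- tapply(r[!is.na(r)], cls[!is.na(r)], stats::median)
  combs <- utils::combn(sort(unique(cls[!is.na(cls)])), 2)
  tests <- apply(combs, 2, function(pr) {
    a <- r[cls == pr[1] & !is.na(r)]
    b <- r[cls == pr[2] & !is.na(r)]
    kt <- suppressWarnings(stats::ks.test(a, b))
    data.frame(class1 = pr[1], class2 = pr[2], ks = unname(kt$statistic),
               p = kt$p.value, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  tests$p_adj <- stats::p.adjust(tests$p, method = "hochberg")
  list(medians = med, tests = tests, classes = cls)
}

#' Correlation of recombination rate with genomic features
#'
#' @param track a `rate_track`.
#' @param features data.frame of per-grid-point feature columns aligned to
#'   `track` rows (NAs dropped pairwise).
#' @return data.frame `feature`, `r` (Pearson), `n`.
#' @export
feature_correlation <- function(track, features) {
  out <- do.call(rbind, lapply(names(features), function(f) {
    ok <- !is.na(track$rate) & !is.na(features[[f]])
    data.frame(feature = f,
               r = stats::cor(track$rate[ok], features[[f]][ok]),
               n = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Filter a variant site table
#'
#' Applies, in order: (1) biallelic-SNP filter; (2) depth within
#' `mode +/- depth_sd_mult * SD`, the mode being the modal integer depth and
#' the SD computed over retained biallelic sites; (3) allele-balance window
#' for heterozygous genotypes; (4) optionally, parental informativeness
#' (parents fixed and different, each with depth >= `parent_min_depth`).
#'
#' @param table variant site table (see [simulate_variant_sites()]).
#' @param depth_sd_mult depth window half-width in SDs (default 1.78).
#' @param balance allele-balance window (default `c(0.3, 0.7)`).
#' @param parents optional character(2) of parent sample names.
#' @param parent_min_depth minimum parental depth (default 10).
#' @return list: `table` (passing sites), `counts` (named vector of sites
#'   removed by each filter plus `pass`).
#' @export
filter_variant_sites <- function(table, depth_sd_mult = 1.78,
                                 balance = c(0.3, 0.7), parents = NULL,
                                 parent_min_depth = 10) {
  n0 <- nrow(table)
  bi <- table$n_alleles == 2
  t1 <- table[bi, , drop = FALSE]
  dtab <- table(t1$dp)
  mode_dp <- as.numeric(names(dtab)[which.max(dtab)])
  sd_dp <- stats::sd(t1$dp)
  dep <- t1$dp >= mode_dp - depth_sd_mult * sd_dp &
    t1$dp <= mode_dp + depth_sd_mult * sd_dp
  t2 <- t1[dep, , drop = FALSE]
  gts <- grep("^gt_", names(t2), value = TRUE)
  ok_ab <- rep(TRUE, nrow(t2))
  for (g in gts) {
    ab <- t2[[sub("^gt_", "ab_", g)]]
    het <- t2[[g]] == "0/1"
    ok_ab <- ok_ab & (!het | (ab >= balance[1] & ab <= balance[2]))
  }
  t3 <- t2[ok_ab, , drop = FALSE]
  n_par <- 0
  if (!is.null(parents)) {
    g1 <- t3[[paste0("gt_", parents[1])]]
    g2 <- t3[[paste0("gt_", parents[2])]]
    d1 <- t3[[paste0("dp_", parents[1])]]
    d2 <- t3[[paste0("dp_", parents[2])]]
    fixed_diff <- g1 %in% c("0/0", "1/1") & g2 %in% c("0/0", "1/1") &
      g1 != g2 & d1 >= parent_min_depth & d2 >= parent_min_depth
    n_par <- sum(!fixed_diff)
    t3 <- t3[fixed_diff, , drop = FALSE]
  }
  rownames(t3) <- NULL
  counts <- c(input = n0, multiallelic = n0 - nrow(t1),
              depth = nrow(t1) - nrow(t2),
              balance = nrow(t2) - sum(ok_ab),
              parental = n_par, pass = nrow(t3))
  list(table = t3, counts = counts, depth_mode = mode_dp, depth_sd = sd_dp)
}

#' Windowed heterozygosity and residual-heterozygosity map fraction
#'
#' Computes heterozygous SNVs per kb in sliding windows (500 kb window,
#' 50 kb step), calls heterozygous blocks as maximal runs of at least
#' `min_windows` windows with density above `theta` (default 10% of the mean
#' density over non-empty windows), and converts block spans to genetic-map
#' centimorgans by linear interpolation to report the heterozygous fraction
#' of the map.
#'
#' @param table variant table (passing sites) with `chrom`, `pos` and one or
#'   more `gt_*` columns; a site is heterozygous when any sample is "0/1".
#' @param layout a [genome_layout()].
#' @param map genetic map (`chrom`, `bp`, `cM`) for cM conversion.
#' @param window,step window geometry in bp.
#' @param theta density threshold (het SNVs/kb); `NULL` for the default.
#' @param min_windows minimum run length in windows (default 3).
#' @return list: `windows` (data.frame `chrom`, `start`, `end`, `density`),
#'   `blocks` (data.frame `chrom`, `start`, `end`, `cM`), `map_fraction`
#'   (block cM over total map cM), `theta`.
#' @export
heterozygosity_windows <- function(table, layout, map = NULL,
                                   window = 5e5, step = 5e4, theta = NULL,
                                   min_windows = 3) {
  gts <- grep("^gt_", names(table), value = TRUE)
  het <- Reduce(`|`, lapply(gts, function(g) table[[g]] == "0/1"))
  wins <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]; L <- layout$length[i]
    if (L < window) next
    starts <- seq(0, L - window, by = step)
    pos <- table$pos[table$chrom == ch & het]
    cnt <- vapply(starts, function(s)
      sum(pos >= s & pos < s + window), numeric(1))
    wins[[ch]] <- data.frame(chrom = ch, start = starts,
                             end = starts + window,
                             density = cnt / (window / 1e3),
                             stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, wins)
  rownames(windows) <- NULL
  if (is.null(theta)) {
    nz <- windows$density[windows$density > 0]
    theta <- if (length(nz)) 0.1 * mean(nz) else 0
  }
  blocks <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    above <- w$density > theta
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths >= min_windows)) {
      # trim the window width back out of the run bounds: the first/last
      # qualifying windows overlap the underlying block by as little as one
      # step, so the raw union overcovers by ~(window - step) on each side
      a <- w$start[starts[j]] + (window - step)
      b <- w$end[ends[j]] - (window - step)
      if (b <= a) {
        mid <- (w$start[starts[j]] + w$end[ends[j]]) / 2
        a <- mid - step / 2; b <- mid + step / 2
      }
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom = ch, start = a, end = b, stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  map_fraction <- NA_real_
  if (!is.null(map) && nrow(blocks)) {
    blocks$cM <- vapply(seq_len(nrow(blocks)), function(j) {
      m <- map[map$chrom == blocks$chrom[j], , drop = FALSE]
      if (nrow(m) < 2) return(0)
      f <- stats::approxfun(m$bp, m$cM, rule = 2)
      f(blocks$end[j]) - f(blocks$start[j])
    }, numeric(1))
    total <- sum(vapply(unique(map$chrom), function(ch) {
      m <- map$cM[map$chrom == ch]
      max(m) - min(m)
    }, numeric(1)))
    map_fraction <- sum(blocks$cM) / total
  } else if (!is.null(map)) {
    blocks$cM <- numeric(0)
    map_fraction <- 0
  }
  list(windows = windows, blocks = blocks, map_fraction = map_fraction,
       theta = theta)
}
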