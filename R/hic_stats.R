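#' Hi-C matrix balancing
#'
#' Finds per-bin weights `x` such that `diag(x) %*% M %*% diag(x)` has
#' constant row sums (1 after normalization). `method = "KR"` uses the
#' Knight-Ruiz inner-outer Newton iteration with conjugate-gradient inner
#' solves; `method = "ICE"` uses iterative correction (Sinkhorn-style
#' alternating row scaling). Zero-coverage bins are masked (weight `NA`).
#'
#' @param cm a [contact_matrix()] or a plain symmetric matrix.
#' @param method "KR" or "ICE".
#' @param tol convergence tolerance on the row-sum residual.
#' @param max_iter maximum outer iterations.
#' @return for a `contact_matrix`, the same object with `weights` and
#'   `balanced` filled; for a plain matrix, list(`weights`, `balanced`).
#' @export
balance_matrix <- function(cm, method = c("KR", "ICE"), tol = 1e-8,
                           max_iter = 1000) {
  method <- match.arg(method)
  M <- if (inherits(cm, "contact_matrix")) cm$counts else cm
  mask <- rowSums(M) > 0
  A <- M[mask, mask, drop = FALSE]
  if (nrow(A) < 2) stop("matrix degenerate after masking zero-coverage bins")
  x <- if (method == "KR") .kr_balance(A, tol, max_iter)
       else .ice_balance(A, tol, max_iter)
  w <- rep(NA_real_, nrow(M))
  w[mask] <- x
  B <- matrix(NA_real_, nrow(M), ncol(M))
  B[mask, mask] <- A * outer(x, x)
  if (inherits(cm, "contact_matrix")) {
    cm$weights <- w
    cm$balanced <- B
    cm
  } else list(weights = w, balanced = B)
}

# Knight-Ruiz balancing: inexact Newton for x with x * (A x) = e, inner
# conjugate gradient. The matrix is pre-scaled by its mean row sum for
# conditioning; the returned weights absorb the scale so that
# diag(x) A diag(x) has unit row sums.
.kr_balance <- function(A, tol = 1e-8, max_iter = 1000) {
  cscale <- mean(rowSums(A))
  A <- A / cscale
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * (A %*% x)[, 1]
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  it <- 0
  while (rout > rt && it < max_iter) {
    it <- it + 1
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    Z <- p <- rep(0, n)
    rho_km2 <- 0
    while (rho_km1 > innertol && k < 2 * n) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * (A %*% (x * p))[, 1] + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * (A %*% x)[, 1]
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  if (rout > rt)
    stop(sprintf("KR balancing did not converge: residual %.3g", sqrt(rout)))
  x / sqrt(cscale)
}

# iterative correction: alternate scaling by row sums until constant
.ice_balance <- function(A, tol = 1e-8, max_iter = 1000) {
  n <- nrow(A)
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    B <- A * outer(w, w)
    s <- rowSums(B)
    if (max(abs(s - 1)) < tol) return(w)
    s[s == 0] <- 1
    w <- w / sqrt(s)
    # renormalize toward unit row sums
    w <- w / sqrt(mean(rowSums(A * outer(w, w))))
  }
  stop(sprintf("ICE balancing did not converge: residual %.3g",
               max(abs(rowSums(A * outer(w, w)) - 1))))
}

# observed/expected by genomic-distance stratum, per chromosome, on a
# balanced matrix; inter-chromosomal entries scaled by the global inter mean
.oe_matrix <- function(cm) {
  B <- cm$balanced
  if (is.null(B)) stop("balance the matrix first")
  chrom <- cm$bins$chrom
  OE <- matrix(NA_real_, nrow(B), ncol(B))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    sub <- B[idx, idx, drop = FALSE]
    d <- abs(outer(seq_along(idx), seq_along(idx), "-"))
    ok <- !is.na(sub)
    sums <- rowsum(sub[ok], d[ok])
    cnts <- rowsum(rep(1, sum(ok)), d[ok])
    means <- stats::setNames((sums / cnts)[, 1], rownames(sums))
    expd <- means[as.character(d)]
    dim(expd) <- dim(sub)
    OE[idx, idx] <- sub / expd
  }
  inter <- outer(chrom, chrom, "!=")
  m <- mean(B[inter], na.rm = TRUE)
  OE[inter] <- B[inter] / m
  OE
}

#' Infer centromere positions from a contact matrix
#'
#' For each candidate bin `c` the wing score is the mean distance-normalized
#' (O/E) contact `M[c - d, c + d]` over `d = 1..D`, `D` being the shorter
#' candidate arm in bins: the transverse "wing" of p-q arm contacts peaks
#' where the chromosome folds at its centromere. The intra-chromosomal call
#' (argmax) is refined by the inter-chromosomal centromere-cluster signal
#' (mean contact to the other chromosomes' current calls), and flagged
#' low-confidence when the peak is below 1.5x the median candidate score,
#' or "edge" when the call sits within 3 bins of a chromosome end
#' (acrocentric).
#'
#' @param cm a balanced [contact_matrix()] (see [balance_matrix()]).
#' @param min_bins minimum bins per chromosome to attempt a call.
#' @param refine_iter refinement passes over the cross-chromosome signal.
#' @return data.frame: `chrom`, `bin` (global bin id), `start`, `end`,
#'   `score`, `confident`, `flag`.
#' @export
infer_centromeres <- function(cm, min_bins = 20, refine_iter = 2) {
  if (is.null(cm$balanced)) cm <- balance_matrix(cm)
  OE <- .oe_matrix(cm)
  OE[is.na(OE)] <- 0
  chrom <- cm$bins$chrom
  chroms <- unique(chrom)
  scores <- list(); calls <- integer(length(chroms))
  names(calls) <- chroms
  flags <- character(length(chroms)); names(flags) <- chroms
  for (ch in chroms) {
    idx <- which(chrom == ch)
    n <- length(idx)
    if (n < min_bins) {
      calls[ch] <- NA_integer_
      flags[ch] <- "too_short"
      scores[[ch]] <- rep(NA_real_, n)
      next
    }
    s <- rep(NA_real_, n)
    for (c0 in 2:(n - 1)) {
      D <- min(c0 - 1, n - c0)
      dd <- seq_len(D)
      # shrink low-depth (near-edge) scores toward the O/E background of 1
      # so single noisy anti-diagonal pairs cannot outscore a real wing
      s[c0] <- (sum(OE[cbind(idx[c0 - dd], idx[c0 + dd])]) + 3) / (D + 3)
    }
    scores[[ch]] <- s
    calls[ch] <- which.max(s)
    flags[ch] <- ""
  }
  # refinement by inter-chromosomal centromere clustering
  B <- cm$balanced
  B[is.na(B)] <- 0
  for (iter in seq_len(refine_iter)) {
    for (ch in chroms) {
      if (is.na(calls[ch])) next
      idx <- which(chrom == ch)
      others <- chroms[chroms != ch & !is.na(calls[chroms])]
      if (!length(others)) break
      cross <- rowMeans(sapply(others, function(o) {
        oidx <- which(chrom == o)
        tgt <- oidx[pmax(1, pmin(length(oidx),
                                 calls[o] + (-1:1)))]
        rowMeans(B[idx, tgt, drop = FALSE])
      }))
      s <- scores[[ch]]
      comb <- scale(s)[, 1] + scale(cross)[, 1]
      comb[is.na(s)] <- NA
      calls[ch] <- which.max(comb)
    }
  }
  out <- do.call(rbind, lapply(chroms, function(ch) {
    idx <- which(chrom == ch)
    n <- length(idx)
    ci <- calls[ch]
    s <- scores[[ch]]
    if (is.na(ci)) {
      return(data.frame(chrom = ch, bin = NA_integer_, start = NA_real_,
                        end = NA_real_, score = NA_real_, confident = FALSE,
                        flag = flags[ch], stringsAsFactors = FALSE))
    }
    bg <- stats::median(s, na.rm = TRUE)
    conf <- is.finite(s[ci]) && s[ci] >= 1.5 * bg
    fl <- flags[ch]
    if (min(ci - 1, n - ci) < 3) fl <- paste0(fl, "edge/acrocentric")
    if (!conf) fl <- paste(fl, "low_confidence")
    data.frame(chrom = ch, bin = idx[ci], start = cm$bins$start[idx[ci]],
               end = cm$bins$end[idx[ci]], score = s[ci], confident = conf,
               flag = trimws(fl), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call A/B compartments
#'
#' Per chromosome: the balanced matrix is distance-normalized (O/E), the
#' Pearson correlation matrix of its columns is decomposed, and the
#' compartment loading is the eigenvector that best correlates with gene
#' density among the leading `n_pc` (on chromosomes with a strong Rabl wing
#' the first eigenvector can capture the p/q-arm split instead of the
#' checkerboard; gene density disambiguates). The per-chromosome sign is
#' oriented so that positive loadings (compartment A) correlate positively
#' with gene density.
#'
#' @param cm a balanced [contact_matrix()].
#' @param gene_density numeric per-bin gene density track.
#' @param n_pc leading eigenvectors searched (default 3).
#' @return data.frame: `chrom`, `bin`, `loading`, `label` ("A"/"B", NA where
#'   masked), plus a `pc_used` attribute (per chromosome).
#' @export
call_compartments <- function(cm, gene_density, n_pc = 3) {
  if (is.null(cm$balanced)) cm <- balance_matrix(cm)
  OE <- .oe_matrix(cm)
  chrom <- cm$bins$chrom
  out <- data.frame(chrom = chrom, bin = cm$bins$bin,
                    loading = NA_real_, label = NA_character_,
                    stringsAsFactors = FALSE)
  pc_used <- stats::setNames(integer(length(unique(chrom))), unique(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    sub <- OE[idx, idx, drop = FALSE]
    ok <- which(colSums(is.na(sub)) < nrow(sub))
    sub <- sub[ok, ok, drop = FALSE]
    if (length(ok) < 3) next
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    if (max(abs(cc - cc[1, 1])) < 1e-12)
      stop("constant matrix on ", ch, ": compartment PC is degenerate")
    ev <- eigen(cc, symmetric = TRUE)$vectors
    gd <- gene_density[idx][ok]
    k <- min(n_pc, ncol(ev))
    rs <- vapply(seq_len(k), function(j)
      suppressWarnings(stats::cor(ev[, j], gd)), numeric(1))
    rs[is.na(rs)] <- 0
    j <- which.max(abs(rs))
    pc <- ev[, j] * sign(rs[j] + (rs[j] == 0))
    pc_used[ch] <- j
    out$loading[idx[ok]] <- pc
    out$label[idx[ok]] <- ifelse(pc > 0, "A", "B")
  }
  attr(out, "pc_used") <- pc_used
  out
}

#' Compartment segment statistics
#'
#' Collapses a compartment track into maximal same-label segments and
#' reports arithmetic and geometric mean segment lengths per label.
#'
#' @param track output of [call_compartments()], needing `chrom`, `label`.
#' @param bins bin table with `start`, `end` aligned to `track`.
#' @return list: `segments` (data.frame `chrom`, `start`, `end`, `label`,
#'   `length`), `means` (data.frame `label`, `arithmetic`, `geometric`).
#' @export
compartment_stats <- function(track, bins) {
  segs <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch & !is.na(track$label))
    if (!length(idx)) next
    lab <- track$label[idx]
    brk <- c(0, which(lab[-1] != lab[-length(lab)] |
                        diff(idx) != 1), length(lab))
    for (s in seq_len(length(brk) - 1)) {
      a <- idx[brk[s] + 1]; b <- idx[brk[s + 1]]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = bins$start[a], end = bins$end[b],
        label = lab[brk[s] + 1], stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  segments$length <- segments$end - segments$start
  means <- do.call(rbind, lapply(split(segments$length, segments$label),
                                 function(x) data.frame(
                                   arithmetic = mean(x),
                                   geometric = exp(mean(log(x))))))
  means <- cbind(label = rownames(means), means)
  rownames(means) <- NULL
  list(segments = segments, means = means)
}

# PCA scores (PC1, PC2) of bin contact profiles, standardized per
# component. Profiles are distance-normalized (O/E): removing the intra
# decay keeps the embedding from collapsing onto chromosome position, while
# the wing and the inter-chromosomal polarity both remain, so paired p/q
# bins sit close exactly when the nucleus is Rabl-organized.
.profile_scores <- function(cm) {
  B <- .oe_matrix(cm)
  ok <- which(rowSums(!is.na(B)) > 0)
  M <- B[ok, ok, drop = FALSE]
  M[is.na(M)] <- 0
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  sc <- scale(sc)
  # deterministic sign: first nonzero loading positive
  for (j in 1:2) {
    v <- pc$rotation[, j]
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) sc[, j] <- -sc[, j]
  }
  full <- matrix(NA_real_, nrow(B), 2)
  full[ok, ] <- sc
  full
}

#' Rabl interarm constraint (SSD)
#'
#' Bins are embedded by PCA of their genome-wide balanced contact profiles;
#' scores are standardized per component. On each chromosome the i-th p-arm
#' bin (counting away from the centromere) is paired with the i-th q-arm
#' bin, and the SSD is the mean squared Euclidean distance between pair
#' members in (PC1, PC2). Tightly aligned arms (strong Rabl folding) give
#' small SSD. Chromosomes with an arm shorter than `min_arm_bins` are
#' excluded from the genome mean.
#'
#' @param cm a balanced [contact_matrix()].
#' @param centromeres data.frame `chrom`, `bin` (global id) as from
#'   [infer_centromeres()].
#' @param min_arm_bins minimum bins per arm (default 5).
#' @return list: `per_chrom` (data.frame `chrom`, `ssd`, `n_pairs`,
#'   `included`), `genome` (mean SSD over included chromosomes),
#'   `scores` (per-bin PC1/PC2).
#' @export
rabl_ssd <- function(cm, centromeres, min_arm_bins = 5) {
  if (is.null(cm$balanced)) cm <- balance_matrix(cm)
  sc <- .profile_scores(cm)
  chrom <- cm$bins$chrom
  rows <- lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    cb <- centromeres$bin[centromeres$chrom == ch]
    if (!length(cb) || is.na(cb))
      return(data.frame(chrom = ch, ssd = NA_real_, n_pairs = 0L,
                        included = FALSE))
    ci <- match(cb, idx)
    p <- rev(idx[seq_len(ci - 1)])        # away from centromere
    q <- idx[(ci + 1):length(idx)]
    np <- min(length(p), length(q))
    if (length(p) < min_arm_bins || length(q) < min_arm_bins)
      return(data.frame(chrom = ch, ssd = NA_real_, n_pairs = np,
                        included = FALSE))
    d2 <- rowSums((sc[p[seq_len(np)], , drop = FALSE] -
                     sc[q[seq_len(np)], , drop = FALSE])^2)
    data.frame(chrom = ch, ssd = mean(d2, na.rm = TRUE), n_pairs = np,
               included = TRUE)
  })
  per <- do.call(rbind, rows)
  list(per_chrom = per, genome = mean(per$ssd[per$included]), scores = sc)
}

#' Centromere-to-telomere-polar contact enrichment (CTP)
#'
#' Each bin gets a polar coordinate `u` in [0, 1] (0 at its centromere, 1 at
#' its telomere, within its arm). For a chromosome pair the CTP is the mean
#' balanced inter-chromosomal contact among bin pairs with `|u_i - u_j| <=
#' w` divided by the mean among pairs with `|u_i - u_j| > w`; CTP > 1
#' indicates polarized (Rabl-like) alignment of arms.
#'
#' @param cm a balanced [contact_matrix()].
#' @param centromeres data.frame `chrom`, `bin`.
#' @param w polar window on `u` (default 0.2).
#' @return list: `per_pair` (data.frame `chrom1`, `chrom2`, `ctp`), `genome`
#'   (mean over pairs), `u` (per-bin polar coordinate).
#' @export
rabl_ctp <- function(cm, centromeres, w = 0.2) {
  if (is.null(cm$balanced)) cm <- balance_matrix(cm)
  chrom <- cm$bins$chrom
  u <- rep(NA_real_, nrow(cm$bins))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cb <- centromeres$bin[centromeres$chrom == ch]
    if (!length(cb) || is.na(cb)) next
    ci <- match(cb, idx)
    pos <- seq_along(idx)
    arm_p <- ci - 1; arm_q <- length(idx) - ci
    u[idx] <- ifelse(pos < ci, (ci - pos) / max(arm_p, 1),
                     ifelse(pos > ci, (pos - ci) / max(arm_q, 1), 0))
  }
  B <- cm$balanced
  chroms <- unique(chrom)
  pairs <- utils::combn(chroms, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- which(chrom == pr[1] & !is.na(u))
    j <- which(chrom == pr[2] & !is.na(u))
    du <- abs(outer(u[i], u[j], "-"))
    sub <- B[i, j, drop = FALSE]
    near <- mean(sub[du <= w], na.rm = TRUE)
    far <- mean(sub[du > w], na.rm = TRUE)
    data.frame(chrom1 = pr[1], chrom2 = pr[2], ctp = near / far,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_pair = per, genome = mean(per$ctp, na.rm = TRUE), u = u)
}

#' Permutation test by within-chromosome circular rotation
#'
#' Builds the null by circularly rotating bin order within each chromosome
#' (preserving the distance-decay and marginal structure while destroying
#' arm alignment), recomputing the statistic each time. One-sided p-value
#' `(1 + #{null >= observed}) / (n + 1)` (or `<=` for
#' `alternative = "less"`).
#'
#' @param statistic function taking a `contact_matrix` and returning a
#'   scalar.
#' @param cm a [contact_matrix()] (balanced matrices are re-used: the
#'   rotation permutes bins of counts, weights and balanced entries).
#' @param n number of permutations (default 10000).
#' @param alternative "greater" (default) or "less".
#' @param seed integer seed.
#' @return list: `observed`, `p`, `null` (numeric vector).
#' @export
permutation_test <- function(statistic, cm, n = 10000,
                             alternative = c("greater", "less"),
                             seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic(cm)
  chrom <- cm$bins$chrom
  null <- vapply(seq_len(n), function(i) {
    perm <- seq_along(chrom)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      s <- sample.int(length(idx), 1) - 1L
      perm[idx] <- idx[((seq_along(idx) + s - 1L) %% length(idx)) + 1L]
    }
    pm <- cm
    pm$counts <- cm$counts[perm, perm]
    if (!is.null(cm$balanced)) pm$balanced <- cm$balanced[perm, perm]
    if (!is.null(cm$weights)) pm$weights <- cm$weights[perm]
    statistic(pm)
  }, numeric(1))
  p <- if (alternative == "greater") (1 + sum(null >= obs)) / (n + 1)
       else (1 + sum(null <= obs)) / (n + 1)
  list(observed = obs, p = p, null = null)
}

#' Inter-chromosomal arm-concordance enrichment (pp+qq vs pq)
#'
#' Classifies inter-chromosomal contacts by whether the two bins sit on
#' concordant arms (p-p or q-q) or discordant arms (p-q). The expectation
#' under arm-independence comes from arm marginal contact sums
#' (`expect = "marginals"`, the standard contingency-table expectation,
#' default) or from products of per-chromosome arm bin counts
#' (`expect = "bins"`). Reports the observed/expected ratio for the
#' concordant class and the 2-cell chi-square (df = 1).
#'
#' @param cm a [contact_matrix()] (raw counts are used).
#' @param centromeres data.frame `chrom`, `bin`.
#' @param expect expectation mode.
#' @return list: `ratio`, `chisq`, `df`, `p`, `n` (total inter contacts),
#'   `observed`, `expected` (2-vectors: concordant, discordant).
#' @export
interarm_enrichment <- function(cm, centromeres,
                                expect = c("marginals", "bins")) {
  expect <- match.arg(expect)
  chrom <- cm$bins$chrom
  arm <- rep(NA_character_, nrow(cm$bins))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cb <- centromeres$bin[centromeres$chrom == ch]
    ci <- match(cb, idx)
    arm[idx] <- ifelse(seq_along(idx) < ci, "p", "q")
    arm[idx[ci]] <- NA  # centromere bin belongs to neither arm
  }
  M <- cm$counts
  chroms <- unique(chrom)
  obs <- c(conc = 0, disc = 0); exp_ <- c(conc = 0, disc = 0)
  for (a in seq_along(chroms)[-length(chroms)])
    for (b in (a + 1):length(chroms)) {
      i <- which(chrom == chroms[a] & !is.na(arm))
      j <- which(chrom == chroms[b] & !is.na(arm))
      sub <- M[i, j, drop = FALSE]
      conc <- outer(arm[i], arm[j], "==")
      tot <- sum(sub)
      obs["conc"] <- obs["conc"] + sum(sub[conc])
      obs["disc"] <- obs["disc"] + sum(sub[!conc])
      if (expect == "bins") {
        np1 <- sum(arm[i] == "p"); nq1 <- sum(arm[i] == "q")
        np2 <- sum(arm[j] == "p"); nq2 <- sum(arm[j] == "q")
        pc <- (np1 * np2 + nq1 * nq2) / (length(i) * length(j))
      } else {
        rp <- rowSums(sub)[arm[i] == "p"]; rq <- rowSums(sub)[arm[i] == "q"]
        cp <- colSums(sub)[arm[j] == "p"]; cq <- colSums(sub)[arm[j] == "q"]
        pc <- (sum(rp) * sum(cp) + sum(rq) * sum(cq)) / tot^2
        if (!is.finite(pc)) pc <- 0.5
      }
      exp_["conc"] <- exp_["conc"] + tot * pc
      exp_["disc"] <- exp_["disc"] + tot * (1 - pc)
    }
  chisq <- sum((obs - exp_)^2 / exp_)
  list(ratio = obs["conc"] / exp_["conc"], chisq = chisq, df = 1,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE), n = sum(obs),
       observed = obs, expected = exp_)
}

#' Chromosome-territory enrichment
#'
#' Builds the K x K inter-chromosomal contact table, computes expectations
#' under independence from the marginal totals (restricted to off-diagonal
#' cells, which are the only observable ones), and reports the normalized
#' enrichment `C/E`, the global chi-square with df `(K-1)^2`, and per-pair
#' standardized residual tests corrected by Hochberg step-up.
#'
#' @param cm a [contact_matrix()] (raw counts).
#' @return list: `table` (K x K counts), `expected`, `enrichment`, `chisq`,
#'   `df`, `n`, `p`, `pairs` (data.frame with per-pair residual `z`, raw and
#'   Hochberg-adjusted p).
#' @export
territory_enrichment <- function(cm) {
  chrom <- cm$bins$chrom
  chroms <- unique(chrom)
  K <- length(chroms)
  C <- matrix(0, K, K, dimnames = list(chroms, chroms))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) next
    C[a, b] <- sum(cm$counts[chrom == chroms[a], chrom == chroms[b]])
  }
  n <- sum(C)
  # quasi-independence expectation: the diagonal is structurally zero, so a
  # raw marginal product is biased; iterative proportional fitting matches
  # the observed marginals exactly on the off-diagonal cells
  marg <- rowSums(C)
  E <- outer(marg, marg) / n
  diag(E) <- 0
  for (it in 1:200) {
    r <- marg / rowSums(E)
    E <- E * outer(sqrt(r), sqrt(r))
    diag(E) <- 0
    if (max(abs(rowSums(E) - marg) / marg) < 1e-10) break
  }
  enr <- C / E
  diag(enr) <- NA
  off <- upper.tri(C)
  chisq <- sum(((C - E)^2 / E)[off | lower.tri(C)])
  df <- (K - 1)^2
  z <- (C - E) / sqrt(E)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  pairs <- data.frame(chrom1 = chroms[idx[, 1]], chrom2 = chroms[idx[, 2]],
                      observed = C[idx], expected = E[idx],
                      enrichment = enr[idx], z = z[idx])
  pairs$p <- 2 * stats::pnorm(-abs(pairs$z))
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "hochberg")
  list(table = C, expected = E, enrichment = enr, chisq = chisq, df = df,
       n = n, p = stats::pchisq(chisq, df, lower.tail = FALSE),
       pairs = pairs)
}

#' Concordance of two centromere call sets
#'
#' @param calls_a,calls_b data.frames with `chrom`, `start`, `end` (bp).
#' @param tolerance_bp maximum midpoint difference for concordance.
#' @return data.frame: `chrom`, `mid_a`, `mid_b`, `diff_bp`, `concordant`.
#' @export
centromere_concordance <- function(calls_a, calls_b, tolerance_bp) {
  ch <- intersect(calls_a$chrom, calls_b$chrom)
  out <- do.call(rbind, lapply(ch, function(c0) {
    a <- calls_a[calls_a$chrom == c0, ][1, ]
    b <- calls_b[calls_b$chrom == c0, ][1, ]
    ma <- (a$start + a$end) / 2; mb <- (b$start + b$end) / 2
    data.frame(chrom = c0, mid_a = ma, mid_b = mb, diff_bp = abs(ma - mb),
               concordant = abs(ma - mb) <= tolerance_bp,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
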