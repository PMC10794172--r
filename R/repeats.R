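#' Tandem-repeat monomer clustering and landscape statistics
#'
#' Tandem-array monomers are reported with arbitrary rotational phase, so
#' clustering works on dimers: each candidate is aligned against the
#' head-to-tail duplication of a cluster representative, which makes the
#' comparison rotation-invariant. Greedy centroid clustering joins a monomer
#' to the first cluster whose representative it matches at >= `identity`
#' over >= `coverage` of its length.
#'
#' @name repeats
NULL

# rotation-invariant identity and coverage of monomer a against monomer b:
# local alignment of a within the dimer of b
.dimer_align <- function(a, b) {
  dimer <- Biostrings::DNAString(paste0(b, b))
  best <- NULL
  for (q in c(a, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(a))))) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), dimer, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 2, gapExtension = 1)
    cand <- list(identity = Biostrings::nmatch(al) /
                   max(1, Biostrings::nchar(Biostrings::pattern(al))),
                 coverage = Biostrings::nchar(Biostrings::pattern(al)) /
                   nchar(a))
    if (is.null(best) || cand$identity * cand$coverage >
        best$identity * best$coverage) best <- cand
  }
  best
}

#' Cluster tandem-repeat monomers into a non-redundant database
#'
#' Greedy centroid clustering on dimerized representatives (rotation
#' invariant, both strands). Input order is fixed to length-descending then
#' lexicographic, so the result is deterministic. The cluster representative
#' reported at the end is the member whose length equals the modal member
#' length (first such member).
#'
#' @param monomers named character vector of monomer sequences (> 10 bp).
#' @param identity minimum fractional identity (default 0.75).
#' @param coverage minimum fractional alignment coverage (default 0.45).
#' @return data.frame: `monomer` (name), `cluster` (integer id),
#'   `representative` (name), `rep_seq`.
#' @export
build_monomer_db <- function(monomers, identity = 0.75, coverage = 0.45) {
  if (!length(monomers))
    return(data.frame(monomer = character(0), cluster = integer(0),
                      representative = character(0), rep_seq = character(0)))
  if (any(nchar(monomers) <= 10)) stop("monomers must be > 10 bp")
  if (is.null(names(monomers)))
    names(monomers) <- sprintf("m%04d", seq_along(monomers))
  ord <- order(-nchar(monomers), names(monomers))
  monomers <- monomers[ord]
  centroid <- character(0)   # seed sequence per cluster
  assign <- integer(length(monomers))
  for (i in seq_along(monomers)) {
    hit <- 0L
    for (k in seq_along(centroid)) {
      al <- .dimer_align(monomers[[i]], centroid[[k]])
      if (al$identity >= identity && al$coverage >= coverage) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      centroid <- c(centroid, monomers[[i]])
      hit <- length(centroid)
    }
    assign[i] <- hit
  }
  out <- data.frame(monomer = names(monomers), cluster = assign,
                    stringsAsFactors = FALSE)
  reps <- vapply(split(seq_along(monomers), assign), function(idx) {
    lens <- nchar(monomers[idx])
    tl <- table(lens)
    modal <- as.numeric(names(tl)[which.max(tl)])
    idx[lens == modal][1]
  }, numeric(1))
  out$representative <- names(monomers)[reps[out$cluster]]
  out$rep_seq <- unname(monomers[reps[out$cluster]])
  rownames(out) <- NULL
  out
}

#' Regional footprint enrichment of monomer clusters
#'
#' For each cluster, the density of its tandem-array footprint inside the
#' region of interest divided by its density over the rest of the genome
#' (with a 1-bp pseudocount on the rest footprint), ranked descending.
#'
#' @param footprints data.frame `cluster`, `roi_bp`, `rest_bp` (footprint bp
#'   inside and outside the region of interest); or computed from `arrays`
#'   (BED-like, with a `cluster` column) and `roi` intervals via
#'   [cluster_footprints()].
#' @param roi_len,rest_len total bp of the region of interest and the rest.
#' @return data.frame sorted by decreasing `enrichment`.
#' @export
region_enrichment <- function(footprints, roi_len, rest_len) {
  enr <- (footprints$roi_bp / roi_len) /
    ((footprints$rest_bp + 1) / rest_len)
  out <- cbind(footprints, enrichment = enr)
  out <- out[order(-out$enrichment), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-cluster footprints inside/outside a region set
#'
#' @param arrays BED-like data.frame `chrom`, `start`, `end`, `cluster`.
#' @param roi data.frame `chrom`, `start`, `end` regions of interest.
#' @return data.frame `cluster`, `roi_bp`, `rest_bp`.
#' @export
cluster_footprints <- function(arrays, roi) {
  ov <- numeric(nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    r <- roi[roi$chrom == arrays$chrom[i], , drop = FALSE]
    if (nrow(r)) {
      ir <- IRanges::IRanges(r$start + 1, r$end)
      ia <- IRanges::IRanges(arrays$start[i] + 1, arrays$end[i])
      ov[i] <- sum(IRanges::width(IRanges::pintersect(
        IRanges::findOverlapPairs(ia, IRanges::reduce(ir)))))
    }
  }
  len <- arrays$end - arrays$start
  agg <- stats::aggregate(cbind(roi_bp = ov, rest_bp = len - ov),
                          by = list(cluster = arrays$cluster), FUN = sum)
  agg
}

#' Jukes-Cantor distance
#'
#' `-(3/4) * log(1 - 4p/3)` for a mismatch fraction `p < 0.75`; used to age
#' repeat copies against their consensus.
#'
#' @param p mismatch fraction(s) in `[0, 0.75)`.
#' @return JC distance(s).
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("JC distance is undefined for p outside [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Tetramer enrichment in tandem vs background sequence
#'
#' Counts motif occurrences per kb (both strands by default) in the tandem
#' and background sequence sets and reports the ratio with a pseudocount of
#' one occurrence on each side. Motifs absent from the tandem set are
#' flagged `absent`.
#'
#' @param tandem,background character vectors of sequences.
#' @param motifs motifs to test (default TGGG, AGGG, ACAG).
#' @param both_strands also count on the reverse complement (default TRUE).
#' @return data.frame: `motif`, `tandem_per_kb`, `background_per_kb`,
#'   `enrichment`, `absent`.
#' @export
tetramer_enrichment <- function(tandem, background,
                                motifs = c("TGGG", "AGGG", "ACAG"),
                                both_strands = TRUE) {
  count_set <- function(seqs, motif) {
    ss <- Biostrings::DNAStringSet(seqs)
    n <- sum(Biostrings::vcountPattern(motif, ss))
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
      n <- n + sum(Biostrings::vcountPattern(rc, ss))
    }
    n
  }
  kb_t <- sum(nchar(tandem)) / 1e3
  kb_b <- sum(nchar(background)) / 1e3
  out <- do.call(rbind, lapply(motifs, function(m) {
    nt <- count_set(tandem, m); nb <- count_set(background, m)
    data.frame(motif = m, tandem_per_kb = nt / kb_t,
               background_per_kb = nb / kb_b,
               enrichment = if (nt == 0 && nb == 0) NA_real_ else
                 ((nt + 1) / kb_t) / ((nb + 1) / kb_b),
               absent = nt == 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Binned feature density
#'
#' Sliding-window densities: for interval annotations, overlap bp per
#' window; for a sequence, GC fraction per window. Window/step default to
#' the repeat-density setting (1 Mb / 200 kb); GC uses 1 Mb / 50 kb and gene
#' density 250 kb / 12.5 kb in the published landscape settings.
#'
#' @param x either a data.frame of intervals (`start`, `end`, bp within one
#'   chromosome) or a single character DNA sequence.
#' @param chrom_length chromosome length in bp (inferred from the sequence).
#' @param window,step window geometry in bp.
#' @return data.frame `start`, `end`, `value` (overlap bp or GC fraction).
#' @export
binned_density <- function(x, chrom_length = NULL, window = 1e6,
                           step = 2e5) {
  if (is.character(x) && length(x) == 1) {
    L <- nchar(x)
    gc <- as.integer(strsplit(chartr("ACGT", "0110", toupper(x)), "")[[1]])
    cums <- c(0, cumsum(gc))
    starts <- seq(0, max(0, L - window), by = step)
    ends <- pmin(starts + window, L)
    val <- (cums[ends + 1] - cums[starts + 1]) / (ends - starts)
    return(data.frame(start = starts, end = ends, value = val))
  }
  if (is.null(chrom_length)) stop("chrom_length required for intervals")
  L <- chrom_length
  starts <- seq(0, max(0, L - window), by = step)
  ends <- pmin(starts + window, L)
  iv <- IRanges::reduce(IRanges::IRanges(x$start + 1, x$end))
  wins <- IRanges::IRanges(starts + 1, ends)
  hits <- IRanges::findOverlapPairs(wins, iv)
  ovl <- IRanges::width(IRanges::pintersect(hits))
  qi <- S4Vectors::queryHits(IRanges::findOverlaps(wins, iv))
  val <- numeric(length(starts))
  agg <- tapply(ovl, qi, sum)
  val[as.integer(names(agg))] <- agg
  data.frame(start = starts, end = ends, value = val)
}

#' PCA of a density matrix and correlation with a compartment track
#'
#' Columns (features) are standardized and decomposed; each component's
#' per-bin scores are smoothed with a cubic smoothing spline and correlated
#' against a supplied per-bin compartment sign track.
#'
#' @param density matrix or data.frame, bins x features.
#' @param compartment_track optional numeric per-bin track (e.g. signed A/B
#'   loadings).
#' @param n_components number of components to return.
#' @return list: `scores` (bins x components), `smoothed`, `loadings`,
#'   `correlations` (per component vs track, or NULL).
#' @export
density_pca <- function(density, compartment_track = NULL,
                        n_components = 3) {
  X <- as.matrix(density)
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  sm <- apply(sc, 2, function(v) {
    if (length(v) > 10)
      stats::smooth.spline(seq_along(v), v)$y
    else v
  })
  cors <- NULL
  if (!is.null(compartment_track)) {
    cors <- apply(sc, 2, function(v)
      suppressWarnings(stats::cor(v, compartment_track,
                                  use = "pairwise.complete.obs")))
  }
  list(scores = sc, smoothed = sm, loadings = pc$rotation[, seq_len(k)],
       correlations = cors, sdev = pc$sdev)
}
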