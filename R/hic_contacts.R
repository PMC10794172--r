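#' Binned Hi-C contact matrices
#'
#' A `contact_matrix` couples a bin table (chrom, start, end, bin id; bins
#' tile each chromosome without overlap) with a symmetric count matrix at a
#' fixed bin size, plus optional balancing weights and a model expectation
#' matrix (populated by the simulator).
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`, `bin`
#'   (1-based consecutive ids in row order).
#' @param counts symmetric numeric matrix, `nrow(bins)` square, counts >= 0.
#' @param bin_size bin size in bp.
#' @param weights optional balancing weight per bin (NA where masked).
#' @param expected optional expectation matrix (same shape as `counts`).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, counts, bin_size, weights = NULL,
                           expected = NULL) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "bin") %in% names(bins)),
            nrow(counts) == nrow(bins), ncol(counts) == nrow(bins))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8) stop("counts must be symmetric")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (any(b$end <= b$start)) stop("empty or inverted bin on ", ch)
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping bins on ", ch)
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      stop("bins do not tile chromosome ", ch)
  }
  structure(list(bins = bins, counts = counts, bin_size = bin_size,
                 weights = weights, expected = expected),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$bins), "bins,",
      length(unique(x$bins$chrom)), "chromosomes, bin size", x$bin_size,
      "bp, total counts", sum(x$counts[upper.tri(x$counts, diag = TRUE)]),
      "\n")
  invisible(x)
}

#' Read a contact matrix from a bins + triplets TSV pair
#'
#' `bins_file` has columns `chrom`, `start`, `end`, `bin`; `triplets_file`
#' has `bin1`, `bin2`, `count`. Upper-triangle input is symmetrized; if both
#' triangles are present they must agree.
#'
#' @param bins_file,triplets_file file paths.
#' @param bin_size bin size in bp; inferred from the bin table when `NULL`.
#' @return a [contact_matrix()].
#' @export
load_contacts <- function(bins_file, triplets_file, bin_size = NULL) {
  bins <- utils::read.table(bins_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  trip <- utils::read.table(triplets_file, header = TRUE, sep = "\t")
  n <- nrow(bins)
  if (is.null(bin_size)) bin_size <- max(bins$end - bins$start)
  m <- matrix(0, n, n)
  m[cbind(trip$bin1, trip$bin2)] <- trip$count
  low <- m[lower.tri(m)]
  upt <- t(m)[lower.tri(m)]
  both <- low > 0 & upt > 0
  if (any(both) && any(low[both] != upt[both]))
    stop("triplets present in both triangles disagree")
  m <- pmax(m, t(m))
  contact_matrix(bins, m, bin_size)
}

#' Write a contact matrix as a bins + triplets TSV pair
#'
#' Writes the upper triangle (including diagonal) of non-zero counts.
#'
#' @param cm a [contact_matrix()].
#' @param prefix output path prefix; writes `<prefix>.bins.tsv` and
#'   `<prefix>.triplets.tsv`.
#' @return invisibly, the two paths.
#' @export
write_contacts <- function(cm, prefix) {
  bf <- paste0(prefix, ".bins.tsv")
  tf <- paste0(prefix, ".triplets.tsv")
  utils::write.table(cm$bins, bf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts > 0,
               arr.ind = TRUE)
  trip <- data.frame(bin1 = idx[, 1], bin2 = idx[, 2],
                     count = cm$counts[idx])
  utils::write.table(trip, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bf, tf))
}

#' Bin a genome layout
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin size in bp.
#' @return bin table with per-bin geometry: `chrom`, `start`, `end`, `bin`,
#'   `mid`, `arm` ("p"/"q"), `d_cen` (bp to centromere), `d_tel` (bp to the
#'   telomere of the bin's own arm), `arm_len`, `u` (relative arm position in
#'   `[0, 1]`, 0 at the centromere).
#' @export
make_bins <- function(layout, bin_size) {
  if (bin_size <= 0) stop("bin size must be positive")
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]; cen <- layout$centromere[i]
    starts <- seq(0, L - 1, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    mid <- (starts + ends) / 2
    arm <- ifelse(mid < cen, "p", "q")
    d_cen <- abs(mid - cen)
    d_tel <- ifelse(arm == "p", mid, L - mid)
    arm_len <- ifelse(arm == "p", cen, L - cen)
    data.frame(chrom = layout$chrom[i], start = starts, end = ends,
               mid = mid, arm = arm, d_cen = d_cen, d_tel = d_tel,
               arm_len = arm_len, u = pmin(1, d_cen / arm_len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bin <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "bin", "mid", "arm", "d_cen", "d_tel",
          "arm_len", "u")]
}
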