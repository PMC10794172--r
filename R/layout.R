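#' Genome layout: chromosomes, lengths and centromere positions
#'
#' A genome layout is the minimal karyotype description used throughout the
#' package: one row per chromosome with its length and centromere position
#' (both bp, 0-based half-open coordinates). Arms and region classes
#' (subtelomere, arm interior, pericentromere) are derived from it.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer-ish vector of chromosome lengths in bp.
#' @param centromere centromere positions in bp, strictly inside `(0, length)`.
#' @return A `data.frame` of class `genome_layout` with columns `chrom`,
#'   `length`, `centromere`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(200e6, 150e6), c(90e6, 30e6))
#' @export
genome_layout <- function(chrom, length, centromere) {
  stopifnot(!anyDuplicated(chrom), base::length(chrom) == base::length(length),
            base::length(chrom) == base::length(centromere))
  length <- as.numeric(length)
  centromere <- as.numeric(centromere)
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (any(centromere <= 0 | centromere >= length))
    stop("centromeres must lie strictly inside (0, length)")
  out <- data.frame(chrom = as.character(chrom), length = length,
                    centromere = centromere, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Chromosome arms of a layout
#'
#' @param layout a [genome_layout()].
#' @return data.frame with one row per arm: `chrom`, `arm` ("p"/"q"),
#'   `start`, `end` (0-based half-open; p = `[0, centromere)`,
#'   q = `[centromere, length)`).
#' @export
layout_arms <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  rbind(
    data.frame(chrom = layout$chrom, arm = "p", start = 0,
               end = layout$centromere, stringsAsFactors = FALSE),
    data.frame(chrom = layout$chrom, arm = "q", start = layout$centromere,
               end = layout$length, stringsAsFactors = FALSE)
  )
}

#' Region classes along chromosomes
#'
#' Partitions each chromosome into `subtelomere`, `arm` and `pericentromere`
#' intervals. Subtelomeres are the terminal `subtel_bp` of each chromosome;
#' on acrocentric chromosomes (centromere within `subtel_bp` of an end) the
#' `peri_excl_bp` window around the centromere is carved out of the
#' subtelomere. The pericentromere is `peri_bp` centred on the centromere.
#'
#' @param layout a [genome_layout()].
#' @param subtel_bp subtelomere extent from each chromosome end (default
#'   30 Mb, the extended-subtelomere scale of large frog chromosomes).
#' @param peri_bp pericentromere width centred on the centromere (default
#'   5 Mb).
#' @param peri_excl_bp half-width of the pericentromeric exclusion carved
#'   from acrocentric subtelomeres (default 7.5 Mb, i.e. a 15 Mb window).
#' @return data.frame `chrom`, `start`, `end`, `class` with non-overlapping
#'   intervals tiling each chromosome; `class` in
#'   `c("subtelomere", "arm", "pericentromere")`.
#' @export
layout_regions <- function(layout, subtel_bp = 30e6, peri_bp = 5e6,
                           peri_excl_bp = 7.5e6) {
  stopifnot(inherits(layout, "genome_layout"))
  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    L <- layout$length[i]; cen <- layout$centromere[i]
    ch <- layout$chrom[i]
    st <- min(subtel_bp, L / 2)
    acro <- min(cen, L - cen) < subtel_bp
    peri <- c(max(0, cen - peri_bp / 2), min(L, cen + peri_bp / 2))
    # candidate subtelomere windows at both ends
    subs <- rbind(c(0, st), c(L - st, L))
    if (acro) {
      excl <- c(max(0, cen - peri_excl_bp), min(L, cen + peri_excl_bp))
      subs <- do.call(rbind, apply(subs, 1, function(s) {
        .interval_setdiff(s, excl)
      }, simplify = FALSE))
    }
    # pericentromere always wins over any overlap
    subs <- do.call(rbind, apply(subs, 1, .interval_setdiff, b = peri,
                                 simplify = FALSE))
    pieces <- rbind(
      data.frame(start = peri[1], end = peri[2], class = "pericentromere"),
      if (!is.null(subs) && nrow(subs))
        data.frame(start = subs[, 1], end = subs[, 2], class = "subtelomere")
    )
    pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
    pieces <- pieces[order(pieces$start), , drop = FALSE]
    # fill remaining gaps with "arm"
    gaps <- .interval_complement(pieces[, c("start", "end")], L)
    if (nrow(gaps))
      pieces <- rbind(pieces, data.frame(start = gaps$start, end = gaps$end,
                                         class = "arm"))
    pieces <- pieces[order(pieces$start), , drop = FALSE]
    rows[[i]] <- data.frame(chrom = ch, pieces, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# interval a minus interval b; returns 0-2 row matrix
.interval_setdiff <- function(a, b) {
  out <- NULL
  if (a[1] < min(a[2], b[1])) out <- rbind(out, c(a[1], min(a[2], b[1])))
  if (max(a[1], b[2]) < a[2]) out <- rbind(out, c(max(a[1], b[2]), a[2]))
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

# complement of a set of disjoint sorted intervals within [0, L)
.interval_complement <- function(iv, L) {
  iv <- iv[order(iv$start), , drop = FALSE]
  starts <- c(0, iv$end)
  ends <- c(iv$start, L)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Write / read a genome layout TSV
#'
#' @param layout a [genome_layout()].
#' @param path file path.
#' @return `read_layout` returns a [genome_layout()].
#' @export
write_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  genome_layout(d$chrom, d$length, d$centromere)
}
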