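#' Simulate tandem-repeat arrays and monomer sequences
#'
#' Plants tandem arrays of >= 5 copies of > 10 bp monomers on a genome
#' layout, with per-copy point mutations at a given divergence and regional
#' placement biased by per-monomer enrichment weights (e.g. a subtelomeric
#' satellite, a centromeric satellite, and uniform background families). The
#' reported monomer sequence of each array is a randomly rotated, mutated
#' copy, emulating the arbitrary phase of tandem-repeat-finder output.
#'
#' @param layout a [genome_layout()].
#' @param monomers named character vector of base monomer sequences
#'   (names are family ids); `NULL` draws `n_families` random monomers of
#'   length `monomer_len`.
#' @param divergence per-base substitution probability of array copies.
#' @param enrichment named list mapping family id to a named numeric vector
#'   of relative placement weights over region classes
#'   (`subtelomere`, `arm`, `pericentromere`); default uniform.
#' @param n_arrays total number of arrays.
#' @param copies_range integer range of copy numbers (min >= 5).
#' @param n_families,monomer_len used when `monomers` is `NULL`.
#' @param seed integer seed.
#' @return list with `arrays` (BED-like data.frame: `chrom`, `start`, `end`,
#'   `family`, `copies`, `monomer` [observed rotated sequence], `region`
#'   [true region class]) and `monomers` (the base sequences).
#' @export
simulate_tandem_annotations <- function(layout, monomers = NULL,
                                        divergence = 0.05,
                                        enrichment = NULL, n_arrays = 60,
                                        copies_range = c(5L, 30L),
                                        n_families = 4, monomer_len = 205,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (copies_range[1] < 5) stop("arrays must have >= 5 copies")
  bases <- c("A", "C", "G", "T")
  if (is.null(monomers)) {
    monomers <- vapply(seq_len(n_families), function(i)
      paste(sample(bases, monomer_len, replace = TRUE), collapse = ""),
      character(1))
    names(monomers) <- sprintf("fam%02d", seq_len(n_families))
  }
  if (any(nchar(monomers) <= 10)) stop("monomers must be > 10 bp")
  regions <- layout_regions(layout)
  regions$len <- regions$end - regions$start
  fams <- sample(names(monomers), n_arrays, replace = TRUE)
  rows <- vector("list", n_arrays)
  for (a in seq_len(n_arrays)) {
    fam <- fams[a]
    w <- c(subtelomere = 1, arm = 1, pericentromere = 1)
    if (!is.null(enrichment) && !is.null(enrichment[[fam]]))
      w[names(enrichment[[fam]])] <- enrichment[[fam]]
    rw <- regions$len * w[regions$class]
    ri <- sample.int(nrow(regions), 1, prob = rw)
    ncopy <- sample(copies_range[1]:copies_range[2], 1)
    width <- ncopy * nchar(monomers[[fam]])
    start <- floor(stats::runif(1, regions$start[ri],
                                max(regions$start[ri],
                                    regions$end[ri] - width)))
    obs <- .mutate_seq(.rotate_seq(monomers[[fam]],
                                   sample.int(nchar(monomers[[fam]]), 1) - 1L),
                       divergence)
    rows[[a]] <- data.frame(chrom = regions$chrom[ri], start = start,
                            end = start + width, family = fam,
                            copies = ncopy, monomer = obs,
                            region = regions$class[ri],
                            stringsAsFactors = FALSE)
  }
  arrays <- do.call(rbind, rows)
  list(arrays = arrays, monomers = monomers, divergence = divergence)
}

.rotate_seq <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

.mutate_seq <- function(s, p) {
  if (p <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(v)) < p
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1), "")
  }
  paste(v, collapse = "")
}

#' Observed per-copy divergence of simulated arrays
#'
#' Regenerates mutated copies of a monomer and returns mismatch fractions to
#' the original, for calibrating simulated divergence against Jukes-Cantor
#' expectations.
#'
#' @param monomer base sequence.
#' @param divergence per-base substitution probability.
#' @param n_copies number of copies.
#' @param seed integer seed.
#' @return numeric vector of mismatch fractions.
#' @export
simulate_copy_divergence <- function(monomer, divergence, n_copies = 100,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- strsplit(monomer, "")[[1]]
  vapply(seq_len(n_copies), function(i) {
    mean(strsplit(.mutate_seq(monomer, divergence), "")[[1]] != ref)
  }, numeric(1))
}
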