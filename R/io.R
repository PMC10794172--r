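#' Tabular writers and readers for pipeline inputs/outputs
#'
#' Plain-TSV serializers for ortholog tables, BED intervals and FASTA
#' monomers, used by the analysis drivers.
#'
#' @name io
NULL

#' @param table ortholog table.
#' @param path file path.
#' @rdname io
#' @export
write_orthologs <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_orthologs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   name/score columns.
#' @rdname io
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param seqs named character vector of sequences.
#' @rdname io
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
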