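#' Ancestral syntenic elements from cross-species ortholog placements
#'
#' An ortholog table has one row per one-to-one ortholog with, for each
#' species `sp`, columns `<sp>.chrom` and `<sp>.pos`. Elements are inferred
#' in two stages: strict chromosome-signature clustering, then merging of
#' cluster pairs whose root state is reconstructed as "together" (same
#' chromosome) by two-state Fitch parsimony on the species tree.
#'
#' @name synteny
NULL

.ortho_species <- function(table) {
  sub("\\.chrom$", "", grep("\\.chrom$", names(table), value = TRUE))
}

.signature <- function(table, species) {
  do.call(paste, c(lapply(species, function(sp) table[[paste0(sp, ".chrom")]]),
                   sep = "|"))
}

#' Remove stray orthologs
#'
#' Drops genes whose cross-species chromosome signature is shared by fewer
#' than `m` genes; such isolated placements are treated as ortholog-calling
#' or assembly noise.
#'
#' @param table ortholog table.
#' @param m minimum signature support (default 3).
#' @return filtered table, with attribute `removed` listing dropped genes.
#' @export
filter_stray_orthologs <- function(table, m = 3) {
  sp <- .ortho_species(table)
  sig <- .signature(table, sp)
  n <- table(sig)[sig]
  keep <- as.vector(n) >= m
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- table$gene[!keep]
  out
}

#' Collinear runs between a species pair
#'
#' Finds maximal runs of genes that lie on one chromosome in each species
#' with consistent order (either orientation). Collinearity is assessed on
#' gene ranks within each chromosome pair, so the result is independent of
#' assembly scale. Runs shorter than `min_run` genes are dropped. A rank gap
#' of up to `max_gap` intervening genes is tolerated within a run.
#'
#' @param table ortholog table.
#' @param sp1,sp2 species names (must match `<sp>.chrom` columns).
#' @param min_run minimum run size in genes (default 3).
#' @param max_gap maximum tolerated rank gap (default 5).
#' @return data.frame: `run`, `chrom1`, `chrom2`, `n_genes`, `orientation`
#'   (+1/-1), `genes` (comma-separated ids).
#' @export
collinear_runs <- function(table, sp1, sp2, min_run = 3, max_gap = 5) {
  for (sp in c(sp1, sp2))
    if (!paste0(sp, ".chrom") %in% names(table))
      stop("species absent from table: ", sp)
  c1 <- table[[paste0(sp1, ".chrom")]]; p1 <- table[[paste0(sp1, ".pos")]]
  c2 <- table[[paste0(sp2, ".chrom")]]; p2 <- table[[paste0(sp2, ".pos")]]
  runs <- list()
  for (ch1 in unique(c1)) for (ch2 in unique(c2[c1 == ch1])) {
    idx <- which(c1 == ch1 & c2 == ch2)
    if (length(idx) < min_run) next
    idx <- idx[order(p1[idx])]
    r2 <- rank(p2[idx])
    start <- 1; dir <- 0
    flush <- function(a, b, dir) {
      if (b - a + 1 >= min_run)
        runs[[length(runs) + 1]] <<- data.frame(
          chrom1 = ch1, chrom2 = ch2, n_genes = b - a + 1,
          orientation = dir,
          genes = paste(table$gene[idx[a:b]], collapse = ","),
          stringsAsFactors = FALSE)
    }
    for (i in seq_along(idx)[-1]) {
      step <- r2[i] - r2[i - 1]
      ok <- abs(step) <= max_gap + 1 &&
        (dir == 0 || sign(step) == dir)
      if (ok) {
        if (dir == 0) dir <- sign(step)
      } else {
        flush(start, i - 1, if (dir == 0) 1 else dir)
        start <- i; dir <- 0
      }
    }
    flush(start, length(idx), if (dir == 0) 1 else dir)
  }
  if (!length(runs))
    return(data.frame(run = integer(0), chrom1 = character(0),
                      chrom2 = character(0), n_genes = integer(0),
                      orientation = integer(0), genes = character(0)))
  out <- do.call(rbind, runs)
  out <- cbind(run = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# two-state parsimony root state (Sankoff min-change costs; handles
# multifurcations, so reconstruction on an unrooted/trifurcating-root tree
# is exact); states are 1/2; returns "1", "2" or "both" on a tie
.fitch_root <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  cost <- matrix(Inf, nn, 2)
  for (i in seq_len(ntip)) {
    s <- tip_states[tree$tip.label[i]]
    cost[i, ] <- c(if (s == 1L) 0 else Inf, if (s == 2L) 0 else Inf)
  }
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  done <- logical(nn)
  done[seq_len(ntip)] <- TRUE
  repeat {
    todo <- which(!done)
    if (!length(todo)) break
    progressed <- FALSE
    for (node in todo) {
      ch <- kids[[as.character(node)]]
      if (is.null(ch) || !all(done[ch])) next
      for (st in 1:2) {
        other <- 3 - st
        cost[node, st] <- sum(pmin(cost[ch, st], cost[ch, other] + 1))
      }
      done[node] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) stop("tree traversal failed")
  }
  root <- ntip + 1L
  if (cost[root, 1] < cost[root, 2]) "1"
  else if (cost[root, 2] < cost[root, 1]) "2"
  else "both"
}

#' Infer ancestral syntenic elements
#'
#' Stage 1 groups genes with identical cross-species chromosome signatures.
#' Stage 2 reconstructs, for every pair of signature clusters, the root
#' state of the binary together/apart character (same chromosome or not in
#' each species) by Fitch parsimony on the species tree; pairs unambiguously
#' "together" at the root are merged (ties resolved as "apart" so that
#' merging stays conservative). Connected components of the merge graph are
#' the ancestral elements, labelled in the order of the reference species'
#' chromosomes (falling back to size order).
#'
#' @param table filtered ortholog table (see [filter_stray_orthologs()]).
#' @param tree `ape::phylo` whose tip labels are the table's species.
#' @param ref_species reference species used to order and label elements;
#'   default the first species.
#' @return list of class `element_assignment`: `elements` (data.frame
#'   `gene`, `element`), `n_elements`, `clusters` (signature-cluster ids per
#'   gene), `labels` (element labels).
#' @export
infer_elements <- function(table, tree = NULL, ref_species = NULL) {
  sp <- .ortho_species(table)
  if (length(sp) == 1) {
    ele <- table[[paste0(sp, ".chrom")]]
    labs <- sort(unique(ele))
  } else {
    if (is.null(tree)) stop("a tree is required for >1 species")
    if (!setequal(tree$tip.label, sp))
      stop("tree leaves do not match table species")
    if (is.null(ref_species)) ref_species <- sp[1]
    sig <- .signature(table, sp)
    usig <- sort(unique(sig))
    k <- length(usig)
    cl <- match(sig, usig)
    # per-cluster chromosome per species
    first <- match(usig, sig)
    chmat <- sapply(sp, function(s) table[[paste0(s, ".chrom")]][first])
    chmat <- matrix(chmat, nrow = k,
                    dimnames = list(NULL, sp))
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        states <- stats::setNames(
          ifelse(chmat[i, sp] == chmat[j, sp], 1L, 2L), sp)
        root <- .fitch_root(tree, states)
        if (root == "1") {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(k), find, integer(1))
    ele_of_cluster <- match(comp, sort(unique(comp)))
    ele <- ele_of_cluster[cl]
    # label by reference species chromosome order (median gene position)
    refc <- table[[paste0(ref_species, ".chrom")]]
    refp <- table[[paste0(ref_species, ".pos")]]
    ord <- order(vapply(sort(unique(ele)), function(e) {
      ch <- names(sort(table(refc[ele == e]), decreasing = TRUE))[1]
      match(ch, sort(unique(refc))) * 1e12 +
        stats::median(refp[ele == e & refc == ch])
    }, numeric(1)))
    labs <- character(length(ord))
    labs[ord] <- if (length(ord) <= 26) LETTERS[seq_along(ord)] else
      sprintf("E%02d", seq_along(ord))
    ele <- labs[ele]
    labs <- labs[order(labs)]
    out <- list(elements = data.frame(gene = table$gene, element = ele,
                                      stringsAsFactors = FALSE),
                n_elements = length(unique(ele)), labels = labs,
                clusters = cl)
    class(out) <- "element_assignment"
    return(out)
  }
  out <- list(elements = data.frame(gene = table$gene, element = ele,
                                    stringsAsFactors = FALSE),
              n_elements = length(labs), labels = labs,
              clusters = match(ele, labs))
  class(out) <- "element_assignment"
  out
}

#' Fraction of orthologs conserved within their element
#'
#' A gene is conserved when, in every species, it lies on a chromosome that
#' hosts at least `min_support` genes of its own element in that species
#' (i.e. the gene travels with its element everywhere; isolated placements
#' break conservation).
#'
#' @param assignment an `element_assignment`.
#' @param table the ortholog table the assignment was computed from.
#' @param min_support minimum co-resident element genes (default 3).
#' @return fraction in `[0, 1]`.
#' @export
conservation_fraction <- function(assignment, table, min_support = 3) {
  sp <- .ortho_species(table)
  ele <- assignment$elements$element[match(table$gene,
                                           assignment$elements$gene)]
  ok <- rep(TRUE, nrow(table))
  for (s in sp) {
    ch <- table[[paste0(s, ".chrom")]]
    cnt <- table(ele, ch)
    ok <- ok & cnt[cbind(ele, ch)] >= min_support
  }
  mean(ok)
}

#' Per-species element proportions
#'
#' For each species and element, the fraction of total genome bp, gene count
#' and (optionally) repeat count attributable to the element, plus the
#' across-species coefficient of variation of each fraction. Chromosomes
#' hosting several elements split their bp/repeats between them in
#' proportion to element gene counts on that chromosome.
#'
#' @param assignment an `element_assignment`.
#' @param table ortholog table.
#' @param chrom_stats named list (by species) of data.frames with columns
#'   `chrom`, `bp` and optionally `repeats`.
#' @return data.frame: `species`, `element`, `frac_bp`, `frac_genes`,
#'   (`frac_repeats`); attribute `cv` holds per-element across-species CVs.
#' @export
element_proportions <- function(assignment, table, chrom_stats) {
  sp <- names(chrom_stats)
  ele <- assignment$elements$element[match(table$gene,
                                           assignment$elements$gene)]
  labs <- sort(unique(ele))
  rows <- list()
  for (s in sp) {
    ch <- table[[paste0(s, ".chrom")]]
    cs <- chrom_stats[[s]]
    gene_cnt <- table(factor(ele, labs), ch)
    chrom_tot <- colSums(gene_cnt)
    w <- sweep(gene_cnt, 2, pmax(chrom_tot, 1), "/")
    bp_by_chrom <- cs$bp[match(colnames(w), cs$chrom)]
    frac_bp <- as.vector(w %*% bp_by_chrom) / sum(cs$bp)
    frac_genes <- as.vector(rowSums(gene_cnt)) / length(ch)
    row <- data.frame(species = s, element = labs, frac_bp = frac_bp,
                      frac_genes = frac_genes, stringsAsFactors = FALSE)
    if (!is.null(cs$repeats)) {
      rp <- cs$repeats[match(colnames(w), cs$chrom)]
      row$frac_repeats <- as.vector(w %*% rp) / sum(cs$repeats)
    }
    rows[[s]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cv <- do.call(rbind, lapply(labs, function(e) {
    x <- out$frac_bp[out$element == e]
    data.frame(element = e,
               cv_bp = stats::sd(x) / mean(x),
               cv_genes = {
                 g <- out$frac_genes[out$element == e]
                 stats::sd(g) / mean(g)
               })
  }))
  attr(out, "cv") <- cv
  out
}
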