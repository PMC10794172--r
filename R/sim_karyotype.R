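#' Karyotype history simulation
#'
#' Simulates the evolution of a set of ancestral chromosomes ("elements")
#' along a dated phylogeny under per-type Poisson rearrangement processes:
#' Robertsonian fusions/fissions (breaks and joins at centromeres),
#' end-to-end fusions (joins at telomeric ends, one centromere silenced),
#' reciprocal translocations (mid-arm tail exchange) and inversions. Gene
#' content is conserved along every branch and each derived chromosome is a
#' concatenation of ancestral-element segments, so every simulated history
#' can be replayed exactly from its recorded event list.
#'
#' Internal chromosome representation: a list with `name`, `centromere`
#' (bp) and `segments`, a data.frame of `(element, start, end, strand)`
#' blocks in ancestral-element coordinates (0-based half-open).
#'
#' @name sim_karyotype
NULL

# ---- chromosome primitives -------------------------------------------------

.chrom_new <- function(name, element, length, centromere) {
  list(name = name, centromere = centromere,
       segments = data.frame(element = element, start = 0, end = length,
                             strand = "+", stringsAsFactors = FALSE))
}

.chrom_length <- function(ch) sum(ch$segments$end - ch$segments$start)

.chrom_flip <- function(ch) {
  L <- .chrom_length(ch)
  seg <- ch$segments[rev(seq_len(nrow(ch$segments))), , drop = FALSE]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  rownames(seg) <- NULL
  ch$segments <- seg
  ch$centromere <- L - ch$centromere
  ch
}

# split segments at chromosome coordinate pos; returns list(left, right)
# segment data.frames (without centromere bookkeeping)
.segments_split <- function(segments, pos) {
  offs <- cumsum(c(0, segments$end - segments$start))
  left <- NULL; right <- NULL
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, , drop = FALSE]
    w <- s$end - s$start
    a <- offs[i]; b <- offs[i] + w
    if (b <= pos) {
      left <- rbind(left, s)
    } else if (a >= pos) {
      right <- rbind(right, s)
    } else {
      cut <- pos - a
      s1 <- s; s2 <- s
      if (s$strand == "+") {
        s1$end <- s$start + cut
        s2$start <- s$start + cut
      } else {
        s1$start <- s$end - cut
        s2$end <- s$end - cut
      }
      left <- rbind(left, s1)
      right <- rbind(right, s2)
    }
  }
  list(left = left, right = right)
}

.chrom_concat <- function(name, ch1, ch2, centromere) {
  seg <- rbind(ch1$segments, ch2$segments)
  rownames(seg) <- NULL
  list(name = name, centromere = centromere, segments = seg)
}

# ---- events ----------------------------------------------------------------

#' Apply a rearrangement event to a chromosome set
#'
#' Replays one recorded event. Used both during simulation and when
#' replaying a stored history, so replay is exact by construction.
#'
#' @param chroms named list of chromosome objects.
#' @param ev an event list as produced by [simulate_karyotype_history()]
#'   (fields: `type`, plus type-specific replay fields).
#' @return the modified chromosome list.
#' @export
apply_event <- function(chroms, ev) {
  switch(ev$type,
    robertsonian_fusion = ,
    end_to_end_fusion = {
      c1 <- chroms[[ev$chrom1]]; c2 <- chroms[[ev$chrom2]]
      if (ev$flip1) c1 <- .chrom_flip(c1)
      if (ev$flip2) c2 <- .chrom_flip(c2)
      L1 <- .chrom_length(c1)
      cen <- if (ev$survivor == 1L) c1$centromere else L1 + c2$centromere
      new <- .chrom_concat(ev$child, c1, c2, cen)
      chroms[[ev$chrom1]] <- NULL
      chroms[[ev$chrom2]] <- NULL
      chroms[[ev$child]] <- new
      chroms
    },
    robertsonian_fission = {
      ch <- chroms[[ev$chrom]]
      L <- .chrom_length(ch)
      pos <- ev$position
      if (pos <= 0 || pos >= L)
        stop("fission break must be internal to the chromosome")
      sp <- .segments_split(ch$segments, pos)
      off <- ev$cen_offset
      left <- list(name = ev$child1, centromere = max(1, pos - off),
                   segments = sp$left)
      right <- list(name = ev$child2, centromere = min(L - pos - 1, off),
                    segments = sp$right)
      right$centromere <- max(1, right$centromere)
      chroms[[ev$chrom]] <- NULL
      chroms[[ev$child1]] <- left
      chroms[[ev$child2]] <- right
      chroms
    },
    reciprocal_translocation = {
      c1 <- chroms[[ev$chrom1]]; c2 <- chroms[[ev$chrom2]]
      sp1 <- .segments_split(c1$segments, ev$break1)
      sp2 <- .segments_split(c2$segments, ev$break2)
      n1 <- list(name = ev$child1, centromere = c1$centromere,
                 segments = rbind(sp1$left, sp2$right))
      n2 <- list(name = ev$child2, centromere = c2$centromere,
                 segments = rbind(sp2$left, sp1$right))
      chroms[[ev$chrom1]] <- NULL
      chroms[[ev$chrom2]] <- NULL
      chroms[[ev$child1]] <- n1
      chroms[[ev$child2]] <- n2
      chroms
    },
    inversion = {
      ch <- chroms[[ev$chrom]]
      spa <- .segments_split(ch$segments, ev$start)
      spb <- .segments_split(spa$right, ev$end - ev$start)
      mid <- spb$left[rev(seq_len(nrow(spb$left))), , drop = FALSE]
      mid$strand <- ifelse(mid$strand == "+", "-", "+")
      ch$segments <- rbind(spa$left, mid, spb$right)
      rownames(ch$segments) <- NULL
      if (ch$centromere >= ev$start && ch$centromere < ev$end)
        ch$centromere <- ev$start + (ev$end - ch$centromere)
      chroms[[ev$chrom]] <- ch
      chroms
    },
    stop("unknown event type: ", ev$type)
  )
}

#' Construct a fission event
#'
#' Robertsonian fissions break at the centromere. `at = "junction"` breaks
#' instead at an internal ancestral-segment junction and errors when the
#' chromosome is a single intact element with no internal junction.
#'
#' @param chroms chromosome list.
#' @param chrom chromosome name.
#' @param at `"centromere"` or `"junction"`.
#' @param new_names two names for the products.
#' @param cen_offset offset (bp) of the product centromeres from the broken
#'   end; products are acrocentric.
#' @return an event list suitable for [apply_event()].
#' @export
make_fission_event <- function(chroms, chrom, at = c("centromere", "junction"),
                               new_names, cen_offset = 1e6) {
  at <- match.arg(at)
  ch <- chroms[[chrom]]
  if (is.null(ch)) stop("no such chromosome: ", chrom)
  L <- .chrom_length(ch)
  pos <- if (at == "centromere") {
    ch$centromere
  } else {
    offs <- cumsum(ch$segments$end - ch$segments$start)
    internal <- offs[offs > 0 & offs < L]
    if (!length(internal))
      stop("chromosome ", chrom,
           " is a single element with no internal junction; cannot fission")
    internal[1]
  }
  list(type = "robertsonian_fission", chrom = chrom, position = pos,
       child1 = new_names[1], child2 = new_names[2], cen_offset = cen_offset,
       junctions = data.frame(chrom = chrom, pos = pos))
}

# ---- event sampling --------------------------------------------------------

# distance from a chromosome end to the centromere, both ends
.end_cen_dist <- function(ch) {
  L <- .chrom_length(ch)
  c(left = ch$centromere, right = L - ch$centromere)
}

.sample_event <- function(chroms, type, counter, eps_c = 5e6, eps_t = 5e6,
                          margin = 5e6) {
  nm <- names(chroms)
  if (type == "robertsonian_fusion") {
    ok <- nm[vapply(chroms, function(ch) min(.end_cen_dist(ch)) < eps_c,
                    logical(1))]
    if (length(ok) < 2) return(NULL)
    pick <- sample(ok, 2)
    c1 <- chroms[[pick[1]]]; c2 <- chroms[[pick[2]]]
    d1 <- .end_cen_dist(c1); d2 <- .end_cen_dist(c2)
    # orient centromeric end of c1 to the right, of c2 to the left
    flip1 <- names(which.min(d1)) == "left"
    flip2 <- names(which.min(d2)) == "right"
    j1 <- if (which.min(d1) == 1) 0 else .chrom_length(c1)
    j2 <- if (which.min(d2) == 1) 0 else .chrom_length(c2)
    list(type = type, chrom1 = pick[1], chrom2 = pick[2],
         flip1 = flip1, flip2 = flip2, survivor = sample(1:2, 1),
         child = sprintf("n%04d", counter),
         junctions = data.frame(chrom = pick, pos = c(j1, j2)))
  } else if (type == "end_to_end_fusion") {
    ok <- nm[vapply(chroms, function(ch) max(.end_cen_dist(ch)) > eps_c,
                    logical(1))]
    if (length(ok) < 2) return(NULL)
    pick <- sample(ok, 2)
    c1 <- chroms[[pick[1]]]; c2 <- chroms[[pick[2]]]
    d1 <- .end_cen_dist(c1); d2 <- .end_cen_dist(c2)
    # join the telomeric (centromere-distal) ends
    flip1 <- names(which.max(d1)) == "left"
    flip2 <- names(which.max(d2)) == "right"
    j1 <- if (which.max(d1) == 1) 0 else .chrom_length(c1)
    j2 <- if (which.max(d2) == 1) 0 else .chrom_length(c2)
    list(type = type, chrom1 = pick[1], chrom2 = pick[2],
         flip1 = flip1, flip2 = flip2, survivor = sample(1:2, 1),
         child = sprintf("n%04d", counter),
         junctions = data.frame(chrom = pick, pos = c(j1, j2)))
  } else if (type == "robertsonian_fission") {
    ok <- nm[vapply(chroms, function(ch) {
      min(.end_cen_dist(ch)) > 2 * 1e6
    }, logical(1))]
    if (!length(ok)) return(NULL)
    pick <- sample(ok, 1)
    ev <- make_fission_event(chroms, pick, "centromere",
                             sprintf("n%04d", counter + 0:1))
    ev
  } else if (type == "reciprocal_translocation") {
    ok <- nm[vapply(chroms, function(ch) {
      L <- .chrom_length(ch)
      (L - margin) - (ch$centromere + margin) > 1e6
    }, logical(1))]
    if (length(ok) < 2) return(NULL)
    pick <- sample(ok, 2)
    c1 <- chroms[[pick[1]]]; c2 <- chroms[[pick[2]]]
    L1 <- .chrom_length(c1); L2 <- .chrom_length(c2)
    b1 <- stats::runif(1, c1$centromere + margin, L1 - margin)
    b2 <- stats::runif(1, c2$centromere + margin, L2 - margin)
    list(type = type, chrom1 = pick[1], chrom2 = pick[2],
         break1 = b1, break2 = b2,
         child1 = sprintf("n%04d", counter),
         child2 = sprintf("n%04d", counter + 1),
         junctions = data.frame(chrom = pick, pos = c(b1, b2)))
  } else if (type == "inversion") {
    ok <- nm[vapply(chroms, function(ch) .chrom_length(ch) > 4e6, logical(1))]
    if (!length(ok)) return(NULL)
    pick <- sample(ok, 1)
    L <- .chrom_length(chroms[[pick]])
    a <- stats::runif(1, 0, L - 2e6)
    b <- stats::runif(1, a + 1e6, L)
    list(type = type, chrom = pick, start = a, end = b,
         junctions = data.frame(chrom = pick, pos = c(a, b)))
  } else stop("unknown event type: ", type)
}

# ---- default ancestral karyotype -------------------------------------------

#' Default seven-species study tree
#'
#' A dated, ultrametric seven-species tree with 1050 My of combined branch
#' length, a trifurcating root (the unrooted topology, on which root-state
#' reconstruction is better determined) and short basal stems: frog families
#' radiated rapidly, so most branch length sits on terminal lineages.
#'
#' @return an `ape::phylo`.
#' @export
default_species_tree <- function() {
  tree <- ape::read.tree(text = paste0(
    "((sp1:148,sp2:148):12,(sp3:150,sp4:150):10,",
    "(sp5:150,(sp6:100,sp7:100):50):10);"))
  tree$edge.length <- tree$edge.length * (1050 / sum(tree$edge.length))
  tree
}

#' Default 13-element ancestral frog karyotype
#'
#' Thirteen ancestral chromosomes labelled `A`..`M` with lengths spanning
#' roughly 240-60 Mb. Eight are acrocentric (centromere 1.5 Mb from an end),
#' giving Robertsonian fusions a realistic partner pool; the remaining five
#' are (sub)metacentric (centromere at 40% of the length) and provide the
#' fission-eligible internal centromeres.
#'
#' @return a [genome_layout()] with 13 elements.
#' @export
ancestral_frog_layout <- function() {
  lens <- round(seq(240e6, 60e6, length.out = 13))
  cen <- round(0.4 * lens)
  acro <- c(3, 5, 6, 8, 9, 11, 12, 13)
  cen[acro] <- 1.5e6
  genome_layout(LETTERS[1:13], lens, cen)
}

#' Default per-type rearrangement rates
#'
#' Event intensities (per My) matching the inventory inferred for pipanuran
#' frogs: 8 Robertsonian fusions, 2 Robertsonian fissions, 2 end-to-end
#' fusions and 2 reciprocal translocations per 1050 My of branch length,
#' plus intra-chromosomal inversions (excluded from translocation counts).
#'
#' @return named numeric vector of rates per My.
#' @export
default_event_rates <- function() {
  c(robertsonian_fusion = 8 / 1050, robertsonian_fission = 2 / 1050,
    end_to_end_fusion = 2 / 1050, reciprocal_translocation = 2 / 1050,
    inversion = 4 / 1050)
}

# ---- history simulation ----------------------------------------------------

#' Simulate a karyotype history along a dated tree
#'
#' Draws rearrangement events per branch per type as Poisson processes with
#' intensity `rate * branch_length` (branch lengths in My), applies them
#' sequentially, and returns the full replayable truth together with an
#' ortholog table of genes placed on the ancestral elements and mapped
#' through every leaf karyotype.
#'
#' Events whose geometric eligibility cannot be satisfied on the current
#' karyotype (e.g. a Robertsonian fusion with fewer than two
#' centromere-terminal chromosomes) are skipped and not recorded.
#'
#' @param tree an `ape::phylo` tree with branch lengths in My.
#' @param rates named numeric vector of per-My rates; recognised names:
#'   `robertsonian_fusion`, `robertsonian_fission`, `end_to_end_fusion`,
#'   `reciprocal_translocation`, `inversion`. Missing types have rate 0.
#' @param ancestral_layout a [genome_layout()]; default
#'   [ancestral_frog_layout()].
#' @param n_genes number of one-to-one orthologs placed uniformly along the
#'   ancestral elements (proportional to length).
#' @param seed integer seed.
#' @return an object of class `simulated_history`: list with `ancestor`
#'   (chromosome list), `tree`, `events` (list of per-edge event lists),
#'   `node_chroms`, `leaf_layouts` (named list of [genome_layout()]),
#'   `leaf_chroms`, `orthologs` (data.frame: gene, element, then
#'   `<species>.chrom` / `<species>.pos` per leaf) and `rates`.
#' @export
simulate_karyotype_history <- function(tree, rates,
                                       ancestral_layout = ancestral_frog_layout(),
                                       n_genes = 1000, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length <= 0)) stop("tree branch lengths must be positive")
  if (any(rates < 0)) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  types <- c("robertsonian_fusion", "robertsonian_fission",
             "end_to_end_fusion", "reciprocal_translocation", "inversion")
  r <- stats::setNames(numeric(length(types)), types)
  r[names(rates)] <- rates

  anc <- mapply(.chrom_new, ancestral_layout$chrom, ancestral_layout$chrom,
                ancestral_layout$length, ancestral_layout$centromere,
                SIMPLIFY = FALSE)
  names(anc) <- ancestral_layout$chrom

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_chroms <- vector("list", ntip + tree$Nnode)
  node_chroms[[root]] <- anc
  edge_events <- vector("list", nrow(tree$edge))
  counter <- 1L

  # preorder over edges
  ord <- order(tree$edge[, 1])  # parents before children given ape numbering
  ord <- .preorder_edges(tree)
  for (e in ord) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    chroms <- node_chroms[[parent]]
    evs <- list()
    n_by_type <- stats::rpois(length(types), r * len)
    names(n_by_type) <- types
    todo <- sample(rep(types, n_by_type))
    for (ty in todo) {
      ev <- .sample_event(chroms, ty, counter)
      if (is.null(ev)) next
      counter <- counter + 2L
      ev$edge <- e
      ev$branch <- paste0(.node_label(tree, parent), "->",
                          .node_label(tree, child))
      chroms <- apply_event(chroms, ev)
      evs[[length(evs) + 1L]] <- ev
    }
    edge_events[[e]] <- evs
    node_chroms[[child]] <- chroms
  }

  # ortholog placement on ancestral elements
  lens <- ancestral_layout$length
  n_per <- pmax(1, round(n_genes * lens / sum(lens)))
  genes <- data.frame(
    gene = sprintf("g%05d", seq_len(sum(n_per))),
    element = rep(ancestral_layout$chrom, n_per),
    epos = unlist(lapply(seq_along(n_per), function(i)
      sort(stats::runif(n_per[i], 0, lens[i])))),
    stringsAsFactors = FALSE)

  leaf_chroms <- stats::setNames(node_chroms[seq_len(ntip)], tree$tip.label)
  orth <- genes[, c("gene", "element")]
  for (sp in tree$tip.label) {
    m <- .map_genes(genes, leaf_chroms[[sp]])
    orth[[paste0(sp, ".chrom")]] <- m$chrom
    orth[[paste0(sp, ".pos")]] <- m$pos
  }

  leaf_layouts <- lapply(leaf_chroms, .chroms_to_layout)
  out <- list(ancestor = anc, tree = tree, events = edge_events,
              node_chroms = node_chroms, leaf_chroms = leaf_chroms,
              leaf_layouts = leaf_layouts, orthologs = orth, rates = r)
  class(out) <- "simulated_history"
  out
}

.preorder_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- integer(0)
  stack <- which(tree$edge[, 1] == root)
  while (length(stack)) {
    e <- stack[1]; stack <- stack[-1]
    out <- c(out, e)
    kids <- which(tree$edge[, 1] == tree$edge[e, 2])
    stack <- c(kids, stack)
  }
  out
}

.node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node] else paste0("node", node)
}

# map genes (element, epos) through a chromosome list
.map_genes <- function(genes, chroms) {
  chrom <- character(nrow(genes)); pos <- numeric(nrow(genes))
  for (ch in chroms) {
    seg <- ch$segments
    offs <- cumsum(c(0, seg$end - seg$start))
    for (i in seq_len(nrow(seg))) {
      hit <- genes$element == seg$element[i] &
        genes$epos >= seg$start[i] & genes$epos < seg$end[i]
      if (!any(hit)) next
      p <- genes$epos[hit]
      pos[hit] <- if (seg$strand[i] == "+") offs[i] + (p - seg$start[i])
                  else offs[i] + (seg$end[i] - p)
      chrom[hit] <- ch$name
    }
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

.chroms_to_layout <- function(chroms) {
  genome_layout(vapply(chroms, `[[`, "", "name"),
                vapply(chroms, .chrom_length, 0),
                vapply(chroms, `[[`, 0, "centromere"))
}

#' Replay a recorded event history
#'
#' Applies the stored per-edge event lists of a [simulate_karyotype_history()]
#' result to the ancestral karyotype and returns the reconstructed leaf
#' chromosome sets. Replay is exact: the result equals the simulated leaf
#' karyotypes bit for bit.
#'
#' @param history a `simulated_history`.
#' @return named list of leaf chromosome lists.
#' @export
replay_history <- function(history) {
  tree <- history$tree
  ntip <- length(tree$tip.label)
  node_chroms <- vector("list", ntip + tree$Nnode)
  node_chroms[[ntip + 1L]] <- history$ancestor
  for (e in .preorder_edges(tree)) {
    chroms <- node_chroms[[tree$edge[e, 1]]]
    for (ev in history$events[[e]]) chroms <- apply_event(chroms, ev)
    node_chroms[[tree$edge[e, 2]]] <- chroms
  }
  stats::setNames(node_chroms[seq_len(ntip)], tree$tip.label)
}

#' Flatten the event lists of a history into a data.frame
#'
#' @param history a `simulated_history`.
#' @return data.frame with `branch`, `type` and participant columns; zero
#'   rows when no events occurred.
#' @export
history_events <- function(history) {
  evs <- unlist(history$events, recursive = FALSE)
  if (!length(evs))
    return(data.frame(branch = character(0), type = character(0)))
  do.call(rbind, lapply(evs, function(ev) {
    data.frame(branch = ev$branch, type = ev$type,
               chroms = paste(ev$junctions$chrom, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
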