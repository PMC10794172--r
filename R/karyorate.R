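#' Rearrangement classification and karyotype-rate tests
#'
#' Classifies rearrangement junctions against centromere/telomere geometry
#' (Robertsonian vs end-to-end vs reciprocal), counts translocations with
#' composite handling of multi-way reciprocal events, and tests
#' rearrangement-rate hypotheses under a homogeneous Poisson model on a
#' dated tree.
#'
#' @name karyorate
NULL

#' Classify a rearrangement junction
#'
#' Robertsonian when every breakpoint lies within `eps_c` of its
#' chromosome's centromere; end-to-end when every junction lies within
#' `eps_t` of a chromosome end (and is not Robertsonian); otherwise a
#' reciprocal translocation.
#'
#' @param layout parent [genome_layout()].
#' @param junctions data.frame `chrom`, `pos` (parent-frame breakpoints).
#' @param eps_c,eps_t centromere / telomere windows in bp (default 5 Mb).
#' @return one of `"robertsonian"`, `"end_to_end"`,
#'   `"reciprocal_translocation"`.
#' @export
classify_junction <- function(layout, junctions, eps_c = 5e6, eps_t = 5e6) {
  i <- match(junctions$chrom, layout$chrom)
  if (anyNA(i)) stop("junction on unknown chromosome")
  L <- layout$length[i]; cen <- layout$centromere[i]; pos <- junctions$pos
  if (any(pos < 0 | pos > L)) stop("junction outside chromosome bounds")
  if (all(abs(pos - cen) <= eps_c)) return("robertsonian")
  if (all(pmin(pos, L - pos) <= eps_t)) return("end_to_end")
  "reciprocal_translocation"
}

#' Classify every event of a simulated history
#'
#' Applies [classify_junction()] to each recorded event's junctions in its
#' parent-node layout. Inversions are passed through unchanged.
#'
#' @param history a `simulated_history`.
#' @param eps_c,eps_t classification windows (bp).
#' @return data.frame `branch`, `true_type`, `classified`.
#' @export
classify_history_events <- function(history, eps_c = 5e6, eps_t = 5e6) {
  rows <- list()
  for (e in seq_along(history$events)) {
    parent <- history$tree$edge[e, 1]
    chroms <- history$node_chroms[[parent]]
    for (ev in history$events[[e]]) {
      if (ev$type == "inversion") {
        cls <- "inversion"
      } else {
        cls <- classify_junction(.chroms_to_layout(chroms), ev$junctions,
                                 eps_c, eps_t)
        if (cls == "robertsonian")
          cls <- if (grepl("fission", ev$type)) "robertsonian_fission"
                 else "robertsonian_fusion"
        if (cls == "end_to_end") cls <- "end_to_end_fusion"
      }
      rows[[length(rows) + 1]] <- data.frame(
        branch = ev$branch, true_type = ev$type, classified = cls,
        stringsAsFactors = FALSE)
      chroms <- apply_event(chroms, ev)
    }
  }
  if (!length(rows))
    return(data.frame(branch = character(0), true_type = character(0),
                      classified = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count translocations in an event list
#'
#' Inversions are excluded. A k-way reciprocal event (field `k_way` > 2)
#' counts as `four_way_as` pairwise rearrangements when `k_way = 4`
#' (a four-way reciprocal fusion is a composite of three pairwise
#' rearrangements), and more generally as `k_way - 1`.
#'
#' @param events data.frame with a `type` column and optional `k_way`.
#' @param four_way_as pairwise-equivalents of a four-way event (default 3).
#' @return integer translocation count.
#' @export
count_translocations <- function(events, four_way_as = 3) {
  if (!nrow(events)) return(0L)
  ev <- events[events$type != "inversion", , drop = FALSE]
  if (!nrow(ev)) return(0L)
  k <- if ("k_way" %in% names(ev)) ev$k_way else rep(2, nrow(ev))
  k[is.na(k)] <- 2
  sum(ifelse(k <= 2, 1, ifelse(k == 4, four_way_as, k - 1)))
}

#' Average waiting time between karyotype changes
#'
#' @param count number of changes (>= 0).
#' @param total_length_My total tree branch length in My (> 0).
#' @return My per change, or `NA` with a `"no events"` message attribute
#'   when `count` is 0.
#' @export
karyotype_change_rate <- function(count, total_length_My) {
  if (total_length_My <= 0) stop("total branch length must be positive")
  if (count < 0) stop("count must be non-negative")
  if (count == 0) {
    out <- NA_real_
    attr(out, "note") <- "no events"
    return(out)
  }
  total_length_My / count
}

#' Poisson branch test for rearrangement-rate deviation
#'
#' Under a homogeneous Poisson model with genome-wide rate `rate` per My,
#' tests whether `k` observed events on a branch of length `length_My`
#' deviate from expectation `lambda = length_My * rate`. Reports the smaller
#' one-sided tail (`P(X <= k)` or `P(X >= k)`) and the tail-doubled
#' two-sided p capped at 1.
#'
#' @param length_My branch length in My.
#' @param k observed events.
#' @param rate genome-wide events per My (> 0).
#' @return list: `lambda`, `one_sided`, `two_sided`, `direction`
#'   ("fewer"/"more").
#' @export
branch_poisson_test <- function(length_My, k, rate) {
  if (rate <= 0) stop("rate must be positive")
  lambda <- length_My * rate
  lower <- stats::ppois(k, lambda)
  upper <- stats::ppois(k - 1, lambda, lower.tail = FALSE)
  if (lower <= upper) {
    list(lambda = lambda, one_sided = lower,
         two_sided = min(1, 2 * lower), direction = "fewer")
  } else {
    list(lambda = lambda, one_sided = upper,
         two_sided = min(1, 2 * upper), direction = "more")
  }
}

#' Poisson branch tests across a tree with family-wise correction
#'
#' @param branch_lengths named vector of branch lengths (My).
#' @param counts observed event counts per branch (same order).
#' @param rate genome-wide rate per My.
#' @return data.frame with per-branch `lambda`, `one_sided`, `two_sided` and
#'   Hochberg step-up corrected `p_adj`.
#' @export
branch_poisson_tests <- function(branch_lengths, counts, rate) {
  res <- mapply(function(l, k) branch_poisson_test(l, k, rate),
                branch_lengths, counts, SIMPLIFY = FALSE)
  out <- data.frame(
    branch = if (is.null(names(branch_lengths)))
      seq_along(branch_lengths) else names(branch_lengths),
    length_My = branch_lengths, k = counts,
    lambda = vapply(res, `[[`, 0, "lambda"),
    one_sided = vapply(res, `[[`, 0, "one_sided"),
    two_sided = vapply(res, `[[`, 0, "two_sided"),
    direction = vapply(res, `[[`, "", "direction"))
  out$p_adj <- stats::p.adjust(out$two_sided, method = "hochberg")
  rownames(out) <- NULL
  out
}

#' Random chromosome-break model test
#'
#' Under random breakage, the probability that a break falls in an arm
#' interior is `q = 1 - (terminal window bp) / (genome bp)`, where terminal
#' windows are `eps_c` around each centromere and `eps_t` inside each
#' telomere. With `n` breaks the expected number of interior (arm-breaking)
#' events is `n * q`; the observed deficit is tested with the exact binomial
#' lower tail `P(X <= observed)`.
#'
#' @param layouts list of [genome_layout()] (one per sampled genome; windows
#'   are pooled across them).
#' @param n number of breakpoints placed.
#' @param observed observed arm-interior breaks.
#' @param eps_c,eps_t terminal window sizes in bp.
#' @return list: `q`, `expected`, `p`.
#' @export
random_break_test <- function(layouts, n, observed, eps_c = 5e6,
                              eps_t = 5e6) {
  tot <- 0; term <- 0
  for (lay in layouts) {
    if (any(eps_c > lay$length / 2) || any(eps_t > lay$length / 2))
      stop("terminal windows exceed chromosome length")
    tot <- tot + sum(lay$length)
    # merge centromere and telomere windows per chromosome to avoid double
    # counting on acrocentric chromosomes
    w <- numeric(nrow(lay))
    for (i in seq_len(nrow(lay))) {
      iv <- rbind(c(max(0, lay$centromere[i] - eps_c),
                    min(lay$length[i], lay$centromere[i] + eps_c)),
                  c(0, min(eps_t, lay$length[i])),
                  c(max(0, lay$length[i] - eps_t), lay$length[i]))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      merged <- iv[1, , drop = FALSE]
      for (j in 2:nrow(iv)) {
        last <- nrow(merged)
        if (iv[j, 1] <= merged[last, 2])
          merged[last, 2] <- max(merged[last, 2], iv[j, 2])
        else merged <- rbind(merged, iv[j, , drop = FALSE])
      }
      w[i] <- sum(merged[, 2] - merged[, 1])
    }
    term <- term + sum(w)
  }
  q <- 1 - term / tot
  list(q = q, expected = n * q,
       p = stats::pbinom(observed, n, q))
}
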