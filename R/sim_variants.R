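#' Simulate a variant site table with planted filter labels
#'
#' Generates biallelic and multiallelic SNP sites with per-site total depth,
#' per-sample genotypes and allele balance, planting known pass/fail labels
#' for each downstream filter: depth inliers are drawn tightly around
#' `depth_mode` while planted outliers are placed far outside the
#' `mode +/- 1.78 SD` band; heterozygote allele balance is drawn inside
#' [0.3, 0.7] for passing sites and outside for planted failures.
#'
#' @param n_sites number of sites.
#' @param depth_mode modal sequencing depth.
#' @param depth_sd sd of inlier depth around the mode.
#' @param frac_depth_outlier fraction of sites with extreme depth.
#' @param frac_bad_balance fraction of het sites with out-of-band balance.
#' @param frac_multiallelic fraction of sites with a third allele.
#' @param samples sample names.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `pos`, `alleles`, `n_alleles`,
#'   `dp`, per-sample `gt_<s>` ("0/0", "0/1", "1/1") and `ab_<s>` (alt
#'   fraction, NA for homozygotes), and truth columns `true_pass_biallelic`,
#'   `true_pass_depth`, `true_pass_balance`, `true_pass`.
#' @export
simulate_variant_sites <- function(n_sites = 1000, depth_mode = 30,
                                   depth_sd = 3, frac_depth_outlier = 0.1,
                                   frac_bad_balance = 0.05,
                                   frac_multiallelic = 0.05,
                                   samples = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  multi <- stats::runif(n_sites) < frac_multiallelic
  out_dp <- stats::runif(n_sites) < frac_depth_outlier
  dp <- round(stats::rnorm(n_sites, depth_mode, depth_sd))
  dp[dp < 1] <- 1
  # outliers sit far above the mode: with ~10% planted outliers the depth SD
  # is inflated by the outliers themselves, so the mode - 1.78 SD bound drops
  # below zero and only the high side can separate planted classes exactly
  dp[out_dp] <- depth_mode * 5 + stats::rpois(sum(out_dp), 10)
  bases <- c("A", "C", "G", "T")
  alleles <- vapply(multi, function(m) {
    paste(sample(bases, if (m) 3 else 2), collapse = ",")
  }, character(1))
  d <- data.frame(chrom = "chr1",
                  pos = sort(sample.int(n_sites * 100, n_sites)),
                  alleles = alleles, n_alleles = ifelse(multi, 3L, 2L),
                  dp = dp, stringsAsFactors = FALSE)
  bad_ab_site <- stats::runif(n_sites) < frac_bad_balance
  for (s in samples) {
    het <- stats::runif(n_sites) < 0.5
    gt <- ifelse(het, "0/1",
                 ifelse(stats::runif(n_sites) < 0.5, "0/0", "1/1"))
    ab <- rep(NA_real_, n_sites)
    good <- het & !bad_ab_site
    bad <- het & bad_ab_site
    ab[good] <- stats::runif(sum(good), 0.35, 0.65)
    ab[bad] <- ifelse(stats::runif(sum(bad)) < 0.5,
                      stats::runif(sum(bad), 0, 0.25),
                      stats::runif(sum(bad), 0.75, 1))
    d[[paste0("gt_", s)]] <- gt
    d[[paste0("ab_", s)]] <- ab
  }
  has_het <- Reduce(`|`, lapply(samples, function(s) d[[paste0("gt_", s)]] == "0/1"))
  d$true_pass_biallelic <- !multi
  d$true_pass_depth <- !out_dp
  d$true_pass_balance <- !(bad_ab_site & has_het)
  d$true_pass <- d$true_pass_biallelic & d$true_pass_depth &
    d$true_pass_balance
  d
}
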