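# Window diversity statistics: per-site nucleotide diversity (pi),
# Watterson's theta and Tajima's D in non-overlapping windows, with
# pairwise-deletion handling of missing genotypes.

# half-open window tiling [1, 1+w), [1+w, 1+2w), ... per chromosome
window_index <- function(chrom, pos, window_bp) {
  start <- ((pos - 1L) %/% as.integer(window_bp)) * as.integer(window_bp) + 1L
  list(key = paste(chrom, start, sep = ":"), start = start,
       end = start + as.integer(window_bp))
}

harmonic <- function(n) {
  # a_n = sum_{i=1}^{n} 1/i, vectorised via cumsum lookup; a_0 = 0
  n <- as.integer(n)
  top <- max(n, 1L)
  H <- cumsum(1 / seq_len(top))
  ifelse(n < 1L, 0, H[pmax(n, 1L)])
}

tajima_constants <- function(n) {
  # Tajima (1989) e1, e2 for sample size n (haplotypes)
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(max(n - 1, 0))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Window diversity statistics (pi, Watterson's theta, Tajima's D)
#'
#' Sites are tiled into non-overlapping windows. Within a window, sites with
#' genotype call rate >= `accessible_call_rate` are "accessible" and form the
#' denominator of the per-site estimates; windows whose fraction of
#' accessible sites falls below `min_data_fraction` are discarded. Per
#' accessible site, `n` is the number of non-missing haplotypes
#' (pairwise deletion). pi is the mean pairwise difference per accessible
#' site, theta the Watterson estimator `S / a_{n-1}` (summed per site for
#' varying n), and Tajima's D uses the standard e1/e2 constants evaluated at
#' the window's mean `n`. D is `NA` when fewer than 4 haplotypes are typed
#' or the variance term is non-positive.
#'
#' @param g a [geno_matrix()].
#' @param window_bp window size in bp (default 10,000).
#' @param min_data_fraction minimum accessible-site fraction per window.
#' @param accessible_call_rate call-rate threshold defining accessible sites.
#' @return data.frame with columns `chrom`, `start`, `end`, `n_sites_typed`,
#'   `data_fraction`, `S`, `pi`, `theta_w`, `tajima_d`.
#' @export
window_diversity <- function(g, window_bp = 10000L, min_data_fraction = 0.3,
                             accessible_call_rate = 0.8) {
  if (n_sites(g) == 0) stop("genotype matrix has no sites", call. = FALSE)
  wi <- window_index(g$chrom, g$pos, window_bp)
  ac <- site_allele_counts(g)
  cr <- site_call_rate(g)
  accessible <- cr >= accessible_call_rate & ac$n >= 2
  n <- ac$n; d <- ac$d
  poly <- accessible & d > 0 & d < n
  # per-site contributions
  pi_site <- ifelse(poly, 2 * d * (n - d) / (n * (n - 1)), 0)
  th_site <- ifelse(poly, 1 / harmonic(pmax(n - 1, 1)), 0)

  keys <- factor(wi$key, levels = unique(wi$key))
  agg <- function(x) as.numeric(tapply(x, keys, sum))
  total_sites <- as.numeric(tapply(rep(1, length(n)), keys, sum))
  acc_sites <- agg(as.numeric(accessible))
  S <- agg(as.numeric(poly))
  pi_sum <- agg(pi_site)
  th_sum <- agg(th_site)
  n_mean <- as.numeric(tapply(ifelse(accessible, n, NA), keys, mean, na.rm = TRUE))

  first <- !duplicated(wi$key)
  out <- data.frame(
    chrom = g$chrom[first], start = wi$start[first], end = wi$end[first],
    n_sites_typed = acc_sites, data_fraction = acc_sites / total_sites,
    S = S,
    pi = ifelse(acc_sites > 0, pi_sum / acc_sites, NA_real_),
    theta_w = ifelse(acc_sites > 0, th_sum / acc_sites, NA_real_),
    tajima_d = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    nw <- n_mean[i]
    if (is.na(nw) || nw < 4 || S[i] < 1) next
    k <- tajima_constants(round(nw))
    v <- k$e1 * S[i] + k$e2 * S[i] * (S[i] - 1)
    if (v > 0) out$tajima_d[i] <- (pi_sum[i] - th_sum[i]) / sqrt(v)
  }
  out[out$data_fraction >= min_data_fraction & out$n_sites_typed > 0, , drop = FALSE]
}

#' Hudson's Fst in non-overlapping windows
#'
#' Ratio-of-averages Hudson estimator: per window,
#' `Fst = sum(num) / sum(den)` over usable sites, with
#' `num = (p1 - p2)^2 - p1 (1 - p1)/(n1 - 1) - p2 (1 - p2)/(n2 - 1)` and
#' `den = p1 (1 - p2) + p2 (1 - p1)`. Sites with fewer than 2 non-missing
#' alleles in either population are skipped; windows with no usable site
#' (or zero denominator) are omitted.
#'
#' @param gA,gB [geno_matrix()] objects for the two populations; must share
#'   identical site coordinates.
#' @param window_bp window size in bp.
#' @return data.frame `chrom`, `start`, `end`, `fst`, `n_sites`.
#' @export
hudson_fst <- function(gA, gB, window_bp = 10000L) {
  if (!identical(gA$chrom, gB$chrom) || !identical(gA$pos, gB$pos)) {
    stop("populations must share site coordinates", call. = FALSE)
  }
  a <- site_allele_counts(gA); b <- site_allele_counts(gB)
  use <- a$n >= 2 & b$n >= 2
  p1 <- a$d / pmax(a$n, 1); p2 <- b$d / pmax(b$n, 1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(a$n - 1, 1) - p2 * (1 - p2) / pmax(b$n - 1, 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!use] <- 0; den[!use] <- 0
  wi <- window_index(gA$chrom, gA$pos, window_bp)
  keys <- factor(wi$key, levels = unique(wi$key))
  num_w <- as.numeric(tapply(num, keys, sum))
  den_w <- as.numeric(tapply(den, keys, sum))
  n_use <- as.numeric(tapply(as.numeric(use), keys, sum))
  first <- !duplicated(wi$key)
  out <- data.frame(chrom = gA$chrom[first], start = wi$start[first],
                    end = wi$end[first],
                    fst = ifelse(den_w > 0, num_w / den_w, NA_real_),
                    n_sites = n_use, stringsAsFactors = FALSE)
  out[out$n_sites > 0 & !is.na(out$fst), , drop = FALSE]
}

#' Observed carriers of a causal allele
#'
#' Returns the domesticate samples observed to carry a locus's derived
#' allele: for a SNP locus, samples with alt-allele dosage >= 1 at the
#' causal site; for a gene-deletion locus, samples whose read-depth call is
#' `deleted`. This is the partition the diversity-ratio sweep scan is run
#' on — within a sweep, the carriers share the selected haplotype, so their
#' diversity collapses.
#'
#' @param g a [geno_matrix()].
#' @param samples a `sample_table`.
#' @param locus one-row data.frame with `locus_id`, `chrom`, `pos`, `type`.
#' @param calls [call_deletions()] output (required for deletion loci).
#' @return character vector of sample ids.
#' @export
observed_carriers <- function(g, samples, locus, calls = NULL) {
  dom <- samples$sample_id[samples$species == "domesticate"]
  if (locus$type == "snp") {
    j <- which(g$chrom == locus$chrom & g$pos == locus$pos)
    if (length(j) != 1) stop("causal site not found: ", locus$locus_id, call. = FALSE)
    dos <- dosage(g)[, j]
    ids <- g$sample_ids[!is.na(dos) & dos >= 1]
  } else {
    if (is.null(calls)) stop("deletion calls required for locus ", locus$locus_id,
                             call. = FALSE)
    ids <- calls$sample_id[calls$gene_id == locus$locus_id & calls$call == "deleted"]
  }
  intersect(ids, dom)
}

#' Selective-sweep scan from a wild/domesticate diversity ratio
#'
#' Joins wild and domesticate window-diversity frames on shared windows and
#' computes `ratio = pi_wild / pi_dom`. A window is flagged as a sweep
#' candidate when its ratio reaches the empirical 99th percentile of the
#' finite genome-wide ratios (and strictly exceeds the genome-wide minimum,
#' so a degenerate all-equal distribution flags nothing); windows where
#' `pi_dom` is zero but `pi_wild` positive have infinite ratio and are
#' always flagged.
#'
#' @param wild_stats,dom_stats outputs of [window_diversity()] for the wild
#'   and domesticated populations.
#' @param top_fraction upper tail fraction defining the flag threshold.
#' @return data.frame `chrom`, `start`, `end`, `pi_wild`, `pi_dom`, `ratio`,
#'   `top1pct_flag`.
#' @export
sweep_scan <- function(wild_stats, dom_stats, top_fraction = 0.01) {
  key_w <- paste(wild_stats$chrom, wild_stats$start)
  key_d <- paste(dom_stats$chrom, dom_stats$start)
  shared <- intersect(key_w, key_d)
  if (length(shared) == 0) stop("no shared windows between populations", call. = FALSE)
  iw <- match(shared, key_w); id <- match(shared, key_d)
  pi_w <- wild_stats$pi[iw]; pi_d <- dom_stats$pi[id]
  ratio <- ifelse(pi_d > 0, pi_w / pi_d, ifelse(pi_w > 0, Inf, NaN))
  fin <- is.finite(ratio)
  out <- data.frame(chrom = wild_stats$chrom[iw], start = wild_stats$start[iw],
                    end = wild_stats$end[iw], pi_wild = pi_w, pi_dom = pi_d,
                    ratio = ratio, top1pct_flag = FALSE, stringsAsFactors = FALSE)
  if (any(fin)) {
    q <- quantile(ratio[fin], 1 - top_fraction, names = FALSE, type = 7)
    lo <- min(ratio[fin])
    out$top1pct_flag <- !is.nan(ratio) &
      (is.infinite(ratio) | (ratio >= q & ratio > lo))
  } else {
    out$top1pct_flag <- is.infinite(ratio)
  }
  out
}
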