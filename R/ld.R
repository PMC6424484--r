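#' LD decay: mean r-squared in distance bins
#'
#' Pairwise r-squared is the squared Pearson correlation of alt-allele
#' dosage vectors over samples non-missing at both sites (genotype-based,
#' phase-free). Pairs are restricted to the same non-overlapping region
#' window, binned by inter-site distance, and summarised as the mean and
#' pair count per bin. Pairs where either site has zero dosage variance are
#' skipped. For large matrices, sites can be deterministically subsampled
#' first via `max_sites`.
#'
#' @param g a [geno_matrix()].
#' @param region_window_bp non-overlapping pairing window (default 1 Mbp).
#' @param bin_bp distance bin width (default 1,000 bp).
#' @param max_sites optional cap on the number of sites used (uniform
#'   subsample, reproducible given `seed`).
#' @param seed RNG seed used only when `max_sites` triggers subsampling.
#' @return data.frame `distance_bin_start`, `distance_bin_end`, `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(g, region_window_bp = 1000000L, bin_bp = 1000L,
                     max_sites = NULL, seed = 1L) {
  if (n_sites(g) < 2) stop("need at least 2 sites", call. = FALSE)
  if (!is.null(max_sites) && n_sites(g) > max_sites) {
    g <- run_with_seed(seed, subset_sites(g, sort(sample.int(n_sites(g), max_sites))))
  }
  wi <- window_index(g$chrom, g$pos, region_window_bp)
  x <- dosage(g)
  max_bin <- as.integer((region_window_bp - 1L) %/% bin_bp)
  num <- numeric(max_bin + 1L); cnt <- numeric(max_bin + 1L)
  for (w in unique(wi$key)) {
    idx <- which(wi$key == w)
    if (length(idx) < 2) next
    xs <- x[, idx, drop = FALSE]
    storage.mode(xs) <- "double"
    r <- suppressWarnings(cor(xs, use = "pairwise.complete.obs"))
    r2 <- r^2
    dmat <- abs(outer(g$pos[idx], g$pos[idx], "-"))
    ut <- upper.tri(r2)
    ok <- ut & !is.na(r2)
    b <- (dmat[ok] %/% bin_bp) + 1L
    v <- r2[ok]
    for (u in unique(b)) {
      sel <- b == u
      num[u] <- num[u] + sum(v[sel])
      cnt[u] <- cnt[u] + sum(sel)
    }
  }
  keep <- which(cnt > 0)
  data.frame(
    distance_bin_start = (keep - 1L) * bin_bp,
    distance_bin_end = keep * bin_bp,
    mean_r2 = num[keep] / cnt[keep],
    n_pairs = cnt[keep]
  )
}

#' Centered moving-average smoother for LD decay curves
#'
#' Simple plotting aid over the binned means; no model fitting.
#'
#' @param bins output of [ld_decay()].
#' @param k odd window length in bins.
#' @return `bins` with an extra `smoothed_r2` column.
#' @export
ld_smooth <- function(bins, k = 5L) {
  if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
  half <- (k - 1L) %/% 2L
  n <- nrow(bins)
  sm <- vapply(seq_len(n), function(i) {
    ix <- max(1L, i - half):min(n, i + half)
    mean(bins$mean_r2[ix])
  }, numeric(1))
  bins$smoothed_r2 <- sm
  bins
}
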