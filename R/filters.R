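#' Filter sites on call rate and minor allele frequency
#'
#' Retains sites whose genotype call rate is at least `min_call_rate` and
#' whose minor allele frequency, computed over non-missing alleles, is at
#' least `min_maf`. Site order is preserved.
#'
#' @param g a [geno_matrix()].
#' @param min_call_rate minimum fraction of samples with a genotype call.
#' @param min_maf minimum minor allele frequency (<= 0.5).
#' @return the filtered [geno_matrix()].
#' @export
filter_sites <- function(g, min_call_rate = 0.8, min_maf = 0.02) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]", call. = FALSE)
  if (min_call_rate < 0 || min_call_rate > 1) {
    stop("min_call_rate must lie in [0, 1]", call. = FALSE)
  }
  cr <- site_call_rate(g)
  ac <- site_allele_counts(g)
  p <- ifelse(ac$n > 0, ac$d / ac$n, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- cr >= min_call_rate & !is.na(maf) & maf >= min_maf
  subset_sites(g, keep)
}

#' Thin sites for LD reduction
#'
#' Randomly picks at most one polymorphic site per non-overlapping window,
#' then enforces a minimum spacing between consecutive retained sites
#' (earlier sites win). Selection is uniform among a window's sites and
#' reproducible for a given seed.
#'
#' @param g a [geno_matrix()].
#' @param window_bp non-overlapping window size (default 50 kbp).
#' @param min_spacing_bp minimum distance between retained sites
#'   (default 25 kbp; must be < `window_bp`).
#' @param seed integer RNG seed.
#' @return the thinned [geno_matrix()].
#' @export
thin_sites <- function(g, window_bp = 50000L, min_spacing_bp = 25000L, seed = 1L) {
  if (!(window_bp > min_spacing_bp && min_spacing_bp >= 0)) {
    stop("require window_bp > min_spacing_bp >= 0", call. = FALSE)
  }
  run_with_seed(seed, {
    win <- paste(g$chrom, (g$pos - 1L) %/% as.integer(window_bp), sep = ":")
    picked <- vapply(split(seq_along(g$pos), factor(win, levels = unique(win))),
                     function(ix) if (length(ix) == 1L) ix else sample(ix, 1L),
                     integer(1))
    picked <- sort(unname(picked))
    keep <- integer(0)
    last_chrom <- ""; last_pos <- -Inf
    for (i in picked) {
      if (g$chrom[i] != last_chrom || g$pos[i] - last_pos >= min_spacing_bp) {
        keep <- c(keep, i)
        last_chrom <- g$chrom[i]; last_pos <- g$pos[i]
      }
    }
    subset_sites(g, keep)
  })
}
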