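#' Four-population f4 test with block jackknife
#'
#' `f4(A, B; C, D)` is the mean over usable sites of
#' `(pA - pB) * (pC - pD)`, where `p` are alt-allele frequencies computed
#' over non-missing alleles. The standard error comes from a delete-one
#' block jackknife over consecutive blocks of `block_size` sites, and
#' `z = f4 / SE`.
#'
#' @param gA,gB,gC,gD [geno_matrix()] objects sharing site coordinates.
#' @param block_size SNPs per jackknife block (default 100; at least 2
#'   blocks are required).
#' @return list of class `f4_result`: `f4_value`, `jackknife_se`, `z_score`,
#'   `n_blocks`, `n_sites`.
#' @export
f4_test <- function(gA, gB, gC, gD, block_size = 100L) {
  mats <- list(gA, gB, gC, gD)
  for (g in mats[-1]) {
    if (!identical(gA$chrom, g$chrom) || !identical(gA$pos, g$pos)) {
      stop("all four populations must share site coordinates", call. = FALSE)
    }
  }
  fr <- lapply(mats, function(g) {
    ac <- site_allele_counts(g)
    ifelse(ac$n > 0, ac$d / ac$n, NA_real_)
  })
  val <- (fr[[1]] - fr[[2]]) * (fr[[3]] - fr[[4]])
  use <- !is.na(val)
  if (!any(use)) stop("no usable sites for f4", call. = FALSE)
  poly <- Reduce(`|`, lapply(fr, function(p) !is.na(p) & p > 0 & p < 1))
  if (!any(poly & use)) stop("all sites monomorphic in all four groups", call. = FALSE)
  v <- val[use]
  n <- length(v)
  blocks <- ((seq_len(n) - 1L) %/% as.integer(block_size)) + 1L
  B <- max(blocks)
  if (B < 2) stop("need at least 2 jackknife blocks", call. = FALSE)
  f4_all <- mean(v)
  f4_jack <- vapply(seq_len(B), function(b) mean(v[blocks != b]), numeric(1))
  se <- sqrt((B - 1) / B * sum((f4_jack - mean(f4_jack))^2))
  structure(list(f4_value = f4_all, jackknife_se = se,
                 z_score = if (se > 0) f4_all / se else NA_real_,
                 n_blocks = B, n_sites = n),
            class = "f4_result")
}

#' @export
print.f4_result <- function(x, ...) {
  cat(sprintf("f4 = %.6g  (jackknife SE %.3g, Z = %.3g, %d blocks over %d sites)\n",
              x$f4_value, x$jackknife_se, x$z_score, x$n_blocks, x$n_sites))
  invisible(x)
}
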