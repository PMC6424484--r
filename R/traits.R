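# Panicle threshability: percent-shattering to SES score conversion,
# group comparisons by pairwise Mann-Whitney U tests, and
# genotype-phenotype concordance tabulation.

#' Convert percent shattering to an SES panicle-threshability score
#'
#' Band mapping on the 1/3/5/7/9 scale: `< 1%` scores 1, `1-5%` scores 3,
#' `(5, 25]%` scores 5, `(25, 50]%` scores 7 and `(50, 100]%` scores 9.
#' Band boundaries are closed on the upper side. (The published band labels
#' give 6-15% for score 5 and 26-50% for score 7; the 16-25% gap between
#' them is assigned to score 5, following the standard evaluation scale, so
#' the mapping is monotone and total on \[0, 100\].)
#'
#' @param percent_shattering numeric vector in \[0, 100\].
#' @return integer SES scores in `{1, 3, 5, 7, 9}`.
#' @export
ses_score <- function(percent_shattering) {
  x <- percent_shattering
  if (any(is.na(x)) || any(x < 0 | x > 100)) {
    stop("percent_shattering must lie in [0, 100]", call. = FALSE)
  }
  ifelse(x < 1, 1L,
         ifelse(x <= 5, 3L,
                ifelse(x <= 25, 5L,
                       ifelse(x <= 50, 7L, 9L))))
}

# exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (handles ties); U is counted for the first group
mwu_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  vals <- c(x, y)
  r <- rank(vals)
  cmb <- combn(n, n1)
  u_all <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# tie-corrected normal approximation (two-sided, no continuity shortcut
# beyond the standard 0.5 correction)
mwu_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Pairwise Mann-Whitney U tests across groups
#'
#' Two-sided tests for every group pair: exact enumeration of the U
#' permutation distribution when the combined sample size is at most
#' `exact_max_n` (ties handled exactly), otherwise a tie-corrected normal
#' approximation. P-values are Bonferroni-corrected by the number of pairs
#' and capped at 1.
#'
#' @param scores numeric vector of per-sample scores.
#' @param groups group label per score.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param exact_max_n maximum combined n for exact enumeration (default 20).
#' @return symmetric matrix of corrected p-values (diagonal `NA`).
#' @export
pairwise_mwu <- function(scores, groups, correction = c("bonferroni", "none"),
                         exact_max_n = 20L) {
  correction <- match.arg(correction)
  groups <- as.character(groups)
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- groups[keep]
  sizes <- table(groups)
  if (any(sizes == 0) || length(sizes) < 2) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  gl <- names(sizes)
  k <- length(gl)
  n_pairs <- k * (k - 1) / 2
  p <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- scores[groups == gl[i]]; y <- scores[groups == gl[j]]
      raw <- if (length(x) + length(y) <= exact_max_n) mwu_exact_p(x, y)
             else mwu_normal_p(x, y)
      adj <- if (correction == "bonferroni") min(1, raw * n_pairs) else raw
      p[i, j] <- p[j, i] <- adj
    }
  }
  p
}

#' Genotype-phenotype concordance cross-tabulation
#'
#' Tabulates, per genetic group, the number of samples in each combination
#' of allele statuses and SES score band, and flags groups in which
#' identical genotype combinations nevertheless yield different score bands
#' — the signature of an unaccounted-for causal gene.
#'
#' @param statuses data.frame of per-sample allele statuses; first column
#'   must be `sample_id`, remaining columns are locus statuses (e.g.
#'   `"deleted"`/`"present"`, `"derived"`/`"ancestral"`).
#' @param scores data.frame with columns `sample_id`, `ses_score`.
#' @param samples a `sample_table` providing `group` per sample.
#' @return list of class `concordance_table`: `table` (counts per group x
#'   genotype x score), `discordant` (data.frame of group x genotype
#'   combinations spanning >1 score band).
#' @export
concordance_table <- function(statuses, scores, samples) {
  if (names(statuses)[1] != "sample_id") {
    stop("first column of statuses must be sample_id", call. = FALSE)
  }
  df <- merge(statuses, scores[, c("sample_id", "ses_score")], by = "sample_id")
  df$group <- samples$group[match(df$sample_id, samples$sample_id)]
  if (anyNA(df$group)) {
    stop("statuses contain sample(s) absent from the sample table", call. = FALSE)
  }
  loci <- setdiff(names(statuses), "sample_id")
  df$genotype <- do.call(paste, c(df[loci], sep = "/"))
  tab <- as.data.frame(table(group = df$group, genotype = df$genotype,
                             ses_score = df$ses_score), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "n"
  rownames(tab) <- NULL
  agg <- stats::aggregate(ses_score ~ group + genotype, data = df,
                          FUN = function(v) length(unique(v)))
  disc <- agg[agg$ses_score > 1, c("group", "genotype"), drop = FALSE]
  names(disc) <- c("group", "genotype")
  rownames(disc) <- NULL
  structure(list(table = tab, discordant = disc), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("concordance_table:\n")
  print(x$table)
  if (nrow(x$discordant)) {
    cat("groups with identical genotypes but differing score bands:\n")
    print(x$discordant)
  } else {
    cat("no genotype-phenotype discordance flagged\n")
  }
  invisible(x)
}
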