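# Genetic distances, population-relationship summaries (NJ tree, classical
# MDS) and the silhouette-score iterative core-set filter used to curate
# genetically coherent group memberships before downstream analyses.

#' Pairwise identity-by-state genetic distances
#'
#' `d(i, j) = 1 - IBS(i, j)` with IBS the mean, over mutually non-missing
#' sites, of `(2 - |dosage_i - dosage_j|) / 2`.
#'
#' @param g a [geno_matrix()] with at least 2 samples.
#' @return symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
pairwise_distance <- function(g) {
  n <- n_samples(g)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  x <- dosage(g)
  ok <- !is.na(x)
  # vectorised over dosage classes: |a - b| summed over mutually typed sites
  # is 1*(#01 + #10 + #12 + #21) + 2*(#02 + #20); d = sum|a-b| / (2 * n_typed)
  I0 <- matrix(as.double(ok & x == 0L), nrow = n)
  I1 <- matrix(as.double(ok & x == 1L), nrow = n)
  I2 <- matrix(as.double(ok & x == 2L), nrow = n)
  Ok <- matrix(as.double(ok), nrow = n)
  Nt <- Ok %*% t(Ok)
  S <- I0 %*% t(I1) + 2 * (I0 %*% t(I2)) + I1 %*% t(I2)
  S <- S + t(S)
  off <- which(Nt == 0 & upper.tri(Nt), arr.ind = TRUE)
  if (nrow(off)) {
    stop("samples ", g$sample_ids[off[1, 1]], " and ", g$sample_ids[off[1, 2]],
         " share no typed sites", call. = FALSE)
  }
  d <- S / (2 * Nt)
  diag(d) <- 0
  dimnames(d) <- list(g$sample_ids, g$sample_ids)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (Studier-Keppler algorithm via
#' \pkg{ape}), returned unrooted with negative branch lengths clamped to
#' zero.
#'
#' @param dm symmetric distance matrix with >= 3 samples.
#' @return an \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  check_distance_matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 samples for a tree", call. = FALSE)
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Classical MDS on double-centred squared distances, axes ordered by
#' eigenvalue. Axis signs follow the convention that the first non-zero
#' loading of each axis is positive.
#'
#' @param dm symmetric distance matrix.
#' @param k number of dimensions (`0 < k < n`).
#' @return list with `points` (n x k coordinate matrix) and `eig`
#'   (eigenvalues).
#' @export
classical_mds <- function(dm, k = 2L) {
  check_distance_matrix(dm)
  n <- nrow(dm)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k >= n) stop("k must be < number of samples", call. = FALSE)
  fit <- cmdscale(stats::as.dist(dm), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(dm)
  list(points = pts, eig = fit$eig)
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (any(abs(dm - t(dm)) > 1e-8)) stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(dm) != 0)) stop("distance matrix must have zero diagonal", call. = FALSE)
  if (any(dm < 0)) stop("distances must be non-negative", call. = FALSE)
  invisible(dm)
}

#' Per-sample silhouette scores for given group labels
#'
#' For sample i, `a_i` is the mean distance to the other members of its own
#' group and `b_i` the minimum over foreign groups of the mean distance to
#' that group (nearest-foreign-cluster convention; set
#' `b_mode = "all-foreign-mean"` to average over all foreign samples
#' instead). The silhouette is `s_i = (b_i - a_i) / max(a_i, b_i)`, `NA`
#' when the maximum is zero or the sample's group currently has a single
#' member.
#'
#' @param dm symmetric distance matrix.
#' @param labels group label per sample (recycled names from `dm` rows).
#' @param b_mode `"nearest-foreign"` (default) or `"all-foreign-mean"`.
#' @return data.frame of class `silhouette_report` with columns `sample_id`,
#'   `group`, `a`, `b`, `s`.
#' @export
silhouette_scores <- function(dm, labels, b_mode = c("nearest-foreign", "all-foreign-mean")) {
  b_mode <- match.arg(b_mode)
  check_distance_matrix(dm)
  n <- nrow(dm)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("every group needs >= 2 members (offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  a <- b <- s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- own[own != i]
    a[i] <- mean(dm[i, own])
    if (b_mode == "nearest-foreign") {
      b[i] <- min(vapply(setdiff(names(sizes), labels[i]), function(gr) {
        mean(dm[i, labels == gr])
      }, numeric(1)))
    } else {
      b[i] <- mean(dm[i, labels != labels[i]])
    }
    mx <- max(a[i], b[i])
    if (mx > 0) s[i] <- (b[i] - a[i]) / mx else s[i] <- NA_real_
  }
  structure(data.frame(sample_id = ids, group = labels, a = a, b = b, s = s,
                       stringsAsFactors = FALSE),
            class = c("silhouette_report", "data.frame"))
}

#' Iterative silhouette-based core-set filter
#'
#' Repeatedly computes silhouette scores on the current members and removes
#' poorly grouped samples: if any score is negative, all negative-score
#' samples are removed in that pass; otherwise all samples with scores at or
#' below `threshold` are removed. Iteration stops when every remaining score
#' exceeds `threshold`, or when a removal would shrink a group below 2
#' members (then the run stops and is flagged). Samples with undefined
#' scores are retained.
#'
#' @param dm symmetric distance matrix.
#' @param labels group label per sample.
#' @param threshold silhouette cutoff in `[-1, 1)` (default 0.1).
#' @param b_mode passed to [silhouette_scores()].
#' @param max_iter safety cap on iterations.
#' @return list of class `core_set`: `retained` (sample ids), `labels`
#'   (their groups), `iterations_run`, `converged`, `removals` (data.frame
#'   sample/group/score/iteration), `final_report`.
#' @export
iterative_core_filter <- function(dm, labels, threshold = 0.1,
                                  b_mode = "nearest-foreign", max_iter = nrow(dm)) {
  if (threshold < -1 || threshold >= 1) {
    stop("threshold must lie in [-1, 1)", call. = FALSE)
  }
  check_distance_matrix(dm)
  ids <- rownames(dm)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(dm)))
    dimnames(dm) <- list(ids, ids)
  }
  labels <- setNames(as.character(labels), ids)
  keep <- ids
  removals <- data.frame(sample_id = character(0), group = character(0),
                         s = numeric(0), iteration = integer(0),
                         stringsAsFactors = FALSE)
  converged <- FALSE
  iter <- 0L
  rep_now <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    rep_now <- silhouette_scores(dm[keep, keep, drop = FALSE], labels[keep],
                                 b_mode = b_mode)
    sc <- rep_now$s
    drop <- if (any(sc < 0, na.rm = TRUE)) {
      which(!is.na(sc) & sc < 0)
    } else {
      which(!is.na(sc) & sc <= threshold)
    }
    if (length(drop) == 0) {
      converged <- TRUE
      break
    }
    # stop (flagged) rather than let a group fall below 2 members
    if (any(table(factor(rep_now$group[-drop], levels = unique(rep_now$group))) < 2)) {
      break
    }
    removals <- rbind(removals, data.frame(
      sample_id = rep_now$sample_id[drop], group = rep_now$group[drop],
      s = sc[drop], iteration = iter, stringsAsFactors = FALSE))
    keep <- setdiff(keep, rep_now$sample_id[drop])
  }
  structure(list(retained = keep, labels = labels[keep],
                 iterations_run = iter, converged = converged,
                 removals = removals, final_report = rep_now),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d samples retained after %d iteration(s); %d removed%s\n",
              length(x$retained), x$iterations_run, nrow(x$removals),
              if (x$converged) "" else " [stopped: group-size floor]"))
  invisible(x)
}
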