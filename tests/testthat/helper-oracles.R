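# Independent brute-force oracles. Each recomputes a statistic from first
# principles (explicit loops, published formulas), sharing no code with the
# package implementation.

# Tajima (1989) constants and window statistics from a complete haplotype
# matrix (rows = haplotypes, no missing data, one window)
oracle_diversity <- function(haps) {
  n <- nrow(haps); m <- ncol(haps)
  stopifnot(!anyNA(haps))
  # mean pairwise difference, explicit double loop
  pi_total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi_total <- pi_total + sum(haps[i, ] != haps[j, ])
    }
  }
  pi_total <- pi_total / choose(n, 2)
  freqs <- colSums(haps)
  S <- sum(freqs > 0 & freqs < n)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_total <- S / a1
  v <- e1 * S + e2 * S * (S - 1)
  D <- if (v > 0) (pi_total - theta_total) / sqrt(v) else NA_real_
  list(pi = pi_total / m, theta_w = theta_total / m, S = S, tajima_d = D)
}

# Hudson Fst, per-site loop over one window given dosage matrices
oracle_fst <- function(dosA, dosB) {
  num <- den <- 0
  for (j in seq_len(ncol(dosA))) {
    a <- dosA[, j]; b <- dosB[, j]
    n1 <- 2 * sum(!is.na(a)); n2 <- 2 * sum(!is.na(b))
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(a, na.rm = TRUE) / n1; p2 <- sum(b, na.rm = TRUE) / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den > 0) num / den else NA_real_
}

# all-pairs r^2 binned by distance (single region window)
oracle_ld_bins <- function(dos, pos, bin_bp) {
  m <- ncol(dos)
  sums <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ok <- !is.na(dos[, i]) & !is.na(dos[, j])
      x <- dos[ok, i]; y <- dos[ok, j]
      if (length(x) < 2 || var(x) == 0 || var(y) == 0) next
      r2 <- (sum((x - mean(x)) * (y - mean(y))) /
               sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
      b <- (abs(pos[j] - pos[i]) %/% bin_bp)
      key <- as.character(b)
      if (is.null(sums[[key]])) sums[[key]] <- c(0, 0)
      sums[[key]] <- sums[[key]] + c(r2, 1)
    }
  }
  keys <- sort(as.integer(names(sums)))
  data.frame(distance_bin_start = keys * bin_bp,
             mean_r2 = vapply(as.character(keys), function(k) sums[[k]][1] / sums[[k]][2], 0),
             n_pairs = vapply(as.character(keys), function(k) sums[[k]][2], 0))
}

# f4 with explicit delete-one-block jackknife
oracle_f4 <- function(freqA, freqB, freqC, freqD, block_size) {
  v <- (freqA - freqB) * (freqC - freqD)
  v <- v[!is.na(v)]
  n <- length(v)
  blocks <- ((seq_len(n) - 1) %/% block_size) + 1
  B <- max(blocks)
  f4 <- mean(v)
  jk <- numeric(B)
  for (b in seq_len(B)) jk[b] <- mean(v[blocks != b])
  se <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
  list(f4 = f4, se = se)
}

# IBS distance per definition, explicit pair loop
oracle_distance <- function(dos) {
  n <- nrow(dos)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
      ibs <- mean((2 - abs(dos[i, ok] - dos[j, ok])) / 2)
      d[i, j] <- d[j, i] <- 1 - ibs
    }
  }
  d
}

# silhouette per definition (nearest foreign cluster)
oracle_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- a <- b <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    a[i] <- mean(d[i, own])
    b[i] <- min(vapply(setdiff(unique(labels), labels[i]), function(gr) {
      mean(d[i, which(labels == gr)])
    }, 0))
    s[i] <- if (max(a[i], b[i]) > 0) (b[i] - a[i]) / max(a[i], b[i]) else NA_real_
  }
  data.frame(a = a, b = b, s = s)
}

# exact two-sided Mann-Whitney p by bitmask enumeration of assignments,
# U counted directly over pairs (handles ties); combined n <= 15
oracle_mwu <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); n1 <- length(x)
  u_of <- function(xs, ys) {
    u <- 0
    for (xi in xs) for (yi in ys) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(x, y)
  us <- c()
  for (mask in 0:(2^n - 1)) {
    if (sum(bitwAnd(mask, 2^(0:(n - 1))) > 0) != n1) next
    sel <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    us <- c(us, u_of(vals[sel], vals[!sel]))
  }
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# minimum spanning tree total weight by exhaustive Pruefer enumeration
oracle_mst_total <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2, n <= 6)
  if (n == 2) return(D[1, 2])
  decode <- function(pruefer) {
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, nrow = n - 1, ncol = 2)
    k <- 1L
    pr <- pruefer
    for (v in pr) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, v); k <- k + 1L
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    rest <- which(degree == 1L)
    edges[k, ] <- rest
    edges
  }
  best <- Inf
  seqs <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
  for (r in seq_len(nrow(seqs))) {
    ed <- decode(as.integer(seqs[r, ]))
    w <- sum(D[ed])
    if (w < best) best <- w
  }
  best
}
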