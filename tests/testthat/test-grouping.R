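test_that("IBS distances match definition and the pair-loop oracle", {
  g1 <- make_geno(rbind(c(0, 1, 2), c(0, 1, 2)))
  d1 <- pairwise_distance(g1)
  expect_equal(d1[1, 2], 0)
  g2 <- make_geno(rbind(c(0, 0, 0), c(2, 2, 2)))
  expect_equal(pairwise_distance(g2)[1, 2], 1)
  for (s in 1:20) {
    g <- random_geno(8, 50, miss = 0.2, seed = s + 9)
    expect_equal(unname(pairwise_distance(g)), oracle_distance(dosage(g)),
                 tolerance = 1e-9)
  }
  # a pair with no shared typed sites errors with the pair named
  dos <- rbind(c(0L, NA), c(NA, 1L), c(1L, 1L))
  expect_error(pairwise_distance(make_geno(dos)), "s01.*s02")
})

test_that("neighbor joining recovers an additive 4-taxon topology", {
  # additive matrix for ((A,B),(C,D)) with internal branch 3
  dm <- matrix(c(0, 2, 7, 7,
                 2, 0, 7, 7,
                 7, 7, 0, 2,
                 7, 7, 2, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(dm)
  # the split {A,B} | {C,D} must be present: A and B form a cherry
  pairs <- ape::prop.part(tr)
  tips_of <- function(tr) {
    cher <- ape::extract.clade(tr, ape::getMRCA(tr, c("A", "B")))
    sort(cher$tip.label)
  }
  expect_identical(tips_of(ape::root(tr, outgroup = "C", resolve.root = TRUE)),
                   c("A", "B"))
  # tree distances reproduce the additive input
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(dm), rownames(dm)]),
               unname(dm), tolerance = 1e-9)
  # permuting input order keeps the same unrooted topology
  perm <- c(3, 1, 4, 2)
  tr2 <- neighbor_joining(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
  asym <- dm; asym[1, 2] <- 5
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("classical MDS recovers Euclidean configurations", {
  set.seed(3)
  pts <- cbind(runif(9, -5, 5), runif(9, -5, 5))
  dm <- as.matrix(dist(pts))
  fit <- classical_mds(dm, 2)
  expect_equal(as.matrix(dist(fit$points)), dm, ignore_attr = TRUE,
               tolerance = 1e-9)
  # sign convention: first non-zero loading of each axis positive
  for (j in 1:2) {
    nz <- which(abs(fit$points[, j]) > 1e-12)
    expect_gt(fit$points[nz[1], j], 0)
  }
  # regular simplex: all distances preserved
  dm3 <- matrix(1, 4, 4); diag(dm3) <- 0
  fit3 <- classical_mds(dm3, 3)
  expect_equal(as.matrix(dist(fit3$points)), dm3, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(classical_mds(dm, 0), "positive")
  expect_error(classical_mds(dm, 9), "< number")
})

test_that("silhouette scores match the closed form and the oracle", {
  # two tight clusters: within-distance 1, between-distance 3 -> s = 2/3
  d <- matrix(3, 6, 6)
  d[1:3, 1:3] <- 1; d[4:6, 4:6] <- 1
  diag(d) <- 0
  dimnames(d) <- list(letters[1:6], letters[1:6])
  rep1 <- silhouette_scores(d, rep(c("g1", "g2"), each = 3))
  expect_equal(rep1$s, rep(2 / 3, 6))
  expect_equal(rep1$a, rep(1, 6))
  expect_equal(rep1$b, rep(3, 6))
  # a == b -> s == 0
  d0 <- matrix(2, 4, 4); diag(d0) <- 0
  rep0 <- silhouette_scores(d0, c("x", "x", "y", "y"))
  expect_equal(rep0$s, rep(0, 4))
  # random fixtures against the definition oracle, and cluster::silhouette
  for (s in 1:20) {
    set.seed(s + 100)
    n <- 12
    labels <- sample(rep(c("p", "q", "r"), each = 4))
    d <- as.matrix(dist(matrix(runif(n * 3), n, 3)))
    got <- silhouette_scores(d, labels)
    want <- oracle_silhouette(d, labels)
    expect_equal(got$s, want$s, tolerance = 1e-9)
    expect_equal(got$a, want$a, tolerance = 1e-9)
    expect_equal(got$b, want$b, tolerance = 1e-9)
    sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
    expect_equal(got$s, unname(sil[, "sil_width"]), tolerance = 1e-9)
    expect_true(all(got$s >= -1 & got$s <= 1))
    # Eq identity on every row
    expect_equal(got$s, (got$b - got$a) / pmax(got$a, got$b), tolerance = 1e-12)
  }
  expect_error(silhouette_scores(d0, c("x", "x", "y", "z")), ">= 2 members")
})

test_that("iterative core filter removes planted midway samples and terminates", {
  # 3 clean clusters of 10 in 2-D plus 4 samples midway between cluster centers
  set.seed(5)
  centers <- rbind(c(0, 0), c(10, 0), c(5, 9))
  pts <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(20, sd = 0.3), 10, 2), 2, centers[k, ], "+")
  }))
  mids <- rbind((centers[1, ] + centers[2, ]) / 2 + rnorm(2, sd = 0.05),
                (centers[1, ] + centers[2, ]) / 2 + rnorm(2, sd = 0.05),
                (centers[2, ] + centers[3, ]) / 2 + rnorm(2, sd = 0.05),
                (centers[1, ] + centers[3, ]) / 2 + rnorm(2, sd = 0.05))
  all_pts <- rbind(pts, mids)
  ids <- sprintf("x%02d", 1:34)
  dm <- as.matrix(dist(all_pts)); dimnames(dm) <- list(ids, ids)
  labels <- c(rep(c("A", "B", "C"), each = 10), "A", "B", "C", "C")
  core <- iterative_core_filter(dm, labels, threshold = 0.1)
  expect_setequal(setdiff(ids, core$retained), ids[31:34])
  expect_true(core$converged)
  expect_true(all(core$final_report$s > 0.1, na.rm = TRUE))
  expect_lte(core$iterations_run, 34)
  # monotone in the threshold: stricter cutoff retains a subset
  strict <- iterative_core_filter(dm, labels, threshold = 0.12)
  expect_true(all(strict$retained %in% core$retained))
  # fixed point: clean clusters only, no removals
  clean <- iterative_core_filter(dm[1:30, 1:30], labels[1:30], threshold = 0.1)
  expect_equal(clean$iterations_run, 1L)
  expect_equal(nrow(clean$removals), 0L)
  expect_error(iterative_core_filter(dm, labels, threshold = 1), "threshold")
})

test_that("group structure of the synthetic domesticates is visible in MDS", {
  sim <- tiny_sim(seed = 13L)
  smp <- sim$samples
  ids <- smp$sample_id[smp$species == "domesticate"]
  gt <- thin_sites(subset_samples(sim$genotypes, ids),
                   window_bp = 5000L, min_spacing_bp = 2000L, seed = 1L)
  dm <- pairwise_distance(gt)
  labels <- smp$group[match(ids, smp$sample_id)]
  fit <- classical_mds(dm, 2)
  within <- mean(sapply(unique(labels), function(l) {
    mean(dist(fit$points[labels == l, ]))
  }))
  between <- mean(dist(fit$points))
  expect_lt(within, between)
})
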