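mk_net <- function(labels, members, status, edges) {
  # minimal haplo_network for unit tests: members is a list of carrier ids,
  # edges a data.frame(from, to, weight)
  structure(list(
    nodes = data.frame(label = labels,
                       haplotype = paste0("h", seq_along(labels)),
                       count = lengths(members), causal_status = status,
                       stringsAsFactors = FALSE),
    members = members, edges = edges,
    alleles = matrix(0L, length(labels), 1)
  ), class = "haplo_network")
}

test_that("haplotype geography tallies carriers per region", {
  samples <- toy_sample_table(
    c("m1", "m2", "g1", "x1"), groups = rep("G", 4),
    country = c("Mali", "Mali", "Guinea", "Chad"))
  net <- mk_net("I", list(c("m1", "m1", "m2", "g1")), "ancestral",
                data.frame(from = character(0), to = character(0),
                           weight = numeric(0)))
  geo <- haplotype_geography(net, samples)
  gI <- geo$I
  expect_equal(gI$count[gI$region == "Mali"], 3L)
  expect_equal(gI$count[gI$region == "Guinea"], 1L)
  expect_equal(attr(gI, "n"), 4L)
  # frequencies divide by per-region sampled haplotypes (2 per sample)
  expect_equal(gI$freq[gI$region == "Mali"], 3 / 4)
  # carriers without geography fall under "unknown"
  samples2 <- samples; samples2$country[1:2] <- NA
  geo2 <- haplotype_geography(net, samples2)
  expect_equal(geo2$I$count[geo2$I$region == "unknown"], 3L)
  expect_true(is.na(geo2$I$freq[geo2$I$region == "unknown"]))
})

test_that("nearest ancestral pairs follow tree-path distances with ties reported", {
  # chain anc -- d1 -- d2 with unit weights
  net <- mk_net(c("I", "II", "III"),
                list("a", "b", "c"),
                c("ancestral", "derived", "derived"),
                data.frame(from = c("I", "II"), to = c("II", "III"),
                           weight = c(1, 1)))
  pairs <- nearest_ancestral(net)
  expect_equal(pairs$distance[pairs$derived == "II"], 1)
  expect_equal(pairs$distance[pairs$derived == "III"], 2)
  expect_true(pairs$founding[pairs$derived == "II"])
  expect_false(pairs$founding[pairs$derived == "III"])
  # two ancestral nodes equidistant from one derived: both reported
  net2 <- mk_net(c("I", "II", "III"),
                 list("a", "b", "c"),
                 c("ancestral", "derived", "ancestral"),
                 data.frame(from = c("I", "II"), to = c("II", "III"),
                            weight = c(2, 2)))
  pairs2 <- nearest_ancestral(net2)
  expect_equal(nrow(pairs2), 2L)
  expect_setequal(pairs2$ancestral, c("I", "III"))
  net3 <- mk_net("I", list("a"), "derived",
                 data.frame(from = character(0), to = character(0),
                            weight = numeric(0)))
  expect_error(nearest_ancestral(net3), "polarized")
})

test_that("a derived haplotype two mutations from its ancestor is reported at distance 2", {
  # haplotype II separated from ancestral I by a linked SNP plus the causal
  # mutation; VI one further step from II
  haps <- rbind(c(0, 0, 0), # I  (ancestral)
                c(1, 1, 0), # II (derived: linked site + causal)
                c(1, 1, 1)) # VI (derived, evolved from II)
  hs <- list(chrom = "chr4", start = 25146000L, end = 25153000L,
             pos = c(25146871L, 25152034L, 25152500L),
             alleles = haps[c(1, 1, 1, 1, 2, 2, 2, 3, 3), ],
             carrier = c("w1", "w1", "w2", "w2", "g1", "g1", "g2", "g3", "g3"),
             causal_status = rep("unknown", 9), n_excluded = 0L)
  class(hs) <- "haplotype_set"
  hs <- set_causal_status(hs, causal_pos = 25152034L)
  net <- hamming_mst(collapse_haplotypes(hs))
  pairs <- nearest_ancestral(net)
  founding <- pairs[pairs$founding, ]
  expect_equal(founding$distance, 2)
  # the founding derived node is the II-analog (most common derived string)
  lab_II <- net$nodes$label[net$nodes$haplotype == "110"]
  expect_equal(founding$derived, lab_II)
})

test_that("origin inference scores range overlap and flags disjoint ranges", {
  mk_geo <- function(regions, counts, totals) {
    df <- data.frame(region = regions, count = counts,
                     freq = counts / totals, stringsAsFactors = FALSE)
    attr(df, "n") <- sum(counts)
    class(df) <- c("geo_distribution", "data.frame")
    df
  }
  anc <- mk_geo(c("Mali", "Cameroon"), c(2, 3), 20)
  der <- mk_geo(c("Mali", "Guinea"), c(5, 4), 20)
  orig <- infer_origin(anc, der, locus_id = "sh4-like")
  expect_equal(orig$top_regions, "Mali")
  expect_equal(orig$status, "determinate")
  expect_equal(orig$n_ancestral, 5L)
  expect_equal(orig$n_derived, 9L)
  # symmetry of the overlap score
  rev <- infer_origin(der, anc)
  expect_equal(orig$scores$overlap[order(orig$scores$region)],
               rev$scores$overlap[order(rev$scores$region)])
  # identical uniform distributions: all shared regions tie
  unif <- mk_geo(c("Mali", "Cameroon"), c(3, 3), 20)
  same <- infer_origin(unif, unif)
  expect_setequal(same$top_regions, c("Mali", "Cameroon"))
  # disjoint ranges: indeterminate
  dis <- infer_origin(mk_geo("Chad", 4, 10), mk_geo("Guinea", 6, 10))
  expect_equal(dis$status, "disjoint")
  expect_equal(length(dis$top_regions), 0L)
  # overlap bounded by both marginal frequencies
  expect_true(all(orig$scores$overlap <= orig$scores$freq_anc + 1e-12))
  expect_true(all(orig$scores$overlap <= orig$scores$freq_der + 1e-12))
})

test_that("per-region carrier counts on synthetic data equal the truth tallies", {
  sim <- tiny_sim(seed = 19L)
  loci <- sim$truth$loci
  wild <- sim$samples$sample_id[sim$samples$species == "wild" &
                                  sim$samples$group != "FER"]
  dom <- sim$samples$sample_id[sim$samples$species == "domesticate"]
  sc <- select_nonrecombining_region(sim$genotypes, loci$chrom[1], loci$pos[1],
                                     loci$sweep_halfwidth[1], wild, dom)
  expect_equal(sc$status, "ok")
  h <- set_causal_status(sc$haplotypes, causal_pos = loci$pos[1])
  net <- hamming_mst(collapse_haplotypes(h))
  geo <- haplotype_geography(net, sim$samples)
  der_nodes <- net$nodes$label[net$nodes$causal_status == "derived"]
  # summed derived-node counts per country equal truth carrier haplotypes
  got <- Reduce(`+`, lapply(der_nodes, function(l) {
    v <- setNames(rep(0L, 5), paste0("country_", 1:5))
    gg <- geo[[l]]
    v[gg$region] <- v[gg$region] + gg$count
    v
  }))
  carriers <- intersect(sim$truth$derived_carriers$snpA, c(wild, dom))
  want <- vapply(paste0("country_", 1:5), function(cty) {
    2L * sum(sim$samples$country[match(carriers, sim$samples$sample_id)] == cty)
  }, integer(1))
  expect_equal(got, want)
})
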