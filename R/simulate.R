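# Synthetic metapopulation generator.
#
# The model is a founder-haplotype pool, not a coalescent: each geographic
# region (a cell on a 1-D west->east axis) holds a pool of k wild founder
# haplotypes, each differing from the regional consensus by a random set of
# mutations (Poisson-distributed count, rate founder_mut_rate per site).
# Wild samples copy two founders from their region's pool. The domesticate
# passed through a bottleneck: its per-region pool is a thinned subset of
# b < k founders drawn with skewed frequencies. Causal domestication loci
# (a SNP and whole-gene deletions) each arise on one founder haplotype in
# one seeded origin region; a domesticate in region r carries the derived
# haplotype with probability d^|r - origin|, and every carrier is homozygous
# for the single derived founder segment within sweep_halfwidth of the locus
# (a local sweep). Gene deletions additionally blank all genotypes inside
# the deleted span and force zero read depth. The feral group is a
# per-chromosome mosaic of domesticate and wild genomes.

run_with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Default causal-locus table for the synthetic generator
#'
#' Three loci mirror the archetypes of crop-domestication genetics: a causal
#' SNP (a nonsense-mutation analogue) and two whole-gene deletions, each
#' seeded in a different origin region with a local sweep.
#'
#' @return data.frame with columns `locus_id`, `chrom`, `pos`, `type`,
#'   `origin_region`, `sweep_halfwidth`, `del_halfwidth`, `trait`.
#' @export
default_loci <- function() {
  data.frame(
    locus_id = c("snpA", "delB", "delC"),
    chrom = c("chr1", "chr2", "chr3"),
    pos = c(1000000L, 600000L, 1400000L),
    type = c("snp", "gene_deletion", "gene_deletion"),
    origin_region = c(3L, 2L, 4L),
    sweep_halfwidth = c(12000L, 10000L, 10000L),
    del_halfwidth = c(0L, 3000L, 3000L),
    trait = c("shattering", "shattering", "growth"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-data generator configuration
#'
#' Defaults define the standard study conditions used by the package's own
#' validation: 5 regions, 30 domesticates per regional group, 15 wild
#' samples per region (labelled as two wild genetic groups, west and east),
#' 20 feral hybrids descended from 6 founder lineages, 4 chromosomes of
#' 2 Mbp with ~1 segregating site per 100 bp, wild pools of 12 founders
#' (bottlenecked to 4, with skewed frequencies, in the domesticate),
#' diffusion d = 0.5 and 15x sequencing coverage.
#'
#' @param n_regions number of geographic cells on the west->east axis.
#' @param n_dom_per_group domesticate samples per regional genetic group.
#' @param n_wild_per_region wild samples per region.
#' @param n_feral feral (wild-labelled mosaic) samples.
#' @param n_chrom,chrom_length,n_sites_per_chrom genome dimensions.
#' @param k_founders wild founder haplotypes per regional pool.
#' @param b_founders bottlenecked founder count per domesticate pool
#'   (must be < `k_founders`).
#' @param founder_mut_rate per-site probability that a founder differs from
#'   its regional consensus (expected mutations per founder,
#'   `lambda_w = founder_mut_rate * n_sites_per_chrom`).
#' @param region_mut_rate per-site probability that a regional consensus
#'   differs from the global ancestral haplotype.
#' @param dom_drift_rate per-site mutation mass on the domestication-drift
#'   branches: each domesticate pool haplotype is a drifted child of its
#'   wild founder, which creates within-domesticate group differentiation.
#' @param dom_stem_rate mutation mass on the domestication stem (sites
#'   fixed derived in every domesticate pool haplotype, absent in the
#'   wild): the bottleneck's fixed differences driving wild/domesticate
#'   Fst.
#' @param dom_founder_weights sampling weights of the `b_founders`
#'   domesticate-pool haplotypes (recycled/normalised).
#' @param loci causal-locus table, see [default_loci()].
#' @param diffusion d in \[0, 1\]: a domesticate in region r carries a locus's
#'   derived haplotype with probability `d^|r - origin_region|`.
#' @param feral_admixture probability that a feral chromosome is copied from
#'   a wild rather than a domesticate sample.
#' @param n_feral_founders size of the feral group's founder haplotype pool
#'   (the de-domesticated population descends from few hybrid lineages,
#'   which is what elevates its LD).
#' @param mean_coverage mean sequencing depth per sample (reads per base).
#' @param rng_seed integer seed; identical config + seed give identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 5L,
                       n_dom_per_group = 30L,
                       n_wild_per_region = 15L,
                       n_feral = 20L,
                       n_chrom = 4L,
                       chrom_length = 2000000L,
                       n_sites_per_chrom = 20000L,
                       k_founders = 12L,
                       b_founders = 4L,
                       founder_mut_rate = 0.10,
                       region_mut_rate = 0.03,
                       dom_drift_rate = 0.02,
                       dom_stem_rate = 0.08,
                       dom_founder_weights = c(0.4, 0.3, 0.2, 0.1),
                       loci = default_loci(),
                       diffusion = 0.5,
                       feral_admixture = 0.25,
                       n_feral_founders = 6L,
                       mean_coverage = 15,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("n_regions", "n_dom_per_group", "n_wild_per_region", "n_feral",
               "n_chrom", "chrom_length", "n_sites_per_chrom", "k_founders",
               "b_founders", "n_feral_founders")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  for (nm in c("n_regions", "n_dom_per_group", "n_wild_per_region", "n_chrom",
               "chrom_length", "n_sites_per_chrom", "k_founders", "b_founders")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop(nm, " must be a positive integer", call. = FALSE)
    }
  }
  if (cfg$n_feral < 0) stop("n_feral must be >= 0", call. = FALSE)
  if (cfg$b_founders >= cfg$k_founders) {
    stop("b_founders must be < k_founders (domestication bottleneck)", call. = FALSE)
  }
  if (cfg$diffusion < 0 || cfg$diffusion > 1) stop("diffusion must lie in [0, 1]", call. = FALSE)
  if (cfg$feral_admixture < 0 || cfg$feral_admixture > 1) {
    stop("feral_admixture must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$mean_coverage < 0) stop("mean_coverage must be >= 0", call. = FALSE)
  if (cfg$founder_mut_rate < 0 || cfg$founder_mut_rate > 1 ||
      cfg$region_mut_rate < 0 || cfg$region_mut_rate > 1 ||
      cfg$dom_drift_rate < 0 || cfg$dom_drift_rate > 1 ||
      cfg$dom_stem_rate < 0 || cfg$dom_stem_rate > 1) {
    stop("mutation rates must lie in [0, 1]", call. = FALSE)
  }
  loci <- cfg$loci
  need <- c("locus_id", "chrom", "pos", "type", "origin_region",
            "sweep_halfwidth", "del_halfwidth", "trait")
  if (!all(need %in% names(loci))) {
    stop("loci table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!loci$type %in% c("snp", "gene_deletion"))) {
    stop("locus type must be 'snp' or 'gene_deletion'", call. = FALSE)
  }
  if (any(loci$origin_region < 1L | loci$origin_region > cfg$n_regions)) {
    stop("origin_region must lie in 1..n_regions", call. = FALSE)
  }
  if (any(loci$sweep_halfwidth < 0)) stop("sweep_halfwidth must be >= 0", call. = FALSE)
  cfg$dom_founder_weights <- rep_len(cfg$dom_founder_weights, cfg$b_founders)
  cfg$dom_founder_weights <- cfg$dom_founder_weights / sum(cfg$dom_founder_weights)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured wild/domesticate/feral dataset
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (phased [geno_matrix()]), `samples`
#'   (a `sample_table` with extra `region` column), `truth` (ground-truth
#'   record: loci with sweep intervals, derived carriers, deletion carriers,
#'   founder lineage ids) and `phenotype` (per-sample percent shattering and
#'   SES score derived from the shattering-trait loci).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  run_with_seed(cfg$rng_seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  R <- cfg$n_regions
  samples <- build_sample_frame(cfg)
  N <- nrow(samples)
  hap_region <- rep(samples$region, each = 2L)
  is_dom_hap <- rep(samples$species == "domesticate", each = 2L)
  dom_rows <- which(samples$species == "domesticate")
  wild_rows <- which(samples$species == "wild" & samples$group != "FER")
  feral_rows <- which(samples$group == "FER")

  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  # per-locus carrier draw (domesticates; once per individual per locus)
  loci <- cfg$loci
  carrier <- matrix(FALSE, nrow = N, ncol = nrow(loci),
                    dimnames = list(samples$sample_id, loci$locus_id))
  for (l in seq_len(nrow(loci))) {
    pr <- cfg$diffusion ^ abs(samples$region - loci$origin_region[l])
    pr[samples$species != "domesticate" | samples$group == "FER"] <- 0
    carrier[, l] <- runif(N) < pr
  }

  # feral mosaics: each of a feral's two copies of each chromosome is
  # copied from an independent random source haplotype (wild with
  # probability feral_admixture, else domesticate), so ferals are
  # domesticate x wild hybrids with admixture LD. feral_hap_src[[ci]] maps
  # each feral haplotype row to its source sample index.
  feral_hap_src <- vector("list", cfg$n_chrom)

  hap_list <- vector("list", cfg$n_chrom)
  site_chrom <- character(0); site_pos <- integer(0)
  lineage <- vector("list", cfg$n_chrom)
  sweep_truth <- data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
                            start = pmax(1L, loci$pos - loci$sweep_halfwidth),
                            end = loci$pos + loci$sweep_halfwidth,
                            stringsAsFactors = FALSE)

  for (ci in seq_len(cfg$n_chrom)) {
    chrom <- chroms[ci]
    m <- cfg$n_sites_per_chrom
    pos <- sort(sample.int(cfg$chrom_length, m))
    # causal SNP positions must exist as sites
    for (l in which(loci$chrom == chrom & loci$type == "snp")) {
      pos <- sort(unique(c(pos, loci$pos[l])))
    }
    m <- length(pos)

    # founder pools on a perfect phylogeny: every site receives exactly one
    # mutation on one branch of a founder genealogy (regional stem, a nested
    # within-region clade, or a founder-private tip), so founder haplotypes
    # are infinite-sites compatible and recombination-free regions pass the
    # four-gamete test by construction.
    founders <- build_founder_pool(cfg, m)

    loc_here <- which(loci$chrom == chrom)
    # causal SNP columns start ancestral everywhere
    for (l in loc_here) {
      if (loci$type[l] == "snp") founders[, match(loci$pos[l], pos)] <- 0L
    }

    # assign founder haplotypes
    founder_idx <- integer(2L * N)
    for (i in seq_len(N)) {
      r <- samples$region[i]
      hr <- c(2L * i - 1L, 2L * i)
      if (i %in% dom_rows) {
        pool <- R * cfg$k_founders + (r - 1L) * cfg$b_founders + seq_len(cfg$b_founders)
        founder_idx[hr] <- sample(pool, 2L, replace = TRUE, prob = cfg$dom_founder_weights)
      } else if (i %in% wild_rows) {
        pool <- (r - 1L) * cfg$k_founders + seq_len(cfg$k_founders)
        founder_idx[hr] <- sample(pool, 2L, replace = TRUE)
      }
    }
    haps <- founders[pmax(founder_idx, 1L), , drop = FALSE]
    haps[founder_idx == 0L, ] <- NA_integer_ # feral rows, filled after loci

    # causal loci on wild/domesticate haplotypes: derived founder segment
    # (homozygous in carriers), deletion blanking
    for (l in loc_here) {
      hw <- loci$sweep_halfwidth[l]
      seg <- which(pos >= loci$pos[l] - hw & pos <= loci$pos[l] + hw)
      origin_pool1 <- (loci$origin_region[l] - 1L) * cfg$k_founders + 1L
      derived_seg <- founders[origin_pool1, seg]
      if (loci$type[l] == "snp") {
        derived_seg[match(match(loci$pos[l], pos), seg)] <- 1L
      }
      rows <- which(rep(carrier[, l], each = 2L))
      if (length(rows) && length(seg)) {
        haps[rows, seg] <- matrix(derived_seg, nrow = length(rows),
                                  ncol = length(seg), byrow = TRUE)
      }
      if (loci$type[l] == "gene_deletion") {
        dhw <- loci$del_halfwidth[l]
        span <- which(pos >= loci$pos[l] - dhw & pos < loci$pos[l] + dhw)
        if (length(rows) && length(span)) haps[rows, span] <- NA_integer_
      }
    }

    # feral group: a de-domesticated hybrid population descended from a
    # small pool of founder lineages. Per chromosome, each feral founder
    # haplotype is copied from a random source haplotype (wild with
    # probability feral_admixture, else domesticate) -- a per-chromosome
    # mosaic -- and each feral individual draws its two copies from that
    # founder pool, giving the group its characteristic founder-effect LD.
    # Carrier segments and deletion blanks are inherited verbatim.
    if (length(feral_rows)) {
      nf <- cfg$n_feral_founders
      from_wild <- runif(nf) < cfg$feral_admixture
      ff_src <- integer(nf)
      ff_src[from_wild] <- sample(wild_rows, sum(from_wild), replace = TRUE)
      ff_src[!from_wild] <- sample(dom_rows, sum(!from_wild), replace = TRUE)
      ff_hap <- 2L * ff_src - sample(0:1, nf, replace = TRUE)
      n_fh <- 2L * length(feral_rows)
      pick <- sample.int(nf, n_fh, replace = TRUE)
      fh_rows <- as.vector(rbind(2L * feral_rows - 1L, 2L * feral_rows))
      haps[fh_rows, ] <- haps[ff_hap[pick], , drop = FALSE]
      founder_idx[fh_rows] <- founder_idx[ff_hap[pick]]
      feral_hap_src[[ci]] <- setNames(ff_src[pick], fh_rows)
    }

    hap_list[[ci]] <- haps
    lineage[[ci]] <- founder_idx
    site_chrom <- c(site_chrom, rep(chrom, m))
    site_pos <- c(site_pos, pos)
  }

  haplotypes <- do.call(cbind, hap_list)
  g <- geno_matrix(samples$sample_id, site_chrom, site_pos,
                   ref = rep("A", length(site_pos)), alt = rep("T", length(site_pos)),
                   haplotypes = haplotypes)

  # causal-allele copy number: domesticate carriers are homozygous (2);
  # ferals inherit per copied haplotype (0, 1 or 2)
  copies <- matrix(0L, nrow = N, ncol = nrow(loci),
                   dimnames = list(samples$sample_id, loci$locus_id))
  copies[carrier] <- 2L
  if (length(feral_rows)) {
    chrom_of <- match(loci$chrom, chroms)
    for (l in seq_len(nrow(loci))) {
      src <- feral_hap_src[[chrom_of[l]]]
      for (i in feral_rows) {
        s <- src[as.character(c(2L * i - 1L, 2L * i))]
        copies[i, l] <- sum(carrier[s, l])
        carrier[i, l] <- copies[i, l] >= 1L
      }
    }
  }

  deletion_loci <- loci$locus_id[loci$type == "gene_deletion"]
  deletion_carriers <- lapply(setNames(deletion_loci, deletion_loci), function(id) {
    samples$sample_id[copies[, id] == 2L]
  })
  derived_carriers <- lapply(setNames(loci$locus_id, loci$locus_id), function(id) {
    samples$sample_id[carrier[, id]]
  })

  truth <- list(
    loci = cbind(loci, sweep_start = sweep_truth$start, sweep_end = sweep_truth$end),
    origin_region = setNames(loci$origin_region, loci$locus_id),
    origin_country = setNames(paste0("country_", loci$origin_region), loci$locus_id),
    derived_carriers = derived_carriers,
    deletion_carriers = deletion_carriers,
    deletion_copies = copies[, deletion_loci, drop = FALSE],
    region = setNames(samples$region, samples$sample_id),
    lineage = lineage,
    config = cfg
  )

  phenotype <- simulate_phenotype(samples, truth)
  list(genotypes = g, samples = samples, truth = truth, phenotype = phenotype)
}

# one-mutation-per-site founder construction: branches are (i) the regional
# stem carrying all k wild founders of one region, (ii) nested caterpillar
# clades within a region, (iii) founder-private tips, and (iv)
# domestication-drift tips private to the domesticate copy of a pool
# founder. The domesticate pool haplotype h of region r is a drifted child
# of wild founder h, so it inherits every wild branch above it. Each site
# mutates on exactly one branch, so the full haplotype pool is
# infinite-sites compatible (a perfect phylogeny): recombination-free
# regions pass the four-gamete test by construction. Branch weights derive
# from region_mut_rate (stem mass), founder_mut_rate (clade + tip mass,
# split evenly) and dom_drift_rate (drift-tip mass per region).
# Returns rows 1..R*k = wild founders, rows R*k + (r-1)*b + h = domesticate
# pool haplotypes.
build_founder_pool <- function(cfg, m) {
  R <- cfg$n_regions; k <- cfg$k_founders; b <- cfg$b_founders
  wrow <- function(r, f) (r - 1L) * k + f
  drow <- function(r, h) R * k + (r - 1L) * b + h
  branches <- list(); w <- numeric(0)
  add <- function(rows, weight) {
    branches[[length(branches) + 1L]] <<- rows
    w <<- c(w, weight)
  }
  # domestication stem: sites fixed derived across the whole domesticate
  # pool and absent from the wild (the bottleneck's fixed differences).
  # Monomorphic within each four-gamete partition, so tree-consistency of
  # the wild-only and domesticate-only partitions is preserved.
  all_dom <- as.vector(vapply(seq_len(R), function(r) drow(r, seq_len(b)),
                              integer(b)))
  add(all_dom, cfg$dom_stem_rate)
  for (r in seq_len(R)) {
    dom_of <- function(fs) drow(r, fs[fs <= b])
    add(c(wrow(r, seq_len(k)), drow(r, seq_len(b))), cfg$region_mut_rate)
    perm <- sample(k)
    if (k > 2) {
      for (t in 2:(k - 1)) {
        fs <- perm[t:k]
        add(c(wrow(r, fs), dom_of(fs)), cfg$founder_mut_rate / (2 * (k - 2)))
      }
    }
    for (f in seq_len(k)) {
      add(c(wrow(r, f), dom_of(f)), cfg$founder_mut_rate / (2 * k))
    }
    for (h in seq_len(b)) {
      add(drow(r, h), cfg$dom_drift_rate / b)
    }
  }
  founders <- matrix(0L, nrow = R * k + R * b, ncol = m)
  if (sum(w) > 0) {
    ib <- sample.int(length(branches), m, replace = TRUE, prob = w)
    for (bi in seq_along(branches)) {
      cols <- which(ib == bi)
      if (length(cols)) founders[branches[[bi]], cols] <- 1L
    }
  }
  founders
}

build_sample_frame <- function(cfg) {
  R <- cfg$n_regions
  ids <- character(0); species <- character(0); group <- character(0); region <- integer(0)
  for (r in seq_len(R)) {
    n <- cfg$n_dom_per_group
    ids <- c(ids, sprintf("dom_r%d_%02d", r, seq_len(n)))
    species <- c(species, rep("domesticate", n))
    group <- c(group, rep(sprintf("DOM%d", r), n))
    region <- c(region, rep(r, n))
  }
  west <- seq_len(R) <= ceiling(R / 2)
  for (r in seq_len(R)) {
    n <- cfg$n_wild_per_region
    ids <- c(ids, sprintf("wild_r%d_%02d", r, seq_len(n)))
    species <- c(species, rep("wild", n))
    group <- c(group, rep(if (west[r]) "WLD-W" else "WLD-E", n))
    region <- c(region, rep(r, n))
  }
  if (cfg$n_feral > 0) {
    ids <- c(ids, sprintf("feral_%02d", seq_len(cfg$n_feral)))
    species <- c(species, rep("wild", cfg$n_feral)) # mislabeled as wild
    group <- c(group, rep("FER", cfg$n_feral))
    region <- c(region, sample.int(R, cfg$n_feral, replace = TRUE))
  }
  # geographic cells on a west->east axis; coordinates jittered within cells
  lon0 <- -16; cell_w <- 2.5
  lon <- lon0 + (region - 1L) * cell_w + runif(length(ids), 0, cell_w)
  lat <- runif(length(ids), 9, 14)
  as_sample_table(data.frame(
    sample_id = ids, species = species, group = group,
    country = paste0("country_", region),
    lat = round(lat, 5), lon = round(lon, 5),
    mean_coverage = cfg$mean_coverage,
    region = region,
    stringsAsFactors = FALSE
  ))
}

# percent shattering decreases with the number of derived shattering-trait
# alleles carried; wild samples shatter fully.
simulate_phenotype <- function(samples, truth) {
  loci <- truth$loci
  sh_loci <- loci$locus_id[loci$trait == "shattering"]
  n_derived <- rowSums(vapply(sh_loci, function(id) {
    samples$sample_id %in% truth$derived_carriers[[id]]
  }, logical(nrow(samples))))
  pct <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    pct[i] <- if (n_derived[i] >= 2) runif(1, 0, 0.9)
    else if (n_derived[i] == 1) runif(1, 1, 15)
    else if (samples$species[i] == "domesticate") runif(1, 26, 100)
    else runif(1, 51, 100)
  }
  data.frame(sample_id = samples$sample_id,
             percent_shattering = round(pct, 3),
             ses_score = ses_score(round(pct, 3)),
             stringsAsFactors = FALSE)
}

#' Simulate per-gene median read depths
#'
#' For every (sample, gene) pair the median of per-base read depths drawn
#' from Poisson(`mean_coverage`) is reported; genes deleted in the truth
#' record have depth exactly zero.
#'
#' @param truth truth record from [simulate_dataset()] (uses
#'   `deletion_carriers`).
#' @param samples a `sample_table` (uses `mean_coverage`).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   intervals half-open and non-overlapping. Rows whose `gene_id` matches a
#'   deletion locus are zeroed for that locus's carriers.
#' @param seed integer RNG seed.
#' @return a `depth_table`.
#' @export
simulate_depths <- function(truth, samples, genes, seed = 1L) {
  if (any(samples$mean_coverage < 0)) stop("mean_coverage must be >= 0", call. = FALSE)
  if (any(genes$start >= genes$end)) stop("gene intervals must satisfy start < end", call. = FALSE)
  o <- order(genes$chrom, genes$start)
  gs <- genes[o, ]
  same <- gs$chrom[-1] == gs$chrom[-nrow(gs)]
  if (nrow(gs) > 1 && any(same & gs$start[-1] < gs$end[-nrow(gs)])) {
    stop("gene intervals must be non-overlapping", call. = FALSE)
  }
  run_with_seed(seed, {
    rows <- expand.grid(sample_id = samples$sample_id, gene_id = genes$gene_id,
                        stringsAsFactors = FALSE)
    rows <- merge(rows, genes, by = "gene_id", sort = FALSE)
    rows$median_depth <- NA_real_
    cov <- samples$mean_coverage[match(rows$sample_id, samples$sample_id)]
    cp <- truth$deletion_copies
    for (k in seq_len(nrow(rows))) {
      gid <- rows$gene_id[k]
      # deleted haplotype copies reduce coverage proportionally; a
      # homozygous deletion has exactly zero depth
      n_del <- if (!is.null(cp) && gid %in% colnames(cp)) {
        cp[rows$sample_id[k], gid]
      } else if (gid %in% names(truth$deletion_carriers)) {
        2L * (rows$sample_id[k] %in% truth$deletion_carriers[[gid]])
      } else 0L
      if (n_del == 2L) {
        rows$median_depth[k] <- 0
      } else {
        L <- rows$end[k] - rows$start[k]
        rows$median_depth[k] <- median(rpois(L, cov[k] * (2L - n_del) / 2))
      }
    }
    as_depth_table(rows[, c("sample_id", "gene_id", "chrom", "start", "end",
                            "median_depth")])
  })
}

#' Gene intervals matching the default causal-locus table
#'
#' Target genes span each default deletion locus; a control gene lies on a
#' chromosome with no deletions.
#'
#' @param cfg a [sim_config()].
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
default_genes <- function(cfg = sim_config()) {
  loci <- cfg$loci
  del <- loci[loci$type == "gene_deletion", ]
  genes <- data.frame(
    gene_id = del$locus_id, chrom = del$chrom,
    start = del$pos - del$del_halfwidth, end = del$pos + del$del_halfwidth,
    stringsAsFactors = FALSE
  )
  ctrl_chrom <- setdiff(paste0("chr", seq_len(cfg$n_chrom)), del$chrom)[1]
  if (is.na(ctrl_chrom)) ctrl_chrom <- paste0("chr", cfg$n_chrom)
  rbind(genes, data.frame(gene_id = "control", chrom = ctrl_chrom,
                          start = 1000000L, end = 1006000L))
}
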