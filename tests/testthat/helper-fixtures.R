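# small in-code fixtures shared across test files

# unphased genotype matrix from a dosage matrix (samples x sites)
make_geno <- function(dos, pos = NULL, chrom = "chr1", ids = NULL) {
  dos <- as.matrix(dos)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(dos)))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 100L
  geno_matrix(ids, rep(chrom, ncol(dos)), pos,
              ref = rep("A", ncol(dos)), alt = rep("G", ncol(dos)),
              dosage = dos)
}

# phased genotype matrix from a haplotype matrix ((2 x samples) x sites)
make_hap_geno <- function(haps, pos = NULL, chrom = "chr1", ids = NULL) {
  haps <- as.matrix(haps)
  n <- nrow(haps) / 2
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  if (is.null(pos)) pos <- seq_len(ncol(haps)) * 100L
  geno_matrix(ids, rep(chrom, ncol(haps)), pos,
              ref = rep("A", ncol(haps)), alt = rep("G", ncol(haps)),
              haplotypes = haps)
}

# random unphased matrix with optional missingness
random_geno <- function(n, m, miss = 0, seed = 1) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) dos[runif(n * m) < miss] <- NA
  make_geno(dos)
}

# a quick small simulation for pipeline-level tests
tiny_sim <- function(seed = 7L, ...) {
  simulate_dataset(sim_config(
    n_dom_per_group = 8L, n_wild_per_region = 6L, n_feral = 6L,
    n_chrom = 2L, chrom_length = 400000L, n_sites_per_chrom = 3000L,
    loci = data.frame(locus_id = c("snpA", "delB"),
                      chrom = c("chr1", "chr2"),
                      pos = c(200000L, 200000L),
                      type = c("snp", "gene_deletion"),
                      origin_region = c(3L, 2L),
                      sweep_halfwidth = c(8000L, 8000L),
                      del_halfwidth = c(0L, 2000L),
                      trait = c("shattering", "shattering"),
                      stringsAsFactors = FALSE),
    rng_seed = seed, ...))
}

toy_sample_table <- function(ids, groups, species = NULL, country = NULL) {
  n <- length(ids)
  if (is.null(species)) species <- rep("domesticate", n)
  if (is.null(country)) country <- rep("countryX", n)
  as_sample_table(data.frame(
    sample_id = ids, species = species, group = groups, country = country,
    lat = rep(10, n), lon = rep(-10, n), mean_coverage = rep(15, n),
    stringsAsFactors = FALSE))
}
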