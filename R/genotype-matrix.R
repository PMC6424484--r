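#' Genotype matrix container
#'
#' A `geno_matrix` holds biallelic SNP genotypes for a set of samples:
#' per-site chromosome, 1-based position (VCF convention), reference and
#' alternate alleles, and either an unphased diploid alt-allele dosage matrix
#' (values 0/1/2, `NA` for missing) or, for phased data, additionally a
#' haplotype matrix with two rows per sample (values 0/1, `NA` missing).
#' Sites are kept sorted by chromosome and strictly increasing position.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param chrom character vector, contig name per site.
#' @param pos integer vector, 1-based coordinate per site.
#' @param ref,alt single-character alleles per site; must differ at every site.
#' @param dosage samples x sites integer matrix of alt-allele dosages
#'   (0, 1, 2 or `NA`). Derived from `haplotypes` when phased data are given.
#' @param haplotypes optional (2 x samples) x sites matrix of 0/1 alleles;
#'   rows `2i - 1` and `2i` are the two haplotypes of sample `i`.
#' @param phased logical flag; `TRUE` requires `haplotypes`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sample_ids, chrom, pos, ref, alt,
                        dosage = NULL, haplotypes = NULL, phased = !is.null(haplotypes)) {
  sample_ids <- as.character(sample_ids)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  m <- length(pos)
  if (length(chrom) != m || length(ref) != m || length(alt) != m) {
    stop("chrom, pos, ref, alt must have one entry per site", call. = FALSE)
  }
  if (m > 0 && any(ref == alt)) {
    stop("ref and alt alleles must differ at every site", call. = FALSE)
  }
  if (phased) {
    if (is.null(haplotypes)) stop("phased data require a haplotype matrix", call. = FALSE)
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) != 2L * length(sample_ids) || ncol(haplotypes) != m) {
      stop("haplotypes must be (2 x samples) x sites", call. = FALSE)
    }
    if (any(haplotypes < 0L | haplotypes > 1L, na.rm = TRUE)) {
      stop("haplotype alleles must be 0 or 1", call. = FALSE)
    }
    odd <- seq(1L, nrow(haplotypes), by = 2L)
    dosage <- haplotypes[odd, , drop = FALSE] + haplotypes[odd + 1L, , drop = FALSE]
    rownames(haplotypes) <- paste0(rep(sample_ids, each = 2L), c("_1", "_2"))
  } else {
    if (is.null(dosage)) stop("unphased data require a dosage matrix", call. = FALSE)
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (any(dosage < 0L | dosage > 2L, na.rm = TRUE)) {
      stop("dosages must be 0, 1 or 2", call. = FALSE)
    }
  }
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != m) {
    stop("dosage must be samples x sites", call. = FALSE)
  }
  rownames(dosage) <- sample_ids
  # enforce (chrom, pos) sort, strictly increasing within chrom
  ord <- order(factor(chrom, levels = unique(chrom)), pos)
  if (!identical(ord, seq_len(m))) {
    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    dosage <- dosage[, ord, drop = FALSE]
    if (phased) haplotypes <- haplotypes[, ord, drop = FALSE]
  }
  if (m > 1) {
    same <- chrom[-1] == chrom[-m]
    if (any(same & diff(pos) <= 0L)) {
      stop("site positions must be strictly increasing within a chromosome", call. = FALSE)
    }
  }
  structure(
    list(sample_ids = sample_ids, chrom = chrom, pos = pos,
         ref_allele = ref, alt_allele = alt,
         dosage = dosage, haplotypes = if (phased) haplotypes else NULL,
         phased = isTRUE(phased)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites (%s), %d chromosome(s)\n",
              n_samples(x), n_sites(x),
              if (x$phased) "phased" else "unphased",
              length(unique(x$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param g a `geno_matrix`.
#' @return integer count.
#' @export
n_samples <- function(g) length(g$sample_ids)

#' @rdname n_samples
#' @export
n_sites <- function(g) length(g$pos)

#' Alt-allele dosage matrix
#'
#' @param g a `geno_matrix`.
#' @return samples x sites integer matrix (0/1/2, `NA` missing).
#' @export
dosage <- function(g) g$dosage

#' Haplotype allele matrix of a phased genotype matrix
#'
#' @param g a phased `geno_matrix`.
#' @return (2 x samples) x sites 0/1 matrix.
#' @export
hap_matrix <- function(g) {
  if (!g$phased) stop("genotype matrix is not phased", call. = FALSE)
  g$haplotypes
}

#' Subset a genotype matrix by samples
#'
#' @param g a `geno_matrix`.
#' @param ids character vector of sample ids to keep (order respected).
#' @return a `geno_matrix` restricted to `ids`.
#' @export
subset_samples <- function(g, ids) {
  ids <- as.character(ids)
  idx <- match(ids, g$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample id(s): ", paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (g$phased) {
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    geno_matrix(ids, g$chrom, g$pos, g$ref_allele, g$alt_allele,
                haplotypes = g$haplotypes[hrows, , drop = FALSE])
  } else {
    geno_matrix(ids, g$chrom, g$pos, g$ref_allele, g$alt_allele,
                dosage = g$dosage[idx, , drop = FALSE])
  }
}

#' Subset a genotype matrix by site index
#'
#' @param g a `geno_matrix`.
#' @param idx logical or integer index over sites (kept in genomic order).
#' @return a `geno_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(g, idx) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- sort(unique(as.integer(idx)))
  if (g$phased) {
    geno_matrix(g$sample_ids, g$chrom[idx], g$pos[idx],
                g$ref_allele[idx], g$alt_allele[idx],
                haplotypes = g$haplotypes[, idx, drop = FALSE])
  } else {
    geno_matrix(g$sample_ids, g$chrom[idx], g$pos[idx],
                g$ref_allele[idx], g$alt_allele[idx],
                dosage = g$dosage[, idx, drop = FALSE])
  }
}

# allele-count summaries used throughout the window statistics:
# per site, number of non-missing haplotypes (n) and alt-allele count (d).
# For phased data these are counted on haplotypes, otherwise on dosages
# (each called diploid contributes two alleles).
site_allele_counts <- function(g, sample_ids = NULL) {
  if (!is.null(sample_ids)) g <- subset_samples(g, sample_ids)
  if (g$phased) {
    h <- g$haplotypes
    n <- colSums(!is.na(h))
    d <- colSums(h, na.rm = TRUE)
  } else {
    x <- g$dosage
    n <- 2L * colSums(!is.na(x))
    d <- colSums(x, na.rm = TRUE)
  }
  list(n = as.numeric(n), d = as.numeric(d))
}

# per-site genotype call rate (fraction of samples with a call)
site_call_rate <- function(g) {
  colMeans(!is.na(g$dosage))
}
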