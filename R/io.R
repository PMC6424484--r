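#' Read a per-sample metadata table
#'
#' The metadata TSV must have a header row with columns
#' `sample_id species group country lat lon mean_coverage`. `species` is
#' either `"wild"` or `"domesticate"`; `lat`/`lon` are decimal degrees and may
#' be empty (`NA`).
#'
#' @param path path to a tab-separated file.
#' @return a `data.frame` (class `sample_table`) with one row per sample.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  as_sample_table(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with columns `sample_id`, `species`, `group`,
#'   `country`, `lat`, `lon`, `mean_coverage`.
#' @return the validated data.frame with class `sample_table` prepended.
#' @export
as_sample_table <- function(df) {
  need <- c("sample_id", "species", "group", "country", "lat", "lon", "mean_coverage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  bad <- !df$species %in% c("wild", "domesticate")
  if (any(bad)) {
    stop("species must be 'wild' or 'domesticate' (offending: ",
         paste(unique(df$species[bad]), collapse = ", "), ")", call. = FALSE)
  }
  if (any(!is.na(df$lat) & (df$lat < -90 | df$lat > 90))) {
    stop("lat must lie in [-90, 90]", call. = FALSE)
  }
  if (any(!is.na(df$lon) & (df$lon < -180 | df$lon > 180))) {
    stop("lon must lie in [-180, 180]", call. = FALSE)
  }
  if (any(!is.na(df$mean_coverage) & df$mean_coverage < 0)) {
    stop("mean_coverage must be >= 0", call. = FALSE)
  }
  class(df) <- unique(c("sample_table", class(df)))
  df
}

#' Write a sample metadata table
#' @param samples a `sample_table` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample per-gene read-depth table
#'
#' Columns: `sample_id gene_id chrom start end median_depth`, one row per
#' (sample, gene). Intervals are half-open `[start, end)`.
#'
#' @param path path to a tab-separated file.
#' @return a `data.frame` (class `depth_table`).
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("depth file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  as_depth_table(df)
}

#' Validate a depth table
#' @param df data.frame with columns `sample_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `median_depth`.
#' @return the validated data.frame with class `depth_table` prepended.
#' @export
as_depth_table <- function(df) {
  need <- c("sample_id", "gene_id", "chrom", "start", "end", "median_depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("depth table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end", call. = FALSE)
  if (any(df$median_depth < 0)) stop("median_depth must be >= 0", call. = FALSE)
  if (anyDuplicated(df[, c("sample_id", "gene_id")])) {
    stop("one row per (sample, gene) required", call. = FALSE)
  }
  class(df) <- unique(c("depth_table", class(df)))
  df
}

#' @rdname read_depth_table
#' @param depths a `depth_table`.
#' @param path output TSV path.
#' @export
write_depth_table <- function(depths, path) {
  write.table(depths, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a VCF + metadata dataset
#'
#' Reads biallelic SNP records from a VCF 4.x file (multiallelic or
#' non-SNP records are skipped with a message reporting the count) together
#' with the sample metadata table. Every VCF sample must be present in the
#' metadata; missing genotypes are preserved as `NA`.
#'
#' @param vcf_path path to a VCF file (plain or gzipped).
#' @param metadata_path path to the metadata TSV (see [read_sample_table()]).
#' @return a list with elements `genotypes` (a [geno_matrix()]) and
#'   `samples` (a `sample_table`).
#' @export
load_dataset <- function(vcf_path, metadata_path) {
  samples <- read_sample_table(metadata_path)
  g <- read_vcf(vcf_path)
  missing <- setdiff(g$sample_ids, samples$sample_id)
  if (length(missing)) {
    stop("VCF sample(s) absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(genotypes = g, samples = samples)
}

#' Read biallelic SNPs from a VCF file
#'
#' @param vcf_path path to a VCF file.
#' @return a [geno_matrix()]; phased when every genotype call uses `|`.
#' @export
read_vcf <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path, call. = FALSE)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  sample_ids <- colnames(gt)
  calls <- gt[!is.na(gt)]
  phased <- length(calls) > 0 && all(grepl("|", calls, fixed = TRUE))
  allele <- function(s, i) {
    a <- vapply(strsplit(s, "[|/]"), function(x) if (length(x) >= i) x[i] else ".", "")
    out <- suppressWarnings(as.integer(a))
    out
  }
  m <- nrow(gt)
  if (phased) {
    haps <- matrix(NA_integer_, nrow = 2L * length(sample_ids), ncol = m)
    for (j in seq_along(sample_ids)) {
      s <- gt[, j]
      haps[2L * j - 1L, ] <- allele(s, 1L)
      haps[2L * j, ] <- allele(s, 2L)
    }
    geno_matrix(sample_ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                ref[keep], alt[keep], haplotypes = haps)
  } else {
    dos <- matrix(NA_integer_, nrow = length(sample_ids), ncol = m)
    for (j in seq_along(sample_ids)) {
      s <- gt[, j]
      dos[j, ] <- allele(s, 1L) + allele(s, 2L)
    }
    geno_matrix(sample_ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                ref[keep], alt[keep], dosage = dos)
  }
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one biallelic SNP record per site with GT-only genotype fields;
#' phased matrices use `|` separators, unphased `/`, missing calls `./.`.
#' Re-loading the file with [read_vcf()] reproduces the matrix entry by entry.
#'
#' @param g a [geno_matrix()].
#' @param path output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  sep <- if (g$phased) "|" else "/"
  m <- n_sites(g)
  if (g$phased) {
    h <- g$haplotypes
    a1 <- h[seq(1L, nrow(h), 2L), , drop = FALSE]
    a2 <- h[seq(2L, nrow(h), 2L), , drop = FALSE]
  } else {
    # unphased dosage -> conventional genotype strings (1 -> "0/1")
    a1 <- pmax(g$dosage - 1L, 0L)
    a2 <- pmin(g$dosage, 1L)
  }
  gt <- matrix(paste(a1, a2, sep = sep), nrow = nrow(a1))
  gt[is.na(a1) | is.na(a2)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hapgeo",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            g$sample_ids), collapse = "\t")
  ), con)
  if (m > 0) {
    body <- paste(g$chrom, g$pos, ".", g$ref_allele, g$alt_allele, ".", "PASS", ".", "GT",
                  sep = "\t")
    gt_cols <- apply(gt, 2L, paste, collapse = "\t")
    writeLines(paste(body, gt_cols, sep = "\t"), con)
  }
  invisible(path)
}
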