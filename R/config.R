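#' Pipeline configuration
#'
#' Collects the tunable parameters of the analysis pipeline with the
#' defaults used throughout: non-overlapping 10,000 bp windows that must
#' contain at least 30% of their sites with data, an 80% genotype call-rate
#' site filter with minor-allele-frequency cutoff 2%, 1 Mbp LD windows
#' summarised in 1,000 bp bins, a 1% fourth-gamete error tolerance, a 0.1
#' silhouette cutoff for core-set curation, a 0.1 target/control read-depth
#' ratio for deletion calls gated at control depth 1x, and 100-SNP jackknife
#' blocks for the f4 test.
#'
#' @param window_size diversity/Fst window size in bp.
#' @param min_window_data_fraction minimum fraction of a window's sites with
#'   data for the window to be reported.
#' @param min_call_rate minimum per-site genotype call rate.
#' @param min_maf minimum minor allele frequency (must be <= 0.5).
#' @param ld_window LD pairing window in bp.
#' @param ld_bin LD distance bin width in bp.
#' @param fg_error_freq fourth-gamete error-tolerance frequency.
#' @param silhouette_threshold silhouette cutoff for the iterative core filter.
#' @param deletion_ratio_threshold target/control median-depth ratio below or
#'   at which a gene is called deleted.
#' @param control_min_depth minimum control-gene median depth for a call.
#' @param f4_block_size SNPs per jackknife block.
#' @param rng_seed integer seed recorded with pipeline runs.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_size = 10000L,
                            min_window_data_fraction = 0.3,
                            min_call_rate = 0.8,
                            min_maf = 0.02,
                            ld_window = 1000000L,
                            ld_bin = 1000L,
                            fg_error_freq = 0.01,
                            silhouette_threshold = 0.1,
                            deletion_ratio_threshold = 0.1,
                            control_min_depth = 1,
                            f4_block_size = 100L,
                            rng_seed = 1L) {
  cfg <- list(window_size = as.integer(window_size),
              min_window_data_fraction = min_window_data_fraction,
              min_call_rate = min_call_rate,
              min_maf = min_maf,
              ld_window = as.integer(ld_window),
              ld_bin = as.integer(ld_bin),
              fg_error_freq = fg_error_freq,
              silhouette_threshold = silhouette_threshold,
              deletion_ratio_threshold = deletion_ratio_threshold,
              control_min_depth = control_min_depth,
              f4_block_size = as.integer(f4_block_size),
              rng_seed = as.integer(rng_seed))
  for (nm in c("window_size", "ld_window", "ld_bin", "f4_block_size")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      stop(nm, " must be a positive integer", call. = FALSE)
    }
  }
  for (nm in c("min_window_data_fraction", "min_call_rate", "min_maf",
               "fg_error_freq")) {
    x <- cfg[[nm]]
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$min_maf > 0.5) {
    stop("min_maf must be <= 0.5 (minor allele frequency)", call. = FALSE)
  }
  if (cfg$silhouette_threshold < -1 || cfg$silhouette_threshold >= 1) {
    stop("silhouette_threshold must lie in [-1, 1)", call. = FALSE)
  }
  if (cfg$deletion_ratio_threshold < 0 || cfg$deletion_ratio_threshold > 1) {
    stop("deletion_ratio_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$control_min_depth < 0) stop("control_min_depth must be >= 0", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
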