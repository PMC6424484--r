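# Read-depth presence/absence genotyping of candidate whole-gene deletions:
# the median depth over the candidate gene is compared with the median depth
# over a control gene outside the deletion region. A zero target median, or
# a target/control ratio at or below the threshold, is called a deletion;
# samples whose control gene is too shallowly covered are not called.

#' Call gene deletions from read depth
#'
#' @param depths a `depth_table` (see [read_depth_table()]).
#' @param target_gene gene id of the candidate deleted gene.
#' @param control_gene gene id of the control gene outside the deletion.
#' @param ratio_threshold call `deleted` when
#'   `target_median / control_median <= ratio_threshold` (or target median
#'   is exactly zero).
#' @param control_min_depth minimum control median depth for any call;
#'   below it the sample gets `no_call`.
#' @return data.frame `sample_id`, `gene_id`, `target_median`,
#'   `control_median`, `ratio`, `call` (one of `deleted`, `present`,
#'   `no_call`), `reason` for no-calls.
#' @export
call_deletions <- function(depths, target_gene, control_gene,
                           ratio_threshold = 0.1, control_min_depth = 1) {
  tg <- depths[depths$gene_id == target_gene, ]
  cg <- depths[depths$gene_id == control_gene, ]
  if (nrow(tg) == 0) stop("target gene not in depth table: ", target_gene, call. = FALSE)
  if (nrow(cg) == 0) stop("control gene not in depth table: ", control_gene, call. = FALSE)
  ids <- unique(depths$sample_id)
  t_med <- tg$median_depth[match(ids, tg$sample_id)]
  c_med <- cg$median_depth[match(ids, cg$sample_id)]
  ratio <- ifelse(!is.na(c_med) & c_med > 0, t_med / c_med, NA_real_)
  call <- rep("no_call", length(ids))
  reason <- rep(NA_character_, length(ids))
  missing_row <- is.na(t_med) | is.na(c_med)
  reason[missing_row] <- "missing depth row"
  low_ctrl <- !missing_row & c_med < control_min_depth
  reason[low_ctrl] <- "control below control_min_depth"
  callable <- !missing_row & !low_ctrl
  del <- callable & (t_med == 0 | (!is.na(ratio) & ratio <= ratio_threshold))
  call[del] <- "deleted"
  call[callable & !del] <- "present"
  data.frame(sample_id = ids, gene_id = target_gene,
             target_median = t_med, control_median = c_med,
             ratio = ratio, call = call, reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-group deletion frequencies
#'
#' `frequency = deleted / (deleted + present)` per group; `no_call` samples
#' are excluded from the denominator, and groups with no callable sample are
#' omitted with a warning. Percentages are additionally reported rounded to
#' the nearest integer.
#'
#' @param calls output of [call_deletions()].
#' @param samples a `sample_table` mapping `sample_id` to `group`.
#' @return data.frame `group`, `n_deleted`, `n_present`, `frequency`,
#'   `percent`.
#' @export
deletion_frequency <- function(calls, samples) {
  grp <- samples$group[match(calls$sample_id, samples$sample_id)]
  if (anyNA(grp)) {
    stop("calls contain sample(s) absent from the sample table: ",
         paste(unique(calls$sample_id[is.na(grp)]), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(unique(grp), function(gl) {
    sub <- calls[grp == gl, ]
    nd <- sum(sub$call == "deleted"); np <- sum(sub$call == "present")
    data.frame(group = gl, n_deleted = nd, n_present = np,
               frequency = if (nd + np > 0) nd / (nd + np) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  empty <- is.na(out$frequency)
  if (any(empty)) {
    warning("group(s) with zero callable samples omitted: ",
            paste(out$group[empty], collapse = ", "), call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  out$percent <- round(100 * out$frequency)
  out
}

#' Locate SNP deserts (candidate deleted regions)
#'
#' Scans each chromosome for maximal gaps between consecutive quality-passing
#' sites. Gaps of at least `min_gap_bp` are reported with their flanking
#' passing-site coordinates — stretches where no polymorphic site passed the
#' quality filter are the signature of a shared deletion.
#'
#' @param g a [geno_matrix()].
#' @param passing_mask logical vector, one entry per site of `g`: does the
#'   site pass the quality-control filter?
#' @param min_gap_bp minimum gap length reported.
#' @return data.frame `chrom`, `gap_start`, `gap_end`, `gap_length` (the
#'   flanking passing positions and their separation).
#' @export
snp_desert_regions <- function(g, passing_mask, min_gap_bp) {
  if (length(passing_mask) != n_sites(g)) {
    stop("passing_mask must align to the sites of g", call. = FALSE)
  }
  if (!any(passing_mask)) stop("passing_mask selects no sites", call. = FALSE)
  out <- list()
  for (ch in unique(g$chrom)) {
    p <- g$pos[g$chrom == ch & passing_mask]
    if (length(p) < 2) next
    gap <- diff(p)
    hit <- which(gap >= min_gap_bp)
    if (length(hit)) {
      out[[ch]] <- data.frame(chrom = ch, gap_start = p[hit], gap_end = p[hit + 1L],
                              gap_length = gap[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), gap_start = integer(0),
                      gap_end = integer(0), gap_length = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
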