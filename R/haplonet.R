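# Haplotype networks over non-recombining regions: four-gamete screening
# with an error tolerance, haplotype collapsing, and hamming-distance
# minimum-spanning-tree construction with deterministic tie-breaking.

#' Extract phased haplotypes over a genomic region
#'
#' Haplotypes with any missing allele inside the region are excluded (their
#' count is reported via a message), since unresolved sites would corrupt
#' hamming distances.
#'
#' @param g a phased [geno_matrix()].
#' @param chrom chromosome name.
#' @param start,end region bounds (inclusive positions).
#' @param sample_ids optional subset of samples.
#' @return list of class `haplotype_set`: `chrom`, `start`, `end`, `pos`
#'   (site positions), `alleles` (haplotypes x sites 0/1 matrix), `carrier`
#'   (sample id per haplotype), `causal_status` (per haplotype, initially
#'   `"unknown"`), `n_excluded`.
#' @export
extract_haplotypes <- function(g, chrom, start, end, sample_ids = NULL) {
  if (!g$phased) stop("haplotype analysis requires phased genotypes", call. = FALSE)
  if (!is.null(sample_ids)) g <- subset_samples(g, sample_ids)
  idx <- which(g$chrom == chrom & g$pos >= start & g$pos <= end)
  if (length(idx) == 0) stop("no sites in the requested region", call. = FALSE)
  h <- g$haplotypes[, idx, drop = FALSE]
  carrier <- rep(g$sample_ids, each = 2L)
  ok <- rowSums(is.na(h)) == 0L
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(sprintf("extract_haplotypes: excluded %d haplotype(s) with missing data",
                    n_excluded))
  }
  structure(list(chrom = chrom, start = start, end = end,
                 pos = g$pos[idx],
                 alleles = h[ok, , drop = FALSE],
                 carrier = carrier[ok],
                 causal_status = rep("unknown", sum(ok)),
                 n_excluded = n_excluded),
            class = "haplotype_set")
}

#' Label haplotypes as derived or ancestral
#'
#' Either by the allele carried at a causal site inside the region
#' (`causal_pos`), or by a set of carrier sample ids (`carrier_ids`, e.g.
#' gene-deletion carriers whose causal state is not a SNP in the matrix).
#'
#' @param h a `haplotype_set`.
#' @param causal_pos position of the causal SNP (must be a site of `h`).
#' @param derived_allele allele coding the derived state at `causal_pos`.
#' @param carrier_ids sample ids whose haplotypes are derived.
#' @return `h` with `causal_status` filled with `"derived"`/`"ancestral"`.
#' @export
set_causal_status <- function(h, causal_pos = NULL, derived_allele = 1L,
                              carrier_ids = NULL) {
  if (!is.null(causal_pos)) {
    j <- match(causal_pos, h$pos)
    if (is.na(j)) stop("causal_pos is not a site of the haplotype set", call. = FALSE)
    h$causal_status <- ifelse(h$alleles[, j] == derived_allele, "derived", "ancestral")
  } else if (!is.null(carrier_ids)) {
    h$causal_status <- ifelse(h$carrier %in% carrier_ids, "derived", "ancestral")
  } else {
    stop("provide causal_pos or carrier_ids", call. = FALSE)
  }
  h
}

#' Four-gamete test for one pair of biallelic sites
#'
#' Returns `TRUE` (evidence of recombination) iff all four gametes
#' `00, 01, 10, 11` are observed among haplotypes non-missing at both sites
#' and the rarest gamete's frequency is at least `error_freq`; a fourth
#' gamete below that frequency is treated as genotyping error. Fewer than
#' two distinct gametes is vacuously `FALSE`.
#'
#' @param col_i,col_j 0/1 haplotype allele vectors of equal length.
#' @param error_freq fourth-gamete error tolerance (default 1%).
#' @return logical.
#' @export
four_gamete_pair <- function(col_i, col_j, error_freq = 0.01) {
  if (length(col_i) != length(col_j)) stop("columns differ in length", call. = FALSE)
  ok <- !is.na(col_i) & !is.na(col_j)
  a <- col_i[ok]; b <- col_j[ok]
  n <- length(a)
  if (n == 0) return(FALSE)
  counts <- c(`00` = sum(a == 0 & b == 0), `01` = sum(a == 0 & b == 1),
              `10` = sum(a == 1 & b == 0), `11` = sum(a == 1 & b == 1))
  if (sum(counts > 0) < 4) return(FALSE)
  min(counts) / n >= error_freq
}

# gamete counts for all site pairs at once; returns four J x J matrices
pair_gamete_counts <- function(X) {
  O <- !is.na(X)
  A <- X; A[!O] <- 0L; storage.mode(A) <- "double"
  B <- O - A
  list(n11 = crossprod(A), n01 = crossprod(B, A), n10 = crossprod(A, B),
       n00 = crossprod(B))
}

# failing pairs (all four gametes at or above tolerance) within one partition
failing_pairs <- function(X, error_freq) {
  if (ncol(X) < 2 || nrow(X) == 0) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  gc <- pair_gamete_counts(X)
  tot <- gc$n11 + gc$n01 + gc$n10 + gc$n00
  minc <- pmin(gc$n11, gc$n01, gc$n10, gc$n00)
  all4 <- gc$n11 > 0 & gc$n01 > 0 & gc$n10 > 0 & gc$n00 > 0
  fail <- all4 & tot > 0 & (minc / pmax(tot, 1)) >= error_freq
  fail[lower.tri(fail, diag = TRUE)] <- FALSE
  w <- which(fail, arr.ind = TRUE)
  data.frame(i = w[, 1], j = w[, 2])
}

# the "fourth" (minority) gamete at a failing pair; ties broken by the
# gamete carrying the rarer allele at site i, then at site j
fourth_gamete <- function(a, b) {
  counts <- c(`00` = sum(a == 0 & b == 0, na.rm = TRUE),
              `01` = sum(a == 0 & b == 1, na.rm = TRUE),
              `10` = sum(a == 1 & b == 0, na.rm = TRUE),
              `11` = sum(a == 1 & b == 1, na.rm = TRUE))
  cand <- names(counts)[counts == min(counts)]
  if (length(cand) > 1) {
    rare_i <- if (sum(a == 1, na.rm = TRUE) <= sum(a == 0, na.rm = TRUE)) "1" else "0"
    pref <- cand[substr(cand, 1, 1) == rare_i]
    if (length(pref)) cand <- pref
    if (length(cand) > 1) {
      rare_j <- if (sum(b == 1, na.rm = TRUE) <= sum(b == 0, na.rm = TRUE)) "1" else "0"
      pref <- cand[substr(cand, 2, 2) == rare_j]
      if (length(pref)) cand <- pref
    }
  }
  cand[1]
}

#' Four-gamete scan of a candidate non-recombining region
#'
#' All site pairs are tested separately within the wild and the domesticate
#' partition. Any failing pair inside the domesticate partition rejects the
#' region (the caller should shrink it). Failures confined to the wild
#' partition are attributed to wild-side recombination: haplotypes carrying
#' the minority (fourth) gamete at each failing pair are removed, the scan
#' repeats, and the cleaned set is returned once it passes in both
#' partitions.
#'
#' @param h a `haplotype_set`.
#' @param wild_ids,dom_ids sample ids of the wild and domesticate partitions
#'   (both must be non-empty within `h`).
#' @param error_freq fourth-gamete error tolerance.
#' @param max_iter safety cap on removal rounds.
#' @return list of class `fg_scan`: `status` (`"ok"` or `"rejected"`),
#'   `haplotypes` (cleaned `haplotype_set`), `removed` (indices into the
#'   input set), `report` (data.frame of failing pairs per round).
#' @export
nonrecombining_scan <- function(h, wild_ids, dom_ids, error_freq = 0.01,
                                max_iter = 100L) {
  in_wild <- h$carrier %in% wild_ids
  in_dom <- h$carrier %in% dom_ids
  if (!any(in_wild) || !any(in_dom)) {
    stop("both partitions must be non-empty", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(h$alleles))
  report <- list()
  for (it in seq_len(max_iter)) {
    Xd <- h$alleles[keep & in_dom, , drop = FALSE]
    fd <- failing_pairs(Xd, error_freq)
    if (nrow(fd) > 0) {
      report[[length(report) + 1L]] <- data.frame(
        iteration = it, partition = "domesticate",
        site_i = h$pos[fd$i], site_j = h$pos[fd$j], verdict = "reject")
      return(structure(list(status = "rejected", haplotypes = h,
                            removed = integer(0),
                            report = do.call(rbind, report)),
                       class = "fg_scan"))
    }
    Xw <- h$alleles[keep & in_wild, , drop = FALSE]
    fw <- failing_pairs(Xw, error_freq)
    if (nrow(fw) == 0) break
    drop_now <- logical(length(keep))
    for (r in seq_len(nrow(fw))) {
      i <- fw$i[r]; j <- fw$j[r]
      fg <- fourth_gamete(Xw[, i], Xw[, j])
      ai <- as.integer(substr(fg, 1, 1)); aj <- as.integer(substr(fg, 2, 2))
      hit <- keep & h$alleles[, i] == ai & h$alleles[, j] == aj
      drop_now <- drop_now | hit
      report[[length(report) + 1L]] <- data.frame(
        iteration = it, partition = "wild",
        site_i = h$pos[i], site_j = h$pos[j],
        verdict = sprintf("removed %d carrier haplotype(s) of gamete %s", sum(hit), fg))
    }
    keep <- keep & !drop_now
  }
  out <- h
  out$alleles <- h$alleles[keep, , drop = FALSE]
  out$carrier <- h$carrier[keep]
  out$causal_status <- h$causal_status[keep]
  structure(list(status = "ok", haplotypes = out, removed = which(!keep),
                 report = if (length(report)) do.call(rbind, report) else
                   data.frame(iteration = integer(0), partition = character(0),
                              site_i = integer(0), site_j = integer(0),
                              verdict = character(0))),
            class = "fg_scan")
}

#' Shrink a region symmetrically until the four-gamete scan accepts it
#'
#' Convenience wrapper for pipeline use: starts from `halfwidth` around
#' `center` and multiplies the halfwidth by `shrink` until
#' [nonrecombining_scan()] returns `"ok"` or fewer than `min_sites` sites
#' remain.
#'
#' @param g phased [geno_matrix()].
#' @param chrom,center locus position.
#' @param halfwidth initial halfwidth in bp.
#' @param wild_ids,dom_ids partition sample ids.
#' @param error_freq fourth-gamete tolerance.
#' @param shrink multiplicative shrink factor per attempt.
#' @param min_sites minimum number of region sites to attempt.
#' @return the accepted `fg_scan` (with `region_halfwidth` recorded), or the
#'   last rejected scan if no acceptable region was found.
#' @export
select_nonrecombining_region <- function(g, chrom, center, halfwidth,
                                         wild_ids, dom_ids, error_freq = 0.01,
                                         shrink = 0.75, min_sites = 4L) {
  hw <- halfwidth
  last <- NULL
  repeat {
    idx <- which(g$chrom == chrom & g$pos >= center - hw & g$pos <= center + hw)
    if (length(idx) < min_sites) break
    h <- extract_haplotypes(g, chrom, center - hw, center + hw,
                            sample_ids = c(wild_ids, dom_ids))
    sc <- nonrecombining_scan(h, wild_ids, dom_ids, error_freq)
    sc$region_halfwidth <- hw
    last <- sc
    if (sc$status == "ok") return(sc)
    hw <- floor(hw * shrink)
  }
  last
}

#' Collapse identical haplotypes into network nodes
#'
#' Nodes are labelled with roman numerals ordered by descending carrier
#' count, ties broken by first occurrence in the input.
#'
#' @param h a (cleaned) `haplotype_set`.
#' @return list of class `hap_nodes`: `alleles` (nodes x sites), `label`,
#'   `count`, `members` (list of carrier sample ids), `causal_status`
#'   (`"mixed"` if a node's haplotypes disagree), `pos`.
#' @export
collapse_haplotypes <- function(h) {
  if (nrow(h$alleles) == 0) stop("empty haplotype set", call. = FALSE)
  key <- apply(h$alleles, 1L, paste, collapse = "")
  first <- match(unique(key), key)
  counts <- as.integer(table(key)[unique(key)])
  ord <- order(-counts, first)
  uk <- unique(key)[ord]
  members <- lapply(uk, function(k) h$carrier[key == k])
  status <- vapply(uk, function(k) {
    st <- unique(h$causal_status[key == k])
    if (length(st) == 1) st else "mixed"
  }, "")
  structure(list(alleles = h$alleles[match(uk, key), , drop = FALSE],
                 label = as.character(utils::as.roman(seq_along(uk))),
                 count = counts[ord],
                 members = members,
                 causal_status = unname(status),
                 pos = h$pos),
            class = "hap_nodes")
}

#' Hamming-distance minimum spanning tree over haplotype nodes
#'
#' Kruskal's algorithm over the complete hamming graph of the nodes.
#' Ties among equal-weight candidate edges are broken deterministically by
#' preferring the edge whose endpoint labels come earliest in node order,
#' so the emitted tree is reproducible (MSTs are not unique in general,
#' but the total weight is always minimal).
#'
#' @param nodes a `hap_nodes` object from [collapse_haplotypes()].
#' @return list of class `haplo_network`: `nodes` (data.frame `label`,
#'   `haplotype`, `count`, `causal_status`), `members`, `edges` (data.frame
#'   `from`, `to`, `weight`), `alleles`.
#' @export
hamming_mst <- function(nodes) {
  n <- length(nodes$label)
  X <- nodes$alleles
  if (n == 1) {
    edges <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  } else {
    D <- as.matrix(stats::dist(X, method = "manhattan"))
    cand <- which(upper.tri(D), arr.ind = TRUE)
    ord <- order(D[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    sel <- integer(0)
    for (r in seq_len(nrow(cand))) {
      a <- find(cand[r, 1]); b <- find(cand[r, 2])
      if (a != b) {
        parent[a] <- b
        sel <- c(sel, r)
        if (length(sel) == n - 1L) break
      }
    }
    e <- cand[sel, , drop = FALSE]
    edges <- data.frame(from = nodes$label[e[, 1]], to = nodes$label[e[, 2]],
                        weight = D[e], stringsAsFactors = FALSE)
  }
  structure(list(
    nodes = data.frame(label = nodes$label,
                       haplotype = apply(X, 1L, paste, collapse = ""),
                       count = nodes$count,
                       causal_status = nodes$causal_status,
                       stringsAsFactors = FALSE),
    members = nodes$members,
    edges = edges,
    alleles = X,
    pos = nodes$pos
  ), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d node(s), %d edge(s), total weight %g\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Write a haplotype network as GraphML
#'
#' @param net a `haplo_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
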