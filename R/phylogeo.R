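# Geographic origin inference for a causal mutation: tabulate where each
# network haplotype is found, pair derived haplotypes with their nearest
# ancestral haplotypes along the network, and score the overlap of their
# geographic ranges — the region where the ancestral (mutation-free) and
# derived (mutation-bearing) haplotypes co-occur is the best supported
# place of origin of the allele.

#' Geographic distribution of each network haplotype
#'
#' Counts each node's carrier haplotypes per region (by default the
#' `country` column of the sample table). Samples without geography are
#' tallied under `"unknown"` and excluded from frequencies. Frequencies are
#' carrier haplotypes divided by the total haplotypes sampled in that
#' region (2 per diploid sample).
#'
#' @param net a `haplo_network`.
#' @param samples a `sample_table`.
#' @param by metadata column giving the region label (default `"country"`).
#' @return named list (one per node label) of class `geo_distribution`
#'   data.frames with columns `region`, `count`, `freq`, plus attribute
#'   `n` (total carriers of the node).
#' @export
haplotype_geography <- function(net, samples, by = "country") {
  if (!by %in% names(samples)) stop("column not in sample table: ", by, call. = FALSE)
  region_of <- setNames(as.character(samples[[by]]), samples$sample_id)
  region_totals <- 2 * table(samples[[by]], useNA = "no")
  out <- lapply(seq_len(nrow(net$nodes)), function(i) {
    mem <- net$members[[i]]
    unmatched <- setdiff(unique(mem), names(region_of))
    if (length(unmatched)) {
      stop("network member(s) missing from sample table: ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    }
    reg <- region_of[mem]
    reg[is.na(reg)] <- "unknown"
    tab <- table(reg)
    df <- data.frame(region = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df$freq <- ifelse(df$region == "unknown", NA_real_,
                      df$count / as.numeric(region_totals[df$region]))
    attr(df, "n") <- length(mem)
    class(df) <- c("geo_distribution", "data.frame")
    df
  })
  names(out) <- net$nodes$label
  out
}

#' Pair each derived haplotype with its nearest ancestral haplotype
#'
#' Distances are path weights along the network (the unique tree path of
#' the MST). Each derived node is paired with the ancestral-status node(s)
#' at minimum path weight; ties yield multiple rows. The derived node with
#' the globally smallest distance to any ancestral node is flagged as the
#' putative founding haplotype of the mutation.
#'
#' @param net a `haplo_network` whose nodes carry causal status labels.
#' @return data.frame `derived`, `ancestral`, `distance`, `founding`.
#' @export
nearest_ancestral <- function(net) {
  der <- net$nodes$label[net$nodes$causal_status == "derived"]
  anc <- net$nodes$label[net$nodes$causal_status == "ancestral"]
  if (length(anc) == 0) {
    stop("no ancestral-status nodes: origin cannot be polarized", call. = FALSE)
  }
  if (length(der) == 0) stop("no derived-status nodes", call. = FALSE)
  ig <- as_igraph(net)
  D <- igraph::distances(ig, v = der, to = anc, weights = igraph::E(ig)$weight)
  rows <- list()
  best_per_derived <- apply(D, 1L, min)
  global_best <- min(best_per_derived)
  for (i in seq_along(der)) {
    hit <- which(D[i, ] == best_per_derived[i])
    rows[[i]] <- data.frame(derived = der[i], ancestral = unname(anc[hit]),
                            distance = unname(best_per_derived[i]),
                            founding = unname(best_per_derived[i] == global_best),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Infer the geographic origin of a causal mutation
#'
#' Scores each region by the overlap of the ancestral and derived haplotype
#' ranges: `min(freq_anc, freq_der)` per region (or their product with
#' `method = "product"`). The top-scoring region(s) are the inferred
#' origin; if the ranges are disjoint the origin is indeterminate. Carrier
#' counts of both haplotypes are reported so small-sample caveats stay
#' visible.
#'
#' @param anc,der `geo_distribution` data.frames (see
#'   [haplotype_geography()]).
#' @param locus_id optional locus identifier carried into the report.
#' @param method `"min"` (default) or `"product"` overlap score.
#' @return list of class `origin_inference`: `locus_id`, `scores`
#'   (data.frame `region`, `freq_anc`, `freq_der`, `overlap`),
#'   `top_regions`, `status` (`"determinate"`/`"disjoint"`), `n_ancestral`,
#'   `n_derived`.
#' @export
infer_origin <- function(anc, der, locus_id = NA_character_,
                         method = c("min", "product")) {
  method <- match.arg(method)
  if (nrow(anc) == 0 || nrow(der) == 0) stop("empty distribution", call. = FALSE)
  a <- anc[anc$region != "unknown", ]
  d <- der[der$region != "unknown", ]
  regions <- sort(union(a$region, d$region))
  fa <- setNames(rep(0, length(regions)), regions)
  fd <- fa
  fa[a$region] <- a$freq
  fd[d$region] <- d$freq
  overlap <- if (method == "min") pmin(fa, fd) else fa * fd
  scores <- data.frame(region = regions, freq_anc = unname(fa),
                       freq_der = unname(fd), overlap = unname(overlap),
                       stringsAsFactors = FALSE)
  top <- scores$region[scores$overlap == max(scores$overlap) & scores$overlap > 0]
  structure(list(locus_id = locus_id, scores = scores,
                 top_regions = top,
                 status = if (length(top)) "determinate" else "disjoint",
                 n_ancestral = attr(anc, "n"), n_derived = attr(der, "n")),
            class = "origin_inference")
}

#' @export
print.origin_inference <- function(x, ...) {
  cat(sprintf("origin_inference%s: %s\n",
              if (is.na(x$locus_id)) "" else paste0(" [", x$locus_id, "]"),
              if (x$status == "determinate")
                paste("top region(s):", paste(x$top_regions, collapse = ", "))
              else "disjoint ranges - origin indeterminate"))
  cat(sprintf("  ancestral n = %s, derived n = %s\n",
              format(x$n_ancestral), format(x$n_derived)))
  invisible(x)
}
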