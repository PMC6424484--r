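# End-to-end pipeline: load -> site filters -> window statistics & sweep
# scan -> distance/silhouette core-set curation -> deletion calling ->
# haplotype networks -> origin inference -> trait comparisons, with every
# stage writing a plain-text report under the output directory.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits `genotypes.vcf`, `metadata.tsv`, `depths.tsv`, `phenotype.tsv`,
#' `loci.tsv`, `genes.tsv` and `truth.json` under `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param depth_seed seed for [simulate_depths()].
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, depth_seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_sample_table(sim$samples, file.path(dir, "metadata.tsv"))
  genes <- default_genes(sim$truth$config)
  depths <- simulate_depths(sim$truth, sim$samples, genes, seed = depth_seed)
  write_depth_table(depths, file.path(dir, "depths.tsv"))
  write_tsv(sim$phenotype, file.path(dir, "phenotype.tsv"))
  write_tsv(sim$truth$loci, file.path(dir, "loci.tsv"))
  write_tsv(genes, file.path(dir, "genes.tsv"))
  truth_json <- list(
    origin_region = as.list(sim$truth$origin_region),
    origin_country = as.list(sim$truth$origin_country),
    derived_carriers = sim$truth$derived_carriers,
    deletion_carriers = sim$truth$deletion_carriers
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a dataset laid out as written by
#' [write_sim_dataset()] (or assembled by hand in the same formats) and
#' writes one report file per stage under `out_dir`. Any stage failure
#' aborts with the stage name and cause. Outputs are deterministic for a
#' fixed configuration and input.
#'
#' @param config a [pipeline_config()].
#' @param data_dir directory containing `genotypes.vcf` and `metadata.tsv`
#'   (and optionally `depths.tsv`, `loci.tsv`, `phenotype.tsv`).
#' @param out_dir output directory (created if needed).
#' @param stages which analysis stages to run (dataset loading and site
#'   filtering always run; dependencies are pulled in automatically).
#' @return invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(config, data_dir, out_dir,
                         stages = c("stats", "group", "deldetect", "sweep",
                                    "hapnet", "origin", "traits")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("stats", "group", "deldetect", "sweep", "hapnet", "origin",
                  "traits")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # dependencies: sweep scans need window stats and deletion calls; the
  # haplotype-network/origin stage needs deletion calls to label deletion
  # carriers; trait concordance needs the calls too
  if (any(c("sweep", "origin") %in% stages)) stages <- c(stages, "stats")
  if (any(c("sweep", "hapnet", "origin", "traits") %in% stages)) {
    stages <- c(stages, "deldetect")
  }
  if ("origin" %in% stages) stages <- c(stages, "hapnet")
  want <- function(x) x %in% stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  ds <- with_stage("load", load_dataset(file.path(data_dir, "genotypes.vcf"),
                                        file.path(data_dir, "metadata.tsv")))
  g <- ds$genotypes; samples <- ds$samples
  loci_path <- file.path(data_dir, "loci.tsv")
  loci <- if (file.exists(loci_path)) {
    read.table(loci_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else NULL

  gf <- with_stage("filter", filter_sites(g, config$min_call_rate, config$min_maf))

  if (want("stats")) res$windows <- with_stage("stats", {
    wild_ids <- samples$sample_id[samples$species == "wild"]
    dom_ids <- samples$sample_id[samples$species == "domesticate"]
    stats_w <- window_diversity(subset_samples(g, wild_ids), config$window_size,
                                config$min_window_data_fraction)
    stats_d <- window_diversity(subset_samples(g, dom_ids), config$window_size,
                                config$min_window_data_fraction)
    write_tsv(stats_w, file.path(out_dir, "diversity_wild.tsv"))
    write_tsv(stats_d, file.path(out_dir, "diversity_domesticate.tsv"))
    fst <- hudson_fst(subset_samples(gf, wild_ids), subset_samples(gf, dom_ids),
                      config$window_size)
    write_tsv(fst, file.path(out_dir, "fst_wild_vs_domesticate.tsv"))
    ld <- ld_decay(gf, config$ld_window, config$ld_bin, max_sites = 4000L,
                   seed = config$rng_seed)
    write_tsv(ld, file.path(out_dir, "ld_decay.tsv"))
    list(wild = stats_w, dom = stats_d, fst = fst, ld = ld)
  })

  if (want("group")) res$grouping <- with_stage("group", {
    gt <- thin_sites(gf, seed = config$rng_seed)
    keep_groups <- names(which(table(samples$group) >= 2))
    ids <- samples$sample_id[samples$group %in% keep_groups]
    dm <- pairwise_distance(subset_samples(gt, ids))
    labels <- samples$group[match(ids, samples$sample_id)]
    write_tsv(cbind(data.frame(sample_id = rownames(dm)), as.data.frame(dm)),
              file.path(out_dir, "distance_matrix.tsv"))
    core <- iterative_core_filter(dm, labels, config$silhouette_threshold)
    rep_df <- core$final_report
    write_tsv(rep_df, file.path(out_dir, "silhouette_report.tsv"))
    write_tsv(data.frame(sample_id = core$retained, group = core$labels),
              file.path(out_dir, "core_set.tsv"))
    mds <- classical_mds(dm, 2L)
    write_tsv(cbind(data.frame(sample_id = rownames(mds$points)),
                    as.data.frame(mds$points)),
              file.path(out_dir, "mds_coordinates.tsv"))
    tr <- neighbor_joining(dm)
    ape::write.tree(tr, file.path(out_dir, "nj_tree.nwk"))
    list(dm = dm, core = core, mds = mds, tree = tr)
  })

  depth_path <- file.path(data_dir, "depths.tsv")
  if (want("deldetect") && file.exists(depth_path) && !is.null(loci)) {
    res$deletions <- with_stage("deldetect", {
      depths <- read_depth_table(depth_path)
      del_loci <- loci[loci$type == "gene_deletion", , drop = FALSE]
      control <- setdiff(unique(depths$gene_id), del_loci$locus_id)[1]
      if (is.na(control)) stop("no control gene available in the depth table")
      calls <- do.call(rbind, lapply(del_loci$locus_id, function(id) {
        call_deletions(depths, id, control, config$deletion_ratio_threshold,
                       config$control_min_depth)
      }))
      write_tsv(calls, file.path(out_dir, "deletion_calls.tsv"))
      freq <- do.call(rbind, lapply(split(calls, calls$gene_id), function(cc) {
        f <- deletion_frequency(cc, samples)
        cbind(gene_id = cc$gene_id[1], f)
      }))
      rownames(freq) <- NULL
      write_tsv(freq, file.path(out_dir, "deletion_frequency.tsv"))
      list(calls = calls, freq = freq)
    })
  }

  if (want("sweep") && !is.null(loci)) {
    res$sweep <- with_stage("sweep", {
      wild_ids <- samples$sample_id[samples$species == "wild"]
      stats_w <- res$windows$wild
      scans <- list()
      for (k in seq_len(nrow(loci))) {
        lid <- loci$locus_id[k]
        carriers <- observed_carriers(g, samples, loci[k, , drop = FALSE],
                                      calls = res$deletions$calls)
        if (length(carriers) < 2) next
        stats_c <- window_diversity(subset_samples(g, carriers),
                                    config$window_size,
                                    config$min_window_data_fraction)
        sc <- sweep_scan(stats_w, stats_c)
        sc$locus_id <- lid
        scans[[lid]] <- sc
      }
      all_scans <- do.call(rbind, scans)
      rownames(all_scans) <- NULL
      write_tsv(all_scans, file.path(out_dir, "sweep_scan.tsv"))
      scans
    })
  }

  if (want("hapnet") && !is.null(loci) && g$phased) {
    res$origin <- with_stage("hapnet+origin", {
      wild_ids <- samples$sample_id[samples$species == "wild"]
      dom_ids <- samples$sample_id[samples$species == "domesticate"]
      reports <- list()
      for (k in seq_len(nrow(loci))) {
        lid <- loci$locus_id[k]
        hw <- max(loci$sweep_halfwidth[k], 5000L)
        sc <- select_nonrecombining_region(g, loci$chrom[k], loci$pos[k], hw,
                                           wild_ids, dom_ids, config$fg_error_freq)
        if (is.null(sc) || sc$status != "ok") {
          reports[[lid]] <- list(locus_id = lid, status = "region_rejected")
          next
        }
        h <- sc$haplotypes
        h <- if (loci$type[k] == "snp") {
          set_causal_status(h, causal_pos = loci$pos[k])
        } else if (!is.null(res$deletions)) {
          carriers <- res$deletions$calls
          carriers <- carriers$sample_id[carriers$gene_id == lid &
                                           carriers$call == "deleted"]
          set_causal_status(h, carrier_ids = carriers)
        } else h
        net <- hamming_mst(collapse_haplotypes(h))
        write_graphml(net, file.path(out_dir, paste0("hapnet_", lid, ".graphml")))
        write_tsv(net$nodes, file.path(out_dir, paste0("hapnet_", lid, "_nodes.tsv")))
        if (!all(h$causal_status == "unknown") &&
            any(net$nodes$causal_status == "derived") &&
            any(net$nodes$causal_status == "ancestral")) {
          geo <- haplotype_geography(net, samples)
          pairs <- nearest_ancestral(net)
          founding <- pairs[pairs$founding, , drop = FALSE][1, ]
          orig <- infer_origin(geo[[founding$ancestral]], geo[[founding$derived]],
                               locus_id = lid)
          reports[[lid]] <- list(locus_id = lid, status = orig$status,
                                 top_regions = orig$top_regions,
                                 founding_derived = founding$derived,
                                 nearest_ancestral = founding$ancestral,
                                 distance = founding$distance,
                                 n_ancestral = orig$n_ancestral,
                                 n_derived = orig$n_derived,
                                 scores = orig$scores)
        } else {
          reports[[lid]] <- list(locus_id = lid, status = "unpolarized")
        }
      }
      origin_rows <- do.call(rbind, lapply(reports, function(r) {
        data.frame(locus_id = r$locus_id, status = r$status,
                   top_regions = if (is.null(r$top_regions)) NA_character_
                                 else paste(r$top_regions, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
      write_tsv(origin_rows, file.path(out_dir, "origin_inference.tsv"))
      jsonlite::write_json(reports, file.path(out_dir, "origin_inference.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      reports
    })
  }

  pheno_path <- file.path(data_dir, "phenotype.tsv")
  if (want("traits") && file.exists(pheno_path)) {
    res$traits <- with_stage("traits", {
      pheno <- read.table(pheno_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      if (!"ses_score" %in% names(pheno)) {
        pheno$ses_score <- ses_score(pheno$percent_shattering)
      }
      grp <- samples$group[match(pheno$sample_id, samples$sample_id)]
      dom <- samples$species[match(pheno$sample_id, samples$sample_id)] == "domesticate"
      pm <- pairwise_mwu(pheno$ses_score[dom], grp[dom])
      write_tsv(cbind(data.frame(group = rownames(pm)), as.data.frame(pm)),
                file.path(out_dir, "threshability_mwu.tsv"))
      conc <- NULL
      if (!is.null(res$deletions)) {
        stat_df <- data.frame(sample_id = unique(res$deletions$calls$sample_id),
                              stringsAsFactors = FALSE)
        for (gid in unique(res$deletions$calls$gene_id)) {
          cc <- res$deletions$calls[res$deletions$calls$gene_id == gid, ]
          stat_df[[gid]] <- cc$call[match(stat_df$sample_id, cc$sample_id)]
        }
        conc <- concordance_table(stat_df, pheno, samples)
        write_tsv(conc$table, file.path(out_dir, "concordance.tsv"))
      }
      list(mwu = pm, concordance = conc)
    })
  }

  log_lines <- c("hapgeo pipeline run",
                 sprintf("seed: %d", config$rng_seed),
                 vapply(names(unclass(config)), function(nm)
                   sprintf("config %s: %s", nm, format(config[[nm]])), ""))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
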