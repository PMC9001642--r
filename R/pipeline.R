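#' Assemble a pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()]. One master
#' seed deterministically derives every stage seed, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param counts OTU table (samples x OTUs).
#' @param metadata data.frame with `sample_id`, `group`, `habitat`.
#' @param out_dir Output directory (created if missing).
#' @param tree Optional rooted phylogeny (required by the assembly stage).
#' @param stages Stages to run, a subset of `rarefy`, `diversity`,
#'   `partition`, `network`, `stability`, `assembly`, `sourcetrack`, in
#'   dependency order.
#' @param seed Master seed (all stage seeds derive from it).
#' @param depth Rarefaction depth (default: the minimum sample total).
#' @param min_mean_reads SparCC OTU pre-filter (default 5).
#' @param rho_min,alpha Network edge thresholds (defaults 0.6, 0.05).
#' @param n_perm Permutations for ANOSIM/PERMANOVA (default 999).
#' @param n_iter,n_boot SparCC Dirichlet iterations and bootstraps
#'   (defaults 20, 100).
#' @param n_null Null draws for betaNTI and RC (default 999).
#' @param n_rep Repetitions per robustness-curve point (default 100).
#' @param robustness_fractions Removal grid (default 0 to 0.95 by 0.05).
#' @param source_habitats,sink_habitat Habitats used as sources and sink in
#'   the source-tracking stage (defaults `c("water", "biofloc")`, `"gut"`).
#' @param sloan_pool_habitat Habitat whose pooled community is the Sloan
#'   source pool (default `"water"`).
#' @param sourcetrack_rarefy Sink depth for the Gibbs sampler (default 1000).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, metadata, out_dir, tree = NULL,
                            stages = c("rarefy", "diversity", "partition",
                                       "network", "stability", "assembly",
                                       "sourcetrack"),
                            seed = 1, depth = NULL, min_mean_reads = 5,
                            rho_min = 0.6, alpha = 0.05, n_perm = 999,
                            n_iter = 20, n_boot = 100, n_null = 999,
                            n_rep = 100,
                            robustness_fractions = seq(0, 0.95, by = 0.05),
                            source_habitats = c("water", "biofloc"),
                            sink_habitat = "gut",
                            sloan_pool_habitat = "water",
                            sourcetrack_rarefy = 1000) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on one experiment —
#' rarefaction, diversity and ordination statistics, taxon partitioning,
#' per-group SparCC networks, stability (cohesion and robustness), assembly
#' processes (betaNTI + RC + Sloan), and source apportionment — writing a
#' TSV per result table, a JSON summary, and a run log into the output
#' directory. Stage seeds derive from the master seed, so repeated runs
#' with an identical configuration produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  order_all <- c("rarefy", "diversity", "partition", "network", "stability",
                 "assembly", "sourcetrack")
  stages <- intersect(order_all, cfg$stages)
  if (length(setdiff(cfg$stages, order_all)))
    stop("unknown stage(s): ", paste(setdiff(cfg$stages, order_all), collapse = ", "))
  # pre-flight dependency checks before any computation
  if ("stability" %in% stages && !"network" %in% stages)
    stop("stability stage requires the network stage")
  if ("assembly" %in% stages && is.null(cfg$tree))
    stop("assembly stage requires a phylogeny (tree)")
  need_hab <- c(if ("sourcetrack" %in% stages) c(cfg$source_habitats, cfg$sink_habitat),
                if ("assembly" %in% stages) cfg$sloan_pool_habitat)
  if (length(setdiff(need_hab, unique(cfg$metadata$habitat))))
    stop("habitat(s) absent from metadata: ",
         paste(setdiff(need_hab, unique(cfg$metadata$habitat)), collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(cfg$out_dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  stage_seed <- function(k) as.integer((cfg$seed * 97L + k) %% .Machine$integer.max)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(tdir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  log_lines <- c(sprintf("microstab %s", as.character(utils::packageVersion("microstab"))),
                 sprintf("master seed: %d", cfg$seed),
                 sprintf("stages: %s", paste(stages, collapse = ", ")))
  res <- list()
  summary <- list(seed = cfg$seed, stages = stages)

  counts <- cfg$counts
  md <- cfg$metadata
  groups <- unique(md$group)
  habitats <- unique(md$habitat)

  if ("rarefy" %in% stages) {
    depth <- if (is.null(cfg$depth)) min(rowSums(counts)) else cfg$depth
    counts <- rarefy_counts(counts, depth = depth, seed = stage_seed(1))
    md <- md[md$sample_id %in% rownames(counts), ]
    log_lines <- c(log_lines, sprintf("rarefy: depth %d, dropped %d sample(s)",
                                      depth, length(attr(counts, "dropped_samples"))))
    summary$rarefy <- list(depth = depth, dropped = attr(counts, "dropped_samples"))
    tsv(data.frame(sample_id = rownames(counts), counts, check.names = FALSE),
        "rarefied_counts")
  }
  rel <- relative_abundance(counts)
  grp_of <- stats::setNames(md$group, md$sample_id)
  hab_of <- stats::setNames(md$habitat, md$sample_id)

  if ("diversity" %in% stages) {
    alpha_df <- alpha_diversity(counts, tree = cfg$tree)
    alpha_df$group <- grp_of[alpha_df$sample_id]
    alpha_df$habitat <- hab_of[alpha_df$sample_id]
    tsv(alpha_df, "alpha_diversity")
    cell <- paste(alpha_df$group, alpha_df$habitat, sep = ".")
    cv <- data.frame(cell = sort(unique(cell)),
                     cv_richness = group_cv(alpha_df$richness, cell)[sort(unique(cell))],
                     cv_evenness = group_cv(alpha_df$evenness, cell)[sort(unique(cell))])
    tsv(cv, "alpha_cv")
    d <- bray_curtis(rel)
    ord <- pcoa_ordination(d)
    tsv(data.frame(sample_id = rownames(ord$coordinates),
                   ord$coordinates[, seq_len(min(3, ncol(ord$coordinates))), drop = FALSE]),
        "pcoa")
    # Table-1-style pairwise panels: groups within habitat, habitats within group
    dm <- as.matrix(d)
    panel <- function(ids, label_of) {
      lv <- unique(label_of[ids])
      combos <- utils::combn(lv, 2, simplify = FALSE)
      rows <- lapply(combos, function(pr) {
        sub <- ids[label_of[ids] %in% pr]
        an <- anosim_test(dm[sub, sub], label_of[sub], n_perm = cfg$n_perm,
                          seed = stage_seed(2))
        pm <- permanova_test(dm[sub, sub], label_of[sub], n_perm = cfg$n_perm,
                             seed = stage_seed(3))
        data.frame(comparison = paste(pr, collapse = " vs "),
                   anosim_r = an$statistic, anosim_p = an$p,
                   permanova_f = pm$statistic, r_squared = pm$r_squared,
                   permanova_p = pm$p)
      })
      out <- do.call(rbind, rows)
      out$anosim_p_adj <- bh_adjust(out$anosim_p)
      out$permanova_p_adj <- bh_adjust(out$permanova_p)
      out
    }
    perm_rows <- list()
    for (h in habitats) {
      ids <- md$sample_id[md$habitat == h]
      if (length(unique(grp_of[ids])) >= 2) {
        pp <- panel(ids, grp_of)
        pp$panel <- h
        perm_rows[[h]] <- pp
      }
    }
    for (g in groups) {
      ids <- md$sample_id[md$group == g]
      if (length(unique(hab_of[ids])) >= 2) {
        pp <- panel(ids, hab_of)
        pp$panel <- g
        perm_rows[[g]] <- pp
      }
    }
    perm_df <- do.call(rbind, perm_rows)
    tsv(perm_df, "permutation_tests")
    disp <- group_dispersion(d, paste(md$group, md$habitat, sep = "."))
    tsv(disp, "group_dispersion")
    res$diversity <- list(alpha = alpha_df, tests = perm_df, pcoa = ord)
    summary$diversity <- list(n_tests = nrow(perm_df))
  }

  cls <- NULL
  if ("partition" %in% stages) {
    part <- classify_otus(counts, md)
    cls <- part$class
    nb <- niche_breadth(rel)
    tsv(data.frame(otu_id = names(cls), class = unname(cls),
                   niche_breadth = unname(nb[names(cls)])), "otu_classes")
    res$partition <- part
    summary$partition <- as.list(table(cls))
  }

  nets <- list()
  spa <- list()
  if ("network" %in% stages) {
    for (g in groups) {
      ids <- md$sample_id[md$group == g]
      sub <- filter_mean_reads(counts[ids, , drop = FALSE], cfg$min_mean_reads)
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      rho <- sparcc(sub, n_iter = cfg$n_iter, seed = stage_seed(10))
      pv <- sparcc_pvalues(sub, rho, n_boot = cfg$n_boot, seed = stage_seed(11))
      node_cls <- if (!is.null(cls)) {
        ifelse(cls[colnames(sub)] == "core", "core", "specific")
      } else NULL
      net <- build_network(rho, pv, rho_min = cfg$rho_min, alpha = cfg$alpha,
                           node_classes = node_cls,
                           mean_abundance = colMeans(rel[ids, colnames(sub), drop = FALSE]))
      nets[[g]] <- net
      spa[[g]] <- list(rho = rho, p = pv, samples = ids)
      if (igraph::ecount(net) > 0) {
        ends <- igraph::as_edgelist(net)
        tsv(data.frame(otu_a = ends[, 1], otu_b = ends[, 2],
                       rho = igraph::E(net)$rho, sign = igraph::E(net)$sign),
            paste0("network_edges_", g))
        top <- topology_metrics(net)
        zp <- zipi(net, top$modules)
        tsv(merge(top$nodes, zp[, c("otu_id", "zi", "pi", "role")], by = "otu_id"),
            paste0("network_nodes_", g))
        summary$network[[g]] <- top$summary[c("n_nodes", "n_edges", "avg_degree",
                                              "avg_clustering", "avg_path_length",
                                              "modularity")]
        res$network[[g]] <- list(net = net, topology = top, zipi = zp)
      } else {
        summary$network[[g]] <- list(n_nodes = 0, n_edges = 0)
      }
    }
  }

  if ("stability" %in% stages) {
    coh_rows <- list()
    rob_rows <- list()
    for (g in groups) {
      sp <- spa[[g]]
      conn <- connectedness(sp$rho, sp$p, rho_min = cfg$rho_min, alpha = cfg$alpha)
      coh <- cohesion(rel[sp$samples, conn$otu_id, drop = FALSE], conn)
      coh$group <- g
      coh_rows[[g]] <- coh
      net <- nets[[g]]
      if (igraph::ecount(net) == 0) next
      targets <- list(all = igraph::V(net)$name)
      if (!is.null(igraph::V(net)$class)) {
        targets$core <- igraph::V(net)$name[igraph::V(net)$class == "core"]
        targets$specific <- igraph::V(net)$name[igraph::V(net)$class == "specific"]
      }
      for (tn in names(targets)) {
        if (length(targets[[tn]]) == 0) next
        rc <- robustness_curve(net, targets[[tn]],
                               fractions = cfg$robustness_fractions,
                               n_rep = cfg$n_rep, seed = stage_seed(20))
        rc$target <- tn
        rc$group <- g
        rob_rows[[paste(g, tn)]] <- rc
      }
    }
    coh_df <- do.call(rbind, coh_rows)
    tsv(coh_df, "cohesion")
    if (length(rob_rows)) tsv(do.call(rbind, rob_rows), "robustness")
    res$stability <- list(cohesion = coh_df, robustness = rob_rows)
    summary$stability <- list(mean_ratio = stats::setNames(
      vapply(split(coh_df$ratio, coh_df$group), mean, numeric(1), na.rm = TRUE),
      NULL))
  }

  if ("assembly" %in% stages) {
    proc_rows <- list()
    sloan_rows <- list()
    for (g in groups) {
      ids <- md$sample_id[md$group == g]
      sub <- counts[ids, , drop = FALSE]
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      bn <- bnti(sub, cfg$tree, n_null = cfg$n_null, seed = stage_seed(30))
      rc <- rc_bray(sub, n_null = cfg$n_null, seed = stage_seed(31))
      pp <- partition_processes(bn, rc, labels = hab_of[ids])
      long <- pp$pairs
      long$group <- g
      proc_rows[[g]] <- long
      summary$assembly$fractions[[g]] <- pp$fractions
      pool_ids <- md$sample_id[md$group == g & md$habitat == cfg$sloan_pool_habitat]
      sink_ids <- md$sample_id[md$group == g & md$habitat == cfg$sink_habitat]
      if (length(pool_ids) && length(sink_ids) >= 2) {
        fit <- tryCatch(sloan_fit(counts[sink_ids, , drop = FALSE],
                                  counts[pool_ids, , drop = FALSE]),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          sloan_rows[[g]] <- data.frame(group = g, m = fit$m, Nm = fit$Nm,
                                        r_squared = fit$r_squared, d = fit$d)
          summary$assembly$sloan[[g]] <- list(m = fit$m, r_squared = fit$r_squared)
        }
      }
    }
    tsv(do.call(rbind, proc_rows), "assembly_pairs")
    if (length(sloan_rows)) tsv(do.call(rbind, sloan_rows), "sloan_fits")
    res$assembly <- list(pairs = proc_rows, sloan = sloan_rows)
  }

  if ("sourcetrack" %in% stages) {
    st_rows <- list()
    for (g in groups) {
      srcs <- t(vapply(cfg$source_habitats, function(h) {
        ids <- md$sample_id[md$group == g & md$habitat == h]
        colSums(counts[ids, , drop = FALSE])
      }, numeric(ncol(counts))))
      rownames(srcs) <- cfg$source_habitats
      sink_ids <- md$sample_id[md$group == g & md$habitat == cfg$sink_habitat]
      ap <- gibbs_source_apportion(srcs, counts[sink_ids, , drop = FALSE],
                                   rarefy_to = cfg$sourcetrack_rarefy,
                                   seed = stage_seed(40))
      df <- data.frame(group = g,
                       sink_id = rep(rownames(ap$proportions), ncol(ap$proportions)),
                       source = rep(colnames(ap$proportions), each = nrow(ap$proportions)),
                       proportion = as.vector(ap$proportions),
                       sd = as.vector(ap$sd))
      st_rows[[g]] <- df
      summary$sourcetrack[[g]] <- colMeans(ap$proportions)
    }
    st_df <- do.call(rbind, st_rows)
    tsv(st_df, "source_apportionment")
    res$sourcetrack <- st_df
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(res)
}

#' Pairwise Welch t tests with significance stars
#'
#' Two-sided two-sample t tests between every pair of groups (Welch by
#' default; set `pooled = TRUE` for the equal-variance form), with star
#' bands `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @param pooled Use the pooled-variance t test instead of Welch.
#' @return data.frame with `group_a`, `group_b`, `t`, `p`, `stars`.
#' @export
compare_groups <- function(values, groups, pooled = FALSE) {
  lv <- unique(as.character(groups))
  combos <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(combos, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning("singleton group in comparison ", paste(pr, collapse = " vs "))
      return(data.frame(group_a = pr[1], group_b = pr[2], t = NA_real_,
                        p = NA_real_, stars = NA_character_))
    }
    tt <- stats::t.test(a, b, var.equal = pooled)
    data.frame(group_a = pr[1], group_b = pr[2], t = unname(tt$statistic),
               p = tt$p.value, stars = significance_stars(tt$p.value))
  })
  do.call(rbind, rows)
}

#' Significance stars
#'
#' @param p Numeric vector of p-values.
#' @return `"****"` for p < 0.0001, `"***"` < 0.001, `"**"` < 0.01,
#'   `"*"` < 0.05, otherwise `""`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "")))))
}
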