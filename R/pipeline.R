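# Write a data frame as TSV/CSV with numeric columns fixed at 6 significant
# digits, so repeated runs with one seed are byte-identical.
write_table_6g <- function(df, path, sep = "\t") {
  for (k in colnames(df)) {
    if (is.numeric(df[[k]])) {
      df[[k]] <- formatC(signif(df[[k]], 6), digits = 6, format = "g")
    }
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-to-contribution pipeline
#'
#' Chains every stage on a synthetic multi-site dataset: simulation
#' (phylogeny, metadata, planted truth, communities), per-site ensemble
#' network inference, cross-network edge classification and keystones,
#' per-group assembly null models, alpha diversity and distance-decay,
#' the site-level methane response and its random-forest contribution
#' analysis, and the keystone-functional gene network. All randomness flows
#' from `config$seed` through named substreams, so two runs with one seed
#' write byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's tables are
#'   written there as TSV/CSV/JSON (numbers at 6 significant digits).
#' @param n_sites,samples_per_site,n_taxa,depth scale of the simulated
#'   dataset (defaults mirror the emulated field design, 39 x 11).
#' @param truth_args named list of overrides for [synthetic_truth()].
#' @param run_functional include the gene-signal stages (default TRUE).
#' @return A list with the simulation (`sim`), per-site `networks`,
#'   `topology` (+ `net_index`), `frequencies`, `groups`, `alpha`, `ch4`,
#'   `rf_env` / `contrib_env`, `rf_groups` / `contrib_groups`, `assembly`,
#'   `ddr`, `genes`, `functional`, `gene_weights`, `weight_regression`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         n_sites = 39, samples_per_site = 11, n_taxa = 50,
                         depth = 5000, truth_args = list(),
                         run_functional = TRUE) {
  seed <- config$seed
  sim <- do.call(simulate_dataset, c(
    list(n_sites = n_sites, samples_per_site = samples_per_site,
         n_taxa = n_taxa, depth = depth, seed = seed),
    truth_args
  ))
  comm <- filter_low_abundance(sim$community, config$min_total_reads)
  meta <- sim$metadata
  sites <- unique(meta$site_id)

  networks <- lapply(sites, function(s) {
    cols <- meta$sample_id[meta$site_id == s]
    infer_network(comm$counts[, cols, drop = FALSE], config,
                  network_id = s,
                  seed = stage_seed(seed, paste0("network_", s)))
  })
  names(networks) <- sites
  topo <- t(vapply(networks, function(nw) nw$topology, numeric(8)))
  rownames(topo) <- sites
  net_index <- tryCatch(network_index(topo), error = function(e) {
    # degenerate topology table (e.g. mostly empty networks): fall back to
    # standardized edge counts so downstream stages keep a complexity index
    warning("network index PCA degenerate; using standardized edge counts")
    en <- topo[, "edge_number"]
    z <- if (stats::sd(en) > 0) (en - mean(en)) / stats::sd(en) else en * 0
    list(index = stats::setNames(z, sites), explained = NA_real_,
         loadings = NULL, dropped = colnames(topo))
  })

  freqs <- edge_frequencies(networks)
  groups <- classify_edges(freqs, config$group_thresholds)

  alpha <- alpha_diversity(comm)
  site_of <- meta$site_id[match(alpha$sample_id, meta$sample_id)]
  shannon_site <- tapply(alpha$shannon, site_of, mean)[sites]

  ch4 <- generate_ch4(meta, net_index$index, shannon_site,
                      sim$truth$ch4_coefficients,
                      seed = stage_seed(seed, "ch4"))
  ch4_vec <- stats::setNames(ch4$ch4, ch4$site_id)

  env_site <- do.call(rbind, lapply(sites, function(s) {
    rows <- meta[meta$site_id == s, , drop = FALSE]
    data.frame(mat = mean(rows$mat), map = mean(rows$map),
               toc = mean(rows$toc), tn = mean(rows$tn),
               tp = mean(rows$tp), ph = mean(rows$ph))
  }))
  rownames(env_site) <- sites
  predictors <- cbind(env_site,
                      network_index = as.numeric(net_index$index[sites]),
                      shannon = as.numeric(shannon_site))

  rf_env <- NULL
  contrib_env <- NULL
  rf_groups <- NULL
  contrib_groups <- NULL
  if (length(sites) >= 10) {
    rf_env <- rf_importance(predictors, ch4_vec[sites],
                            n_trees = config$rf_ntree,
                            n_perm_sig = config$rf_n_perm_sig,
                            seed = stage_seed(seed, "rf_env"))
    contrib_env <- importance_to_contribution(rf_env)
    gf_site <- group_edge_features(networks, groups)[sites, , drop = FALSE]
    keep <- apply(gf_site, 2, stats::sd) > 0
    if (sum(keep) >= 2) {
      rf_groups <- rf_importance(as.data.frame(gf_site[, keep, drop = FALSE]),
                                 ch4_vec[sites],
                                 n_trees = config$rf_ntree,
                                 n_perm_sig = config$rf_n_perm_sig,
                                 seed = stage_seed(seed, "rf_groups"))
      contrib_groups <- importance_to_contribution(rf_groups)
    }
  }

  assembly <- group_assembly(comm, sim$tree, groups, config,
                             seed = stage_seed(seed, "assembly"))
  ddr <- ddr_all_scales(comm, meta, config$ddr_windows)

  genes <- NULL
  functional <- NULL
  gene_weights <- NULL
  weight_regression <- NULL
  keystones <- groups$keystones
  if (run_functional && length(keystones) >= 2) {
    site_map <- stats::setNames(meta$site_id, meta$sample_id)
    raw_genes <- generate_gene_signals(comm, keystones,
                                       seed = stage_seed(seed, "genes"))
    genes <- geochip_preprocess(raw_genes, site_map,
                                snr_min = config$geochip_snr_min,
                                constant = config$geochip_constant,
                                detection_min = config$geochip_detection_min)
    functional <- functional_network(comm, keystones, genes, config,
                                     seed = stage_seed(seed, "functional"))
    gene_weights <- site_gene_weights(comm, genes, functional, site_map)
    if (length(gene_weights) >= 5) {
      weight_regression <- tryCatch(
        weight_ch4_regression(gene_weights, ch4_vec),
        error = function(e) NULL
      )
    }
  }

  result <- list(
    config = config, sim = sim, community = comm,
    networks = networks, topology = topo, net_index = net_index,
    frequencies = freqs, groups = groups,
    alpha = alpha, shannon_site = shannon_site, ch4 = ch4,
    predictors = predictors,
    rf_env = rf_env, contrib_env = contrib_env,
    rf_groups = rf_groups, contrib_groups = contrib_groups,
    assembly = assembly, ddr = ddr,
    genes = genes, functional = functional,
    gene_weights = gene_weights, weight_regression = weight_regression
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write every pipeline stage's outputs to a directory
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)

  write_community_table(result$community, fp("community.tsv"))
  write_metadata(result$sim$metadata, fp("metadata.csv"))
  ape::write.tree(result$sim$tree, fp("tree.nwk"))
  write_truth_json(result$sim$truth, fp("truth.json"))

  all_edges <- do.call(rbind, lapply(result$networks, `[[`, "edges"))
  if (is.null(all_edges) || !nrow(all_edges)) all_edges <- empty_edge_list()
  write_edge_list(all_edges, fp("edges.tsv"))

  topo_df <- data.frame(network_id = rownames(result$topology),
                        result$topology,
                        network_index =
                          as.numeric(result$net_index$index[
                            rownames(result$topology)]),
                        row.names = NULL, check.names = FALSE)
  write_table_6g(topo_df, fp("topology.tsv"))

  write_table_6g(result$frequencies, fp("edge_frequencies.tsv"))
  write_table_6g(group_summary(result$groups), fp("groups.tsv"))
  utils::write.table(data.frame(otu_id = result$groups$keystones),
                     fp("keystones.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  asm <- do.call(rbind, lapply(names(result$assembly), function(g) {
    a <- result$assembly[[g]]
    data.frame(group = g, available = a$available,
               determinism_pct = a$fractions["determinism_pct"],
               stochasticity_pct = a$fractions["stochasticity_pct"],
               n_pairs = a$n_pairs, n_otus = a$n_otus,
               row.names = NULL)
  }))
  write_table_6g(asm, fp("assembly.tsv"))
  bnti <- do.call(rbind, lapply(names(result$assembly), function(g) {
    v <- result$assembly[[g]]$beta_nti_values
    if (!length(v)) return(NULL)
    data.frame(group = g, beta_nti = v)
  }))
  if (!is.null(bnti)) write_table_6g(bnti, fp("beta_nti_values.tsv"))

  write_table_6g(result$alpha, fp("diversity.tsv"))
  write_table_6g(result$ddr, fp("ddr.tsv"))
  write_table_6g(result$ch4, fp("ch4.tsv"), sep = ",")

  if (!is.null(result$rf_env)) {
    env_df <- data.frame(predictor = names(result$rf_env$importance),
                         importance = result$rf_env$importance,
                         p_value = result$rf_env$p_values,
                         contribution_pct =
                           as.numeric(result$contrib_env[
                             names(result$rf_env$importance)]),
                         row.names = NULL)
    write_table_6g(env_df, fp("contribution_env.tsv"))
  }
  if (!is.null(result$rf_groups)) {
    grp_df <- data.frame(group = names(result$rf_groups$importance),
                         importance = result$rf_groups$importance,
                         p_value = result$rf_groups$p_values,
                         contribution_pct =
                           as.numeric(result$contrib_groups[
                             names(result$rf_groups$importance)]),
                         row.names = NULL)
    write_table_6g(grp_df, fp("contribution_groups.tsv"))
  }
  if (!is.null(result$functional)) {
    write_table_6g(result$functional$edges, fp("functional_edges.tsv"))
    jsonlite::write_json(
      list(category_sums = as.list(signif(result$functional$category_sums,
                                          6)),
           n_nodes = result$functional$n_nodes,
           n_edges = result$functional$n_edges),
      fp("functional_sums.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$gene_weights)) {
    write_table_6g(data.frame(site_id = names(result$gene_weights),
                              species_gene_weight =
                                as.numeric(result$gene_weights)),
                   fp("site_gene_weights.tsv"))
  }

  summary_list <- list(
    seed = result$config$seed,
    n_sites = length(result$networks),
    n_otus = length(result$community$otu_ids),
    n_samples = length(result$community$sample_ids),
    total_distinct_edges = result$groups$total_edges,
    n_keystones = length(result$groups$keystones),
    pc1_explained_pct = signif(100 * result$net_index$explained, 6),
    var_explained_pct = if (!is.null(result$rf_env)) {
      signif(result$rf_env$var_explained_pct, 6)
    } else NULL
  )
  jsonlite::write_json(summary_list[!vapply(summary_list, is.null,
                                            logical(1))],
                       fp("summary.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}
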