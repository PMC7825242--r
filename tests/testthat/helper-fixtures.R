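# Shared fixtures and cached pipeline runs (computed once per test session).

.cache <- new.env(parent = emptyenv())

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_counts <- function() {
  m <- matrix(c(5, 1, 0, 0, 2, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("s1", "s2")))
  m
}

# Independent lognormal abundance table (no planted structure).
random_table <- function(n_otu, n_samp, seed, depth = NULL) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_otu * n_samp, 0, 1), n_otu, n_samp,
              dimnames = list(paste0("OTU_", seq_len(n_otu)),
                              paste0("s", seq_len(n_samp))))
  if (!is.null(depth)) {
    m <- apply(m, 2, function(p) stats::rmultinom(1, depth, p)[, 1])
    rownames(m) <- paste0("OTU_", seq_len(n_otu))
  }
  m
}

# Build a minimal canonical edge data frame for classification tests.
make_edges <- function(pairs, network_id, sign = "+") {
  if (!length(pairs)) return(methacoex:::empty_edge_list())
  df <- methacoex:::empty_edge_list()
  for (p in pairs) {
    pc <- sort(p)
    df <- rbind(df, data.frame(
      otu_a = pc[1], otu_b = pc[2], sign = sign,
      score_pearson = 0.9, score_spearman = 0.9,
      score_braycurtis = 0.2, score_kl = 0.1,
      p_pearson = 0.001, p_spearman = 0.001,
      p_braycurtis = 0.001, p_kl = 0.001,
      merged_p = 0.001, q_value = 0.01, network_id = network_id,
      stringsAsFactors = FALSE
    ))
  }
  df
}

pair_key <- function(pairs) {
  vapply(pairs, function(p) paste(sort(p), collapse = "-"), character(1))
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(pmin(edges$otu_a, edges$otu_b), pmax(edges$otu_a, edges$otu_b),
        sep = "-")
}

# Scaled-down end-to-end run shared across test files: 6 sites at the
# study's per-site sample size (detection power depends on samples per site,
# so sites are scaled down, not samples).
small_run <- function() {
  if (is.null(.cache$small_run)) {
    # frequency thresholds rescaled to the 6-network universe so the common
    # groups stay populated (the defaults assume 39 networks)
    cfg <- pipeline_config(n_perm = 300, n_boot = 300, n_null_phylo = 199,
                           rf_n_perm_sig = 50, seed = 101,
                           group_thresholds = c(1L, 2L, 3L, 4L))
    .cache$small_run <- suppressWarnings(
      run_pipeline(cfg, n_sites = 6, samples_per_site = 11, n_taxa = 30,
                   depth = 4000)
    )
  }
  .cache$small_run
}

# Full default-scale run (the study design: 39 sites x 11 samples) used by
# the planted-structure recovery checks; computed once.
default_run <- function() {
  if (is.null(.cache$default_run)) {
    cfg <- pipeline_config(seed = 20)
    .cache$default_run <- suppressWarnings(run_pipeline(cfg))
  }
  .cache$default_run
}

# Coexistence groups taken directly from the planted truth (common pairs into
# the two common groups, endemic pairs into always_endemic), used to probe
# the assembly stage in isolation from edge detection.
truth_groups <- function(truth) {
  ck <- t(vapply(truth$common_pairs, sort, character(2)))
  ek <- t(vapply(unlist(truth$endemic_pairs, recursive = FALSE), sort,
                 character(2)))
  fr <- data.frame(
    otu_a = c(ck[, 1], ek[, 1]),
    otu_b = c(ck[, 2], ek[, 2]),
    frequency = c(rep(c(15L, 25L), length.out = nrow(ck)),
                  rep(1L, nrow(ek))),
    networks = "planted", stringsAsFactors = FALSE
  )
  classify_edges(fr)
}

# Assembly-stage variant: sparse communities with stochastic occupancy, weak
# latent factors, and either temperature filtering concentrated on the common
# members (ts = 1, sigma_c small) or a fully neutral configuration.
assembly_variant <- function(ts, sigma_c, seed) {
  cfg <- pipeline_config(n_null_phylo = 199, seed = seed)
  sim <- simulate_dataset(n_sites = 6, samples_per_site = 11, n_taxa = 30,
                          depth = 500, seed = seed, trait_signal = ts,
                          niche_sigma = 1000, niche_sigma_common = sigma_c,
                          latent_weight = 0.5, abundance_sd = 0.8,
                          noise_sd = 2)
  cg <- truth_groups(sim$truth)
  comm <- filter_low_abundance(sim$community, 2)
  suppressWarnings(group_assembly(comm, sim$tree, cg, cfg,
                                  seed = stage_seed(seed, "assembly")))
}

pooled_determinism <- function(asm, groups) {
  v <- unlist(lapply(groups, function(g) asm[[g]]$beta_nti_values))
  if (!length(v)) return(NA_real_)
  unname(assembly_fractions(v)[1])
}
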