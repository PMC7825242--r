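#!/usr/bin/env Rscript
# Stage 4 — community assembly per coexistence group.
#
# For each group, subsets the community to the group's related OTUs and
# computes betaNTI for all sample pairs under 999 taxa-label randomizations
# of the phylogeny; |betaNTI| beyond 2 is read as deterministic assembly.
# Writes the per-group determinism/stochasticity table and the betaNTI
# distributions under results/assembly/.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

seed <- arg_seed(1L)
cfg <- analysis_config(seed)
out <- results_dir("assembly")

comm <- filter_low_abundance(
  read_community_table(file.path("results", "data", "community.tsv")),
  cfg$min_total_reads
)
tree <- read_newick(file.path("results", "data", "tree.nwk"))
check_tree_tips(tree, comm$otu_ids)
edges <- read_edge_list(file.path("results", "networks", "edges.tsv"))
freqs <- edge_frequencies(split(edges, edges$network_id))
groups <- classify_edges(freqs, cfg$group_thresholds)

assembly <- group_assembly(comm, tree, groups, cfg,
                           seed = stage_seed(seed, "assembly"))

tab <- do.call(rbind, lapply(names(assembly), function(g) {
  a <- assembly[[g]]
  data.frame(group = g, available = a$available,
             determinism_pct = round(a$fractions["determinism_pct"], 2),
             stochasticity_pct = round(a$fractions["stochasticity_pct"], 2),
             n_pairs = a$n_pairs, n_otus = a$n_otus, row.names = NULL)
}))
utils::write.table(tab, file.path(out, "assembly.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
vals <- do.call(rbind, lapply(names(assembly), function(g) {
  v <- assembly[[g]]$beta_nti_values
  if (!length(v)) return(NULL)
  data.frame(group = g, beta_nti = v)
}))
if (!is.null(vals)) {
  utils::write.table(vals, file.path(out, "beta_nti_values.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
print(tab, row.names = FALSE)
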