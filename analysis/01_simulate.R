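#!/usr/bin/env Rscript
# Stage 1 — simulate the multi-site survey.
#
# Generates the synthetic stand-in for a 39-paddy, 11-samples-per-site
# methanogen survey: a Yule phylogeny over 50 OTUs, site metadata with
# latitude-driven mean annual temperature, a planted coexistence truth
# (10 cross-site-common pairs, 2 endemic pairs per site), and multinomial
# community counts at depth 5000. Writes community.tsv, metadata.csv,
# tree.nwk and truth.json under results/data/.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

seed <- arg_seed(1L)
out <- results_dir("data")

sim <- simulate_dataset(seed = seed)

write_community_table(sim$community, file.path(out, "community.tsv"))
write_metadata(sim$metadata, file.path(out, "metadata.csv"))
ape::write.tree(sim$tree, file.path(out, "tree.nwk"))
write_truth_json(sim$truth, file.path(out, "truth.json"))

cat(sprintf(
  "simulated %d OTUs x %d samples over %d sites (seed %d)\n",
  length(sim$community$otu_ids), length(sim$community$sample_ids),
  length(unique(sim$metadata$site_id)), seed
))
cat(sprintf("planted: %d common pairs, %d endemic pairs\n",
            length(sim$truth$common_pairs),
            length(unlist(sim$truth$endemic_pairs, recursive = FALSE))))
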