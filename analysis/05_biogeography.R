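#!/usr/bin/env Rscript
# Stage 5 — diversity and distance-decay biogeography.
#
# Per-sample richness and Shannon diversity, pairwise Bray-Curtis
# dissimilarity and geographic distance, and distance-decay slopes
# (ln similarity on ln distance) at the local (1-100 m), meso (0.1-50 km)
# and regional (100-3500 km) scales. Writes results/biogeography/.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

seed <- arg_seed(1L)
cfg <- analysis_config(seed)
out <- results_dir("biogeography")

comm <- filter_low_abundance(
  read_community_table(file.path("results", "data", "community.tsv")),
  cfg$min_total_reads
)
meta <- read_metadata(file.path("results", "data", "metadata.csv"),
                      community = comm)

alpha <- alpha_diversity(comm)
utils::write.table(alpha, file.path(out, "diversity.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

ddr <- ddr_all_scales(comm, meta, cfg$ddr_windows)
utils::write.table(ddr, file.path(out, "ddr.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(ddr, row.names = FALSE)

site_of <- meta$site_id[match(alpha$sample_id, meta$sample_id)]
cat(sprintf("mean per-site Shannon: %.2f (range %.2f-%.2f)\n",
            mean(tapply(alpha$shannon, site_of, mean)),
            min(alpha$shannon), max(alpha$shannon)))
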