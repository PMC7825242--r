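#!/usr/bin/env Rscript
# Stage 3 — cross-network edge classification.
#
# Matches edges across the local networks, bins them by occurrence frequency
# into the five coexistence groups (always/conditionally endemic, moderate,
# conditionally/always common), and extracts the keystone OTU set (related
# OTUs of the two common groups). Writes the frequency table, the
# group-summary table and the keystone list under results/classification/,
# and reports recovery of the planted truth.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

seed <- arg_seed(1L)
cfg <- analysis_config(seed)
out <- results_dir("classification")

edges <- read_edge_list(file.path("results", "networks", "edges.tsv"))
networks <- split(edges, edges$network_id)
freqs <- edge_frequencies(networks)
groups <- classify_edges(freqs, cfg$group_thresholds)

utils::write.table(freqs, file.path(out, "edge_frequencies.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(group_summary(groups), file.path(out, "groups.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(otu_id = keystone_set(groups)),
                   file.path(out, "keystones.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

print(groups)

truth_file <- file.path("results", "data", "truth.json")
if (file.exists(truth_file)) {
  truth <- jsonlite::read_json(truth_file)
  fkey <- paste(freqs$otu_a, freqs$otu_b, sep = "-")
  ck <- vapply(truth$common_pairs, function(p) {
    paste(sort(unlist(p)), collapse = "-")
  }, character(1))
  ek <- vapply(unlist(truth$endemic_pairs, recursive = FALSE,
                      use.names = FALSE), function(p) {
    paste(sort(unlist(p)), collapse = "-")
  }, character(1))
  fc <- freqs$frequency[match(ck, fkey)]
  fc[is.na(fc)] <- 0
  fe <- freqs$frequency[match(ek, fkey)]
  fe[is.na(fe)] <- 0
  cat(sprintf("planted common pairs at frequency > 10: %.0f%%\n",
              100 * mean(fc > 10)))
  cat(sprintf("planted endemic pairs at frequency <= 3: %.0f%%\n",
              100 * mean(fe <= 3)))
}
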