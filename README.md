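# methacoex

Coexistence networks and community assembly of paddy soil methanogens.

Methanogenic archaea drive methane emission from rice paddies, and their
pairwise coexistence — syntrophic partnerships, shared niches, substrate
competition — can be read from co-occurrence networks inferred per paddy
across a multi-site survey. `methacoex` is an R package plus a numbered
analysis workflow that implements that study design end to end, for
microbial ecologists who want the full chain as tested, reusable functions:

* **Ensemble network inference** per site: Pearson, Spearman, Bray-Curtis
  and Kullback-Leibler scores on relative abundances; initial thresholds
  retrieving the 1000 strongest candidate edges per direction and measure;
  a *renormalized permutation* null (each OTU's abundances permuted, every
  sample re-closed to sum 1, countering compositionality bias) with a
  bootstrap direction-stability veto; Brown's method for combining the four
  dependent p-values, `T = Σ −2 log p_i` against a scaled chi-square with
  moment-matched degrees of freedom; Benjamini-Hochberg retention at
  q < 0.05.
* **Edge classification** across the local networks by occurrence
  frequency into five coexistence groups — always endemic (1 network),
  conditionally endemic (≤ 3), moderate (≤ 10), conditionally common
  (≤ 20), always common (> 20) — with the keystone OTU set as the union of
  the two common groups' members.
* **Assembly null models**: MNTD, ses.MNTD (= −NTI), abundance-weighted
  βMNTD and βNTI under taxa-label randomization of the phylogeny;
  `βNTI > 2 or ≤ −2` is read as deterministic assembly, values between as
  stochastic, per coexistence group.
* **Biogeography**: richness and Shannon diversity, Bray-Curtis
  dissimilarity, great-circle distances, and distance-decay slopes
  (ln similarity on ln distance) at local, meso and regional scales;
  methane production potential from incubation series.
* **Contribution analysis**: random-forest permutation importance (%IncMSE)
  of climate, soil, network-index and diversity predictors of methane, with
  response-permutation significance; group-wise contributions;
  functional-gene (microarray-style) preprocessing and the
  keystone-functional-gene network with category-wise edge-weight sums.
* **A synthetic multi-site generator** with planted ground truth —
  cross-site-common and site-endemic correlated pairs via shared latent
  factors, temperature niche filtering with phylogenetic signal, a methane
  response with known coefficients — so every stage has a recoverable
  target.

## Worked example

```r
library(methacoex)

# a small synthetic survey: 3 sites x 11 samples, 20 OTUs, known truth
sim <- simulate_dataset(n_sites = 3, samples_per_site = 11, n_taxa = 20,
                        depth = 3000, seed = 7, n_common = 4,
                        endemic_per_site = 1)
pair <- sort(sim$truth$common_pairs[[1]])   # "OTU_1" "OTU_4"

# is the planted pair supported at site 1?
cols <- sim$metadata$sample_id[sim$metadata$site_id == "site_01"]
reboot_pvalue(sim$community$counts[, cols], pair, "spearman",
              n_perm = 999, n_boot = 200, seed = 1)
#> $observed  0.864      # Spearman correlation of the pair's profiles
#> $p         0.001      # renormalized-permutation p (floor 1/1000)
#> $direction "+"        # co-presence
#> $stable    TRUE       # >= 95% of bootstrap scores confirm the direction
```

The pair planted as commonly coexisting is recovered with the strongest
attainable permutation p-value and a stable positive direction.

```r
# relative proportions of five coexistence groups from per-group edge counts
group_proportions(c(4049, 2928, 2206, 342, 157))
#>        always_endemic conditionally_endemic              moderate
#>                 41.82                 30.24                 22.78
#>  conditionally_common         always_common
#>                  3.53                  1.62
```

Endemic links dominate numerically (72% of distinct edges) while the two
common groups hold under 6% — the frequency profile that makes their
members interesting as keystone candidates.

```r
# nearest-taxon statistics on a toy 3-tip tree ((A:1,B:1):1,C:2);
tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
mntd(c(A = 1, B = 1, C = 1), tr)                          # 2.666667
beta_mntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 1), tr)  # 2.5
```

The full pipeline — simulation, per-site networks, classification,
assembly, distance decay, contribution analysis — is one call,
`run_pipeline(pipeline_config(seed = 1), out_dir = "results/run")`, or the
numbered scripts under `analysis/` (`01_simulate.R` … `06_contribution.R`),
each of which prints what it found and writes its tables under `results/`.

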