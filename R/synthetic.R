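#' Planted ground truth for a synthetic multi-site dataset
#'
#' Chooses the planted structure every downstream stage is asked to recover:
#' OTU pairs correlated at all sites (common coexistence), pairs correlated at
#' a single site (endemic coexistence), the niche model controlling
#' temperature filtering, and the coefficients of the methane response.
#'
#' @param otu_ids OTU pool.
#' @param site_ids site identifiers.
#' @param n_common number of pairs planted at every site.
#' @param endemic_per_site pairs planted at exactly one site, per site.
#' @param niche_sigma niche breadth (deg C) of the Gaussian temperature filter.
#' @param niche_sigma_common optional niche breadth for members of common
#'   pairs; NULL means `niche_sigma`. A smaller value concentrates
#'   temperature filtering on the broadly coexisting taxa.
#' @param trait_signal phylogenetic-signal weight in \[0, 1\] for the niche
#'   optima: 1 = optima follow Brownian motion on the tree, 0 = optima are
#'   independent of the tree (star-like).
#' @param latent_weight weight of the shared latent Gaussian factor inducing
#'   the planted within-site correlations (log-abundance scale).
#' @param noise_sd per-OTU-per-sample log-abundance noise sd.
#' @param abundance_sd sd of the static per-OTU log-abundance baseline
#'   (controls how uneven, and hence how sparse after multinomial sampling,
#'   the community is).
#' @param ch4_coefficients named vector `(b0, b_network, b_diversity, b_mat,
#'   sd)` of the site-level methane response.
#' @param phylogeny optional tree over `otu_ids`; when given, each common
#'   pair couples a tip with its nearest unused relative, mirroring the
#'   taxonomic clustering of broadly coexisting taxa (and keeping niche
#'   optima phylogenetically coherent within pairs).
#' @param seed RNG seed for the pair draw.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(otu_ids, site_ids,
                            n_common = 10,
                            endemic_per_site = 2,
                            niche_sigma = 6,
                            niche_sigma_common = NULL,
                            trait_signal = 0.7,
                            latent_weight = 1.5,
                            noise_sd = 0.45,
                            abundance_sd = 0.8,
                            ch4_coefficients = c(
                              b0 = 5, b_network = 1.5, b_diversity = 0.6,
                              b_mat = 0.15, sd = 0.5
                            ),
                            phylogeny = NULL,
                            seed = 1) {
  stopifnot(niche_sigma > 0, trait_signal >= 0, trait_signal <= 1)
  n_otu <- length(otu_ids)
  if (2 * n_common + 2 * endemic_per_site > n_otu) {
    stop("OTU pool too small for the requested pairs")
  }
  set.seed(stage_seed(seed, "truth"))
  otus <- sort(otu_ids)
  # common pairs use disjoint members, and endemic pairs (disjoint within
  # their site) avoid common-pair members, so each planted correlation is
  # attributable to exactly one latent factor
  if (n_common > 0 && !is.null(phylogeny)) {
    d <- cophenetic_matrix(phylogeny)[otus, otus]
    pool <- otus
    common <- vector("list", n_common)
    for (k in seq_len(n_common)) {
      a <- sample(pool, 1)
      rest <- setdiff(pool, a)
      b <- rest[which.min(d[a, rest])]
      common[[k]] <- c(a, b)
      pool <- setdiff(pool, c(a, b))
    }
    common_members <- unlist(common)
  } else if (n_common > 0) {
    common_members <- sample(otus, 2 * n_common)
    common <- lapply(seq_len(n_common), function(k) {
      common_members[c(2 * k - 1, 2 * k)]
    })
  } else {
    common_members <- character(0)
    common <- list()
  }
  free <- setdiff(otus, common_members)
  endemic <- stats::setNames(vector("list", length(site_ids)), site_ids)
  for (s in site_ids) {
    endemic[[s]] <- if (endemic_per_site > 0) {
      mem <- sample(free, 2 * endemic_per_site)
      lapply(seq_len(endemic_per_site), function(e) mem[c(2 * e - 1, 2 * e)])
    } else list()
  }
  structure(
    list(
      otu_ids = otu_ids,
      site_ids = site_ids,
      common_pairs = common,
      endemic_pairs = endemic,
      niche_sigma = niche_sigma,
      niche_sigma_common = niche_sigma_common,
      trait_signal = trait_signal,
      latent_weight = latent_weight,
      noise_sd = noise_sd,
      abundance_sd = abundance_sd,
      ch4_coefficients = ch4_coefficients,
      seed = seed
    ),
    class = "synthetic_truth"
  )
}

#' Simulate a pure-birth phylogeny over the OTU pool
#'
#' Yule (pure-birth) tree with `n_taxa` tips labeled `OTU_1..OTU_n`;
#' ultrametric with strictly positive branch lengths. The tree only needs to
#' supply a distance structure with phylogenetic signal for the nearest-taxon
#' statistics, so one birth rate is the only shape parameter.
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate Yule speciation rate.
#' @param seed RNG seed.
#' @return An [ape::phylo] tree.
#' @export
generate_phylogeny <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 3) stop("need at least 3 taxa for a phylogeny")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tr$tip.label <- paste0("OTU_", seq_len(n_taxa))
  tr
}

#' Simulate site and sample metadata
#'
#' Site centers are uniform in a geographic box; mean annual temperature is
#' linear in latitude, spanning `mat_range` (warmest at the southern edge) and
#' constant within a site, as for climate covariates taken from a gridded
#' climatology. The samples of a site are jittered within a 100 m x 100 m
#' plot. Mean annual precipitation and soil chemistry are plausible
#' correlated/noisy covariates, not targets of any recovery test.
#'
#' @param n_sites number of sites (>= 2).
#' @param samples_per_site samples per site (>= 2).
#' @param mat_range (min, max) mean annual temperature in deg C.
#' @param geo_box named vector `lat_min, lat_max, lon_min, lon_max`.
#' @param seed RNG seed.
#' @return Data frame with one row per sample: `sample_id`, `site_id`,
#'   `latitude`, `longitude`, `mat`, `map`, `ph`, `toc`, `tn`, `tp`,
#'   `ch4_potential` (NA until a methane response is attached).
#' @export
generate_metadata <- function(n_sites, samples_per_site,
                              mat_range = c(1.5, 23.8),
                              geo_box = c(lat_min = 19.5, lat_max = 47,
                                          lon_min = 110.2, lon_max = 126.2),
                              seed = 1) {
  if (n_sites < 2) stop("need at least 2 sites")
  if (samples_per_site < 2) stop("need at least 2 samples per site")
  if (mat_range[1] > mat_range[2]) stop("mat_range must be ordered")
  if (mat_range[1] == mat_range[2]) {
    warning("degenerate mat_range: temperature carries no site signal")
  }
  set.seed(seed)
  site_ids <- sprintf("site_%02d", seq_len(n_sites))
  lat <- stats::runif(n_sites, geo_box["lat_min"], geo_box["lat_max"])
  lon <- stats::runif(n_sites, geo_box["lon_min"], geo_box["lon_max"])
  lat_span <- geo_box["lat_max"] - geo_box["lat_min"]
  mat <- mat_range[2] -
    (lat - geo_box["lat_min"]) / lat_span * diff(mat_range)
  map <- 400 + 75 * mat + stats::rnorm(n_sites, 0, 100)
  rows <- vector("list", n_sites)
  km_per_deg <- 111.19493
  for (s in seq_len(n_sites)) {
    # jitter within +/- 50 m so all within-plot pairs stay under 0.2 km
    dlat <- stats::runif(samples_per_site, -0.05, 0.05) / km_per_deg
    dlon <- stats::runif(samples_per_site, -0.05, 0.05) /
      (km_per_deg * cos(lat[s] * pi / 180))
    rows[[s]] <- data.frame(
      sample_id = sprintf("%s_s%02d", site_ids[s], seq_len(samples_per_site)),
      site_id = site_ids[s],
      latitude = lat[s] + dlat,
      longitude = lon[s] + dlon,
      mat = mat[s],
      map = map[s],
      ph = stats::rnorm(samples_per_site, 6.5, 0.4),
      toc = stats::rlnorm(samples_per_site, log(15), 0.3),
      tn = stats::rlnorm(samples_per_site, log(1.5), 0.3),
      tp = stats::rlnorm(samples_per_site, log(0.6), 0.3),
      ch4_potential = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Niche optima on the temperature axis: blend of standardized Brownian-motion
# tip values (weight = trait_signal) and iid noise, rescaled to mat_range.
niche_optima <- function(phylogeny, mat_range, trait_signal) {
  tips <- phylogeny$tip.label
  bm <- ape::rTraitCont(phylogeny, model = "BM", sigma = 1)
  u <- stats::rnorm(length(tips))
  names(u) <- tips
  z_bm <- if (stats::sd(bm) > 0) (bm - mean(bm)) / stats::sd(bm) else bm * 0
  raw <- trait_signal * z_bm + (1 - trait_signal) * u
  rng <- range(raw)
  if (diff(rng) == 0 || diff(mat_range) == 0) {
    out <- rep(mean(mat_range), length(tips))
  } else {
    out <- mat_range[1] + (raw - rng[1]) / diff(rng) * diff(mat_range)
  }
  names(out) <- tips
  out
}

#' Simulate multi-site community counts with planted coexistence
#'
#' Per OTU i and sample j, expected log abundance is
#' `b_i - (MAT_j - o_i)^2 / (2 sigma^2)`: a Gaussian temperature filter around
#' the OTU's niche optimum `o_i`, which carries phylogenetic signal controlled
#' by `trait_signal` (see [synthetic_truth()]). Each planted pair shares an
#' additional latent Gaussian factor (weight `latent_weight`) at its
#' designated sites, inducing positive within-site correlation that survives
#' compositional closure. Counts are drawn multinomially per sample at the
#' given depth, so every sample column sums exactly to `depth`.
#'
#' @param phylogeny tree whose tips cover `truth$otu_ids`.
#' @param metadata per-sample metadata from [generate_metadata()].
#' @param truth a [synthetic_truth()].
#' @param depth reads per sample.
#' @param seed RNG seed.
#' @return A [community_table()] of integer counts.
#' @export
generate_communities <- function(phylogeny, metadata, truth,
                                 depth = 5000, seed = 1) {
  if (depth < 100) {
    warning("sequencing depth below 100: planted correlations are ",
            "unlikely to be recoverable")
  }
  check_tree_tips(phylogeny, truth$otu_ids)
  all_pairs <- c(truth$common_pairs, unlist(truth$endemic_pairs,
                                            recursive = FALSE))
  for (p in all_pairs) {
    if (!all(p %in% truth$otu_ids)) {
      stop("planted pair outside the OTU pool: ", paste(p, collapse = "-"))
    }
  }
  set.seed(seed)
  otus <- truth$otu_ids
  n_otu <- length(otus)
  n_samp <- nrow(metadata)
  mat_range <- range(metadata$mat)
  opt <- niche_optima(phylogeny, mat_range, truth$trait_signal)[otus]
  base <- stats::rnorm(n_otu, 0, truth$abundance_sd)
  names(base) <- otus
  # planted-pair members are drawn toward a common, slightly elevated
  # baseline: coexisting partners have comparable abundance scales (which
  # keeps their dissimilarity-measure support detectable) and keystones tend
  # to be reasonably abundant
  planted_members <- unique(unlist(all_pairs))
  base[planted_members] <- 0.5 + 0.3 * base[planted_members]
  # coexisting partners share a temperature niche (second member takes the
  # first member's optimum, lightly jittered), so a planted pair is jointly
  # abundant wherever either member is
  for (pair in all_pairs) {
    opt[pair[2]] <- opt[pair[1]] + stats::rnorm(1, 0, 0.5)
  }
  # per-OTU niche breadth: filtering can be concentrated on the members of
  # common pairs via truth$niche_sigma_common
  sigma <- rep(truth$niche_sigma, n_otu)
  names(sigma) <- otus
  if (!is.null(truth$niche_sigma_common)) {
    cm <- unique(unlist(truth$common_pairs))
    sigma[cm] <- truth$niche_sigma_common
  }
  eta <- matrix(base, nrow = n_otu, ncol = n_samp)
  eta <- eta - (outer(opt, metadata$mat, "-"))^2 / (2 * sigma^2)
  dimnames(eta) <- list(otus, metadata$sample_id)
  add_factor <- function(eta, pair, cols, w) {
    z <- stats::rnorm(length(cols))
    eta[pair[1], cols] <- eta[pair[1], cols] + w * z
    eta[pair[2], cols] <- eta[pair[2], cols] + w * z
    eta
  }
  for (pair in truth$common_pairs) {
    for (s in unique(metadata$site_id)) {
      eta <- add_factor(eta, pair, which(metadata$site_id == s),
                        truth$latent_weight)
    }
  }
  for (s in names(truth$endemic_pairs)) {
    for (pair in truth$endemic_pairs[[s]]) {
      eta <- add_factor(eta, pair, which(metadata$site_id == s),
                        truth$latent_weight)
    }
  }
  if (truth$noise_sd > 0) {
    eta <- eta + matrix(stats::rnorm(n_otu * n_samp, 0, truth$noise_sd),
                        n_otu, n_samp)
  }
  counts <- matrix(0L, n_otu, n_samp, dimnames = dimnames(eta))
  for (j in seq_len(n_samp)) {
    p <- exp(eta[, j] - max(eta[, j]))
    counts[, j] <- stats::rmultinom(1, depth, p / sum(p))[, 1]
  }
  community_table(counts)
}

#' Simulate a site-level methane response
#'
#' `ch4_s = b0 + b_network * x_net_s + b_diversity * x_div_s + b_mat * MAT_s
#' + Normal(0, sd)`, one value per site.
#'
#' @param metadata per-sample metadata (site MAT is read from it).
#' @param network_index named per-site scalar (e.g. from [network_index()]).
#' @param diversity named per-site diversity (e.g. mean Shannon).
#' @param coefficients named vector `(b0, b_network, b_diversity, b_mat, sd)`.
#' @param seed RNG seed.
#' @return Data frame `site_id`, `ch4`.
#' @export
generate_ch4 <- function(metadata, network_index, diversity,
                         coefficients = c(b0 = 5, b_network = 1.5,
                                          b_diversity = 0.6, b_mat = 0.15,
                                          sd = 0.5),
                         seed = 1) {
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  sites <- unique(metadata$site_id)
  if (!all(sites %in% names(network_index)) ||
      !all(sites %in% names(diversity))) {
    stop("network_index and diversity must be named by site_id")
  }
  mat_site <- tapply(metadata$mat, metadata$site_id, mean)[sites]
  set.seed(seed)
  eps <- if (coefficients["sd"] > 0) {
    stats::rnorm(length(sites), 0, coefficients["sd"])
  } else rep(0, length(sites))
  ch4 <- coefficients["b0"] +
    coefficients["b_network"] * as.numeric(network_index[sites]) +
    coefficients["b_diversity"] * as.numeric(diversity[sites]) +
    coefficients["b_mat"] * as.numeric(mat_site) +
    eps
  data.frame(site_id = sites, ch4 = as.numeric(ch4),
             stringsAsFactors = FALSE)
}

#' Construct a functional-gene signal table
#'
#' @param signals probes-by-samples numeric matrix (rownames probe ids).
#' @param gene gene label per probe (e.g. "mcrA").
#' @param snr per-spot signal-to-noise ratios, same shape as `signals`.
#' @return A `gene_table` list.
#' @export
gene_table <- function(signals, gene, snr = NULL) {
  stopifnot(is.matrix(signals), !is.null(rownames(signals)),
            !is.null(colnames(signals)))
  if (anyDuplicated(rownames(signals))) stop("probe ids must be unique")
  if (length(gene) != nrow(signals)) {
    stop("one gene label per probe is required")
  }
  if (any(signals < 0)) stop("gene signals must be nonnegative")
  if (is.null(snr)) snr <- matrix(Inf, nrow(signals), ncol(signals),
                                  dimnames = dimnames(signals))
  stopifnot(all(dim(snr) == dim(signals)))
  structure(
    list(probe_ids = rownames(signals), gene = gene,
         sample_ids = colnames(signals), signals = signals, snr = snr),
    class = "gene_table"
  )
}

#' @export
print.gene_table <- function(x, ...) {
  cat("gene_table:", length(x$probe_ids), "probes x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' Simulate functional-gene signals driven by keystone taxa
#'
#' Each probe's per-sample signal is a weighted sum of keystone relative
#' abundances plus Gaussian noise, clamped at zero — a microarray-style proxy
#' of methanogenesis pathway genes (mcrA, fwdB, mtbA, mtbC by default)
#' tracking the taxa that carry them.
#'
#' @param community [community_table()] of counts.
#' @param keystones OTU ids driving the signals (subset of the table's OTUs).
#' @param genes character vector of gene labels, one probe per entry.
#' @param weights optional genes-by-keystones weight matrix; by default each
#'   probe loads on 1-3 randomly chosen keystones with unit-mean weights.
#' @param noise_sd additive signal noise sd.
#' @param seed RNG seed.
#' @return A [gene_table()].
#' @export
generate_gene_signals <- function(community, keystones,
                                  genes = c("mcrA", "mcrA", "fwdB", "fwdB",
                                            "mtbA", "mtbC"),
                                  weights = NULL, noise_sd = 0.02, seed = 1) {
  if (!length(genes)) stop("gene list must be non-empty")
  m <- as_community_matrix(community)
  absent <- setdiff(keystones, rownames(m))
  if (length(absent)) {
    stop("keystones absent from community: ", paste(absent, collapse = ", "))
  }
  rel <- relativize(m)[keystones, , drop = FALSE]
  set.seed(seed)
  n_g <- length(genes)
  n_k <- length(keystones)
  if (is.null(weights)) {
    weights <- matrix(0, n_g, n_k)
    for (g in seq_len(n_g)) {
      on <- sample.int(n_k, min(n_k, sample(1:3, 1)))
      weights[g, on] <- stats::runif(length(on), 0.5, 1.5)
    }
  }
  stopifnot(nrow(weights) == n_g, ncol(weights) == n_k)
  sig <- weights %*% rel
  if (noise_sd > 0) {
    sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd),
                        nrow(sig), ncol(sig))
  }
  sig[sig < 0] <- 0
  rownames(sig) <- sprintf("probe_%02d_%s", seq_len(n_g), genes)
  colnames(sig) <- colnames(rel)
  gene_table(sig, genes, snr = matrix(10, n_g, ncol(rel),
                                      dimnames = dimnames(sig)))
}

#' Simulate a complete multi-site dataset
#'
#' Convenience wrapper chaining [generate_phylogeny()], [generate_metadata()],
#' [synthetic_truth()] and [generate_communities()] under named seed
#' substreams of one master seed. The default scale mirrors the field design
#' the generator emulates: 39 sites of 11 samples.
#'
#' @param n_sites,samples_per_site,mat_range,geo_box passed to
#'   [generate_metadata()].
#' @param n_taxa,birth_rate passed to [generate_phylogeny()].
#' @param depth reads per sample.
#' @param seed master seed.
#' @param ... passed to [synthetic_truth()] (planted pair counts, niche
#'   parameters, methane coefficients).
#' @return List with `tree`, `metadata`, `truth`, `community`.
#' @export
simulate_dataset <- function(n_sites = 39, samples_per_site = 11,
                             n_taxa = 50, birth_rate = 1, depth = 5000,
                             mat_range = c(1.5, 23.8),
                             geo_box = c(lat_min = 19.5, lat_max = 47,
                                         lon_min = 110.2, lon_max = 126.2),
                             seed = 1, ...) {
  tree <- generate_phylogeny(n_taxa, birth_rate,
                             seed = stage_seed(seed, "phylogeny"))
  metadata <- generate_metadata(n_sites, samples_per_site, mat_range,
                                geo_box, seed = stage_seed(seed, "metadata"))
  truth <- synthetic_truth(tree$tip.label, unique(metadata$site_id),
                           phylogeny = tree,
                           seed = stage_seed(seed, "truth"), ...)
  community <- generate_communities(tree, metadata, truth, depth,
                                    seed = stage_seed(seed, "communities"))
  list(tree = tree, metadata = metadata, truth = truth, community = community)
}

#' Serialize a synthetic truth to JSON
#'
#' @param truth a [synthetic_truth()].
#' @param path output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(
    otu_ids = truth$otu_ids,
    site_ids = truth$site_ids,
    common_pairs = lapply(truth$common_pairs, as.character),
    endemic_pairs = lapply(truth$endemic_pairs, function(ps) {
      lapply(ps, as.character)
    }),
    niche_sigma = truth$niche_sigma,
    niche_sigma_common = truth$niche_sigma_common,
    trait_signal = truth$trait_signal,
    latent_weight = truth$latent_weight,
    noise_sd = truth$noise_sd,
    abundance_sd = truth$abundance_sd,
    ch4_coefficients = as.list(truth$ch4_coefficients),
    seed = truth$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
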