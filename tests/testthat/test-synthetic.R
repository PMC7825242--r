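test_that("Yule phylogenies have the right shape and are reproducible", {
  tr <- generate_phylogeny(3, 1, seed = 5)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(nrow(tr$edge), 4) # rooted binary, 3 tips
  expect_true(ape::is.ultrametric(tr))
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(generate_phylogeny(20, 1, seed = 9)),
                   ape::write.tree(generate_phylogeny(20, 1, seed = 9)))
  expect_error(generate_phylogeny(2), "at least 3")
})

test_that("cophenetic distances form a metric on a 50-tip tree", {
  tr <- generate_phylogeny(50, 1, seed = 3)
  d <- cophenetic_matrix(tr)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality over all triples
  trip <- utils::combn(50, 3)
  viol <- 0
  for (k in seq_len(ncol(trip))) {
    a <- trip[1, k]; b <- trip[2, k]; cc <- trip[3, k]
    if (d[a, b] > d[a, cc] + d[cc, b] + 1e-9 ||
        d[a, cc] > d[a, b] + d[b, cc] + 1e-9 ||
        d[b, cc] > d[b, a] + d[a, cc] + 1e-9) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("metadata emulates the multi-site plot design", {
  md <- generate_metadata(39, 11, seed = 2)
  expect_equal(nrow(md), 429)
  expect_equal(length(unique(md$site_id)), 39)
  expect_equal(nrow(generate_metadata(2, 2)), 4)
  # within-site MAT constant; MAT spans the requested range direction
  expect_true(all(tapply(md$mat, md$site_id, function(v) length(unique(v)))
                  == 1))
  expect_true(min(md$mat) >= 1.5 - 1e-9 && max(md$mat) <= 23.8 + 1e-9)
  # all within-plot sample pairs within 0.2 km
  for (s in unique(md$site_id)[1:5]) {
    rows <- md[md$site_id == s, ]
    dmax <- 0
    for (i in 1:(nrow(rows) - 1)) {
      dmax <- max(dmax, haversine_km(rows$latitude[i], rows$longitude[i],
                                     rows$latitude[-(1:i)],
                                     rows$longitude[-(1:i)]))
    }
    expect_lt(dmax, 0.2)
  }
})

test_that("community generation conserves depth and handles degenerate truth", {
  sim <- simulate_dataset(n_sites = 3, samples_per_site = 4, n_taxa = 12,
                          depth = 750, seed = 4, n_common = 3,
                          endemic_per_site = 1)
  expect_true(all(colSums(sim$community$counts) == 750))
  expect_true(all(sim$community$counts == round(sim$community$counts)))

  # single OTU, single sample: that OTU takes every read
  tr <- generate_phylogeny(3, 1, seed = 1)
  truth <- synthetic_truth("OTU_1", "site_01", n_common = 0,
                           endemic_per_site = 0, noise_sd = 0)
  md <- data.frame(sample_id = "s1", site_id = "site_01", latitude = 30,
                   longitude = 115, mat = 12)
  comm <- generate_communities(tr, md, truth, depth = 500, seed = 1)
  expect_equal(unname(comm$counts["OTU_1", "s1"]), 500)

  expect_warning(generate_communities(tr, md, truth, depth = 50, seed = 1),
                 "depth")
})

test_that("planted pairs induce positive within-site correlation", {
  frac_pos <- replicate(3, NA_real_)
  for (r in 1:3) {
    sim <- simulate_dataset(n_sites = 5, samples_per_site = 20, n_taxa = 25,
                            depth = 4000, seed = 200 + r)
    pair <- sim$truth$common_pairs[[1]]
    rho <- vapply(unique(sim$metadata$site_id), function(s) {
      cols <- sim$metadata$sample_id[sim$metadata$site_id == s]
      suppressWarnings(stats::cor(sim$community$counts[pair[1], cols],
                                  sim$community$counts[pair[2], cols],
                                  method = "spearman"))
    }, numeric(1))
    frac_pos[r] <- mean(rho > 0, na.rm = TRUE)
  }
  expect_gt(mean(frac_pos), 0.9)
})

test_that("latent weight monotonically strengthens planted correlations", {
  mean_rho <- vapply(c(0.5, 1.5, 2.5), function(w) {
    rhos <- c()
    for (r in 1:4) {
      sim <- simulate_dataset(n_sites = 4, samples_per_site = 15,
                              n_taxa = 20, depth = 3000, seed = 40 + r,
                              latent_weight = w, n_common = 4,
                              endemic_per_site = 1)
      for (pair in sim$truth$common_pairs[1:4]) {
        for (s in unique(sim$metadata$site_id)) {
          cols <- sim$metadata$sample_id[sim$metadata$site_id == s]
          rhos <- c(rhos, suppressWarnings(
            stats::cor(sim$community$counts[pair[1], cols],
                       sim$community$counts[pair[2], cols],
                       method = "spearman")))
        }
      }
    }
    mean(rhos, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_rho) > 0))
})

test_that("the methane response follows its planted coefficients", {
  md <- generate_metadata(10, 2, seed = 6)
  sites <- unique(md$site_id)
  x_net <- stats::setNames(seq_along(sites), sites)
  x_div <- stats::setNames(rev(seq_along(sites)), sites)

  const <- generate_ch4(md, x_net, x_div,
                        c(b0 = 3, b_network = 0, b_diversity = 0,
                          b_mat = 0, sd = 0))
  expect_true(all(const$ch4 == 3))

  mono <- generate_ch4(md, x_net, x_div,
                       c(b0 = 0, b_network = 1, b_diversity = 0,
                         b_mat = 0, sd = 0))
  expect_equal(order(mono$ch4), order(x_net[mono$site_id]))

  # variance decomposition at 200 sites
  md2 <- generate_metadata(200, 2, seed = 7)
  sites2 <- unique(md2$site_id)
  set.seed(8)
  xn <- stats::setNames(stats::rnorm(200, 0, 2), sites2)
  xd <- stats::setNames(stats::rnorm(200, 0, 1), sites2)
  cf <- c(b0 = 1, b_network = 1.2, b_diversity = 0.8, b_mat = 0.3, sd = 0.5)
  y <- generate_ch4(md2, xn, xd, cf, seed = 9)$ch4
  mat_site <- tapply(md2$mat, md2$site_id, mean)[sites2]
  pred <- cf["b_network"] * xn + cf["b_diversity"] * xd +
    cf["b_mat"] * mat_site
  expected_var <- stats::var(as.numeric(pred)) + cf["sd"]^2
  expect_lt(abs(stats::var(y) - expected_var) / expected_var, 0.15)
})

test_that("gene signals track their keystone drivers", {
  m <- random_table(8, 40, seed = 10, depth = 3000)
  ks <- c("OTU_1", "OTU_2")
  w <- rbind(c(1, 0), c(1, 0)) # two probes on the same keystone
  gt <- generate_gene_signals(community_table(m), ks,
                              genes = c("mcrA", "fwdB"),
                              weights = w, noise_sd = 0, seed = 11)
  rel <- methacoex:::relativize(m)
  expect_equal(unname(gt$signals[1, ]), unname(rel["OTU_1", ]),
               tolerance = 1e-12)
  expect_equal(stats::cor(gt$signals[1, ], gt$signals[2, ]), 1,
               tolerance = 1e-12)
  expect_error(generate_gene_signals(community_table(m), ks,
                                     genes = character(0)),
               "non-empty")
})

test_that("truth JSON serializes the planted structure", {
  sim <- simulate_dataset(n_sites = 2, samples_per_site = 2, n_taxa = 8,
                          depth = 400, seed = 12, n_common = 2,
                          endemic_per_site = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back$common_pairs), length(sim$truth$common_pairs))
  expect_equal(back$niche_sigma, sim$truth$niche_sigma)
  # planted pair sets are disjoint
  ck <- pair_key(sim$truth$common_pairs)
  ek <- pair_key(unlist(sim$truth$endemic_pairs, recursive = FALSE))
  expect_length(intersect(ck, ek), 0)
})
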