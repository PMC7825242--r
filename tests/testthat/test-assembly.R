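test_that("MNTD matches hand-computed values on the toy tree", {
  tr <- toy_tree()
  ab <- c(A = 1, B = 1, C = 0)
  expect_equal(mntd(ab, tr), 2)
  ab3 <- c(A = 1, B = 1, C = 1)
  expect_equal(mntd(ab3, tr), 8 / 3)
  expect_equal(mntd(c(A = 3, B = 1, C = 0), tr, weighted = TRUE), 2)
  expect_error(mntd(c(A = 1, B = 0, C = 0), tr), "2 present")
})

test_that("MNTD and betaMNTD agree with brute force on an 8-tip tree", {
  tr <- generate_phylogeny(8, 1, seed = 21)
  d <- cophenetic_matrix(tr)
  set.seed(22)
  ab1 <- stats::setNames(stats::rpois(8, 3), tr$tip.label)
  ab2 <- stats::setNames(stats::rpois(8, 3), tr$tip.label)
  ab1[1] <- ab1[1] + 1 # at least 2 present
  ab2[2] <- ab2[2] + 1

  brute_mntd <- function(ab, weighted) {
    pres <- names(ab)[ab > 0]
    nn <- numeric(0)
    for (t1 in pres) {
      best <- Inf
      for (t2 in setdiff(pres, t1)) best <- min(best, d[t1, t2])
      nn <- c(nn, best)
    }
    if (weighted) sum(ab[pres] / sum(ab[pres]) * nn) else mean(nn)
  }
  expect_equal(mntd(ab1, tr), brute_mntd(ab1, FALSE), tolerance = 1e-12)
  expect_equal(mntd(ab1, tr, weighted = TRUE), brute_mntd(ab1, TRUE),
               tolerance = 1e-12)

  brute_beta <- function(a1, a2) {
    p1 <- names(a1)[a1 > 0]; p2 <- names(a2)[a2 > 0]
    s1 <- 0
    for (t1 in p1) {
      best <- Inf
      for (t2 in p2) best <- min(best, d[t1, t2])
      s1 <- s1 + a1[t1] / sum(a1[p1]) * best
    }
    s2 <- 0
    for (t2 in p2) {
      best <- Inf
      for (t1 in p1) best <- min(best, d[t2, t1])
      s2 <- s2 + a2[t2] / sum(a2[p2]) * best
    }
    unname(0.5 * (s1 + s2))
  }
  expect_equal(beta_mntd(ab1, ab2, tr), brute_beta(ab1, ab2),
               tolerance = 1e-12)
  expect_equal(beta_mntd(ab1, ab2, tr), beta_mntd(ab2, ab1, tr),
               tolerance = 1e-15)
})

test_that("betaMNTD reproduces the toy-tree worked examples", {
  tr <- toy_tree()
  expect_equal(beta_mntd(c(A = 2, B = 1, C = 0), c(A = 2, B = 1, C = 0),
                         tr), 0)
  expect_equal(beta_mntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 0),
                         tr), 2)
  expect_equal(beta_mntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 1),
                         tr), 2.5)
})

test_that("betaMNTD agrees with an independent reference implementation", {
  tr <- generate_phylogeny(8, 1, seed = 23)
  set.seed(24)
  comm <- matrix(stats::rpois(8 * 5, 2), nrow = 5,
                 dimnames = list(paste0("s", 1:5), tr$tip.label))
  comm[comm == 0 & col(comm) <= 2] <- 1 # keep samples non-empty
  ref <- as.matrix(picante::comdistnt(comm, cophenetic_matrix(tr),
                                      abundance.weighted = TRUE))
  ours <- methacoex:::beta_mntd_all(t(comm), cophenetic_matrix(tr))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("taxa-label shuffling preserves the distance multiset", {
  tr <- generate_phylogeny(12, 1, seed = 25)
  d <- cophenetic_matrix(tr)
  set.seed(26)
  for (r in 1:5) {
    perm <- sample.int(12)
    dp <- d[perm, perm]
    expect_equal(sort(dp[upper.tri(dp)]), sort(d[upper.tri(d)]),
                 tolerance = 1e-12)
  }
})

test_that("ses.MNTD self-calibrates on random draws and flags saturation", {
  tr <- generate_phylogeny(16, 1, seed = 27)
  full <- stats::setNames(rep(1, 16), tr$tip.label)
  expect_warning(res <- ses_mntd(full, tr, n_null = 49, seed = 28),
                 "zero spread")
  expect_true(is.na(res$z))

  set.seed(29)
  zs <- vapply(1:60, function(r) {
    ab <- stats::setNames(numeric(16), tr$tip.label)
    ab[sample.int(16, 6)] <- 1
    ses_mntd(ab, tr, n_null = 99, seed = 300 + r)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.3)

  # clade-confined communities are phylogenetically clustered (z < 0)
  d <- cophenetic_matrix(tr)
  hc <- stats::hclust(stats::as.dist(d))
  clade <- cutree(hc, k = 2)
  members <- names(clade)[clade == 1]
  if (length(members) < 4) members <- names(clade)[clade == 2]
  ab <- stats::setNames(numeric(16), tr$tip.label)
  ab[members] <- 1
  zc <- vapply(1:10, function(r) ses_mntd(ab, tr, n_null = 99,
                                          seed = 400 + r)$z, numeric(1))
  expect_true(mean(zc < 0) >= 0.9)
})

test_that("betaNTI is NA for identical communities and calibrated on nulls", {
  tr <- generate_phylogeny(10, 1, seed = 30)
  ab <- stats::setNames(c(rep(1, 5), rep(0, 5)), tr$tip.label)
  expect_warning(res <- beta_nti(ab, ab, tr, n_null = 49, seed = 31),
                 "zero spread")
  expect_true(is.na(res$z))

  # independent random communities: z distribution roughly standard
  tr2 <- generate_phylogeny(32, 1, seed = 32)
  set.seed(33)
  comm <- matrix(0, 32, 24, dimnames = list(tr2$tip.label,
                                            paste0("s", 1:24)))
  for (j in 1:24) comm[sample.int(32, 12), j] <- stats::rlnorm(12, 0, 1)
  z <- beta_nti_matrix(comm, tr2, n_null = 299, seed = 34)
  vals <- z[upper.tri(z)]
  vals <- vals[is.finite(vals)]
  expect_gt(length(vals), 100)
  expect_lt(abs(mean(vals)), 0.3)
  expect_true(stats::sd(vals) > 0.7 && stats::sd(vals) < 1.3)
  frac_in <- mean(abs(vals) <= 2)
  expect_gt(frac_in, 0.9)
})

test_that("the determinism partition applies the printed boundary rule", {
  expect_equal(unname(assembly_fractions(c(3, -3, 0, 1))), c(50, 50))
  expect_equal(unname(assembly_fractions(c(0.5, -1.5, 1.9))), c(0, 100))
  # exactly -2 deterministic, exactly +2 stochastic
  expect_equal(unname(assembly_fractions(c(-2, 2))[1]), 50)
  expect_equal(unname(assembly_fractions(c(2))[1]), 0)
  expect_equal(unname(assembly_fractions(c(-2))[1]), 100)
  # symmetric option counts both boundaries
  expect_equal(unname(assembly_fractions(c(-2, 2), symmetric = TRUE)[1]),
               100)
  expect_error(assembly_fractions(c(NA_real_, NaN)), "no usable")
})

test_that("stronger niche structure raises the deterministic fraction", {
  # sparse communities with stochastic occupancy (betaMNTD needs membership
  # turnover); deterministic fraction averaged over two seeds per setting
  det_at <- function(ts, sigma, seed) {
    sim <- simulate_dataset(n_sites = 6, samples_per_site = 4, n_taxa = 30,
                            depth = 500, seed = seed, trait_signal = ts,
                            niche_sigma = sigma, latent_weight = 0.5,
                            noise_sd = 2)
    z <- beta_nti_matrix(sim$community$counts, sim$tree, n_null = 199,
                         seed = seed + 1)
    unname(assembly_fractions(z[upper.tri(z)])[1])
  }
  grid <- list(list(ts = 0, sigma = 1000), list(ts = 0.9, sigma = 3),
               list(ts = 1, sigma = 1.5))
  det_frac <- vapply(grid, function(g) {
    mean(vapply(c(50, 90), function(s) det_at(g$ts, g$sigma, s),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(det_frac) >= 0))
  expect_gt(det_frac[3], det_frac[1] + 10)
})

test_that("per-group assembly handles small groups and subsets correctly", {
  run <- small_run()
  asm <- run$assembly
  expect_named(asm, methacoex:::coexistence_group_names)
  for (g in names(asm)) {
    a <- asm[[g]]
    if (!a$available) next
    expect_equal(sum(a$fractions), 100, tolerance = 1e-9)
    expect_equal(length(a$beta_nti_values), a$n_pairs)
  }
})
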