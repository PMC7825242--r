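#' Cophenetic distance matrix of a phylogeny
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return Symmetric tip-by-tip patristic distance matrix.
#' @export
cophenetic_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

resolve_distances <- function(tree_or_dist) {
  if (inherits(tree_or_dist, "phylo")) return(cophenetic_matrix(tree_or_dist))
  d <- as.matrix(tree_or_dist)
  stopifnot(nrow(d) == ncol(d), !is.null(rownames(d)))
  d
}

#' Mean nearest taxon distance of one community
#'
#' For every OTU present in the sample, the cophenetic distance to its
#' nearest other present OTU; averaged (abundance-weighted if `weighted`).
#'
#' @param abund named abundance vector over OTUs.
#' @param tree phylogeny (or precomputed cophenetic matrix).
#' @param weighted weight each OTU by its relative abundance.
#' @return MNTD (numeric scalar).
#' @export
mntd <- function(abund, tree, weighted = FALSE) {
  d <- resolve_distances(tree)
  stopifnot(!is.null(names(abund)))
  present <- names(abund)[abund > 0]
  if (length(present) < 2) stop("MNTD needs at least 2 present OTUs")
  missing <- setdiff(present, rownames(d))
  if (length(missing)) {
    stop("OTUs absent from the tree: ", paste(missing, collapse = ", "))
  }
  sub <- d[present, present, drop = FALSE]
  diag(sub) <- Inf
  nn <- apply(sub, 1, min)
  if (weighted) {
    w <- abund[present] / sum(abund[present])
    sum(w * nn)
  } else {
    mean(nn)
  }
}

#' Standardized effect size of MNTD (ses.MNTD / -NTI)
#'
#' Null model: the taxa labels of the phylogeny are shuffled (`n_null`
#' randomizations), leaving community membership and the distance multiset
#' unchanged; `z = (MNTD_obs - mean(null)) / sd(null)`. Negative z indicates
#' phylogenetic clustering; the nearest taxon index is `NTI = -z`.
#'
#' @inheritParams mntd
#' @param n_null randomizations (default 999).
#' @param seed RNG seed.
#' @return List with `mntd_obs`, `z` (ses.MNTD), `nti`, `null_mean`,
#'   `null_sd`; `z` is NA with a warning when the null has zero spread.
#' @export
ses_mntd <- function(abund, tree, n_null = 999, weighted = FALSE, seed = 1) {
  d <- resolve_distances(tree)
  obs <- mntd(abund, d, weighted)
  pool <- rownames(d)
  present <- names(abund)[abund > 0]
  pidx <- match(present, pool)
  sub_w <- abund[present]
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(t) {
    perm <- sample.int(length(pool))
    dp <- d[perm, perm]
    sub <- dp[pidx, pidx, drop = FALSE]
    diag(sub) <- Inf
    nn <- apply(sub, 1, min)
    if (weighted) sum(sub_w / sum(sub_w) * nn) else mean(nn)
  }, numeric(1))
  mu <- mean(nulls)
  sdev <- stats::sd(nulls)
  if (!is.finite(sdev) || sdev == 0) {
    warning("null MNTD has zero spread; ses.MNTD undefined")
    z <- NA_real_
  } else {
    z <- (obs - mu) / sdev
  }
  list(mntd_obs = obs, z = z, nti = -z, null_mean = mu, null_sd = sdev)
}

# Taxa-label shuffle of a distance matrix: taxon i takes over row/column
# perm[i] while keeping its own label, so downstream name lookups see the
# shuffled distances (plain d[perm, perm] would carry the permuted labels
# along and undo the shuffle under name-based subsetting).
shuffle_distances <- function(d, perm) {
  dp <- d[perm, perm, drop = FALSE]
  dimnames(dp) <- dimnames(d)
  dp
}

# Abundance-weighted betaMNTD for every pair of samples at once.
# comm: OTU-by-sample abundance matrix restricted to taxa on the tree;
# d: cophenetic matrix over (at least) those taxa, in any consistent order.
# For each sample j, nearest[t, j] is taxon t's distance to its closest taxon
# present in j (zero if t itself is present there); with F the within-sample
# relative abundances, betaMNTD = (t(F) %*% nearest + its transpose) / 2.
beta_mntd_all <- function(comm, d) {
  taxa <- rownames(comm)
  d <- d[taxa, taxa, drop = FALSE]
  cs <- colSums(comm)
  if (any(cs <= 0)) stop("every sample needs at least one present OTU")
  f <- sweep(comm, 2, cs, "/")
  nearest <- vapply(seq_len(ncol(comm)), function(j) {
    s <- comm[, j] > 0
    apply(d[, s, drop = FALSE], 1, min)
  }, numeric(nrow(comm)))
  w <- crossprod(f, nearest)
  out <- (w + t(w)) / 2
  dimnames(out) <- list(colnames(comm), colnames(comm))
  out
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted mean phylogenetic distance between each taxon of one
#' community and its closest relative in the other:
#' `0.5 * [sum_i f_i d(i, nearest in j) + sum_j f_j d(j, nearest in i)]`,
#' with `f` the relative abundances within each community. A taxon present in
#' both communities has nearest distance zero.
#'
#' @param abund_i,abund_j named abundance vectors over OTUs.
#' @param tree phylogeny (or cophenetic matrix).
#' @param weighted use within-community relative abundances as weights
#'   (FALSE gives equal weights over present taxa).
#' @return betaMNTD (numeric scalar); zero for identical communities.
#' @export
beta_mntd <- function(abund_i, abund_j, tree, weighted = TRUE) {
  d <- resolve_distances(tree)
  pi <- names(abund_i)[abund_i > 0]
  pj <- names(abund_j)[abund_j > 0]
  if (!length(pi) || !length(pj)) stop("empty community")
  missing <- setdiff(c(pi, pj), rownames(d))
  if (length(missing)) {
    stop("OTUs absent from the tree: ", paste(missing, collapse = ", "))
  }
  wi <- if (weighted) abund_i[pi] / sum(abund_i[pi]) else
    rep(1 / length(pi), length(pi))
  wj <- if (weighted) abund_j[pj] / sum(abund_j[pj]) else
    rep(1 / length(pj), length(pj))
  di <- apply(d[pi, pj, drop = FALSE], 1, min)
  dj <- apply(d[pj, pi, drop = FALSE], 1, min)
  0.5 * (sum(wi * di) + sum(wj * dj))
}

#' Beta nearest taxon index (betaNTI) for one sample pair
#'
#' `z = (betaMNTD_obs - mean(null)) / sd(null)` under taxa-label shuffling of
#' the phylogeny with abundances fixed. |z| beyond the conventional cutoff of
#' 2 is read as deterministic assembly.
#'
#' @inheritParams beta_mntd
#' @param n_null taxa-label randomizations (default 999).
#' @param seed RNG seed.
#' @return List with `beta_mntd_obs`, `z`, `null_mean`, `null_sd`; `z` is NA
#'   with a warning when the null has zero spread (e.g. identical
#'   communities, whose shared-taxon distances stay zero under relabeling).
#' @export
beta_nti <- function(abund_i, abund_j, tree, n_null = 999, seed = 1,
                     weighted = TRUE) {
  d <- resolve_distances(tree)
  comm <- cbind(i = abund_i[rownames(d)], j = abund_j[rownames(d)])
  comm[is.na(comm)] <- 0
  rownames(comm) <- rownames(d)
  if (!weighted) comm <- (comm > 0) * 1
  obs <- beta_mntd_all(comm, d)["i", "j"]
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(t) {
    perm <- sample.int(nrow(d))
    beta_mntd_all(comm, shuffle_distances(d, perm))["i", "j"]
  }, numeric(1))
  mu <- mean(nulls)
  sdev <- stats::sd(nulls)
  if (!is.finite(sdev) || sdev == 0) {
    warning("null betaMNTD has zero spread; betaNTI undefined")
    z <- NA_real_
  } else {
    z <- (obs - mu) / sdev
  }
  list(beta_mntd_obs = obs, z = z, null_mean = mu, null_sd = sdev)
}

#' betaNTI for all sample pairs of a community table
#'
#' Shares one set of taxa-label randomizations across every sample pair, so
#' large pair universes stay tractable; running means and variances of the
#' null betaMNTD are accumulated per pair.
#'
#' @param x community table or OTU-by-sample matrix (taxa must be on the
#'   tree); samples with no present OTU are dropped.
#' @param tree phylogeny (or cophenetic matrix) covering the OTUs.
#' @param n_null taxa-label randomizations.
#' @param seed RNG seed.
#' @return Symmetric sample-by-sample matrix of betaNTI z-scores (NA where
#'   the null spread is zero), with attribute `n_dropped_samples`.
#' @export
beta_nti_matrix <- function(x, tree, n_null = 999, seed = 1) {
  m <- as_community_matrix(x)
  d <- resolve_distances(tree)
  check_tree_tips(list(tip.label = rownames(d)), rownames(m))
  keep <- colSums(m) > 0
  dropped <- sum(!keep)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 non-empty samples")
  d <- d[rownames(m), rownames(m), drop = FALSE]
  obs <- beta_mntd_all(m, d)
  set.seed(seed)
  s1 <- matrix(0, ncol(m), ncol(m))
  s2 <- matrix(0, ncol(m), ncol(m))
  for (t in seq_len(n_null)) {
    perm <- sample.int(nrow(d))
    b <- beta_mntd_all(m, shuffle_distances(d, perm))
    s1 <- s1 + b
    s2 <- s2 + b * b
  }
  mu <- s1 / n_null
  varn <- (s2 - n_null * mu * mu) / (n_null - 1)
  varn[varn < 0] <- 0
  sdn <- sqrt(varn)
  z <- (obs - mu) / sdn
  z[sdn == 0] <- NA_real_
  diag(z) <- NA_real_
  dimnames(z) <- dimnames(obs)
  attr(z, "n_dropped_samples") <- dropped
  z
}

#' Determinism / stochasticity partition of betaNTI values
#'
#' The printed convention is applied literally: z > cutoff or z <= -cutoff
#' counts as determinism (so exactly -2 is deterministic and exactly +2
#' stochastic); `symmetric = TRUE` switches to |z| >= cutoff.
#'
#' @param beta_nti_values numeric vector of z-scores (NAs are ignored).
#' @param cutoff determinism cutoff (default 2).
#' @param symmetric use the symmetric |z| >= cutoff rule.
#' @return Named vector `determinism_pct`, `stochasticity_pct` summing to 100.
#' @export
#' @examples
#' assembly_fractions(c(3, -3, 0, 1))
assembly_fractions <- function(beta_nti_values, cutoff = 2,
                               symmetric = FALSE) {
  z <- beta_nti_values[is.finite(beta_nti_values)]
  if (!length(z)) stop("no usable betaNTI values")
  det <- if (symmetric) abs(z) >= cutoff else (z > cutoff | z <= -cutoff)
  p <- 100 * mean(det)
  c(determinism_pct = p, stochasticity_pct = 100 - p)
}

#' Community assembly partition per coexistence group
#'
#' For each of the five groups, the community table is subset to the group's
#' related OTUs, betaNTI is computed for all non-empty sample pairs under
#' shared taxa-label randomizations, and the deterministic/stochastic
#' fractions are reported.
#'
#' @param x community table (full dataset).
#' @param tree phylogeny covering the table's OTUs.
#' @param groups a `coexistence_groups` object from [classify_edges()].
#' @param config a [pipeline_config()] (uses `n_null_phylo`,
#'   `beta_nti_cutoff`, `symmetric_cutoff`, `seed`).
#' @param seed RNG seed (one substream per group is derived from it).
#' @return Named list of per-group results: `beta_nti_values`,
#'   `fractions` (determinism/stochasticity %), `n_pairs`, `n_otus`,
#'   `available` (FALSE when fewer than 2 usable OTUs or samples).
#' @export
group_assembly <- function(x, tree, groups, config = pipeline_config(),
                           seed = config$seed) {
  m <- as_community_matrix(x)
  d <- resolve_distances(tree)
  out <- list()
  for (g in names(groups$groups)) {
    otus <- intersect(groups$groups[[g]]$related_otus,
                      intersect(rownames(m), rownames(d)))
    if (length(otus) < 2) {
      out[[g]] <- list(available = FALSE, beta_nti_values = numeric(0),
                       fractions = c(determinism_pct = NA_real_,
                                     stochasticity_pct = NA_real_),
                       n_pairs = 0L, n_otus = length(otus))
      next
    }
    sub <- m[otus, , drop = FALSE]
    nonempty <- colSums(sub) > 0
    if (sum(nonempty) < 2) {
      out[[g]] <- list(available = FALSE, beta_nti_values = numeric(0),
                       fractions = c(determinism_pct = NA_real_,
                                     stochasticity_pct = NA_real_),
                       n_pairs = 0L, n_otus = length(otus))
      next
    }
    z <- beta_nti_matrix(sub[, nonempty, drop = FALSE],
                         d[otus, otus, drop = FALSE],
                         n_null = config$n_null_phylo,
                         seed = stage_seed(seed, paste0("assembly_", g)))
    vals <- z[upper.tri(z)]
    vals <- vals[is.finite(vals)]
    out[[g]] <- list(
      available = length(vals) > 0,
      beta_nti_values = vals,
      fractions = if (length(vals)) {
        assembly_fractions(vals, config$beta_nti_cutoff,
                           config$symmetric_cutoff)
      } else {
        c(determinism_pct = NA_real_, stochasticity_pct = NA_real_)
      },
      n_pairs = length(vals),
      n_otus = length(otus)
    )
  }
  out
}
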