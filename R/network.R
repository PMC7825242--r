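#' Candidate edges from measure-specific initial thresholds
#'
#' Selects, for one measure, the `n_pos` strongest positive-direction and
#' `n_neg` strongest negative-direction OTU pairs. Correlations rank by the
#' signed coefficient (largest r = strongest positive, most negative =
#' strongest negative); dissimilarities rank by value (smallest = strongest
#' positive, largest = strongest negative). Ties at the cutoff are all kept;
#' if fewer candidates exist than requested, all are kept.
#'
#' @param scores symmetric score matrix from [pairwise_scores()].
#' @param measure the measure the scores came from.
#' @param n_pos,n_neg candidates retrieved per direction.
#' @return Data frame `i`, `j` (row/column indices, i < j), `otu_a`, `otu_b`,
#'   `dir` (`"+"`/`"-"`), `score`.
#' @export
initial_thresholds <- function(scores, measure = measure_names,
                               n_pos = 1000, n_neg = 1000) {
  measure <- match.arg(measure)
  ids <- rownames(scores)
  ut <- upper.tri(scores)
  idx <- which(ut, arr.ind = TRUE)
  v <- scores[ut]
  ok <- is.finite(v)
  idx <- idx[ok, , drop = FALSE]
  v <- v[ok]
  is_corr <- measure %in% c("pearson", "spearman")
  top_k <- function(vals, k, decreasing) {
    # indices of the k strongest values, keeping all ties at the cutoff
    if (!length(vals) || k <= 0) return(integer(0))
    if (length(vals) <= k) return(seq_along(vals))
    thr <- sort(vals, decreasing = decreasing)[k]
    if (decreasing) which(vals >= thr) else which(vals <= thr)
  }
  if (is_corr) {
    pos_pool <- which(v > 0)
    neg_pool <- which(v < 0)
    pos <- pos_pool[top_k(v[pos_pool], n_pos, decreasing = TRUE)]
    neg <- neg_pool[top_k(v[neg_pool], n_neg, decreasing = FALSE)]
  } else {
    pos <- top_k(v, n_pos, decreasing = FALSE)
    neg <- top_k(v, n_neg, decreasing = TRUE)
    both <- intersect(pos, neg)
    if (length(both)) {
      # a pair qualifying for both tails goes to the side where it ranks
      # stronger (only possible when the pair universe is small)
      r_pos <- rank(v)
      r_neg <- rank(-v)
      to_neg <- both[r_neg[both] < r_pos[both]]
      pos <- setdiff(pos, to_neg)
      neg <- setdiff(neg, setdiff(both, to_neg))
    }
  }
  keep <- c(pos, neg)
  out <- data.frame(
    i = idx[keep, 1], j = idx[keep, 2],
    otu_a = ids[idx[keep, 1]], otu_b = ids[idx[keep, 2]],
    dir = rep(c("+", "-"), c(length(pos), length(neg))),
    score = v[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$i, out$j), , drop = FALSE]
}

#' Intersect per-measure candidate sets
#'
#' An edge enters the permutation stage only if all four measures support it
#' with a consistent direction; direction conflicts are dropped and counted.
#'
#' @param candidates named list of four data frames from
#'   [initial_thresholds()].
#' @return Data frame `i`, `j`, `otu_a`, `otu_b`, `dir` with attribute
#'   `n_conflicts`.
#' @export
intersect_measures <- function(candidates) {
  stopifnot(length(candidates) == 4L)
  key <- function(df) paste(df$i, df$j)
  common <- Reduce(intersect, lapply(candidates, key))
  n_conflicts <- 0L
  rows <- list()
  if (length(common)) {
    first <- candidates[[1]]
    first <- first[key(first) %in% common, , drop = FALSE]
    dirs <- vapply(candidates, function(df) {
      d <- df$dir[match(common, key(df))]
      d
    }, character(length(common)))
    if (length(common) == 1L) dirs <- matrix(dirs, nrow = 1)
    consistent <- apply(dirs, 1, function(d) length(unique(d)) == 1L)
    n_conflicts <- sum(!consistent)
    first <- first[match(common, key(first)), , drop = FALSE]
    rows <- first[consistent, c("i", "j", "otu_a", "otu_b", "dir"),
                  drop = FALSE]
    rows$dir <- dirs[consistent, 1]
  } else {
    rows <- data.frame(i = integer(0), j = integer(0),
                       otu_a = character(0), otu_b = character(0),
                       dir = character(0), stringsAsFactors = FALSE)
  }
  attr(rows, "n_conflicts") <- n_conflicts
  rows
}

# Re-close columns to sum 1, tolerating all-zero columns (uniform fill).
reclose <- function(m) {
  cs <- colSums(m)
  zero <- cs <= 0
  if (any(zero)) {
    m[, zero] <- 1 / nrow(m)
    cs[zero] <- 1
  }
  sweep(m, 2, cs, "/")
}

permute_rows <- function(m) {
  for (i in seq_len(nrow(m))) m[i, ] <- m[i, sample.int(ncol(m))]
  m
}

# Permutation-null and bootstrap score arrays for a set of candidate pairs.
# Null: each OTU's abundances permuted across samples independently, samples
# re-closed to sum 1 (the renormalization countering compositionality bias).
# Bootstrap: samples resampled with replacement.
reboot_scores <- function(rel, pair_idx, n_perm, n_boot, pseudocount,
                          measures = measure_names) {
  n_pair <- nrow(pair_idx)
  null <- array(NA_real_, c(n_perm, n_pair, length(measures)),
                dimnames = list(NULL, NULL, measures))
  boot <- array(NA_real_, c(n_boot, n_pair, length(measures)),
                dimnames = list(NULL, NULL, measures))
  for (t in seq_len(n_perm)) {
    pm <- reclose(permute_rows(rel))
    sc <- score_matrices(pm, pseudocount, measures)
    for (mz in measures) null[t, , mz] <- sc[[mz]][pair_idx]
  }
  for (t in seq_len(n_boot)) {
    bm <- rel[, sample.int(ncol(rel), replace = TRUE), drop = FALSE]
    sc <- score_matrices(reclose(bm), pseudocount, measures)
    for (mz in measures) boot[t, , mz] <- sc[[mz]][pair_idx]
  }
  list(null = null, boot = boot)
}

# Two-sided permutation p-value around the null mean, with pseudocount floor:
# p = (1 + #{|null - mean| >= |obs - mean|}) / (n_perm + 1).
perm_pvalue <- function(obs, null_scores) {
  mu0 <- mean(null_scores)
  dev <- abs(null_scores - mu0)
  (1 + sum(dev >= abs(obs - mu0) - 1e-12)) / (length(null_scores) + 1)
}

# Per-permutation empirical p-values of the null scores themselves (feeds the
# covariance estimate of Brown's method).
null_pvalues <- function(null_scores) {
  n <- length(null_scores)
  dev <- abs(null_scores - mean(null_scores))
  (n - rank(dev, ties.method = "min") + 2) / (n + 1)
}

# Direction of an observed score: correlations by sign, dissimilarities by
# position relative to the permutation-null mean (below = co-presence = "+").
score_direction <- function(obs, null_mean, measure) {
  if (measure %in% c("pearson", "spearman")) {
    if (obs >= 0) "+" else "-"
  } else {
    if (obs < null_mean) "+" else "-"
  }
}

# Fraction of bootstrap scores on the observed side of the null mean.
# Bootstrap resamples that leave a score undefined (e.g. a sparse OTU drawn
# with only zero samples) count against stability.
boot_side_fraction <- function(boot_scores, null_mean, dir, measure) {
  on_side <- if (measure %in% c("pearson", "spearman")) {
    if (dir == "+") boot_scores > null_mean else boot_scores < null_mean
  } else {
    if (dir == "+") boot_scores < null_mean else boot_scores > null_mean
  }
  on_side[!is.finite(on_side)] <- FALSE
  mean(on_side)
}

#' Renormalized-permutation p-value for one pair and measure
#'
#' The null distribution permutes each OTU's abundances across samples
#' independently and re-closes every sample to sum 1 before recomputing the
#' measure, so the null carries the same compositional bias as the observed
#' score. The p-value is the two-sided exceedance of the observed score's
#' deviation from the permutation-null mean, floored at `1/(n_perm + 1)`.
#' Separately, `n_boot` bootstrap scores (samples resampled with replacement)
#' must confirm the observed direction: if fewer than `stability` of them fall
#' on the observed side of the null mean, the measure's support is withdrawn
#' and the p-value set to 1.
#'
#' @param x community table or OTU-by-sample count matrix.
#' @param pair character vector of two OTU ids.
#' @param measure one of the four ensemble measures.
#' @param n_perm permutations (>= 100).
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed.
#' @param stability bootstrap direction-stability threshold (default 0.95).
#' @param pseudocount KL pseudocount (NULL = automatic).
#' @return List with `p` (post-veto), `p_perm` (pre-veto), `direction`,
#'   `stable`, `observed`, `null_mean`.
#' @export
reboot_pvalue <- function(x, pair, measure = measure_names,
                          n_perm = 1000, n_boot = 1000, seed = 1,
                          stability = 0.95, pseudocount = NULL) {
  measure <- match.arg(measure)
  if (n_perm < 100) stop("n_perm below 100 gives too coarse a p-value")
  m <- as_community_matrix(x)
  stopifnot(length(pair) == 2L, all(pair %in% rownames(m)))
  rel <- relativize(m)
  p0 <- if (is.null(pseudocount)) default_pseudocount(rel) else pseudocount
  idx <- matrix(match(pair, rownames(m)), nrow = 1)
  obs <- score_matrices(rel, p0, measures = measure)[[measure]][idx]
  if (!is.finite(obs)) stop("score undefined for this pair (constant OTU?)")
  set.seed(seed)
  rb <- reboot_scores(rel, idx, n_perm, n_boot, p0, measures = measure)
  nu <- rb$null[, 1, measure]
  mu0 <- mean(nu)
  p_perm <- perm_pvalue(obs, nu)
  dir <- score_direction(obs, mu0, measure)
  if (n_boot > 0) {
    side <- boot_side_fraction(rb$boot[, 1, measure], mu0, dir, measure)
    stable <- side >= stability
  } else {
    # n_boot = 0 disables the stability veto (pure permutation p-value)
    stable <- NA
  }
  list(p = if (isFALSE(stable)) 1 else p_perm, p_perm = p_perm,
       direction = dir, stable = stable, observed = obs, null_mean = mu0)
}

#' Combine dependent p-values with Brown's method
#'
#' Fisher's statistic `T = sum(-2 log p)` referred to a scaled chi-square
#' whose scale and degrees of freedom are moment-matched to the dependence
#' among the tests: `E[T] = 2k`, `Var[T] = 4k + 2 sum_{i<j} cov(-2 log P_i,
#' -2 log P_j)` with covariances estimated from per-permutation null p-values
#' of the same permutations. With no null matrix the covariances are taken as
#' zero and the method reduces to Fisher's.
#'
#' @param p_values the k observed p-values, each in (0, 1].
#' @param null_p_matrix optional n-by-k matrix of null p-values.
#' @return The merged p-value.
#' @export
#' @examples
#' brown_merge(rep(0.05, 4)) # Fisher limit, about 0.00234
brown_merge <- function(p_values, null_p_matrix = NULL) {
  k <- length(p_values)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  tstat <- sum(-2 * log(p_values))
  if (is.null(null_p_matrix)) {
    return(stats::pchisq(tstat, df = 2 * k, lower.tail = FALSE))
  }
  stopifnot(ncol(null_p_matrix) == k)
  if (any(null_p_matrix <= 0)) stop("null p-values must be positive")
  x <- -2 * log(null_p_matrix)
  cv <- stats::cov(x)
  vT <- 4 * k + 2 * sum(cv[upper.tri(cv)])
  eT <- 2 * k
  if (!is.finite(vT) || vT <= 0) {
    # degenerate covariance estimate: fall back to independence
    return(stats::pchisq(tstat, df = 2 * k, lower.tail = FALSE))
  }
  scale <- vT / (2 * eT)
  df <- 2 * eT^2 / vT
  stats::pchisq(tstat / scale, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg retention of candidate edges
#'
#' Step-up BH over the merged p-values of all candidate edges of one network;
#' edges with q below `alpha` are retained.
#'
#' @param edges data frame carrying a `merged_p` column (or a bare numeric
#'   vector of p-values).
#' @param alpha q-value cutoff.
#' @return The retained rows with a `q_value` column added.
#' @export
bh_filter <- function(edges, alpha = 0.05) {
  if (is.numeric(edges)) {
    edges <- data.frame(merged_p = edges)
  }
  if (!nrow(edges)) {
    edges$q_value <- numeric(0)
    return(edges)
  }
  edges$q_value <- stats::p.adjust(edges$merged_p, method = "BH")
  edges[edges$q_value < alpha, , drop = FALSE]
}

#' Infer one local co-occurrence network
#'
#' The full ensemble procedure for one site: the four association measures
#' are scored on relative abundances; measure-specific initial thresholds
#' retrieve the strongest `n_pos_edges` positive and `n_neg_edges` negative
#' candidates; only pairs supported by all four measures with a consistent
#' direction proceed; each surviving pair receives four renormalized
#' permutation p-values with bootstrap direction-stability vetoes; the four
#' p-values are merged with Brown's method using the same permutations'
#' empirical dependence; and Benjamini-Hochberg control at `alpha` decides
#' retention.
#'
#' @param x community table or count matrix (one site's samples).
#' @param config a [pipeline_config()].
#' @param network_id identifier recorded on every edge.
#' @param seed RNG seed for the permutation/bootstrap draws.
#' @return A `local_network`: list with `network_id`, `nodes` (OTUs incident
#'   to retained edges), `edges` (canonical edge data frame), `topology`
#'   (eight attributes from [topology_metrics()]), and candidate/veto/conflict
#'   counters.
#' @export
infer_network <- function(x, config = pipeline_config(),
                          network_id = "network_1", seed = config$seed) {
  m <- as_community_matrix(x)
  if (ncol(m) < 4) stop("need at least 4 samples to infer a network")
  m <- m[rowSums(m) > 0, , drop = FALSE] # OTUs absent from this site
  if (nrow(m) < 2) stop("fewer than 2 OTUs present in this network's samples")
  rel <- relativize(m)
  p0 <- if (is.null(config$pseudocount)) default_pseudocount(rel)
    else config$pseudocount
  obs_sc <- score_matrices(rel, p0)
  cands <- lapply(measure_names, function(mz) {
    initial_thresholds(obs_sc[[mz]], mz, config$n_pos_edges,
                       config$n_neg_edges)
  })
  names(cands) <- measure_names
  pairs <- intersect_measures(cands)
  counters <- c(
    n_pairs_total = sum(upper.tri(obs_sc$pearson)),
    n_candidates = nrow(pairs),
    n_direction_conflicts = attr(pairs, "n_conflicts"),
    n_vetoed = 0L, n_skipped_na = 0L
  )
  if (!nrow(pairs)) {
    return(empty_network(network_id, counters))
  }
  idx <- cbind(pairs$i, pairs$j)
  obs <- vapply(measure_names, function(mz) obs_sc[[mz]][idx],
                numeric(nrow(idx)))
  if (nrow(idx) == 1L) obs <- matrix(obs, nrow = 1,
                                     dimnames = list(NULL, measure_names))
  set.seed(seed)
  rb <- reboot_scores(rel, idx, config$n_perm, config$n_boot, p0)
  n_pair <- nrow(idx)
  pvals <- matrix(NA_real_, n_pair, 4, dimnames = list(NULL, measure_names))
  dirs <- matrix(NA_character_, n_pair, 4)
  vetoed <- logical(n_pair)
  skipped <- logical(n_pair)
  merged <- rep(NA_real_, n_pair)
  for (i in seq_len(n_pair)) {
    null_p <- matrix(NA_real_, config$n_perm, 4)
    for (k in seq_along(measure_names)) {
      mz <- measure_names[k]
      nu <- rb$null[, i, mz]
      if (!is.finite(obs[i, k]) || anyNA(nu)) {
        skipped[i] <- TRUE
        next
      }
      mu0 <- mean(nu)
      p <- perm_pvalue(obs[i, k], nu)
      d <- score_direction(obs[i, k], mu0, mz)
      side <- boot_side_fraction(rb$boot[, i, mz], mu0, d, mz)
      if (side < config$bootstrap_stability) {
        p <- 1
        vetoed[i] <- TRUE
      }
      pvals[i, k] <- p
      dirs[i, k] <- d
      null_p[, k] <- null_pvalues(nu)
    }
    if (skipped[i]) next
    if (length(unique(dirs[i, ])) != 1L) {
      skipped[i] <- TRUE
      counters["n_direction_conflicts"] <-
        counters["n_direction_conflicts"] + 1L
      next
    }
    merged[i] <- brown_merge(pvals[i, ], null_p)
  }
  counters["n_vetoed"] <- sum(vetoed & !skipped)
  counters["n_skipped_na"] <- sum(skipped)
  usable <- !skipped
  if (!any(usable)) return(empty_network(network_id, counters))
  edges <- data.frame(
    otu_a = pairs$otu_a[usable], otu_b = pairs$otu_b[usable],
    sign = dirs[usable, 1],
    score_pearson = obs[usable, "pearson"],
    score_spearman = obs[usable, "spearman"],
    score_braycurtis = obs[usable, "braycurtis"],
    score_kl = obs[usable, "kl"],
    p_pearson = pvals[usable, "pearson"],
    p_spearman = pvals[usable, "spearman"],
    p_braycurtis = pvals[usable, "braycurtis"],
    p_kl = pvals[usable, "kl"],
    merged_p = merged[usable],
    q_value = NA_real_,
    network_id = network_id,
    stringsAsFactors = FALSE
  )
  retained <- bh_filter(edges, config$alpha)
  retained <- canonicalize_edges(retained)
  structure(
    list(
      network_id = network_id,
      nodes = sort(unique(c(retained$otu_a, retained$otu_b))),
      edges = retained,
      topology = topology_metrics(retained),
      counters = counters
    ),
    class = "local_network"
  )
}

empty_network <- function(network_id, counters) {
  structure(
    list(
      network_id = network_id,
      nodes = character(0),
      edges = empty_edge_list(),
      topology = suppressWarnings(topology_metrics(empty_edge_list())),
      counters = counters
    ),
    class = "local_network"
  )
}

#' @export
print.local_network <- function(x, ...) {
  cat("local_network", x$network_id, ":", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Eight topological attributes of a co-occurrence network
#'
#' Node number, edge number, modularity (deterministic greedy agglomeration
#' on the unsigned graph), positive and negative edge counts, average local
#' clustering coefficient (nodes of degree < 2 contribute 0), network
#' diameter, and characteristic path length; the latter two are computed on
#' the largest connected component so they stay finite.
#'
#' @param network a `local_network` or its edge data frame.
#' @return Named numeric vector of the eight attributes.
#' @export
topology_metrics <- function(network) {
  edges <- if (inherits(network, "local_network")) network$edges else network
  out <- c(node_number = 0, edge_number = 0, modularity = 0,
           positive = 0, negative = 0, avg_clustering = 0,
           diameter = 0, char_path_length = 0)
  if (!nrow(edges)) {
    warning("empty network: all topology metrics set to 0")
    return(out)
  }
  g <- igraph::simplify(edges_to_igraph(edges))
  out["node_number"] <- igraph::vcount(g)
  out["edge_number"] <- igraph::ecount(g)
  out["positive"] <- sum(edges$sign == "+")
  out["negative"] <- sum(edges$sign == "-")
  cl <- igraph::cluster_fast_greedy(g)
  out["modularity"] <- igraph::modularity(cl)
  lc <- igraph::transitivity(g, type = "local")
  lc[!is.finite(lc)] <- 0
  out["avg_clustering"] <- mean(lc)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  out["diameter"] <- igraph::diameter(sub, weights = NA)
  out["char_path_length"] <- igraph::mean_distance(sub, weights = NA)
  out
}

#' Network complexity index across local networks
#'
#' Standardizes the eight topological attributes across networks and returns
#' the first principal component scores, with the sign convention that the
#' index correlates positively with edge number; constant attributes are
#' dropped before the PCA.
#'
#' @param topologies matrix or data frame, one row per network, eight
#'   attribute columns (rownames = network ids).
#' @return List with `index` (named scores), `explained` (fraction of
#'   variance on PC1), `loadings`, `dropped` (constant attributes removed).
#' @export
network_index <- function(topologies) {
  x <- as.matrix(topologies)
  if (nrow(x) < 3) stop("need at least 3 networks for the index")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  keep <- setdiff(colnames(x), dropped)
  if (length(keep) < 2) stop("too few varying attributes for a PCA")
  z <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  ref <- if ("edge_number" %in% keep) x[, "edge_number"] else rowMeans(z)
  if (stats::cor(scores, ref) < 0) {
    scores <- -scores
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  names(scores) <- rownames(x)
  list(
    index = scores,
    explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    loadings = pc$rotation[, 1],
    dropped = dropped
  )
}
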