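#' Preprocess a functional-gene microarray table
#'
#' Three standard steps: (i) spots with signal-to-noise ratio below `snr_min`
#' are removed; (ii) per sample, each signal is divided by the sample's total
#' detected intensity, multiplied by a constant, and natural-log transformed
#' (`ln(1 + x)`); (iii) within each site's replicate set, probes detected in
#' at most `detection_min` samples are zeroed for that site ("detected" means
#' nonzero signal after the SNR filter).
#'
#' @param genes a [gene_table()] with `snr` populated.
#' @param site_map named character vector mapping sample id to site id.
#' @param snr_min signal-to-noise cutoff (default 2.0).
#' @param constant normalization constant (default 1e6).
#' @param detection_min per-site detection floor (default 2, inclusive).
#' @return A [gene_table()] of normalized signals (snr carried through).
#' @export
geochip_preprocess <- function(genes, site_map, snr_min = 2,
                               constant = 1e6, detection_min = 2) {
  stopifnot(inherits(genes, "gene_table"))
  absent <- setdiff(genes$sample_ids, names(site_map))
  if (length(absent)) {
    stop("samples missing from site map: ", paste(absent, collapse = ", "))
  }
  sig <- genes$signals
  sig[genes$snr < snr_min] <- 0
  totals <- colSums(sig)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total detected intensity: ",
         paste(genes$sample_ids[totals <= 0], collapse = ", "))
  }
  norm <- log1p(sweep(sig, 2, totals, "/") * constant)
  sites <- site_map[genes$sample_ids]
  for (s in unique(sites)) {
    cols <- which(sites == s)
    detected <- rowSums(sig[, cols, drop = FALSE] > 0)
    norm[detected <= detection_min, cols] <- 0
  }
  gene_table(norm, genes$gene, genes$snr)
}

#' Random-forest importance of methane predictors
#'
#' Fits a random-forest regression of the response on the predictor table and
#' reports permutation importance (mean MSE increase, the %IncMSE convention),
#' a response-permutation significance p per predictor (the observed
#' importance ranked against importances from refits with the response
#' shuffled), and the model's percent variance explained.
#'
#' @param x data frame or matrix of predictors (>= 10 observations).
#' @param y numeric response (e.g. site-level CH4 emission potential).
#' @param n_trees trees per forest (default 500).
#' @param n_perm_sig response-permutation refits (default 100).
#' @param seed RNG seed.
#' @return A `contribution_result` list: `importance` (named %IncMSE),
#'   `p_values`, `var_explained_pct`, `n_obs`.
#' @export
rf_importance <- function(x, y, n_trees = 500, n_perm_sig = 100, seed = 1) {
  x <- as.data.frame(x)
  if (nrow(x) < 10) stop("need at least 10 observations")
  if (length(y) != nrow(x)) stop("response length must match predictors")
  if (stats::sd(y) == 0) stop("constant response")
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1]
  var_exp <- 100 * (1 - utils::tail(fit$mse, 1) / stats::var(y))
  null_imp <- matrix(NA_real_, n_perm_sig, length(imp))
  for (b in seq_len(n_perm_sig)) {
    fit_b <- randomForest::randomForest(x, sample(y), ntree = n_trees,
                                        importance = TRUE)
    null_imp[b, ] <- randomForest::importance(fit_b, type = 1)[, 1]
  }
  p <- vapply(seq_along(imp), function(k) {
    (1 + sum(null_imp[, k] >= imp[k])) / (n_perm_sig + 1)
  }, numeric(1))
  names(p) <- names(imp)
  structure(
    list(importance = imp, p_values = p,
         var_explained_pct = as.numeric(var_exp), n_obs = nrow(x)),
    class = "contribution_result"
  )
}

#' @export
print.contribution_result <- function(x, ...) {
  cat("random-forest contribution:",
      sprintf("%.1f%% variance explained, %d obs\n",
              x$var_explained_pct, x$n_obs))
  ord <- order(x$importance, decreasing = TRUE)
  for (k in ord) {
    cat(sprintf("  %-24s imp %8.3f  p %.3f\n", names(x$importance)[k],
                x$importance[k], x$p_values[k]))
  }
  invisible(x)
}

#' Normalize importances to percentage contributions
#'
#' Over a stated subset of predictors, negative importances are clipped to
#' zero and the remainder rescaled to sum to 100.
#'
#' @param result a `contribution_result` (or named importance vector).
#' @param subset predictor names to normalize over (default all).
#' @return Named percentages summing to 100.
#' @export
#' @examples
#' importance_to_contribution(c(a = 5, b = 3, c = 2))
importance_to_contribution <- function(result, subset = NULL) {
  imp <- if (inherits(result, "contribution_result")) result$importance
    else result
  if (is.null(subset)) subset <- names(imp)
  missing <- setdiff(subset, names(imp))
  if (length(missing)) {
    stop("predictors not in the model: ", paste(missing, collapse = ", "))
  }
  v <- imp[subset]
  v[v < 0] <- 0
  if (sum(v) <= 0) stop("all importances zero after clipping")
  100 * v / sum(v)
}

#' Per-sample abundance features of the coexistence groups
#'
#' For each of the five groups, the summed relative abundance of the group's
#' related OTUs in every sample — the feature encoding used to regress CH4 on
#' group membership.
#'
#' @param x community table.
#' @param groups a `coexistence_groups` object.
#' @return Samples-by-groups matrix of summed relative abundances.
#' @export
group_abundance_features <- function(x, groups) {
  m <- relativize(as_community_matrix(x))
  feats <- vapply(groups$groups, function(g) {
    otus <- intersect(g$related_otus, rownames(m))
    if (!length(otus)) return(rep(0, ncol(m)))
    colSums(m[otus, , drop = FALSE])
  }, numeric(ncol(m)))
  rownames(feats) <- colnames(m)
  feats
}

#' Per-network edge-count features of the coexistence groups
#'
#' For each local network, the number of its edges falling in each of the
#' five coexistence groups — a site-level interaction-density encoding of
#' group activity. Unlike summed related-OTU abundances (see
#' [group_abundance_features()]), these features are not tied together by
#' compositional closure, so their contributions remain identifiable.
#'
#' @param networks list of `local_network` objects (or edge data frames).
#' @param groups a `coexistence_groups` object built from those networks.
#' @return Networks-by-groups matrix of edge counts.
#' @export
group_edge_features <- function(networks, groups) {
  stopifnot(inherits(groups, "coexistence_groups"))
  key_of <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  group_of <- unlist(lapply(names(groups$groups), function(g) {
    e <- groups$groups[[g]]$edges
    if (!nrow(e)) return(character(0))
    stats::setNames(rep(g, nrow(e)), key_of(e$otu_a, e$otu_b))
  }))
  feats <- t(vapply(networks, function(nw) {
    e <- if (inherits(nw, "local_network")) nw$edges else nw
    out <- stats::setNames(numeric(length(groups$groups)),
                           names(groups$groups))
    if (nrow(e)) {
      tab <- table(group_of[key_of(e$otu_a, e$otu_b)])
      out[names(tab)] <- as.numeric(tab)
    }
    out
  }, numeric(length(groups$groups))))
  ids <- vapply(networks, function(nw) {
    if (inherits(nw, "local_network")) nw$network_id
    else if (nrow(nw)) nw$network_id[1] else NA_character_
  }, character(1))
  rownames(feats) <- ids
  feats
}

#' Keystone-functional gene co-occurrence network
#'
#' Runs the same four-measure ensemble used for the taxon networks on the
#' stacked matrix of keystone OTU relative abundances and preprocessed gene
#' signals over their shared samples, then reports edge weights
#' (|mean of the Pearson and Spearman scores|) summed within three
#' categories: gene-gene, species-gene, species-species.
#'
#' @param x community table (counts; keystone rows are extracted from it).
#' @param keystones keystone OTU ids.
#' @param genes preprocessed [gene_table()].
#' @param config a [pipeline_config()].
#' @param seed RNG seed.
#' @return List with `edges` (edge data frame plus `weight` and `category`),
#'   `category_sums`, `n_nodes`, `n_edges`, `network`.
#' @export
functional_network <- function(x, keystones, genes,
                               config = pipeline_config(),
                               seed = config$seed) {
  m <- as_community_matrix(x)
  absent <- setdiff(keystones, rownames(m))
  if (length(absent)) {
    stop("keystones absent from community: ", paste(absent, collapse = ", "))
  }
  shared <- intersect(colnames(m), genes$sample_ids)
  if (length(shared) < 4) stop("need at least 4 shared samples")
  rel <- relativize(m[, shared, drop = FALSE])[keystones, , drop = FALSE]
  gs <- genes$signals[, shared, drop = FALSE]
  stacked <- rbind(rel, gs)
  keep <- rowSums(stacked) > 0
  stacked <- stacked[keep, , drop = FALSE]
  type <- c(rep("species", length(keystones)),
            rep("gene", nrow(gs)))[keep]
  names(type) <- rownames(stacked)
  nw <- infer_network(stacked, config, network_id = "functional",
                      seed = seed)
  edges <- nw$edges
  if (nrow(edges)) {
    edges$weight <- abs((edges$score_pearson + edges$score_spearman) / 2)
    ta <- type[edges$otu_a]
    tb <- type[edges$otu_b]
    edges$category <- ifelse(ta == "gene" & tb == "gene", "gene_gene",
                      ifelse(ta == "species" & tb == "species",
                             "species_species", "species_gene"))
  } else {
    edges$weight <- numeric(0)
    edges$category <- character(0)
  }
  sums <- vapply(c("gene_gene", "species_gene", "species_species"),
                 function(cat) sum(edges$weight[edges$category == cat]),
                 numeric(1))
  list(edges = edges, category_sums = sums,
       n_nodes = length(nw$nodes), n_edges = nrow(edges),
       node_types = type, network = nw)
}

#' Per-site species-gene linkage weights
#'
#' Re-scores the globally retained species-gene edges within each site's
#' samples (|mean of Pearson and Spearman| on the stacked profiles) and sums
#' them, giving one linkage-weight value per site.
#'
#' @param x community table.
#' @param genes preprocessed [gene_table()].
#' @param fn result of [functional_network()].
#' @param site_map named character vector mapping sample id to site id.
#' @return Named numeric vector of per-site species-gene weight sums.
#' @export
site_gene_weights <- function(x, genes, fn, site_map) {
  edges <- fn$edges[fn$edges$category == "species_gene", , drop = FALSE]
  m <- as_community_matrix(x)
  shared <- intersect(colnames(m), genes$sample_ids)
  sites <- site_map[shared]
  out <- stats::setNames(numeric(0), character(0))
  rel <- relativize(m[, shared, drop = FALSE])
  stacked <- rbind(rel, genes$signals[, shared, drop = FALSE])
  for (s in unique(sites)) {
    cols <- which(sites == s)
    w <- 0
    if (nrow(edges) && length(cols) >= 4) {
      for (e in seq_len(nrow(edges))) {
        a <- stacked[edges$otu_a[e], cols]
        b <- stacked[edges$otu_b[e], cols]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) next
        pe <- stats::cor(a, b)
        sp <- stats::cor(a, b, method = "spearman")
        w <- w + abs((pe + sp) / 2)
      }
    }
    out[s] <- w
  }
  out
}

#' Regression of linkage weights on methane emission
#'
#' OLS slope of CH4 on the per-site species-gene weight sums, with a
#' two-sided Spearman rank-correlation p-value.
#'
#' @param weights named per-site weight sums.
#' @param ch4 named per-site CH4 values (matched by name).
#' @return List with `slope`, `intercept`, `p_value` (Spearman), `rho`,
#'   `n_sites`, `available`.
#' @export
weight_ch4_regression <- function(weights, ch4) {
  sites <- intersect(names(weights), names(ch4))
  if (length(sites) < 5) stop("need at least 5 sites")
  w <- as.numeric(weights[sites])
  y <- as.numeric(ch4[sites])
  if (stats::sd(w) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
                rho = NA_real_, n_sites = length(sites), available = FALSE))
  }
  fit <- stats::lm(y ~ w)
  ct <- suppressWarnings(stats::cor.test(w, y, method = "spearman"))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = ct$p.value, rho = unname(ct$estimate),
       n_sites = length(sites), available = TRUE)
}
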