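measure_names <- c("pearson", "spearman", "braycurtis", "kl")

#' Close samples to relative abundance
#'
#' @param m OTU-by-sample matrix of nonnegative abundances.
#' @return Matrix whose columns each sum to 1.
#' @export
relativize <- function(m) {
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("cannot relativize: sample(s) with zero total abundance: ",
         paste(colnames(m)[cs <= 0], collapse = ", "))
  }
  sweep(m, 2, cs, "/")
}

# Half the smallest nonzero value: default pseudocount for the KL measure.
default_pseudocount <- function(rel) {
  nz <- rel[rel > 0]
  if (!length(nz)) stop("all-zero matrix")
  min(nz) / 2
}

# Symmetrized Kullback-Leibler divergence between OTU abundance profiles.
# Rows are zero-replaced with the pseudocount and renormalized to sum 1.
kl_matrix <- function(rel, pseudocount) {
  p <- rel
  p[p == 0] <- pseudocount
  p <- p / rowSums(p)
  lp <- log(p)
  m <- p %*% t(lp)
  a <- diag(m)
  d <- 0.5 * (outer(a, a, "+") - m - t(m))
  d[d < 0] <- 0 # numerical floor; KL >= 0
  dimnames(d) <- list(rownames(rel), rownames(rel))
  d
}

# Pairwise score matrices on a relative-abundance table (all four measures by
# default). Constant rows yield NA under pearson/spearman and those pairs are
# skipped downstream.
score_matrices <- function(rel, pseudocount, measures = measure_names) {
  out <- list()
  if ("pearson" %in% measures) {
    out$pearson <- suppressWarnings(stats::cor(t(rel)))
  }
  if ("spearman" %in% measures) {
    rk <- t(apply(rel, 1, rank))
    out$spearman <- suppressWarnings(stats::cor(t(rk)))
  }
  if ("braycurtis" %in% measures) {
    out$braycurtis <- as.matrix(suppressWarnings(
      vegan::vegdist(rel, method = "bray")
    ))
  }
  if ("kl" %in% measures) out$kl <- kl_matrix(rel, pseudocount)
  out
}

#' Pairwise association scores for one measure
#'
#' Evaluates one of the four ensemble measures between all OTU pairs of a
#' community table: Pearson and Spearman correlations of relative-abundance
#' profiles, Bray-Curtis dissimilarity, or symmetrized Kullback-Leibler
#' divergence (zeros replaced by a pseudocount, by default half the smallest
#' nonzero relative abundance). Dissimilarity measures carry no intrinsic
#' sign; their direction is assigned later relative to the permutation-null
#' expectation (below the null mean = positive association).
#'
#' @param x community table or OTU-by-sample matrix.
#' @param measure one of `"pearson"`, `"spearman"`, `"braycurtis"`, `"kl"`.
#' @param pseudocount zero replacement for KL; NULL = half the smallest
#'   nonzero relative abundance.
#' @return Symmetric OTU-by-OTU score matrix (diagonal not meaningful).
#' @export
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
#' colnames(m) <- paste0("s", 1:4)
#' pairwise_scores(m, "pearson")["a", "b"]
pairwise_scores <- function(x, measure = measure_names, pseudocount = NULL) {
  measure <- match.arg(measure)
  m <- as_community_matrix(x)
  if (ncol(m) < 4) stop("need at least 4 samples for association scores")
  if (nrow(m) < 2) stop("need at least 2 OTUs")
  rel <- relativize(m)
  p0 <- if (is.null(pseudocount)) default_pseudocount(rel) else pseudocount
  score_matrices(rel, p0)[[measure]]
}
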