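#' Pipeline configuration
#'
#' Builds the full set of tunables used across the pipeline, with defaults
#' matching the study design: per-measure initial thresholds retrieving 1000
#' positive and 1000 negative candidate edges, 1000 renormalized permutations
#' and 1000 bootstraps per network, merged-p significance at alpha = 0.05
#' after Benjamini-Hochberg control, 999 phylogenetic-null randomizations and
#' a betaNTI determinism cutoff of 2, and edge-frequency group thresholds
#' (1, 3, 10, 20) over the local networks.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `methacoex_config`.
#'
#' @details Tunables and defaults:
#' \describe{
#'   \item{n_pos_edges, n_neg_edges}{candidate edges retrieved per measure per
#'     direction before the permutation stage (1000 / 1000).}
#'   \item{n_perm, n_boot}{renormalized permutation and bootstrap iterations
#'     per network (1000 / 1000).}
#'   \item{alpha}{Benjamini-Hochberg q-value cutoff for edge retention (0.05).}
#'   \item{bootstrap_stability}{fraction of bootstrap scores that must fall on
#'     the observed side of the permutation-null mean for a measure to keep its
#'     p-value (0.95).}
#'   \item{n_null_phylo}{taxa-label randomizations for ses.MNTD / betaNTI (999).}
#'   \item{beta_nti_cutoff}{|betaNTI| threshold separating deterministic from
#'     stochastic assembly (2).}
#'   \item{symmetric_cutoff}{if TRUE use |z| >= cutoff for determinism; the
#'     default FALSE applies the asymmetric rule z > cutoff or z <= -cutoff.}
#'   \item{group_thresholds}{edge-frequency breaks for the five coexistence
#'     groups (1, 3, 10, 20).}
#'   \item{ddr_windows}{named list of distance windows in km for the
#'     distance-decay fits: local 0.001-0.1, meso 0.1-50, regional 100-3500.}
#'   \item{min_total_reads}{OTUs whose total read count is <= this are removed
#'     before analysis (2).}
#'   \item{pseudocount}{zero replacement for the Kullback-Leibler measure;
#'     NULL means half the smallest nonzero relative abundance.}
#'   \item{geochip_snr_min, geochip_constant, geochip_detection_min}{functional
#'     microarray preprocessing: signal-to-noise cutoff (2.0), normalization
#'     constant (1e6), and per-site detection floor (probes detected in <= 2
#'     replicates of a site are zeroed there).}
#'   \item{rf_ntree, rf_n_perm_sig}{random-forest trees (500) and
#'     response-permutation refits for predictor significance (100).}
#'   \item{seed}{master seed; every stage draws a named substream from it via
#'     [stage_seed()].}
#' }
#' @export
#' @examples
#' cfg <- pipeline_config(n_perm = 200, seed = 42)
#' cfg$n_perm
pipeline_config <- function(...) {
  cfg <- list(
    n_pos_edges = 1000L,
    n_neg_edges = 1000L,
    n_perm = 1000L,
    n_boot = 1000L,
    alpha = 0.05,
    bootstrap_stability = 0.95,
    n_null_phylo = 999L,
    beta_nti_cutoff = 2,
    symmetric_cutoff = FALSE,
    group_thresholds = c(1L, 3L, 10L, 20L),
    ddr_windows = list(
      local = c(0.001, 0.1),
      meso = c(0.1, 50),
      regional = c(100, 3500)
    ),
    min_total_reads = 2L,
    pseudocount = NULL,
    geochip_snr_min = 2,
    geochip_constant = 1e6,
    geochip_detection_min = 2L,
    rf_ntree = 500L,
    rf_n_perm_sig = 100L,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("configuration overrides must be named")
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  class(cfg) <- c("methacoex_config", "list")
  cfg
}

validate_config <- function(cfg) {
  count_keys <- c(
    "n_pos_edges", "n_neg_edges", "n_perm", "n_boot",
    "n_null_phylo", "rf_ntree", "rf_n_perm_sig"
  )
  for (k in count_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
      stop("config '", k, "' must be a positive integer")
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config 'alpha' must lie in (0, 1)")
  }
  th <- cfg$group_thresholds
  if (length(th) != 4L || any(diff(th) <= 0)) {
    stop("config 'group_thresholds' must be 4 strictly increasing values")
  }
  for (w in cfg$ddr_windows) {
    if (length(w) != 2L || any(w <= 0) || w[1] >= w[2]) {
      stop("each DDR window must be positive with min < max")
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Every key mirrors an argument of [pipeline_config()]; values given in the
#' file override the defaults, and further overrides passed here win over the
#' file (mirroring command-line-over-file precedence).
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return A `methacoex_config` list.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

#' Derive a per-stage child seed from the master seed
#'
#' All randomness flows from one master seed through named substreams, so a
#' stage re-run alone reproduces exactly what it did inside a full run. The
#' child seed is a deterministic hash of the stage name folded into the master
#' seed, kept inside the 32-bit integer range.
#'
#' @param master master seed (integer).
#' @param stage stage name, e.g. `"networks"`.
#' @return An integer seed.
#' @export
#' @examples
#' stage_seed(1, "networks")
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master))
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% m
  h <- (h * 48271) %% m
  as.integer((abs(as.numeric(master)) %% m + h) %% m)
}
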