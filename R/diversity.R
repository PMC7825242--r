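#' Per-sample alpha diversity
#'
#' Richness (OTUs with abundance > 0) and Shannon index (natural log) for
#' every sample of a community table.
#'
#' @param x community table or OTU-by-sample matrix.
#' @return Data frame `sample_id`, `richness`, `shannon`.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 10, 10, 10), s2 = c(7, 0, 0, 0))
#' rownames(m) <- paste0("OTU_", 1:4)
#' alpha_diversity(m)
alpha_diversity <- function(x) {
  m <- as_community_matrix(x)
  empty <- colSums(m) == 0
  if (any(empty)) warning("empty sample(s): richness and Shannon set to 0")
  sh <- suppressWarnings(vegan::diversity(t(m), index = "shannon"))
  sh[empty] <- 0
  data.frame(
    sample_id = colnames(m),
    richness = colSums(m > 0),
    shannon = as.numeric(sh),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over OTUs, on
#' relative-abundance profiles by default (raw counts also supported).
#'
#' @param x community table or matrix.
#' @param relative close samples to relative abundance first (default TRUE).
#' @return Symmetric sample-by-sample dissimilarity matrix in \[0, 1\]; NA
#'   where both samples are empty.
#' @export
bray_curtis_matrix <- function(x, relative = TRUE) {
  m <- as_community_matrix(x)
  empty <- colSums(m) == 0
  if (relative && !any(empty)) m <- relativize(m)
  if (relative && any(empty)) {
    m[, !empty] <- relativize(m[, !empty, drop = FALSE])
  }
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(m), method = "bray")))
  if (any(empty)) {
    d[empty, empty] <- NA_real_
    diag(d) <- 0
  }
  d
}

#' Great-circle distance in kilometers
#'
#' Haversine formula on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 1, 0) # about 111.19
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * r * asin(sqrt(a))
}

#' Pairwise geographic distances between samples
#'
#' @param metadata data frame with `latitude` and `longitude` (row order
#'   defines the matrix order; `sample_id` used for dimnames when present).
#' @return Symmetric distance matrix in km.
#' @export
geographic_distance_matrix <- function(metadata) {
  n <- nrow(metadata)
  ids <- if ("sample_id" %in% colnames(metadata)) metadata$sample_id
    else seq_len(n)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- haversine_km(metadata$latitude[i], metadata$longitude[i],
                            metadata$latitude[j], metadata$longitude[j])
    d[j, i] <- d[i, j]
  }
  d
}

#' Distance-decay slope within a spatial window
#'
#' Ordinary least squares of `ln(similarity)` on `ln(distance)` over
#' unordered sample pairs whose geographic distance falls in the half-open
#' window `[min, max)` km; similarity is `1 - Bray-Curtis`. Pairs with zero
#' similarity or zero distance are dropped (ln undefined) and counted.
#'
#' @param similarity sample-by-sample similarity matrix.
#' @param distance sample-by-sample distance matrix (km).
#' @param window `(min, max)` in km.
#' @param label scale label carried into the result (e.g. `"regional"`).
#' @return A `ddr_result` list: `label`, `window`, `slope`, `intercept`,
#'   `r_squared`, `n_pairs`, `n_dropped`, `available`.
#' @export
ddr_slope <- function(similarity, distance, window, label = "scale") {
  stopifnot(length(window) == 2, window[1] < window[2])
  ut <- upper.tri(distance)
  d <- distance[ut]
  s <- similarity[ut]
  in_win <- is.finite(d) & is.finite(s) & d >= window[1] & d < window[2]
  usable <- in_win & d > 0 & s > 0
  n_dropped <- sum(in_win) - sum(usable)
  if (sum(usable) < 3) {
    return(structure(list(label = label, window = window,
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_pairs = sum(usable),
                          n_dropped = n_dropped, available = FALSE),
                     class = "ddr_result"))
  }
  fit <- stats::lm(log(s[usable]) ~ log(d[usable]))
  structure(list(
    label = label, window = window,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    # suppress the perfect-fit note on exactly log-linear input
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_pairs = sum(usable), n_dropped = n_dropped,
    available = TRUE
  ), class = "ddr_result")
}

#' Distance-decay relationships at the three spatial scales
#'
#' @param x community table.
#' @param metadata per-sample metadata (must align with the table's samples).
#' @param windows named list of `(min, max)` km windows; defaults from
#'   [pipeline_config()]: local 0.001-0.1, meso 0.1-50, regional 100-3500.
#' @return Data frame with one row per scale (slope, intercept, r-squared,
#'   pair counts).
#' @export
ddr_all_scales <- function(x, metadata,
                           windows = pipeline_config()$ddr_windows) {
  m <- as_community_matrix(x)
  stopifnot(all(colnames(m) %in% metadata$sample_id))
  metadata <- metadata[match(colnames(m), metadata$sample_id), , drop = FALSE]
  sim <- 1 - bray_curtis_matrix(m)
  gd <- geographic_distance_matrix(metadata)
  res <- lapply(names(windows), function(lbl) {
    r <- ddr_slope(sim, gd, windows[[lbl]], lbl)
    data.frame(scale = lbl, window_min_km = r$window[1],
               window_max_km = r$window[2], slope = r$slope,
               intercept = r$intercept, r_squared = r$r_squared,
               n_pairs = r$n_pairs, n_dropped = r$n_dropped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Methane production potential from an incubation series
#'
#' OLS slope of CH4 concentration against incubation time (hours), converted
#' to micrograms CH4 per gram per day.
#'
#' @param times incubation times in hours (>= 2 points).
#' @param concentrations CH4 in micrograms per gram.
#' @return Production potential in micrograms CH4 per gram per day; negative
#'   values (net consumption) are returned with a warning.
#' @export
#' @examples
#' ch4_potential_slope(c(1, 50), c(0, 49)) # 24
ch4_potential_slope <- function(times, concentrations) {
  if (length(times) < 2 || length(times) != length(concentrations)) {
    stop("need at least 2 matching time points")
  }
  slope <- unname(stats::coef(stats::lm(concentrations ~ times))[2])
  out <- slope * 24
  if (is.finite(out) && abs(out) < 1e-12) out <- 0 # flat series, fp noise
  if (is.finite(out) && out < 0) {
    warning("negative production potential: consumption exceeds production")
  }
  out
}
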