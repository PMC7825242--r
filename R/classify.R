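coexistence_group_names <- c(
  "always_endemic", "conditionally_endemic", "moderate",
  "conditionally_common", "always_common"
)

#' Canonical identity of an OTU pair
#'
#' Lexicographically ordered pair; the sign of the association is ignored for
#' identity, so a pair positive at one site and negative at another counts as
#' the same coexistence link.
#'
#' @param otu_a,otu_b distinct OTU ids.
#' @return Length-2 character vector (ordered pair).
#' @export
#' @examples
#' canonical_edge_id("OTU_9", "OTU_2")
canonical_edge_id <- function(otu_a, otu_b) {
  if (otu_a == otu_b) stop("self-pair is not a valid edge: ", otu_a)
  if (otu_a < otu_b) c(otu_a, otu_b) else c(otu_b, otu_a)
}

#' Edge occurrence frequencies across local networks
#'
#' Counts, for every distinct canonical edge, the number of local networks
#' that contain it (at most once per network; duplicates within one network
#' are counted once with a warning).
#'
#' @param networks list of `local_network` objects (or of edge data frames).
#' @return Data frame `otu_a`, `otu_b`, `frequency`, `networks`
#'   (comma-separated network ids).
#' @export
edge_frequencies <- function(networks) {
  if (length(networks) < 2) stop("need at least 2 networks")
  per_net <- lapply(networks, function(nw) {
    edges <- if (inherits(nw, "local_network")) nw$edges else nw
    if (!nrow(edges)) return(NULL)
    key <- paste(pmin(edges$otu_a, edges$otu_b),
                 pmax(edges$otu_a, edges$otu_b), sep = "\t")
    if (anyDuplicated(key)) {
      warning("duplicate edge within network '", edges$network_id[1],
              "' counted once")
      key <- unique(key)
    }
    data.frame(key = key,
               network_id = if (nrow(edges)) edges$network_id[1] else NA,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_net)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(otu_a = character(0), otu_b = character(0),
                      frequency = integer(0), networks = character(0),
                      stringsAsFactors = FALSE))
  }
  freq <- tapply(all$network_id, all$key, function(ids) {
    paste(sort(unique(ids)), collapse = ",")
  })
  keys <- names(freq)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    otu_a = vapply(parts, `[`, character(1), 1),
    otu_b = vapply(parts, `[`, character(1), 2),
    frequency = vapply(strsplit(unname(freq), ",", fixed = TRUE),
                       length, integer(1)),
    networks = unname(freq),
    stringsAsFactors = FALSE
  )
  out[order(out$otu_a, out$otu_b), , drop = FALSE]
}

frequency_to_group <- function(frequency, thresholds = c(1, 3, 10, 20)) {
  if (any(frequency < 1)) stop("edge frequency below 1 is impossible")
  cut(frequency,
      breaks = c(0, thresholds, Inf),
      labels = coexistence_group_names,
      right = TRUE)
}

#' Classify edges into the five coexistence groups
#'
#' Frequency bins over the local networks: 1 network = always endemic,
#' (1, 3] = conditionally endemic, (3, 10] = moderate, (10, 20] =
#' conditionally common, > 20 = always common.
#'
#' @param frequencies data frame from [edge_frequencies()].
#' @param thresholds four strictly increasing frequency breaks.
#' @return A `coexistence_groups` list: per group the edge data frame, edge
#'   count, relative proportion, related OTU set; plus `keystones` (union of
#'   related OTUs of the two common groups) and `thresholds`.
#' @export
classify_edges <- function(frequencies, thresholds = c(1, 3, 10, 20)) {
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 4 strictly increasing values")
  }
  grp <- frequency_to_group(frequencies$frequency, thresholds)
  total <- nrow(frequencies)
  groups <- lapply(coexistence_group_names, function(g) {
    rows <- frequencies[grp == g, , drop = FALSE]
    list(
      edges = rows,
      edge_count = nrow(rows),
      proportion = if (total > 0) nrow(rows) / total else NA_real_,
      related_otus = related_otus(rows)
    )
  })
  names(groups) <- coexistence_group_names
  structure(
    list(groups = groups, total_edges = total, thresholds = thresholds,
         keystones = keystone_set_internal(groups)),
    class = "coexistence_groups"
  )
}

#' @export
print.coexistence_groups <- function(x, ...) {
  cat("coexistence_groups:", x$total_edges, "distinct edges\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %-22s %6d edges  %6.2f%%  %4d related OTUs\n", g,
                x$groups[[g]]$edge_count,
                100 * x$groups[[g]]$proportion,
                length(x$groups[[g]]$related_otus)))
  }
  cat("  keystones:", length(x$keystones), "OTUs\n")
  invisible(x)
}

#' Relative proportions of the five groups
#'
#' @param groups a `coexistence_groups` object, or a numeric vector of five
#'   per-group edge counts.
#' @return Named percentages (rounded to 2 decimals) summing to 100.
#' @export
#' @examples
#' group_proportions(c(4049, 2928, 2206, 342, 157))
group_proportions <- function(groups) {
  counts <- if (inherits(groups, "coexistence_groups")) {
    vapply(groups$groups, `[[`, numeric(1), "edge_count")
  } else {
    stats::setNames(as.numeric(groups), coexistence_group_names)
  }
  if (sum(counts) <= 0) stop("no edges to apportion")
  round(100 * counts / sum(counts), 2)
}

#' OTUs related to a group's edges
#'
#' @param group one element of a `coexistence_groups` object, or an edge data
#'   frame with `otu_a`/`otu_b` columns.
#' @return Sorted character vector (union of endpoints).
#' @export
related_otus <- function(group) {
  edges <- if (is.data.frame(group)) group else group$edges
  if (!nrow(edges)) return(character(0))
  sort(unique(c(edges$otu_a, edges$otu_b)))
}

keystone_set_internal <- function(groups) {
  sort(unique(c(groups[["conditionally_common"]]$related_otus,
                groups[["always_common"]]$related_otus)))
}

#' Keystone OTU set
#'
#' OTUs participating in conditionally or always common links — the taxa
#' whose broad coexistence marks them as candidate keystones; the union is
#' de-duplicated.
#'
#' @param groups a `coexistence_groups` object.
#' @return Sorted character vector of keystone OTU ids.
#' @export
keystone_set <- function(groups) {
  stopifnot(inherits(groups, "coexistence_groups"))
  groups$keystones
}

#' Summarize coexistence groups as a table
#'
#' One row per group: edge count, relative proportion (%), related-OTU count.
#'
#' @param groups a `coexistence_groups` object.
#' @return Data frame with five rows.
#' @export
group_summary <- function(groups) {
  stopifnot(inherits(groups, "coexistence_groups"))
  data.frame(
    group = names(groups$groups),
    edge_count = vapply(groups$groups, `[[`, numeric(1), "edge_count"),
    proportion_pct = as.numeric(group_proportions(groups)),
    related_otus = vapply(groups$groups, function(g) {
      length(g$related_otus)
    }, numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
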