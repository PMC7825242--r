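#' Construct and validate a community table
#'
#' The universal community input: an OTU-by-sample abundance matrix with
#' unique IDs on both margins and no negative values. Relative tables must
#' have every sample column summing to one.
#'
#' @param counts numeric matrix, OTUs in rows (rownames = OTU IDs), samples in
#'   columns (colnames = sample IDs).
#' @param is_relative logical; TRUE if columns are relative abundances.
#' @return An object of class `community_table` with fields `otu_ids`,
#'   `sample_ids`, `counts`, `is_relative`.
#' @export
#' @examples
#' m <- matrix(c(5, 1, 0, 0, 2, 7), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' community_table(m)
community_table <- function(counts, is_relative = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must carry OTU rownames and sample colnames")
  }
  dup_otu <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_otu)) stop("duplicated OTU id: ", dup_otu[1])
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s)) stop("duplicated sample id: ", dup_s[1])
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("community counts must be finite and non-missing")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(
      "negative abundance at OTU '", rownames(counts)[bad[1]],
      "', sample '", colnames(counts)[bad[2]], "'"
    )
  }
  if (is_relative && any(abs(colSums(counts) - 1) > 1e-9)) {
    stop("relative table columns must each sum to 1")
  }
  structure(
    list(
      otu_ids = rownames(counts),
      sample_ids = colnames(counts),
      counts = counts,
      is_relative = is_relative
    ),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat(
    "community_table:", length(x$otu_ids), "OTUs x",
    length(x$sample_ids), "samples",
    if (x$is_relative) "(relative)" else "(counts)", "\n"
  )
  invisible(x)
}

# Accept either a community_table or a bare dimnamed matrix.
as_community_matrix <- function(x) {
  if (inherits(x, "community_table")) return(x$counts)
  community_table(x)$counts
}

#' Read a community table from TSV or BIOM
#'
#' TSV dialect: first column OTU IDs, header row sample IDs, tab-separated
#' numeric cells, OTUs in rows (the classic QIIME-era orientation). BIOM files
#' (JSON, format 1.0) are accepted as an alternative.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom"`.
#' @return A [community_table()].
#' @export
read_community_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM input requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(community_table(m))
  }
  if (file.size(path) == 0) stop("community table file is empty: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("community table must have a header row, an OTU id column and at ",
         "least one sample column: ", path)
  }
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated OTU id: ", dup[1])
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
              dimnames = list(ids, colnames(df)[-1]))
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("non-numeric cell at OTU '", ids[i], "', sample '",
           colnames(m)[j], "'")
    }
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      stop("negative abundance at OTU '", ids[i], "', sample '",
           colnames(m)[j], "'")
    }
    m[, j] <- v
  }
  community_table(m)
}

#' Write a community table as TSV
#'
#' @param x a [community_table()] or OTU-by-sample matrix.
#' @param path output file.
#' @export
write_community_table <- function(x, path) {
  m <- as_community_matrix(x)
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop OTUs below a total-read floor
#'
#' Sparse-OTU filter applied before analysis; OTUs whose summed reads across
#' all samples are at or below `min_total` are removed.
#'
#' @param x community table.
#' @param min_total inclusive removal threshold on total reads (default 2).
#' @return A filtered [community_table()].
#' @export
filter_low_abundance <- function(x, min_total = 2) {
  m <- as_community_matrix(x)
  keep <- rowSums(m) > min_total
  if (!any(keep)) stop("no OTUs pass the total-read filter")
  community_table(m[keep, , drop = FALSE])
}

#' Read a phylogeny from a Newick file
#'
#' Requires a single tree with branch lengths on every edge; tip labels must
#' cover the OTUs used in the phylogenetic analyses (checked separately with
#' [check_tree_tips()]).
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop("could not parse Newick tree: ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("tree must carry a branch length on every edge: ", path)
  }
  tr
}

#' Check that a tree covers a set of OTUs
#'
#' @param tree an [ape::phylo] tree.
#' @param otu_ids OTU IDs that must be tips.
#' @return Invisibly TRUE; errors listing any missing IDs.
#' @export
check_tree_tips <- function(tree, otu_ids) {
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing)) {
    stop("OTUs absent from the tree: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

edge_list_columns <- c(
  "otu_a", "otu_b", "sign",
  "score_pearson", "score_spearman", "score_braycurtis", "score_kl",
  "p_pearson", "p_spearman", "p_braycurtis", "p_kl",
  "merged_p", "q_value", "network_id"
)

empty_edge_list <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(edge_list_columns)),
                    edge_list_columns),
    stringsAsFactors = FALSE
  )
  num <- setdiff(edge_list_columns, c("otu_a", "otu_b", "sign", "network_id"))
  for (k in num) df[[k]] <- numeric(0)
  df
}

validate_edge_list <- function(edges) {
  if (!is.data.frame(edges)) stop("edges must be a data frame")
  missing <- setdiff(edge_list_columns, colnames(edges))
  if (length(missing)) {
    stop("edge list lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(edges) && any(edges$otu_a == edges$otu_b)) {
    stop("self-edges are not allowed")
  }
  edges
}

# Canonicalize endpoint order (otu_a < otu_b), flipping rows where needed.
canonicalize_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  flip <- edges$otu_a > edges$otu_b
  if (any(flip)) {
    tmp <- edges$otu_a[flip]
    edges$otu_a[flip] <- edges$otu_b[flip]
    edges$otu_b[flip] <- tmp
  }
  edges[order(edges$network_id, edges$otu_a, edges$otu_b), , drop = FALSE]
}

#' Write an edge list
#'
#' Writes the canonical edge table either as TSV (full precision, lossless
#' round-trip through [read_edge_list()]) or as GraphML with the same
#' attributes on edges.
#'
#' @param edges edge data frame (see [infer_network()]).
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_edge_list <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  edges <- canonicalize_edges(validate_edge_list(edges))
  if (format == "tsv") {
    out <- edges[, edge_list_columns, drop = FALSE]
    num <- vapply(out, is.numeric, logical(1))
    for (k in names(out)[num]) {
      out[[k]] <- formatC(out[[k]], digits = 15, format = "g")
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- edges_to_igraph(edges)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path TSV file.
#' @return Edge data frame with canonical ordering.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = "character")
  if (!nrow(df)) return(empty_edge_list())
  num <- setdiff(edge_list_columns, c("otu_a", "otu_b", "sign", "network_id"))
  for (k in num) df[[k]] <- as.numeric(df[[k]])
  canonicalize_edges(validate_edge_list(df))
}

# Build an igraph from an edge data frame, carrying scores as attributes.
edges_to_igraph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$otu_a, edges$otu_b)))
  if (!nrow(edges)) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  igraph::graph_from_data_frame(
    edges[, c("otu_a", "otu_b",
              setdiff(colnames(edges), c("otu_a", "otu_b"))), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
}

#' Read sample metadata from CSV
#'
#' Expects at least `sample_id`, `site_id`, `latitude`, `longitude` columns;
#' climate (`mat`, `map`), soil chemistry and `ch4_potential` columns are kept
#' when present. Empty cells and "NA" are read as missing and stay missing.
#'
#' @param path CSV file.
#' @param community optional [community_table()]; if given, every sample id in
#'   the metadata must appear in the table.
#' @return A data frame of per-sample metadata.
#' @export
read_metadata <- function(path, community = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  need <- c("sample_id", "site_id", "latitude", "longitude")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("metadata lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]")
  }
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]")
  }
  if (!is.null(community)) {
    comm <- if (inherits(community, "community_table")) community
      else community_table(community)
    absent <- setdiff(df$sample_id, comm$sample_ids)
    if (length(absent)) {
      stop("metadata samples absent from community table: ",
           paste(absent, collapse = ", "))
    }
  }
  df
}

#' Write sample metadata as CSV
#'
#' @param metadata per-sample data frame.
#' @param path output file.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, na = "NA")
  invisible(path)
}
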