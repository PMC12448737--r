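#' Read an interaction edge list (2-column TSV or 3-column SIF)
#'
#' Ingests an undirected protein/gene interaction list. Lines with two
#' tab-separated fields are read as `a<TAB>b`; lines with three as the SIF
#' dialect `a<TAB>relation<TAB>b` (the relation is ignored). Self-loops are
#' dropped (and counted) and duplicate edges, in either orientation, are
#' collapsed.
#'
#' @param path Path to the file.
#' @return A list of class `edge_list`: `edges` (data.frame `from`, `to`),
#'   `node_ids`, `n_self_loops`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty edge list")
    return(structure(list(edges = data.frame(from = character(0),
                                             to = character(0)),
                          node_ids = character(0), n_self_loops = 0L),
                     class = "edge_list"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pairs <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) == 2L) c(f[1L], f[2L])
    else if (length(f) == 3L) c(f[1L], f[3L])
    else stop("malformed edge line ", i, ": expected 2 or 3 fields, got ",
              length(f))
  })
  from <- vapply(pairs, `[`, character(1), 1L)
  to <- vapply(pairs, `[`, character(1), 2L)
  loops <- from == to
  n_loops <- sum(loops)
  from <- from[!loops]; to <- to[!loops]
  lo <- pmin(from, to); hi <- pmax(from, to)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  edges <- data.frame(from = lo[!dup], to = hi[!dup],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges,
                 node_ids = sort(unique(c(edges$from, edges$to))),
                 n_self_loops = as.integer(n_loops)),
            class = "edge_list")
}

#' Rank hub nodes by degree
#'
#' Degree centrality on the simple undirected graph (the cytoHubba "Degree"
#' notion): nodes sorted by degree descending, ties by node id ascending.
#'
#' @param g An `edge_list` from [read_edge_list()].
#' @param k Number of hubs to return (default 10; fewer if the graph is
#'   smaller).
#' @return `data.frame` with columns `rank`, `node`, `degree`.
#' @export
top_hubs_by_degree <- function(g, k = 10L) {
  stopifnot(inherits(g, "edge_list"), k >= 1L)
  if (nrow(g$edges) == 0L) {
    return(data.frame(rank = integer(0), node = character(0),
                      degree = integer(0)))
  }
  gr <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$node_ids)
  deg <- igraph::degree(gr)
  ord <- order(-deg, names(deg))
  keep <- utils::head(ord, k)
  data.frame(rank = seq_along(keep), node = names(deg)[keep],
             degree = as.integer(deg[keep]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a hub ranking as TSV
#'
#' Emits `rank<TAB>node<TAB>degree`.
#'
#' @param hubs Output of [top_hubs_by_degree()].
#' @param path Output path.
#' @export
write_hub_ranking <- function(hubs, path) {
  utils::write.table(hubs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
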