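#' Queen-contiguity adjacency over block polygons
#'
#' Two blocks are adjacent when their boundaries come within \code{tolerance}
#' of touching: a shared boundary segment and a shared corner vertex both
#' qualify (queen contiguity). The snap tolerance absorbs minor boundary
#' misalignment in real cadastral/census files; with \code{tolerance = 0}
#' only exact contact counts.
#'
#' @param blocks a [block_set()].
#' @param tolerance snap distance in map units (default \code{1e-6});
#'   must be \eqn{\ge 0}.
#' @return An object of class \code{adjacency_graph} with elements
#'   \code{nodes} (block ids), \code{edges} (two-column character matrix of
#'   unordered pairs, each stored with the lexicographically smaller id
#'   first), \code{tolerance} and an internal igraph representation.
#' @examples
#' b <- grid_blocks(2, 2, 1)
#' g <- build_adjacency(b)
#' nrow(g$edges)  # complete graph on 4 blocks: corners touch
#' @export
build_adjacency <- function(blocks, tolerance = 1e-6) {
  stopifnot(inherits(blocks, "block_set"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop("tolerance must be a single number >= 0")
  }
  n <- length(blocks$ids)
  segs <- lapply(blocks$parts, geometry_segments)
  bb <- blocks$bboxes
  from <- character(0L); to <- character(0L)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        # bbox prefilter, expanded by the tolerance
        if (bb[i, "xmin"] > bb[j, "xmax"] + tolerance ||
            bb[j, "xmin"] > bb[i, "xmax"] + tolerance ||
            bb[i, "ymin"] > bb[j, "ymax"] + tolerance ||
            bb[j, "ymin"] > bb[i, "ymax"] + tolerance) next
        if (segset_min_dist(segs[[i]], segs[[j]]) <= tolerance) {
          from <- c(from, blocks$ids[[i]]); to <- c(to, blocks$ids[[j]])
        }
      }
    }
  }
  edges <- cbind(pmin(from, to), pmax(from, to))
  colnames(edges) <- c("block_a", "block_b")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L]),
    directed = FALSE,
    vertices = data.frame(name = blocks$ids)
  )
  structure(list(nodes = blocks$ids, edges = edges,
                 tolerance = tolerance, graph = g),
            class = "adjacency_graph")
}

#' Build an adjacency graph directly from an edge list
#'
#' Used when adjacency has been computed elsewhere (or read back from the
#' exported edge CSV). Self-loops are rejected; edges are symmetrized.
#'
#' @param nodes character vector of block ids.
#' @param edges two-column matrix or data.frame of block id pairs.
#' @return An \code{adjacency_graph}.
#' @export
adjacency_from_edges <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate block_id(s) in nodes")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  edges <- matrix(as.character(edges), ncol = 2L)
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown) > 0L) {
    stop("edge endpoint(s) not in nodes: ", paste(unknown, collapse = ", "))
  }
  edges <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                        pmax(edges[, 1L], edges[, 2L])))
  colnames(edges) <- c("block_a", "block_b")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L]),
    directed = FALSE, vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges, tolerance = NA_real_,
                 graph = g),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("adjacency_graph:", length(x$nodes), "blocks,",
      nrow(x$edges), "queen-contiguity edges")
  if (!is.na(x$tolerance)) cat(" (snap tolerance ", x$tolerance, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Neighbors of a block in the adjacency graph
#' @param graph an \code{adjacency_graph}.
#' @param block_id a node id.
#' @return Character vector of adjacent block ids (sorted).
#' @export
block_neighbors <- function(graph, block_id) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (!block_id %in% graph$nodes) stop("unknown block_id: ", block_id)
  sort(names(igraph::neighbors(graph$graph, block_id)))
}

#' Adjacency-community moving window around a focal block
#'
#' The order-0 window is the block itself; the order-1 window is the primary
#' adjacency community (PAC): the focal block plus all queen-contiguous
#' neighbors; the order-2 window is the secondary adjacency community (SAC):
#' the PAC plus all blocks adjacent to any PAC member. Equivalently, the
#' window of order \eqn{k} is the graph ball of radius \eqn{k} around the
#' focal block. Orders above 2 are rejected.
#'
#' @param graph an \code{adjacency_graph}.
#' @param focal a block id present in the graph.
#' @param order 0 (block), 1 (PAC) or 2 (SAC).
#' @return An object of class \code{community_window} with fields
#'   \code{focal}, \code{order} and \code{members} (sorted block ids,
#'   always including the focal block).
#' @export
community_window <- function(graph, focal, order) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(focal) != 1L || !focal %in% graph$nodes) {
    stop("unknown focal block_id: ", focal)
  }
  if (length(order) != 1L || !order %in% c(0L, 1L, 2L)) {
    stop("order must be 0 (block), 1 (PAC) or 2 (SAC); got ",
         deparse(order))
  }
  members <- sort(names(igraph::ego(graph$graph, order = order,
                                    nodes = focal)[[1L]]))
  structure(list(focal = focal, order = as.integer(order), members = members),
            class = "community_window")
}

#' @export
print.community_window <- function(x, ...) {
  lvl <- c("block", "PAC", "SAC")[x$order + 1L]
  cat(sprintf("%s window of %s: %d member block(s)\n",
              lvl, x$focal, length(x$members)))
  invisible(x)
}

#' All moving windows of one order
#'
#' One window per block; windows overlap (a moving-window construction, not
#' a partition).
#'
#' @param graph an \code{adjacency_graph}.
#' @param order 0, 1 (PAC) or 2 (SAC).
#' @return Named list of [community_window()] objects, one per block id.
#' @export
all_windows <- function(graph, order) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(order) != 1L || !order %in% c(0L, 1L, 2L)) {
    stop("order must be 0, 1 or 2; got ", deparse(order))
  }
  egos <- igraph::ego(graph$graph, order = order, nodes = graph$nodes)
  out <- lapply(seq_along(graph$nodes), function(i) {
    structure(list(focal = graph$nodes[[i]], order = as.integer(order),
                   members = sort(names(egos[[i]]))),
              class = "community_window")
  })
  names(out) <- graph$nodes
  out
}

#' Sidewalk segment record
#'
#' Sidewalks are audited as polylines with two binary conditions: broken or
#' unbroken, and obstructed or unobstructed. No index is derived from them;
#' the type exists so sidewalk audits can be stored and validated alongside
#' the other spatial datasets.
#'
#' @param segment_id identifier string.
#' @param polyline n x 2 numeric matrix of planar vertices, n >= 2.
#' @param broken,obstructed binary condition flags (0/1).
#' @return An object of class \code{sidewalk_segment}.
#' @export
sidewalk_segment <- function(segment_id, polyline, broken = 0L,
                             obstructed = 0L) {
  polyline <- as.matrix(polyline)
  if (!is.numeric(polyline) || ncol(polyline) != 2L || nrow(polyline) < 2L) {
    stop("polyline must be an n x 2 numeric matrix with at least 2 vertices")
  }
  if (!broken %in% c(0, 1) || !obstructed %in% c(0, 1)) {
    stop("broken and obstructed must be binary (0/1)")
  }
  structure(list(segment_id = as.character(segment_id), polyline = polyline,
                 broken = as.integer(broken),
                 obstructed = as.integer(obstructed)),
            class = "sidewalk_segment")
}

#' Export adjacency edges to CSV
#' @param graph an \code{adjacency_graph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_adjacency_csv <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  utils::write.csv(as.data.frame(graph$edges), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export windows to long CSV (focal, order, member)
#' @param windows result of [all_windows()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  rows <- do.call(rbind, lapply(windows, function(w) {
    data.frame(focal = w$focal, order = w$order, member = w$members,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
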