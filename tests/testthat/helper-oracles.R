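# Independent oracles used to cross-check the package's implementations.

# breadth-first-search ball of radius k over an edge list (hand-rolled,
# independent of the igraph-backed implementation)
bfs_ball <- function(nodes, edges, focal, k) {
  adj <- lapply(setNames(nodes, nodes), function(n) {
    c(edges[edges[, 1L] == n, 2L], edges[edges[, 2L] == n, 1L])
  })
  seen <- focal
  frontier <- focal
  if (k > 0) for (d in seq_len(k)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (length(nxt) == 0L) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# a randomized layout of axis-aligned rectangles on a grid of cells, each
# rectangle shrunk from its cell by per-side gaps that are either exactly 0
# (contact with the neighboring cell) or clearly larger than any snap
# tolerance; adjacency is then known in closed form from rectangle distance
rect_layout <- function(nx = 4, ny = 4, s = 10, seed = 1) {
  set.seed(seed)
  ids <- character(0L)
  rects <- matrix(numeric(0L), ncol = 4L)
  geoms <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    gap <- function() if (runif(1) < 0.5) 0 else runif(1, 0.5, 2)
    x1 <- (i - 1) * s + gap(); x2 <- i * s - gap()
    y1 <- (j - 1) * s + gap(); y2 <- j * s - gap()
    id <- sprintf("R%02d%02d", i, j)
    ids <- c(ids, id)
    rects <- rbind(rects, c(x1, y1, x2, y2))
    geoms[[id]] <- rbind(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2))
  }
  rownames(rects) <- ids
  list(ids = ids, rects = rects, blocks = block_set(geoms))
}

# closed-form minimum distance between two axis-aligned rectangles
# (x1, y1, x2, y2); zero when they touch or overlap
rect_dist <- function(a, b) {
  dx <- max(0, a[1L] - b[3L], b[1L] - a[3L])
  dy <- max(0, a[2L] - b[4L], b[2L] - a[4L])
  sqrt(dx^2 + dy^2)
}

# all-pairs adjacency oracle over a rect_layout, as a sorted edge matrix
rect_oracle_edges <- function(layout, tol = 1e-6) {
  ids <- layout$ids
  from <- character(0L); to <- character(0L)
  for (i in seq_len(length(ids) - 1L)) for (j in seq.int(i + 1L, length(ids))) {
    if (rect_dist(layout$rects[i, ], layout$rects[j, ]) <= tol) {
      from <- c(from, ids[i]); to <- c(to, ids[j])
    }
  }
  edge_key(cbind(pmin(from, to), pmax(from, to)))
}

edge_key <- function(edges) {
  if (nrow(edges) == 0L) return(character(0L))
  sort(paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L])))
}

# containment oracle for grid blocks: pure coordinate arithmetic, ties going
# to the lexicographically smallest block id (smallest column, then row)
grid_assign_oracle <- function(x, y, nx, ny, size) {
  wid <- max(2L, nchar(max(nx, ny)))
  vapply(seq_along(x), function(k) {
    # candidate columns/rows (two when exactly on an interior boundary)
    ci <- unique(pmax(1L, pmin(nx, c(floor(x[k] / size) + 1L,
                                     if (x[k] %% size == 0) x[k] / size))))
    rj <- unique(pmax(1L, pmin(ny, c(floor(y[k] / size) + 1L,
                                     if (y[k] %% size == 0) y[k] / size))))
    ok <- character(0L)
    for (i in ci) for (j in rj) {
      if (x[k] >= (i - 1L) * size && x[k] <= i * size &&
          y[k] >= (j - 1L) * size && y[k] <= j * size) {
        ok <- c(ok, sprintf("B%0*d%0*d", wid, i, wid, j))
      }
    }
    if (length(ok) == 0L) NA_character_ else min(ok)
  }, character(1L))
}

# one-way ANOVA mean squares via stats::aov (independent of the package's
# direct sum-of-squares arithmetic)
icc_aov_oracle <- function(m) {
  d <- data.frame(rating = as.vector(m),
                  target = factor(rep(seq_len(nrow(m)), ncol(m))))
  tab <- summary(stats::aov(rating ~ target, data = d))[[1L]]
  msb <- tab["target", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  list(single = (msb - msw) / (msb + (k - 1) * msw),
       average = (msb - msw) / msb)
}

# pairwise-agreement oracle by explicit enumeration over rater pairs
agreement_oracle <- function(m) {
  pairs <- utils::combn(ncol(m), 2L)
  mean(apply(m, 1L, function(row) {
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      row[pairs[1L, p]] == row[pairs[2L, p]]
    }, logical(1L)))
  }))
}

# a small valid parcel frame for index tests
tiny_parcels <- function(block_id, ...) {
  obs <- list(...)
  n <- length(block_id)
  df <- data.frame(parcel_id = sprintf("P%03d", seq_len(n)),
                   x = NA_real_, y = NA_real_, block_id = block_id,
                   occupancy = rep("occupied", n),
                   property_type = rep("residential", n),
                   stringsAsFactors = FALSE)
  for (v in names(obs)) df[[v]] <- obs[[v]]
  df
}
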