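test_that("queen contiguity joins blocks sharing an edge or only a corner", {
  b <- grid_blocks(2, 2, 1)
  g <- build_adjacency(b)
  # diagonal pairs share a corner, so the graph is complete on 4 nodes
  expect_equal(nrow(g$edges), 6L)
  expect_setequal(block_neighbors(g, "B0101"), setdiff(b$ids, "B0101"))

  apart <- block_set(list(
    A = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    B = rbind(c(2, 0), c(3, 0), c(3, 1), c(2, 1))))
  expect_equal(nrow(build_adjacency(apart, tolerance = 1e-6)$edges), 0L)
  # a tolerance wider than the gap snaps them together
  expect_equal(nrow(build_adjacency(apart, tolerance = 1.5)$edges), 1L)
})

test_that("adjacency equals the closed-form all-pairs oracle on random rectangle layouts", {
  for (seed in 1:25) {
    layout <- rect_layout(4, 4, 10, seed = seed)
    g <- build_adjacency(layout$blocks, tolerance = 1e-6)
    expect_identical(edge_key(g$edges), rect_oracle_edges(layout, tol = 1e-6),
                     info = paste("seed", seed))
  }
})

test_that("adjacency is invariant under translation and node relabeling", {
  layout <- rect_layout(3, 3, 10, seed = 42)
  g1 <- build_adjacency(layout$blocks)
  shifted <- lapply(seq_along(layout$ids), function(i) {
    r <- layout$rects[i, ]
    rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4])) +
      matrix(c(1234.5, -987.25), 4, 2, byrow = TRUE)
  })
  names(shifted) <- layout$ids
  g2 <- build_adjacency(block_set(shifted))
  expect_identical(edge_key(g1$edges), edge_key(g2$edges))

  relabeled <- shifted
  names(relabeled) <- paste0("Z", rev(layout$ids))
  g3 <- build_adjacency(block_set(relabeled))
  relabel <- setNames(paste0("Z", rev(layout$ids)), layout$ids)
  expect_identical(edge_key(g3$edges),
                   edge_key(cbind(relabel[g1$edges[, 1L]],
                                  relabel[g1$edges[, 2L]])))
})

test_that("invalid block input is rejected with the offending block named", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(block_set(list(A = sq, A = sq + 5)), "duplicate")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(block_set(list(OK = sq + 10, BAD = bowtie)), "BAD")
  degenerate <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_error(block_set(list(FLAT = degenerate)), "FLAT")
})

test_that("community windows are BFS balls, nested, and capped at order 2", {
  b <- grid_blocks(3, 3, 1)
  g <- build_adjacency(b)
  expect_equal(length(community_window(g, "B0202", 1)$members), 9L)
  expect_equal(community_window(g, "B0101", 0)$members, "B0101")

  b5 <- grid_blocks(5, 5, 1)
  g5 <- build_adjacency(b5)
  expect_equal(length(community_window(g5, "B0303", 2)$members), 25L)
  # corner windows on a 5x5 grid
  expect_equal(length(community_window(g5, "B0101", 1)$members), 4L)
  expect_equal(length(community_window(g5, "B0101", 2)$members), 9L)

  expect_error(community_window(g, "nope", 1), "unknown focal")
  expect_error(community_window(g, "B0101", 3), "order")
  expect_error(all_windows(g, -1), "order")

  # path graph A-B-C reaches everything within distance 2
  pg <- adjacency_from_edges(c("A", "B", "C"),
                             rbind(c("A", "B"), c("B", "C")))
  expect_equal(community_window(pg, "A", 2)$members, c("A", "B", "C"))
  expect_equal(community_window(pg, "A", 1)$members, c("A", "B"))
})

test_that("windows match the hand-rolled BFS oracle on random layouts", {
  for (seed in c(3, 11, 27)) {
    layout <- rect_layout(4, 4, 10, seed = seed)
    g <- build_adjacency(layout$blocks)
    for (k in 0:2) {
      w <- all_windows(g, k)
      for (id in layout$ids) {
        expect_equal(w[[id]]$members, bfs_ball(g$nodes, g$edges, id, k),
                     info = paste("seed", seed, "order", k, "focal", id))
      }
    }
  }
})

test_that("window families satisfy symmetry, nesting and the cumulative SAC identity", {
  layout <- rect_layout(4, 4, 10, seed = 99)
  g <- build_adjacency(layout$blocks)
  pac <- all_windows(g, 1)
  sac <- all_windows(g, 2)
  for (a in g$nodes) {
    expect_true(a %in% pac[[a]]$members)
    expect_true(all(pac[[a]]$members %in% sac[[a]]$members))
    # PAC membership is symmetric
    for (m in pac[[a]]$members) expect_true(a %in% pac[[m]]$members)
    # SAC = union of PACs over PAC members
    expect_setequal(sac[[a]]$members,
                    unique(unlist(lapply(pac[[a]]$members,
                                         function(m) pac[[m]]$members))))
  }
  # order 0 windows are singletons
  expect_true(all(vapply(all_windows(g, 0),
                         function(w) identical(w$members, w$focal), logical(1L))))
})

test_that("regular grids have the expected interior and corner window sizes", {
  for (n in c(5, 7)) {
    g <- build_adjacency(grid_blocks(n, n, 50))
    pac <- all_windows(g, 1); sac <- all_windows(g, 2)
    sizes1 <- vapply(pac, function(w) length(w$members), integer(1L))
    sizes2 <- vapply(sac, function(w) length(w$members), integer(1L))
    wid <- max(2L, nchar(n))
    interior <- sprintf("B%0*d%0*d", wid, 3L, wid, 3L)
    corner <- sprintf("B%0*d%0*d", wid, 1L, wid, 1L)
    expect_equal(sizes1[[interior]], 9L)
    expect_equal(sizes2[[interior]], 25L)
    expect_equal(sizes1[[corner]], 4L)
    expect_equal(sizes2[[corner]], 9L)
  }
})

test_that("blocks round-trip through GeoJSON and adjacency through the edge CSV", {
  b <- grid_blocks(3, 2, 10)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_blocks_geojson(b, path)
  back <- read_blocks_geojson(path)
  expect_equal(back$ids, b$ids)
  g1 <- build_adjacency(b); g2 <- build_adjacency(back)
  expect_identical(edge_key(g1$edges), edge_key(g2$edges))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_csv(g1, csv)
  g3 <- adjacency_from_edges(b$ids, utils::read.csv(csv))
  expect_identical(edge_key(g3$edges), edge_key(g1$edges))
})

test_that("sidewalk segments validate their polyline and binary conditions", {
  s <- sidewalk_segment("S1", rbind(c(0, 0), c(1, 0), c(2, 0.5)), broken = 1)
  expect_s3_class(s, "sidewalk_segment")
  expect_equal(s$broken, 1L)
  expect_error(sidewalk_segment("S2", rbind(c(0, 0))), "at least 2")
  expect_error(sidewalk_segment("S3", rbind(c(0, 0), c(1, 1)), broken = 2),
               "binary")
})
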