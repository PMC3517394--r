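test_that("block variable counts sum presences with zero rows for empty blocks", {
  reg <- default_registry()
  b <- grid_blocks(2, 1, 10)
  parcels <- tiny_parcels(rep("B0101", 3), litter = c(1, 1, 0),
                          roof_damage = c(0, 0, 1),
                          other_condition = c("", "cracked porch", ""))
  counts <- block_variable_counts(parcels, reg, b, "parcel")
  expect_equal(counts["B0101", "litter"], 2L)
  expect_equal(counts["B0101", "roof_damage"], 1L)
  # text variables count when non-empty
  expect_equal(counts["B0101", "other_condition"], 1L)
  # empty block: an all-zero row, not a missing one
  expect_true("B0201" %in% rownames(counts))
  expect_equal(sum(counts["B0201", ]), 0L)
  # conservation per variable
  expect_equal(sum(counts[, "litter"]), 2L)

  bad <- tiny_parcels("B0101", not_a_variable = 1)
  expect_error(block_variable_counts(bad, reg, b, "parcel"), "not in the registry")
  out_of_range <- tiny_parcels("B0101", litter = 2)
  expect_error(block_variable_counts(out_of_range, reg, b, "parcel"),
               "outside \\{0, 1\\}")
})

test_that("vacancy flags follow occupancy and vacant-lot type", {
  p <- data.frame(
    occupancy = c("occupied", "unoccupied", "demolished", "occupied"),
    property_type = c("residential", "commercial", "residential",
                      "unoccupied_lot"))
  expect_equal(vacancy_flags(p), c(0L, 1L, 1L, 1L))
  expect_error(vacancy_flags(transform(p, occupancy = "maybe")),
               "unknown occupancy")
})

test_that("domain indices equal a brute-force re-sum over raw records", {
  reg <- default_registry()
  b <- grid_blocks(2, 2, 10)
  set.seed(3)
  n <- 40
  vars <- c("boarded_door", "roof_damage", "litter", "garbage", "security_bars")
  parcels <- tiny_parcels(sample(b$ids, n, replace = TRUE))
  for (v in vars) parcels[[v]] <- rbinom(n, 1, 0.4)
  counts <- block_variable_counts(parcels, reg, b, "parcel")
  hd <- domain_index(counts, reg, "housing_damage")
  pd <- domain_index(counts, reg, "property_disorder")
  for (id in b$ids) {
    rows <- parcels[parcels$block_id == id, , drop = FALSE]
    expect_equal(unname(hd[id]), sum(rows$boarded_door, rows$roof_damage))
    expect_equal(unname(pd[id]), sum(rows$litter, rows$garbage))
  }
  expect_equal(sum(hd), sum(parcels$boarded_door, parcels$roof_damage))
  expect_error(domain_index(counts, reg, "crime"), "unrecognized domain")
})

test_that("window aggregation sums members and is the identity at order 0", {
  pg <- adjacency_from_edges(c("A", "B", "C"),
                             rbind(c("A", "B"), c("B", "C")))
  vals <- c(A = 1, B = 2, C = 3)
  pac <- aggregate_to_windows(vals, all_windows(pg, 1))
  expect_equal(pac[["B"]], 6)
  expect_equal(pac[["A"]], 3)
  expect_equal(aggregate_to_windows(vals, all_windows(pg, 0)), vals)

  g3 <- build_adjacency(grid_blocks(3, 3, 1))
  ones <- setNames(rep(1, 9), g3$nodes)
  expect_equal(aggregate_to_windows(ones, all_windows(g3, 1))[["B0202"]], 9)
  g5 <- build_adjacency(grid_blocks(5, 5, 1))
  ones25 <- setNames(rep(1, 25), g5$nodes)
  expect_equal(aggregate_to_windows(ones25, all_windows(g5, 2))[["B0303"]], 25)

  expect_error(aggregate_to_windows(vals[-1L], all_windows(pg, 1)),
               "missing from block values")
})

test_that("index table is monotone over window order and conserves raw totals", {
  reg <- default_registry()
  for (seed in c(2, 9)) {
    city <- suppressWarnings(generate_city(
      synth_config(grid_nx = 5, grid_ny = 5, seed = seed)))
    p <- suppressMessages(assign_parcels_to_blocks(city$parcels, city$blocks))
    nui <- suppressMessages(assign_parcels_to_blocks(city$nuisances, city$blocks))
    ten <- classify_tenure(p)
    cc <- aggregate_crime(city$crimes, city$blocks)
    g <- build_adjacency(city$blocks)
    idx <- build_index_table(p, nui, ten, cc, g, reg, city$blocks)

    wide <- list(block = index_wide(idx, "block"),
                 pac = index_wide(idx, "pac"),
                 sac = index_wide(idx, "sac"))
    for (ix in setdiff(names(wide$block), "block_id")) {
      expect_true(all(wide$block[[ix]] <= wide$pac[[ix]]),
                  info = paste(seed, ix))
      expect_true(all(wide$pac[[ix]] <= wide$sac[[ix]]),
                  info = paste(seed, ix))
    }
    # block-level conservation against raw inputs
    nuis_vars <- registry_variables(reg, "public_space")
    nuis_vars <- intersect(nuis_vars, names(nui))
    expect_equal(sum(wide$block$nuisances),
                 sum(sapply(nui[nuis_vars], function(v)
                   sum(suppressWarnings(as.numeric(v)) == 1, na.rm = TRUE))))
    expect_equal(sum(wide$block$vacancy), sum(vacancy_flags(p)))
    expect_equal(sum(wide$block$tenure),
                 sum(ten$call == "renter_occupied"))
    expect_equal(sum(wide$block$crime), sum(cc$total))
    hd_vars <- domain_variables(reg, "housing_damage")$name
    expect_equal(sum(wide$block$housing_damage),
                 sum(sapply(intersect(hd_vars, names(p)), function(v)
                   sum(p[[v]] == 1, na.rm = TRUE))))
  }
})

test_that("index correlations are symmetric with unit diagonal; degenerate indices flagged", {
  # hand-built long table: two indices exact negatives of each other
  blocks <- sprintf("b%d", 1:5)
  idx <- data.frame(
    block_id = rep(blocks, 3),
    level = "block",
    index = rep(c("housing_damage", "property_disorder", "vacancy"), each = 5),
    value = c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1, rep(2, 5)),
    n_parcels = 10, rate = NA_real_)
  class(idx) <- c("index_table", "data.frame")
  expect_warning(cm <- correlate_indices(idx, "block"), "zero-variance")
  expect_equal(cm["housing_damage", "property_disorder"], -1)
  expect_equal(cm["housing_damage", "housing_damage"], 1)
  expect_true(all(is.na(cm["vacancy", ])))
  expect_equal(attr(cm, "undefined"), "vacancy")
  expect_equal(cm, t(cm))
})

test_that("a planted shared factor makes property disorder and nuisances the top correlation", {
  cfg <- synth_config(grid_nx = 8, grid_ny = 8, seed = 31,
                      latent_factor_loadings = c(property_disorder = 1.2,
                                                 nuisance = 1.2),
                      nuisance_points_per_block = 8)
  city <- suppressWarnings(generate_city(cfg))
  p <- suppressMessages(assign_parcels_to_blocks(city$parcels, city$blocks))
  nui <- suppressMessages(assign_parcels_to_blocks(city$nuisances, city$blocks))
  g <- build_adjacency(city$blocks)
  idx <- build_index_table(p, nui, NULL, NULL, g, default_registry(),
                           city$blocks, levels = "block")
  cm <- suppressWarnings(correlate_indices(idx, "block"))
  off <- cm
  diag(off) <- NA
  top <- max(abs(off), na.rm = TRUE)
  expect_equal(abs(off["property_disorder", "nuisances"]), top)
  expect_gt(off["property_disorder", "nuisances"], 0.5)
})
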