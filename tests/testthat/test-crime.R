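test_that("offense classification is a pure, case-insensitive lookup", {
  m <- data.frame(label = c("BURGLARY", "ASSAULT"),
                  category = c("property", "violent"))
  expect_equal(classify_offense("Burglary", m), "property")
  expect_equal(classify_offense(c("assault", "BURGLARY "), m),
               c("violent", "property"))
  expect_warning(out <- classify_offense("JAYWALKING", m), "unclassified")
  expect_equal(out, "unclassified")
  expect_identical(classify_offense("Burglary", m),
                   classify_offense("Burglary", m))
  expect_true(all(classify_offense(default_offense_mapping()$label) !=
                    "unclassified"))
})

test_that("point-to-block assignment matches the containment oracle and tie-breaks deterministically", {
  b <- grid_blocks(3, 3, 10)
  # block centroids land in their own block
  cent_x <- rep((1:3) * 10 - 5, each = 3)
  cent_y <- rep((1:3) * 10 - 5, times = 3)
  expect_equal(assign_to_block(cent_x, cent_y, b), b$ids)
  # outside the union
  expect_true(is.na(assign_to_block(100, 100, b)))
  # shared boundary: lexicographically smallest containing id wins
  expect_equal(assign_to_block(10, 5, b), "B0101")   # B0101 | B0201 edge
  expect_equal(assign_to_block(10, 10, b), "B0101")  # four-corner point
  # 1000 random points (some outside) against the arithmetic oracle
  set.seed(21)
  x <- runif(1000, -5, 35); y <- runif(1000, -5, 35)
  expect_equal(assign_to_block(x, y, b), grid_assign_oracle(x, y, 3, 3, 10))
})

test_that("crime aggregation counts by category and conserves incidents", {
  b <- grid_blocks(2, 2, 10)
  none <- data.frame(incident_id = character(0L), x = numeric(0L),
                     y = numeric(0L), offense_label = character(0L))
  z <- aggregate_crime(none, b)
  expect_equal(z$total, rep(0L, 4L))
  expect_equal(nrow(attr(z, "unassigned")), 0L)

  inc <- data.frame(
    incident_id = sprintf("c%d", 1:6),
    x = c(rep(5, 5), 50), y = c(rep(5, 5), 50),
    offense_label = c(rep("ASSAULT", 3), rep("LARCENY", 2), "ARSON"))
  cc <- aggregate_crime(inc, b)
  row <- cc[cc$block_id == "B0101", ]
  expect_equal(row$violent, 3L)
  expect_equal(row$theft, 2L)
  expect_equal(row$total, 5L)
  expect_equal(nrow(attr(cc, "unassigned")), 1L)
  expect_equal(sum(cc$total) + nrow(attr(cc, "unassigned")), nrow(inc))
})

test_that("unclassified offenses still count toward the block total", {
  b <- grid_blocks(1, 1, 10)
  inc <- data.frame(incident_id = c("a", "b"), x = 5, y = 5,
                    offense_label = c("ASSAULT", "MYSTERY"))
  cc <- suppressWarnings(aggregate_crime(inc, b))
  expect_equal(cc$total, 2L)
  expect_equal(cc$unclassified, 1L)
  expect_gte(cc$total, max(cc$violent, cc$property, cc$vice, cc$theft,
                           cc$vehicular))
})

test_that("synthetic crime recovers planted block and category truth", {
  city <- suppressWarnings(generate_city(synth_config(grid_nx = 4, grid_ny = 4, seed = 12)))
  cc <- aggregate_crime(city$crimes, city$blocks)
  expect_equal(nrow(attr(cc, "unassigned")), 0L)
  expect_equal(sum(cc$total), nrow(city$crimes))
  truth_tab <- table(factor(city$truth$crime_block, levels = city$blocks$ids))
  expect_equal(cc$total, as.integer(truth_tab))
  cats <- classify_offense(city$crimes$offense_label)
  expect_equal(cats, unname(city$truth$crime_category[city$crimes$incident_id]))
})
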