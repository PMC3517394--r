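test_that("address normalization canonicalizes components and is idempotent", {
  a <- normalize_address("123 North Main Street")
  expect_equal(a$house_number, "123")
  expect_equal(a$directional, "N")
  expect_equal(a$street_name, "MAIN")
  expect_equal(a$street_type, "ST")

  b <- normalize_address("123 N. Main St, Apt 4B")
  expect_equal(b$unit, "4B")
  expect_equal(b$street_name, "MAIN")

  e <- normalize_address("")
  expect_equal(e$house_number, "")
  expect_length(e$street_name, 0L)
  expect_equal(format(e), "")

  set.seed(5)
  streets <- c("Oakmont", "Cedar Hill", "SOUTH", "Main", "42nd")
  types <- c("Street", "Ave.", "BOULEVARD", "trail", "")
  dirs <- c("North", "SW", "", "east")
  for (i in 1:40) {
    raw <- paste(sample(0:99999, 1), sample(dirs, 1), sample(streets, 1),
                 sample(types, 1))
    once <- normalize_address(raw)
    twice <- normalize_address(format(once))
    expect_equal(twice[setdiff(names(once), "raw")],
                 once[setdiff(names(once), "raw")], info = raw)
  }
})

test_that("match score is symmetric, reflexive, and capped on house-number mismatch", {
  a <- normalize_address("123 N Main St")
  expect_equal(match_score(a, a), 1)
  expect_equal(match_score(normalize_address("123 MAIN STREET"),
                           normalize_address("123 Main St")), 1)
  pobox <- normalize_address("PO BOX 442")
  expect_lte(match_score(normalize_address("123 MAIN ST"), pobox), 0.2)
  # same street, different house number: capped
  expect_lte(match_score(normalize_address("123 Main St"),
                         normalize_address("125 Main St")), 0.2)
  set.seed(11)
  corpus <- c("12 Oak St", "99 S Cedar Ave", "401 Main St Apt 2",
              "7 Willowbrook Ln", "7 Willowbrook Dr", "PO BOX 9")
  for (i in 1:30) {
    p <- sample(corpus, 2L)
    x <- normalize_address(p[1L]); y <- normalize_address(p[2L])
    s <- match_score(x, y)
    expect_equal(s, match_score(y, x))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("tenure classification follows the match threshold and conventions", {
  parcels <- data.frame(
    parcel_id = c("a", "b", "c", "d"),
    situs_address = c("12 Oak St", "12 Oak St", "12 Oak St", "12 Oak St"),
    owner_address = c("12 Oak St", "12 Oak Street", "900 Cedar Ave", NA),
    stringsAsFactors = FALSE)
  expect_warning(calls <- classify_tenure(parcels), "missing owner")
  expect_equal(calls$call, c("owner_occupied", "owner_occupied",
                             "renter_occupied", "renter_occupied"))
  expect_equal(calls$score[4L], 0)
  expect_true(all(calls$call[calls$score >= 0.85] == "owner_occupied"))

  strict <- suppressWarnings(classify_tenure(parcels, strict = TRUE))
  expect_equal(strict$call[4L], "unknown")

  missing_situs <- data.frame(parcel_id = "z", situs_address = NA,
                              owner_address = "1 A St")
  res <- classify_tenure(missing_situs)
  expect_equal(nrow(res), 0L)
  expect_match(attr(res, "errors"), "missing situs")
})

test_that("raising the threshold never converts a renter call to an owner call", {
  city <- suppressWarnings(generate_city(synth_config(grid_nx = 3, grid_ny = 3, seed = 4)))
  prev <- NULL
  for (thr in seq(0, 1, by = 0.1)) {
    calls <- classify_tenure(city$parcels, threshold = thr)
    owners <- calls$parcel_id[calls$call == "owner_occupied"]
    if (!is.null(prev)) expect_true(all(owners %in% prev))
    prev <- owners
  }
})

test_that("clean synthetic addresses recover the planted renter fraction exactly", {
  # 5x5 x 18 parcels: 450 parcels, so 30% is a whole number of renters
  city <- suppressWarnings(generate_city(synth_config(grid_nx = 5, grid_ny = 5, seed = 8)))
  calls <- classify_tenure(city$parcels)
  renters <- calls$parcel_id[calls$call == "renter_occupied"]
  expect_setequal(renters, city$truth$renter_ids)
  expect_equal(mean(calls$call == "renter_occupied"), 0.3)
  expect_equal(city$truth$renter_fraction, 0.3)
})
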