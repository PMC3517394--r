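# Seeded synthetic inputs with known ground truth: a square grid of block
# polygons, parcels with Bernoulli observations, public-space nuisance
# points, crime incidents, situs/owner address pairs, and rating matrices
# with a planted intraclass correlation.

#' Regular grid of square blocks
#'
#' @param nx,ny grid dimensions (blocks per row/column).
#' @param block_size side length in map units.
#' @param origin lower-left corner, length-2 numeric.
#' @return A [block_set()] with ids \code{B<col><row>} zero-padded so that
#'   lexicographic order equals grid order.
#' @export
grid_blocks <- function(nx, ny, block_size = 100, origin = c(0, 0)) {
  stopifnot(nx >= 1L, ny >= 1L, block_size > 0)
  wid <- max(2L, nchar(max(nx, ny)))
  geoms <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      x0 <- origin[1L] + (i - 1L) * block_size
      y0 <- origin[2L] + (j - 1L) * block_size
      ring <- rbind(c(x0, y0), c(x0 + block_size, y0),
                    c(x0 + block_size, y0 + block_size), c(x0, y0 + block_size))
      id <- sprintf("B%0*d%0*d", wid, i, wid, j)
      geoms[[id]] <- ring
    }
  }
  block_set(geoms)
}

# default per-variable Bernoulli prevalences, anchored to plausible
# parcel-audit frequencies (rare damage items, common driveways/greenery);
# variables not listed default to `default` in synth_config()
default_prevalence <- function() {
  c(boarded_windows = 0.135, peeling_paint = 0.209, driveway_present = 0.753,
    greenery = 0.635, litter = 0.307, high_weeds = 0.126,
    security_sign = 0.243, window_ac_unit = 0.136, roof_damage = 0.026,
    foundation_damage = 0.002, condemned = 0.002, eviction_notice = 0.002,
    garden = 0.027, for_sale_sign = 0.022, for_rent_sign = 0.018,
    graffiti_private = 0.0014, garbage = 0.15, fencing = 0.25,
    security_bars = 0.08, boarded_door = 0.02)
}

default_nuisance_prevalence <- function() {
  c(litter = 0.5, broken_glass = 0.25, food_garbage = 0.3,
    cigarette_butts = 0.25, high_weeds = 0.12, alcohol_container = 0.08,
    drug_paraphernalia = 0.002, graffiti_public = 0.001,
    discarded_appliances = 0.004, discarded_tires = 0.004, condoms = 0.005)
}

#' Synthetic-city configuration
#'
#' Defaults describe a compact audit-sized city: a 10 x 10 grid of
#' 100-map-unit blocks with 18 parcels per block (the per-block density of a
#' city-scale parcel audit), a 30\% renter fraction, modest per-block crime
#' intensities, and per-variable prevalences spanning rare damage items to
#' common amenities.
#'
#' @param grid_nx,grid_ny block grid dimensions.
#' @param block_size block side length in map units.
#' @param parcels_per_block single count or length-2 range.
#' @param prevalence named Bernoulli probabilities for parcel variables;
#'   unnamed variables use \code{prevalence_default}.
#' @param prevalence_default prevalence for variables not named.
#' @param nuisance_prevalence named probabilities for public-space variables.
#' @param nuisance_points_per_block Poisson mean of nuisance points per block.
#' @param renter_fraction fraction of parcels whose owner address differs
#'   from the situs address; the generated renter count is exact
#'   (\code{round(fraction * n)}).
#' @param vacancy_rate probability a parcel is unoccupied.
#' @param demolished_rate probability a parcel is demolished.
#' @param crime_rate named per-block Poisson means by category
#'   (violent/property/vice/theft/vehicular).
#' @param latent_factor_loadings named log-odds loadings per domain
#'   (\code{housing_damage}, \code{property_disorder}, \code{territoriality},
#'   \code{nuisance}, \code{miscellaneous}) on a shared per-block latent
#'   factor; nonzero loadings plant cross-index correlation.
#' @param seed integer seed; identical configs generate identical cities.
#' @return A validated list of class \code{synth_config}.
#' @export
synth_config <- function(grid_nx = 10L, grid_ny = 10L, block_size = 100,
                         parcels_per_block = 18L,
                         prevalence = default_prevalence(),
                         prevalence_default = 0.02,
                         nuisance_prevalence = default_nuisance_prevalence(),
                         nuisance_points_per_block = 5,
                         renter_fraction = 0.3,
                         vacancy_rate = 0.06,
                         demolished_rate = 0.005,
                         crime_rate = c(violent = 0.5, property = 1.0,
                                        vice = 0.3, theft = 0.8,
                                        vehicular = 0.4),
                         latent_factor_loadings = numeric(0L),
                         seed = 1L) {
  stopifnot(grid_nx >= 1L, grid_ny >= 1L, block_size > 0)
  if (!length(parcels_per_block) %in% c(1L, 2L) || any(parcels_per_block < 0)) {
    stop("parcels_per_block must be a count or a length-2 range")
  }
  probs <- c(prevalence, nuisance_prevalence, prevalence_default,
             renter_fraction, vacancy_rate, demolished_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(crime_rate < 0)) stop("crime rates must be nonnegative")
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 block_size = block_size,
                 parcels_per_block = parcels_per_block,
                 prevalence = prevalence,
                 prevalence_default = prevalence_default,
                 nuisance_prevalence = nuisance_prevalence,
                 nuisance_points_per_block = nuisance_points_per_block,
                 renter_fraction = renter_fraction,
                 vacancy_rate = vacancy_rate,
                 demolished_rate = demolished_rate,
                 crime_rate = crime_rate,
                 latent_factor_loadings = latent_factor_loadings,
                 seed = as.integer(seed)),
            class = "synth_config")
}

street_corpus <- function() {
  path <- system.file("extdata", "street_names.txt", package = "pacsac",
                      mustWork = TRUE)
  readLines(path)
}

prob_with_loading <- function(p, loading, z) {
  if (loading == 0) return(rep(p, length(z)))
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  stats::plogis(stats::qlogis(p) + loading * z)
}

#' Generate a synthetic city with known ground truth
#'
#' Produces grid block polygons, parcels strictly interior to their blocks
#' with Bernoulli-drawn observations (optionally modulated by a per-block
#' latent factor to plant cross-index correlations), situs/owner address
#' pairs with an exact planted renter count, public-space nuisance points,
#' and per-block Poisson crime incidents. The \code{truth} element records
#' every planted quantity. The same config (including seed) always yields
#' identical output.
#'
#' @param config a [synth_config()].
#' @param registry registry defining the observation schema
#'   (default [default_registry()]).
#' @return List with elements \code{blocks} ([block_set()]), \code{parcels},
#'   \code{nuisances}, \code{crimes} (data.frames) and \code{truth} (list).
#' @export
generate_city <- function(config = synth_config(),
                          registry = default_registry()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nx <- config$grid_nx; ny <- config$grid_ny; size <- config$block_size
  blocks <- grid_blocks(nx, ny, size)
  ids <- blocks$ids
  nb <- length(ids)
  z <- stats::rnorm(nb)  # per-block latent factor
  names(z) <- ids
  loadings <- config$latent_factor_loadings
  loading_for <- function(domain) {
    if (domain %in% names(loadings)) loadings[[domain]] else 0
  }

  block_origin <- function(id) {
    i <- match(id, ids) - 1L
    c((i %/% ny) * size, (i %% ny) * size)
  }

  # parcels -----------------------------------------------------------------
  n_per <- if (length(config$parcels_per_block) == 2L) {
    sample(seq.int(config$parcels_per_block[1L], config$parcels_per_block[2L]),
           nb, replace = TRUE)
  } else rep(as.integer(config$parcels_per_block), nb)
  n_parcels <- sum(n_per)
  parcel_block <- rep(ids, n_per)
  origins <- t(vapply(parcel_block, block_origin, numeric(2L)))
  px <- origins[, 1L] + stats::runif(n_parcels, 0.02, 0.98) * size
  py <- origins[, 2L] + stats::runif(n_parcels, 0.02, 0.98) * size

  parcels <- data.frame(
    parcel_id = sprintf("P%06d", seq_len(n_parcels)),
    x = px, y = py, stringsAsFactors = FALSE)

  ptype <- sample(c("residential", "commercial", "religious", "community",
                    "unoccupied_lot", "other"), n_parcels, replace = TRUE,
                  prob = c(0.85, 0.04, 0.01, 0.015, 0.035, 0.05))
  subtype <- rep("", n_parcels)
  res <- ptype == "residential"
  subtype[res] <- sample(c("single_family", "apartment",
                           "senior_care_duplex_other"),
                         sum(res), replace = TRUE, prob = c(0.83, 0.04, 0.13))
  occ <- sample(c("occupied", "unoccupied", "demolished"), n_parcels,
                replace = TRUE,
                prob = c(1 - config$vacancy_rate - config$demolished_rate,
                         config$vacancy_rate, config$demolished_rate))
  occ[ptype == "unoccupied_lot"] <- "unoccupied"
  parcels$property_type <- ptype
  parcels$property_subtype <- subtype
  parcels$occupancy <- occ

  # addresses: exact planted renter count, renters get unrelated addresses
  streets <- street_corpus()
  types <- c("ST", "AVE", "RD", "DR", "LN", "CT")
  block_street <- paste(sample(streets, nb, replace = TRUE),
                        sample(types, nb, replace = TRUE))
  names(block_street) <- ids
  situs <- sprintf("%d %s", sample(100:9999, n_parcels, replace = TRUE),
                   block_street[parcel_block])
  n_renters <- round(config$renter_fraction * n_parcels)
  renter_idx <- sample.int(n_parcels, n_renters)
  owner <- situs
  if (n_renters > 0L) {
    other_street <- vapply(renter_idx, function(i) {
      home <- sub(" .*$", "", block_street[[parcel_block[i]]])
      s <- sample(streets, 1L)
      while (s == home) s <- sample(streets, 1L)
      sprintf("%d %s %s", sample(100:9999, 1L), s, sample(types, 1L))
    }, character(1L))
    owner[renter_idx] <- other_street
  }
  parcels$situs_address <- situs
  parcels$owner_address <- owner

  # observations per registry parcel variable
  preg <- registry[registry$applicability == "parcel", , drop = FALSE]
  zb <- z[parcel_block]
  for (r in seq_len(nrow(preg))) {
    v <- preg$name[r]; kind <- preg$value_kind[r]
    if (kind == "binary") {
      if (v %in% c("occupied", "unoccupied", "demolished")) {
        parcels[[v]] <- as.integer(occ == v)
      } else {
        p <- if (v %in% names(config$prevalence)) config$prevalence[[v]]
             else config$prevalence_default
        pv <- prob_with_loading(p, loading_for(preg$domain[r]), zb)
        parcels[[v]] <- stats::rbinom(n_parcels, 1L, pv)
      }
    } else if (kind == "text") {
      parcels[[v]] <- ""
    }
    # categorical registry variables are carried by the typed columns above
  }

  # nuisance points ----------------------------------------------------------
  n_nuis <- stats::rpois(nb, config$nuisance_points_per_block)
  nuis_block <- rep(ids, n_nuis)
  n_nuis_tot <- length(nuis_block)
  norg <- if (n_nuis_tot > 0L) t(vapply(nuis_block, block_origin, numeric(2L)))
          else matrix(numeric(0L), ncol = 2L)
  nuisances <- data.frame(
    nuisance_id = if (n_nuis_tot > 0L) sprintf("N%06d", seq_len(n_nuis_tot))
                  else character(0L),
    x = norg[, 1L] + stats::runif(n_nuis_tot, 0.02, 0.98) * size,
    y = norg[, 2L] + stats::runif(n_nuis_tot, 0.02, 0.98) * size,
    stringsAsFactors = FALSE)
  nreg <- registry[registry$applicability == "public_space", , drop = FALSE]
  zn <- z[nuis_block]
  for (r in seq_len(nrow(nreg))) {
    v <- nreg$name[r]
    if (nreg$value_kind[r] == "binary") {
      p <- if (v %in% names(config$nuisance_prevalence))
        config$nuisance_prevalence[[v]] else config$prevalence_default
      pv <- prob_with_loading(p, loading_for("nuisance"), zn)
      nuisances[[v]] <- stats::rbinom(n_nuis_tot, 1L, pv)
    } else {
      nuisances[[v]] <- rep("", n_nuis_tot)
    }
  }

  # crime incidents ----------------------------------------------------------
  mapping <- default_offense_mapping()
  crime_rows <- list()
  for (cat_ in names(config$crime_rate)) {
    counts <- stats::rpois(nb, config$crime_rate[[cat_]])
    cb <- rep(ids, counts)
    if (length(cb) == 0L) next
    corg <- t(vapply(cb, block_origin, numeric(2L)))
    labels <- sample(mapping$label[mapping$category == cat_],
                     length(cb), replace = TRUE)
    crime_rows[[cat_]] <- data.frame(
      block_truth = cb,
      x = corg[, 1L] + stats::runif(length(cb), 0.02, 0.98) * size,
      y = corg[, 2L] + stats::runif(length(cb), 0.02, 0.98) * size,
      offense_label = labels, category_truth = cat_,
      stringsAsFactors = FALSE)
  }
  crimes <- if (length(crime_rows) > 0L) do.call(rbind, crime_rows)
            else data.frame(block_truth = character(0L), x = numeric(0L),
                            y = numeric(0L), offense_label = character(0L),
                            category_truth = character(0L))
  rownames(crimes) <- NULL
  if (nrow(crimes) > 0L) {
    ord <- sample.int(nrow(crimes))  # shuffle so input order carries no signal
    crimes <- crimes[ord, , drop = FALSE]
    rownames(crimes) <- NULL
  }
  crimes <- cbind(incident_id = sprintf("C%06d", seq_len(max(nrow(crimes), 0L))),
                  crimes, stringsAsFactors = FALSE)

  truth <- list(
    config = config,
    block_ids = ids,
    latent = z,
    parcel_block = stats::setNames(parcel_block, parcels$parcel_id),
    renter_ids = parcels$parcel_id[sort(renter_idx)],
    renter_fraction = n_renters / n_parcels,
    n_parcels = n_parcels,
    vacancy_truth = stats::setNames(vacancy_flags(parcels), parcels$parcel_id),
    crime_block = if (nrow(crimes) > 0L)
      stats::setNames(crimes$block_truth, crimes$incident_id) else character(0L),
    crime_category = if (nrow(crimes) > 0L)
      stats::setNames(crimes$category_truth, crimes$incident_id) else character(0L)
  )
  list(blocks = blocks, parcels = parcels, nuisances = nuisances,
       crimes = crimes[, c("incident_id", "x", "y", "offense_label"),
                       drop = FALSE],
       truth = truth)
}

#' Generate a rating matrix with a planted intraclass correlation
#'
#' Continuous scores are a target effect with variance \code{planted_icc}
#' plus rater noise with variance \code{1 - planted_icc}, so the population
#' one-way single-rater ICC equals \code{planted_icc}. Optional thresholding
#' to binary attenuates the ICC (recorded in the truth).
#'
#' @param n targets (rows); \code{k} raters (columns).
#' @param k number of raters.
#' @param planted_icc true single-rater ICC in \eqn{[0, 1)}.
#' @param seed integer seed.
#' @param binary threshold scores at 0 to produce 0/1 ratings.
#' @return List with \code{ratings} (n x k matrix) and \code{truth}.
#' @export
generate_ratings <- function(n, k, planted_icc, seed = 1L, binary = FALSE) {
  stopifnot(n >= 2L, k >= 2L)
  if (planted_icc < 0 || planted_icc >= 1) stop("planted_icc must be in [0, 1)")
  set.seed(seed)
  target <- stats::rnorm(n, sd = sqrt(planted_icc))
  eps <- matrix(stats::rnorm(n * k, sd = sqrt(1 - planted_icc)), n, k)
  m <- target + eps
  if (binary) m <- (m > 0) + 0L
  list(ratings = m,
       truth = list(planted_icc = planted_icc, n = n, k = k, binary = binary,
                    seed = seed))
}

#' Write a synthetic city to disk in the pipeline's input formats
#'
#' @param city result of [generate_city()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_city <- function(city, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(blocks = file.path(dir, "blocks.geojson"),
             parcels = file.path(dir, "parcels.csv"),
             nuisances = file.path(dir, "nuisances.csv"),
             crimes = file.path(dir, "crimes.csv"))
  write_blocks_geojson(city$blocks, paths[["blocks"]])
  utils::write.csv(city$parcels, paths[["parcels"]], row.names = FALSE)
  utils::write.csv(city$nuisances, paths[["nuisances"]], row.names = FALSE)
  utils::write.csv(city$crimes, paths[["crimes"]], row.names = FALSE)
  invisible(paths)
}
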