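# One-shot end-to-end pipeline: read inputs, assign points to blocks, build
# adjacency and windows, classify tenure, aggregate crime, build the index
# table and correlation matrices, and write every stage as plain CSV plus a
# manifest. All outputs are deterministic given fixed inputs and config.

pipeline_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Pipeline run configuration
#'
#' @param blocks path to a GeoJSON FeatureCollection of block polygons.
#' @param parcels path to a parcel CSV (\code{parcel_id}, \code{x},
#'   \code{y}, \code{situs_address}, \code{owner_address},
#'   \code{occupancy}, \code{property_type}, observation columns).
#' @param nuisances optional path to a public-space point CSV.
#' @param crimes optional path to a crime incident CSV
#'   (\code{incident_id}, \code{x}, \code{y}, \code{offense_label}).
#' @param registry \code{"default"} or a path to a registry config CSV.
#' @param offense_mapping \code{"default"} or a path to a mapping CSV.
#' @param id_property GeoJSON property holding the block id.
#' @param tolerance queen-contiguity snap tolerance (map units).
#' @param tenure_threshold owner-occupancy score threshold.
#' @param levels aggregation levels to compute.
#' @param correlation_method \code{"pearson"} or \code{"spearman"}.
#' @param out_dir output directory.
#' @return A \code{run_config} list.
#' @export
run_config <- function(blocks, parcels, nuisances = NULL, crimes = NULL,
                       registry = "default", offense_mapping = "default",
                       id_property = "GEOID", tolerance = 1e-6,
                       tenure_threshold = 0.85,
                       levels = c("block", "pac", "sac"),
                       correlation_method = "pearson", out_dir = ".") {
  levels <- match.arg(levels, several.ok = TRUE)
  structure(list(blocks = blocks, parcels = parcels, nuisances = nuisances,
                 crimes = crimes, registry = registry,
                 offense_mapping = offense_mapping,
                 id_property = id_property, tolerance = tolerance,
                 tenure_threshold = tenure_threshold, levels = levels,
                 correlation_method = correlation_method, out_dir = out_dir),
            class = "run_config")
}

#' Run the full assessment pipeline
#'
#' Executes assign, counts, adjacency, windows, indices and correlations and
#' writes each stage to \code{out_dir} as CSV, plus a \code{manifest.json}
#' listing the written files, a hash of the configuration and the package
#' version. Stage-count messages mirror a field-accounting style (records
#' read, excluded, assigned). Nothing is written until every stage has
#' validated, so a schema error leaves no partial index files. Errors carry
#' condition classes \code{pacsac_missing_input} and
#' \code{pacsac_schema_error} so callers (and the command-line wrapper) can
#' map them to exit codes.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  for (p in c(config$blocks, config$parcels, config$nuisances, config$crimes)) {
    if (!file.exists(p)) pipeline_error(paste0("missing input: ", p),
                                        "pacsac_missing_input")
  }
  as_schema_error <- function(expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "pacsac_missing_input")) stop(e)
      pipeline_error(conditionMessage(e), "pacsac_schema_error")
    })
  }

  registry <- as_schema_error(
    if (identical(config$registry, "default")) default_registry()
    else load_registry(config$registry))
  mapping <- as_schema_error(
    if (identical(config$offense_mapping, "default")) default_offense_mapping()
    else load_offense_mapping(config$offense_mapping))
  blocks <- as_schema_error(
    read_blocks_geojson(config$blocks, id_property = config$id_property))
  say(length(blocks$ids), " blocks read")

  parcels <- as_schema_error(
    utils::read.csv(config$parcels, stringsAsFactors = FALSE))
  say(nrow(parcels), " parcels read")
  parcels <- as_schema_error(
    suppressMessages(assign_parcels_to_blocks(parcels, blocks)))
  say(sum(!is.na(parcels$block_id)), " parcels assigned to blocks, ",
      sum(is.na(parcels$block_id)), " unassigned")

  nuisances <- NULL
  if (!is.null(config$nuisances)) {
    nuisances <- as_schema_error(
      utils::read.csv(config$nuisances, stringsAsFactors = FALSE))
    nuisances <- as_schema_error(
      suppressMessages(assign_parcels_to_blocks(nuisances, blocks)))
    say(nrow(nuisances), " nuisance points read (",
        sum(is.na(nuisances$block_id)), " unassigned)")
  }

  tenure <- as_schema_error(suppressWarnings(
    classify_tenure(parcels, threshold = config$tenure_threshold)))
  say(sum(tenure$call == "renter_occupied"), " of ", nrow(tenure),
      " parcels called renter-occupied")

  crime_counts <- NULL
  if (!is.null(config$crimes)) {
    crimes <- as_schema_error(
      utils::read.csv(config$crimes, stringsAsFactors = FALSE))
    crime_counts <- as_schema_error(
      suppressWarnings(aggregate_crime(crimes, blocks, mapping)))
    say(nrow(crimes), " crime incidents read (",
        nrow(attr(crime_counts, "unassigned")), " unassigned)")
  }

  graph <- as_schema_error(build_adjacency(blocks, tolerance = config$tolerance))
  say(nrow(graph$edges), " adjacency edges")
  idx <- as_schema_error(build_index_table(
    parcels, nuisances, tenure, crime_counts, graph, registry, blocks,
    levels = config$levels))
  cors <- lapply(stats::setNames(config$levels, config$levels), function(lev) {
    suppressWarnings(correlate_indices(idx, level = lev,
                                       method = config$correlation_method))
  })

  # all stages validated; write outputs
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  files <- character(0L)
  wr <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  wr(as.data.frame(graph$edges), "adjacency_edges.csv")
  for (lev in setdiff(config$levels, "block")) {
    w <- all_windows(graph, c(block = 0L, pac = 1L, sac = 2L)[[lev]])
    write_windows_csv(w, file.path(out, paste0("windows_", lev, ".csv")))
    files <- c(files, file.path(out, paste0("windows_", lev, ".csv")))
  }
  wr(tenure, "tenure_calls.csv")
  if (!is.null(crime_counts)) wr(crime_counts, "crime_block_counts.csv")
  wr(as.data.frame(idx), "indices_long.csv")
  for (lev in config$levels) {
    wr(index_wide(idx, lev), paste0("indices_wide_", lev, ".csv"))
    cm <- cors[[lev]]
    wr(data.frame(index = rownames(cm), as.data.frame(cm)),
       paste0("correlations_", lev, ".csv"))
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  cfg_file <- file.path(out, "run_config.json")
  writeLines(cfg_json, cfg_file)
  files <- c(files, cfg_file)
  manifest <- list(
    files = basename(files),
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("pacsac")))
  manifest_file <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE)
  say("wrote ", length(files) + 1L, " files to ", out)
  invisible(manifest)
}
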