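INDEX_NAMES <- c("nuisances", "housing_damage", "property_disorder",
                 "territoriality", "vacancy", "tenure", "crime")

COUNT_DOMAINS <- c("housing_damage", "property_disorder", "territoriality")

#' Assign parcels (or nuisance points) to blocks
#'
#' Point-in-polygon assignment of record centroids to block polygons, with
#' the same deterministic boundary tie-break as [assign_to_block()]
#' (lexicographically smallest containing block id). Records outside every
#' block get \code{NA} and are reported in the \code{unassigned} attribute.
#'
#' @param records data.frame with \code{x}, \code{y} coordinate columns.
#' @param blocks a [block_set()].
#' @return \code{records} with a \code{block_id} column set.
#' @export
assign_parcels_to_blocks <- function(records, blocks) {
  stopifnot(inherits(blocks, "block_set"))
  if (!all(c("x", "y") %in% names(records))) {
    stop("records need x and y coordinate columns")
  }
  records$block_id <- assign_to_block(records$x, records$y, blocks)
  n_un <- sum(is.na(records$block_id))
  if (n_un > 0L) {
    message(n_un, " record(s) fall outside all blocks (block_id = NA)")
  }
  attr(records, "unassigned") <- which(is.na(records$block_id))
  records
}

# presence of an observation given its registry value kind: binary 1,
# or non-empty text for free-text "other" variables
observation_presence <- function(values, value_kind) {
  if (value_kind == "binary") {
    v <- suppressWarnings(as.numeric(values))
    bad <- !is.na(v) & !v %in% c(0, 1)
    if (any(bad)) stop("binary observation with value outside {0, 1}")
    !is.na(v) & v == 1
  } else if (value_kind == "text") {
    !is.na(values) & nzchar(trimws(as.character(values)))
  } else {
    rep(FALSE, length(values))  # categorical variables carry no presence count
  }
}

#' Per-block counts of each observed variable
#'
#' Sums presences (binary value 1, or non-empty text for the free-text
#' "other" variables) of every registry variable over the records assigned
#' to each block. Blocks with no records get an all-zero row, never a
#' missing one. Observation columns not present in the registry (for the
#' given applicability) are a validation error; unobserved variables simply
#' count zero, matching a default-absent recording convention.
#'
#' @param records block-assigned data.frame of parcels (or nuisance points)
#'   whose observation columns are named after registry variables.
#' @param registry a [be_registry()].
#' @param blocks a [block_set()] (defines the full set of block rows).
#' @param applicability \code{"parcel"} or \code{"public_space"}: which side
#'   of the registry the records' observations belong to.
#' @return matrix of counts, rows = block ids, columns = registry variables
#'   of that applicability.
#' @export
block_variable_counts <- function(records, registry, blocks,
                                  applicability = c("parcel", "public_space")) {
  stopifnot(inherits(registry, "be_registry"), inherits(blocks, "block_set"))
  applicability <- match.arg(applicability)
  if (!"block_id" %in% names(records)) {
    stop("records must be block-assigned first (see assign_parcels_to_blocks)")
  }
  reg <- registry[registry$applicability == applicability, , drop = FALSE]
  vars <- reg$name
  id_cols <- c("parcel_id", "nuisance_id", "record_id", "x", "y", "block_id",
               "situs_address", "owner_address", "occupancy",
               "property_type", "property_subtype")
  obs_cols <- setdiff(names(records), id_cols)
  unknown <- setdiff(obs_cols, vars)
  if (length(unknown) > 0L) {
    stop("observation column(s) not in the registry (", applicability, "): ",
         paste(unknown, collapse = ", "))
  }
  counts <- matrix(0L, nrow = length(blocks$ids), ncol = length(vars),
                   dimnames = list(blocks$ids, vars))
  assigned <- !is.na(records$block_id)
  if (!any(assigned)) return(counts)
  fac <- factor(records$block_id[assigned], levels = blocks$ids)
  for (j in seq_along(vars)) {
    v <- vars[[j]]
    if (!v %in% names(records)) next
    pres <- observation_presence(records[[v]][assigned], reg$value_kind[[j]])
    counts[, j] <- as.integer(tapply(pres, fac, sum, default = 0L))
  }
  counts
}

#' Vacancy flag per parcel
#'
#' A parcel counts toward the vacancy index when it is unoccupied or
#' demolished, or when it is a vacant (unoccupied) lot by property type —
#' unoccupied residential, commercial, religious and community properties
#' all qualify through the occupancy field.
#'
#' @param parcels data.frame with \code{occupancy} (occupied/unoccupied/
#'   demolished) and \code{property_type} columns.
#' @return Integer vector of 0/1 flags.
#' @export
vacancy_flags <- function(parcels) {
  if (!all(c("occupancy", "property_type") %in% names(parcels))) {
    stop("parcels need occupancy and property_type columns")
  }
  occ <- as.character(parcels$occupancy)
  bad <- !occ %in% c("occupied", "unoccupied", "demolished")
  if (any(bad)) stop("unknown occupancy value(s): ",
                     paste(unique(occ[bad]), collapse = ", "))
  as.integer(occ %in% c("unoccupied", "demolished") |
               parcels$property_type == "unoccupied_lot")
}

#' Per-block index for one built-environment domain
#'
#' Sums the block-level variable counts over the variables assigned to the
#' domain in the registry.
#'
#' @param block_counts matrix from [block_variable_counts()].
#' @param registry a [be_registry()].
#' @param domain one of the registry domains.
#' @return Named numeric vector of per-block counts.
#' @export
domain_index <- function(block_counts, registry, domain) {
  vars <- domain_variables(registry, domain)$name
  vars <- intersect(vars, colnames(block_counts))
  if (length(vars) == 0L) {
    return(stats::setNames(rep(0, nrow(block_counts)), rownames(block_counts)))
  }
  rowSums(block_counts[, vars, drop = FALSE])
}

#' Aggregate per-block values over moving windows
#'
#' The window value for a focal block is the sum of the block-level values
#' over the window's member blocks; order-0 windows reproduce the block
#' values exactly.
#'
#' @param block_values named numeric vector (names = block ids).
#' @param windows result of [all_windows()].
#' @return Named numeric vector keyed by focal block id.
#' @export
aggregate_to_windows <- function(block_values, windows) {
  vals <- vapply(windows, function(w) {
    missing_m <- setdiff(w$members, names(block_values))
    if (length(missing_m) > 0L) {
      stop("window member(s) missing from block values: ",
           paste(missing_m, collapse = ", "))
    }
    sum(block_values[w$members])
  }, numeric(1L))
  names(vals) <- vapply(windows, function(w) w$focal, character(1L))
  vals
}

#' Build the block/PAC/SAC index table
#'
#' Computes the seven neighborhood indices per block — nuisances, housing
#' damage, property disorder, territoriality (variable-presence counts),
#' vacancy (vacant-parcel count), tenure (renter-occupied count) and crime
#' (total incident count) — and aggregates each to the requested
#' moving-window levels by summation. Count indices grow mechanically with
#' window size, so per-parcel rates are emitted alongside (value divided by
#' the number of assessed parcels in the window; missing, never 0, where a
#' window contains no parcels).
#'
#' @param parcels block-assigned parcel data.frame (observation columns
#'   named after registry parcel variables, plus \code{occupancy} and
#'   \code{property_type}).
#' @param nuisances block-assigned public-space point data.frame
#'   (observation columns named after registry nuisance variables); may be
#'   \code{NULL}.
#' @param tenure_calls result of [classify_tenure()]; may be \code{NULL}.
#' @param crime_counts result of [aggregate_crime()]; may be \code{NULL}.
#' @param graph an [build_adjacency()] graph over the same blocks.
#' @param registry a [be_registry()].
#' @param blocks a [block_set()].
#' @param levels subset of \code{c("block", "pac", "sac")}.
#' @return An object of class \code{index_table}: long data.frame with
#'   columns \code{block_id}, \code{level}, \code{index}, \code{value},
#'   \code{n_parcels} (parcels in the window) and \code{rate}
#'   (\code{value / n_parcels}).
#' @export
build_index_table <- function(parcels, nuisances = NULL, tenure_calls = NULL,
                              crime_counts = NULL, graph, registry, blocks,
                              levels = c("block", "pac", "sac")) {
  stopifnot(inherits(graph, "adjacency_graph"), inherits(blocks, "block_set"))
  levels <- match.arg(levels, several.ok = TRUE)
  ids <- blocks$ids
  zero <- stats::setNames(rep(0, length(ids)), ids)

  pc <- block_variable_counts(parcels, registry, blocks, "parcel")

  block_vals <- list()
  for (d in COUNT_DOMAINS) block_vals[[d]] <- domain_index(pc, registry, d)

  block_vals$nuisances <- if (is.null(nuisances)) zero else {
    nc <- block_variable_counts(nuisances, registry, blocks, "public_space")
    domain_index(nc, registry, "nuisance")
  }

  vflag <- vacancy_flags(parcels)
  assigned <- !is.na(parcels$block_id)
  block_vals$vacancy <- as.numeric(table(
    factor(parcels$block_id[assigned & vflag == 1L], levels = ids)))
  names(block_vals$vacancy) <- ids

  block_vals$tenure <- if (is.null(tenure_calls)) zero else {
    renter_ids <- tenure_calls$parcel_id[tenure_calls$call == "renter_occupied"]
    is_renter <- as.character(parcels$parcel_id) %in% renter_ids
    stats::setNames(as.numeric(table(
      factor(parcels$block_id[assigned & is_renter], levels = ids))), ids)
  }

  block_vals$crime <- if (is.null(crime_counts)) zero else {
    stats::setNames(crime_counts$total[match(ids, crime_counts$block_id)], ids)
  }

  n_parcels_block <- stats::setNames(
    as.numeric(table(factor(parcels$block_id[assigned], levels = ids))), ids)

  order_of <- c(block = 0L, pac = 1L, sac = 2L)
  rows <- list()
  for (lev in levels) {
    w <- all_windows(graph, order_of[[lev]])
    n_parcels <- aggregate_to_windows(n_parcels_block, w)
    for (ix in INDEX_NAMES) {
      val <- aggregate_to_windows(block_vals[[ix]], w)
      rows[[length(rows) + 1L]] <- data.frame(
        block_id = names(val), level = lev, index = ix,
        value = as.numeric(val), n_parcels = as.numeric(n_parcels[names(val)]),
        rate = ifelse(n_parcels[names(val)] > 0,
                      as.numeric(val) / as.numeric(n_parcels[names(val)]),
                      NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_table", "data.frame")
  out
}

#' @export
print.index_table <- function(x, ...) {
  cat("index_table:", length(unique(x$block_id)), "blocks x",
      length(unique(x$index)), "indices at level(s):",
      paste(unique(x$level), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Wide per-level view of an index table
#' @param index_table an [build_index_table()] result.
#' @param level one of \code{"block"}, \code{"pac"}, \code{"sac"}.
#' @param what \code{"value"} (counts) or \code{"rate"} (per-parcel rates).
#' @return data.frame with one row per block and one column per index.
#' @export
index_wide <- function(index_table, level = "block", what = c("value", "rate")) {
  what <- match.arg(what)
  sub <- index_table[index_table$level == level, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows at level '", level, "'")
  ids <- unique(sub$block_id)
  out <- data.frame(block_id = ids, stringsAsFactors = FALSE)
  for (ix in unique(sub$index)) {
    v <- sub[sub$index == ix, , drop = FALSE]
    out[[ix]] <- v[[what]][match(ids, v$block_id)]
  }
  out
}

#' Correlation matrix between indices at one aggregation level
#'
#' Correlates the seven indices across blocks within one level. An index
#' with zero variance across blocks has no defined correlation: its row and
#' column are \code{NA} and the index is named in the \code{undefined}
#' attribute (and a warning), never silently reported as 0.
#'
#' @param index_table an [build_index_table()] result.
#' @param level \code{"block"}, \code{"pac"} or \code{"sac"}.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param what correlate raw counts (\code{"value"}, default) or per-parcel
#'   rates (\code{"rate"}).
#' @return Symmetric correlation matrix with unit diagonal (for defined
#'   indices).
#' @export
correlate_indices <- function(index_table, level = "block",
                              method = c("pearson", "spearman"),
                              what = "value") {
  method <- match.arg(method)
  wide <- index_wide(index_table, level = level, what = what)
  mat <- as.matrix(wide[, setdiff(names(wide), "block_id"), drop = FALSE])
  if (nrow(mat) < 3L) stop("need at least 3 blocks to correlate indices")
  sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  flat <- names(sds)[!is.na(sds) & sds == 0]
  cm <- suppressWarnings(stats::cor(mat, method = method,
                                    use = "pairwise.complete.obs"))
  if (length(flat) > 0L) {
    cm[flat, ] <- NA_real_
    cm[, flat] <- NA_real_
    warning("zero-variance index(es) have undefined correlations: ",
            paste(flat, collapse = ", "))
  }
  attr(cm, "undefined") <- flat
  cm
}
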