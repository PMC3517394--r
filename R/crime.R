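CRIME_CATEGORIES <- c("violent", "property", "vice", "theft", "vehicular")

#' Default offense-label to crime-category mapping
#'
#' An illustrative mapping of common offense labels into the five major
#' categories (violent, property, vice, theft, vehicular). Real deployments
#' should supply the jurisdiction's own mapping via [load_offense_mapping()],
#' since police departments differ in offense terminology.
#'
#' @return data.frame with columns \code{label}, \code{category}.
#' @export
default_offense_mapping <- function() {
  path <- system.file("extdata", "offense_categories.csv", package = "pacsac",
                      mustWork = TRUE)
  load_offense_mapping(path)
}

#' Load an offense mapping from CSV
#' @param path CSV with columns \code{label}, \code{category}.
#' @return Validated mapping data.frame.
#' @export
load_offense_mapping <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("label", "category") %in% names(m))) {
    stop("offense mapping needs columns label, category")
  }
  bad <- setdiff(unique(m$category), CRIME_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown crime category(ies): ", paste(bad, collapse = ", "),
         "; valid: ", paste(CRIME_CATEGORIES, collapse = ", "))
  }
  if (anyDuplicated(toupper(m$label))) stop("duplicate offense label(s) in mapping")
  m
}

#' Classify offense labels into major crime categories
#'
#' Exact, case-insensitive lookup of each label in the mapping. Labels with
#' no mapping entry are returned as \code{"unclassified"} with one summary
#' warning; classification is deterministic.
#'
#' @param offense_label character vector of raw offense labels.
#' @param mapping mapping data.frame (default [default_offense_mapping()]).
#' @return Character vector of categories (one of violent, property, vice,
#'   theft, vehicular, unclassified).
#' @export
classify_offense <- function(offense_label, mapping = default_offense_mapping()) {
  lut <- stats::setNames(mapping$category, toupper(trimws(mapping$label)))
  key <- toupper(trimws(as.character(offense_label)))
  out <- unname(lut[key])
  unmapped <- is.na(out)
  if (any(unmapped)) {
    warning(sum(unmapped), " offense label(s) not in mapping left unclassified: ",
            paste(utils::head(unique(offense_label[unmapped]), 5L), collapse = ", "))
    out[unmapped] <- "unclassified"
  }
  out
}

#' Assign planar points to blocks
#'
#' Point-in-polygon assignment with a deterministic tie-break: a point lying
#' on a shared boundary (within a small epsilon) is assigned to the
#' lexicographically smallest containing block id. Points outside every
#' block get \code{NA}.
#'
#' @param x,y point coordinates (map units).
#' @param blocks a [block_set()].
#' @param boundary_eps treat points within this distance of a boundary as
#'   contained (default \code{1e-9} map units).
#' @return Character vector of block ids (or \code{NA}) parallel to the
#'   points.
#' @export
assign_to_block <- function(x, y, blocks, boundary_eps = 1e-9) {
  stopifnot(inherits(blocks, "block_set"), length(x) == length(y))
  assigned <- rep(NA_character_, length(x))
  # visit blocks in lexicographic id order so the first hit is the tie-break
  for (i in order(blocks$ids)) {
    todo <- which(is.na(assigned))
    if (length(todo) == 0L) break
    bb <- blocks$bboxes[i, ]
    cand <- todo[x[todo] >= bb["xmin"] - boundary_eps &
                 x[todo] <= bb["xmax"] + boundary_eps &
                 y[todo] >= bb["ymin"] - boundary_eps &
                 y[todo] <= bb["ymax"] + boundary_eps]
    if (length(cand) == 0L) next
    hit <- points_in_geometry(x[cand], y[cand], blocks$parts[[i]],
                              boundary_eps = boundary_eps)
    assigned[cand[hit]] <- blocks$ids[[i]]
  }
  assigned
}

#' Aggregate classified crime incidents to block counts
#'
#' Each incident is classified from its offense label, assigned to a block
#' by point-in-polygon, and counted. \code{total} counts every incident
#' assigned to the block regardless of category (including unclassified
#' offenses), matching the convention that "total" is its own category.
#' Incidents falling outside all blocks are never silently dropped: they
#' are returned in the \code{unassigned} attribute.
#'
#' @param incidents data.frame with columns \code{incident_id}, \code{x},
#'   \code{y}, \code{offense_label} (or a precomputed \code{category}
#'   column, which is used as-is).
#' @param blocks a [block_set()].
#' @param mapping offense mapping (default packaged mapping).
#' @return data.frame with one row per block: \code{block_id}, the five
#'   category counts, \code{unclassified} and \code{total}; unassigned
#'   incidents in \code{attr(, "unassigned")}.
#' @export
aggregate_crime <- function(incidents, blocks, mapping = default_offense_mapping()) {
  stopifnot(inherits(blocks, "block_set"))
  req <- c("incident_id", "x", "y")
  if (!all(req %in% names(incidents))) {
    stop("incidents must have columns: ", paste(req, collapse = ", "))
  }
  cats <- c(CRIME_CATEGORIES, "unclassified")
  n <- nrow(incidents)
  category <- if ("category" %in% names(incidents)) {
    as.character(incidents$category)
  } else if ("offense_label" %in% names(incidents)) {
    if (n > 0L) classify_offense(incidents$offense_label, mapping) else character(0L)
  } else {
    stop("incidents need an offense_label (or category) column")
  }
  bad <- setdiff(unique(category), cats)
  if (length(bad) > 0L) stop("unknown category(ies): ", paste(bad, collapse = ", "))

  block_id <- if (n > 0L) assign_to_block(incidents$x, incidents$y, blocks)
              else character(0L)
  out <- data.frame(block_id = blocks$ids, stringsAsFactors = FALSE)
  assigned <- !is.na(block_id)
  for (cat_ in cats) {
    tab <- table(factor(block_id[assigned & category == cat_],
                        levels = blocks$ids))
    out[[cat_]] <- as.integer(tab)
  }
  tot <- table(factor(block_id[assigned], levels = blocks$ids))
  out$total <- as.integer(tot)
  attr(out, "unassigned") <- incidents[!assigned, , drop = FALSE]
  out
}
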