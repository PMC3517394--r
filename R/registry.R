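#' @keywords internal
BE_DOMAINS <- c("housing_damage", "property_disorder", "territoriality",
                "vacancy", "nuisance", "miscellaneous")

#' @keywords internal
BE_SOURCES <- c("literature", "community", "project_leaders")

#' @keywords internal
BE_APPLICABILITY <- c("parcel", "public_space")

#' @keywords internal
BE_VALUE_KINDS <- c("binary", "categorical", "text")

#' Construct a validated built-environment variable registry
#'
#' A registry is the schema for a systematic social observation instrument:
#' an ordered set of variable definitions, each assigned to exactly one
#' built-environment domain, a provenance source, an applicability (observed
#' on tax parcels or in public spaces) and a value kind.
#'
#' Validation enforces the structural rules of the instrument: variable names
#' are unique within an applicability (case-insensitively; the same feature,
#' e.g. high weeds, may legitimately appear once for parcels and once for
#' public spaces as two distinct variables), the \code{nuisance} domain is
#' public-space only, and every other domain is parcel only.
#'
#' @param variables data.frame with columns \code{name}, \code{domain},
#'   \code{source}, \code{applicability}, \code{value_kind}.
#' @param version version string recorded on the registry.
#' @return An object of class \code{be_registry}: the validated data.frame
#'   with a \code{version} attribute.
#' @seealso [default_registry()], [load_registry()], [domain_variables()]
#' @export
be_registry <- function(variables, version = "custom") {
  required <- c("name", "domain", "source", "applicability", "value_kind")
  missing_cols <- setdiff(required, names(variables))
  if (length(missing_cols) > 0L) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  variables <- as.data.frame(variables)[required]
  for (col in required) variables[[col]] <- as.character(variables[[col]])

  bad_domain <- setdiff(unique(variables$domain), BE_DOMAINS)
  if (length(bad_domain) > 0L) {
    stop("unknown domain(s): ", paste(bad_domain, collapse = ", "),
         "; valid domains are: ", paste(BE_DOMAINS, collapse = ", "))
  }
  bad_source <- setdiff(unique(variables$source), BE_SOURCES)
  if (length(bad_source) > 0L) {
    stop("unknown source(s): ", paste(bad_source, collapse = ", "),
         "; valid sources are: ", paste(BE_SOURCES, collapse = ", "))
  }
  bad_app <- setdiff(unique(variables$applicability), BE_APPLICABILITY)
  if (length(bad_app) > 0L) {
    stop("unknown applicability value(s): ", paste(bad_app, collapse = ", "),
         "; valid values are: ", paste(BE_APPLICABILITY, collapse = ", "))
  }
  bad_kind <- setdiff(unique(variables$value_kind), BE_VALUE_KINDS)
  if (length(bad_kind) > 0L) {
    stop("unknown value_kind(s): ", paste(bad_kind, collapse = ", "),
         "; valid kinds are: ", paste(BE_VALUE_KINDS, collapse = ", "))
  }

  key <- paste(tolower(variables$name), variables$applicability)
  if (anyDuplicated(key)) {
    dups <- unique(variables$name[duplicated(key)])
    stop("duplicate variable name(s) within an applicability: ",
         paste(dups, collapse = ", "))
  }

  # nuisance <=> public_space; all other domains are parcel-applicable
  is_nuis <- variables$domain == "nuisance"
  mism <- (is_nuis & variables$applicability != "public_space") |
    (!is_nuis & variables$applicability != "parcel")
  if (any(mism)) {
    stop("domain/applicability mismatch for variable(s): ",
         paste(variables$name[mism], collapse = ", "),
         " (nuisance variables are public_space; all other domains are parcel)")
  }

  rownames(variables) <- NULL
  structure(variables, version = as.character(version),
            class = c("be_registry", "data.frame"))
}

#' The default built-environment variable registry
#'
#' Returns the packaged instrument schema: 53 parcel-applicable variables
#' spanning housing damage (13), property disorder (14), territoriality (6),
#' vacancy (3) and a miscellaneous set, plus 26 public-space nuisance
#' variables. Free-text "other condition"/"other nuisance" entries are
#' text-valued and counted as present when non-empty; property type and
#' similar enumerations are categorical; all remaining variables are binary
#' presence/absence indicators.
#'
#' @return A \code{be_registry}.
#' @examples
#' reg <- default_registry()
#' sum(reg$applicability == "parcel")
#' nrow(domain_variables(reg, "nuisance"))
#' @export
default_registry <- function() {
  path <- system.file("extdata", "be_variables.csv", package = "pacsac",
                      mustWork = TRUE)
  load_registry(path)
}

#' Load a variable registry from a CSV config file
#'
#' The config is a flat CSV with one record per variable and columns
#' \code{name}, \code{domain}, \code{source}, \code{applicability},
#' \code{value_kind}. The result is validated as in [be_registry()];
#' duplicates and domain/applicability mismatches are rejected.
#'
#' @param path path to the CSV file.
#' @param version version string; defaults to the file name.
#' @return A \code{be_registry}.
#' @export
load_registry <- function(path, version = NULL) {
  if (!file.exists(path)) stop("registry config not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (is.null(version)) version <- basename(path)
  be_registry(df, version = version)
}

#' Write a registry to a CSV config file
#'
#' Round-trips with [load_registry()].
#'
#' @param registry a \code{be_registry}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "be_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Variables assigned to one built-environment domain
#'
#' @param registry a \code{be_registry}.
#' @param domain one of \code{housing_damage}, \code{property_disorder},
#'   \code{territoriality}, \code{vacancy}, \code{nuisance},
#'   \code{miscellaneous}.
#' @return The registry rows with that domain, in registry order.
#' @export
domain_variables <- function(registry, domain) {
  stopifnot(inherits(registry, "be_registry"))
  if (length(domain) != 1L || !domain %in% BE_DOMAINS) {
    stop("unrecognized domain ", deparse(as.character(domain)),
         "; valid domains are: ", paste(BE_DOMAINS, collapse = ", "))
  }
  out <- registry[registry$domain == domain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Names of parcel-applicable or public-space variables
#' @param registry a \code{be_registry}.
#' @param applicability \code{"parcel"} or \code{"public_space"}.
#' @return Character vector of variable names in registry order.
#' @export
registry_variables <- function(registry, applicability = c("parcel", "public_space")) {
  stopifnot(inherits(registry, "be_registry"))
  applicability <- match.arg(applicability)
  registry$name[registry$applicability == applicability]
}

#' @export
print.be_registry <- function(x, ...) {
  cat("Built-environment variable registry (version ",
      attr(x, "version"), ")\n", sep = "")
  cat(nrow(x), " variables: ",
      sum(x$applicability == "parcel"), " parcel, ",
      sum(x$applicability == "public_space"), " public-space\n", sep = "")
  tab <- table(factor(x$domain, levels = BE_DOMAINS))
  for (d in names(tab)) cat("  ", format(d, width = 18), tab[[d]], "\n")
  invisible(x)
}
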