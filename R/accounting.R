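# Field-exclusion and property-category accounting. A parcel roster is a
# one-row-per-parcel table; the tabulation recomputes every headline count
# (assessable parcels, category totals, residual categories) from the rows,
# so published roster totals can be expanded and re-tabulated as an
# arithmetic consistency check.

#' Published 2008 assessment roster totals
#'
#' The packaged roster totals for the 2008 curbside audit: parcels in the
#' study area, parcels excluded for field-safety/visibility reasons, and
#' the tabulated property categories and residential subtypes.
#'
#' @return Named integer vector.
#' @export
assessment_totals <- function() {
  path <- system.file("extdata", "assessment_totals_2008.csv",
                      package = "pacsac", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$count), df$quantity)
}

#' Expand roster totals into a one-row-per-parcel roster
#'
#' Builds a parcel roster whose marginal counts equal the given totals:
#' \code{excluded} flags, property categories over the assessable parcels
#' (parcels beyond the named categories are \code{other}), and residential
#' subtypes (residential parcels beyond apartments and single-family homes
#' are \code{other_residential}).
#'
#' @param totals named counts as returned by [assessment_totals()].
#' @return data.frame with columns \code{parcel_id}, \code{excluded},
#'   \code{category}, \code{subtype}.
#' @export
build_roster <- function(totals = assessment_totals()) {
  need <- c("parcels_in_study_area", "excluded_unsafe_or_not_visible",
            "residential", "commercial", "unoccupied_or_demolished_lot",
            "religious_institution", "community_property",
            "residential_apartment", "residential_single_family")
  missing_q <- setdiff(need, names(totals))
  if (length(missing_q) > 0L) {
    stop("totals missing quantity(ies): ", paste(missing_q, collapse = ", "))
  }
  n_total <- totals[["parcels_in_study_area"]]
  n_excl <- totals[["excluded_unsafe_or_not_visible"]]
  n_assessable <- n_total - n_excl
  cats <- c(residential = totals[["residential"]],
            commercial = totals[["commercial"]],
            unoccupied_or_demolished_lot = totals[["unoccupied_or_demolished_lot"]],
            religious_institution = totals[["religious_institution"]],
            community_property = totals[["community_property"]])
  n_other <- n_assessable - sum(cats)
  if (n_other < 0L) stop("category counts exceed assessable parcels")
  category <- c(rep(names(cats), cats), rep("other", n_other),
                rep(NA_character_, n_excl))
  excluded <- c(rep(FALSE, n_assessable), rep(TRUE, n_excl))

  n_res <- cats[["residential"]]
  n_apt <- totals[["residential_apartment"]]
  n_sfh <- totals[["residential_single_family"]]
  if (n_apt + n_sfh > n_res) stop("residential subtypes exceed residential total")
  subtype <- rep(NA_character_, n_total)
  res_rows <- which(category == "residential")
  subtype[res_rows] <- c(rep("apartment", n_apt), rep("single_family", n_sfh),
                         rep("other_residential", n_res - n_apt - n_sfh))
  data.frame(parcel_id = sprintf("R%05d", seq_len(n_total)),
             excluded = excluded, category = category, subtype = subtype,
             stringsAsFactors = FALSE)
}

#' Tabulate a parcel roster
#'
#' Recomputes the assessment accounting from roster rows: assessable
#' parcels (not excluded), counts per property category, parcels in
#' unnamed ("other") categories, and residual residential parcels (senior
#' housing, care facilities, duplexes, multi-address or other homes, i.e.
#' residential minus apartments and single-family).
#'
#' @param roster data.frame as from [build_roster()].
#' @return Named list of counts.
#' @export
tabulate_assessment <- function(roster) {
  stopifnot(all(c("excluded", "category", "subtype") %in% names(roster)))
  assessed <- roster[!roster$excluded, , drop = FALSE]
  res <- assessed[assessed$category %in% "residential", , drop = FALSE]
  list(
    n_parcels = nrow(roster),
    n_excluded = sum(roster$excluded),
    n_assessable = nrow(assessed),
    n_residential = nrow(res),
    n_commercial = sum(assessed$category %in% "commercial"),
    n_unoccupied_or_demolished_lot =
      sum(assessed$category %in% "unoccupied_or_demolished_lot"),
    n_religious = sum(assessed$category %in% "religious_institution"),
    n_community = sum(assessed$category %in% "community_property"),
    n_other_category = sum(assessed$category %in% "other"),
    n_apartment = sum(res$subtype %in% "apartment"),
    n_single_family = sum(res$subtype %in% "single_family"),
    n_residual_residential = sum(res$subtype %in% "other_residential")
  )
}
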