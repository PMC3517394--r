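# Owner-occupancy ("tenure") classification: a parcel is called
# owner-occupied when its situs (geographic) address matches the owner's
# mailing address strongly enough, renter-occupied otherwise.

DIRECTIONALS <- c(
  NORTH = "N", SOUTH = "S", EAST = "E", WEST = "W",
  NORTHEAST = "NE", NORTHWEST = "NW", SOUTHEAST = "SE", SOUTHWEST = "SW",
  N = "N", S = "S", E = "E", W = "W", NE = "NE", NW = "NW",
  SE = "SE", SW = "SW"
)

STREET_TYPES <- c(
  STREET = "ST", ST = "ST", AVENUE = "AVE", AVE = "AVE", AV = "AVE",
  ROAD = "RD", RD = "RD", DRIVE = "DR", DR = "DR", LANE = "LN", LN = "LN",
  COURT = "CT", CT = "CT", BOULEVARD = "BLVD", BLVD = "BLVD",
  PLACE = "PL", PL = "PL", CIRCLE = "CIR", CIR = "CIR",
  TERRACE = "TER", TER = "TER", TRAIL = "TRL", TRL = "TRL",
  PARKWAY = "PKWY", PKWY = "PKWY", HIGHWAY = "HWY", HWY = "HWY",
  WAY = "WAY", LOOP = "LOOP", ALLEY = "ALY", ALY = "ALY"
)

UNIT_DESIGNATORS <- c("APT", "APARTMENT", "UNIT", "STE", "SUITE", "#", "NO")

#' Normalize a street address into canonical components
#'
#' Uppercases, strips punctuation, maps directionals to single/double-letter
#' canonical tokens (NORTH to N, ...), street types to USPS-style
#' abbreviations (STREET to ST, AVENUE to AVE, ...), and splits a trailing
#' unit designator (APT/UNIT/#) into the unit field. Normalization is
#' idempotent: re-normalizing the canonical form changes nothing.
#'
#' @param raw address string (may be empty or \code{NA}).
#' @return An object of class \code{address_canonical} with fields
#'   \code{house_number}, \code{directional}, \code{street_name} (character
#'   vector of tokens), \code{street_type}, \code{unit} and \code{raw}.
#' @examples
#' normalize_address("123 North Main Street")
#' @export
normalize_address <- function(raw) {
  if (length(raw) != 1L) stop("normalize_address() takes one address at a time")
  orig <- if (is.na(raw)) "" else as.character(raw)
  s <- toupper(orig)
  s <- gsub("#", " # ", s, fixed = TRUE)
  s <- gsub("[^A-Z0-9#]+", " ", s)
  tokens <- strsplit(trimws(s), " +")[[1L]]
  tokens <- tokens[nzchar(tokens)]

  out <- list(house_number = "", directional = "", street_name = character(0L),
              street_type = "", unit = "", raw = orig)

  # unit: designator token plus everything after it
  ui <- which(tokens %in% UNIT_DESIGNATORS)
  if (length(ui) > 0L) {
    ui <- ui[length(ui)]
    if (ui < length(tokens)) out$unit <- paste(tokens[seq.int(ui + 1L, length(tokens))],
                                               collapse = "")
    tokens <- tokens[seq_len(ui - 1L)]
  }

  if (length(tokens) > 0L && grepl("^[0-9]+$", tokens[1L])) {
    out$house_number <- sub("^0+(?=.)", "", tokens[1L], perl = TRUE)
    tokens <- tokens[-1L]
  }
  if (length(tokens) > 1L && tokens[1L] %in% names(DIRECTIONALS)) {
    out$directional <- unname(DIRECTIONALS[tokens[1L]])
    tokens <- tokens[-1L]
  }
  if (length(tokens) > 1L && tokens[length(tokens)] %in% names(STREET_TYPES)) {
    out$street_type <- unname(STREET_TYPES[tokens[length(tokens)]])
    tokens <- tokens[-length(tokens)]
  } else if (length(tokens) == 1L && tokens %in% names(STREET_TYPES) &&
             !tokens %in% names(DIRECTIONALS)) {
    # bare "AVE" etc. with no name left
    out$street_type <- unname(STREET_TYPES[tokens])
    tokens <- character(0L)
  }
  out$street_name <- tokens
  class(out) <- "address_canonical"
  out
}

#' @export
print.address_canonical <- function(x, ...) {
  cat("<address>", format(x), "\n")
  invisible(x)
}

#' @export
format.address_canonical <- function(x, ...) {
  parts <- c(x$house_number, x$directional, x$street_name, x$street_type,
             if (nzchar(x$unit)) c("#", x$unit))
  paste(parts[nzchar(parts)], collapse = " ")
}

is_empty_address <- function(a) {
  !nzchar(a$house_number) && !nzchar(a$directional) &&
    length(a$street_name) == 0L && !nzchar(a$street_type) && !nzchar(a$unit)
}

#' Score the match between two canonical addresses
#'
#' A weighted token-agreement score in \eqn{[0, 1]}. The house number,
#' street name, directional and street type contribute fixed weights
#' (defaults 0.2 / 0.5 / 0.15 / 0.15). Street-name agreement is the Jaccard
#' overlap of name tokens; the other components agree exactly or not at all
#' (two empty fields agree; an empty versus a present house number is a
#' disagreement). When the house numbers disagree the total score is capped
#' at \code{house_mismatch_cap} (default 0.2), since two different house
#' numbers on the same street are different properties. The score is
#' symmetric, and identical non-empty addresses score exactly 1.
#'
#' @param a,b \code{address_canonical} objects (see [normalize_address()]).
#' @param weights named numeric vector with entries \code{house},
#'   \code{name}, \code{directional}, \code{type}; normalized to sum to 1.
#' @param house_mismatch_cap score ceiling when house numbers disagree.
#' @return A single number in \eqn{[0, 1]}.
#' @export
match_score <- function(a, b,
                        weights = c(house = 0.2, name = 0.5,
                                    directional = 0.15, type = 0.15),
                        house_mismatch_cap = 0.2) {
  stopifnot(inherits(a, "address_canonical"), inherits(b, "address_canonical"))
  req <- c("house", "name", "directional", "type")
  if (!all(req %in% names(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative and name house/name/directional/type")
  }
  w <- weights[req] / sum(weights[req])
  if (is_empty_address(a) || is_empty_address(b)) return(0)

  house_agree <- identical(a$house_number, b$house_number)
  name_sim <- if (length(a$street_name) == 0L && length(b$street_name) == 0L) {
    1
  } else if (length(a$street_name) == 0L || length(b$street_name) == 0L) {
    0
  } else {
    length(intersect(a$street_name, b$street_name)) /
      length(union(a$street_name, b$street_name))
  }
  dir_agree <- identical(a$directional, b$directional)
  type_agree <- identical(a$street_type, b$street_type)

  score <- w[["house"]] * house_agree + w[["name"]] * name_sim +
    w[["directional"]] * dir_agree + w[["type"]] * type_agree
  if (!house_agree) score <- min(score, house_mismatch_cap)
  unname(score)
}

#' Classify parcels as owner- or renter-occupied
#'
#' Compares each parcel's situs address to its owner mailing address with
#' [match_score()] and calls the parcel owner-occupied when the score is at
#' least \code{threshold}, renter-occupied otherwise. A missing owner
#' address yields a renter call with score 0 (with a warning), or an
#' \code{unknown} call under \code{strict = TRUE}. Parcels with a missing
#' situs address cannot be scored: they are skipped and reported in the
#' \code{errors} attribute of the result.
#'
#' @param parcels data.frame with columns \code{parcel_id},
#'   \code{situs_address}, \code{owner_address}.
#' @param threshold owner-occupancy score threshold in \eqn{[0, 1]}
#'   (default 0.85).
#' @param strict if \code{TRUE}, missing owner addresses produce an
#'   \code{unknown} call instead of \code{renter_occupied}.
#' @param weights,house_mismatch_cap passed to [match_score()].
#' @return data.frame with columns \code{parcel_id}, \code{score},
#'   \code{call} (\code{owner_occupied}/\code{renter_occupied}/
#'   \code{unknown}), \code{threshold_used}; skipped records in
#'   \code{attr(, "errors")}.
#' @export
classify_tenure <- function(parcels, threshold = 0.85, strict = FALSE,
                            weights = c(house = 0.2, name = 0.5,
                                        directional = 0.15, type = 0.15),
                            house_mismatch_cap = 0.2) {
  req <- c("parcel_id", "situs_address", "owner_address")
  if (!all(req %in% names(parcels))) {
    stop("parcels must have columns: ", paste(req, collapse = ", "))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]")
  }
  n <- nrow(parcels)
  score <- numeric(n); call <- character(n); keep <- rep(TRUE, n)
  errors <- character(0L)
  n_missing_owner <- 0L
  for (i in seq_len(n)) {
    situs <- parcels$situs_address[i]
    owner <- parcels$owner_address[i]
    if (is.na(situs) || !nzchar(trimws(situs))) {
      keep[i] <- FALSE
      errors <- c(errors, paste0(parcels$parcel_id[i], ": missing situs address"))
      next
    }
    if (is.na(owner) || !nzchar(trimws(owner))) {
      n_missing_owner <- n_missing_owner + 1L
      score[i] <- 0
      call[i] <- if (strict) "unknown" else "renter_occupied"
      next
    }
    score[i] <- match_score(normalize_address(situs), normalize_address(owner),
                            weights = weights,
                            house_mismatch_cap = house_mismatch_cap)
    call[i] <- if (score[i] >= threshold) "owner_occupied" else "renter_occupied"
  }
  if (n_missing_owner > 0L) {
    warning(n_missing_owner, " parcel(s) with missing owner address called ",
            if (strict) "unknown" else "renter_occupied", " with score 0")
  }
  out <- data.frame(parcel_id = as.character(parcels$parcel_id)[keep],
                    score = score[keep], call = call[keep],
                    threshold_used = rep(threshold, sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "errors") <- errors
  out
}
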