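# Inter-rater reliability for multi-rater assessments: pairwise percent
# agreement and the one-way random-effects intraclass correlation, in its
# single-rater and average-of-k forms (related by the Spearman-Brown
# identity), with F-based confidence intervals.

check_rating_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("ratings must be numeric")
  if (anyNA(m)) stop("rating matrix has missing cells; apply listwise deletion upstream")
  if (nrow(m) < 2L) stop("need at least 2 targets (rows)")
  if (ncol(m) < 2L) stop("need at least 2 raters (columns)")
  m
}

#' Mean pairwise percent agreement
#'
#' For each target (row), the fraction of rater pairs giving identical
#' ratings; averaged over targets.
#'
#' @param m numeric targets x raters matrix with no missing cells.
#' @return A number in \eqn{[0, 1]}.
#' @export
percent_agreement <- function(m) {
  m <- check_rating_matrix(m)
  k <- ncol(m)
  npairs <- k * (k - 1L) / 2L
  per_target <- apply(m, 1L, function(row) {
    agree <- 0L
    for (i in seq_len(k - 1L)) {
      agree <- agree + sum(row[seq.int(i + 1L, k)] == row[i])
    }
    agree / npairs
  })
  mean(per_target)
}

#' One-way random-effects intraclass correlation
#'
#' Decomposes the rating matrix by one-way ANOVA (targets as the random
#' factor, raters nested as replicate measurements). With between-target
#' mean square MSB on \eqn{n - 1} degrees of freedom and within-target mean
#' square MSW on \eqn{n(k - 1)}:
#' \deqn{ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW)}
#' \deqn{ICC(k) = (MSB - MSW) / MSB}
#' The two forms obey the Spearman-Brown relation
#' \eqn{ICC(k) = k\,ICC(1) / (1 + (k - 1)\,ICC(1))}. Confidence limits come
#' from the F distribution on \eqn{(n - 1,\; n(k - 1))} degrees of freedom.
#'
#' @param m numeric targets x raters matrix with no missing cells.
#' @param form \code{"single"} (reliability of one rater) or
#'   \code{"average"} (reliability of the mean of the k raters). Both
#'   estimates are always returned; \code{form} selects which one the
#'   confidence interval describes.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return An object of class \code{icc_oneway}: list with
#'   \code{icc_single}, \code{icc_average}, \code{ci_low}, \code{ci_high},
#'   \code{form}, \code{confidence}, \code{percent_agreement},
#'   \code{msb}, \code{msw}, \code{n}, \code{k}.
#' @examples
#' m <- cbind(c(1, 0, 1, 0), c(1, 0, 1, 1))
#' icc_oneway(m)
#' @export
icc_oneway <- function(m, form = c("single", "average"), confidence = 0.95) {
  m <- check_rating_matrix(m)
  form <- match.arg(form)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)")
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  if (ssb + ssw <= 0) stop("degenerate ratings: zero total variance, ICC undefined")
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))

  icc_single <- (msb - msw) / (msb + (k - 1) * msw)
  icc_average <- (msb - msw) / msb

  alpha <- 1 - confidence
  df1 <- n - 1; df2 <- n * (k - 1)
  if (msw > 0) {
    fobs <- msb / msw
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  } else {
    fl <- fu <- Inf
  }
  if (form == "single") {
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    ci <- c(1 - 1 / fl, 1 - 1 / fu)
  }
  ci[is.nan(ci)] <- 1

  structure(list(icc_single = icc_single, icc_average = icc_average,
                 ci_low = ci[1L], ci_high = ci[2L], form = form,
                 confidence = confidence,
                 percent_agreement = percent_agreement(m),
                 msb = msb, msw = msw, n = n, k = k),
            class = "icc_oneway")
}

#' @export
print.icc_oneway <- function(x, ...) {
  est <- if (x$form == "single") x$icc_single else x$icc_average
  cat(sprintf("One-way ICC (%s of %d raters, %d targets): %.3f\n",
              x$form, x$k, x$n, est))
  cat(sprintf("  %.0f%% CI: (%.3f, %.3f)\n", 100 * x$confidence,
              x$ci_low, x$ci_high))
  cat(sprintf("  single %.3f | average %.3f | percent agreement %.3f\n",
              x$icc_single, x$icc_average, x$percent_agreement))
  invisible(x)
}

#' Reliability table from long-format ratings
#'
#' Computes per-variable one-way ICC and percent agreement, plus a pooled
#' \code{ALL} row obtained by stacking the per-variable target rows into one
#' rating matrix (each parcel-variable combination is a target). Variables
#' whose stacked matrix is degenerate (zero variance) are reported with
#' \code{NA} estimates.
#'
#' @param ratings data.frame with columns \code{parcel_id}, \code{variable},
#'   \code{rater}, \code{rating}. Parcels with missing raters for a variable
#'   are dropped listwise (and counted in the \code{dropped} attribute).
#' @param form,confidence passed to [icc_oneway()].
#' @return data.frame with columns \code{variable}, \code{n_targets},
#'   \code{icc_single}, \code{ci_low}, \code{ci_high}, \code{icc_average},
#'   \code{percent_agreement}; first row is \code{ALL}.
#' @export
reliability_table <- function(ratings, form = "single", confidence = 0.95) {
  req <- c("parcel_id", "variable", "rater", "rating")
  if (!all(req %in% names(ratings))) {
    stop("ratings must have columns: ", paste(req, collapse = ", "))
  }
  raters <- sort(unique(as.character(ratings$rater)))
  k <- length(raters)
  dropped <- 0L
  per_var_mats <- list()
  for (v in unique(as.character(ratings$variable))) {
    sub <- ratings[ratings$variable == v, , drop = FALSE]
    wide <- stats::reshape(
      sub[, c("parcel_id", "rater", "rating")], direction = "wide",
      idvar = "parcel_id", timevar = "rater")
    mat <- as.matrix(wide[, -1L, drop = FALSE])
    complete <- stats::complete.cases(mat)
    dropped <- dropped + sum(!complete)
    per_var_mats[[v]] <- mat[complete, , drop = FALSE]
  }
  stacked <- do.call(rbind, per_var_mats)

  one_row <- function(name, mat) {
    res <- tryCatch(icc_oneway(mat, form = form, confidence = confidence),
                    error = function(e) NULL)
    data.frame(variable = name, n_targets = nrow(mat),
               icc_single = if (is.null(res)) NA_real_ else res$icc_single,
               ci_low = if (is.null(res)) NA_real_ else res$ci_low,
               ci_high = if (is.null(res)) NA_real_ else res$ci_high,
               icc_average = if (is.null(res)) NA_real_ else res$icc_average,
               percent_agreement =
                 if (is.null(res)) NA_real_ else res$percent_agreement,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_row("ALL", stacked),
               do.call(rbind, Map(one_row, names(per_var_mats), per_var_mats)))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "k") <- k
  out
}
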