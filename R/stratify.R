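# Mean-of-medians pivot and UP/DOWN stratification with an optional percent
# exclusion band.

#' Mean of the outcome-group medians
#'
#' The pivot separating UP from DOWN strata: the mean of the per-group
#' medians, \code{(median(pos) + median(neg)) / 2}.  Unlike the overall
#' median, it is not pulled toward the larger outcome group when group sizes
#' are unbalanced.
#'
#' @param valuesPositive,valuesNegative numeric feature values of the
#'   positive and negative outcome groups (both non-empty).
#' @return single numeric pivot, or \code{NA} with a warning when a group is
#'   empty (the feature is then skipped).
#' @examples
#' meanOfMedians(c(1, 2, 3), c(5, 6, 7))  # 4
#' @export
meanOfMedians <- function(valuesPositive, valuesNegative) {
  if (!length(valuesPositive) || !length(valuesNegative)) {
    warning("empty outcome group; stratification skipped")
    return(NA_real_)
  }
  (stats::median(valuesPositive) + stats::median(valuesNegative)) / 2
}

#' Stratify patients around the pivot
#'
#' Assigns each patient to the UP stratum (value above the upper bound), the
#' DOWN stratum (below the lower bound) or, for a positive threshold, the
#' excluded band in between.  The threshold gives the distance of the bounds
#' from the pivot in percent of the pivot's magnitude:
#' \code{bound = mom * (1 +/- threshold/100)} for non-negative pivots.  At
#' threshold 0 no patient is excluded and values exactly equal to the pivot
#' go DOWN.  Band membership is inclusive on both bounds.  Thresholds above
#' 20 are allowed but warned against: the number of excluded patients makes
#' significant survival differences unlikely.
#'
#' @param values named numeric vector (names are case ids).
#' @param mom the pivot, usually from \code{\link{meanOfMedians}}.
#' @param thresholdPct percent half-width of the exclusion band (>= 0).
#' @param featureId optional feature id carried into the result.
#' @return a \code{\link{PivotStratification}}.
#' @examples
#' v <- c(a = 1, b = 3.9, c = 4.1, d = 7)
#' s <- stratifyByPivot(v, mom = 4, thresholdPct = 5)
#' upIds(s); downIds(s); excludedIds(s)
#' @export
stratifyByPivot <- function(values, mom, thresholdPct = 0,
                            featureId = NA_character_) {
  if (length(thresholdPct) != 1L || is.na(thresholdPct) || thresholdPct < 0)
    stop("'thresholdPct' must be a single non-negative number")
  if (thresholdPct > 20)
    warning("threshold above 20 is not advised: too many patients excluded")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be named by case id")
  if (is.na(mom)) stop("'mom' is NA")

  half <- abs(mom) * thresholdPct / 100
  boundL <- mom - half
  boundU <- mom + half
  if (thresholdPct == 0) {
    up <- values > mom
    down <- !up
    excl <- rep(FALSE, length(values))
  } else {
    up <- values > boundU
    down <- values < boundL
    excl <- !up & !down
  }
  new("PivotStratification",
      featureId = as.character(featureId), mom = mom,
      thresholdPct = thresholdPct, boundL = boundL, boundU = boundU,
      upIds = names(values)[up], downIds = names(values)[down],
      excludedIds = names(values)[excl])
}

#' Export a stratification as a table
#'
#' @param strat a \code{\link{PivotStratification}}.
#' @param values the named value vector it was computed from.
#' @return data.frame with \code{feature_id}, \code{case_id}, \code{value},
#'   \code{stratum}.
#' @export
stratificationTable <- function(strat, values) {
  stratum <- rep(NA_character_, length(values))
  stratum[names(values) %in% upIds(strat)] <- "UP"
  stratum[names(values) %in% downIds(strat)] <- "DOWN"
  stratum[names(values) %in% excludedIds(strat)] <- "excluded"
  data.frame(feature_id = strat@featureId, case_id = names(values),
             value = unname(values), stratum = stratum,
             stringsAsFactors = FALSE)
}
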