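# The validation stage: base plots (UP vs DOWN strata among treated
# patients), UP/DOWN validation plots (treated vs untreated within a stratum
# over the full cohort), the label-consistency filter, vp-product ranking and
# the per-DMR-position threshold optimization.

.clinicalLookup <- function(clinical, ids) {
  idx <- match(ids, clinical$case_id)
  if (anyNA(idx)) stop("case ids missing from clinical table")
  list(time = clinical$time_years[idx],
       event = as.integer(clinical$vital_status[idx] == "dead"))
}

# Per-threshold base-plot Cox results for one feature on one patient subset:
# stratify `values[ids]` at the mean of the outcome-group medians and compare
# UP vs DOWN strata.  Returns a data.frame with one row per threshold
# (p/coefficient NA where a threshold is degenerate).
.basePvals <- function(values, clinical, outcome, ids, thresholds) {
  oc <- .outcomeVec(outcome)
  v <- values[ids]
  pos <- ids[oc[ids] == "positive"]
  neg <- ids[oc[ids] == "negative"]
  out <- data.frame(threshold_pct = thresholds, p_value = NA_real_,
                    coefficient = NA_real_, n_included = NA_integer_)
  if (!length(pos) || !length(neg)) return(out)
  mom <- suppressWarnings(meanOfMedians(v[pos], v[neg]))
  for (i in seq_along(thresholds)) {
    s <- suppressWarnings(stratifyByPivot(v, mom, thresholds[i]))
    up <- upIds(s); down <- downIds(s)
    if (!length(up) || !length(down)) next
    inc <- c(up, down)
    cl <- .clinicalLookup(clinical, inc)
    cx <- suppressWarnings(coxGroupP(cl$time, cl$event, inc %in% up))
    if (is.null(cx)) next
    out$p_value[i] <- cx$p_value
    out$coefficient[i] <- cx$coefficient
    out$n_included[i] <- cx$n
  }
  out
}

.bestRow <- function(perThreshold) {
  ok <- which(!is.na(perThreshold$p_value))
  if (!length(ok)) return(NULL)
  ok[which.min(perThreshold$p_value[ok])]   # ties: smallest threshold wins
}

#' Base survival plot for one feature
#'
#' Restricted to treated patients, the feature values are dichotomised at the
#' mean of the treated outcome-group medians and the UP and DOWN strata are
#' compared with a Cox model.  Every threshold in \code{thresholds} is tried
#' and the lowest p-value is kept.  The label names the stratum with the
#' longer survival: a negative coefficient (UP stratum at lower hazard)
#' labels the plot UP.
#'
#' @param values named numeric vector of feature values (all case ids).
#' @param clinical patient data.frame (\code{case_id}, \code{vital_status},
#'   \code{time_years}).
#' @param outcome outcome assignment, see \code{\link{applyCutoff}}.
#' @param treatedIds ids of the treated patients.
#' @param thresholds numeric vector of percent thresholds to scan.
#' @param featureId optional id carried through.
#' @return one-row data.frame (\code{feature_id}, \code{plot_kind},
#'   \code{threshold_pct}, \code{p_value}, \code{label}, \code{n_included},
#'   \code{coefficient}), or \code{NULL} when no threshold admits a
#'   comparison.
#' @export
basePlot <- function(values, clinical, outcome, treatedIds, thresholds = 0,
                     featureId = NA_character_) {
  pt <- .basePvals(values, clinical, outcome, treatedIds, thresholds)
  i <- .bestRow(pt)
  if (is.null(i)) return(NULL)
  data.frame(feature_id = featureId, plot_kind = "base",
             threshold_pct = pt$threshold_pct[i], p_value = pt$p_value[i],
             label = if (pt$coefficient[i] < 0) "UP" else "DOWN",
             n_included = pt$n_included[i], coefficient = pt$coefficient[i],
             stringsAsFactors = FALSE)
}

#' UP and DOWN validation plots for one feature
#'
#' The pivot is recomputed on the full cohort (treated plus untreated), the
#' cohort is stratified, and within each stratum treated patients are
#' compared against untreated patients with a Cox model.  Per plot, the best
#' p-value over the scanned thresholds is retained.  A plot is labelled UP
#' when the treated arm outlives the untreated arm (negative coefficient of
#' the treated indicator), DOWN otherwise.
#'
#' @inheritParams basePlot
#' @param untreatedIds ids of the untreated patients; validation is
#'   impossible without them (\code{NULL} returned with a warning).
#' @return list with elements \code{up_val} and \code{down_val} (one-row
#'   data.frames like \code{\link{basePlot}}, or \code{NULL} where the
#'   stratum never admitted a comparison), or \code{NULL} when there are no
#'   untreated patients.
#' @export
validationPlots <- function(values, clinical, outcome, treatedIds,
                            untreatedIds, thresholds = 0,
                            featureId = NA_character_) {
  if (!length(untreatedIds)) {
    warning("no untreated patients: validation impossible")
    return(NULL)
  }
  ids <- c(treatedIds, untreatedIds)
  oc <- .outcomeVec(outcome)
  v <- values[ids]
  pos <- ids[oc[ids] == "positive"]
  neg <- ids[oc[ids] == "negative"]
  if (!length(pos) || !length(neg)) {
    warning("an outcome group is empty on the full cohort")
    return(NULL)
  }
  mom <- suppressWarnings(meanOfMedians(v[pos], v[neg]))

  onePlot <- function(side) {
    best <- NULL
    for (t in thresholds) {
      s <- suppressWarnings(stratifyByPivot(v, mom, t))
      stratum <- if (side == "up") upIds(s) else downIds(s)
      tr <- intersect(stratum, treatedIds)
      un <- intersect(stratum, untreatedIds)
      if (!length(tr) || !length(un)) next
      inc <- c(tr, un)
      cl <- .clinicalLookup(clinical, inc)
      cx <- suppressWarnings(coxGroupP(cl$time, cl$event, inc %in% tr))
      if (is.null(cx)) next
      if (is.null(best) || cx$p_value < best$p_value)
        best <- list(threshold_pct = t, p_value = cx$p_value,
                     coefficient = cx$coefficient, n_included = cx$n)
    }
    if (is.null(best)) return(NULL)
    data.frame(feature_id = featureId,
               plot_kind = paste0(side, "_validation"),
               threshold_pct = best$threshold_pct, p_value = best$p_value,
               label = if (best$coefficient < 0) "UP" else "DOWN",
               n_included = best$n_included, coefficient = best$coefficient,
               stringsAsFactors = FALSE)
  }
  list(up_val = onePlot("up"), down_val = onePlot("down"))
}

#' Label-consistency filter
#'
#' An UP-labelled base plot passes only when the UP validation plot is also
#' labelled UP (the DOWN validation is unconstrained); a DOWN-labelled base
#' plot passes only when the DOWN validation is labelled DOWN.  Exactly four
#' of the eight label compositions pass.
#'
#' @param baseLabel,upValLabel,downValLabel character vectors of
#'   \code{"UP"}/\code{"DOWN"} labels (recycled).
#' @return logical vector.
#' @export
consistencyFilter <- function(baseLabel, upValLabel, downValLabel) {
  ifelse(baseLabel == "UP", upValLabel == "UP", downValLabel == "DOWN")
}

#' vp-product of base and matching validation p-values
#'
#' The ranking score: the product of the base-plot p-value and the
#' direction-matching validation p-value (UP validation for UP-labelled base
#' plots, DOWN validation otherwise).  A biomarker is a valid candidate when
#' the product is strictly below the limit (default 0.0025 = 0.05^2); a very
#' low p-value in one plot can offset a p-value above 0.05 in the other.
#'
#' @param baseP,validationP p-values in [0,1] (vectorized).
#' @param limit candidate limit on the product.
#' @return list with \code{product} and logical \code{is_candidate}.
#' @export
vpProduct <- function(baseP, validationP, limit = 0.0025) {
  stopifnot(all(baseP >= 0 & baseP <= 1, na.rm = TRUE),
            all(validationP >= 0 & validationP <= 1, na.rm = TRUE))
  product <- baseP * validationP
  list(product = product, is_candidate = !is.na(product) & product < limit)
}

#' Evaluate one feature through base plot, validation and ranking
#'
#' Runs \code{\link{basePlot}} and \code{\link{validationPlots}}, applies the
#' label-consistency filter and computes the vp-product with the
#' direction-matching validation p-value.
#'
#' @inheritParams validationPlots
#' @param vpLimit candidate limit on the vp-product.
#' @return one-row data.frame with base/validation p-values and labels,
#'   \code{passed_filter}, \code{vp_product} and \code{is_candidate}.
#' @export
evaluateMarker <- function(values, clinical, outcome, treatedIds,
                           untreatedIds, thresholds = 0, vpLimit = 0.0025,
                           featureId = NA_character_) {
  out <- data.frame(
    feature_id = featureId, base_label = NA_character_, p_base = NA_real_,
    base_threshold = NA_real_, up_val_label = NA_character_,
    p_up_val = NA_real_, down_val_label = NA_character_,
    p_down_val = NA_real_, passed_filter = FALSE, vp_product = NA_real_,
    is_candidate = FALSE, n_treated = length(treatedIds),
    n_untreated = length(untreatedIds), stringsAsFactors = FALSE)

  bp <- basePlot(values, clinical, outcome, treatedIds, thresholds,
                 featureId)
  if (is.null(bp)) return(out)
  out$base_label <- bp$label
  out$p_base <- bp$p_value
  out$base_threshold <- bp$threshold_pct

  vp <- withCallingHandlers(
    validationPlots(values, clinical, outcome, treatedIds, untreatedIds,
                    thresholds, featureId),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(vp)) return(out)
  if (!is.null(vp$up_val)) {
    out$up_val_label <- vp$up_val$label
    out$p_up_val <- vp$up_val$p_value
  }
  if (!is.null(vp$down_val)) {
    out$down_val_label <- vp$down_val$label
    out$p_down_val <- vp$down_val$p_value
  }
  matching <- if (bp$label == "UP") vp$up_val else vp$down_val
  if (is.null(matching)) return(out)

  labUp <- out$up_val_label
  labDown <- out$down_val_label
  # a missing non-matching validation plot leaves the filter decidable
  if (bp$label == "UP" && is.na(labDown)) labDown <- "UP"
  if (bp$label == "DOWN" && is.na(labUp)) labUp <- "DOWN"
  out$passed_filter <- !is.na(labUp) && !is.na(labDown) &&
    consistencyFilter(bp$label, labUp, labDown)
  v <- vpProduct(bp$p_value, matching$p_value, vpLimit)
  out$vp_product <- v$product
  out$is_candidate <- out$passed_filter && v$is_candidate
  out
}

#' Best DMR position per threshold
#'
#' For every CpG position of a region and every threshold value, the
#' base-plot Cox p-value is computed; for each threshold the position where
#' it performs best is recorded.  Downstream validation then evaluates each
#' recorded position.
#'
#' @param positions integer vector of 1-based CpG positions of the region.
#' @param betas full positions x patients beta matrix.
#' @param coords coordinate data.frame matching \code{betas} rows.
#' @param chrom chromosome of the region.
#' @inheritParams basePlot
#' @return data.frame with \code{threshold_pct}, \code{position},
#'   \code{p_value}; thresholds where no position admits a comparison are
#'   omitted.
#' @export
bestDmrPositions <- function(positions, betas, coords, chrom, clinical,
                             outcome, treatedIds, thresholds = 0) {
  rows <- which(coords$chrom == chrom & coords$pos %in% positions)
  if (!length(rows)) stop("no beta data for the requested positions")
  pmat <- matrix(NA_real_, nrow = length(rows), ncol = length(thresholds))
  for (j in seq_along(rows)) {
    v <- betas[rows[j], ]
    if (all(is.na(v))) next
    pt <- .basePvals(v, clinical, outcome, treatedIds, thresholds)
    pmat[j, ] <- pt$p_value
  }
  out <- lapply(seq_along(thresholds), function(k) {
    ok <- which(!is.na(pmat[, k]))
    if (!length(ok)) return(NULL)
    j <- ok[which.min(pmat[ok, k])]   # ties: leftmost position
    data.frame(threshold_pct = thresholds[k], position = coords$pos[rows[j]],
               p_value = pmat[j, k])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(threshold_pct = numeric(0), position = integer(0),
                      p_value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Rank evaluated markers by vp-product
#'
#' Keeps rows that passed the consistency filter and the vp-product limit and
#' sorts them by ascending vp-product (ties by feature id, then set id when
#' present).
#'
#' @param evals data.frame of \code{\link{evaluateMarker}} rows (typically
#'   with a \code{set_id} column added by the pipeline).
#' @return the ranked subset with a \code{rank} column.
#' @export
rankCandidates <- function(evals) {
  keep <- evals[!is.na(evals$vp_product) & evals$is_candidate, ,
                drop = FALSE]
  if (!nrow(keep)) {
    keep$rank <- integer(0)
    return(keep)
  }
  tieId <- if ("set_id" %in% names(keep)) keep$set_id else ""
  o <- order(keep$vp_product, keep$feature_id, tieId)
  keep <- keep[o, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}

.geomMean <- function(x) exp(mean(log(x)))

#' Per-set aggregation of ranked candidates
#'
#' For every case set with candidates: the geometric mean of the members'
#' vp-products and the member count, ordered by decreasing count (then by
#' geometric mean).
#'
#' @param ranked output of \code{\link{rankCandidates}} with a \code{set_id}
#'   column.
#' @return data.frame with \code{set_id}, \code{n_candidates},
#'   \code{geometric_mean_vp}.
#' @export
aggregateCandidates <- function(ranked) {
  if (!nrow(ranked))
    return(data.frame(set_id = character(0), n_candidates = integer(0),
                      geometric_mean_vp = numeric(0)))
  sp <- split(ranked$vp_product, ranked$set_id)
  out <- data.frame(set_id = names(sp),
                    n_candidates = vapply(sp, length, integer(1)),
                    geometric_mean_vp = vapply(sp, .geomMean, numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_candidates, out$geometric_mean_vp, out$set_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
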