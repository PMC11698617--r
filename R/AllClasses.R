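#' @import methods
NULL

#' CaseSet: one differential-analysis unit
#'
#' A \code{CaseSet} describes one unit of differential analysis: a selection
#' of cancer projects, a sex selector (\code{"female"}, \code{"male"} or
#' \code{"both"}), a survival cutoff in years, the patient ids matching the
#' selector, and -- once \code{\link{partitionByTreatment}} has been applied --
#' the disjoint treated/untreated partition of the members.
#'
#' @slot projects character vector of cancer-type codes (non-empty).
#' @slot sexSelector one of \code{"female"}, \code{"male"}, \code{"both"}.
#' @slot cutoffYears single non-negative numeric; survival cutoff in years.
#' @slot memberIds character vector of case ids in the set.
#' @slot treatedIds subset of \code{memberIds} treated with one of the
#'   requested drug combinations.
#' @slot untreatedIds the complement of \code{treatedIds} within the members.
#'
#' @aliases CaseSet
#' @exportClass CaseSet
setClass("CaseSet",
  representation(
    projects     = "character",
    sexSelector  = "character",
    cutoffYears  = "numeric",
    memberIds    = "character",
    treatedIds   = "character",
    untreatedIds = "character"
  ),
  prototype(treatedIds = character(0), untreatedIds = character(0))
)

setValidity("CaseSet", function(object) {
  msg <- character(0)
  if (length(object@projects) < 1L)
    msg <- c(msg, "'projects' must be non-empty")
  if (length(object@sexSelector) != 1L ||
      !object@sexSelector %in% c("female", "male", "both"))
    msg <- c(msg, "'sexSelector' must be one of female, male, both")
  if (length(object@cutoffYears) != 1L || is.na(object@cutoffYears) ||
      object@cutoffYears < 0)
    msg <- c(msg, "'cutoffYears' must be a single non-negative number")
  if (anyDuplicated(object@memberIds))
    msg <- c(msg, "duplicate member ids")
  if (!all(object@treatedIds %in% object@memberIds))
    msg <- c(msg, "treated ids must be members")
  if (!all(object@untreatedIds %in% object@memberIds))
    msg <- c(msg, "untreated ids must be members")
  if (length(intersect(object@treatedIds, object@untreatedIds)))
    msg <- c(msg, "treated and untreated ids must be disjoint")
  if (length(msg)) msg else TRUE
})

#' PivotStratification: UP/DOWN patient assignment around a pivot
#'
#' Records, for one feature, the mean-of-medians pivot, the exclusion-band
#' bounds derived from a percent threshold, and the resulting partition of
#' patients into UP, DOWN and excluded groups.
#'
#' @slot featureId feature identifier (may be \code{NA}).
#' @slot mom mean of the outcome-group medians (the pivot).
#' @slot thresholdPct percent half-width of the exclusion band (>= 0).
#' @slot boundL,boundU lower/upper band bounds; equal to \code{mom} at
#'   threshold 0.
#' @slot upIds,downIds,excludedIds the partition of the stratified patients.
#'
#' @aliases PivotStratification
#' @exportClass PivotStratification
setClass("PivotStratification",
  representation(
    featureId    = "character",
    mom          = "numeric",
    thresholdPct = "numeric",
    boundL       = "numeric",
    boundU       = "numeric",
    upIds        = "character",
    downIds      = "character",
    excludedIds  = "character"
  )
)

setValidity("PivotStratification", function(object) {
  msg <- character(0)
  if (length(object@mom) != 1L || !is.finite(object@mom))
    msg <- c(msg, "'mom' must be a single finite number")
  if (object@thresholdPct < 0)
    msg <- c(msg, "'thresholdPct' must be non-negative")
  if (!(object@boundL <= object@mom && object@mom <= object@boundU))
    msg <- c(msg, "bounds must bracket the pivot")
  ids <- c(object@upIds, object@downIds, object@excludedIds)
  if (anyDuplicated(ids))
    msg <- c(msg, "up/down/excluded groups must be disjoint")
  if (object@thresholdPct == 0 && length(object@excludedIds))
    msg <- c(msg, "threshold 0 must not exclude patients")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated cohort with ground truth
#'
#' Container returned by \code{\link{generateCohort}}: patient metadata in the
#' on-disk TSV dialect, a genes x patients count matrix, a CpG x patients
#' beta-value matrix with genomic coordinates, and the ground-truth tables
#' (planted markers, per-patient latent strata, true treatment assignment).
#'
#' @slot metadata data.frame in the metadata TSV dialect (raw, possibly
#'   misspelled drug strings).
#' @slot counts integer matrix, genes x patients.
#' @slot betas numeric matrix in [0,1], CpG positions x patients.
#' @slot coords data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   one row per row of \code{betas}.
#' @slot truth list with elements \code{markers}, \code{strata},
#'   \code{treated}, \code{hazard}, \code{drugs}.
#' @slot config the \code{simulationConfig} used.
#'
#' @aliases SyntheticCohort
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    metadata = "data.frame",
    counts   = "matrix",
    betas    = "matrix",
    coords   = "data.frame",
    truth    = "list",
    config   = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character(0)
  if (ncol(object@counts) &&
      !identical(colnames(object@counts), object@metadata$case_id))
    msg <- c(msg, "count columns must match metadata case ids")
  if (nrow(object@betas) != nrow(object@coords))
    msg <- c(msg, "one coordinate row per beta row required")
  if (nrow(object@betas) &&
      (min(object@betas) < 0 || max(object@betas) > 1))
    msg <- c(msg, "beta values must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
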