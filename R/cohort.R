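# Cohort construction: metadata ingestion, drug-name harmonization, outcome
# cutoff reclassification and the combinatorial case-set tree.

.normName <- function(x) tolower(trimws(x))

#' Harmonize drug names
#'
#' Normalizes raw drug names (trim whitespace, lowercase) and maps known
#' synonyms/misspellings onto canonical names.  Empty names are dropped with a
#' warning and returned as \code{NA}.
#'
#' @param raw character vector of raw drug names.
#' @param synonymMap named character vector mapping lowercase variants to
#'   lowercase canonical names, e.g. \code{c(cisplatinum = "cisplatin")}.
#' @return character vector of canonical names (\code{NA} for empty input).
#' @examples
#' harmonizeDrugNames("  Cisplatinum ", c(cisplatinum = "cisplatin"))
#' @export
harmonizeDrugNames <- function(raw, synonymMap = character(0)) {
  stopifnot(is.character(raw))
  if (length(synonymMap)) {
    if (is.null(names(synonymMap)) ||
        !identical(names(synonymMap), tolower(names(synonymMap))) ||
        !identical(unname(synonymMap), tolower(unname(synonymMap))))
      stop("synonymMap keys and values must be lowercase")
  }
  norm <- .normName(raw)
  empty <- !is.na(norm) & !nzchar(norm)
  if (any(empty))
    warning(sprintf("dropping %d empty drug name(s)", sum(empty)))
  norm[empty | is.na(norm)] <- NA_character_
  hit <- match(norm, names(synonymMap))
  has <- !is.na(hit)
  norm[has] <- unname(synonymMap[hit[has]])
  norm
}

#' Built-in drug-name synonym map
#'
#' A small map of common clinical-metadata spelling variants for the platinum
#' and taxane agents used in the examples.  Real analyses should extend it
#' with a study-specific map.
#'
#' @return named character vector (variant -> canonical), all lowercase.
#' @export
defaultDrugSynonyms <- function() {
  c("cisplatinum"        = "cisplatin",
    "cis-platin"         = "cisplatin",
    "cddp"               = "cisplatin",
    "carboplatinum"      = "carboplatin",
    "paraplatin"         = "carboplatin",
    "taxol"              = "paclitaxel",
    "paclitaxel (taxol)" = "paclitaxel",
    "5-fu"               = "fluorouracil",
    "5-fluorouracil"     = "fluorouracil")
}

# Split ";"-separated drug strings into canonical, sorted, unique drug sets.
.splitDrugs <- function(x, synonymMap = character(0)) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(x, function(s) {
    if (!nzchar(trimws(s))) return(character(0))
    h <- harmonizeDrugNames(strsplit(s, ";", fixed = TRUE)[[1]], synonymMap)
    sort(unique(h[!is.na(h)]))
  })
}

#' Read and harmonize patient metadata
#'
#' Reads the patient metadata table (TSV path or data.frame) with columns
#' \code{case_id}, \code{project}, \code{sex}, \code{vital_status},
#' \code{drugnames} (";"-separated), \code{age}, and either \code{time_years}
#' or the day-resolution pair \code{days_to_death} /
#' \code{days_to_last_followup} (converted by /365.25).  For dead patients the
#' time is survival-in-years, for alive patients years-to-last-followup.
#' Records with missing sex, vital status or time, or with a sex outside
#' female/male, are dropped with a warning.
#'
#' @param x file path or data.frame.
#' @param synonymMap drug-name synonym map, see
#'   \code{\link{harmonizeDrugNames}}.
#' @return data.frame with columns \code{case_id}, \code{project}, \code{sex},
#'   \code{vital_status}, \code{time_years}, \code{age} and a list-column
#'   \code{drugs} of canonical drug sets.
#' @export
readPatientMetadata <- function(x, synonymMap = defaultDrugSynonyms()) {
  md <- if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  need <- c("case_id", "project", "sex", "vital_status")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))

  md$sex <- .normName(md$sex)
  md$vital_status <- .normName(md$vital_status)

  if ("time_years" %in% names(md)) {
    time <- as.numeric(md$time_years)
  } else if (all(c("days_to_death", "days_to_last_followup") %in% names(md))) {
    dead <- md$vital_status == "dead"
    time <- ifelse(dead, as.numeric(md$days_to_death),
                   as.numeric(md$days_to_last_followup)) / 365.25
  } else {
    stop("metadata needs 'time_years' or 'days_to_death'/",
         "'days_to_last_followup' columns")
  }

  badSex <- !md$sex %in% c("female", "male")
  if (any(badSex))
    warning(sprintf("dropping %d record(s) with sex outside female/male",
                    sum(badSex)))
  incomplete <- is.na(time) | !md$vital_status %in% c("alive", "dead") |
    is.na(md$case_id) | !nzchar(md$case_id)
  if (any(incomplete & !badSex))
    warning(sprintf(
      "dropping %d record(s) with missing vital status, time or id",
      sum(incomplete & !badSex)))
  keep <- !badSex & !incomplete

  drugCol <- intersect(c("drugnames", "drugs"), names(md))[1]
  drugs <- if (!is.na(drugCol)) .splitDrugs(md[[drugCol]], synonymMap)
           else rep(list(character(0)), nrow(md))
  out <- data.frame(
    case_id = as.character(md$case_id),
    project = as.character(md$project),
    sex = md$sex,
    vital_status = md$vital_status,
    time_years = time,
    age = if ("age" %in% names(md)) as.numeric(md$age) else NA_real_,
    stringsAsFactors = FALSE
  )
  out$drugs <- drugs
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$time_years < 0))
    stop("negative survival/followup times in metadata")
  out
}

#' Reclassify outcomes with a survival cutoff
#'
#' Assigns each patient to the positive or negative outcome group.  With the
#' default cutoff of 0 this reproduces the vital status (alive = positive,
#' dead = negative); with a cutoff c > 0, dead patients who survived longer
#' than c years are reclassified into the positive group.  Alive patients are
#' always positive, regardless of followup length.
#'
#' @param patients data.frame as returned by \code{\link{readPatientMetadata}}
#'   (needs \code{case_id}, \code{vital_status}, \code{time_years}).
#' @param cutoffYears single non-negative number (years).
#' @return data.frame with columns \code{case_id}, \code{outcome_group}
#'   (\code{"positive"}/\code{"negative"}) and \code{cutoff_years}.
#' @export
applyCutoff <- function(patients, cutoffYears = 0) {
  if (length(cutoffYears) != 1L || is.na(cutoffYears) || cutoffYears < 0)
    stop("'cutoffYears' must be a single non-negative number")
  dead <- patients$vital_status == "dead"
  # the default cutoff 0 reproduces the raw vital-status grouping
  positive <- !dead | (cutoffYears > 0 & patients$time_years > cutoffYears)
  data.frame(
    case_id = patients$case_id,
    outcome_group = ifelse(positive, "positive", "negative"),
    cutoff_years = cutoffYears,
    stringsAsFactors = FALSE
  )
}

#' Dead-to-alive turnover across cutoff values
#'
#' Tabulates, for each cutoff, the sizes of the positive and negative outcome
#' groups, the number of dead patients reclassified into the positive group
#' relative to the default grouping, and the reclassification rate in percent
#' of the cohort.
#'
#' @inheritParams applyCutoff
#' @param cutoffs numeric vector of cutoffs; 0 is always included.
#' @return data.frame with one row per cutoff: \code{cutoff_years},
#'   \code{n_positive}, \code{n_negative}, \code{turnover}, \code{percent}.
#' @export
cutoffTurnover <- function(patients, cutoffs = 0) {
  cutoffs <- sort(unique(c(0, cutoffs)))
  n <- nrow(patients)
  base <- sum(applyCutoff(patients, 0)$outcome_group == "positive")
  rows <- lapply(cutoffs, function(cc) {
    oc <- applyCutoff(patients, cc)
    np <- sum(oc$outcome_group == "positive")
    data.frame(cutoff_years = cc, n_positive = np, n_negative = n - np,
               turnover = np - base, percent = (np - base) / n * 100)
  })
  do.call(rbind, rows)
}

.newCaseSet <- function(projects, sel, cutoff, ids) {
  new("CaseSet", projects = projects, sexSelector = sel,
      cutoffYears = cutoff, memberIds = sort(ids))
}

#' Build the combinatorial tree of case sets
#'
#' For every project, one case set is created per sex present plus a combined
#' set when both sexes are present (a single-sex project therefore yields
#' exactly one set).  With more than one project, pooled basket sets over all
#' projects are added for each sex selector with members (the combined pooled
#' set again requires both sexes in the pool).  The whole collection is
#' crossed with every cutoff value; the default cutoff 0 is always included.
#'
#' @inheritParams applyCutoff
#' @param projects character vector of project codes to use, in order.
#' @param cutoffs numeric vector of cutoffs (0 is added if absent).
#' @return list of \code{\link{CaseSet}} objects.
#' @examples
#' md <- data.frame(case_id = as.character(1:6),
#'                  project = c("A", "A", "B", "B", "B", "B"),
#'                  sex = c("female", "female", "female", "male",
#'                          "male", "female"),
#'                  vital_status = "alive", time_years = 1)
#' length(buildCaseSets(md, c("A", "B")))  # 7 sets
#' @export
buildCaseSets <- function(patients, projects = unique(patients$project),
                          cutoffs = 0) {
  if (!length(projects)) stop("'projects' must be non-empty")
  if (any(is.na(cutoffs)) || any(cutoffs < 0))
    stop("cutoffs must be non-negative")
  cutoffs <- sort(unique(c(0, cutoffs)))

  kept <- character(0)
  selectors <- list()
  for (p in projects) {
    pp <- patients[patients$project == p, , drop = FALSE]
    if (!nrow(pp)) {
      warning(sprintf("project '%s' has no patients; dropped", p))
      next
    }
    kept <- c(kept, p)
    sexes <- intersect(c("female", "male"), unique(pp$sex))
    sels <- c(sexes, if (length(sexes) == 2L) "both")
    for (sel in sels) {
      ids <- pp$case_id[if (sel == "both") TRUE else pp$sex == sel]
      selectors[[length(selectors) + 1L]] <- list(projects = p, sel = sel,
                                                  ids = ids)
    }
  }
  if (!length(kept)) stop("no project with patients")

  if (length(kept) > 1L) {
    pool <- patients[patients$project %in% kept, , drop = FALSE]
    sexes <- intersect(c("female", "male"), unique(pool$sex))
    sels <- c(sexes, if (length(sexes) == 2L) "both")
    for (sel in sels) {
      ids <- pool$case_id[if (sel == "both") TRUE else pool$sex == sel]
      selectors[[length(selectors) + 1L]] <- list(projects = kept, sel = sel,
                                                  ids = ids)
    }
  }

  sets <- list()
  for (s in selectors)
    for (cc in cutoffs)
      sets[[length(sets) + 1L]] <- .newCaseSet(s$projects, s$sel, cc, s$ids)
  sets
}

#' Partition a case set into treated and untreated patients
#'
#' A member counts as treated when its harmonized drug set matches one of the
#' requested drug combinations.  With \code{match = "exact"} (the default) the
#' patient's whole drug set must equal a combination -- combinations are
#' atomic units, so \code{c("carboplatin", "paclitaxel")} does not match a
#' patient treated with carboplatin alone.  With \code{match = "subset"} a
#' combination contained in the patient's drug set suffices.
#'
#' @param caseSet a \code{\link{CaseSet}}.
#' @inheritParams applyCutoff
#' @param drugCombos list of character vectors; each vector is one canonical
#'   drug combination.
#' @param match \code{"exact"} or \code{"subset"}.
#' @return the \code{CaseSet} with \code{treatedIds}/\code{untreatedIds}
#'   filled in.
#' @export
partitionByTreatment <- function(caseSet, patients, drugCombos,
                                 match = c("exact", "subset")) {
  match <- match.arg(match)
  if (!length(drugCombos)) stop("'drugCombos' must be non-empty")
  combos <- lapply(drugCombos, function(d) {
    d <- sort(unique(harmonizeDrugNames(as.character(d))))
    if (!length(d)) stop("empty drug combination")
    d
  })
  idx <- base::match(memberIds(caseSet), patients$case_id)
  if (anyNA(idx)) stop("case set members missing from metadata")
  drugs <- patients$drugs[idx]
  isTreated <- vapply(drugs, function(d) {
    any(vapply(combos, function(cmb) {
      if (match == "exact") setequal(d, cmb) else all(cmb %in% d)
    }, logical(1)))
  }, logical(1))
  ids <- memberIds(caseSet)
  initialize(caseSet, treatedIds = ids[isTreated],
             untreatedIds = ids[!isTreated])
}
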