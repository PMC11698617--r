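# Single-call pipeline driver: case-set construction -> differential
# features -> stratified survival validation -> vp-product ranking, with an
# on-disk per-(set, analysis) cache honouring no-overwrite/reuse semantics.

# Normalise a result block through a TSV text round-trip so that cached and
# freshly computed blocks are byte-identical when written again.
.roundtrip <- function(df) {
  if (is.null(df) || !nrow(df)) return(df)
  tc <- textConnection("rtbuf", "w", local = TRUE)
  utils::write.table(df, tc, sep = "\t", quote = FALSE, row.names = FALSE)
  close(tc)
  out <- utils::read.delim(text = paste(rtbuf, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  out
}

.emptyEvalBlock <- function() {
  data.frame(
    set_id = character(0), analysis = character(0), projects = character(0),
    sex = character(0), cutoff_years = numeric(0), feature_id = character(0),
    kind = character(0), effect = numeric(0), p_adjusted_diff = numeric(0),
    chrom = character(0), start = integer(0), end = integer(0),
    position = integer(0), base_label = character(0), p_base = numeric(0),
    base_threshold = numeric(0), up_val_label = character(0),
    p_up_val = numeric(0), down_val_label = character(0),
    p_down_val = numeric(0), passed_filter = logical(0),
    vp_product = numeric(0), is_candidate = logical(0),
    n_treated = integer(0), n_untreated = integer(0),
    stringsAsFactors = FALSE)
}

.evalBlockExpression <- function(set, patients, counts, thresholds, alpha,
                                 maxPerDirection, vpLimit) {
  members <- memberIds(set)
  treated <- treatedIds(set)
  clinical <- patients[match(members, patients$case_id), , drop = FALSE]
  outcome <- applyCutoff(clinical, cutoffYears(set))
  nc <- suppressWarnings(
    normalizeCounts(counts[, members, drop = FALSE]))
  # untreated patients are used exclusively in the validation step
  ocTreated <- outcome[outcome$case_id %in% treated, , drop = FALSE]
  if (length(unique(ocTreated$outcome_group)) < 2L) {
    message("set ", caseSetId(set),
            ": one treated outcome group is empty; skipped")
    return(.emptyEvalBlock())
  }
  de <- testDE(nc[, treated, drop = FALSE], ocTreated)
  cands <- selectCandidates(de, alpha, maxPerDirection)
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    fid <- cands$feature_id[i]
    ev <- evaluateMarker(nc[fid, ], clinical, outcome, treated,
                         untreatedIds(set), thresholds, vpLimit, fid)
    cbind(data.frame(set_id = caseSetId(set), analysis = "expression",
                     projects = paste(setProjects(set), collapse = "-"),
                     sex = sexSelector(set), cutoff_years = cutoffYears(set),
                     stringsAsFactors = FALSE),
          ev[, "feature_id", drop = FALSE],
          data.frame(kind = "gene", effect = cands$effect[i],
                     p_adjusted_diff = cands$p_adjusted[i],
                     chrom = NA_character_, start = NA_integer_,
                     end = NA_integer_, position = NA_integer_,
                     stringsAsFactors = FALSE),
          ev[, setdiff(names(ev), "feature_id"), drop = FALSE])
  })
  if (!length(rows)) return(.emptyEvalBlock())
  do.call(rbind, rows)
}

.evalBlockMethylation <- function(set, patients, betas, coords, thresholds,
                                  alpha, maxPerDirection, vpLimit, minCpgs,
                                  maxGap, minDelta) {
  members <- memberIds(set)
  treated <- treatedIds(set)
  clinical <- patients[match(members, patients$case_id), , drop = FALSE]
  outcome <- applyCutoff(clinical, cutoffYears(set))
  b <- betas[, members, drop = FALSE]
  ocTreated <- outcome[outcome$case_id %in% treated, , drop = FALSE]
  if (length(unique(ocTreated$outcome_group)) < 2L) {
    message("set ", caseSetId(set),
            ": one treated outcome group is empty; skipped")
    return(.emptyEvalBlock())
  }
  dmrs <- callDMRs(b[, treated, drop = FALSE], coords, ocTreated,
                   minCpgs, maxGap, minDelta)
  cands <- selectCandidates(dmrs, alpha, maxPerDirection)
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    bp <- bestDmrPositions(cands$positions[[i]], b, coords, cands$chrom[i],
                           clinical, outcome, treated, thresholds)
    for (pos in sort(unique(bp$position))) {
      v <- b[coords$chrom == cands$chrom[i] & coords$pos == pos, ]
      ev <- evaluateMarker(v, clinical, outcome, treated, untreatedIds(set),
                           thresholds, vpLimit, cands$feature_id[i])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(set_id = caseSetId(set), analysis = "methylation",
                   projects = paste(setProjects(set), collapse = "-"),
                   sex = sexSelector(set), cutoff_years = cutoffYears(set),
                   stringsAsFactors = FALSE),
        ev[, "feature_id", drop = FALSE],
        data.frame(kind = "dmr", effect = cands$effect[i],
                   p_adjusted_diff = cands$p_adjusted[i],
                   chrom = cands$chrom[i], start = cands$start[i],
                   end = cands$end[i], position = pos,
                   stringsAsFactors = FALSE),
        ev[, setdiff(names(ev), "feature_id"), drop = FALSE])
    }
  }
  if (!length(rows)) return(.emptyEvalBlock())
  do.call(rbind, rows)
}

#' Run the full biomarker-discovery pipeline
#'
#' Builds the combinatorial case sets from the metadata, partitions each by
#' treatment, runs the differential analysis on the treated members
#' (untreated patients enter only the validation step), scans thresholds and
#' evaluates every selected feature through base plot, validation plots,
#' label-consistency filter and vp-product, and finally ranks and aggregates
#' candidates.  The default cutoff 0 and threshold 0 are always included.
#' With \code{outDir} set, per-(set, analysis) result blocks are cached as
#' TSV under \code{outDir/cache}; existing blocks are reused, never
#' overwritten, so a rerun with an added cutoff equals a fresh run with the
#' union of cutoffs.
#'
#' @param metadata metadata TSV path or data.frame (see
#'   \code{\link{readPatientMetadata}}).
#' @param counts genes x patients count matrix (or TSV path); required for
#'   the expression analysis.
#' @param betas positions x patients beta matrix (or TSV path, in which case
#'   \code{betaCoords} is taken from the file); required for methylation.
#' @param betaCoords coordinate data.frame matching \code{betas}.
#' @param projects project codes to analyse (default: all in the metadata).
#' @param drugCombos list of canonical drug combinations defining
#'   "treated".
#' @param cutoffs,thresholds numeric vectors; 0 is always added.
#' @param analyses subset of \code{c("expression", "methylation")}.
#' @param synonymMap drug-name synonym map.
#' @param alpha,maxPerDirection candidate-selection parameters.
#' @param vpLimit vp-product candidate limit.
#' @param minCpgs,maxGap,minDelta DMR-caller parameters.
#' @param matchMode treatment matching, \code{"exact"} or \code{"subset"}.
#' @param outDir optional output/cache directory.
#' @return list of class \code{"markerPipelineResult"}: \code{evaluations}
#'   (all evaluated features), \code{ranked}, \code{summary},
#'   \code{sets} (per-set overview), \code{overview} (patient overview
#'   tables), \code{kmCurves}, \code{config}.
#' @export
runPipeline <- function(metadata, counts = NULL, betas = NULL,
                        betaCoords = NULL, projects = NULL, drugCombos,
                        cutoffs = 0, thresholds = 0,
                        analyses = c("expression", "methylation"),
                        synonymMap = defaultDrugSynonyms(), alpha = 0.05,
                        maxPerDirection = 60, vpLimit = 0.0025, minCpgs = 5,
                        maxGap = 300, minDelta = 0.1,
                        matchMode = c("exact", "subset"), outDir = NULL) {
  matchMode <- match.arg(matchMode)
  analyses <- match.arg(analyses, c("expression", "methylation"),
                        several.ok = TRUE)
  if (is.character(metadata) && !file.exists(metadata))
    stop("metadata file not found: ", metadata)
  patients <- readPatientMetadata(metadata, synonymMap)
  if (is.character(counts)) counts <- readCountMatrix(counts)
  if (is.character(betas)) {
    bm <- readBetaMatrix(betas)
    betas <- bm$betas
    betaCoords <- bm$coords
  }
  if ("expression" %in% analyses && is.null(counts))
    analyses <- setdiff(analyses, "expression")
  if ("methylation" %in% analyses && (is.null(betas) || is.null(betaCoords)))
    analyses <- setdiff(analyses, "methylation")
  if (!length(analyses)) stop("no analysis type has input data")

  if (is.null(projects)) projects <- unique(patients$project)
  cutoffs <- sort(unique(c(0, cutoffs)))
  thresholds <- sort(unique(c(0, thresholds)))

  sets <- buildCaseSets(patients, projects, cutoffs)
  sets <- lapply(sets, partitionByTreatment, patients = patients,
                 drugCombos = drugCombos, match = matchMode)

  cacheDir <- if (!is.null(outDir)) file.path(outDir, "cache")
  if (!is.null(cacheDir))
    dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)

  blocks <- list()
  setRows <- list()
  skipped <- character(0)
  for (set in sets) {
    setRows[[length(setRows) + 1L]] <- data.frame(
      set_id = caseSetId(set),
      projects = paste(setProjects(set), collapse = "-"),
      sex = sexSelector(set), cutoff_years = cutoffYears(set),
      n_members = length(memberIds(set)),
      n_treated = length(treatedIds(set)),
      n_untreated = length(untreatedIds(set)), stringsAsFactors = FALSE)
    if (!length(treatedIds(set))) {
      skipped <- c(skipped, caseSetId(set))
      next
    }
    for (an in analyses) {
      key <- paste0(caseSetId(set), "_", an)
      cacheFile <- if (!is.null(cacheDir))
        file.path(cacheDir, paste0(key, ".tsv"))
      if (!is.null(cacheFile) && file.exists(cacheFile)) {
        blk <- utils::read.delim(cacheFile, stringsAsFactors = FALSE,
                                 check.names = FALSE)
      } else {
        blk <- if (an == "expression") {
          .evalBlockExpression(set, patients, counts, thresholds, alpha,
                               maxPerDirection, vpLimit)
        } else {
          .evalBlockMethylation(set, patients, betas, betaCoords,
                                thresholds, alpha, maxPerDirection, vpLimit,
                                minCpgs, maxGap, minDelta)
        }
        blk <- .roundtrip(blk)
        if (!is.null(cacheFile) && !is.null(blk) && nrow(blk))
          utils::write.table(blk, cacheFile, sep = "\t", quote = FALSE,
                             row.names = FALSE)
      }
      if (!is.null(blk) && nrow(blk))
        blocks[[length(blocks) + 1L]] <- blk
    }
  }
  if (length(skipped))
    message("skipped (no treated patients): ", paste(skipped, collapse = ", "))

  evals <- if (length(blocks)) do.call(rbind, blocks) else .emptyEvalBlock()
  rownames(evals) <- NULL
  ranked <- rankCandidates(evals)
  res <- list(
    evaluations = evals,
    ranked = ranked,
    summary = aggregateCandidates(ranked),
    sets = do.call(rbind, setRows),
    overview = patientOverview(patients, drugCombos, synonymMap, matchMode),
    kmCurves = .rankedKmCurves(ranked, patients, counts, betas, betaCoords,
                               sets, thresholds),
    config = list(projects = projects, drugCombos = drugCombos,
                  cutoffs = cutoffs, thresholds = thresholds,
                  analyses = analyses, alpha = alpha,
                  maxPerDirection = maxPerDirection, vpLimit = vpLimit,
                  minCpgs = minCpgs, maxGap = maxGap, minDelta = minDelta,
                  matchMode = matchMode))
  class(res) <- "markerPipelineResult"
  res
}

#' @export
print.markerPipelineResult <- function(x, ...) {
  cat("Biomarker pipeline result\n")
  cat(sprintf("  case sets: %d (%d with treated patients)\n",
              nrow(x$sets), sum(x$sets$n_treated > 0)))
  cat(sprintf("  evaluated features: %d; candidates: %d\n",
              nrow(x$evaluations), nrow(x$ranked)))
  if (nrow(x$ranked)) {
    top <- utils::head(x$ranked[, c("set_id", "feature_id", "base_label",
                                    "vp_product")], 5)
    print(top, row.names = FALSE)
  }
  invisible(x)
}

# Base-plot KM curves (UP vs DOWN strata at the best threshold) for the top
# ranked candidates, for the report bundle.
.rankedKmCurves <- function(ranked, patients, counts, betas, betaCoords,
                            sets, thresholds, topN = 20) {
  empty <- data.frame(set_id = character(0), feature_id = character(0),
                      stratum = character(0), time = numeric(0),
                      survival = numeric(0), at_risk = integer(0),
                      n_events = integer(0))
  if (!nrow(ranked)) return(empty)
  setById <- stats::setNames(sets, vapply(sets, caseSetId, character(1)))
  out <- list()
  for (i in seq_len(min(nrow(ranked), topN))) {
    set <- setById[[ranked$set_id[i]]]
    if (is.null(set)) next
    members <- memberIds(set)
    treated <- treatedIds(set)
    clinical <- patients[match(members, patients$case_id), , drop = FALSE]
    outcome <- applyCutoff(clinical, cutoffYears(set))
    v <- if (ranked$analysis[i] == "expression") {
      nc <- suppressWarnings(normalizeCounts(counts[, members,
                                                    drop = FALSE]))
      nc[ranked$feature_id[i], ]
    } else {
      betas[betaCoords$chrom == ranked$chrom[i] &
              betaCoords$pos == ranked$position[i], members]
    }
    oc <- .outcomeVec(outcome)
    pos <- treated[oc[treated] == "positive"]
    neg <- treated[oc[treated] == "negative"]
    if (!length(pos) || !length(neg)) next
    mom <- meanOfMedians(v[pos], v[neg])
    s <- suppressWarnings(stratifyByPivot(v[treated], mom,
                                          ranked$base_threshold[i]))
    for (side in c("UP", "DOWN")) {
      ids <- if (side == "UP") upIds(s) else downIds(s)
      if (!length(ids)) next
      cl <- .clinicalLookup(patients, ids)
      km <- kmEstimate(cl$time, cl$event)
      if (!nrow(km)) next
      out[[length(out) + 1L]] <- cbind(
        data.frame(set_id = ranked$set_id[i],
                   feature_id = ranked$feature_id[i], stratum = side,
                   stringsAsFactors = FALSE), km)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Patient-overview tables
#'
#' Descriptive decomposition of the cohort: counts per vital status, sex,
#' project and treatment status (with a total row), a per-(project, sex) age
#' summary, and the survival listing (case-level times) that supports
#' choosing a data-based cutoff.
#'
#' @param patients metadata data.frame from
#'   \code{\link{readPatientMetadata}}.
#' @param drugCombos list of canonical drug combinations defining "treated".
#' @param synonymMap drug-name synonym map (applied to the combinations).
#' @param matchMode treatment matching mode.
#' @return list with \code{composition}, \code{ageSummary},
#'   \code{survivalListing}.
#' @export
patientOverview <- function(patients, drugCombos,
                            synonymMap = defaultDrugSynonyms(),
                            matchMode = "exact") {
  combos <- lapply(drugCombos, function(d)
    sort(unique(harmonizeDrugNames(as.character(d), synonymMap))))
  isTreated <- vapply(patients$drugs, function(d) {
    any(vapply(combos, function(cmb) {
      if (matchMode == "exact") setequal(d, cmb) else all(cmb %in% d)
    }, logical(1)))
  }, logical(1))

  cells <- expand.grid(vital_status = c("alive", "dead"),
                       sex = c("female", "male"),
                       project = sort(unique(patients$project)),
                       stringsAsFactors = FALSE)
  comp <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- patients$vital_status == cells$vital_status[i] &
      patients$sex == cells$sex[i] & patients$project == cells$project[i]
    data.frame(cells[i, ], n_treated = sum(sel & isTreated),
               n_untreated = sum(sel & !isTreated),
               stringsAsFactors = FALSE)
  }))
  comp <- comp[comp$n_treated + comp$n_untreated > 0, , drop = FALSE]
  total <- data.frame(vital_status = "total", sex = "", project = "",
                      n_treated = sum(comp$n_treated),
                      n_untreated = sum(comp$n_untreated),
                      stringsAsFactors = FALSE)
  comp <- rbind(comp, total)
  rownames(comp) <- NULL

  grp <- interaction(patients$project, patients$sex, drop = TRUE)
  ageSummary <- do.call(rbind, lapply(levels(grp), function(g) {
    a <- patients$age[grp == g]
    data.frame(group = g, n = length(a),
               min = suppressWarnings(min(a, na.rm = TRUE)),
               median = stats::median(a, na.rm = TRUE),
               mean = mean(a, na.rm = TRUE),
               max = suppressWarnings(max(a, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))

  listing <- patients[order(patients$vital_status, -patients$time_years),
                      c("case_id", "project", "sex", "vital_status",
                        "time_years")]
  rownames(listing) <- NULL
  list(composition = comp, ageSummary = ageSummary,
       survivalListing = listing)
}
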