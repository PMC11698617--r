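# Seeded synthetic cohorts emulating TCGA-like structure: negative-binomial
# counts, Beta-distributed methylation on synthetic chromosomes, exponential
# survival with independent exponential censoring, treatment assignment with
# noisy drug spellings, and planted treatment-specific / universal / null
# markers with per-patient ground truth.

#' Describe planted markers
#'
#' Builds the planted-marker table for \code{\link{simulationConfig}}.  A
#' \emph{treatment-specific} marker lowers the hazard of high-stratum
#' patients only when they are treated (interaction hazard ratio, default
#' 0.25); a \emph{universal} marker changes the hazard of high-stratum
#' patients regardless of treatment (stratum hazard ratio, default 0.4, i.e.
#' a strong prognostic program of the proliferation/stage-surrogate kind --
#' exactly the signal the validation stage exists to reject, and strong
#' enough for the differential step to discover it); a \emph{null} marker
#' has no
#' survival effect and no expression/methylation shift.
#'
#' @param nTreatmentSpecific,nUniversal,nNull marker counts.
#' @param kind \code{"gene"} or \code{"dmr"}.
#' @param stratumEffect hazard ratio of the high stratum for universal
#'   markers.
#' @param interactionEffect hazard ratio applied to treated high-stratum
#'   patients for treatment-specific markers.
#' @return data.frame with \code{kind}, \code{mechanism},
#'   \code{stratum_effect}, \code{interaction}.
#' @export
plantedMarkers <- function(nTreatmentSpecific = 2, nUniversal = 2,
                           nNull = 0, kind = "gene", stratumEffect = 0.4,
                           interactionEffect = 0.25) {
  stopifnot(kind %in% c("gene", "dmr"))
  total <- nTreatmentSpecific + nUniversal + nNull
  data.frame(
    kind = rep(kind, total),
    mechanism = rep(c("treatment_specific", "universal", "null"),
                    c(nTreatmentSpecific, nUniversal, nNull)),
    stratum_effect = rep(c(1, stratumEffect, 1),
                         c(nTreatmentSpecific, nUniversal, nNull)),
    interaction = rep(c(interactionEffect, 1, 1),
                      c(nTreatmentSpecific, nUniversal, nNull)),
    stringsAsFactors = FALSE)
}

#' Configure a synthetic cohort
#'
#' Collects every tunable of the generator with defaults chosen to resemble
#' a mid-sized multi-project tumour cohort: two projects of which one has
#' female cases only, exponential survival with a baseline hazard of
#' 0.15/year (median ~4.6 years), independent exponential censoring at
#' 0.1/year, half the patients treated with one of three platinum/taxane
#' combinations, and drug names corrupted at a stated rate with case/space
#' variants and known synonyms so that harmonization is exercised.
#'
#' @param projects named list: project code -> character vector of sexes
#'   available.
#' @param nPerCell patients per (project, sex) cell.
#' @param treatmentFraction probability that a patient received one of the
#'   requested combinations.
#' @param drugCombos list of canonical drug combinations under study.
#' @param misspellRate per-drug-token corruption probability.
#' @param nGenes,nbMeanRange,nbSizeRange gene count and negative-binomial
#'   mean (log-uniform) / size (uniform) ranges.
#' @param nCpgs,nChroms,betaConcentration CpG count, number of synthetic
#'   chromosomes and Beta-distribution concentration (a+b).
#' @param baselineHazard,censorRate exponential hazards per year.
#' @param exprLfc log2 fold-change of planted genes between latent strata.
#' @param betaDelta beta-value shift of planted DMRs in the high stratum.
#' @param dmrCpgs CpGs per planted DMR.
#' @param markers planted-marker table from \code{\link{plantedMarkers}}
#'   (rows of gene and/or dmr kind); may have zero rows.
#' @param seed integer seed fixing the full output.
#' @return a classed list (\code{"simulationConfig"}).
#' @export
simulationConfig <- function(projects = list("SYN-A" = "female",
                                             "SYN-B" = c("female", "male")),
                             nPerCell = 100,
                             treatmentFraction = 0.5,
                             drugCombos = list("cisplatin",
                                               c("carboplatin", "paclitaxel"),
                                               "carboplatin"),
                             misspellRate = 0.15,
                             nGenes = 200,
                             nbMeanRange = c(20, 2000),
                             nbSizeRange = c(2, 10),
                             nCpgs = 200,
                             nChroms = 2,
                             betaConcentration = 30,
                             baselineHazard = 0.15,
                             censorRate = 0.1,
                             exprLfc = 2,
                             betaDelta = 0.3,
                             dmrCpgs = 8,
                             markers = rbind(plantedMarkers(2, 2, 0, "gene"),
                                             plantedMarkers(1, 1, 0, "dmr")),
                             seed = 1L) {
  stopifnot(length(projects) >= 1, !is.null(names(projects)),
            treatmentFraction >= 0, treatmentFraction <= 1,
            misspellRate >= 0, misspellRate <= 1,
            baselineHazard > 0, censorRate >= 0,
            nPerCell >= 1, nGenes >= 1, nCpgs >= 1)
  bad <- vapply(projects, function(s) !all(s %in% c("female", "male")),
                logical(1))
  if (any(bad)) stop("project sexes must be female/male")
  if (nrow(markers) && sum(markers$kind == "gene") > nGenes)
    stop("more planted gene markers than genes")
  structure(as.list(environment()), class = "simulationConfig")
}

# spelling corruptions recoverable by trim/lowercase + defaultDrugSynonyms()
.misspell <- function(drug) {
  variants <- c(toupper(drug),
                paste0(toupper(substr(drug, 1, 1)), substr(drug, 2, 1e6)),
                paste0(drug, " "), paste0("  ", drug))
  syn <- defaultDrugSynonyms()
  variants <- c(variants, names(syn)[syn == drug])
  sample(variants, 1L)
}

.backgroundDrugSets <- function() {
  list(character(0), character(0), "docetaxel", "gemcitabine",
       c("docetaxel", "gemcitabine"), "fluorouracil", "cetuximab",
       "paclitaxel")   # paclitaxel alone is NOT one of the studied combos
}

#' Generate a synthetic cohort with planted markers
#'
#' Draws a full cohort under \code{\link{simulationConfig}}: patients per
#' (project, sex) cell; treatment assignment with misspelled drug strings;
#' per-patient latent high/low strata for every planted marker; exponential
#' survival times with hazard
#' \code{baseline * stratum_effect^high * interaction^(high & treated)}
#' multiplied over the planted markers; independent exponential censoring;
#' negative-binomial counts (planted genes shifted by \code{exprLfc} in the
#' high stratum) and Beta-distributed beta values (planted DMRs shifted by
#' \code{betaDelta}).  The seed fixes the complete output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\link{SyntheticCohort}}.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)

  cells <- do.call(rbind, lapply(names(config$projects), function(p) {
    data.frame(project = p, sex = config$projects[[p]],
               stringsAsFactors = FALSE)
  }))
  n <- nrow(cells) * config$nPerCell
  meta <- data.frame(
    case_id = sprintf("case_%04d", seq_len(n)),
    project = rep(cells$project, each = config$nPerCell),
    sex = rep(cells$sex, each = config$nPerCell),
    stringsAsFactors = FALSE)

  treated <- stats::runif(n) < config$treatmentFraction
  comboIdx <- rep(NA_integer_, n)
  comboIdx[treated] <- sample.int(length(config$drugCombos),
                                  sum(treated), replace = TRUE)
  bg <- .backgroundDrugSets()
  bgIdx <- sample.int(length(bg), n, replace = TRUE)
  drugsClean <- lapply(seq_len(n), function(i) {
    if (treated[i]) sort(unique(as.character(
      config$drugCombos[[comboIdx[i]]])))
    else sort(unique(bg[[bgIdx[i]]]))
  })
  drugsRaw <- vapply(drugsClean, function(d) {
    if (!length(d)) return("")
    noisy <- vapply(d, function(x) {
      if (stats::runif(1) < config$misspellRate) .misspell(x) else x
    }, character(1))
    paste(noisy, collapse = ";")
  }, character(1))

  # planted markers and latent strata.  Markers sharing a survival mechanism
  # form one co-regulated program with a single latent high/low stratum
  # (independent markers with strong effects would stack into a degenerate
  # frailty that erases every marginal effect); null markers draw
  # independent strata.
  markers <- config$markers
  nMark <- if (is.null(markers)) 0L else nrow(markers)
  strata <- matrix(logical(0), nrow = n, ncol = 0)
  if (nMark) {
    if (is.null(markers$group))
      markers$group <- ifelse(markers$mechanism == "null",
                              paste0("null_", seq_len(nMark)),
                              markers$mechanism)
    groups <- unique(markers$group)
    groupStrata <- matrix(stats::runif(n * length(groups)) < 0.5, nrow = n,
                          dimnames = list(NULL, groups))
    strata <- groupStrata[, markers$group, drop = FALSE]
    markers$feature_id <- NA_character_
    markers$chrom <- NA_character_
    markers$start <- NA_integer_
    markers$end <- NA_integer_
  }

  # survival: multiplicative hazards, one factor per mechanism group.  The
  # planted effects are relative hazard ratios; the per-patient factors are
  # recentred by their cohort geometric mean so that the overall death rate
  # stays at the configured baseline.
  hazard <- rep(config$baselineHazard, n)
  if (nMark) {
    logf <- rep(0, n)
    for (g in unique(markers$group)) {
      m <- which(markers$group == g)[1]
      if (markers$mechanism[m] == "null") next
      high <- strata[, m]
      logf <- logf + log(markers$stratum_effect[m]) * high +
        log(markers$interaction[m]) * (high & treated)
    }
    hazard <- hazard * exp(logf - mean(logf))
  }
  tDeath <- stats::rexp(n, hazard)
  tCens <- if (config$censorRate > 0) stats::rexp(n, config$censorRate)
           else rep(Inf, n)
  meta$vital_status <- ifelse(tDeath <= tCens, "dead", "alive")
  meta$time_years <- round(pmin(tDeath, tCens), 6)
  meta$time_years[meta$time_years == 0] <- 1e-6
  meta$drugnames <- drugsRaw
  meta$age <- pmin(90, pmax(20, round(stats::rnorm(n, 62, 11))))

  # counts
  geneIds <- sprintf("gene_%04d", seq_len(config$nGenes))
  isGeneMarker <- which(nMark > 0 & markers$kind == "gene")
  if (length(isGeneMarker)) {
    slots <- sample.int(config$nGenes, length(isGeneMarker))
    markers$feature_id[isGeneMarker] <- geneIds[slots]
  }
  mu <- exp(stats::runif(config$nGenes, log(config$nbMeanRange[1]),
                         log(config$nbMeanRange[2])))
  size <- stats::runif(config$nGenes, config$nbSizeRange[1],
                       config$nbSizeRange[2])
  counts <- matrix(0L, nrow = config$nGenes, ncol = n,
                   dimnames = list(geneIds, meta$case_id))
  for (g in seq_len(config$nGenes)) {
    m <- match(geneIds[g], markers$feature_id)
    muG <- rep(mu[g], n)
    if (!is.na(m) && markers$mechanism[m] != "null")
      muG <- muG * 2^(config$exprLfc * strata[, m])
    counts[g, ] <- stats::rnbinom(n, mu = muG, size = size[g])
  }

  # methylation
  perChrom <- diff(round(seq(0, config$nCpgs, length.out =
                               config$nChroms + 1)))
  coords <- do.call(rbind, lapply(seq_len(config$nChroms), function(k) {
    if (perChrom[k] == 0) return(NULL)
    data.frame(chrom = sprintf("chrS%d", k),
               pos = 10000L + cumsum(sample(30:300, perChrom[k],
                                            replace = TRUE)),
               stringsAsFactors = FALSE)
  }))
  isDmrMarker <- which(nMark > 0 & markers$kind == "dmr")
  dmrRows <- vector("list", length(isDmrMarker))
  if (length(isDmrMarker)) {
    if (length(isDmrMarker) * config$dmrCpgs > nrow(coords))
      stop("not enough CpGs for the planted DMRs")
    # non-overlapping blocks of consecutive positions
    blockStarts <- seq(1L, by = config$dmrCpgs, length.out =
                         length(isDmrMarker))
    avail <- nrow(coords) - length(isDmrMarker) * config$dmrCpgs
    offsets <- sort(sample.int(max(avail, 1L), length(isDmrMarker),
                               replace = TRUE))
    for (k in seq_along(isDmrMarker)) {
      st <- blockStarts[k] + offsets[k] - 1L
      rows <- st:(st + config$dmrCpgs - 1L)
      # keep a block within one chromosome
      if (length(unique(coords$chrom[rows])) > 1L) {
        ch <- coords$chrom[rows[1]]
        last <- max(which(coords$chrom == ch))
        rows <- (last - config$dmrCpgs + 1L):last
      }
      dmrRows[[k]] <- rows
      m <- isDmrMarker[k]
      markers$feature_id[m] <- sprintf("%s:%d-%d", coords$chrom[rows[1]],
                                       coords$pos[rows[1]],
                                       coords$pos[rows[length(rows)]])
      markers$chrom[m] <- coords$chrom[rows[1]]
      markers$start[m] <- coords$pos[rows[1]] - 1L
      markers$end[m] <- coords$pos[rows[length(rows)]]
    }
  }
  mBeta <- stats::runif(nrow(coords), 0.1, 0.9)
  betas <- matrix(0, nrow = nrow(coords), ncol = n,
                  dimnames = list(paste0(coords$chrom, ":", coords$pos),
                                  meta$case_id))
  shift <- matrix(0, nrow = nrow(coords), ncol = n)
  for (k in seq_along(isDmrMarker)) {
    m <- isDmrMarker[k]
    if (markers$mechanism[m] != "null")
      shift[dmrRows[[k]], strata[, m]] <- config$betaDelta
  }
  for (j in seq_len(nrow(coords))) {
    mj <- pmin(0.98, pmax(0.02, mBeta[j] + shift[j, ]))
    betas[j, ] <- stats::rbeta(n, mj * config$betaConcentration,
                               (1 - mj) * config$betaConcentration)
  }

  if (nMark) colnames(strata) <- markers$feature_id
  rownames(strata) <- meta$case_id
  truth <- list(
    markers = markers,
    strata = strata,
    treated = stats::setNames(treated, meta$case_id),
    hazard = stats::setNames(hazard, meta$case_id),
    drugs = stats::setNames(drugsClean, meta$case_id))

  new("SyntheticCohort", metadata = meta, counts = counts, betas = betas,
      coords = coords, truth = truth, config = unclass(config))
}

#' Write a synthetic cohort to the on-disk TSV dialects
#'
#' Writes \code{metadata.tsv}, \code{counts.tsv} (first column gene id),
#' \code{betas.tsv} (chrom, pos, then patients) and the ground-truth tables
#' \code{truth_markers.tsv} and \code{truth_strata.tsv}.
#'
#' @param cohort a \code{\link{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    w(cohortMetadata(cohort), "metadata.tsv"),
    w(data.frame(gene_id = rownames(cohortCounts(cohort)),
                 cohortCounts(cohort), check.names = FALSE),
      "counts.tsv"),
    w(cbind(cohortCoords(cohort),
            as.data.frame(cohortBetas(cohort), check.names = FALSE)),
      "betas.tsv"))
  truth <- cohortTruth(cohort)
  if (!is.null(truth$markers) && nrow(truth$markers))
    paths <- c(paths, w(truth$markers, "truth_markers.tsv"),
               w(data.frame(case_id = rownames(truth$strata),
                            truth$strata, check.names = FALSE),
                 "truth_strata.tsv"))
  invisible(paths)
}
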