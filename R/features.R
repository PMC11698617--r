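# Differential-feature contract: normalization, built-in stand-in scorers for
# expression and methylation, backend-result ingestion and the 60-per-direction
# candidate selection rule.

#' Read a gene-level count matrix
#'
#' TSV with the gene id in the first column and one column per patient.
#'
#' @param path file path.
#' @return integer matrix genes x patients with dimnames.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Read a CpG beta-value matrix
#'
#' TSV with columns \code{chrom}, \code{pos} followed by one column per
#' patient.
#'
#' @param path file path.
#' @return list with \code{betas} (matrix positions x patients) and
#'   \code{coords} (data.frame chrom, pos).
#' @export
readBetaMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(df)[1:2]))
  betas <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(betas) <- paste0(df$chrom, ":", df$pos)
  list(betas = betas,
       coords = data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                           stringsAsFactors = FALSE))
}

#' Library-size normalize a count matrix
#'
#' Counts-per-million per patient followed by log2(x + 1).  Patients with an
#' all-zero library are dropped with a warning.  This scale is used for the
#' pivot stratification of expression features.
#'
#' @param counts non-negative genes x patients matrix.
#' @return numeric matrix of log2(CPM + 1) values.
#' @export
normalizeCounts <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  libs <- colSums(counts)
  zero <- libs == 0
  if (all(zero)) stop("all libraries are empty")
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero librar%s",
                    sum(zero), if (sum(zero) == 1) "y" else "ies"))
    counts <- counts[, !zero, drop = FALSE]
    libs <- libs[!zero]
  }
  log2(sweep(counts, 2, libs, "/") * 1e6 + 1)
}

# Named outcome vector ("positive"/"negative") from applyCutoff output or a
# named character vector.
.outcomeVec <- function(outcome) {
  if (is.data.frame(outcome)) {
    v <- outcome$outcome_group
    names(v) <- outcome$case_id
  } else {
    v <- outcome
  }
  stopifnot(!is.null(names(v)), all(v %in% c("positive", "negative")))
  v
}

# Two-sided rank-sum p-value (normal approximation with continuity
# correction); constant input yields p = 1.
.rankSumP <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

#' Built-in differential-expression stand-in
#'
#' Scores each gene with a two-sided rank-sum test between the positive and
#' negative outcome groups on the normalized scale, reports the effect as
#' log2((mean_pos + 1) / (mean_neg + 1)) and adjusts p-values with
#' Benjamini-Hochberg.  This is a simple, dependency-free stand-in honoring
#' the backend result contract; precomputed results from a dedicated
#' differential-expression tool can be supplied via
#' \code{\link{readFeatureResults}} instead.
#'
#' @param normCounts matrix from \code{\link{normalizeCounts}}.
#' @param outcome outcome assignment (data.frame from
#'   \code{\link{applyCutoff}} or named character vector).
#' @return data.frame of feature results: \code{feature_id}, \code{kind},
#'   \code{effect}, \code{p_value}, \code{p_adjusted}, \code{direction}.
#' @export
testDE <- function(normCounts, outcome) {
  oc <- .outcomeVec(outcome)
  oc <- oc[names(oc) %in% colnames(normCounts)]
  posIds <- names(oc)[oc == "positive"]
  negIds <- names(oc)[oc == "negative"]
  if (!length(posIds) || !length(negIds))
    stop("both outcome groups must be non-empty")
  xp <- normCounts[, posIds, drop = FALSE]
  xn <- normCounts[, negIds, drop = FALSE]
  p <- vapply(seq_len(nrow(normCounts)),
              function(i) .rankSumP(xp[i, ], xn[i, ]), numeric(1))
  effect <- log2((rowMeans(xp) + 1) / (rowMeans(xn) + 1))
  data.frame(
    feature_id = rownames(normCounts),
    kind = "gene",
    effect = effect,
    p_value = p,
    p_adjusted = stats::p.adjust(p, method = "BH"),
    direction = ifelse(effect > 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Built-in DMR caller stand-in
#'
#' A deliberately simple region caller: CpG positions whose mean beta
#' difference between outcome groups reaches \code{minDelta} act as seeds;
#' consecutive seeds on the same chromosome at most \code{maxGap} bp apart are
#' merged, and merged runs with at least \code{minCpgs} seeds become regions.
#' Each region is scored with a rank-sum test on the per-patient mean beta
#' over its seed positions; the effect is the mean methylation difference
#' (mmd) of those region means, and p-values are BH-adjusted across regions.
#' Region coordinates are stored 0-based half-open; ids are printed 1-based.
#'
#' @param betas positions x patients matrix of beta values in [0,1].
#' @param coords data.frame with \code{chrom}, \code{pos} (1-based, strictly
#'   increasing within each chromosome), one row per row of \code{betas}.
#' @param outcome outcome assignment, see \code{\link{testDE}}.
#' @param minCpgs minimum number of seed CpGs per region.
#' @param maxGap maximum distance (bp) between consecutive seeds.
#' @param minDelta minimum absolute group mean difference for a seed.
#' @return data.frame of feature results with additional columns
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{n_cpgs} and list-column \code{positions} (1-based seed positions).
#' @export
callDMRs <- function(betas, coords, outcome, minCpgs = 5, maxGap = 300,
                     minDelta = 0.1) {
  stopifnot(nrow(betas) == nrow(coords))
  for (ch in unique(coords$chrom)) {
    pp <- coords$pos[coords$chrom == ch]
    if (any(diff(pp) <= 0))
      stop("positions must be strictly increasing within a chromosome")
  }
  empty <- data.frame(
    feature_id = character(0), kind = character(0), effect = numeric(0),
    p_value = numeric(0), p_adjusted = numeric(0), direction = character(0),
    chrom = character(0), start = integer(0), end = integer(0),
    n_cpgs = integer(0), stringsAsFactors = FALSE)
  empty$positions <- list()
  if (nrow(betas) < minCpgs) return(empty)

  oc <- .outcomeVec(outcome)
  oc <- oc[names(oc) %in% colnames(betas)]
  posIds <- names(oc)[oc == "positive"]
  negIds <- names(oc)[oc == "negative"]
  if (!length(posIds) || !length(negIds))
    stop("both outcome groups must be non-empty")

  delta <- rowMeans(betas[, posIds, drop = FALSE]) -
    rowMeans(betas[, negIds, drop = FALSE])
  seed <- which(abs(delta) >= minDelta)
  if (!length(seed)) return(empty)

  # split seeds into runs: same chromosome, gap <= maxGap
  ch <- coords$chrom[seed]
  pos <- coords$pos[seed]
  brk <- c(TRUE, ch[-1] != ch[-length(ch)] | diff(pos) > maxGap)
  runId <- cumsum(brk)
  rows <- list()
  for (r in split(seed, runId)) {
    if (length(r) < minCpgs) next
    rpos <- coords$pos[r]
    regionMeans <- colMeans(betas[r, , drop = FALSE])
    mmd <- mean(regionMeans[posIds]) - mean(regionMeans[negIds])
    p <- .rankSumP(regionMeans[posIds], regionMeans[negIds])
    chrom <- coords$chrom[r[1]]
    row <- data.frame(
      feature_id = sprintf("%s:%d-%d", chrom, min(rpos), max(rpos)),
      kind = "dmr", effect = mmd, p_value = p, p_adjusted = NA_real_,
      direction = if (mmd > 0) "up" else "down",
      chrom = chrom, start = min(rpos) - 1L, end = max(rpos),
      n_cpgs = length(r), stringsAsFactors = FALSE)
    row$positions <- list(rpos)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read precomputed feature results from an external backend
#'
#' Ingests a TSV carrying the feature-result contract columns
#' (\code{feature_id}, \code{kind}, \code{effect}, \code{p_value},
#' \code{p_adjusted}, optionally \code{chrom}/\code{start}/\code{end}/
#' \code{n_cpgs} for regions).  \code{direction} is derived from the effect
#' sign when absent.
#'
#' @param path file path.
#' @return data.frame of feature results.
#' @export
readFeatureResults <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "kind", "effect", "p_value", "p_adjusted")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("result table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"direction" %in% names(df))
    df$direction <- ifelse(df$effect > 0, "up", "down")
  df
}

#' Select candidate features for survival analysis
#'
#' Keeps features with adjusted p-value below \code{alpha}, splits them by
#' effect direction and, within each direction, retains at most
#' \code{maxPerDirection} features with the smallest adjusted p-values
#' (ties broken by larger absolute effect, then feature id).
#'
#' @param results feature-result data.frame (\code{\link{testDE}},
#'   \code{\link{callDMRs}} or \code{\link{readFeatureResults}}).
#' @param alpha significance level on the adjusted p-value.
#' @param maxPerDirection cap per direction (default 60).
#' @return data.frame of selected features (possibly empty).
#' @export
selectCandidates <- function(results, alpha = 0.05, maxPerDirection = 60) {
  sig <- results[!is.na(results$p_adjusted) & results$p_adjusted < alpha, ,
                 drop = FALSE]
  if (!nrow(sig)) return(sig)
  pick <- function(dir) {
    d <- sig[sig$direction == dir, , drop = FALSE]
    if (!nrow(d)) return(d)
    o <- order(d$p_adjusted, -abs(d$effect), d$feature_id)
    d[o[seq_len(min(nrow(d), maxPerDirection))], , drop = FALSE]
  }
  out <- rbind(pick("up"), pick("down"))
  rownames(out) <- NULL
  out
}

#' Feature results as genomic ranges
#'
#' Converts region-type feature results (DMRs) into a \code{GRanges} object
#' (1-based closed intervals, as displayed in reports).
#'
#' @param results feature-result data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @return a \code{GenomicRanges::GRanges} with the remaining columns as
#'   metadata.
#' @export
featureRanges <- function(results) {
  d <- results[results$kind == "dmr", , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end))
  mcols <- d[, c("feature_id", "effect", "p_value", "p_adjusted",
                 "direction", "n_cpgs"), drop = FALSE]
  GenomicRanges::mcols(gr) <- mcols
  names(gr) <- d$feature_id
  gr
}
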