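test_that("CPM/log2 normalization follows the stated formula", {
  counts <- matrix(c(1, 999999), ncol = 1,
                   dimnames = list(c("g1", "g2"), "p1"))
  nc <- normalizeCounts(counts)
  expect_equal(nc["g1", "p1"], 1)          # 1 read in a 1e6 library
  expect_equal(normalizeCounts(matrix(c(0, 10), 2, 1,
                                      dimnames = list(c("a", "b"),
                                                      "p")))["a", "p"], 0)
  # equal counts across equal libraries give identical normalized values
  eq <- matrix(5, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_true(all(normalizeCounts(eq) == normalizeCounts(eq)[1, 1]))
  # all-zero libraries are dropped
  z <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("p1", "p2")))
  expect_warning(nz <- normalizeCounts(z), "all-zero")
  expect_identical(colnames(nz), "p1")
  expect_error(normalizeCounts(matrix(0, 2, 2)), "empty")
})

test_that("adjusted p-values agree with a brute-force BH oracle", {
  set.seed(21)
  for (m in c(4, 17, 100)) {
    vals <- matrix(rnorm(m * 20, mean = 5), nrow = m,
                   dimnames = list(paste0("g", seq_len(m)),
                                   paste0("p", 1:20)))
    oc <- setNames(rep(c("positive", "negative"), each = 10),
                   colnames(vals))
    de <- testDE(vals, oc)
    expect_equal(de$p_adjusted, bhOracle(de$p_value), tolerance = 1e-12)
    # monotone in the raw p ranks
    o <- order(de$p_value)
    expect_true(all(diff(de$p_adjusted[o]) >= -1e-12))
  }
  expect_equal(bhOracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("rank-sum DE flags planted shifts and is silent on constants", {
  vals <- matrix(3, nrow = 2, ncol = 8,
                 dimnames = list(c("g1", "g2"), paste0("p", 1:8)))
  oc <- setNames(rep(c("positive", "negative"), each = 4), paste0("p", 1:8))
  de <- testDE(vals, oc)
  expect_equal(de$p_value, c(1, 1))   # constant genes carry no signal
  expect_equal(de$effect, c(0, 0))

  # planted 4-fold (2 log2 units) shifted gene, n = 30 per group
  set.seed(31)
  hits <- vapply(1:200, function(r) {
    m <- matrix(rnorm(20 * 60, mean = 5), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("p", 1:60)))
    m[1, 1:30] <- m[1, 1:30] + 2
    oc <- setNames(rep(c("positive", "negative"), each = 30),
                   colnames(m))
    de <- testDE(m, oc)
    de$p_adjusted[de$feature_id == "g1"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the DMR stand-in recovers planted regions and respects gates", {
  set.seed(41)
  n <- 40
  ids <- paste0("p", seq_len(n))
  oc <- setNames(rep(c("positive", "negative"), each = n / 2), ids)
  coords <- data.frame(chrom = "chr1",
                       pos = cumsum(sample(50:150, 30, replace = TRUE)))
  base <- matrix(rbeta(30 * n, 8, 12), nrow = 30,
                 dimnames = list(paste0(coords$chrom, ":", coords$pos), ids))

  # identical group distributions: no seeds, no regions
  expect_identical(nrow(callDMRs(base, coords, oc)), 0L)

  # planted region of 8 CpGs with delta-beta 0.3 in the positive group
  planted <- base
  planted[10:17, oc == "positive"] <-
    pmin(base[10:17, oc == "positive"] + 0.3, 1)
  dmr <- callDMRs(planted, coords, oc, minCpgs = 5, minDelta = 0.1,
                  maxGap = 300)
  expect_identical(nrow(dmr), 1L)
  expect_equal(dmr$start, coords$pos[10] - 1L)
  expect_equal(dmr$end, coords$pos[17])
  expect_identical(dmr$n_cpgs, 8L)
  expect_gt(dmr$effect, 0.2)
  expect_identical(dmr$direction, "up")

  # one isolated seed below minCpgs yields nothing
  iso <- base
  iso[5, oc == "positive"] <- pmin(base[5, oc == "positive"] + 0.4, 1)
  expect_identical(nrow(callDMRs(iso, coords, oc, minCpgs = 5)), 0L)

  # fewer positions than minCpgs yields an empty result
  expect_identical(nrow(callDMRs(base[1:3, , drop = FALSE], coords[1:3, ],
                                 oc, minCpgs = 5)), 0L)
})

test_that("candidate selection caps at 60 per direction deterministically", {
  set.seed(51)
  res <- data.frame(
    feature_id = sprintf("f%03d", 1:150),
    kind = "gene",
    effect = c(runif(80, 0.5, 3), -runif(70, 0.5, 3)),
    p_value = runif(150, 0, 0.01),
    stringsAsFactors = FALSE)
  res$p_adjusted <- res$p_value * 2
  res$direction <- ifelse(res$effect > 0, "up", "down")
  sel <- selectCandidates(res)
  expect_identical(sum(sel$direction == "up"), 60L)
  expect_identical(sum(sel$direction == "down"), 60L)
  up <- res[res$direction == "up", ]
  expect_setequal(sel$feature_id[sel$direction == "up"],
                  up$feature_id[order(up$p_adjusted)][1:60])
  # permutation invariance
  perm <- res[sample(nrow(res)), ]
  sel2 <- selectCandidates(perm)
  expect_identical(sel$feature_id[order(sel$feature_id)],
                   sel2$feature_id[order(sel2$feature_id)])
  # alpha gate
  none <- res; none$p_adjusted <- 0.2
  expect_identical(nrow(selectCandidates(none)), 0L)
  expect_identical(nrow(selectCandidates(res[0, ])), 0L)
  # ties broken by |effect| then id
  tie <- data.frame(feature_id = c("b", "a", "c"), kind = "gene",
                    effect = c(1, 2, 2), p_value = 0.001,
                    p_adjusted = 0.01, direction = "up",
                    stringsAsFactors = FALSE)
  expect_identical(selectCandidates(tie, maxPerDirection = 2)$feature_id,
                   c("a", "c"))
})

test_that("DMR results convert to 1-based genomic ranges", {
  d <- data.frame(feature_id = "chr2:101-200", kind = "dmr", effect = 0.2,
                  p_value = 0.001, p_adjusted = 0.01, direction = "up",
                  chrom = "chr2", start = 100L, end = 200L, n_cpgs = 6L,
                  stringsAsFactors = FALSE)
  gr <- featureRanges(d)
  expect_s4_class(gr, "GRanges")
  expect_equal(GenomicRanges::start(gr), 101)
  expect_equal(GenomicRanges::end(gr), 200)
})
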