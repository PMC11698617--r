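test_that("the label-consistency filter passes exactly four compositions", {
  labs <- c("UP", "DOWN")
  grid <- expand.grid(base = labs, up = labs, down = labs,
                      stringsAsFactors = FALSE)
  pass <- consistencyFilter(grid$base, grid$up, grid$down)
  expect_identical(sum(pass), 4L)
  passed <- grid[pass, ]
  expect_true(all(passed$up[passed$base == "UP"] == "UP"))
  expect_true(all(passed$down[passed$base == "DOWN"] == "DOWN"))
  # the spec rows
  expect_true(consistencyFilter("UP", "UP", "DOWN"))
  expect_false(consistencyFilter("UP", "DOWN", "UP"))
  expect_true(consistencyFilter("DOWN", "UP", "DOWN"))
})

test_that("the vp-product applies a strict limit and offsets large p", {
  expect_false(vpProduct(0.05, 0.05)$is_candidate)     # 0.0025 not < 0.0025
  expect_equal(vpProduct(0.05, 0.05)$product, 0.0025)
  v <- vpProduct(0.001, 0.9)
  expect_true(v$is_candidate)                          # offset behaviour
  expect_equal(v$product, 9e-4)
  expect_false(vpProduct(0.2, 0.2)$is_candidate)
  # symmetric, monotone, bounded by the smaller factor
  set.seed(151)
  a <- runif(20); b <- runif(20)
  expect_equal(vpProduct(a, b)$product, vpProduct(b, a)$product)
  expect_true(all(vpProduct(a, b)$product <= pmin(a, b) + 1e-15))
  expect_true(all(vpProduct(a / 2, b)$product <= vpProduct(a, b)$product))
})

test_that("a single-threshold base plot equals the direct computation", {
  set.seed(161)
  inst <- simMarkerInstance(n = 80, hrHigh = 0.4)
  bp <- basePlot(inst$values, inst$clinical, inst$outcome, inst$treatedIds,
                 thresholds = 0, featureId = "m1")
  # direct computation: pivot, split, Cox
  oc <- setNames(inst$outcome$outcome_group, inst$outcome$case_id)
  v <- inst$values[inst$treatedIds]
  mom <- meanOfMedians(v[oc[names(v)] == "positive"],
                       v[oc[names(v)] == "negative"])
  s <- stratifyByPivot(v, mom, 0)
  ids <- c(upIds(s), downIds(s))
  idx <- match(ids, inst$clinical$case_id)
  cx <- coxGroupP(inst$clinical$time_years[idx],
                  inst$clinical$vital_status[idx] == "dead",
                  ids %in% upIds(s))
  expect_equal(bp$p_value, cx$p_value)
  expect_equal(bp$coefficient, cx$coefficient)
  expect_identical(bp$label, if (cx$coefficient < 0) "UP" else "DOWN")
})

test_that("adding thresholds never worsens the best base-plot p", {
  set.seed(171)
  for (r in 1:10) {
    inst <- simMarkerInstance(n = 60, hrHigh = 0.6)
    p1 <- basePlot(inst$values, inst$clinical, inst$outcome,
                   inst$treatedIds, thresholds = c(0, 5))$p_value
    p2 <- basePlot(inst$values, inst$clinical, inst$outcome,
                   inst$treatedIds, thresholds = c(0, 5, 10))$p_value
    expect_lte(p2, p1)
  }
})

test_that("base plots recover a planted treatment-specific marker", {
  set.seed(181)
  hits <- vapply(1:100, function(r) {
    inst <- simMarkerInstance(n = 150, hrTreatedHigh = 0.25)
    bp <- basePlot(inst$values, inst$clinical, inst$outcome,
                   inst$treatedIds, thresholds = 0)
    !is.null(bp) && bp$label == "UP" && bp$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("null features yield calibrated base-plot p-values", {
  set.seed(191)
  inst <- simMarkerInstance(n = 120)          # survival independent of value
  ps <- vapply(1:500, function(r) {
    v <- setNames(rnorm(length(inst$values), 5),
                  names(inst$values))
    basePlot(v, inst$clinical, inst$outcome, inst$treatedIds,
             thresholds = 0)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("validation plots separate treatment-specific from universal", {
  set.seed(201)
  # universal marker: both validation arms behave alike, p stays large
  pUniv <- vapply(1:100, function(r) {
    inst <- simMarkerInstance(n = 100, nUntreated = 100, hrHigh = 0.4)
    vp <- validationPlots(inst$values, inst$clinical, inst$outcome,
                          inst$treatedIds, inst$untreatedIds, 0)
    if (is.null(vp$up_val)) NA_real_ else vp$up_val$p_value
  }, numeric(1))
  expect_gt(median(pUniv, na.rm = TRUE), 0.2)

  # treatment-specific UP marker: treated outlive untreated in the UP stratum
  inst <- simMarkerInstance(n = 200, nUntreated = 200,
                            hrTreatedHigh = 0.25)
  vp <- validationPlots(inst$values, inst$clinical, inst$outcome,
                        inst$treatedIds, inst$untreatedIds, 0)
  expect_identical(vp$up_val$label, "UP")
  expect_lt(vp$up_val$p_value, 0.05)

  # identically drawn treated and untreated: rarely significant
  set.seed(211)
  pNull <- vapply(1:50, function(r) {
    inst <- simMarkerInstance(n = 80, nUntreated = 80)
    vp <- validationPlots(inst$values, inst$clinical, inst$outcome,
                          inst$treatedIds, inst$untreatedIds, 0)
    if (is.null(vp$up_val)) NA_real_ else vp$up_val$p_value
  }, numeric(1))
  expect_gte(mean(pNull > 0.05, na.rm = TRUE), 0.90)

  expect_warning(expect_null(
    validationPlots(inst$values, inst$clinical, inst$outcome,
                    inst$treatedIds, character(0), 0)), "untreated")
})

test_that("marker evaluation combines filter and vp-product", {
  set.seed(221)
  inst <- simMarkerInstance(n = 200, nUntreated = 200,
                            hrTreatedHigh = 0.2)
  ev <- evaluateMarker(inst$values, inst$clinical, inst$outcome,
                       inst$treatedIds, inst$untreatedIds, 0,
                       featureId = "m1")
  expect_identical(ev$base_label, "UP")
  expect_true(ev$passed_filter)
  expect_equal(ev$vp_product, ev$p_base * ev$p_up_val)
  expect_true(ev$is_candidate)
})

test_that("per-threshold best DMR positions are recorded", {
  set.seed(231)
  inst <- simMarkerInstance(n = 120, hrHigh = 0.3)
  ids <- names(inst$values)
  coords <- data.frame(chrom = "chrT", pos = c(100L, 200L, 300L))
  # position 200 carries the survival signal, the flanks are noise
  betas <- rbind(matrix(rbeta(length(ids), 10, 10), 1),
                 matrix(pmin(pmax((inst$values - 3) / 5, 0.01), 0.99), 1),
                 matrix(rbeta(length(ids), 10, 10), 1))
  colnames(betas) <- ids
  bp <- bestDmrPositions(c(100L, 200L, 300L), betas, coords, "chrT",
                         inst$clinical, inst$outcome, inst$treatedIds,
                         thresholds = c(0, 5))
  expect_setequal(bp$threshold_pct, c(0, 5))
  expect_true(all(bp$position %in% coords$pos))
  expect_identical(bp$position[bp$threshold_pct == 0], 200L)

  # single position: chosen for every threshold
  one <- bestDmrPositions(200L, betas, coords, "chrT", inst$clinical,
                          inst$outcome, inst$treatedIds, c(0, 5, 10))
  expect_true(all(one$position == 200L))
})

test_that("ranking sorts by vp-product and aggregates geometric means", {
  set.seed(241)
  evals <- data.frame(
    set_id = rep(c("s1", "s2"), c(4, 3)),
    feature_id = paste0("f", 1:7),
    vp_product = c(1e-4, 1e-6, 0.3, NA, 2e-5, 1e-3, 4e-8),
    is_candidate = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  evals$is_candidate[3] <- FALSE
  ranked <- rankCandidates(evals)
  expect_identical(ranked$vp_product, sort(evals$vp_product[
    evals$is_candidate & !is.na(evals$vp_product)]))
  expect_identical(ranked$rank, seq_len(nrow(ranked)))

  agg <- aggregateCandidates(ranked)
  expect_identical(agg$set_id[1], "s2")          # more candidates first
  expect_equal(agg$geometric_mean_vp[agg$set_id == "s1"],
               sqrt(1e-4 * 1e-6))
  # a single candidate's geometric mean is its own vp-product
  one <- aggregateCandidates(ranked[ranked$set_id == "s2", ][1, ])
  expect_equal(one$geometric_mean_vp,
               ranked$vp_product[ranked$set_id == "s2"][1])
  expect_equal(aggregateCandidates(rankCandidates(evals[0, ]))$set_id,
               character(0))
})
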