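test_that("drug names are normalized and mapped through the synonym map", {
  expect_identical(harmonizeDrugNames("cisplatin"), "cisplatin")
  expect_identical(
    harmonizeDrugNames("  Cisplatinum ", c(cisplatinum = "cisplatin")),
    "cisplatin")
  expect_identical(harmonizeDrugNames("CARBOPLATIN"), "carboplatin")
  expect_warning(out <- harmonizeDrugNames(c("", "cisplatin")), "empty")
  expect_identical(out, c(NA, "cisplatin"))
  expect_error(harmonizeDrugNames("x", c(Cisplatinum = "cisplatin")),
               "lowercase")
})

test_that("outcome cutoff reclassifies only long-surviving dead patients", {
  md <- data.frame(case_id = c("a", "b", "c"),
                   vital_status = c("dead", "dead", "alive"),
                   time_years = c(9, 3, 0.2), stringsAsFactors = FALSE)
  oc8 <- applyCutoff(md, 8)
  expect_identical(oc8$outcome_group, c("positive", "negative", "positive"))
  # cutoff 0 reproduces the vital status, including short-followup alive
  oc0 <- applyCutoff(md, 0)
  expect_identical(oc0$outcome_group,
                   ifelse(md$vital_status == "alive", "positive", "negative"))
  expect_error(applyCutoff(md, -1), "non-negative")
})

test_that("cutoff grouping matches direct enumeration on a random cohort", {
  set.seed(11)
  md <- data.frame(case_id = sprintf("d%03d", 1:100),
                   vital_status = "dead",
                   time_years = runif(100, 0, 10), stringsAsFactors = FALSE)
  oc <- applyCutoff(md, 5)
  expect_equal(sum(oc$outcome_group == "positive"), sum(md$time_years > 5))
  # monotone turnover: a larger cutoff never converts more patients
  pos5 <- oc$case_id[oc$outcome_group == "positive"]
  pos8 <- with(applyCutoff(md, 8), case_id[outcome_group == "positive"])
  expect_true(all(pos8 %in% pos5))
})

test_that("case-set combinatorics match the closed form and stated counts", {
  md <- twoProjectMetadata()
  expect_length(buildCaseSets(md, c("A", "B")), 7)
  expect_length(buildCaseSets(md, c("A", "B"), c(5, 8)), 21)

  # single project with both sexes: three sets, no pooled baskets
  one <- md[md$project == "B", ]
  s <- buildCaseSets(one, "B")
  expect_length(s, 3)
  expect_setequal(vapply(s, sexSelector, character(1)),
                  c("female", "male", "both"))

  # closed form on a random configuration
  set.seed(3)
  for (rep in 1:5) {
    nproj <- sample(1:4, 1)
    sexAvail <- lapply(seq_len(nproj), function(i)
      sample(list("female", "male", c("female", "male")), 1)[[1]])
    rows <- do.call(rbind, lapply(seq_len(nproj), function(i)
      data.frame(case_id = paste0("r", rep, i, seq_along(sexAvail[[i]])),
                 project = paste0("P", i), sex = sexAvail[[i]],
                 vital_status = "alive", time_years = 1,
                 stringsAsFactors = FALSE)))
    cutoffs <- c(0, sample(1:9, sample(0:2, 1)))
    perProj <- vapply(sexAvail, function(sx)
      length(sx) + (length(sx) == 2), numeric(1))
    sexesAll <- unique(unlist(sexAvail))
    pooled <- if (nproj > 1) length(sexesAll) + (length(sexesAll) == 2) else 0
    expected <- (sum(perProj) + pooled) * length(unique(cutoffs))
    expect_length(buildCaseSets(rows, paste0("P", seq_len(nproj)), cutoffs),
                  expected)
  }

  # sets for every cutoff, default always present
  s21 <- buildCaseSets(md, c("A", "B"), c(5, 8))
  expect_setequal(unique(vapply(s21, cutoffYears, numeric(1))), c(0, 5, 8))
  expect_warning(buildCaseSets(md, c("A", "B", "EMPTY")), "no patients")
  # single-sex selectors contain only that sex
  for (cs in s21) {
    if (sexSelector(cs) != "both")
      expect_true(all(md$sex[md$case_id %in% memberIds(cs)] ==
                        sexSelector(cs)))
  }
})

test_that("treatment partition uses exact-set combination matching", {
  md <- twoProjectMetadata()
  md$drugs <- list(c("carboplatin", "paclitaxel"), character(0),
                   "cisplatin", "carboplatin",
                   c("carboplatin", "paclitaxel", "cisplatin"),
                   "docetaxel", "paclitaxel", character(0))
  combos <- list("cisplatin", c("carboplatin", "paclitaxel"), "carboplatin")
  cs <- buildCaseSets(md, c("A", "B"))[[7]]   # pooled both, cutoff 0
  part <- partitionByTreatment(cs, md, combos)
  expect_setequal(treatedIds(part), c("c01", "c03", "c04"))
  # {} never matches; a superset does not match exactly
  expect_true(all(c("c02", "c05", "c07") %in% untreatedIds(part)))
  # partition property
  expect_setequal(c(treatedIds(part), untreatedIds(part)), memberIds(part))
  expect_length(intersect(treatedIds(part), untreatedIds(part)), 0)

  sub <- partitionByTreatment(cs, md, combos, match = "subset")
  expect_true("c05" %in% treatedIds(sub))
  expect_error(partitionByTreatment(cs, md, list()), "non-empty")
})

test_that("metadata ingestion converts days, drops incomplete records", {
  raw <- data.frame(
    case_id = c("x1", "x2", "x3", "x4"),
    project = "P",
    sex = c("female", "male", "unknown", "female"),
    vital_status = c("dead", "alive", "alive", "alive"),
    days_to_death = c(730.5, NA, NA, NA),
    days_to_last_followup = c(NA, 365.25, 100, NA),
    drugnames = c("Cisplatinum; CARBOPLATIN", "", "x", NA),
    age = 60, stringsAsFactors = FALSE)
  expect_warning(expect_warning(md <- readPatientMetadata(raw), "sex"),
                 "missing")
  expect_identical(md$case_id, c("x1", "x2"))
  expect_equal(md$time_years, c(2, 1))
  expect_identical(md$drugs[[1]], c("carboplatin", "cisplatin"))
  expect_identical(md$drugs[[2]], character(0))
})

test_that("turnover table reports counts and reclassification percentages", {
  md <- turnoverCohort(338, 110)
  tt <- cutoffTurnover(md, c(5, 8))
  expect_identical(tt$cutoff_years, c(0, 5, 8))
  expect_identical(tt$n_positive, c(338L, 348L, 341L))
  expect_identical(tt$turnover, c(0L, 10L, 3L))
  expect_equal(tt$percent, c(0, 10, 3) / 448 * 100)
})
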