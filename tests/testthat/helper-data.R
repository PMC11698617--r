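# Small in-code fixtures shared across tests.

# Two projects: A has female cases only (like a cervical cohort), B both
# sexes.  Yields 7 case sets at the default cutoff, 21 with cutoffs {0,5,8}.
twoProjectMetadata <- function() {
  md <- data.frame(
    case_id = sprintf("c%02d", 1:8),
    project = c("A", "A", "A", "B", "B", "B", "B", "B"),
    sex = c("female", "female", "female",
            "female", "female", "male", "male", "male"),
    vital_status = c("alive", "dead", "alive", "dead",
                     "alive", "alive", "dead", "dead"),
    time_years = c(2, 1, 4, 3, 6, 2, 9, 0.5),
    age = 60,
    stringsAsFactors = FALSE)
  md$drugs <- replicate(nrow(md), character(0), simplify = FALSE)
  md
}

# Cohort reproducing the printed dead-to-alive turnover marginals: nAlive
# alive cases plus nDead dead cases of which `over8` survived more than 8
# years and `between58` between 5 and 8 years.
turnoverCohort <- function(nAlive, nDead, over8 = 3, between58 = 7) {
  times <- c(rep(9.5, over8), rep(6.5, between58),
             rep(2, nDead - over8 - between58))
  data.frame(
    case_id = sprintf("p%04d", seq_len(nAlive + nDead)),
    vital_status = rep(c("alive", "dead"), c(nAlive, nDead)),
    time_years = c(rep(3, nAlive), times),
    stringsAsFactors = FALSE)
}

# Directly simulated survival/stratification instance for validation tests:
# `n` treated patients (plus optionally untreated), a bimodal marker value
# separating a latent high stratum, and exponential survival with the given
# hazard ratios.
simMarkerInstance <- function(n = 150, nUntreated = 0, hrHigh = 1,
                              hrTreatedHigh = 1, baseline = 0.15,
                              censor = 0.1, sepSd = 0.4) {
  total <- n + nUntreated
  treated <- rep(c(TRUE, FALSE), c(n, nUntreated))
  high <- runif(total) < 0.5
  values <- rnorm(total, mean = ifelse(high, 6, 4), sd = sepSd)
  hazard <- baseline * hrHigh^high * hrTreatedHigh^(high & treated)
  tDeath <- rexp(total, hazard)
  tCens <- rexp(total, censor)
  ids <- sprintf("s%04d", seq_len(total))
  clinical <- data.frame(
    case_id = ids,
    vital_status = ifelse(tDeath <= tCens, "dead", "alive"),
    time_years = pmax(pmin(tDeath, tCens), 1e-6),
    stringsAsFactors = FALSE)
  list(values = setNames(values, ids), clinical = clinical,
       treatedIds = ids[treated], untreatedIds = ids[!treated],
       high = setNames(high, ids),
       outcome = applyCutoff(clinical, 0))
}
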