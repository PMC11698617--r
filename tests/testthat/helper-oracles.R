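# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (loops, direct formulas) and share no code with the
# package internals.

# Benjamini-Hochberg by the textbook definition: adjusted p of the i-th
# order statistic is min_{j >= i} min(1, p_(j) * m / j).
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Product-limit estimator tabulated by hand at distinct event times.
kmOracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  rows <- lapply(ut, function(t) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <<- s * (1 - d / n)
    data.frame(time = t, survival = s, at_risk = n, n_events = d)
  })
  if (!length(rows))
    return(data.frame(time = numeric(0), survival = numeric(0),
                      at_risk = numeric(0), n_events = numeric(0)))
  do.call(rbind, rows)
}

# Classic (unweighted) log-rank chi-square statistic.
logrankOracle <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
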