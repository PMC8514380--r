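# Independent brute-force oracles and small data builders used across tests.
# The oracles deliberately avoid the package's own code paths (and the
# survival package) so equivalence tests are two independent routes.

# a named expression vector for one sample over the default panel
make_profile <- function(panel = defaultPanel(), up = 10, dn = 10, ctrl = 100) {
  stats::setNames(
    c(rep_len(up, length(upGenes(panel))),
      rep_len(dn, length(downGenes(panel))),
      rep_len(ctrl, length(controlGenes(panel)))),
    panelGenes(panel))
}

random_profile <- function(panel = defaultPanel()) {
  stats::setNames(stats::runif(length(panelGenes(panel)), 0.1, 1000),
                  panelGenes(panel))
}

# all-pairs Mann-Whitney AUC with half credit for ties
brute_auc <- function(score, status) {
  m <- score[status == "mutant"]
  w <- score[status == "wild"]
  tot <- 0
  for (x in m) for (y in w)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(m) * length(w))
}

# product-limit estimator computed event time by event time from risk sets
brute_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# two-group log-rank chi-squared from per-event-time hypergeometric moments
brute_logrank <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# a tiny hand-built cohort with the endpoint and grouping columns filled in
tiny_cohort <- function(time, event, status,
                        endpoint = "rfs") {
  d <- data.frame(sample_id = sprintf("P%02d", seq_along(time)),
                  tp53_status = status, stringsAsFactors = FALSE)
  d[[paste0(endpoint, "_time")]] <- time
  d[[paste0(endpoint, "_event")]] <- event
  d
}

# random survival data for oracle equivalence sweeps
random_surv <- function(n, p_group = 0.5, p_censor = 0.3, tie_prob = 0.3) {
  time <- stats::rexp(n, 0.2)
  # force some exact ties to exercise tie handling
  tie <- stats::runif(n) < tie_prob
  time[tie] <- sample(1:3, sum(tie), replace = TRUE)
  data.frame(
    time = time,
    event = as.integer(stats::runif(n) > p_censor),
    group = ifelse(stats::runif(n) < p_group, "mutant", "wild"),
    stringsAsFactors = FALSE)
}
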