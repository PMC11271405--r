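# Independent reference implementations ("oracles") used to cross-check the
# package kernels. They deliberately use different formulations from the
# production code paths.

# flat truth table over integer percent changes; built with cut() rather
# than the if-chain used in classify_target_change
oracle_percent_table <- function(pr_cut_pct, pd_cut_pct) {
  change <- -100:100
  category <- as.character(cut(change,
    breaks = c(-Inf, -100, pr_cut_pct, pd_cut_pct - 1, Inf),
    labels = c("CR", "PR", "SD", "PD"), right = TRUE))
  # cut() puts -100 in the first bin already; boundary at pd_cut inclusive
  data.frame(change = change, category = category)
}

# textbook two-group log-rank: explicit loop accumulating O, E and the
# hypergeometric variance for group A
oracle_logrank2 <- function(dur, ev, grp) {
  stopifnot(length(unique(grp)) == 2)
  a <- sort(unique(grp))[1]
  O <- E <- V <- 0
  for (t in sort(unique(dur[ev]))) {
    at <- dur >= t
    n <- sum(at); d <- sum(dur == t & ev)
    nA <- sum(at & grp == a); dA <- sum(dur == t & ev & grp == a)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * (nA / n) * (1 - nA / n)
  }
  (O - E)^2 / V
}

# expected counts written out longhand
oracle_chisq <- function(tab) {
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / total
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# Clopper-Pearson by direct root finding on binomial tail sums
oracle_clopper_pearson <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) sum(stats::dbinom(k:n, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) sum(stats::dbinom(0:k, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# product-limit with no censoring collapses to the empirical survival
oracle_km_nocensor <- function(dur, t) mean(dur > t)

# minimal two-group exponential survival sample used by calibration tests
sample_null_groups <- function(n_per_group, rate = 1 / 180) {
  dur <- ceiling(stats::rexp(2 * n_per_group, rate))
  cens <- stats::runif(2 * n_per_group) < 0.15
  list(durations = dur, events = !cens,
       group = rep(c("a", "b"), each = n_per_group))
}
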