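test_that("product-limit estimate matches hand-computed values", {
  toy <- make_fixture("km_toy")
  f <- km_fit(toy$durations, toy$events)
  expect_equal(km_survival_at(f, 1), 4 / 5)
  expect_equal(km_survival_at(f, 3), 4 / 5 * 2 / 3)
  expect_equal(km_survival_at(f, 5), 0)
  expect_equal(km_survival_at(f, 0.5), 1)     # before first time
  expect_equal(km_survival_at(f, 3.9), 4 / 5 * 2 / 3)  # step function
  expect_equal(km_median(f), 5)  # smallest time with S(t) <= 0.5

  expect_equal(km_fit(10, TRUE)$table$surv, 0)    # single subject
  allc <- km_fit(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(allc$table$surv == 1))          # no events
  expect_true(is.na(km_median(allc)))
  expect_error(km_fit(numeric(), logical()), "empty")
  expect_error(km_fit(c(1, -2), c(TRUE, TRUE)), "positive")
})

test_that("product-limit equals empirical survival without censoring", {
  set.seed(31)
  for (rep in 1:20) {
    dur <- sample(1:40, 25, replace = TRUE)
    f <- km_fit(dur, rep(TRUE, 25))
    for (t in c(1, 5, 17, 33))
      expect_equal(km_survival_at(f, t), oracle_km_nocensor(dur, t))
  }
})

test_that("log-rank statistic matches the brute-force O-E oracle", {
  # frozen toy value: A events at 1,2,3; B events at 4,5,6 -> 5.051661
  out <- logrank(1:6, rep(TRUE, 6), rep(c("A", "B"), each = 3))
  expect_equal(out$statistic, 5.051661, tolerance = 1e-6)
  expect_equal(out$df, 1)

  set.seed(11)
  for (rep in 1:25) {
    g <- sample_null_groups(20)
    mine <- logrank(g$durations, g$events, g$group)
    expect_equal(mine$statistic,
                 oracle_logrank2(g$durations, g$events, g$group),
                 tolerance = 1e-9)
  }
})

test_that("log-rank symmetry, k-group df, and input validation", {
  dur <- c(5, 8, 12, 20, 33); ev <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  out <- logrank(rep(dur, 2), rep(ev, 2), rep(c("a", "b"), each = 5))
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)

  set.seed(3)
  g3 <- sample_null_groups(15)
  out3 <- logrank(c(g3$durations, g3$durations[1:10]),
                  c(g3$events, g3$events[1:10]),
                  c(g3$group, rep("c", 10)))
  expect_equal(out3$df, 2)

  expect_error(logrank(c(1, 2), c(TRUE, TRUE), c("a", "a")), "2 non-empty")
  expect_error(logrank(c(1, 2), c(FALSE, FALSE), c("a", "b")),
               "at least one event")
})

test_that("doubling both samples roughly doubles the log-rank statistic", {
  set.seed(17)
  dur <- c(ceiling(rexp(40, 1 / 100)), ceiling(rexp(40, 1 / 180)))
  ev <- rep(TRUE, 80)
  grp <- rep(c("a", "b"), each = 40)
  s1 <- logrank(dur, ev, grp)$statistic
  s2 <- logrank(rep(dur, 2), rep(ev, 2), rep(grp, 2))$statistic
  expect_gt(s2 / s1, 1.6)
  expect_lt(s2 / s1, 2.4)
})

test_that("Cox fit: symmetry, tie-method agreement, flags", {
  # identical event patterns in the two arms: HR = 1
  dur <- rep(c(3, 7, 11, 15, 22, 30), 2)
  ev <- rep(c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE), 2)
  x <- rep(c(0, 1), each = 6)
  f <- cox_fit(dur, ev, x)
  expect_true(f$converged)
  expect_equal(unname(f$hr), 1, tolerance = 1e-6)

  # without ties Breslow and Efron coincide
  set.seed(23)
  dur2 <- sort(runif(30, 1, 100)); ev2 <- runif(30) < 0.7
  x2 <- rbinom(30, 1, 0.5)
  fe <- cox_fit(dur2, ev2, x2, ties = "efron")
  fb <- cox_fit(dur2, ev2, x2, ties = "breslow")
  expect_equal(fe$coef, fb$coef, tolerance = 1e-8)

  # complete separation is flagged, not silent
  sep <- cox_fit(c(1, 2, 3, 10, 20, 30), rep(TRUE, 6),
                 c(1, 1, 1, 0, 0, 0))
  expect_true(sep$separation)
  expect_false(sep$converged)

  expect_error(cox_fit(dur2, ev2, rep(1, 30)), "constant")
})

test_that("Cox fit matches the survival-package oracle with and without ties", {
  skip_if_not_installed("survival")
  set.seed(7)
  n <- 250
  x <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n))
  dur <- ceiling(rexp(n, 0.05 * exp(-0.7 * x[, 1] + 0.3 * x[, 2])))
  ev <- runif(n) < 0.8
  for (tie in c("efron", "breslow")) {
    mine <- cox_fit(dur, ev, x, ties = tie)
    ref <- survival::coxph(survival::Surv(dur, ev) ~ x, ties = tie)
    expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
  mine <- logrank(dur, ev, x[, 1])
  ref <- survival::survdiff(survival::Surv(dur, ev) ~ x[, 1])
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
})

test_that("chi-squared proportion test matches the expected-count oracle", {
  out <- chisq_prop(rbind(c(10, 10), c(10, 10)))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  tab <- rbind(c(53, 44), c(10, 33))
  out <- chisq_prop(tab)
  expect_equal(out$statistic, 11.85594, tolerance = 1e-6)
  expect_equal(out$statistic, oracle_chisq(tab), tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_equal(chisq_prop(cbind(c(5, 6), c(7, 8), c(9, 10)))$df, 2)
  expect_error(chisq_prop(rbind(c(0, 0), c(1, 2))), "zero marginal")

  set.seed(5)
  for (rep in 1:20) {
    t2 <- matrix(sample(1:40, 6), 2, 3)
    expect_equal(chisq_prop(t2)$statistic, oracle_chisq(t2),
                 tolerance = 1e-10)
  }
})

test_that("exact binomial CI matches tail-sum inversion and boundaries", {
  expect_equal(exact_binomial_ci(0, 10)[["lower"]], 0)
  expect_equal(exact_binomial_ci(10, 10)[["upper"]], 1)
  ci <- exact_binomial_ci(13, 31)
  expect_equal(unname(ci), c(0.245476, 0.6092408), tolerance = 1e-6)
  expect_equal(unname(ci), oracle_clopper_pearson(13, 31), tolerance = 1e-9)
  set.seed(2)
  for (rep in 1:15) {
    n <- sample(2:60, 1); k <- sample(0:n, 1)
    expect_equal(unname(exact_binomial_ci(k, n)),
                 oracle_clopper_pearson(k, n), tolerance = 1e-8)
  }
  expect_error(exact_binomial_ci(5, 4), "0 <= k <= n")
})

test_that("exact binomial CI has at least nominal coverage (enumeration)", {
  for (n in c(5, 12, 20, 30)) {
    cis <- t(vapply(0:n, function(k) exact_binomial_ci(k, n), numeric(2)))
    for (p in seq(0.1, 0.9, by = 0.1)) {
      cover <- sum(stats::dbinom(0:n, n, p)[
        cis[, 1] <= p & p <= cis[, 2]])
      expect_gte(cover, 0.95 - 1e-12)
    }
  }
})
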