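# Self-contained statistical kernel: Kaplan-Meier product-limit estimation,
# k-sample log-rank test, Cox proportional-hazards regression (Efron or
# Breslow tie handling), Pearson chi-squared proportion tests and exact
# (Clopper-Pearson) binomial confidence intervals.
#
# The kernel is written from first principles on purpose: the test suite
# cross-checks it against independent oracles (hand-computed product-limit
# values, brute-force O-E tables, and the 'survival' package where
# available), which would be circular if the kernel itself wrapped a
# library.

#' Kaplan-Meier product-limit estimate
#'
#' Subjects censored at an event time are counted at risk at that time
#' (the standard convention).
#'
#' @param durations positive follow-up times.
#' @param events logical (or 0/1) event indicators.
#' @return object of class `km_fit`: data frame of distinct event times with
#'   `n_risk`, `n_event`, `n_censor` and the survival estimate, plus the
#'   sample size.
#' @export
#' @examples
#' f <- km_fit(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
#' km_survival_at(f, 3)  # 0.5333...
km_fit <- function(durations, events) {
  if (length(durations) == 0) abort("empty input to km_fit")
  if (length(durations) != length(events))
    abort("durations and events differ in length")
  if (any(!is.finite(durations)) || any(durations <= 0))
    abort("durations must be positive and finite")
  events <- as.logical(events)
  ord <- order(durations)
  durations <- durations[ord]; events <- events[ord]
  times <- sort(unique(durations))
  n_risk <- n_event <- n_censor <- integer(length(times))
  n <- length(durations)
  for (i in seq_along(times)) {
    n_risk[i] <- sum(durations >= times[i])
    n_event[i] <- sum(durations == times[i] & events)
    n_censor[i] <- sum(durations == times[i] & !events)
  }
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(
    table = data.frame(time = times, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
    n = n), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n =", x$n, "; median =", km_median(x), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Survival probability at a time point
#'
#' Reads the step function (last value carried forward); returns 1 before
#' the first observed time.
#'
#' @param fit a `km_fit`.
#' @param t time point(s).
#' @return survival probabilities.
#' @export
km_survival_at <- function(fit, t) {
  vapply(t, function(tt) {
    idx <- which(fit$table$time <= tt)
    if (length(idx) == 0) 1 else fit$table$surv[max(idx)]
  }, numeric(1))
}

#' Median survival time
#'
#' Smallest observed time with survival <= 0.5; `NA` if never reached.
#'
#' @param fit a `km_fit`.
#' @return the median, or `NA`.
#' @export
km_median <- function(fit) {
  idx <- which(fit$table$surv <= 0.5)
  if (length(idx) == 0) NA_real_ else fit$table$time[min(idx)]
}

#' k-sample log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance; for k
#' groups the quadratic form over the first k-1 groups is referred to a
#' chi-squared distribution with k-1 degrees of freedom. Two groups reduce
#' to the familiar (O-E)^2/V statistic.
#'
#' @param durations positive follow-up times.
#' @param events logical event indicators.
#' @param group group labels (>= 2 distinct, each non-empty).
#' @return list of class `pgt_test` with `statistic`, `df`, `p_value`,
#'   per-group observed and expected event counts.
#' @export
logrank <- function(durations, events, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2)
    abort("logrank needs >= 2 non-empty groups")
  events <- as.logical(events)
  if (!any(events)) abort("logrank needs at least one event")
  k <- nlevels(group)
  times <- sort(unique(durations[events]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in times) {
    at_risk <- durations >= tt
    n <- sum(at_risk)
    d <- sum(at_risk & durations == tt & events)
    ni <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    di <- vapply(levels(group), function(g)
      sum(at_risk & durations == tt & events & group == g), numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      # multivariate hypergeometric covariance of event counts at this time
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(ni / n, k) - tcrossprod(ni / n))
    }
  }
  z <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vsub, z)),
                   error = function(e) drop(t(z) %*% MASS_ginv(Vsub) %*% z))
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "pgt_test")
}

# tiny Moore-Penrose fallback for singular log-rank covariance matrices
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.pgt_test <- function(x, ...) {
  cat(sprintf("<pgt_test> statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood with Efron
#' (default) or Breslow handling of tied event times. Convergence is
#' declared when the change in log partial likelihood falls below `tol`;
#' non-convergence and (suspected) monotone likelihood from complete
#' separation are flagged, never silent.
#'
#' @param durations positive follow-up times.
#' @param events logical event indicators.
#' @param x covariate matrix (or vector for a single covariate); no column
#'   may be constant.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol convergence tolerance on the log partial likelihood.
#' @param max_iter maximum Newton iterations.
#' @return object of class `cox_fit`: `coef`, `hr`, `se`, `loglik`,
#'   `converged`, `separation`, `iter`, `ties`.
#' @export
cox_fit <- function(durations, events, x, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 100L) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  events <- as.logical(events)
  if (nrow(x) != length(durations)) abort("covariate rows != durations")
  if (any(apply(x, 2, function(col) length(unique(col)) == 1)))
    abort("constant covariate column")
  if (!any(events)) abort("no events")

  ord <- order(durations)
  t_o <- durations[ord]; e_o <- events[ord]; x_o <- x[ord, , drop = FALSE]
  p <- ncol(x)
  event_times <- unique(t_o[e_o])

  # index sets, computed once
  risk_idx <- lapply(event_times, function(tt) which(t_o >= tt))
  death_idx <- lapply(event_times, function(tt) which(t_o == tt & e_o))

  neg_ll_grad_hess <- function(beta) {
    eta <- drop(x_o %*% beta)
    w <- exp(eta)
    ll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
    for (j in seq_along(event_times)) {
      R <- risk_idx[[j]]; D <- death_idx[[j]]
      d <- length(D)
      xD <- x_o[D, , drop = FALSE]
      ll <- ll + sum(eta[D])
      grad <- grad + colSums(xD)
      wR <- w[R]
      s0 <- sum(wR)
      s1 <- colSums(wR * x_o[R, , drop = FALSE])
      s2 <- crossprod(x_o[R, , drop = FALSE] * sqrt(wR))
      if (ties == "breslow" || d == 1) {
        ll <- ll - d * log(s0)
        grad <- grad - d * s1 / s0
        hess <- hess - d * (s2 / s0 - tcrossprod(s1 / s0))
      } else {
        wD <- w[D]
        s0d <- sum(wD)
        s1d <- colSums(wD * xD)
        s2d <- crossprod(xD * sqrt(wD))
        for (l in seq_len(d) - 1) {
          a0 <- s0 - l / d * s0d
          a1 <- s1 - l / d * s1d
          a2 <- s2 - l / d * s2d
          ll <- ll - log(a0)
          grad <- grad - a1 / a0
          hess <- hess - (a2 / a0 - tcrossprod(a1 / a0))
        }
      }
    }
    list(ll = ll, grad = grad, hess = hess)
  }

  beta <- numeric(p)
  cur <- neg_ll_grad_hess(beta)
  converged <- FALSE; iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    step <- tryCatch(solve(-cur$hess, cur$grad), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    nxt <- neg_ll_grad_hess(new_beta)
    # step-halving if the likelihood did not improve
    halvings <- 0
    while (nxt$ll < cur$ll && halvings < 20) {
      new_beta <- (beta + new_beta) / 2
      nxt <- neg_ll_grad_hess(new_beta)
      halvings <- halvings + 1
    }
    delta <- abs(nxt$ll - cur$ll)
    beta <- new_beta; cur <- nxt
    if (delta < tol) { converged <- TRUE; break }
  }
  se <- tryCatch(sqrt(diag(solve(-cur$hess))),
                 error = function(e) rep(NA_real_, p))
  separation <- any(abs(beta) > 15) || any(!is.finite(se))
  structure(list(coef = stats::setNames(drop(beta), colnames(x)),
                 hr = stats::setNames(exp(drop(beta)), colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 loglik = cur$ll, converged = converged && !separation,
                 separation = separation, iter = iter, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> ties =", x$ties,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(data.frame(coef = x$coef, HR = x$hr, se = x$se))
  invisible(x)
}

#' Pearson chi-squared test on an r x c contingency table
#'
#' No continuity correction is applied (matching common clinical-trial
#' reporting).
#'
#' @param tab matrix of counts.
#' @return `pgt_test` with statistic, df = (r-1)(c-1), p-value.
#' @export
chisq_prop <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("zero marginal in contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) abort("non-positive expected count")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected),
            class = "pgt_test")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Equal-tailed interval from beta quantiles: lower bound
#' `qbeta(alpha/2, k, n-k+1)` (0 when k = 0), upper bound
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param level confidence level, default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
#' @examples
#' exact_binomial_ci(13, 31)  # c(0.2455, 0.6092)
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    abort("require integers 0 <= k <= n, n >= 1")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}
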