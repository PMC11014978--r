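#' Extract roadblock-associated pauses from an aligned trace
#'
#' Identifies pauses as dwell at fitted levels lying within `window_bp` of
#' the roadblock binding site. Because backtracking excursions keep the EC
#' within a few bp of the pause level, consecutive qualifying sub-steps at
#' nearby levels are merged into a single pause; brief steps (dwell below
#' `substep_min_s`) correspond to ordinary transit through the window and
#' are not counted, which keeps the recovered duration close to the true
#' pause duration instead of inflating it by the window transit time.
#' Pauses shorter than `min_pause_s` are classified as ubiquitous pauses and
#' excluded.
#'
#' @param positions_bp per-sample positions in bp from [apply_scale()]
#'   (`NA` at gaps), assumed piecewise constant
#' @param geometry a [template_geometry()]; supplies the roadblock
#'   (operator) position
#' @param window_bp half-width of the roadblock window, bp (default 60,
#'   the +/- 20 nm rule)
#' @param min_pause_s minimum duration of a roadblock-classified pause, s
#'   (default 20); shorter dwells are ubiquitous pauses
#' @param substep_min_s minimum dwell for a sub-step to count as part of a
#'   pause rather than transit (default 5 s)
#' @param merge_bp maximum level separation, bp, for sub-steps to be merged
#'   into one pause and for edge extension (default 9, just below the
#'   per-sample advance at the default 10 bp/s elongation velocity so that
#'   transit steps never merge; fixed by the round-trip calibration
#'   experiment, see the vignette)
#' @param dt_sample sampling interval, s (default 1)
#' @param end_state outcome to assign to a pause that runs to the end of the
#'   record: `"stalled_censored"` (default) or `"terminated_at_roadblock"`
#' @param trace_id identifier copied into the records
#' @param condition optional [condition()] copied into the records
#' @return a data frame of class `pause_records` with columns `trace_id`,
#'   `start_s`, `duration_s`, `position_bp`, `outcome`; zero rows if no
#'   roadblock-associated pause was found
#' @export
extract_pauses <- function(positions_bp, geometry, window_bp = 60,
                           min_pause_s = 20, substep_min_s = 5,
                           merge_bp = 9, dt_sample = 1,
                           end_state = c("stalled_censored",
                                         "terminated_at_roadblock"),
                           trace_id = "trace", condition = NULL) {
  end_state <- match.arg(end_state)
  op <- geometry$operator_pos
  fin <- which(is.finite(positions_bp))
  empty <- data.frame(trace_id = character(0), start_s = numeric(0),
                      duration_s = numeric(0), position_bp = numeric(0),
                      outcome = character(0))
  class(empty) <- c("pause_records", "data.frame")
  if (length(fin) == 0) return(empty)
  last_finite <- max(fin)

  # run-length encode the (piecewise constant) position series
  seg <- split_on_gaps(positions_bp)
  runs <- NULL
  for (i in seq_len(nrow(seg))) {
    idx <- seg$start[i]:seg$end[i]
    r <- rle(positions_bp[idx])
    ends <- idx[cumsum(r$lengths)]
    starts <- ends - r$lengths + 1L
    runs <- rbind(runs, data.frame(start = starts, end = ends,
                                   level = r$values,
                                   dwell = r$lengths * dt_sample))
  }
  runs <- runs[order(runs$start), , drop = FALSE]

  in_window <- abs(runs$level - op) <= window_bp
  qualifying <- in_window & runs$dwell >= substep_min_s
  if (!any(qualifying)) return(empty)

  # cluster qualifying sub-steps: successive qualifying runs are merged when
  # their levels are within merge_bp and only brief in-window transit
  # separates them
  qi <- which(qualifying)
  cluster <- integer(length(qi))
  cl <- 1L
  cluster[1] <- cl
  for (j in seq_along(qi)[-1]) {
    prev <- qi[j - 1L]; cur <- qi[j]
    between <- if (cur > prev + 1L) runs[(prev + 1L):(cur - 1L), ] else NULL
    sep_ok <- is.null(between) ||
      all(abs(between$level - op) <= window_bp & between$dwell < substep_min_s)
    lev_ok <- abs(runs$level[cur] - runs$level[prev]) <= merge_bp
    if (!(sep_ok && lev_ok)) cl <- cl + 1L
    cluster[j] <- cl
  }

  recs <- lapply(split(qi, cluster), function(ix) {
    # the pause spans from the first to the last qualifying sub-step; brief
    # in-window runs inside the span (plateau wiggle, backtrack excursions)
    # count toward the duration. The span is then extended outward over
    # adjacent short runs whose level stays near the pause level (step-fit
    # fragmentation of the plateau edges); the approach/departure ramps,
    # whose levels move away quickly, are excluded.
    wt <- runs$dwell[ix]
    pos <- sum(runs$level[ix] * wt) / sum(wt)
    first <- min(ix); last <- max(ix)
    while (first > 1L &&
           abs(runs$level[first - 1L] - pos) <= merge_bp &&
           abs(runs$level[first - 1L] - op) <= window_bp)
      first <- first - 1L
    while (last < nrow(runs) &&
           abs(runs$level[last + 1L] - pos) <= merge_bp &&
           abs(runs$level[last + 1L] - op) <= window_bp)
      last <- last + 1L
    span <- first:last
    data.frame(trace_id = trace_id,
               start_s = (min(runs$start[span]) - 1L) * dt_sample,
               duration_s = sum(runs$dwell[span]),
               position_bp = pos,
               outcome = if (max(runs$end[span]) >= last_finite) end_state
                         else "transited")
  })
  out <- do.call(rbind, recs)
  out <- out[out$duration_s >= min_pause_s, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(condition)) attr(out, "condition") <- condition
  class(out) <- c("pause_records", "data.frame")
  out
}

#' Complementary cumulative distribution of pause times
#'
#' Fraction of pauses longer than a given time. With censored records the
#' default is the Kaplan-Meier estimator (censored pauses remain in the
#' at-risk set up to their censoring time); `method = "truncate"` instead
#' drops censored records and returns the simple empirical CCDF.
#'
#' @param sample a [pause_sample()]
#' @param method `"km"` (default) or `"truncate"`
#' @return a data frame with columns `t` and `ccdf`, right-continuous,
#'   starting from 1 at `t = 0`
#' @export
ccdf <- function(sample, method = c("km", "truncate")) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "pause_sample"))
  if (length(sample$durations) == 0) stop("empty sample")
  if (method == "truncate") {
    d <- sort(sample$durations[!sample$censored])
    if (length(d) == 0) stop("no uncensored records")
    n <- length(d)
    t <- unique(d)
    surv <- vapply(t, function(u) mean(d > u), numeric(1))
    return(data.frame(t = c(0, t), ccdf = c(1, surv)))
  }
  fit <- survival::survfit(
    survival::Surv(sample$durations, !sample$censored) ~ 1)
  data.frame(t = c(0, fit$time), ccdf = c(1, fit$surv))
}

# censored exponential log-likelihood
.exp_loglik <- function(d, cens, tau) {
  sum(ifelse(cens, -d / tau, -log(tau) - d / tau))
}

#' Censored single-exponential fit of pause times
#'
#' Maximum-likelihood fit of an exponential lifetime to right-censored
#' durations. The MLE has the closed form
#' `tau = (sum of all durations, censored included) / (number uncensored)`.
#' The confidence interval is a seeded parametric bootstrap: resamples are
#' drawn from `Exp(tau_hat)` and re-censored using the sample's censoring
#' scheme (each censored record's own censoring time; the observation
#' window, when known, for the rest).
#'
#' @param sample a [pause_sample()]
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed seed for the bootstrap (default 1)
#' @param conf confidence level (default 0.90)
#' @param drop_cens if `TRUE`, discard censored records before fitting
#'   (the "excluding indefinite stalls" analysis mode)
#' @param method `"mle"` (default, closed-form censored MLE) or
#'   `"ccdf_ls"` (least squares of `exp(-t/tau)` against the Kaplan-Meier
#'   CCDF, the curve-fitting reading of "fitted by exponential curves");
#'   the two agree closely on exponential data
#' @return an object of class `exp_fit` with fields `model = "single"`,
#'   `tau`, `ci90`, `loglik`, `n_used`
#' @export
fit_exp_single <- function(sample, n_boot = 1000, seed = 1, conf = 0.90,
                           drop_cens = FALSE,
                           method = c("mle", "ccdf_ls")) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "pause_sample"))
  if (drop_cens) sample <- drop_censored(sample)
  d <- sample$durations
  cens <- sample$censored
  n_unc <- sum(!cens)
  if (n_unc == 0) stop("no uncensored records: tau is unidentifiable")
  if (n_unc < 5)
    warning("fewer than 5 uncensored records; fit is unreliable")
  tau <- sum(d) / n_unc
  if (method == "ccdf_ls") {
    cc <- ccdf(sample)
    obj <- function(t_) sum((cc$ccdf - exp(-cc$t / t_))^2)
    tau <- stats::optimize(obj, c(tau / 10, tau * 10))$minimum
  }

  # censoring times for the parametric bootstrap
  ct <- ifelse(cens, d,
               if (is.finite(sample$censor_time)) sample$censor_time else Inf)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  n <- length(d)
  sim <- matrix(stats::rexp(n_boot * n, rate = 1 / tau), nrow = n_boot)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ctm <- matrix(ct, nrow = n_boot, ncol = n, byrow = TRUE)
  cns <- sim >= ctm
  sim <- pmin(sim, ctm)
  nu <- rowSums(!cns)
  tot <- rowSums(sim)
  taus <- (tot / nu)[nu > 0]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(taus, c(alpha, 1 - alpha)))

  structure(list(model = "single", tau = tau, weight = NULL,
                 ci90 = ci, conf = conf,
                 loglik = .exp_loglik(d, cens, tau),
                 n_used = n, n_uncensored = n_unc),
            class = "exp_fit")
}

#' Censored two-exponential mixture fit by EM
#'
#' Fits a two-component exponential mixture to right-censored durations by
#' expectation-maximisation with multiple seeded starts, for distributions
#' showing two stochastic processes with distinct rate constants (e.g. the
#' passive-regime opposing-force/no-GreA condition). Components are
#' returned sorted by increasing `tau`. Degenerate convergence (mixture
#' weight collapsing to 0 or 1, or indistinguishable components) falls back
#' to the single-exponential fit, flagged via `fallback = TRUE`.
#'
#' @param sample a [pause_sample()]
#' @param n_starts number of seeded EM starts (default 5)
#' @param seed master seed for the starts (default 1)
#' @param max_iter,tol EM stopping rule
#' @param drop_cens discard censored records before fitting
#' @return an object of class `exp_fit` with `model = "double"`, `tau`
#'   (length 2, ascending), `weight` (mixture fraction of the fast
#'   component), `loglik`, `n_used`; or the single-exponential fallback
#' @export
fit_exp_double <- function(sample, n_starts = 5, seed = 1, max_iter = 500,
                           tol = 1e-8, drop_cens = FALSE) {
  stopifnot(inherits(sample, "pause_sample"))
  if (drop_cens) sample <- drop_censored(sample)
  d <- sample$durations
  cens <- sample$censored
  n_unc <- sum(!cens)
  if (n_unc < 20)
    warning("fewer than 20 uncensored records; mixture fit is unreliable")
  if (n_unc == 0) stop("no uncensored records")

  em_once <- function(tau1, tau2, w) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E-step: responsibilities of component 1 (fast)
      l1 <- ifelse(cens, -d / tau1, -log(tau1) - d / tau1)
      l2 <- ifelse(cens, -d / tau2, -log(tau2) - d / tau2)
      m <- pmax(l1 + log(w), l2 + log(1 - w))
      p1 <- exp(l1 + log(w) - m)
      p2 <- exp(l2 + log(1 - w) - m)
      ll <- sum(m + log(p1 + p2))
      r1 <- p1 / (p1 + p2)
      # M-step: censored exponential updates with expected residual life
      t1 <- ifelse(cens, d + tau1, d)
      t2 <- ifelse(cens, d + tau2, d)
      s1 <- sum(r1 * (!cens)); s2 <- sum((1 - r1) * (!cens))
      if (s1 <= .Machine$double.eps || s2 <= .Machine$double.eps) break
      tau1 <- sum(r1 * t1) / s1
      tau2 <- sum((1 - r1) * t2) / s2
      w <- mean(r1)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    # log-likelihood at the final parameter values
    l1 <- ifelse(cens, -d / tau1, -log(tau1) - d / tau1)
    l2 <- ifelse(cens, -d / tau2, -log(tau2) - d / tau2)
    m <- pmax(l1 + log(w), l2 + log(1 - w))
    ll <- sum(m + log(exp(l1 + log(w) - m) + exp(l2 + log(1 - w) - m)))
    list(tau1 = tau1, tau2 = tau2, w = w, loglik = ll)
  }

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  tau0 <- sum(d) / max(n_unc, 1)
  best <- NULL
  for (s in seq_len(n_starts)) {
    f1 <- stats::runif(1, 0.05, 0.6)
    f2 <- stats::runif(1, 1.5, 8)
    fit <- em_once(tau0 * f1, tau0 * f2, stats::runif(1, 0.2, 0.8))
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik))
      best <- fit
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  degenerate <- best$w < 0.02 || best$w > 0.98 ||
    abs(best$tau1 - best$tau2) < 0.05 * max(best$tau1, best$tau2)
  if (degenerate) {
    out <- fit_exp_single(sample, seed = seed)
    out$fallback <- TRUE
    return(out)
  }
  ord <- order(c(best$tau1, best$tau2))
  taus <- c(best$tau1, best$tau2)[ord]
  w_fast <- c(best$w, 1 - best$w)[ord][1]
  structure(list(model = "double", tau = taus, weight = w_fast,
                 ci90 = NULL, conf = NA,
                 loglik = best$loglik, n_used = length(d),
                 n_uncensored = n_unc, fallback = FALSE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$model == "single") {
    cat(sprintf("Single-exponential fit: tau = %.1f s", x$tau))
    if (!is.null(x$ci90))
      cat(sprintf(" [%.1f, %.1f] %d%% CI", x$ci90[1], x$ci90[2],
                  round(100 * x$conf)))
    cat(sprintf(" (n = %d, %d uncensored)\n", x$n_used, x$n_uncensored))
  } else {
    cat(sprintf("Double-exponential fit: tau = (%.1f, %.1f) s, fast weight %.2f (n = %d)\n",
                x$tau[1], x$tau[2], x$weight, x$n_used))
  }
  invisible(x)
}

#' Choose between single and double exponential fits by AIC
#'
#' The double model (3 parameters) is preferred only if its AIC is strictly
#' below the single model's (1 parameter); ties go to the simpler model.
#'
#' @param single a `"single"` [fit_exp_single()] result
#' @param double a [fit_exp_double()] result (may itself be a fallback)
#' @return a list with `choice` (`"single"` or `"double"`), `delta_aic`
#'   (AIC(double) - AIC(single)), and both AIC values
#' @export
select_model <- function(single, double) {
  stopifnot(inherits(single, "exp_fit"), inherits(double, "exp_fit"))
  aic_s <- 2 * 1 - 2 * single$loglik
  if (double$model == "single") {
    # degenerate mixture fallback: only the single model is on offer
    return(list(choice = "single", delta_aic = 0,
                aic_single = aic_s, aic_double = aic_s))
  }
  aic_d <- 2 * 3 - 2 * double$loglik
  list(choice = if (aic_d < aic_s) "double" else "single",
       delta_aic = aic_d - aic_s, aic_single = aic_s, aic_double = aic_d)
}

#' Fraction of ECs passing through the roadblock
#'
#' Transited records count as passage; indefinitely stalled (censored) and
#' terminated-at-roadblock records count as non-passage. The interval is
#' the Wilson score interval.
#'
#' @param records a `pause_records` data frame (from [extract_pauses()]) or
#'   a character vector of outcomes
#' @param conf confidence level (default 0.95)
#' @return a list with `fraction`, `ci`, `n_transited`, `n_total`
#' @export
passage_fraction <- function(records, conf = 0.95) {
  outcomes <- if (is.data.frame(records)) records$outcome else records
  n <- length(outcomes)
  if (n == 0) stop("no records")
  k <- sum(outcomes == "transited")
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(fraction = p, ci = c(max(0, centre - half), min(1, centre + half)),
       n_transited = k, n_total = n)
}
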